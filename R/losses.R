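# Similarity, overlap and smoothness losses, plus the composite
# hyper-losses. Every loss used during training has a hand-derived gradient
# with respect to its image (or velocity-field) argument; finite-difference
# checks in the test suite guard the derivations.

#' Noise-scaled mean squared error
#'
#' `sigma^-2` times the mean squared intensity difference, where `sigma` is
#' an estimate of the image noise standard deviation.
#'
#' @param f Fixed image.
#' @param m_warped Warped moving image, same grid.
#' @param sigma Positive noise estimate (default 0.05).
#' @return Non-negative scalar loss.
#' @export
mse_loss <- function(f, m_warped, sigma = 0.05) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    hr_stop("value", "sigma must be a positive scalar")
  check_same_grid(as_grid_array(f), as_grid_array(m_warped), "images")
  mean((as.numeric(m_warped) - as.numeric(f))^2) / sigma^2
}

mse_loss_grad <- function(f, m_warped, sigma = 0.05) {
  d <- as.numeric(m_warped) - as.numeric(f)
  array(2 * d / (length(d) * sigma^2), dim = dim(as_grid_array(m_warped)))
}

#' Local (windowed) normalized cross-correlation
#'
#' Mean over all fully contained `w`-by-`w` neighbourhoods of the squared
#' locally normalized cross-correlation within each window. Returns a
#' similarity in `[0, 1]`; the training loss is its negative. An
#' epsilon-stabilized denominator keeps zero-variance windows finite. With
#' `w` equal to the full extent of a square image this reduces to the global
#' (squared) normalized cross-correlation.
#'
#' @param f,g Images on a shared 2D grid.
#' @param w Odd window edge length, `1 <= w <= min(dim)`.
#' @param eps Denominator stabilizer.
#' @return Scalar similarity.
#' @export
local_ncc <- function(f, g, w = 9, eps = 1e-5) {
  ncc_context(f, g, w, eps)$value
}

ncc_context <- function(f, g, w, eps = 1e-5) {
  fa <- as_grid_array(f); ga <- as_grid_array(g)
  check_same_grid(fa, ga, "images")
  dm <- dim(fa)
  if (length(dm) != 2L)
    hr_stop("shape", "local_ncc is implemented for 2D grids")
  if (length(w) != 1L || w < 1 || w %% 2 != 1)
    hr_stop("value", "window size w must be a positive odd integer")
  if (w > min(dm))
    hr_stop("value", "window size w exceeds the image extent")
  H <- dm[1]; W <- dm[2]
  r <- (w - 1) / 2
  I <- as.numeric(fa); J <- as.numeric(ga)
  n <- w^2
  sI <- boxsum2(I, H, W, as.integer(w))
  sJ <- boxsum2(J, H, W, as.integer(w))
  sII <- boxsum2(I * I, H, W, as.integer(w))
  sJJ <- boxsum2(J * J, H, W, as.integer(w))
  sIJ <- boxsum2(I * J, H, W, as.integer(w))
  # valid centers: windows fully inside the grid
  vi <- rep(seq_len(H) > r & seq_len(H) <= H - r, times = W)
  vj <- rep(seq_len(W) > r & seq_len(W) <= W - r, each = H)
  valid <- vi & vj
  cross <- sIJ - sI * sJ / n
  varI <- pmax(sII - sI^2 / n, 0)
  varJ <- pmax(sJJ - sJ^2 / n, 0)
  den <- varI * varJ + eps
  cc <- cross^2 / den
  list(value = mean(cc[valid]), H = H, W = W, w = as.integer(w), eps = eps,
       I = I, J = J, n = n, sI = sI, sJ = sJ, cross = cross,
       varI = varI, varJ = varJ, den = den, valid = valid)
}

# gradient of local_ncc w.r.t. its second argument g
local_ncc_grad <- function(f, g, w = 9, eps = 1e-5) {
  cx <- ncc_context(f, g, w, eps)
  Nv <- sum(cx$valid)
  dcc_dcross <- 2 * cx$cross / cx$den
  dcc_dvarJ <- -cx$cross^2 * cx$varI / cx$den^2
  # window sums depend on J via sumJ (coef a), sumJJ (coef b), sumIJ (coef c);
  # only valid window centers contribute to the mean
  a <- ifelse(cx$valid, dcc_dcross * (-cx$sI / cx$n) +
                dcc_dvarJ * (-2 * cx$sJ / cx$n), 0)
  b <- ifelse(cx$valid, dcc_dvarJ, 0)
  c_ <- ifelse(cx$valid, dcc_dcross, 0)
  gJ <- boxsum2(a, cx$H, cx$W, cx$w) +
    2 * cx$J * boxsum2(b, cx$H, cx$W, cx$w) +
    cx$I * boxsum2(c_, cx$H, cx$W, cx$w)
  array(gJ / Nv, dim = c(cx$H, cx$W))
}

#' Mutual information with a soft (triangular-kernel) joint histogram
#'
#' Intensities of both images are min-max rescaled to `[0, 1]` and assigned
#' to `bins` evenly spaced histogram centers with triangular (linear
#' partition-of-unity) weights, making the joint histogram differentiable.
#' Returns the mutual information of the soft joint distribution in nats.
#'
#' @param f,g Images on a shared grid.
#' @param bins Number of histogram bins (>= 2).
#' @param rescale If `FALSE`, intensities are assumed already in `[0, 1]`.
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(f, g, bins = 32, rescale = TRUE) {
  mi_context(f, g, bins, rescale)$value
}

mi_rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

mi_weights <- function(x, bins) {
  # triangular weights over centers 0, 1/(bins-1), ..., 1; width one spacing
  h <- 1 / (bins - 1)
  ctr <- (seq_len(bins) - 1) * h
  Wm <- outer(x, ctr, function(a, b) pmax(0, 1 - abs(a - b) / h))
  Wm
}

mi_context <- function(f, g, bins = 32, rescale = TRUE) {
  if (length(bins) != 1L || bins < 2)
    hr_stop("value", "bins must be an integer >= 2")
  fa <- as.numeric(as_grid_array(f)); ga <- as.numeric(as_grid_array(g))
  check_same_grid(as_grid_array(f), as_grid_array(g), "images")
  if (rescale) { fa <- mi_rescale01(fa); ga <- mi_rescale01(ga) }
  N <- length(fa)
  Wf <- mi_weights(fa, bins)
  Wg <- mi_weights(ga, bins)
  P <- crossprod(Wf, Wg) / N        # bins x bins joint
  pf <- rowSums(P); pg <- colSums(P)
  ratio <- P / outer(pf, pg)
  lr <- ifelse(P > 0, log(ratio), 0)
  list(value = sum(P * lr), P = P, pf = pf, pg = pg, lr = lr,
       Wf = Wf, fa = fa, ga = ga, bins = bins, N = N)
}

# gradient of MI w.r.t. the (already rescaled) intensities of g
mutual_information_grad <- function(f, g, bins = 32, rescale = TRUE) {
  cx <- mi_context(f, g, bins, rescale)
  h <- 1 / (cx$bins - 1)
  ctr <- (seq_len(cx$bins) - 1) * h
  # dW_l(x)/dx: -sign(x - c_l)/h on the triangle support
  dWg <- outer(cx$ga, ctr, function(a, b)
    ifelse(abs(a - b) < h, -sign(a - b) / h, 0))
  # dMI/dP_kl = lr_kl (the constant -1 integrates to zero over dP)
  M <- cx$Wf %*% cx$lr               # N x bins
  g1 <- rowSums(M * dWg) / cx$N
  array(g1, dim = dim(as_grid_array(g)))
}

# hard-binned reference MI (non-differentiable oracle, kept for tests/tools)
mutual_information_hard <- function(f, g, bins = 32, rescale = TRUE) {
  fa <- as.numeric(as_grid_array(f)); ga <- as.numeric(as_grid_array(g))
  if (rescale) { fa <- mi_rescale01(fa); ga <- mi_rescale01(ga) }
  bf <- pmin(pmax(floor(fa * bins) + 1, 1), bins)
  bg <- pmin(pmax(floor(ga * bins) + 1, 1), bins)
  P <- table(factor(bf, levels = 1:bins), factor(bg, levels = 1:bins))
  P <- P / sum(P)
  pf <- rowSums(P); pg <- colSums(P)
  idx <- P > 0
  sum(P[idx] * log(P[idx] / outer(pf, pg)[idx]))
}

#' Gradient-magnitude smoothness regularizer
#'
#' One half times the mean (over voxels and vector components) of the
#' squared forward-difference spatial gradients of each velocity component.
#' Averaging rather than summing makes the balance point of the
#' regularization weight independent of grid resolution.
#'
#' @param v Velocity field (array, component axis last).
#' @return Non-negative scalar.
#' @export
grad_smoothness <- function(v) {
  v <- as_field_array(v, "velocity field")
  dm <- dim(v)
  nd <- length(dm) - 1L
  N <- prod(dm[seq_len(nd)])
  total <- 0
  for (a in seq_len(nd)) {
    for (ax in seq_len(nd)) {
      d <- diff_along(v, a, ax, dm, nd)
      total <- total + sum(d^2)
    }
  }
  0.5 * total / (N * nd)
}

diff_along <- function(v, comp, axis, dm, nd) {
  idx <- c(lapply(dm[seq_len(nd)], seq_len), list(comp))
  x <- array(do.call(`[`, c(list(v), idx)), dim = dm[seq_len(nd)])
  n <- dm[axis]
  hi <- lo <- lapply(dm[seq_len(nd)], seq_len)
  hi[[axis]] <- 2:n; lo[[axis]] <- 1:(n - 1)
  do.call(`[`, c(list(x), hi, list(drop = FALSE))) -
    do.call(`[`, c(list(x), lo, list(drop = FALSE)))
}

grad_smoothness_grad <- function(v) {
  v <- as_field_array(v, "velocity field")
  dm <- dim(v)
  nd <- length(dm) - 1L
  N <- prod(dm[seq_len(nd)])
  g <- array(0, dim = dm)
  for (a in seq_len(nd)) {
    idx <- c(lapply(dm[seq_len(nd)], seq_len), list(a))
    x <- array(do.call(`[`, c(list(v), idx)), dim = dm[seq_len(nd)])
    gx <- array(0, dim = dm[seq_len(nd)])
    for (ax in seq_len(nd)) {
      d <- diff_along(v, a, ax, dm, nd)
      # d = x[hi] - x[lo]; dL/dx[hi] += d, dL/dx[lo] -= d (before scaling)
      n <- dm[ax]
      hi <- lo <- lapply(dm[seq_len(nd)], seq_len)
      hi[[ax]] <- 2:n; lo[[ax]] <- 1:(n - 1)
      add_at <- function(gx, where, val) {
        cur <- do.call(`[`, c(list(gx), where, list(drop = FALSE)))
        do.call(`[<-`, c(list(gx), where, list(cur + val)))
      }
      gx <- add_at(gx, hi, d)
      gx <- add_at(gx, lo, -d)
    }
    g <- do.call(`[<-`, c(list(g), lapply(dm[seq_len(nd)], seq_len), list(a),
                          list(do.call(`[`, c(list(g), idx)) + gx)))
  }
  g / (N * nd)
}

#' Soft Dice loss between one-hot label volumes
#'
#' `1 - mean_l 2|A_l intersect B_l| / (|A_l| + |B_l|)` with soft
#' (real-valued) intersections and sums per label channel.
#'
#' @param s_f,s_m_warped Arrays of shape `(grid dims..., L)` holding soft
#'   one-hot label assignments with matching channels.
#' @param eps Stabilizer for empty channels.
#' @return Scalar in `[0, 1]`.
#' @export
soft_dice_loss <- function(s_f, s_m_warped, eps = 1e-7) {
  a <- as_grid_array(s_f); b <- as_grid_array(s_m_warped)
  if (!identical(dim(a), dim(b)))
    hr_stop("shape", "label channel stacks must match in shape")
  nd <- length(dim(a))
  L <- dim(a)[nd]
  am <- matrix(a, ncol = L); bm <- matrix(b, ncol = L)
  inter <- colSums(am * bm)
  sums <- colSums(am) + colSums(bm)
  dice <- (2 * inter + eps) / (sums + eps)
  1 - mean(dice)
}

soft_dice_loss_grad <- function(s_f, s_m_warped, eps = 1e-7) {
  a <- as_grid_array(s_f); b <- as_grid_array(s_m_warped)
  nd <- length(dim(a))
  L <- dim(a)[nd]
  am <- matrix(a, ncol = L); bm <- matrix(b, ncol = L)
  inter <- colSums(am * bm)
  sums <- colSums(am) + colSums(bm)
  # d dice_l / d b = (2 a (sums+eps) - (2 inter+eps)) / (sums+eps)^2
  gb <- -sweep(2 * am, 2, sums + eps, `/`) / L +
    sweep(bm * 0 + 1, 2, (2 * inter + eps) / (sums + eps)^2, `*`) / L
  array(gb, dim = dim(b))
}

# labels -> soft one-hot channel stack over the given label set
one_hot <- function(lab, labels) {
  dm <- dim(as_grid_array(lab))
  out <- array(0, dim = c(dm, length(labels)))
  la <- as.numeric(lab)
  for (l in seq_along(labels))
    out[seq_along(la) + (l - 1) * prod(dm)] <- as.numeric(la == labels[l])
  out
}

# -- similarity registry ----------------------------------------------------

sim_loss_registry <- function() c("mse", "ncc", "mi", "dice")

# value and gradient (w.r.t. warped moving image) of the chosen similarity
# *loss* (lower = better): mse as-is, ncc and mi negated.
sim_loss_value_grad <- function(name, f, mw, hs) {
  switch(name,
    mse = list(value = mse_loss(f, mw, hs$sigma),
               grad = mse_loss_grad(f, mw, hs$sigma)),
    ncc = {
      w <- if (is.null(hs$sim)) 9 else hs$sim
      list(value = -local_ncc(f, mw, w), grad = -local_ncc_grad(f, mw, w))
    },
    mi = {
      bins <- if (is.null(hs$sim)) 32 else hs$sim
      list(value = -mutual_information(f, mw, bins, rescale = FALSE),
           grad = -mutual_information_grad(f, mw, bins, rescale = FALSE))
    },
    hr_stop("value", paste("unknown similarity loss:", name))
  )
}

#' Unsupervised hyper-loss
#'
#' `(1 - lambda) * L_sim(f, m o phi) + lambda * L_reg(v)` with the
#' regularization weight `lambda` constrained to `[0, 1]`.
#'
#' @param m,f Moving and fixed images.
#' @param v Velocity field emitted by the registration network.
#' @param phi Deformation field, `integrate_svf(v)`.
#' @param hs A hyperparameter sample (see [sample_hyper()]), providing
#'   `lam`, `sigma` and any similarity hyperparameter.
#' @param sim_metric One of `"mse"`, `"ncc"`, `"mi"`.
#' @return Scalar loss.
#' @export
hyper_loss_unsupervised <- function(m, f, v, phi, hs, sim_metric = "mse") {
  lam <- hs$lam
  if (is.null(lam) || lam < 0 || lam > 1)
    hr_stop("value", "lambda must lie in [0, 1]")
  mw <- warp(as_grid_array(m), phi, mode = "linear")
  sim <- sim_loss_value_grad(sim_metric, f, mw, hs)$value
  (1 - lam) * sim + lam * grad_smoothness(v)
}

#' Semi-supervised hyper-loss
#'
#' `(1 - lambda)(1 - gamma) * L_sim + lambda * L_reg + gamma * L_seg`, where
#' `L_seg` is the soft Dice loss between the fixed labels and the warped
#' moving labels (soft one-hot channels warped linearly).
#'
#' @inheritParams hyper_loss_unsupervised
#' @param s_m,s_f Label maps for the moving and fixed images.
#' @return Scalar loss.
#' @export
hyper_loss_semisupervised <- function(m, f, s_m, s_f, v, phi, hs,
                                      sim_metric = "mse") {
  gam <- hs$gamma
  if (is.null(gam) || gam < 0 || gam > 1)
    hr_stop("value", "gamma must lie in [0, 1]")
  lam <- hs$lam
  if (is.null(lam) || lam < 0 || lam > 1)
    hr_stop("value", "lambda must lie in [0, 1]")
  labels <- sort(union(attr(as_labelmap(s_m), "label_set"),
                       attr(as_labelmap(s_f), "label_set")))
  sm_hot <- one_hot(s_m, labels)
  sf_hot <- one_hot(s_f, labels)
  u <- as_field_array(phi, "deformation field")
  sm_w <- warp_channels2(sm_hot, u, mode = "linear")
  mw <- warp(as_grid_array(m), phi, mode = "linear")
  sim <- sim_loss_value_grad(sim_metric, f, mw, hs)$value
  (1 - lam) * (1 - gam) * sim + lam * grad_smoothness(v) +
    gam * soft_dice_loss(sf_hot, sm_w)
}
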