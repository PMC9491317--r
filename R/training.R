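# End-to-end stochastic optimization: the hypernetwork is trained over
# random image pairs and hyperparameter draws; fixed-hyperparameter
# baselines train the registration weights directly.

#' Training configuration
#'
#' @param lr0 Initial Adam learning rate (default 1e-4).
#' @param batch Pairs per optimization step (default 1).
#' @param plateau_window Steps without a new minimum of the running-mean
#'   (window 100) training loss before the learning rate is halved
#'   (default 5e4; desk-scale runs use far smaller values).
#' @param max_steps Total optimization steps.
#' @param loss Similarity loss name: `"mse"`, `"ncc"` or `"mi"`.
#' @param prior A [hyper_prior()] (ignored by [train_baseline()]).
#' @param seed RNG seed for pair sampling, hyperparameter draws and
#'   initialization.
#' @param int_steps Scaling-and-squaring steps (default 5).
#' @param semi_supervised Use label maps and the semi-supervised loss.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, batch = 1, plateau_window = 5e4,
                         max_steps = 1000, loss = "mse",
                         prior = hyper_prior(), seed = 1L, int_steps = 5L,
                         semi_supervised = FALSE) {
  if (lr0 <= 0) hr_stop("config", "lr0 must be positive")
  if (batch < 1) hr_stop("config", "batch must be >= 1")
  if (plateau_window < 1) hr_stop("config", "plateau_window must be >= 1")
  loss <- match.arg(loss, c("mse", "ncc", "mi"))
  structure(list(lr0 = lr0, batch = as.integer(batch),
                 plateau_window = as.integer(plateau_window),
                 max_steps = as.integer(max_steps), loss = loss,
                 prior = prior, seed = as.integer(seed),
                 int_steps = as.integer(int_steps),
                 semi_supervised = isTRUE(semi_supervised)),
            class = "train_config")
}

#' Bundle image pairs into a dataset
#'
#' @param pairs List of pairs; each pair is a list with elements `m`, `f`
#'   and optionally `s_m`, `s_f` (label maps) and `v_true` (the generating
#'   velocity field, if known).
#' @return An object of class `pair_dataset`.
#' @export
pair_dataset <- function(pairs) {
  if (length(pairs) < 1L) hr_stop("value", "dataset needs at least one pair")
  g0 <- grid_dim(as_grid_array(pairs[[1]]$m))
  for (p in pairs) {
    if (!identical(as.integer(grid_dim(as_grid_array(p$m))), as.integer(g0)))
      hr_stop("shape", "all dataset members must share one grid shape")
  }
  structure(list(pairs = pairs, grid = g0), class = "pair_dataset")
}

#' @export
length.pair_dataset <- function(x) length(x$pairs)

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset>", length(x$pairs), "pairs on grid",
      paste(x$grid, collapse = "x"), "\n")
  invisible(x)
}

# -- loss + gradient w.r.t. registration weights for one pair ---------------

pair_loss_grad <- function(m, f, weights, config, hs, sim_metric,
                           s_m = NULL, s_f = NULL, int_steps = 5L,
                           want_grad = TRUE) {
  st <- unet_forward(m, f, weights, config, keep_cache = want_grad)
  v <- st$v
  if (!all(is.finite(v)))   # surfaced by the training loop as a diagnostic
    return(list(loss = NaN, sim = NaN, reg = NaN, seg = NaN, v = v))
  dm <- dim(v)
  ctx <- integrate_svf_cache(v, int_steps)
  u <- ctx$u
  ma <- array(as.numeric(as_grid_array(m)), dim = c(dm[1], dm[2], 1))
  mw <- warp_channels2(ma, u)
  sim <- sim_loss_value_grad(sim_metric, as_grid_array(f),
                             array(mw, dim = dm[1:2]), hs)
  lam <- hs$lam
  semi <- !is.null(hs$gamma) && !is.null(s_m)
  csim <- if (semi) (1 - lam) * (1 - hs$gamma) else (1 - lam)
  reg <- grad_smoothness(v)
  seg <- 0
  seg_ctx <- NULL
  if (semi) {
    labels <- sort(union(attr(as_labelmap(s_m), "label_set"),
                         attr(as_labelmap(s_f), "label_set")))
    sm_hot <- one_hot(s_m, labels)
    sf_hot <- one_hot(s_f, labels)
    sm_w <- warp_channels2(sm_hot, u)
    seg <- soft_dice_loss(sf_hot, sm_w)
    seg_ctx <- list(sm_hot = sm_hot, sf_hot = sf_hot, sm_w = sm_w)
  }
  loss <- csim * sim$value + lam * reg + (if (semi) hs$gamma * seg else 0)
  out <- list(loss = loss, sim = sim$value, reg = reg, seg = seg, v = v)
  if (!want_grad) return(out)
  gu <- array(0, dim = dm)
  if (csim != 0) {
    bw <- sample2_linear_bw(as.numeric(ma), dm[1], dm[2], 1L, as.numeric(u),
                            as.numeric(sim$grad))
    gu <- gu + csim * array(bw$gdisp, dim = dm)
  }
  if (semi && hs$gamma != 0) {
    gseg <- soft_dice_loss_grad(seg_ctx$sf_hot, seg_ctx$sm_w)
    bw <- sample2_linear_bw(as.numeric(seg_ctx$sm_hot), dm[1], dm[2],
                            dim(seg_ctx$sm_hot)[3], as.numeric(u),
                            as.numeric(gseg))
    gu <- gu + hs$gamma * array(bw$gdisp, dim = dm)
  }
  gv <- integrate_svf_bw(ctx, gu)
  if (lam != 0) gv <- gv + lam * grad_smoothness_grad(v)
  out$gw <- unet_backward(st, gv)
  out
}

# -- Adam ------------------------------------------------------------------

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, g, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}

# -- learning-rate plateau schedule ----------------------------------------
# "no improvement" = no new minimum of the running mean (window 100) of the
# training loss; when the counter reaches plateau_window the lr halves and
# the counter resets.

plateau_new <- function(lr0, window, rm_window = 100L) {
  list(lr = lr0, window = window, rm_window = rm_window,
       recent = numeric(0), best = Inf, since = 0L)
}

plateau_step <- function(sch, loss) {
  sch$recent <- c(sch$recent, loss)
  if (length(sch$recent) > sch$rm_window)
    sch$recent <- sch$recent[-1]
  rm <- mean(sch$recent)
  if (rm < sch$best) {
    sch$best <- rm
    sch$since <- 0L
  } else {
    sch$since <- sch$since + 1L
    if (sch$since >= sch$window) {
      sch$lr <- sch$lr / 2
      sch$since <- 0L
    }
  }
  sch
}

#' Train a hypernetwork-amortized registration model
#'
#' One optimization step draws one image pair and one hyperparameter sample,
#' emits the registration weights through the hypernetwork, evaluates the
#' composite hyper-loss, and backpropagates into the hypernetwork parameters
#' only.
#'
#' @param data A [pair_dataset()].
#' @param model A [hyper_model()].
#' @param cfg A [train_config()]; `cfg$prior` supplies hyperparameter draws.
#' @return A list: `model` (trained), `history` (data frame of step,
#'   lambda, loss, lr).
#' @export
train_hypernetwork <- function(data, model, cfg) {
  if (any(data$grid %% model$unet_config$pool^4 != 0))
    hr_stop("shape", "grid axes must be divisible by pool^4")
  set.seed(cfg$seed)
  # private, unshared copies: the Adam update mutates these in place
  model$theta <- lapply(model$theta, function(l)
    list(W = l$W + 0, b = l$b + 0))
  adam_m <- lapply(model$theta, function(l)
    list(W = l$W * 0, b = l$b * 0))
  adam_v <- lapply(model$theta, function(l)
    list(W = l$W * 0, b = l$b * 0))
  sch <- plateau_new(cfg$lr0, cfg$plateau_window)
  n <- length(data$pairs)
  hist <- list(step = integer(cfg$max_steps), lam = numeric(cfg$max_steps),
               loss = numeric(cfg$max_steps), lr = numeric(cfg$max_steps))
  for (step in seq_len(cfg$max_steps)) {
    p <- data$pairs[[sample.int(n, 1L)]]
    hs <- sample_hyper(cfg$prior)
    fw <- hypernet_fw(hs$normalized_vec, model)
    pg <- pair_loss_grad(p$m, p$f, fw$out, model$unet_config, hs, cfg$loss,
                         s_m = if (cfg$semi_supervised) p$s_m,
                         s_f = if (cfg$semi_supervised) p$s_f,
                         int_steps = cfg$int_steps)
    if (!is.finite(pg$loss))
      hr_stop("value", sprintf(
        "non-finite training loss at step %d (lambda = %.4f)", step, hs$lam))
    hb <- hypernet_bw(model, fw, pg$gw)
    for (l in seq_along(model$theta)) {
      adam_inplace(model$theta[[l]]$W, adam_m[[l]]$W, adam_v[[l]]$W,
                   hb$gtheta[[l]]$W, sch$lr, step)
      adam_inplace(model$theta[[l]]$b, adam_m[[l]]$b, adam_v[[l]]$b,
                   hb$gtheta[[l]]$b, sch$lr, step)
    }
    sch <- plateau_step(sch, pg$loss)
    hist$step[step] <- step
    hist$lam[step] <- hs$lam
    hist$loss[step] <- pg$loss
    hist$lr[step] <- sch$lr
  }
  list(model = model, history = as.data.frame(hist))
}

#' Train a fixed-hyperparameter baseline registration network
#'
#' Identical architecture and loss, but the registration weights are trained
#' directly with the hyperparameters held fixed.
#'
#' @param data A [pair_dataset()].
#' @param fixed A `hyper_sample` (see [fixed_hyper()]) held constant.
#' @param cfg A [train_config()].
#' @param config A [unet_config()] with `ndims = 2`.
#' @return A list: `weights` (trained flat vector), `history`.
#' @export
train_baseline <- function(data, fixed, cfg, config) {
  if (any(data$grid %% config$pool^4 != 0))
    hr_stop("shape", "grid axes must be divisible by pool^4")
  set.seed(cfg$seed)
  spec <- build_weight_spec(config)
  weights <- init_weight_vector(spec)
  adam_m <- weights * 0
  adam_v <- weights * 0
  sch <- plateau_new(cfg$lr0, cfg$plateau_window)
  n <- length(data$pairs)
  hist <- list(step = integer(cfg$max_steps), loss = numeric(cfg$max_steps),
               lr = numeric(cfg$max_steps))
  for (step in seq_len(cfg$max_steps)) {
    p <- data$pairs[[sample.int(n, 1L)]]
    pg <- pair_loss_grad(p$m, p$f, weights, config, fixed, cfg$loss,
                         s_m = if (cfg$semi_supervised) p$s_m,
                         s_f = if (cfg$semi_supervised) p$s_f,
                         int_steps = cfg$int_steps)
    if (!is.finite(pg$loss))
      hr_stop("value", sprintf("non-finite training loss at step %d", step))
    adam_inplace(weights, adam_m, adam_v, pg$gw, sch$lr, step)
    sch <- plateau_step(sch, pg$loss)
    hist$step[step] <- step
    hist$loss[step] <- pg$loss
    hist$lr[step] <- sch$lr
  }
  list(weights = weights, history = as.data.frame(hist))
}
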