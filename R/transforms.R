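# Spatial transforms: pull-back warping, scaling-and-squaring integration of
# stationary velocity fields, and Jacobian determinants of deformation maps.

#' Warp an image by a deformation field
#'
#' Pull-back warp: the output at voxel `p` samples the input at
#' `phi(p) = p + u(p)`. Sampling positions outside the grid are clamped to
#' the nearest edge so that no artificial zeros enter similarity losses.
#'
#' @param image An [as_image()] or [as_labelmap()] object (or plain array)
#'   on the same grid as `phi`.
#' @param phi A deformation field ([as_deformation()]).
#' @param mode `"linear"` (default for images) or `"nearest"` (used for
#'   label maps; also the default when `image` is a label map).
#' @return A warped object of the same class as `image`.
#' @export
warp <- function(image, phi, mode = if (inherits(image, "hr_labelmap")) "nearest" else "linear") {
  mode <- match.arg(mode, c("linear", "nearest"))
  u <- as_field_array(phi, "deformation field")
  dm <- dim(u)
  nd <- length(dm) - 1L
  is_lab <- inherits(image, "hr_labelmap")
  img <- as_grid_array(image)
  check_same_grid(img, structure(u, class = "hr_deformation"),
                  "image and deformation field")
  if (nd == 2L) {
    H <- dm[1]; W <- dm[2]
    out <- if (mode == "linear")
      sample2_linear_fw(as.numeric(img), H, W, 1L, as.numeric(u))
    else
      sample2_nearest_fw(as.numeric(img), H, W, 1L, as.numeric(u))
    out <- array(out, dim = c(H, W))
  } else {
    H <- dm[1]; W <- dm[2]; D <- dm[3]
    out <- if (mode == "linear")
      sample3_linear_fw(as.numeric(img), H, W, D, 1L, as.numeric(u))
    else
      sample3_nearest_fw(as.numeric(img), H, W, D, 1L, as.numeric(u))
    out <- array(out, dim = c(H, W, D))
  }
  if (is_lab) as_labelmap(round(out), spacing_of(image))
  else if (inherits(image, "hr_image")) as_image(out, spacing_of(image))
  else out
}

# warp a multi-channel stack (H,W,C) with one shared 2D displacement
warp_channels2 <- function(x, u, mode = "linear") {
  dm <- dim(x)
  f <- if (mode == "linear") sample2_linear_fw else sample2_nearest_fw
  array(f(x, dm[1], dm[2], dm[3], u), dim = dm)
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' Approximates the group exponential `phi = exp(v)`: the field is scaled to
#' `v / 2^steps` and the resulting small displacement is composed with
#' itself `steps` times. Displacement composition uses linear interpolation
#' with edge clamping: `u' (p) = u(p + u(p)) + u(p)`.
#'
#' @param v A velocity field ([as_velocity()] or array, component axis last).
#' @param steps Number of scaling-and-squaring steps (default 5).
#' @return An [as_deformation()] displacement field.
#' @export
integrate_svf <- function(v, steps = 5L) {
  if (length(steps) != 1L || is.na(steps) || steps < 0)
    hr_stop("value", "steps must be a non-negative integer")
  v <- as_field_array(v, "velocity field")
  dm <- dim(v)
  nd <- length(dm) - 1L
  u <- v / 2^steps
  if (steps == 0L) return(as_deformation(u))
  for (s in seq_len(steps)) {
    if (nd == 2L) {
      samp <- sample2_linear_fw(u, dm[1], dm[2], 2L, u)
    } else {
      samp <- sample3_linear_fw(as.numeric(u), dm[1], dm[2], dm[3], 3L,
                                as.numeric(u))
    }
    u <- array(u + samp, dim = dm)
  }
  as_deformation(u)
}

# -- differentiable version (2D): returns displacement + the cached half-step
#    fields needed to backpropagate a gradient on u back onto v.
integrate_svf_cache <- function(v, steps = 5L) {
  dm <- dim(v)
  u <- v / 2^steps
  cache <- vector("list", steps)
  if (steps > 0) {
    for (s in seq_len(steps)) {
      cache[[s]] <- u
      samp <- sample2_linear_fw(u, dm[1], dm[2], 2L, u)
      u <- array(u + samp, dim = dm)
    }
  }
  list(u = u, cache = cache, steps = steps, dm = dm)
}

integrate_svf_bw <- function(ctx, gu) {
  dm <- ctx$dm
  g <- as.numeric(gu)
  if (ctx$steps > 0) {
    for (s in rev(seq_len(ctx$steps))) {
      u <- ctx$cache[[s]]
      bw <- sample2_linear_bw(u, dm[1], dm[2], 2L, u, g)
      # u' = sample(u; u) + u: the sampled-values path, the sampling-location
      # path, and the identity path all feed the same u.
      g <- g + as.numeric(bw$gimg) + as.numeric(bw$gdisp)
    }
  }
  array(g / 2^ctx$steps, dim = dm)
}

#' Jacobian determinant of a deformation field
#'
#' Computes `det(J_phi)` per voxel with `J_phi(p) = grad phi(p)` evaluated by
#' central differences on the grid interior. Boundary voxels replicate the
#' nearest interior value so the returned field covers the full grid; summary
#' statistics in [jacobian_sd()] use interior voxels only.
#'
#' @param phi A deformation field.
#' @return A numeric array of per-voxel determinants on the grid of `phi`.
#' @export
jacobian_determinant <- function(phi) {
  u <- as_field_array(phi, "deformation field")
  dm <- dim(u)
  nd <- length(dm) - 1L
  if (any(dm[seq_len(nd)] < 3))
    hr_stop("value", "jacobian requires at least 3 voxels per axis")
  # du[[a]][[b]] = d u_a / d x_b, central differences, interior grid
  cdiff <- function(x, axis) {
    idx_hi <- idx_lo <- lapply(dm[seq_len(nd)], seq_len)
    n <- dm[axis]
    idx_hi[[axis]] <- 3:n
    idx_lo[[axis]] <- 1:(n - 2)
    (do.call(`[`, c(list(x), idx_hi, list(drop = FALSE))) -
       do.call(`[`, c(list(x), idx_lo, list(drop = FALSE)))) / 2
  }
  crop <- function(x) {
    idx <- lapply(dm[seq_len(nd)], function(n) 2:(n - 1))
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  comp <- function(a) {
    idx <- c(lapply(dm[seq_len(nd)], seq_len), list(a))
    array(do.call(`[`, c(list(u), idx)), dim = dm[seq_len(nd)])
  }
  J <- vector("list", nd * nd)
  for (a in seq_len(nd)) {
    ua <- comp(a)
    for (b in seq_len(nd)) {
      g <- if (a == b) 1 else 0
      d <- cdiff(ua, b)
      # align: differentiating along axis b shrinks axis b; crop others
      for (ax in setdiff(seq_len(nd), b)) {
        n <- dim(d)[ax]
        idx <- lapply(dim(d), seq_len)
        idx[[ax]] <- 2:(n - 1)
        d <- do.call(`[`, c(list(d), idx, list(drop = FALSE)))
      }
      J[[(a - 1) * nd + b]] <- d + g
    }
  }
  det_in <- if (nd == 2L) {
    J[[1]] * J[[4]] - J[[2]] * J[[3]]
  } else {
    J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
      J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
      J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  }
  # replicate nearest interior value onto the boundary
  out <- array(NA_real_, dim = dm[seq_len(nd)])
  inner <- lapply(dm[seq_len(nd)], function(n) 2:(n - 1))
  out <- do.call(`[<-`, c(list(out), inner, list(det_in)))
  near <- lapply(dm[seq_len(nd)], function(n) pmin(pmax(seq_len(n), 2), n - 1))
  out <- array(do.call(`[`, c(list(out), near)), dim = dm[seq_len(nd)])
  attr(out, "interior") <- inner
  out
}
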