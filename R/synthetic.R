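# Synthetic registration pairs with known ground truth: smoothed random
# blob images with matching multi-region label maps, deformed by a smooth
# random stationary velocity field, with optional contrast remapping,
# multiplicative low-frequency bias fields, and additive noise on the
# moving image. Stands in for brain-MRI cohorts in desk-scale experiments.

#' Synthetic data configuration
#'
#' @param grid Grid size per axis (2D), divisible by 16.
#' @param n_regions Number of labeled foreground regions.
#' @param n_levels Number of distinct intensity levels shared among the
#'   regions (default 3, mimicking tissue classes: distinct anatomical
#'   structures share intensity, so image similarity alone cannot
#'   disambiguate them and deformation smoothness carries real weight).
#' @param def_amp Maximum ground-truth velocity amplitude (voxels); 0 gives
#'   an identity deformation.
#' @param def_scale Smoothing scale (voxels) of the ground-truth velocity.
#' @param contrast `"identity"`, `"gamma"` (monotone nonlinear remap), or
#'   `"inverted"` (cross-contrast).
#' @param contrast_gamma Exponent of the `"gamma"` remap (default 1.5);
#'   values near 1 give a mild within-contrast intensity mismatch of the
#'   kind seen across scanners.
#' @param noise_sd Additive Gaussian noise SD on the moving image.
#' @param bias_amp Log-amplitude of the multiplicative intensity
#'   inhomogeneity field (0 disables it).
#' @param bias_scale Smoothing scale (voxels) of the bias field.
#' @param region_scale Smoothing scale (voxels) of the blob shapes.
#' @param image_blur Gaussian blur (voxels) applied to the piecewise-constant
#'   base image, emulating partial-volume softness at tissue interfaces and
#'   giving intensity losses a usable capture range.
#' @param seed RNG seed; every pair is deterministic given its config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid = c(64, 64), n_regions = 8, n_levels = 3,
                         def_amp = 6,
                         def_scale = 8, contrast = "identity",
                         contrast_gamma = 1.5,
                         noise_sd = 0.05, bias_amp = 0, bias_scale = 16,
                         region_scale = NULL, image_blur = 1, seed = 1L) {
  grid <- as.integer(rep_len(grid, 2))
  if (any(grid %% 16 != 0))
    hr_stop("config", "grid must be divisible by 16")
  if (def_amp < 0 || noise_sd < 0 || bias_amp < 0)
    hr_stop("config", "amplitudes must be non-negative")
  contrast <- match.arg(contrast, c("identity", "gamma", "inverted"))
  if (is.null(region_scale)) region_scale <- min(grid) / 10
  if (n_levels < 1 || n_levels > n_regions)
    hr_stop("config", "n_levels must lie in [1, n_regions]")
  structure(list(grid = grid, n_regions = as.integer(n_regions),
                 n_levels = as.integer(n_levels),
                 def_amp = def_amp, def_scale = def_scale,
                 contrast = contrast, contrast_gamma = contrast_gamma,
                 noise_sd = noise_sd,
                 bias_amp = bias_amp, bias_scale = bias_scale,
                 region_scale = region_scale, image_blur = image_blur,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# periodic FFT Gaussian blur
gauss_blur <- function(x, sigma) {
  dm <- dim(x)
  att <- lapply(dm, function(n) {
    fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    exp(-2 * pi^2 * fr^2 * sigma^2)
  })
  A <- outer(att[[1]], att[[2]])
  array(Re(fft(fft(x) * A, inverse = TRUE)) / prod(dm), dim = dm)
}

# unit-variance Gaussian random field, periodic FFT smoothing
smooth_noise_field <- function(dm, scale) {
  z <- array(rnorm(prod(dm)), dim = dm)
  if (scale <= 0) return(z)
  att <- lapply(dm, function(n) {
    fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    exp(-2 * pi^2 * fr^2 * scale^2)
  })
  A <- outer(att[[1]], att[[2]])
  sm <- Re(fft(fft(z) * A, inverse = TRUE)) / prod(dm)
  s <- sd(as.numeric(sm))
  if (s > 0) sm <- sm / s
  array(sm, dim = dm)
}

#' Generate one synthetic registration pair
#'
#' The base image consists of smoothed random blobs with one intensity per
#' region and a matching label map. The fixed image is the base warped by a
#' known smooth diffeomorphism (labels warped consistently with
#' nearest-neighbour interpolation); the moving image is the unwarped base
#' after contrast remapping, bias multiplication, and additive noise.
#' Registering `m` to `f` should therefore recover the ground-truth field.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `m`, `f` ([as_image()]), `s_m`, `s_f`
#'   ([as_labelmap()]), and `v_true` ([as_velocity()]).
#' @export
make_pair <- function(cfg) {
  set.seed(cfg$seed)
  dm <- cfg$grid
  k <- cfg$n_regions
  # blob labels: argmax of k smooth fields where any exceeds a threshold
  z <- array(0, dim = c(dm, k))
  for (l in seq_len(k)) z[, , l] <- smooth_noise_field(dm, cfg$region_scale)
  zmax <- apply(z, c(1, 2), max)
  zarg <- apply(z, c(1, 2), which.max)
  lab <- ifelse(zmax > 0.8, zarg, 0)
  # per-region intensities well above background, shared among n_levels
  # tissue-like classes
  levels <- seq(0.35, 0.95, length.out = cfg$n_levels)
  ints <- levels[(sample.int(k) - 1) %% cfg$n_levels + 1]
  base <- array(0.05, dim = dm)
  for (l in seq_len(k)) base[lab == l] <- ints[l]
  if (cfg$image_blur > 0) base <- gauss_blur(base, cfg$image_blur)
  # ground-truth velocity: smoothed white noise, amplitude-scaled
  v_true <- array(0, dim = c(dm, 2))
  if (cfg$def_amp > 0) {
    for (a in 1:2) v_true[, , a] <- smooth_noise_field(dm, cfg$def_scale)
    v_true <- v_true / max(abs(v_true)) * cfg$def_amp
  }
  phi <- integrate_svf(as_velocity(v_true))
  f <- warp(base, phi, mode = "linear")
  s_f <- warp(as_labelmap(lab), phi, mode = "nearest")
  # moving image: corrupted, unwarped base
  mimg <- switch(cfg$contrast,
    identity = base,
    gamma = base^cfg$contrast_gamma,
    inverted = max(base) + min(base) - base)
  if (cfg$bias_amp > 0)
    mimg <- mimg * exp(cfg$bias_amp * smooth_noise_field(dm, cfg$bias_scale))
  if (cfg$noise_sd > 0)
    mimg <- mimg + rnorm(prod(dm), 0, cfg$noise_sd)
  list(m = as_image(array(mimg, dim = dm)),
       f = as_image(array(f, dim = dm)),
       s_m = as_labelmap(lab),
       s_f = as_labelmap(as_grid_array(s_f)),
       v_true = as_velocity(v_true))
}

#' Generate a dataset of independent synthetic pairs
#'
#' Per-pair seeds are derived deterministically from the master seed. An
#' optional two-subpopulation mode assigns distinct deformation amplitudes
#' to the two halves of the dataset.
#'
#' @param cfg A [synth_config()] (its `seed` is the master seed).
#' @param n Number of pairs.
#' @param subpop_amps Optional numeric vector of two deformation amplitudes.
#' @return A [pair_dataset()]; each pair records its `subpop` (1 or 2) when
#'   subpopulations are requested.
#' @export
make_dataset <- function(cfg, n, subpop_amps = NULL) {
  if (n < 1) hr_stop("value", "n must be >= 1")
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- seeds[i]
    sp <- NA_integer_
    if (!is.null(subpop_amps)) {
      sp <- if (i <= n / 2) 1L else 2L
      ci$def_amp <- subpop_amps[sp]
    }
    pairs[[i]] <- make_pair(ci)
    pairs[[i]]$subpop <- sp
    pairs[[i]]$seed <- seeds[i]
  }
  pair_dataset(pairs)
}
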