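# Shared fixtures: all data are generated in code at test time.

# smooth unit-range test image
smooth_image <- function(n = 32, scale = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- array(hyperreg:::smooth_noise_field(c(n, n), scale), c(n, n))
  (x - min(x)) / diff(range(x))
}

# deterministic smooth divergence-style velocity field, max |v| = amp
analytic_velocity <- function(n = 32, amp = 2) {
  ii <- matrix(0:(n - 1), n, n)
  jj <- t(ii)
  v <- array(0, c(n, n, 2))
  v[, , 1] <- amp * sin(2 * pi * ii / n) * cos(2 * pi * jj / n)
  v[, , 2] <- -amp * cos(2 * pi * ii / n) * sin(2 * pi * jj / n)
  v
}

# random smooth velocity field
random_velocity <- function(n = 32, amp = 2, scale = 6, seed = 1) {
  set.seed(seed)
  v <- array(c(hyperreg:::smooth_noise_field(c(n, n), scale),
               hyperreg:::smooth_noise_field(c(n, n), scale)), c(n, n, 2))
  v / max(abs(v)) * amp
}

# small 2D U-Net configuration for fast tests
tiny_unet <- function() {
  unet_config(ndims = 2, enc_channels = c(2, 3, 3, 3),
              dec_channels = c(3, 3, 3, 3, 3, 2, 2))
}

# desk-scale study configuration shared by the scaled-down experiments
desk_unet <- function() {
  unet_config(ndims = 2, enc_channels = c(8, 16, 16, 16),
              dec_channels = c(16, 16, 16, 16, 16, 8, 8))
}

desk_hypernet <- function() hypernet_config(1, c(32, 32, 64, 64, 64))

# forward-difference Euler integration reference for dx/dt = v(x)
euler_flow <- function(v, M) {
  dm <- dim(v)
  u <- array(0, dim = dm)
  for (s in seq_len(M)) {
    vs <- array(hyperreg:::sample2_linear_fw(v, dm[1], dm[2], 2L, u), dm)
    u <- u + vs / M
  }
  u
}

# mean Dice of a model's registration over a set of pairs
eval_mean_dice <- function(weights, config, pairs, int_steps = 5) {
  mean(vapply(pairs, function(p) {
    v <- registration_forward(p$m, p$f, weights, config)
    phi <- integrate_svf(v, int_steps)
    mean(dice_score(p$s_f, warp(p$s_m, phi)), na.rm = TRUE)
  }, numeric(1)))
}
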