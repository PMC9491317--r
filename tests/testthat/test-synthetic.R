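test_that("a degenerate configuration produces identical pair members", {
  cfg <- synth_config(grid = c(32, 32), def_amp = 0, contrast = "identity",
                      noise_sd = 0, bias_amp = 0, seed = 61)
  p <- make_pair(cfg)
  expect_equal(as.numeric(p$m), as.numeric(p$f), tolerance = 1e-12)
  expect_identical(as.numeric(p$s_m), as.numeric(p$s_f))
})

test_that("pair generation is deterministic per seed", {
  cfg <- synth_config(grid = c(32, 32), seed = 62)
  p1 <- make_pair(cfg)
  p2 <- make_pair(cfg)
  expect_identical(p1, p2)
  cfg$seed <- 63L
  expect_gt(max(abs(as.numeric(make_pair(cfg)$m) - as.numeric(p1$m))), 0)
})

test_that("labeled regions carry intensities above the background mean", {
  cfg <- synth_config(grid = c(48, 48), contrast = "identity", noise_sd = 0,
                      bias_amp = 0, seed = 64)
  p <- make_pair(cfg)
  bg_mean <- mean(p$m[p$s_m == 0])
  fg <- as.numeric(p$m)[as.numeric(p$s_m) != 0]
  expect_true(all(fg > bg_mean))   # exhaustive scan over foreground voxels
})

test_that("bias fields stay positive and contrast remaps behave as declared", {
  cfg <- synth_config(grid = c(32, 32), bias_amp = 0.4, noise_sd = 0, seed = 65)
  base <- make_pair(synth_config(grid = c(32, 32), bias_amp = 0, noise_sd = 0,
                                 seed = 65))
  p <- make_pair(cfg)
  # multiplicative field recovered on voxels with nonzero signal
  ratio <- as.numeric(p$m) / as.numeric(base$m)
  expect_true(all(ratio > 0))
  x <- seq(0.05, 0.95, length.out = 50)
  expect_true(all(diff(x^1.5) > 0))                    # gamma remap monotone
  expect_true(all(diff(max(x) + min(x) - x) < 0))      # inverted decreasing
})

test_that("datasets are reproducible and subpopulations scale as configured", {
  cfg <- synth_config(grid = c(32, 32), seed = 66)
  d1 <- make_dataset(cfg, 1)
  expect_length(d1, 1L)
  d <- make_dataset(cfg, 6, subpop_amps = c(1, 3))
  d2 <- make_dataset(cfg, 6, subpop_amps = c(1, 3))
  expect_identical(d$pairs[[4]]$m, d2$pairs[[4]]$m)
  mean_disp <- function(pairs) mean(vapply(pairs, function(p) {
    u <- integrate_svf(p$v_true, 5)
    mean(sqrt(u[, , 1]^2 + u[, , 2]^2))
  }, numeric(1)))
  r <- mean_disp(d$pairs[4:6]) / mean_disp(d$pairs[1:3])
  expect_gt(r, 3 * 0.8)
  expect_lt(r, 3 * 1.2)
  expect_error(make_dataset(cfg, 0), class = "hyperreg_value_error")
})
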