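test_that("noise-scaled MSE follows its closed form", {
  f <- smooth_image(16, seed = 1)
  expect_equal(mse_loss(f, f, 0.1), 0)
  g <- smooth_image(16, seed = 2)
  expect_equal(mse_loss(f, g, 0.05), 4 * mse_loss(f, g, 0.1))
  expect_equal(mse_loss(matrix(c(0, 1), 1), matrix(c(1, 1), 1), 1), 0.5)
  expect_error(mse_loss(f, g, 0), class = "hyperreg_value_error")
})

test_that("local NCC is maximal under local affine intensity maps", {
  f <- smooth_image(24, seed = 3)
  expect_gt(local_ncc(f, f, 9), 1 - 1e-3)
  expect_gt(local_ncc(f, 1.7 * f + 0.3, 9), 1 - 1e-3)
  expect_error(local_ncc(f, f, 8), class = "hyperreg_value_error")
  expect_error(local_ncc(f, f, 31), class = "hyperreg_value_error")
})

test_that("full-extent local NCC reduces to global NCC", {
  n <- 15   # odd so a single window spans the whole image
  set.seed(4)
  f <- matrix(rnorm(n * n), n)
  g <- matrix(rnorm(n * n), n)
  # independent direct formula for (squared) global NCC
  gncc <- (sum((f - mean(f)) * (g - mean(g))))^2 /
    (sum((f - mean(f))^2) * sum((g - mean(g))^2))
  expect_equal(local_ncc(f, g, n, eps = 0), gncc, tolerance = 1e-10)
})

test_that("hard-binned mutual information of an image with itself equals its entropy", {
  expect_equal(mutual_information(matrix(0.5, 20, 20), smooth_image(20), 16), 0)
  set.seed(5)
  f <- matrix(runif(1e4), 100)
  mi <- hyperreg:::mutual_information_hard(f, f, 16, rescale = FALSE)
  # plug-in entropy oracle on the same hard binning
  counts <- tabulate(pmin(floor(f * 16) + 1, 16), 16)
  p <- counts / sum(counts)
  ent <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi, ent, tolerance = 1e-6)
})

test_that("mutual information of independent noise is near zero and symmetric", {
  set.seed(6)
  f <- matrix(runif(1e4), 100)
  g <- matrix(runif(1e4), 100)
  expect_lt(mutual_information(f, g, 8), 0.02)
  expect_equal(mutual_information(f, g, 8), mutual_information(g, f, 8),
               tolerance = 1e-12)
  expect_error(mutual_information(f, g, 1), class = "hyperreg_value_error")
})

test_that("gradient smoothness penalty is zero on constants and quadratic", {
  cst <- array(2.5, c(8, 8, 2))
  expect_equal(grad_smoothness(cst), 0)
  v <- random_velocity(8, amp = 1, seed = 7)
  expect_equal(grad_smoothness(3 * v), 9 * grad_smoothness(v))
  # explicit forward-difference summation oracle for a 1D ramp
  s <- 0.4
  ramp <- array(0, c(8, 8, 2))
  ramp[, , 1] <- s * matrix(0:7, 8, 8)
  # only component 1 varies, only along axis 1: 7*8 differences equal to s
  expect_equal(grad_smoothness(ramp), 0.5 * (7 * 8 * s^2) / (64 * 2))
})

test_that("soft Dice loss matches hand-computed overlaps", {
  a <- array(0, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1
  expect_equal(soft_dice_loss(a, a), 0, tolerance = 1e-6)
  b <- array(0, c(4, 4, 1)); b[3:4, 3:4, 1] <- 1
  expect_equal(soft_dice_loss(a, b), 1, tolerance = 1e-6)
  # two 4-voxel rectangles overlapping in 2 voxels: 1 - 2*2/(4+4) = 0.5
  A <- array(0, c(4, 4, 1)); A[1:2, 1:2, 1] <- 1          # rows 1:2, cols 1:2
  B <- array(0, c(4, 4, 1)); B[2:3, 1:2, 1] <- 1          # rows 2:3, cols 1:2
  expect_equal(soft_dice_loss(A, B), 0.5, tolerance = 1e-6)
  expect_error(soft_dice_loss(A, array(0, c(4, 4, 2))),
               class = "hyperreg_shape_error")
})

test_that("the unsupervised hyper-loss interpolates similarity and regularity", {
  m <- smooth_image(32, seed = 8)
  f <- smooth_image(32, seed = 9)
  v <- random_velocity(32, amp = 1, seed = 10)
  phi <- integrate_svf(v, 4)
  sim <- mse_loss(f, warp(m, phi), 0.05)
  reg <- grad_smoothness(v)
  h <- function(lam) hyper_loss_unsupervised(m, f, v, phi,
                                             fixed_hyper(lam), "mse")
  expect_equal(h(0), sim)
  expect_equal(h(1), reg)
  expect_equal(h(0.5), (sim + reg) / 2)
  expect_error(hyper_loss_unsupervised(m, f, v, phi, list(lam = 1.2), "mse"),
               class = "hyperreg_value_error")
})

test_that("the semi-supervised hyper-loss reduces correctly at the corners", {
  m <- smooth_image(32, seed = 11)
  f <- smooth_image(32, seed = 12)
  lab_m <- matrix(as.integer(m > 0.5), 32)
  lab_f <- matrix(as.integer(f > 0.5), 32)
  v <- random_velocity(32, amp = 1, seed = 13)
  phi <- integrate_svf(v, 4)
  hss <- function(lam, gam)
    hyper_loss_semisupervised(m, f, lab_m, lab_f, v, phi,
                              fixed_hyper(lam, gamma = gam), "mse")
  # gamma = 0 reduces to the unsupervised loss
  expect_equal(hss(0.3, 0),
               hyper_loss_unsupervised(m, f, v, phi, fixed_hyper(0.3), "mse"))
  # gamma = 1, lambda = 0: pure segmentation overlap
  hot_m <- hyperreg:::one_hot(lab_m, 1)
  hot_f <- hyperreg:::one_hot(lab_f, 1)
  seg <- soft_dice_loss(hot_f, hyperreg:::warp_channels2(hot_m, phi))
  expect_equal(hss(0, 1), seg)
  # printed coefficient structure at lambda = 0.25, gamma = 0.5
  sim <- mse_loss(f, warp(m, phi), 0.05)
  reg <- grad_smoothness(v)
  expect_equal(hss(0.25, 0.5), 0.375 * sim + 0.25 * reg + 0.5 * seg)
  expect_error(hss(0.3, NULL), class = "hyperreg_value_error")
})

test_that("loss gradients agree with finite differences", {
  set.seed(14)
  n <- 12
  f <- smooth_image(n, seed = 15)
  g <- smooth_image(n, seed = 16) * 0.8 + 0.1
  fd_check <- function(value_fn, grad, x, k = 8, eps = 1e-6, tol = 1e-3) {
    idx <- sample(length(x), k)
    for (i in idx) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (value_fn(xp) - value_fn(xm)) / (2 * eps)
      if (abs(fd) > 1e-8)
        expect_lt(abs(fd - grad[i]) / max(abs(fd), 1e-8), tol)
    }
  }
  fd_check(function(x) mse_loss(f, x, 0.05),
           hyperreg:::mse_loss_grad(f, g, 0.05), g)
  fd_check(function(x) -local_ncc(f, x, 5),
           -hyperreg:::local_ncc_grad(f, g, 5), g)
  v <- random_velocity(n, amp = 1, seed = 17)
  fd_check(function(x) grad_smoothness(array(x, dim(v))),
           hyperreg:::grad_smoothness_grad(v), v)
  a <- hyperreg:::one_hot(matrix(as.integer(f > 0.5), n), 1)
  b <- array(pmin(pmax(g, 0), 1), c(n, n, 1))
  fd_check(function(x) soft_dice_loss(a, array(x, dim(b))),
           hyperreg:::soft_dice_loss_grad(a, b), b)
  # soft-histogram MI (piecewise-linear kernel: check away from bin edges)
  fd_check(function(x) mutual_information(f, array(x, dim(g)), 8,
                                          rescale = FALSE),
           hyperreg:::mutual_information_grad(f, g, 8, rescale = FALSE),
           g, tol = 5e-3)
})
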