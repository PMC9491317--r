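test_that("Dice scores match hand-computed overlaps", {
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L; a[6:7, 6:7] <- 2L
  expect_equal(dice_score(a, a), c(`1` = 100, `2` = 100))
  b <- matrix(0L, 8, 8); b[2:3, 5:6] <- 1L
  expect_equal(unname(dice_score(a, b)["1"]), 0)
  # 4-voxel squares overlapping in 2 voxels
  d <- matrix(0L, 8, 8); d[3:4, 2:3] <- 1L
  expect_equal(unname(dice_score(a, d)["1"]), 50)
  # symmetry; absent labels are missing, not zero
  expect_equal(dice_score(a, d), dice_score(d, a))
  expect_true(is.na(dice_score(a, d, labels = 5)))
  expect_error(dice_score(a, matrix(0L, 6, 6)),
               class = "hyperreg_shape_error")
})

test_that("95th-percentile surface distance matches a brute-force oracle", {
  sq <- function(r1, c1) {
    m <- matrix(0L, 16, 16); m[r1 + 0:3, c1 + 0:3] <- 1L; m
  }
  a <- sq(3, 3)
  expect_equal(surface_distance_95(a, a, 1), 0)
  b <- sq(6, 3)   # translated 3 voxels along axis 1
  # independent oracle: boundary voxels found by 4-neighbour scan in R,
  # exhaustive pairwise distances, both directions pooled
  boundary <- function(m) {
    out <- NULL
    for (i in 1:16) for (j in 1:16) {
      if (m[i, j] != 1) next
      nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < 16) m[i + 1, j] else 0,
              if (j > 1) m[i, j - 1] else 0, if (j < 16) m[i, j + 1] else 0)
      if (any(nb != 1)) out <- rbind(out, c(i, j))
    }
    out
  }
  pa <- boundary(a); pb <- boundary(b)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2)
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  expect_equal(surface_distance_95(a, b, 1, spacing = c(1, 1)),
               unname(quantile(pooled, 0.95)))
  expect_equal(surface_distance_95(a, b, 1, spacing = c(1, 1)), 3)
  expect_error(surface_distance_95(a, matrix(0L, 16, 16), 1),
               class = "hyperreg_value_error")
})

test_that("surface distance respects anisotropic spacing", {
  a <- matrix(0L, 12, 12); a[4:6, 4:6] <- 1L
  b <- matrix(0L, 12, 12); b[4:6, 5:7] <- 1L   # 1-voxel shift along axis 2
  expect_equal(surface_distance_95(a, b, 1, spacing = c(1, 2)), 2)
})

test_that("jacobian determinant SD separates rigid from non-rigid maps", {
  n <- 16
  expect_equal(jacobian_sd(array(0, c(n, n, 2))), 0)
  # uniform scaling: constant determinant, zero dispersion
  u <- array(0, c(n, n, 2))
  u[, , 1] <- 0.2 * matrix(0:(n - 1), n, n)
  u[, , 2] <- 0.2 * t(matrix(0:(n - 1), n, n))
  expect_equal(jacobian_sd(u), 0, tolerance = 1e-12)
  # random smooth field: matches the SD over the oracle determinant field
  u <- random_velocity(n, amp = 2, seed = 51)
  dets <- c()
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    d11 <- 1 + (u[i + 1, j, 1] - u[i - 1, j, 1]) / 2
    d12 <- (u[i, j + 1, 1] - u[i, j - 1, 1]) / 2
    d21 <- (u[i + 1, j, 2] - u[i - 1, j, 2]) / 2
    d22 <- 1 + (u[i, j + 1, 2] - u[i, j - 1, 2]) / 2
    dets <- c(dets, d11 * d22 - d12 * d21)
  }
  expect_equal(jacobian_sd(u), sd(dets), tolerance = 1e-10)
})

test_that("warping labels by the generating field preserves overlap", {
  cfg <- synth_config(grid = c(48, 48), seed = 52)
  p <- make_pair(cfg)
  phi <- integrate_svf(p$v_true, 5)
  warped <- warp(p$s_m, phi, mode = "nearest")
  expect_gte(mean(dice_score(p$s_f, warped), na.rm = TRUE), 95)
})
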