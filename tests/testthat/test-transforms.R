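test_that("warp is an identity under zero displacement and preserves constants", {
  img <- smooth_image(24, seed = 1)
  zero <- array(0, c(24, 24, 2))
  expect_equal(as.numeric(warp(img, zero)), as.numeric(img))
  const <- array(0.7, c(24, 24))
  u <- random_velocity(24, amp = 3, seed = 2)
  expect_equal(as.numeric(warp(const, u)), rep(0.7, 24 * 24))
})

test_that("nearest warp of an impulse under integer translation obeys the pull-back convention", {
  n <- 16
  for (d in list(c(2, 0), c(0, 3), c(-2, 1))) {
    img <- array(0, c(n, n))
    p <- c(9, 7)
    img[p[1], p[2]] <- 1
    u <- array(0, c(n, n, 2))
    u[, , 1] <- d[1]; u[, , 2] <- d[2]
    out <- warp(img, u, mode = "nearest")
    # brute-force indexing oracle: out(q) = img(q + d)
    expected <- array(0, c(n, n))
    for (i in 1:n) for (j in 1:n) {
      src <- pmin(pmax(c(i, j) + d, 1), n)
      expected[i, j] <- img[src[1], src[2]]
    }
    expect_equal(as.numeric(out), as.numeric(expected))
    # i.e. the impulse lands at p - d
    expect_equal(which(out == 1, arr.ind = TRUE)[1, ],
                 c(row = p[1] - d[1], col = p[2] - d[2]))
  }
})

test_that("warp rejects mismatched grids", {
  img <- smooth_image(16)
  u <- array(0, c(24, 24, 2))
  expect_error(warp(img, u), class = "hyperreg_shape_error")
})

test_that("integrating the zero and constant fields gives identity and translation", {
  z <- array(0, c(32, 32, 2))
  expect_equal(as.numeric(integrate_svf(z, 5)), rep(0, 32 * 32 * 2))
  cst <- array(0, c(32, 32, 2))
  cst[, , 1] <- 1.25; cst[, , 2] <- -0.75
  u <- integrate_svf(cst, 5)
  # flow of a constant field is a translation on the interior
  expect_lt(max(abs(u[5:28, 5:28, 1] - 1.25)), 1e-9)
  expect_lt(max(abs(u[5:28, 5:28, 2] + 0.75)), 1e-9)
  expect_error(integrate_svf(z, -1), class = "hyperreg_value_error")
})

test_that("scaling-and-squaring of a linear field matches the matrix exponential", {
  skip_if_not_installed("pracma")
  n <- 32
  A <- matrix(c(0.02, -0.03, 0.04, 0.01), 2, 2)
  p0 <- (n - 1) / 2
  ii <- matrix(0:(n - 1), n, n); jj <- t(ii)
  v <- array(0, c(n, n, 2))
  v[, , 1] <- A[1, 1] * (ii - p0) + A[1, 2] * (jj - p0)
  v[, , 2] <- A[2, 1] * (ii - p0) + A[2, 2] * (jj - p0)
  u <- integrate_svf(v, 5)
  E <- pracma::expm(A) - diag(2)
  ue <- array(0, c(n, n, 2))
  ue[, , 1] <- E[1, 1] * (ii - p0) + E[1, 2] * (jj - p0)
  ue[, , 2] <- E[2, 1] * (ii - p0) + E[2, 2] * (jj - p0)
  int <- 5:28
  rel <- max(abs(u[int, int, ] - ue[int, int, ])) / max(abs(ue[int, int, ]))
  expect_lt(rel, 1e-3)
})

test_that("scaling-and-squaring converges to fine-step Euler integration", {
  v <- analytic_velocity(32, amp = 2)
  u7 <- integrate_svf(v, 7)
  ue <- euler_flow(v, 256)
  int <- 5:28
  expect_lt(max(abs(u7[int, int, ] - ue[int, int, ])), 1e-2)
})

test_that("inverse velocity integration undoes the forward warp", {
  v <- random_velocity(32, amp = 1.5, seed = 5)
  img <- smooth_image(32, seed = 6)
  fwd <- integrate_svf(v, 5)
  bwd <- integrate_svf(-v, 5)
  back <- warp(warp(img, fwd), bwd)
  int <- 5:28
  mae <- mean(abs((back - img)[int, int]))
  expect_lt(mae, 0.02 * diff(range(img)))
})

test_that("jacobian determinant is exact for identity and uniform scaling", {
  n <- 16
  expect_equal(as.numeric(jacobian_determinant(array(0, c(n, n, 2)))),
               rep(1, n * n))
  s <- 1.3
  ii <- matrix(0:(n - 1), n, n)
  u <- array(0, c(n, n, 2))
  u[, , 1] <- (s - 1) * ii
  u[, , 2] <- (s - 1) * t(ii)
  dj <- jacobian_determinant(u)
  expect_lt(max(abs(dj[2:(n - 1), 2:(n - 1)] - s^2)), 1e-12)
  expect_error(jacobian_determinant(array(0, c(2, 2, 2))),
               class = "hyperreg_value_error")
})

test_that("jacobian determinant matches a brute-force per-voxel oracle", {
  n <- 20
  u <- random_velocity(n, amp = 2, seed = 9)
  dj <- jacobian_determinant(u)
  for (rep in 1:20) {
    i <- sample(2:(n - 1), 1); j <- sample(2:(n - 1), 1)
    d11 <- 1 + (u[i + 1, j, 1] - u[i - 1, j, 1]) / 2
    d12 <- (u[i, j + 1, 1] - u[i, j - 1, 1]) / 2
    d21 <- (u[i + 1, j, 2] - u[i - 1, j, 2]) / 2
    d22 <- 1 + (u[i, j + 1, 2] - u[i, j - 1, 2]) / 2
    expect_lt(abs(dj[i, j] - (d11 * d22 - d12 * d21)), 1e-12)
  }
})

test_that("integrated smooth fields are diffeomorphic (positive jacobian)", {
  for (seed in 1:5) {
    v <- random_velocity(32, amp = 2, scale = 6, seed = seed)
    dj <- jacobian_determinant(integrate_svf(v, 5))
    expect_gt(min(dj), 0)
  }
})

test_that("3D warp and jacobian behave on analytic fields", {
  n <- 12
  img <- array(rnorm(n^3), c(n, n, n))
  zero <- array(0, c(n, n, n, 3))
  expect_equal(as.numeric(warp(img, zero)), as.numeric(img))
  s <- 1.1
  u <- array(0, c(n, n, n, 3))
  for (a in 1:3) {
    coord <- slice.index(array(0, c(n, n, n)), a) - 1
    u[, , , a] <- (s - 1) * coord
  }
  dj <- jacobian_determinant(u)
  expect_lt(max(abs(dj[2:(n - 1), 2:(n - 1), 2:(n - 1)] - s^3)), 1e-10)
})
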