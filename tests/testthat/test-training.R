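test_that("the plateau schedule halves the learning rate as configured", {
  # constant-loss stub: first step sets the best running mean, then the
  # counter reaches the window every `window` steps
  sch <- hyperreg:::plateau_new(1e-3, window = 5L)
  for (i in 1:11) sch <- hyperreg:::plateau_step(sch, 1.0)
  expect_equal(sch$lr, 1e-3 / 4)
  # an improving loss never decays
  sch <- hyperreg:::plateau_new(1e-3, window = 5L)
  for (i in 1:50) sch <- hyperreg:::plateau_step(sch, 1 / i)
  expect_equal(sch$lr, 1e-3)
})

test_that("hypernetwork training reduces the running-mean loss", {
  cfg <- synth_config(grid = c(64, 64), seed = 81)
  data <- make_dataset(cfg, 6)
  set.seed(82)
  model <- hyper_model(
    unet_config(2, c(4, 8, 8, 8), c(8, 8, 8, 8, 8, 4, 4)),
    hypernet_config(1, c(16, 16, 32)))
  tc <- train_config(lr0 = 2e-3, plateau_window = 500, max_steps = 200,
                     loss = "mse", prior = hyper_prior(0.2), seed = 83)
  out <- train_hypernetwork(data, model, tc)
  h <- out$history
  expect_equal(nrow(h), 200L)
  rm_at <- function(s) mean(h$loss[max(1, s - 99):s])
  expect_lt(rm_at(200), rm_at(10))
  # gradient flow: parameters moved, and the emitted weights moved for
  # every hyperparameter input (weight sharing)
  for (lam in c(0.1, 0.5, 0.9)) {
    expect_gt(sum(abs(hypernetwork_forward(lam, out$model) -
                      hypernetwork_forward(lam, model))), 0)
  }
})

test_that("training draws lambda from the configured prior", {
  cfg <- synth_config(grid = c(32, 32), seed = 84)
  data <- make_dataset(cfg, 3)
  set.seed(85)
  model <- hyper_model(tiny_unet(), hypernet_config(1, c(8, 8)))
  tc <- train_config(lr0 = 1e-3, plateau_window = 100, max_steps = 40,
                     loss = "mse",
                     prior = hyper_prior(endpoint_rate = 0,
                                         lam_range = c(0.5, 0.5)),
                     seed = 86)
  out <- train_hypernetwork(data, model, tc)
  expect_true(all(out$history$lam == 0.5))
})

test_that("pure-regularization baselines smooth their velocity output", {
  cfg <- synth_config(grid = c(32, 32), seed = 87)
  data <- make_dataset(cfg, 4)
  held <- make_dataset({cfg$seed <- 88L; cfg}, 3)
  ucfg <- unet_config(2, c(4, 8, 8, 8), c(8, 8, 8, 8, 8, 4, 4))
  tc <- train_config(lr0 = 2e-3, plateau_window = 300, max_steps = 150,
                     loss = "mse", seed = 89)
  # reference: an untrained network with ordinary (non-small) final layer
  set.seed(90)
  spec <- build_weight_spec(ucfg)
  w0 <- init_weight_vector(spec, final_sd = sqrt(2 / (9 * 8)))
  out <- train_baseline(data, fixed_hyper(1), tc, ucfg)
  mean_reg <- function(w) mean(vapply(held$pairs, function(p)
    grad_smoothness(registration_forward(p$m, p$f, w, ucfg)), numeric(1)))
  expect_lt(mean_reg(out$weights), mean_reg(w0))
})

test_that("similarity-only training on self-pairs drives the loss to zero", {
  cfg <- synth_config(grid = c(32, 32), noise_sd = 0, seed = 91)
  ds <- make_dataset(cfg, 3)
  selfpairs <- pair_dataset(lapply(ds$pairs, function(p)
    list(m = p$m, f = p$m, s_m = p$s_m, s_f = p$s_m)))
  ucfg <- unet_config(2, c(4, 8, 8, 8), c(8, 8, 8, 8, 8, 4, 4))
  tc <- train_config(lr0 = 1e-3, plateau_window = 300, max_steps = 120,
                     loss = "mse", seed = 92)
  out <- train_baseline(selfpairs, fixed_hyper(0), tc, ucfg)
  expect_lt(mean(tail(out$history$loss, 20)), 0.05)
})

test_that("fixed seeds reproduce training runs exactly", {
  cfg <- synth_config(grid = c(32, 32), seed = 93)
  data <- make_dataset(cfg, 3)
  ucfg <- tiny_unet()
  tc <- train_config(lr0 = 1e-3, plateau_window = 100, max_steps = 30,
                     loss = "mse", seed = 94)
  a <- train_baseline(data, fixed_hyper(0.4), tc, ucfg)
  b <- train_baseline(data, fixed_hyper(0.4), tc, ucfg)
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
})

test_that("training aborts with a diagnostic on non-finite losses", {
  cfg <- synth_config(grid = c(32, 32), seed = 95)
  data <- make_dataset(cfg, 2)
  data$pairs[[1]]$m[1, 1] <- Inf
  data$pairs[[1]]$f[1, 1] <- Inf
  ucfg <- tiny_unet()
  tc <- train_config(lr0 = 1e-3, plateau_window = 100, max_steps = 10,
                     loss = "mse", seed = 96)
  expect_error(train_baseline(data, fixed_hyper(0.2), tc, ucfg),
               "non-finite")
})
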