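test_that("the 2D weight manifest matches an independent per-layer count", {
  cfg <- unet_config(ndims = 2)
  spec <- build_weight_spec(cfg)
  # independent closed-form count over the wiring: sum(k^n*cin*cout + cout)
  cin <- c(2, 16, 32, 32, 32, 32 + 32, 32 + 32, 32 + 32, 32, 32, 16, 16)
  cout <- c(16, 32, 32, 32, 32, 32, 32, 32, 32, 16, 16, 2)
  expect_equal(spec$total_count,
               sum(vapply(seq_along(cin), function(i)
                 conv_param_count(3, 2, cin[i], cout[i]), integer(1))))
  expect_equal(conv_param_count(3, 2, 1, 1), 10L)   # 9 kernel + 1 bias
  expect_error(unet_config(2, enc_channels = c(16, 32)),
               class = "hyperreg_config_error")
})

test_that("2D and 3D manifests agree with the closed-form layer sum", {
  for (nd in 2:3) {
    cfg <- unet_config(ndims = nd, enc_channels = c(4, 8, 8, 8),
                       dec_channels = c(8, 8, 8, 8, 8, 4, 4))
    spec <- build_weight_spec(cfg)
    tab <- hyperreg:::unet_channel_table(cfg)
    expect_equal(spec$total_count,
                 sum(conv_param_count(3, nd, tab$cin, tab$cout)))
  }
})

test_that("packing weights through the manifest reproduces the forward output", {
  cfg <- tiny_unet()
  spec <- build_weight_spec(cfg)
  set.seed(21)
  w <- init_weight_vector(spec, final_sd = 0.01) + rnorm(spec$total_count, 0, 0.01)
  m <- smooth_image(32, seed = 22)
  f <- smooth_image(32, seed = 23)
  v1 <- registration_forward(m, f, w, cfg)
  wl <- hyperreg:::unpack_weights(w, spec)
  w2 <- hyperreg:::pack_weights(wl, spec)
  expect_identical(w, w2)
  v2 <- registration_forward(m, f, w2, cfg)
  expect_identical(as.numeric(v1), as.numeric(v2))
})

test_that("the registration network is linear-traceable and deterministic", {
  cfg <- tiny_unet()
  spec <- build_weight_spec(cfg)
  m <- smooth_image(32, seed = 24)
  f <- smooth_image(32, seed = 25)
  # all-zero weights emit the zero velocity field
  v0 <- registration_forward(m, f, rep(0, spec$total_count), cfg)
  expect_equal(max(abs(v0)), 0)
  # zero weights except the final-layer bias emit that constant field
  w <- rep(0, spec$total_count)
  w[(spec$total_count - 1):spec$total_count] <- c(0.4, -0.2)
  vb <- registration_forward(m, f, w, cfg)
  expect_equal(as.numeric(vb[, , 1]), rep(0.4, 32 * 32))
  expect_equal(as.numeric(vb[, , 2]), rep(-0.2, 32 * 32))
  # bit-identical repeat evaluation
  set.seed(26)
  w2 <- init_weight_vector(spec)
  expect_identical(as.numeric(registration_forward(m, f, w2, cfg)),
                   as.numeric(registration_forward(m, f, w2, cfg)))
  expect_error(registration_forward(smooth_image(30), smooth_image(30), w2, cfg),
               class = "hyperreg_shape_error")
  expect_error(registration_forward(m, f, w2[-1], cfg),
               class = "hyperreg_spec_error")
})

test_that("the hypernetwork emits spec-length weight vectors deterministically", {
  set.seed(27)
  model <- hyper_model(unet_config(ndims = 3), hypernet_config(1))
  w <- hypernetwork_forward(0.3, model)
  expect_length(w, 313507L)
  expect_identical(w, hypernetwork_forward(0.3, model))
  expect_error(hypernetwork_forward(1.3, model),
               class = "hyperreg_value_error")
  expect_error(hypernetwork_forward(c(0.3, 0.4), model),
               class = "hyperreg_value_error")
  # zero final layer emits the zero weight vector for any input
  model$theta[[length(model$theta)]]$W[] <- 0
  model$theta[[length(model$theta)]]$b[] <- 0
  expect_equal(max(abs(hypernetwork_forward(0.9, model))), 0)
})

test_that("hypernetwork parameter counts match per-layer arithmetic", {
  # stated hidden stack alone (one scalar input, no output layer): 31,168
  dims <- c(1, 32, 64, 64, 128, 128)
  hand <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  expect_equal(hand, 31168)
  set.seed(28)
  model <- hyper_model(unet_config(ndims = 3), hypernet_config(1))
  expect_equal(count_parameters(model), 31168 + 129 * 313507)
  # one linear layer, input 1 -> N: N weights + N biases
  theta <- hyperreg:::init_hypernet_theta(hypernet_config(1, integer(0)), 5)
  expect_equal(count_parameters(list(theta = theta)), 10)
})

test_that("hypernetwork weight sharing couples all hyperparameter inputs", {
  set.seed(29)
  model <- hyper_model(tiny_unet(), hypernet_config(1, c(8, 8)))
  w1 <- hypernetwork_forward(0.2, model)
  w2 <- hypernetwork_forward(0.8, model)
  model2 <- model
  model2$theta[[1]]$W <- model2$theta[[1]]$W + 0.05
  # perturbing shared parameters moves the outputs for every input
  expect_gt(sum(abs(hypernetwork_forward(0.2, model2) - w1)), 0)
  expect_gt(sum(abs(hypernetwork_forward(0.8, model2) - w2)), 0)
})

test_that("conditional architectures wire the hyperparameter input as specified", {
  cfg <- unet_config(ndims = 2, enc_channels = c(4, 8, 8, 8),
                     dec_channels = c(8, 8, 8, 8, 8, 4, 4))
  set.seed(30)
  full <- build_conditional_net("full_integrative", cfg)
  # head emits one scalar per convolutional output channel (enumeration)
  expect_equal(hyperreg:::conditional_head_dim(full),
               sum(c(4, 8, 8, 8), c(8, 8, 8, 8, 8, 4, 4), 2))
  pre <- build_conditional_net("pre_integrative", cfg, cond_channels = 32)
  expect_equal(pre$spec$entries[[1]]$shape[3], 2L + 32L)
  expect_error(build_conditional_net("mid_integrative", cfg))
  # fixed hyperparameters give a deterministic function of (m, f)
  m <- smooth_image(32, seed = 31)
  f <- smooth_image(32, seed = 32)
  for (variant in c("pre_integrative", "post_integrative", "full_integrative")) {
    set.seed(33)
    net <- build_conditional_net(variant, cfg)
    v1 <- conditional_forward(net, m, f, 0.5)
    v2 <- conditional_forward(net, m, f, 0.5)
    expect_identical(as.numeric(v1), as.numeric(v2))
    expect_equal(dim(v1), c(32L, 32L, 2L))
  }
})
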