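# Test-time hyperparameter optimization with frozen hypernetwork
# parameters, and dense sweep tables for interactive-style exploration.

#' Assemble a validation set
#'
#' @param pairs List of pairs with elements `m`, `f`, `s_m`, `s_f`.
#' @param loss Validation loss: currently `"dice"` (1 - mean soft Dice over
#'   the labels present).
#' @param labels Optional label subset used by the validation loss.
#' @return An object of class `validation_set`.
#' @export
validation_set <- function(pairs, loss = "dice", labels = NULL) {
  loss <- match.arg(loss, "dice")
  for (p in pairs) {
    if (is.null(p$s_m) || is.null(p$s_f))
      hr_stop("config", "label-based validation loss needs labelled pairs")
  }
  structure(list(pairs = pairs, loss = loss, labels = labels),
            class = "validation_set")
}

# validation loss value and d(loss)/d(normalized hyperparameter input) for a
# fixed hyperparameter input vector; hypernetwork parameters untouched
val_loss_grad <- function(model, val, lam_vec, int_steps = 5L,
                          want_grad = TRUE) {
  fw <- hypernet_fw(lam_vec, model)
  total <- 0
  gin <- numeric(length(lam_vec))
  for (p in val$pairs) {
    st <- unet_forward(p$m, p$f, fw$out, model$unet_config,
                       keep_cache = want_grad)
    dm <- dim(st$v)
    ctx <- integrate_svf_cache(st$v, int_steps)
    labels <- val$labels
    if (is.null(labels))
      labels <- sort(union(attr(as_labelmap(p$s_m), "label_set"),
                           attr(as_labelmap(p$s_f), "label_set")))
    sm_hot <- one_hot(p$s_m, labels)
    sf_hot <- one_hot(p$s_f, labels)
    sm_w <- warp_channels2(sm_hot, ctx$u)
    total <- total + soft_dice_loss(sf_hot, sm_w)
    if (want_grad) {
      gseg <- soft_dice_loss_grad(sf_hot, sm_w)
      bw <- sample2_linear_bw(as.numeric(sm_hot), dm[1], dm[2],
                              dim(sm_hot)[3], as.numeric(ctx$u),
                              as.numeric(gseg))
      gv <- integrate_svf_bw(ctx, array(bw$gdisp, dim = dm))
      gw <- unet_backward(st, gv)
      gin <- gin + hypernet_bw(model, fw, gw)$ginput
    }
  }
  list(value = total / length(val$pairs), ginput = gin / length(val$pairs))
}

#' Gradient-based test-time hyperparameter optimization
#'
#' Freezes the hypernetwork parameters and performs gradient descent on the
#' normalized hyperparameter input alone, minimizing the validation loss
#' over the validation pairs. The input is reparameterized through a
#' sigmoid so it always respects `[0, 1]`.
#'
#' @param model A trained [hyper_model()] (left bit-identical).
#' @param val A [validation_set()].
#' @param init Initial hyperparameter vector in `[0, 1]^d`.
#' @param steps Optimization steps (Adam on the logit).
#' @param lr Learning rate in logit space.
#' @param int_steps Scaling-and-squaring steps.
#' @return List: `lambda_star` (optimum in `[0, 1]^d`), `trajectory` (data
#'   frame of per-step hyperparameter values and losses), `value` (final
#'   validation loss).
#' @export
optimize_hyperparameters <- function(model, val, init = 0.5, steps = 60,
                                     lr = 0.25, int_steps = 5L) {
  d <- model$hypernet_config$input_dim
  init <- rep_len(as.numeric(init), d)
  if (any(init < 0 | init > 1))
    hr_stop("value", "init must lie in [0, 1]")
  z <- stats::qlogis(pmin(pmax(init, 1e-3), 1 - 1e-3))
  st <- adam_new(d)
  traj <- list(step = integer(steps), loss = numeric(steps))
  lam_hist <- matrix(0, nrow = steps, ncol = d)
  best <- list(value = Inf, lam = init)
  for (s in seq_len(steps)) {
    lam <- stats::plogis(z)
    vg <- val_loss_grad(model, val, lam, int_steps)
    if (vg$value < best$value) best <- list(value = vg$value, lam = lam)
    gz <- vg$ginput * lam * (1 - lam)   # chain through the sigmoid
    upd <- adam_step(st, z, gz, lr)
    z <- upd$theta; st <- upd$state
    traj$step[s] <- s
    traj$loss[s] <- vg$value
    lam_hist[s, ] <- lam
  }
  lam <- stats::plogis(z)
  vg <- val_loss_grad(model, val, lam, int_steps, want_grad = FALSE)
  if (vg$value < best$value) best <- list(value = vg$value, lam = lam)
  traj <- as.data.frame(traj)
  for (j in seq_len(d)) traj[[paste0("lambda", j)]] <- lam_hist[, j]
  list(lambda_star = best$lam, value = best$value, trajectory = traj)
}

#' Dense hyperparameter sweep
#'
#' Registers every pair at every hyperparameter value in `grid` and reports
#' evaluation metrics per (pair, value): the deterministic table behind
#' interactive slider-style exploration.
#'
#' @param model A trained [hyper_model()].
#' @param pairs List of pairs (`m`, `f`, optionally `s_m`, `s_f`).
#' @param grid Numeric vector of lambda values in `[0, 1]`, or a list of
#'   normalized input vectors for multi-hyperparameter models.
#' @param metrics Character subset of `c("dice", "sd95", "jac_sd")`.
#' @param int_steps Scaling-and-squaring steps.
#' @return Data frame with one row per (pair, grid value).
#' @export
sweep_hyper <- function(model, pairs, grid,
                        metrics = c("dice", "jac_sd"), int_steps = 5L) {
  if (length(grid) < 1L) hr_stop("value", "grid must be non-empty")
  metrics <- match.arg(metrics, c("dice", "sd95", "jac_sd"),
                       several.ok = TRUE)
  if (!is.list(grid)) grid <- as.list(grid)
  rows <- list()
  for (gi in seq_along(grid)) {
    lam_vec <- rep_len(as.numeric(grid[[gi]]),
                       model$hypernet_config$input_dim)
    w <- hypernetwork_forward(lam_vec, model)
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      v <- registration_forward(p$m, p$f, w, model$unet_config)
      phi <- integrate_svf(v, int_steps)
      row <- list(pair = pi, lambda = lam_vec[1])
      if (length(lam_vec) > 1)
        for (j in 2:length(lam_vec)) row[[paste0("hyper", j)]] <- lam_vec[j]
      if ("dice" %in% metrics && !is.null(p$s_m)) {
        sm_w <- warp(as_labelmap(p$s_m), phi, mode = "nearest")
        row$dice <- mean(dice_score(p$s_f, sm_w), na.rm = TRUE)
      }
      if ("sd95" %in% metrics && !is.null(p$s_m)) {
        sm_w <- warp(as_labelmap(p$s_m), phi, mode = "nearest")
        labs <- intersect(attr(as_labelmap(p$s_f), "label_set"),
                          attr(sm_w, "label_set"))
        row$sd95 <- mean(vapply(labs, function(l)
          surface_distance_95(p$s_f, sm_w, l), numeric(1)))
      }
      if ("jac_sd" %in% metrics) row$jac_sd <- jacobian_sd(phi)
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, rows)
}
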