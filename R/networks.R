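# Registration U-Net (weights supplied externally as a flat vector), the
# hypernetwork that emits those weights from hyperparameter inputs, and the
# conditional alternative architectures that feed hyperparameters into the
# registration network directly.

#' Registration U-Net configuration
#'
#' Four encoder convolutions (each followed by 2x max pooling), seven
#' decoder convolutions with four nearest-neighbour upsamplings, kernel
#' size 3, LeakyReLU(0.2) activations, and a final linearly activated
#' convolution emitting one velocity channel per spatial axis. Skip
#' connections concatenate the three deepest encoder outputs (at 1/2, 1/4
#' and 1/8 resolution) after the first three upsamplings; the
#' full-resolution encoder output is not concatenated.
#'
#' @param ndims Spatial dimensionality, 2 or 3.
#' @param enc_channels Encoder channels (length 4), default `c(16,32,32,32)`.
#' @param dec_channels Decoder channels (length 7),
#'   default `c(32,32,32,32,32,16,16)`.
#' @param in_channels Input channels (moving + fixed concatenated).
#' @param kernel Convolution kernel edge length (odd).
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param pool Pooling / upsampling factor.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(ndims = 3, enc_channels = c(16, 32, 32, 32),
                        dec_channels = c(32, 32, 32, 32, 32, 16, 16),
                        in_channels = 2, kernel = 3, leaky_slope = 0.2,
                        pool = 2) {
  if (!(ndims %in% c(2, 3))) hr_stop("config", "ndims must be 2 or 3")
  if (length(enc_channels) != 4L)
    hr_stop("config", "enc_channels must list 4 encoder convolutions")
  if (length(dec_channels) != 7L)
    hr_stop("config", "dec_channels must list 7 decoder convolutions")
  if (kernel %% 2 != 1) hr_stop("config", "kernel must be odd")
  structure(list(ndims = as.integer(ndims),
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 in_channels = as.integer(in_channels),
                 kernel = as.integer(kernel),
                 leaky_slope = leaky_slope, pool = as.integer(pool),
                 out_channels = as.integer(ndims)),
            class = "unet_config")
}

# ordered (cin, cout) table of every convolution, encoder -> decoder -> final
unet_channel_table <- function(config, extra_in = 0L, post_extra = 0L) {
  enc <- config$enc_channels; dec <- config$dec_channels
  data.frame(
    name = c(paste0("enc", 1:4), paste0("dec", 1:7), "svf"),
    cin = c(config$in_channels + extra_in, enc[1], enc[2], enc[3],
            enc[4],                 # dec1 consumes the deepest pooled output
            dec[1] + enc[4],        # after up 1: skip at 1/8
            dec[2] + enc[3],        # after up 2: skip at 1/4
            dec[3] + enc[2],        # after up 3: skip at 1/2
            dec[4] + post_extra,    # after final up: no skip
            dec[5], dec[6], dec[7]),
    cout = c(enc, dec, config$out_channels),
    stringsAsFactors = FALSE)
}

#' Parameter count of a single convolution layer
#'
#' `kernel^ndims * cin * cout` kernel elements plus `cout` biases.
#'
#' @param kernel Kernel edge length.
#' @param ndims Spatial dimensionality.
#' @param cin,cout Input and output channel counts.
#' @return Integer parameter count.
#' @export
conv_param_count <- function(kernel, ndims, cin, cout) {
  as.integer(kernel^ndims * cin * cout + cout)
}

#' Build the ordered weight manifest of the registration U-Net
#'
#' Produces the deterministic list of every convolution kernel and bias in
#' traversal order (encoder, then decoder, then the final velocity-field
#' convolution), together with the total trainable parameter count. The
#' stated 3D configuration yields 313,507 parameters.
#'
#' @param config A [unet_config()].
#' @return An object of class `weight_spec`: list with `entries` (each a
#'   list with `name`, `shape`, `role`) and `total_count`.
#' @export
build_weight_spec <- function(config) {
  if (!inherits(config, "unet_config"))
    hr_stop("config", "config must be a unet_config")
  tab <- unet_channel_table(config,
                            extra_in = config$extra_in %||% 0L,
                            post_extra = config$post_extra %||% 0L)
  k <- config$kernel
  entries <- list()
  for (i in seq_len(nrow(tab))) {
    kshape <- c(rep(k, config$ndims), tab$cin[i], tab$cout[i])
    entries[[length(entries) + 1L]] <-
      list(name = paste0(tab$name[i], ".kernel"), shape = kshape,
           role = "kernel")
    entries[[length(entries) + 1L]] <-
      list(name = paste0(tab$name[i], ".bias"), shape = tab$cout[i],
           role = "bias")
  }
  total <- sum(vapply(entries, function(e) prod(e$shape), numeric(1)))
  structure(list(entries = entries, total_count = as.integer(total),
                 ndims = config$ndims),
            class = "weight_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.weight_spec <- function(x, ...) {
  cat("<weight_spec>", length(x$entries), "tensors,", x$total_count,
      "parameters\n")
  invisible(x)
}

# flat vector -> named list of shaped arrays, in manifest order
unpack_weights <- function(wvec, spec) {
  if (length(wvec) != spec$total_count)
    hr_stop("spec", sprintf("weight vector length %d does not match spec (%d)",
                            length(wvec), spec$total_count))
  out <- vector("list", length(spec$entries))
  names(out) <- vapply(spec$entries, `[[`, "", "name")
  pos <- 0L
  for (i in seq_along(spec$entries)) {
    n <- prod(spec$entries[[i]]$shape)
    out[[i]] <- array(wvec[(pos + 1):(pos + n)],
                      dim = spec$entries[[i]]$shape)
    pos <- pos + n
  }
  out
}

pack_weights <- function(wlist, spec) {
  v <- unlist(lapply(wlist, as.numeric), use.names = FALSE)
  if (length(v) != spec$total_count)
    hr_stop("spec", "weight list does not match spec")
  v
}

#' Initialize a registration weight vector
#'
#' Fan-in-scaled (He) random kernels with zero biases; the final
#' velocity-field convolution is drawn with a much smaller scale so the
#' initial deformation is near identity.
#'
#' @param spec A [build_weight_spec()] manifest.
#' @param final_sd Standard deviation of the final convolution kernel.
#' @return Flat numeric weight vector of length `spec$total_count`.
#' @export
init_weight_vector <- function(spec, final_sd = 1e-5) {
  n_ent <- length(spec$entries)
  parts <- vector("list", n_ent)
  for (i in seq_len(n_ent)) {
    e <- spec$entries[[i]]
    if (e$role == "bias") {
      parts[[i]] <- rep(0, prod(e$shape))
    } else {
      fan_in <- prod(e$shape[-length(e$shape)])
      sd <- if (i >= n_ent - 1L) final_sd else sqrt(2 / fan_in)
      parts[[i]] <- rnorm(prod(e$shape), 0, sd)
    }
  }
  unlist(parts, use.names = FALSE)
}

# -- 2D U-Net forward / backward -------------------------------------------

lrelu <- function(x, slope) array(lrelu_fwc(x, slope), dim = dim(x))
lrelu_bw <- function(y, g, slope) array(lrelu_bwc(y, g, slope), dim = dim(y))

conv_fw2 <- function(x, kern, bias, act_slope = NULL) {
  dm <- dim(x); kd <- dim(kern)
  y <- conv2d_fw(x, dm[1], dm[2], kd[3], kern, bias, kd[4], kd[1])
  y <- array(y, dim = c(dm[1], dm[2], kd[4]))
  if (!is.null(act_slope)) y <- lrelu(y, act_slope)
  y
}

#' Evaluate the registration network
#'
#' Runs the registration U-Net with an externally supplied flat weight
#' vector on a concatenated (moving, fixed) pair and returns the stationary
#' velocity field on the full-resolution grid. Forward evaluation is
#' implemented for 2D grids whose axes are divisible by `pool^4`.
#'
#' @param m,f Moving and fixed images on a shared 2D grid.
#' @param weights Flat weight vector matching `build_weight_spec(config)`.
#' @param config A [unet_config()] with `ndims = 2`.
#' @return An [as_velocity()] field.
#' @export
registration_forward <- function(m, f, weights, config) {
  st <- unet_forward(m, f, weights, config, keep_cache = FALSE)
  as_velocity(st$v)
}

unet_forward <- function(m, f, weights, config, keep_cache = TRUE,
                         cond_pre = NULL, cond_post = NULL, offsets = NULL) {
  if (config$ndims != 2L)
    hr_stop("config", "network evaluation is implemented for ndims = 2")
  ma <- as_grid_array(m); fa <- as_grid_array(f)
  check_same_grid(ma, fa, "moving and fixed images")
  dmv <- dim(ma)
  if (any(dmv %% config$pool^4 != 0))
    hr_stop("shape", "grid axes must be divisible by pool^4")
  spec <- build_weight_spec(config)
  wl <- unpack_weights(weights, spec)
  sl <- config$leaky_slope
  H <- dmv[1]; W <- dmv[2]
  x0 <- array(c(ma, fa), dim = c(H, W, 2))
  if (!is.null(cond_pre)) {
    x0 <- array(c(x0, cond_pre), dim = c(H, W, 2 + dim(cond_pre)[3]))
  }
  off <- function(li, y) {
    if (is.null(offsets)) return(y)
    sweep(y, 3, offsets[[li]], `+`)
  }
  cache <- list(x0 = x0)
  # encoder
  xs <- list(); ps <- list(); pidx <- list()
  xin <- x0
  for (i in 1:4) {
    pre <- off(i, conv_fw2(xin, wl[[2 * i - 1]], wl[[2 * i]]))
    xs[[i]] <- lrelu(pre, sl)
    d <- dim(xs[[i]])
    mp <- maxpool2_fw(xs[[i]], d[1], d[2], d[3])
    ps[[i]] <- array(mp$y, dim = c(d[1] / 2, d[2] / 2, d[3]))
    pidx[[i]] <- mp$idx
    xin <- ps[[i]]
  }
  cache$xs <- xs; cache$ps <- ps; cache$pidx <- pidx
  wof <- function(li) wl[[2 * li - 1]]   # kernel of conv index li (1..12)
  bof <- function(li) wl[[2 * li]]
  ys <- list(); cs <- list()
  # dec1 on the deepest pooled output
  ys[[1]] <- lrelu(off(5, conv_fw2(ps[[4]], wof(5), bof(5))), sl)
  up <- function(x) {
    d <- dim(x)
    array(upsample2_fw(x, d[1], d[2], d[3]),
          dim = c(2 * d[1], 2 * d[2], d[3]))
  }
  cat3 <- function(a, b) array(c(a, b), dim = c(dim(a)[1], dim(a)[2],
                                                dim(a)[3] + dim(b)[3]))
  cs[[1]] <- cat3(up(ys[[1]]), xs[[4]])
  ys[[2]] <- lrelu(off(6, conv_fw2(cs[[1]], wof(6), bof(6))), sl)
  cs[[2]] <- cat3(up(ys[[2]]), xs[[3]])
  ys[[3]] <- lrelu(off(7, conv_fw2(cs[[2]], wof(7), bof(7))), sl)
  cs[[3]] <- cat3(up(ys[[3]]), xs[[2]])
  ys[[4]] <- lrelu(off(8, conv_fw2(cs[[3]], wof(8), bof(8))), sl)
  y4in <- ys[[4]]
  if (!is.null(cond_post)) y4in <- cat3(y4in, cond_post)
  cs[[4]] <- up(y4in)
  ys[[5]] <- lrelu(off(9, conv_fw2(cs[[4]], wof(9), bof(9))), sl)
  ys[[6]] <- lrelu(off(10, conv_fw2(ys[[5]], wof(10), bof(10))), sl)
  ys[[7]] <- lrelu(off(11, conv_fw2(ys[[6]], wof(11), bof(11))), sl)
  v <- off(12, conv_fw2(ys[[7]], wof(12), bof(12)))
  cache$ys <- ys; cache$cs <- cs
  st <- list(v = v, spec = spec, config = config)
  if (keep_cache) { st$cache <- cache; st$wl <- wl }
  st
}

# backward: gradient of a scalar loss w.r.t. the flat weight vector, given
# the gradient gv on the emitted velocity field
unet_backward <- function(st, gv) {
  config <- st$config; wl <- st$wl; cache <- st$cache
  sl <- config$leaky_slope
  gw <- vector("list", length(wl))
  conv_bw2 <- function(x, kern, g) {
    dm <- dim(x); kd <- dim(kern)
    r <- conv2d_bw(x, dm[1], dm[2], kd[3], kern, kd[4], kd[1], g)
    list(gx = array(r$gx, dim = dm), gw = array(r$gw, dim = kd), gb = r$gb)
  }
  down <- function(g, d_in) {
    array(upsample2_bw(g, d_in[1], d_in[2], d_in[3]), dim = d_in)
  }
  split3 <- function(g, c1) {
    d <- dim(g)
    list(a = array(g[, , seq_len(c1)], dim = c(d[1], d[2], c1)),
         b = array(g[, , (c1 + 1):d[3]], dim = c(d[1], d[2], d[3] - c1)))
  }
  ys <- cache$ys; cs <- cache$cs; xs <- cache$xs; ps <- cache$ps
  # final conv (linear)
  r <- conv_bw2(ys[[7]], wl[[23]], gv)
  gw[[23]] <- r$gw; gw[[24]] <- r$gb
  g <- lrelu_bw(ys[[7]], r$gx, sl)
  r <- conv_bw2(ys[[6]], wl[[21]], g); gw[[21]] <- r$gw; gw[[22]] <- r$gb
  g <- lrelu_bw(ys[[6]], r$gx, sl)
  r <- conv_bw2(ys[[5]], wl[[19]], g); gw[[19]] <- r$gw; gw[[20]] <- r$gb
  g <- lrelu_bw(ys[[5]], r$gx, sl)
  r <- conv_bw2(cs[[4]], wl[[17]], g); gw[[17]] <- r$gw; gw[[18]] <- r$gb
  g <- down(r$gx, dim(ys[[4]]))                       # through final upsample
  g <- lrelu_bw(ys[[4]], g, sl)
  r <- conv_bw2(cs[[3]], wl[[15]], g); gw[[15]] <- r$gw; gw[[16]] <- r$gb
  sp <- split3(r$gx, dim(ys[[3]])[3])
  gskip2 <- sp$b                                       # -> xs[[2]]
  g <- lrelu_bw(ys[[3]], down(sp$a, dim(ys[[3]])), sl)
  r <- conv_bw2(cs[[2]], wl[[13]], g); gw[[13]] <- r$gw; gw[[14]] <- r$gb
  sp <- split3(r$gx, dim(ys[[2]])[3])
  gskip3 <- sp$b                                       # -> xs[[3]]
  g <- lrelu_bw(ys[[2]], down(sp$a, dim(ys[[2]])), sl)
  r <- conv_bw2(cs[[1]], wl[[11]], g); gw[[11]] <- r$gw; gw[[12]] <- r$gb
  sp <- split3(r$gx, dim(ys[[1]])[3])
  gskip4 <- sp$b                                       # -> xs[[4]]
  g <- lrelu_bw(ys[[1]], down(sp$a, dim(ys[[1]])), sl)
  r <- conv_bw2(ps[[4]], wl[[9]], g); gw[[9]] <- r$gw; gw[[10]] <- r$gb
  gp <- r$gx                                           # grad on ps[[4]]
  gsk <- list(NULL, gskip2, gskip3, gskip4)
  for (i in 4:1) {
    d <- dim(xs[[i]])
    gx <- array(maxpool2_bw(cache$pidx[[i]], gp,
                            d[1], d[2], d[3]), dim = d)
    if (!is.null(gsk[[i]])) gx <- gx + gsk[[i]]
    gx <- lrelu_bw(xs[[i]], gx, sl)
    xin <- if (i == 1) cache$x0 else ps[[i - 1]]
    r <- conv_bw2(xin, wl[[2 * i - 1]], gx)
    gw[[2 * i - 1]] <- r$gw; gw[[2 * i]] <- r$gb
    gp <- r$gx
  }
  unlist(lapply(gw, as.numeric), use.names = FALSE)
}

# -- hypernetwork -----------------------------------------------------------

#' Hypernetwork configuration
#'
#' A fully connected network: five hidden layers of 32, 64, 64, 128 and 128
#' ReLU units by default, followed by a linear output layer with one unit
#' per registration-network parameter.
#'
#' @param input_dim Number of (normalized) hyperparameter inputs.
#' @param hidden_units Hidden layer widths.
#' @return An object of class `hypernet_config`.
#' @export
hypernet_config <- function(input_dim = 1,
                            hidden_units = c(32, 64, 64, 128, 128)) {
  if (input_dim < 1) hr_stop("config", "input_dim must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units)),
            class = "hypernet_config")
}

init_hypernet_theta <- function(hcfg, out_dim, final_gain = 1e-2,
                                final_bias = NULL) {
  dims <- c(hcfg$input_dim, hcfg$hidden_units, out_dim)
  nl <- length(dims) - 1L
  theta <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- dims[l]
    sd <- if (l == nl) final_gain / sqrt(fan_in) else sqrt(2 / fan_in)
    theta[[l]] <- list(W = matrix(rnorm(dims[l] * dims[l + 1], 0, sd),
                                  nrow = dims[l]),
                       b = rep(0, dims[l + 1]))
  }
  # variance-preserving hypernetwork start: the final-layer bias carries a
  # conventional (fan-in-scaled) registration init, so the emitted weights
  # begin at ordinary scale while the input-dependent part starts small
  if (!is.null(final_bias)) theta[[nl]]$b <- final_bias
  theta
}

#' Build a hypernetwork-amortized registration model
#'
#' Couples a hypernetwork to the weight manifest of a registration U-Net:
#' the hypernetwork maps a `[0, 1]`-normalized hyperparameter vector to the
#' full flat weight vector of the registration network. All trainable
#' parameters live in the hypernetwork; hidden layers use fan-in-scaled
#' random initialization, the final layer weights use a small gain, and the
#' final-layer bias carries a conventional registration-network init, so
#' the emitted registration weights start at ordinary scale for every
#' hyperparameter value.
#'
#' @param unet A [unet_config()].
#' @param hyper A [hypernet_config()].
#' @param norm_meta Optional list describing how natural-unit
#'   hyperparameters map onto the input vector (stored with checkpoints).
#' @return An object of class `hyper_model`.
#' @export
hyper_model <- function(unet = unet_config(), hyper = hypernet_config(),
                        norm_meta = NULL) {
  spec <- build_weight_spec(unet)
  theta <- init_hypernet_theta(hyper, spec$total_count,
                               final_bias = init_weight_vector(spec))
  structure(list(unet_config = unet, hypernet_config = hyper, spec = spec,
                 theta = theta, norm_meta = norm_meta, version = "1"),
            class = "hyper_model")
}

#' @export
print.hyper_model <- function(x, ...) {
  cat("<hyper_model> ", x$hypernet_config$input_dim, " hyperparameter(s) -> ",
      x$spec$total_count, " registration weights | ",
      format(count_parameters(x), big.mark = ","),
      " trainable hypernetwork parameters\n", sep = "")
  invisible(x)
}

#' Emit registration weights for given hyperparameter values
#'
#' @param lambda_vec Normalized hyperparameter vector, each component in
#'   `[0, 1]`, of length `input_dim`.
#' @param model A [hyper_model()].
#' @return Flat weight vector of length `spec$total_count`.
#' @export
hypernetwork_forward <- function(lambda_vec, model) {
  hypernet_fw(lambda_vec, model)$out
}

hypernet_fw <- function(lambda_vec, model) {
  lambda_vec <- as.numeric(lambda_vec)
  if (length(lambda_vec) != model$hypernet_config$input_dim)
    hr_stop("value", "hyperparameter vector length must equal input_dim")
  if (any(lambda_vec < 0 | lambda_vec > 1) || any(!is.finite(lambda_vec)))
    hr_stop("value", "normalized hyperparameters must lie in [0, 1]")
  theta <- model$theta
  nl <- length(theta)
  acts <- vector("list", nl + 1L)
  acts[[1]] <- lambda_vec
  h <- lambda_vec
  for (l in seq_len(nl)) {
    a <- drop(crossprod(theta[[l]]$W, h)) + theta[[l]]$b
    if (l < nl) a <- pmax(a, 0)
    acts[[l + 1]] <- a
    h <- a
  }
  list(out = h, acts = acts)
}

# gradient of a scalar loss w.r.t. hypernetwork parameters and the input,
# given the gradient g_out on the emitted weight vector
hypernet_bw <- function(model, fw, g_out) {
  theta <- model$theta
  nl <- length(theta)
  gtheta <- vector("list", nl)
  g <- as.numeric(g_out)
  for (l in rev(seq_len(nl))) {
    if (l < nl) g <- g * (fw$acts[[l + 1]] > 0)
    h_prev <- fw$acts[[l]]
    gtheta[[l]] <- list(W = tcrossprod(h_prev, g), b = g)
    g <- drop(theta[[l]]$W %*% g)
  }
  list(gtheta = gtheta, ginput = g)
}

#' Count trainable parameters of a hyper model
#'
#' All trainable scalars live in the hypernetwork; the registration weights
#' are emitted, not trained.
#'
#' @param model A [hyper_model()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$theta, function(l) length(l$W) + length(l$b), numeric(1)))
}

# flat view of theta (checksums, Adam); order: per layer W then b
theta_to_vec <- function(theta) {
  unlist(lapply(theta, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

vec_to_theta <- function(v, theta_template) {
  pos <- 0L
  out <- theta_template
  for (l in seq_along(out)) {
    nw <- length(out[[l]]$W); nb <- length(out[[l]]$b)
    out[[l]]$W <- matrix(v[(pos + 1):(pos + nw)], nrow = nrow(out[[l]]$W))
    pos <- pos + nw
    out[[l]]$b <- v[(pos + 1):(pos + nb)]
    pos <- pos + nb
  }
  out
}

theta_checksum <- function(model) {
  v <- theta_to_vec(model$theta)
  c(sum = sum(v), sumsq = sum(v^2), n = length(v))
}

# -- conditional alternative architectures ---------------------------------

#' Build a conditional registration network
#'
#' Alternative architectures that feed hyperparameters into the
#' registration network itself instead of using a hypernetwork:
#' \describe{
#'   \item{pre_integrative}{hyperparameters are repeated into an 8x8
#'     multi-channel volume, passed through six 32-channel convolutions with
#'     interleaved upsampling to the image resolution, and concatenated to
#'     the U-Net input.}
#'   \item{post_integrative}{as above, but the conditioning output is
#'     concatenated to the input of the final upsampling layer.}
#'   \item{full_integrative}{a fully connected stack (five layers of 256
#'     ReLU units, linear head) emits one scalar per convolutional output
#'     channel of the U-Net, added per channel.}
#' }
#'
#' @param variant One of `"pre_integrative"`, `"post_integrative"`,
#'   `"full_integrative"`.
#' @param config A [unet_config()] (2D for forward evaluation).
#' @param input_dim Number of hyperparameter inputs.
#' @param cond_channels Channels of each conditioning convolution.
#' @return An object of class `conditional_net`.
#' @export
build_conditional_net <- function(variant, config, input_dim = 1,
                                  cond_channels = 32) {
  variant <- match.arg(variant, c("pre_integrative", "post_integrative",
                                  "full_integrative"))
  extra_in <- if (variant == "pre_integrative") cond_channels else 0L
  post_extra <- if (variant == "post_integrative") cond_channels else 0L
  ucfg <- config
  ucfg$extra_in <- as.integer(extra_in)
  ucfg$post_extra <- as.integer(post_extra)
  spec <- build_weight_spec(ucfg)
  weights <- init_weight_vector(spec)
  cond <- if (variant == "full_integrative") {
    tab <- unet_channel_table(config)
    out_dim <- sum(tab$cout)
    dims <- c(input_dim, rep(256L, 5), out_dim)
    lapply(seq_len(length(dims) - 1L), function(l) {
      sd <- if (l == length(dims) - 1L) 1e-2 / sqrt(dims[l]) else sqrt(2 / dims[l])
      list(W = matrix(rnorm(dims[l] * dims[l + 1], 0, sd), nrow = dims[l]),
           b = rep(0, dims[l + 1]))
    })
  } else {
    # six conv layers on an 8x8 seed volume, cond_channels each
    cins <- c(input_dim, rep(cond_channels, 5))
    lapply(seq_len(6), function(l) {
      k <- config$kernel
      fan_in <- k^2 * cins[l]
      list(kern = array(rnorm(k * k * cins[l] * cond_channels, 0,
                              sqrt(2 / fan_in)),
                        dim = c(k, k, cins[l], cond_channels)),
           bias = rep(0, cond_channels))
    })
  }
  structure(list(variant = variant, unet_config = ucfg, base_config = config,
                 spec = spec, weights = weights, cond = cond,
                 input_dim = as.integer(input_dim),
                 cond_channels = as.integer(cond_channels)),
            class = "conditional_net")
}

# per-channel offset vector length of the full-integrative head
conditional_head_dim <- function(net) {
  if (net$variant != "full_integrative")
    hr_stop("value", "head dimension is defined for the full-integrative variant")
  ncol(net$cond[[length(net$cond)]]$W)
}

# run the conditioning conv stack from the 8x8 seed up to target_hw
cond_stack_fw <- function(net, lam_vec, target_hw) {
  x <- array(rep(lam_vec, each = 64), dim = c(8, 8, length(lam_vec)))
  for (l in seq_along(net$cond)) {
    x <- conv_fw2(x, net$cond[[l]]$kern, net$cond[[l]]$bias,
                  act_slope = net$base_config$leaky_slope)
    d <- dim(x)
    if (d[1] < target_hw[1]) {
      x <- array(upsample2_fw(x, d[1], d[2], d[3]),
                 dim = c(2 * d[1], 2 * d[2], d[3]))
    }
  }
  if (!identical(dim(x)[1:2], as.integer(target_hw)))
    hr_stop("shape", "conditioning stack cannot reach the target resolution")
  x
}

#' Evaluate a conditional registration network
#'
#' @param net A [build_conditional_net()] model.
#' @param m,f Moving and fixed 2D images.
#' @param lam_vec Normalized hyperparameter vector in `[0, 1]`.
#' @return An [as_velocity()] field.
#' @export
conditional_forward <- function(net, m, f, lam_vec) {
  lam_vec <- as.numeric(lam_vec)
  if (length(lam_vec) != net$input_dim ||
      any(lam_vec < 0 | lam_vec > 1))
    hr_stop("value", "hyperparameters must be a [0,1] vector of length input_dim")
  dmv <- dim(as_grid_array(m))
  st <- switch(net$variant,
    pre_integrative = {
      cp <- cond_stack_fw(net, lam_vec, dmv)
      unet_forward(m, f, net$weights, net$unet_config, keep_cache = FALSE,
                   cond_pre = cp)
    },
    post_integrative = {
      cp <- cond_stack_fw(net, lam_vec, dmv / 2)
      unet_forward(m, f, net$weights, net$unet_config, keep_cache = FALSE,
                   cond_post = cp)
    },
    full_integrative = {
      h <- lam_vec
      nl <- length(net$cond)
      for (l in seq_len(nl)) {
        h <- drop(crossprod(net$cond[[l]]$W, h)) + net$cond[[l]]$b
        if (l < nl) h <- pmax(h, 0)
      }
      tab <- unet_channel_table(net$base_config)
      offs <- split(h, rep(seq_len(nrow(tab)), tab$cout))
      unet_forward(m, f, net$weights, net$unet_config, keep_cache = FALSE,
                   offsets = offs)
    })
  as_velocity(st$v)
}
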