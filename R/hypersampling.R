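# Hyperparameter priors, endpoint over-sampling, and normalization of
# discrete hyperparameters to the [0, 1] hypernetwork input range.

#' Define a hyperparameter prior
#'
#' Describes the training-time distribution of the loss hyperparameters: the
#' continuous regularization weight `lambda ~ U(0, 1)` with an optional
#' endpoint over-sampling rate `r` (a fraction `r` of draws is placed
#' exactly at `{0, 1}`, split equally), an optional continuous
#' semi-supervision weight `gamma ~ U(0, 1)`, and an optional discrete
#' similarity hyperparameter (local-NCC window size or MI bin count) drawn
#' uniformly from an ordered value list and normalized to `[0, 1]`.
#'
#' @param endpoint_rate Fraction `r` in `[0, 1]` of lambda draws taken from
#'   the endpoint distribution on `{0, 1}` (default 0.2).
#' @param lam_range Support of the continuous lambda draw (default the full
#'   `c(0, 1)`); a degenerate range `c(a, a)` fixes lambda, which makes
#'   hypernetwork training equivalent in expectation to a fixed-lambda
#'   baseline.
#' @param gamma If `TRUE`, also sample the semi-supervision weight gamma.
#' @param sim_values Optional ordered numeric vector of legal values for the
#'   discrete similarity hyperparameter (e.g. `c(3, 5, 7, 9, 11, 13, 15)`
#'   for 2D local-NCC windows), or `NULL`.
#' @param sigma Fixed noise estimate used to scale the MSE loss
#'   (default 0.05).
#' @return An object of class `hyper_prior`.
#' @export
hyper_prior <- function(endpoint_rate = 0.2, gamma = FALSE, sim_values = NULL,
                        sigma = 0.05, lam_range = c(0, 1)) {
  if (length(endpoint_rate) != 1L || endpoint_rate < 0 || endpoint_rate > 1)
    hr_stop("value", "endpoint_rate must lie in [0, 1]")
  if (length(lam_range) != 2L || lam_range[1] > lam_range[2] ||
      any(lam_range < 0 | lam_range > 1))
    hr_stop("value", "lam_range must be an ordered sub-interval of [0, 1]")
  if (!is.null(sim_values)) {
    if (length(sim_values) < 1L || is.unsorted(sim_values, strictly = TRUE))
      hr_stop("value", "sim_values must be a non-empty strictly increasing list")
  }
  if (sigma <= 0) hr_stop("value", "sigma must be positive")
  structure(list(endpoint_rate = endpoint_rate, gamma = isTRUE(gamma),
                 sim_values = sim_values, sigma = sigma,
                 lam_range = lam_range),
            class = "hyper_prior")
}

#' Draw one hyperparameter sample
#'
#' With probability `r` the continuous lambda is drawn from the endpoint set
#' `{0, 1}` (each with probability `r/2`), otherwise uniformly on `[0, 1]`.
#' Gamma (if enabled) is uniform on `[0, 1]` with no endpoint over-sampling.
#' A discrete similarity hyperparameter is drawn uniformly from its value
#' list and recorded both in natural units and normalized to `[0, 1]`.
#'
#' Draws use R's global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param prior A [hyper_prior()].
#' @return An object of class `hyper_sample`: a list with elements `lam`,
#'   `gamma` (or `NULL`), `sim` (natural units, or `NULL`), `sigma`, and
#'   `normalized_vec`, the `[0, 1]` vector fed to the hypernetwork.
#' @export
sample_hyper <- function(prior) {
  if (!inherits(prior, "hyper_prior"))
    hr_stop("value", "prior must be a hyper_prior object")
  lam <- if (runif(1) < prior$endpoint_rate) {
    if (runif(1) < 0.5) 0 else 1
  } else runif(1, prior$lam_range[1], prior$lam_range[2])
  gam <- if (prior$gamma) runif(1) else NULL
  sim <- sim_norm <- NULL
  if (!is.null(prior$sim_values)) {
    sim <- prior$sim_values[sample.int(length(prior$sim_values), 1L)]
    sim_norm <- normalize_discrete(sim, prior$sim_values)
  }
  new_hyper_sample(lam, gam, sim, prior$sim_values, prior$sigma)
}

new_hyper_sample <- function(lam, gamma = NULL, sim = NULL,
                             sim_values = NULL, sigma = 0.05) {
  vec <- lam
  if (!is.null(gamma)) vec <- c(vec, gamma)
  if (!is.null(sim)) {
    vec <- c(vec, if (is.null(sim_values)) sim
             else normalize_discrete(sim, sim_values))
  }
  if (any(vec < 0 | vec > 1))
    hr_stop("value", "normalized hyperparameters must lie in [0, 1]")
  structure(list(lam = lam, gamma = gamma, sim = sim,
                 sim_values = sim_values, sigma = sigma,
                 normalized_vec = vec),
            class = "hyper_sample")
}

#' Fix a hyperparameter sample at given values
#'
#' Convenience constructor for fixed-hyperparameter baselines, sweeps and
#' the `register` command: hyperparameters are given in natural units and
#' normalized internally.
#'
#' @param lam Regularization weight in `[0, 1]`.
#' @param gamma Optional semi-supervision weight in `[0, 1]`.
#' @param sim Optional discrete similarity hyperparameter in natural units.
#' @param sim_values Ordered legal values for `sim` (required for
#'   normalization when `sim` is given).
#' @param sigma Noise estimate for MSE scaling.
#' @return A `hyper_sample`.
#' @export
fixed_hyper <- function(lam, gamma = NULL, sim = NULL, sim_values = NULL,
                        sigma = 0.05) {
  if (lam < 0 || lam > 1) hr_stop("value", "lambda must lie in [0, 1]")
  if (!is.null(gamma) && (gamma < 0 || gamma > 1))
    hr_stop("value", "gamma must lie in [0, 1]")
  new_hyper_sample(lam, gamma, sim, sim_values, sigma)
}

#' Normalize a discrete hyperparameter value to [0, 1]
#'
#' Maps `value` to `(value - min) / (max - min)` over its ordered domain.
#'
#' @param value A value contained in `domain`.
#' @param domain Ordered (strictly increasing) numeric vector of legal values.
#' @return Normalized value in `[0, 1]`.
#' @seealso [denormalize_discrete()] for the inverse (nearest legal value).
#' @export
normalize_discrete <- function(value, domain) {
  if (length(domain) < 1L || is.unsorted(domain, strictly = TRUE))
    hr_stop("value", "domain must be strictly increasing")
  if (!value %in% domain)
    hr_stop("value", "value is not in the declared domain")
  if (length(domain) == 1L) return(0)
  (value - domain[1]) / (domain[length(domain)] - domain[1])
}

#' Map a continuous query in [0, 1] to the nearest legal discrete value
#'
#' @param x Normalized query in `[0, 1]`.
#' @param domain Ordered numeric vector of legal values.
#' @return The element of `domain` whose normalized position is closest to
#'   `x` (ties resolve to the smaller value).
#' @export
denormalize_discrete <- function(x, domain) {
  if (length(domain) == 1L) return(domain)
  pos <- (domain - domain[1]) / (domain[length(domain)] - domain[1])
  domain[which.min(abs(pos - x))]
}

#' @export
print.hyper_sample <- function(x, ...) {
  cat("<hyper_sample> lambda =", signif(x$lam, 4))
  if (!is.null(x$gamma)) cat(", gamma =", signif(x$gamma, 4))
  if (!is.null(x$sim)) cat(", sim =", x$sim)
  cat(", sigma =", x$sigma, "\n")
  invisible(x)
}
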