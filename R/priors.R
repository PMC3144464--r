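#' Mean prior variance of a marker effect
#'
#' Relates the additive-genetic variance explained jointly by all markers,
#' `sigma2_a_total`, to the variance of the effect of a single randomly
#' sampled marker, given that a marker is fitted with probability `1 - pi`:
#'
#' \deqn{\bar\sigma^2_a = \frac{\sigma^2_a}{(1-\pi)\sum_k 2 p_k (1-p_k)}}
#'
#' @param sigma2_a_total assumed additive-genetic variance explained by the
#'   markers.
#' @param pi prior probability that a marker has zero effect, in `[0, 1)`.
#' @param allele_freqs marker allele frequencies in `(0, 1)`.
#' @return the per-marker effect variance.
#' @export
mean_effect_variance <- function(sigma2_a_total, pi, allele_freqs) {
  if (pi < 0 || pi >= 1)
    stop("pi must lie in [0, 1)", call. = FALSE)
  het <- sum(2 * allele_freqs * (1 - allele_freqs))
  if (het <= 0)
    stop("all allele frequencies are fixed; per-marker variance undefined",
         call. = FALSE)
  sigma2_a_total / ((1 - pi) * het)
}

#' Scale parameter of a scaled inverse chi-square from its mean
#'
#' A scaled-inverse-chi-square(nu, S2) variable has expectation
#' `nu * S2 / (nu - 2)` for `nu > 2`; solving for the scale gives
#' `S2 = mean * (nu - 2) / nu`. Used to derive the scale of every variance
#' prior (marker-effect, residual, polygenic) from an a-priori mean.
#'
#' @param mean_value the desired prior expectation (>= 0).
#' @param nu degrees of freedom, must exceed 2.
#' @return the scale `S2`.
#' @export
scale_from_mean <- function(mean_value, nu) {
  if (nu <= 2) stop("nu must exceed 2 for the prior mean to exist",
                    call. = FALSE)
  mean_value * (nu - 2) / nu
}

#' Build the full prior configuration for a Bayesian-alphabet model
#'
#' Assembles every hyperparameter from user-level quantities. The
#' marker-effect scale `S2_a` is derived by composing
#' [mean_effect_variance()] and [scale_from_mean()]; for BayesA the fixed
#' `pi = 0` enters that derivation, for BayesB the fixed `pi` (default 0.99),
#' and for BayesCpi/BayesDpi the starting value `pi0`, at which the scale is
#' then frozen for the whole chain.
#'
#' @param method one of `"bayesA"`, `"bayesB"`, `"bayesCpi"`, `"bayesDpi"`.
#' @param sigma2_a_total assumed additive-genetic variance explained by SNPs.
#' @param allele_freqs training-panel allele frequencies.
#' @param pi fixed prior inclusion complement for BayesA/BayesB. BayesA
#'   requires 0 (the default); BayesB defaults to 0.99. Passing `pi` for the
#'   pi-unknown methods is an error, as is a non-numeric value such as
#'   `"unknown"` for A/B.
#' @param pi0 starting value of pi for BayesCpi/BayesDpi (default 0.5).
#' @param sigma2_e_prior,sigma2_u_prior a-priori residual and polygenic
#'   variances; if `NULL` they are resolved from the training phenotypes at
#'   [run_mcmc()] time as `var(y) - sigma2_a_total` and `0.05 * var(y)`.
#' @param nu_a,nu_e,nu_u degrees of freedom of the three scaled-inverse
#'   chi-square priors (all default 4.2).
#' @return a `prior_config` list.
#' @export
build_prior_config <- function(method = c("bayesA", "bayesB", "bayesCpi", "bayesDpi"),
                               sigma2_a_total, allele_freqs,
                               pi = NULL, pi0 = 0.5,
                               sigma2_e_prior = NULL, sigma2_u_prior = NULL,
                               nu_a = 4.2, nu_e = 4.2, nu_u = 4.2) {
  method <- match.arg(method)
  if (method %in% c("bayesA", "bayesB")) {
    if (!is.null(pi) && !is.numeric(pi))
      stop("pi must be a fixed numeric value for ", method, call. = FALSE)
    pi <- if (is.null(pi)) switch(method, bayesA = 0, bayesB = 0.99) else pi
    if (method == "bayesA" && pi != 0)
      stop("BayesA requires pi = 0", call. = FALSE)
    if (pi < 0 || pi >= 1) stop("pi must lie in [0, 1)", call. = FALSE)
    pi_mode <- "fixed"
    pi_for_scale <- pi
    pi0 <- pi
  } else {
    if (!is.null(pi))
      stop(method, " treats pi as unknown; supply pi0, not pi", call. = FALSE)
    if (pi0 <= 0 || pi0 >= 1) stop("pi0 must lie in (0, 1)", call. = FALSE)
    pi_mode <- "unknown_uniform"
    pi_for_scale <- pi0
  }
  sbar <- mean_effect_variance(sigma2_a_total, pi_for_scale, allele_freqs)
  structure(list(
    method = method,
    pi_mode = pi_mode,
    pi0 = pi0,
    nu_a = nu_a,
    S2_a = scale_from_mean(sbar, nu_a),
    sigma2_a_total = sigma2_a_total,
    nu_e = nu_e,
    S2_e = if (is.null(sigma2_e_prior)) NA_real_
           else scale_from_mean(sigma2_e_prior, nu_e),
    nu_u = nu_u,
    S2_u = if (is.null(sigma2_u_prior)) NA_real_
           else scale_from_mean(sigma2_u_prior, nu_u),
    dpi_gamma_shape = 1,
    dpi_gamma_rate = 1
  ), class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat(sprintf("<prior_config> %s: pi %s (pi0 = %g), nu_a = %g, S2_a = %g\n",
              x$method, x$pi_mode, x$pi0, x$nu_a, x$S2_a))
  invisible(x)
}
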