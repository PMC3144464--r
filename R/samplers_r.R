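#' Draw from a scaled inverse chi-square distribution
#'
#' @param n number of draws.
#' @param nu degrees of freedom.
#' @param S2 scale parameter.
#' @return numeric vector; `nu * S2 / rchisq(n, nu)`.
#' @export
rscinvchisq <- function(n, nu, S2) nu * S2 / stats::rchisq(n, df = nu)

#' Sample a marker effect from its normal full conditional
#'
#' With `W = diag(weights)`, `c_k = z' W z + sigma2_e / sigma2_ak`, the full
#' conditional of the effect given phenotypes adjusted for everything else is
#' `N(z' W y_adj / c_k, sigma2_e / c_k)`.
#'
#' @param y_adj phenotypes adjusted for all effects other than this marker.
#' @param z marker genotype column.
#' @param sigma2_ak effect variance for this marker (locus-specific, or the
#'   common variance under BayesCpi).
#' @param sigma2_e residual variance.
#' @param weights residual weights (default 1).
#' @return a single draw of the effect.
#' @export
sample_snp_effect <- function(y_adj, z, sigma2_ak, sigma2_e, weights = 1) {
  if (sigma2_ak <= 0 || sigma2_e <= 0)
    stop("variances must be positive", call. = FALSE)
  w <- rep_len(weights, length(z))
  ck <- sum(w * z^2) + sigma2_e / sigma2_ak
  stats::rnorm(1, mean = sum(w * z * y_adj) / ck, sd = sqrt(sigma2_e / ck))
}

#' Sample the overall mean from its full conditional
#'
#' @param y_adj phenotypes adjusted for all effects except the mean.
#' @param sigma2_e residual variance.
#' @param weights residual weights.
#' @return a single draw; `N(sum(w y_adj)/sum(w), sigma2_e/sum(w))`.
#' @export
sample_mu <- function(y_adj, sigma2_e, weights = 1) {
  w <- rep_len(weights, length(y_adj))
  stats::rnorm(1, sum(w * y_adj) / sum(w), sqrt(sigma2_e / sum(w)))
}

#' Sample the residual variance from its full conditional
#'
#' Scaled inverse chi-square with `nu_e + n` degrees of freedom and scale
#' `(e' W e + nu_e S2_e) / (nu_e + n)`.
#'
#' @param e residual vector.
#' @param nu_e,S2_e prior degrees of freedom and scale.
#' @param weights residual weights.
#' @return a single draw.
#' @export
sample_residual_variance <- function(e, nu_e, S2_e, weights = 1) {
  w <- rep_len(weights, length(e))
  n <- length(e)
  rscinvchisq(1, nu_e + n, (sum(w * e^2) + nu_e * S2_e) / (nu_e + n))
}

#' Sample the common marker-effect variance (BayesCpi)
#'
#' Scaled inverse chi-square with `nu_a + m` degrees of freedom and scale
#' `(a'a + nu_a S2_a)/(nu_a + m)`; with `m = 0` this is the prior.
#'
#' @param a vector of currently fitted (nonzero) marker effects.
#' @param m number of fitted markers.
#' @param nu_a,S2_a prior degrees of freedom and scale.
#' @return a single draw.
#' @export
sample_common_variance <- function(a, m, nu_a, S2_a) {
  rscinvchisq(1, nu_a + m, (sum(a^2) + nu_a * S2_a) / (nu_a + m))
}

#' Sample the BayesDpi scale from its gamma full conditional
#'
#' Under the Gamma(shape0, rate0) prior (default Gamma(1,1)) and
#' scaled-inverse-chi-square locus variances, the full conditional of the
#' scale is `Gamma(m nu_a/2 + shape0, (nu_a/2) sum(1/sigma2_ak) + rate0)`,
#' summing over fitted loci only.
#'
#' @param sigma2_ak locus variances of the currently fitted markers.
#' @param nu_a degrees of freedom of the locus-variance prior.
#' @param shape0,rate0 gamma prior parameters.
#' @return a single draw of the scale.
#' @export
sample_dpi_scale <- function(sigma2_ak, nu_a, shape0 = 1, rate0 = 1) {
  sigma2_ak <- sigma2_ak[sigma2_ak > 0]
  m <- length(sigma2_ak)
  stats::rgamma(1, shape = m * nu_a / 2 + shape0,
                rate = nu_a / 2 * sum(1 / sigma2_ak) + rate0)
}

#' Sample pi from its beta full conditional
#'
#' With a uniform(0,1) prior and `m` of `K` markers fitted,
#' `pi ~ Beta(K - m + 1, m + 1)`.
#'
#' @param K number of markers.
#' @param m number fitted in the current iteration.
#' @return a single draw of pi.
#' @export
sample_pi <- function(K, m) stats::rbeta(1, K - m + 1, m + 1)

#' Jointly sample polygenic effects from their full conditional
#'
#' Draws the whole vector `u` exactly from its Gaussian full conditional
#' `N(C^{-1} rhs, C^{-1})` with `C = Z' W Z / sigma2_e + A^{-1} / sigma2_u`
#' via a Cholesky factorisation, where `Z` maps phenotype records to pedigree
#' individuals.
#'
#' @param y_adj phenotypes adjusted for all effects except `u`.
#' @param u_index integer index of the pedigree individual for each record.
#' @param Ainv inverse numerator relationship matrix (see [build_Ainv()]).
#' @param sigma2_u,sigma2_e polygenic and residual variances.
#' @param weights residual weights.
#' @return a draw of `u`, one entry per pedigree individual.
#' @export
sample_polygenic <- function(y_adj, u_index, Ainv, sigma2_u, sigma2_e,
                             weights = 1) {
  n_u <- nrow(Ainv)
  w <- rep_len(weights, length(y_adj))
  C <- Ainv / sigma2_u
  diag_add <- tapply(w, factor(u_index, levels = seq_len(n_u)), sum,
                     default = 0) / sigma2_e
  diag(C) <- diag(C) + diag_add
  rhs <- tapply(w * y_adj, factor(u_index, levels = seq_len(n_u)), sum,
                default = 0) / sigma2_e
  R <- tryCatch(chol(C), error = function(e)
    stop("singular polygenic system; check pedigree connectivity",
         call. = FALSE))
  mean_u <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  as.numeric(mean_u + backsolve(R, stats::rnorm(n_u)))
}

#' Sample the polygenic variance from its full conditional
#'
#' Scaled inverse chi-square with `nu_u + n_u` degrees of freedom and scale
#' `(u' A^{-1} u + nu_u S2_u)/(nu_u + n_u)`.
#'
#' @param u polygenic effect vector.
#' @param Ainv inverse numerator relationship matrix.
#' @param nu_u,S2_u prior degrees of freedom and scale.
#' @return a single draw.
#' @export
sample_polygenic_variance <- function(u, Ainv, nu_u, S2_u) {
  n_u <- length(u)
  q <- as.numeric(t(u) %*% Ainv %*% u)
  rscinvchisq(1, nu_u + n_u, (q + nu_u * S2_u) / (nu_u + n_u))
}
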