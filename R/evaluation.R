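#' Genomic estimated breeding values
#'
#' `GEBV_i = sum_k z_ik * a_hat_k` with `z_ik` the genotype score (0, 1 or 2)
#' and `a_hat_k` the posterior-mean effect of marker k.
#'
#' @param g a [genotype_matrix()].
#' @param snp_effect_means posterior-mean effect per marker (or a tidied
#'   `alphabet_fit`: a data frame with a `posterior_mean` column).
#' @return a tibble `id`, `gebv`.
#' @export
compute_gebv <- function(g, snp_effect_means) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(snp_effect_means))
    snp_effect_means <- snp_effect_means$posterior_mean
  if (length(snp_effect_means) != ncol(g$codes))
    stop("need one effect per marker", call. = FALSE)
  tibble::tibble(id = g$individual_ids,
                 gebv = as.numeric(g$codes %*% snp_effect_means))
}

#' Accuracy of genomic predictions
#'
#' Pearson correlation between GEBVs and the reference values, divided by the
#' mean accuracy (square root of the reliability) of those references. With
#' all reliabilities 1 — the simulation case, where true breeding values are
#' exact — this is the plain correlation.
#'
#' @param gebv predicted values.
#' @param proofs reference values (true breeding values or de-regressed
#'   proofs).
#' @param reliabilities reliabilities of the references (default 1).
#' @return a scalar accuracy.
#' @export
accuracy <- function(gebv, proofs, reliabilities = 1) {
  if (stats::sd(gebv) == 0 || stats::sd(proofs) == 0)
    stop("accuracy undefined: zero variance in predictions or references",
         call. = FALSE)
  stats::cor(gebv, proofs) / mean(sqrt(rep_len(reliabilities, length(proofs))))
}

#' Posterior summary of the number of fitted markers
#'
#' Reports the mean and standard deviation of the per-iteration fitted-marker
#' count, together with the equivalent `(1 - pi_bar) * K` (identical in
#' expectation, paired through the chain).
#'
#' @param fit an `alphabet_fit` from [run_mcmc()].
#' @return a one-row tibble: `nsnp_mean`, `nsnp_sd`, `nsnp_from_pi`.
#' @export
nsnp_summary <- function(fit) {
  stopifnot(inherits(fit, "alphabet_fit"))
  tibble::tibble(nsnp_mean = fit$nsnp_mean, nsnp_sd = fit$nsnp_sd,
                 nsnp_from_pi = (1 - fit$pi_mean) * fit$K)
}

#' Sliding-window genetic variance of GEBVs
#'
#' For each window of `window_size` consecutive markers (sliding by `step`),
#' the empirical variance across individuals of the window's contribution to
#' the GEBV, `sum_{k in window} z_ik a_hat_k`. Peaks indicate chromosomal
#' regions harbouring QTL.
#'
#' @param g a [genotype_matrix()] (markers in map order).
#' @param snp_effect_means posterior-mean effect per marker.
#' @param window_size window width in markers.
#' @param step slide in markers (default 1).
#' @return a tibble `window_start`, `window_end` (marker indices, inclusive),
#'   `variance`.
#' @export
window_variance <- function(g, snp_effect_means, window_size, step = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.data.frame(snp_effect_means))
    snp_effect_means <- snp_effect_means$posterior_mean
  K <- ncol(g$codes)
  if (window_size < 1 || window_size > K)
    stop("window_size must lie in [1, K]", call. = FALSE)
  starts <- seq(1, K - window_size + 1, by = step)
  vals <- vapply(starts, function(s) {
    cols <- s:(s + window_size - 1)
    stats::var(as.numeric(g$codes[, cols, drop = FALSE] %*%
                            snp_effect_means[cols]))
  }, 0)
  tibble::tibble(window_start = starts,
                 window_end = starts + window_size - 1,
                 variance = vals)
}

#' Plot a sliding-window variance track
#'
#' @param track output of [window_variance()].
#' @return a ggplot object.
#' @export
plot_window_variance <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$window_start,
                                      y = .data$variance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (marker index)",
                  y = "GEBV variance in window") +
    ggplot2::theme_minimal()
}

#' Write the marker-effect summary of a fit to CSV
#'
#' @param fit an `alphabet_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  stopifnot(inherits(fit, "alphabet_fit"))
  utils::write.csv(as.data.frame(tidy(fit)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a marker-effect summary written by [write_summary()]
#'
#' @param path file path.
#' @return a tibble `snp_id`, `posterior_mean`, `model_freq`.
#' @export
read_summary <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
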