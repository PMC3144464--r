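#' MCMC chain configuration
#'
#' @param chain_length total number of iterations.
#' @param burn_in iterations discarded before summaries accumulate; must be
#'   smaller than `chain_length`.
#' @param mh_reps Metropolis-Hastings repetitions per locus and iteration for
#'   the mixture-proposal update; `NULL` resolves to the method default (10
#'   for BayesB/BayesDpi, 2 for BayesA, unused by BayesCpi).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed optional integer seed; when given, [run_mcmc()] seeds R's RNG
#'   so that runs are bit-reproducible.
#' @param fit_polygenic fit pedigree polygenic effects alongside the markers.
#' @return a `chain_config` list.
#' @export
chain_config <- function(chain_length = 50000, burn_in = 20000,
                         mh_reps = NULL, thin = 1, seed = NULL,
                         fit_polygenic = FALSE) {
  if (burn_in >= chain_length)
    stop("burn_in must be smaller than chain_length", call. = FALSE)
  if (!is.null(mh_reps) && mh_reps < 1)
    stop("mh_reps must be at least 1", call. = FALSE)
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 mh_reps = mh_reps, thin = as.integer(thin),
                 seed = seed, fit_polygenic = isTRUE(fit_polygenic)),
            class = "chain_config")
}

#' Low-level sampler controls
#'
#' Mostly useful for validation studies: any of the nuisance parameters can
#' be clamped at a known value so that the locus-update mechanism can be
#' compared against exact enumeration.
#'
#' @param fix_mu,fix_sigma2_e,fix_sigma2_a,fix_pi clamp the corresponding
#'   parameter instead of sampling it.
#' @param mu_value,sigma2_e_value,sigma2_a_value clamped values.
#' @param check_every verify the phenotype-reconstruction invariant every
#'   this many iterations (0 disables).
#' @param verbose log progress to stderr every 1000 iterations.
#' @return an `mcmc_control` list.
#' @export
mcmc_control <- function(fix_mu = FALSE, fix_sigma2_e = FALSE,
                         fix_sigma2_a = FALSE, fix_pi = FALSE,
                         mu_value = 0, sigma2_e_value = 1,
                         sigma2_a_value = 1, check_every = 100,
                         verbose = FALSE) {
  list(fix_mu = fix_mu, fix_sigma2_e = fix_sigma2_e,
       fix_sigma2_a = fix_sigma2_a, fix_pi = fix_pi,
       mu_value = mu_value, sigma2_e_value = sigma2_e_value,
       sigma2_a_value = sigma2_a_value, check_every = as.integer(check_every),
       verbose = verbose)
}

method_code <- function(method) {
  match(method, c("bayesA", "bayesB", "bayesCpi", "bayesDpi")) - 1L
}

#' Run a Bayesian-alphabet MCMC analysis
#'
#' Fits one of BayesA, BayesB, BayesCpi or BayesDpi by single-site MCMC.
#' Each iteration updates the overall mean, every marker in ascending index
#' order (Gibbs on the inclusion indicator for BayesCpi; Metropolis-Hastings
#' on the locus variance with the effect integrated out for the others, with
#' BayesA run as BayesB with `pi = 0` and fewer MH repetitions), optional
#' polygenic effects and their variance, the residual variance, the unknown
#' scale for BayesDpi, and pi for the pi-unknown methods. Genotype columns
#' are mean-centered internally; this reparameterises the intercept only and
#' leaves marker effects unchanged.
#'
#' @param genotypes a [genotype_matrix()] (post-QC: no missing codes).
#' @param traits a [trait_data()] whose ids match the genotyped individuals.
#' @param prior a [build_prior_config()].
#' @param chain a [chain_config()].
#' @param ped optional [pedigree()], required when
#'   `chain$fit_polygenic = TRUE`; every phenotyped individual must appear.
#' @param control an [mcmc_control()].
#' @return an `alphabet_fit` object; see [tidy.alphabet_fit()],
#'   [glance.alphabet_fit()] and [autoplot.alphabet_fit()].
#' @export
run_mcmc <- function(genotypes, traits, prior, chain = chain_config(),
                     ped = NULL, control = mcmc_control()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(prior, "prior_config"),
            inherits(chain, "chain_config"))
  if (anyNA(genotypes$codes))
    stop("genotypes contain missing codes; run qc_filter() first",
         call. = FALSE)
  keep <- match(traits$id, genotypes$individual_ids)
  if (anyNA(keep))
    stop("phenotyped individuals missing from genotypes: ",
         paste(utils::head(traits$id[is.na(keep)], 3), collapse = ", "),
         call. = FALSE)
  Z <- genotypes$codes[keep, , drop = FALSE]
  Z <- sweep(Z, 2, colMeans(Z))  # center columns; intercept absorbs the shift
  y <- traits$y
  w <- traits$weight

  prior <- resolve_prior_defaults(prior, y)
  mh_reps <- chain$mh_reps
  if (is.null(mh_reps))
    mh_reps <- switch(prior$method, bayesA = 2L, 10L)

  fit_poly <- chain$fit_polygenic
  if (fit_poly) {
    if (is.null(ped)) stop("fit_polygenic = TRUE requires a pedigree",
                           call. = FALSE)
    Ainv <- build_Ainv(ped)
    u_map <- match(traits$id, ped$id)
    if (anyNA(u_map))
      stop("phenotyped individuals missing from pedigree", call. = FALSE)
    u_map <- u_map - 1L
  } else {
    Ainv <- matrix(0, 0, 0)
    u_map <- integer(length(y))
  }

  if (!is.null(chain$seed)) set.seed(chain$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- mcmc_engine(Z, y, w, method_code(prior$method),
                     prior_engine_list(prior),
                     list(chain_length = chain$chain_length,
                          burn_in = chain$burn_in,
                          mh_reps = as.integer(mh_reps),
                          thin = chain$thin),
                     control, Ainv, u_map, fit_poly)
  elapsed <- proc.time()[["elapsed"]] - t0

  K <- ncol(Z)
  chains <- tibble::tibble(
    iteration = chain$burn_in + seq_len(nrow(res$chains)) * chain$thin,
    pi = res$chains[, 1], nsnp = res$chains[, 2],
    sigma2_e = res$chains[, 3], sigma2_a = res$chains[, 4],
    mu = res$chains[, 5], sigma2_u = res$chains[, 6],
    sigma2_k1 = res$chains[, 7])
  structure(list(
    method = prior$method,
    snp_effects = tibble::tibble(snp_id = genotypes$snp_ids,
                                 posterior_mean = as.numeric(res$snp_effect_means),
                                 model_freq = as.numeric(res$model_freqs)),
    chains = chains,
    K = K, n = length(y),
    nsnp_mean = mean(chains$nsnp), nsnp_sd = stats::sd(chains$nsnp),
    pi_mean = mean(chains$pi),
    recon_max_rel = res$recon_max_rel,
    prior = prior, chain = chain, elapsed = elapsed),
    class = "alphabet_fit")
}

resolve_prior_defaults <- function(prior, y) {
  vy <- stats::var(y)
  if (is.na(prior$S2_e))
    prior$S2_e <- scale_from_mean(max(vy - prior$sigma2_a_total, 0.05 * vy),
                                  prior$nu_e)
  if (is.na(prior$S2_u))
    prior$S2_u <- scale_from_mean(0.05 * vy, prior$nu_u)
  prior
}

prior_engine_list <- function(prior) {
  list(nu_a = prior$nu_a, S2_a = prior$S2_a,
       nu_e = prior$nu_e, S2_e = prior$S2_e,
       nu_u = prior$nu_u, S2_u = prior$S2_u,
       dpi_gamma_shape = prior$dpi_gamma_shape,
       dpi_gamma_rate = prior$dpi_gamma_rate,
       pi0 = prior$pi0)
}

#' @export
print.alphabet_fit <- function(x, ...) {
  cat(sprintf("<alphabet_fit> %s: %d markers, %d records\n",
              x$method, x$K, x$n))
  cat(sprintf("  chain %d (burn-in %d), %.1f s\n",
              x$chain$chain_length, x$chain$burn_in, x$elapsed))
  cat(sprintf("  posterior N_SNP: %.1f (sd %.1f); (1 - pi_bar) K = %.1f\n",
              x$nsnp_mean, x$nsnp_sd, (1 - x$pi_mean) * x$K))
  invisible(x)
}

#' Tidy the marker-effect posterior of a fit
#'
#' @param x an `alphabet_fit`.
#' @param ... unused.
#' @return a tibble with one row per marker: `snp_id`, `posterior_mean` (the
#'   posterior-mean effect) and `model_freq` (posterior inclusion frequency).
#' @export
tidy.alphabet_fit <- function(x, ...) x$snp_effects

#' One-row posterior summary of a fit
#'
#' @param x an `alphabet_fit`.
#' @param ... unused.
#' @return a one-row tibble with the method, posterior mean and sd of the
#'   fitted-marker count, `pi_mean`, posterior-mean variances, and the
#'   maximum relative drift of the phenotype-reconstruction check.
#' @export
glance.alphabet_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, K = x$K,
                 nsnp_mean = x$nsnp_mean, nsnp_sd = x$nsnp_sd,
                 pi_mean = x$pi_mean,
                 sigma2_e_mean = mean(x$chains$sigma2_e),
                 sigma2_a_mean = mean(x$chains$sigma2_a),
                 recon_max_rel = x$recon_max_rel,
                 elapsed = x$elapsed)
}

#' Plot a fitted Bayesian-alphabet model
#'
#' `what = "model_freq"` shows posterior inclusion frequencies along the
#' panel; `what = "trace"` shows post-burn-in traces of pi and the fitted
#' marker count.
#'
#' @param object an `alphabet_fit`.
#' @param what `"model_freq"` or `"trace"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.alphabet_fit <- function(object, what = c("model_freq", "trace"),
                                  ...) {
  what <- match.arg(what)
  if (what == "model_freq") {
    df <- dplyr::mutate(object$snp_effects,
                        index = dplyr::row_number())
    ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$model_freq)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0)) +
      ggplot2::labs(x = "marker index", y = "model frequency",
                    title = paste0(object$method, ": posterior inclusion")) +
      ggplot2::theme_minimal()
  } else {
    df <- tidyr::pivot_longer(object$chains[c("iteration", "pi", "nsnp")],
                              -"iteration")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "iteration", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
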