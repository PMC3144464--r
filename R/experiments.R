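#' Replicated ideal-scenario estimate of the fitted-locus count
#'
#' Runs the full ideal linkage-equilibrium experiment: per replicate,
#' simulate the panel (2,000 unlinked biallelic loci at frequency 0.5,
#' `n_qtl` of them QTL, effects standardized to the additive variance implied
#' by `h2` with unit residual variance), fit the requested Bayesian-alphabet
#' model with `sigma2_a_total = h2/(1-h2)` and a residual-variance prior mean
#' of 1, and record the posterior `N_SNP = (1 - pi_bar) * K` together with
#' the mean per-iteration fitted count.
#'
#' @param method `"bayesCpi"` or `"bayesDpi"` (any alphabet method accepted).
#' @param dist QTL-effect distribution, `"gamma"` or `"normal"`.
#' @param n_qtl number of QTL among the loci.
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r uses `seed * 131 + r` for the
#'   simulation and `seed * 131 + r + 500` for the chain.
#' @param n_ind,n_loci,h2,pi0,chain_length,burn_in experiment settings.
#' @return a tibble with one row per replicate: `rep`, `nsnp` (from
#'   `pi_bar`), `m_mean`, `accuracy` (correlation of GEBVs with true breeding
#'   values on the training set), `elapsed`.
#' @export
ideal_nsnp_experiment <- function(method, dist, n_qtl, n_reps = 6, seed = 1,
                                  n_ind = 1000, n_loci = 2000, h2 = 0.5,
                                  pi0 = 0.5, chain_length = 10000,
                                  burn_in = 4000) {
  reps <- lapply(seq_len(n_reps), function(r) {
    pop <- simulate_ideal(n_ind, n_loci, n_qtl, h2 = h2, dist = dist,
                          seed = seed * 131 + r)
    prior <- build_prior_config(method, target_va_from_h2(h2),
                                allele_freqs(pop$genotypes), pi0 = pi0,
                                sigma2_e_prior = 1)
    fit <- run_mcmc(pop$genotypes, pop$traits, prior,
                    chain_config(chain_length, burn_in,
                                 seed = seed * 131 + r + 500))
    gebv <- compute_gebv(pop$genotypes, tidy(fit))
    tibble::tibble(rep = r, nsnp = (1 - fit$pi_mean) * fit$K,
                   m_mean = fit$nsnp_mean,
                   accuracy = accuracy(gebv$gebv, pop$tbv),
                   elapsed = fit$elapsed)
  })
  dplyr::bind_rows(reps)
}

#' Proportion of segregating loci in the historical simulation
#'
#' Runs the drift-mutation forward simulation at full population size and
#' generation count and reports the fraction of loci still segregating.
#'
#' @param n_loci number of SNP loci simulated.
#' @param n_qtl number of QTL loci.
#' @param seed integer seed.
#' @inheritParams simulate_population
#' @return the segregating proportion (scalar in `[0, 1]`).
#' @export
segregation_experiment <- function(n_base = 1500, generations = 1000,
                                   n_loci = 400, n_qtl = 10,
                                   mutation_rate = 2.5e-5, seed = 1) {
  pop <- simulate_population(n_base, generations, n_loci, n_qtl,
                             mutation_rate, seed = seed)
  segregating_proportion(pop)
}
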