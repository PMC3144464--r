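#' Sample QTL effects
#'
#' Magnitudes are drawn either from a gamma distribution with shape 0.4 and
#' scale 1.66 (many small, few large effects) or from a standard normal.
#' Gamma magnitudes receive a random sign with probability 1/2 each.
#'
#' @param n_qtl number of effects.
#' @param dist `"gamma"` or `"normal"`.
#' @param shape,scale gamma parameters (defaults 0.4 and 1.66).
#' @param seed optional integer seed.
#' @return numeric vector of signed effects.
#' @export
sample_qtl_effects <- function(n_qtl, dist = c("gamma", "normal"),
                               shape = 0.4, scale = 1.66, seed = NULL) {
  dist <- match.arg(dist)
  if (!is.null(seed)) set.seed(seed)
  if (dist == "gamma") {
    mag <- stats::rgamma(n_qtl, shape = shape, scale = scale)
    mag * sample(c(-1, 1), n_qtl, replace = TRUE)
  } else {
    stats::rnorm(n_qtl)
  }
}

#' Standardize QTL effects to a target additive-genetic variance
#'
#' Rescales the effect vector by one scalar so that the empirical variance of
#' the total genotypic value across the simulated individuals equals
#' `target_va` exactly on the realized genotypes. With a residual variance of
#' 1, a heritability `h2` corresponds to `target_va = h2 / (1 - h2)`.
#'
#' @param effects raw QTL effects.
#' @param qtl_genotypes genotype matrix (individuals x QTL, codes 0/1/2).
#' @param target_va target variance of the true breeding values.
#' @return the rescaled effect vector.
#' @export
standardize_effects <- function(effects, qtl_genotypes, target_va) {
  tbv <- as.numeric(qtl_genotypes %*% effects)
  v <- stats::var(tbv)
  if (!is.finite(v) || v <= 0)
    stop("zero genetic variance: all QTL fixed or effects zero", call. = FALSE)
  effects * sqrt(target_va / v)
}

#' Target additive variance for a heritability with unit residual variance
#' @param h2 heritability in (0, 1).
#' @return `h2 / (1 - h2)`.
#' @export
target_va_from_h2 <- function(h2) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)", call. = FALSE)
  h2 / (1 - h2)
}

#' Simulate the ideal linkage-equilibrium scenario
#'
#' All loci behave as if located on different chromosomes: genotypes are
#' independent Binomial(2, 0.5) draws per individual and locus. A random
#' subset of loci is designated QTL; both QTL and non-QTL loci enter the
#' analysis panel, so the true pi is `1 - n_qtl / n_loci`. Phenotypes are the
#' genotypic values (effects standardized to the variance implied by `h2`
#' with residual variance 1) plus standard-normal residuals.
#'
#' @param n_ind number of individuals.
#' @param n_loci total number of biallelic loci (default 2000).
#' @param n_qtl number of QTL among them.
#' @param h2 trait heritability (default 0.5).
#' @param dist QTL-effect distribution, `"gamma"` or `"normal"`.
#' @param freq initial allele frequency (default 0.5).
#' @param seed optional integer seed.
#' @return a `simulated_population` list: `genotypes` (the analysis panel),
#'   `qtl_ids`, `qtl_effects`, `tbv`, `traits` (a [trait_data()]), `h2`,
#'   `true_pi`, `provenance`.
#' @export
simulate_ideal <- function(n_ind, n_loci = 2000, n_qtl, h2 = 0.5,
                           dist = c("gamma", "normal"), freq = 0.5,
                           seed = NULL) {
  dist <- match.arg(dist)
  if (!is.null(seed)) set.seed(seed)
  codes <- matrix(stats::rbinom(n_ind * n_loci, 2, freq), n_ind, n_loci)
  g <- genotype_matrix(codes,
                       individual_ids = paste0("ind", seq_len(n_ind)),
                       snp_ids = paste0("locus", seq_len(n_loci)))
  qtl_idx <- sort(sample.int(n_loci, n_qtl))
  eff <- sample_qtl_effects(n_qtl, dist)
  eff <- standardize_effects(eff, codes[, qtl_idx, drop = FALSE],
                             target_va_from_h2(h2))
  tbv <- as.numeric(codes[, qtl_idx, drop = FALSE] %*% eff)
  y <- tbv + stats::rnorm(n_ind)
  structure(list(
    genotypes = g,
    qtl_ids = g$snp_ids[qtl_idx],
    qtl_effects = eff,
    tbv = tbv,
    traits = trait_data(g$individual_ids, y),
    h2 = h2,
    true_pi = 1 - n_qtl / n_loci,
    provenance = list(scenario = "ideal", n_ind = n_ind, n_loci = n_loci,
                      n_qtl = n_qtl, dist = dist, seed = seed)),
    class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<simulated_population> %s scenario: %d individuals, %d loci, %d QTL (%s effects), h2 = %g\n",
              p$scenario, nrow(x$genotypes$codes), ncol(x$genotypes$codes),
              length(x$qtl_effects), p$dist, x$h2))
  invisible(x)
}

#' Binomial recombination map
#'
#' Crossover counts per meiosis follow Binomial(`max_crossovers`, p) with
#' breakpoints uniform on the chromosome; `p` is set so the expected number
#' of crossovers equals the map length in Morgan (interference enters through
#' the cap). A 1-Morgan chromosome with at most 4 crossovers gives p = 0.25.
#'
#' @param length_morgan chromosome length in Morgan (default 1).
#' @param max_crossovers maximum crossovers per meiosis (default 4).
#' @return a `genome_map` list with `length`, `max_crossovers`, `xo_prob`.
#' @export
binomial_map <- function(length_morgan = 1, max_crossovers = 4) {
  if (length_morgan > max_crossovers)
    stop("map length exceeds the maximum crossover count", call. = FALSE)
  structure(list(length = length_morgan, max_crossovers = max_crossovers,
                 xo_prob = length_morgan / max_crossovers),
            class = "genome_map")
}

#' Simulate a randomly mating historical population
#'
#' Forward-in-time simulation on one chromosome: a base population of
#' `n_base` monoecious individuals (all loci at allele frequency 0.5) is
#' randomly mated (random union of gametes, selfing allowed) for `generations`
#' discrete generations of constant size, building up linkage disequilibrium
#' from drift and mutation. SNP loci are evenly spaced; QTL positions are
#' uniform. Mutation is a recurrent two-allele flip with the given per-locus
#' per-gamete rate; recombination follows the [binomial_map()].
#'
#' @param n_base population size (default 1500).
#' @param generations number of generations (default 1000).
#' @param n_snp_loci number of evenly spaced SNP loci (default 4000).
#' @param n_qtl number of uniformly placed QTL loci.
#' @param mutation_rate per-locus per-gamete flip probability
#'   (default 2.5e-5).
#' @param map a [binomial_map()].
#' @param seed optional integer seed.
#' @return a `raw_population` list: `haplotypes` (2N x L 0/1 matrix),
#'   `positions` (Morgan), `is_qtl` (logical per locus), `map`, `provenance`.
#' @export
simulate_population <- function(n_base = 1500, generations = 1000,
                                n_snp_loci = 4000, n_qtl = 10,
                                mutation_rate = 2.5e-5,
                                map = binomial_map(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_pos <- (seq_len(n_snp_loci) - 0.5) / n_snp_loci * map$length
  qtl_pos <- sort(stats::runif(n_qtl, 0, map$length))
  pos <- c(snp_pos, qtl_pos)
  is_qtl <- c(rep(FALSE, n_snp_loci), rep(TRUE, n_qtl))
  ord <- order(pos)
  pos <- pos[ord]; is_qtl <- is_qtl[ord]
  haps <- forward_sim_cpp(n_base, generations, pos, map$length,
                          mutation_rate, map$max_crossovers, map$xo_prob)
  structure(list(haplotypes = haps, positions = pos, is_qtl = is_qtl,
                 map = map,
                 provenance = list(scenario = "realistic", n_base = n_base,
                                   generations = generations,
                                   n_snp_loci = n_snp_loci, n_qtl = n_qtl,
                                   mutation_rate = mutation_rate,
                                   seed = seed)),
            class = "raw_population")
}

#' Proportion of segregating loci in a raw population
#'
#' @param pop a `raw_population`.
#' @param loci `"all"`, `"snp"` or `"qtl"`.
#' @return the fraction of loci with both alleles present.
#' @export
segregating_proportion <- function(pop, loci = c("all", "snp", "qtl")) {
  loci <- match.arg(loci)
  sel <- switch(loci, all = rep(TRUE, length(pop$is_qtl)),
                snp = !pop$is_qtl, qtl = pop$is_qtl)
  f <- colMeans(pop$haplotypes[, sel, drop = FALSE])
  mean(f > 0 & f < 1)
}

#' Select the analysis SNP panel from a raw population
#'
#' The chromosome is divided into `n_bins` evenly spaced bins; in each bin
#' one SNP with minor allele frequency above `min_maf` is selected uniformly
#' at random. Bins without a qualifying SNP contribute nothing, so the panel
#' may be smaller than `n_bins` (a message reports how many bins were empty).
#'
#' @param pop a `raw_population`.
#' @param n_bins number of bins (default 2000).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param seed optional integer seed.
#' @return integer vector of selected locus indices (columns of
#'   `pop$haplotypes`), ordered by position.
#' @export
select_snp_panel <- function(pop, n_bins = 2000, min_maf = 0.05,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- colMeans(pop$haplotypes)
  maf <- pmin(f, 1 - f)
  eligible <- !pop$is_qtl & maf > min_maf
  if (!any(eligible)) {
    warning("no SNP passes the MAF floor; empty panel", call. = FALSE)
    return(integer(0))
  }
  bin <- pmin(floor(pop$positions / pop$map$length * n_bins), n_bins - 1)
  chosen <- integer(0)
  for (b in unique(bin[eligible])) {
    cand <- which(eligible & bin == b)
    chosen <- c(chosen, if (length(cand) == 1) cand
                else cand[sample.int(length(cand), 1)])
  }
  n_empty <- n_bins - length(chosen)
  if (n_empty > 0)
    message(n_empty, " of ", n_bins, " bins had no qualifying SNP")
  sort(chosen)
}

#' Attach a simulated trait to genotypes
#'
#' True breeding values are the QTL genotypic values with effects
#' standardized to the additive variance implied by `h2` (residual variance
#' 1); phenotypes add standard-normal residuals.
#'
#' @param panel_genotypes a [genotype_matrix()] of analysis SNPs.
#' @param qtl_genotypes matrix of QTL genotype codes for the same
#'   individuals.
#' @param qtl_effects raw QTL effects (see [sample_qtl_effects()]).
#' @param h2 heritability.
#' @param seed optional integer seed.
#' @return a `simulated_population` (see [simulate_ideal()]); `true_pi` is
#'   `NA` because the QTL are not in the analysis panel.
#' @export
attach_trait <- function(panel_genotypes, qtl_genotypes, qtl_effects, h2,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- standardize_effects(qtl_effects, qtl_genotypes,
                             target_va_from_h2(h2))
  tbv <- as.numeric(qtl_genotypes %*% eff)
  y <- tbv + stats::rnorm(length(tbv))
  structure(list(
    genotypes = panel_genotypes,
    qtl_ids = colnames(qtl_genotypes),
    qtl_effects = eff,
    tbv = tbv,
    traits = trait_data(panel_genotypes$individual_ids, y),
    h2 = h2,
    true_pi = NA_real_,
    provenance = list(scenario = "realistic-trait", h2 = h2, seed = seed)),
    class = "simulated_population")
}

#' Simulate the realistic drift-mutation scenario end to end
#'
#' Runs the historical population, draws a training cohort whose members each
#' come from a distinct random parent pair of the final generation, selects
#' the SNP panel and attaches the trait. Only the selected SNPs (not the QTL)
#' enter the analysis panel.
#'
#' @inheritParams simulate_population
#' @param n_train number of training individuals (at most `n_base / 2`).
#' @param n_bins,min_maf SNP-panel selection parameters.
#' @param h2 heritability.
#' @param dist QTL-effect distribution.
#' @param seed optional integer seed.
#' @return a `simulated_population`.
#' @export
simulate_realistic <- function(n_base = 1500, generations = 1000,
                               n_snp_loci = 4000, n_qtl = 10,
                               mutation_rate = 2.5e-5, map = binomial_map(),
                               n_train = 750, n_bins = 2000, min_maf = 0.05,
                               h2 = 0.5, dist = c("gamma", "normal"),
                               seed = NULL) {
  dist <- match.arg(dist)
  if (!is.null(seed)) set.seed(seed)
  pop <- simulate_population(n_base, generations, n_snp_loci, n_qtl,
                             mutation_rate, map)
  if (2 * n_train > n_base)
    stop("n_train must not exceed half the population size", call. = FALSE)
  parents <- sample.int(n_base, 2 * n_train)  # each parent represented once
  off <- mate_pairs_cpp(pop$haplotypes, parents[seq_len(n_train)] - 1L,
                        parents[n_train + seq_len(n_train)] - 1L,
                        pop$positions, map$length, mutation_rate,
                        map$max_crossovers, map$xo_prob)
  geno_all <- off[seq(1, 2 * n_train, 2), , drop = FALSE] +
    off[seq(2, 2 * n_train, 2), , drop = FALSE]
  panel_idx <- select_snp_panel(pop, n_bins, min_maf)
  qtl_idx <- which(pop$is_qtl)
  seg <- colMeans(off[, qtl_idx, drop = FALSE])
  qtl_use <- qtl_idx[seg > 0 & seg < 1]  # fixed QTL carry no variance
  panel <- genotype_matrix(geno_all[, panel_idx, drop = FALSE],
                           individual_ids = paste0("ind", seq_len(n_train)),
                           snp_ids = paste0("snp", panel_idx))
  qtl_g <- geno_all[, qtl_use, drop = FALSE]
  colnames(qtl_g) <- paste0("qtl", qtl_use)
  eff <- sample_qtl_effects(length(qtl_use), dist)
  out <- attach_trait(panel, qtl_g, eff, h2)
  out$provenance <- c(out$provenance,
                      list(scenario_full = "realistic", n_base = n_base,
                           generations = generations, n_qtl = n_qtl,
                           dist = dist, seed = seed))
  out
}
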