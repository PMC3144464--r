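test_that("QTL effect sampling matches its distributions and is seedable", {
  set.seed(51)
  e <- sample_qtl_effects(1e5, "gamma")
  m <- mean(abs(e))
  se <- sd(abs(e)) / sqrt(length(e))
  expect_lt(abs(m - 0.4 * 1.66), 4 * se)           # gamma mean 0.664
  expect_lt(abs(mean(sign(e))), 4 / sqrt(length(e)))  # symmetric signs
  en <- sample_qtl_effects(1e5, "normal")
  expect_lt(abs(var(en) - 1), 4 * sqrt(2 / length(en)))
  expect_identical(sample_qtl_effects(20, "gamma", seed = 3),
                   sample_qtl_effects(20, "gamma", seed = 3))
})

test_that("effect standardization hits the target variance exactly", {
  set.seed(52)
  Q <- matrix(rbinom(200 * 10, 2, 0.5), 200, 10)
  e <- rnorm(10)
  s <- standardize_effects(e, Q, target_va_from_h2(0.5))
  expect_equal(var(as.numeric(Q %*% s)), 1, tolerance = 1e-12)
  expect_equal(target_va_from_h2(0.9), 9, tolerance = 1e-12)
  expect_equal(s / e, rep(s[1] / e[1], 10), tolerance = 1e-12)  # one scalar
  expect_error(standardize_effects(e, matrix(2, 5, 10), 1), "fixed")
})

test_that("ideal scenario generates linkage equilibrium at frequency 0.5", {
  pop <- simulate_ideal(600, 200, n_qtl = 10, seed = 53)
  f <- allele_freqs(pop$genotypes)
  expect_lt(abs(mean(f) - 0.5), 0.01)
  expect_lt(sd(f), 2 * sqrt(0.25 / (2 * 600)))
  # pairwise correlations small
  cc <- cor(pop$genotypes$codes[, 1:50])
  expect_lt(max(abs(cc[upper.tri(cc)])), 5 / sqrt(600))
  expect_equal(pop$true_pi, 1 - 10 / 200)
  # phenotype construction: slope of y on TBV near 1, h2 near target
  expect_equal(unname(coef(lm(pop$traits$y ~ pop$tbv))[2]), 1,
               tolerance = 0.15)
  expect_equal(var(pop$tbv) / var(pop$traits$y), 0.5, tolerance = 0.1)
})

test_that("binomial map fixes the crossover probability from the length", {
  map <- binomial_map(1, 4)
  expect_equal(map$xo_prob, 0.25)
  expect_equal(map$max_crossovers * map$xo_prob, 1)  # expected 1 per Morgan
  expect_error(binomial_map(5, 4), "exceeds")
})

test_that("forward simulation is reproducible and drifts without mutation", {
  p1 <- simulate_population(60, 30, n_snp_loci = 50, n_qtl = 5, seed = 54)
  p2 <- simulate_population(60, 30, n_snp_loci = 50, n_qtl = 5, seed = 54)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_equal(dim(p1$haplotypes), c(120L, 55L))
  # without mutation a single generation moves frequencies only by drift
  set.seed(55)
  reps <- replicate(40, {
    p <- simulate_population(80, 1, n_snp_loci = 30, n_qtl = 0,
                             mutation_rate = 0)
    mean(colMeans(p$haplotypes)) - 0.5
  })
  expect_lt(abs(mean(reps)), 4 * sd(reps) / sqrt(length(reps)))
})

test_that("linkage disequilibrium decays with map distance", {
  pop <- simulate_population(150, 250, n_snp_loci = 120, n_qtl = 0,
                             seed = 56)
  haps <- pop$haplotypes
  geno <- haps[seq(1, nrow(haps), 2), ] + haps[seq(2, nrow(haps), 2), ]
  f <- colMeans(haps)
  keep <- f > 0.1 & f < 0.9
  geno <- geno[, keep]; posn <- pop$positions[keep]
  r2 <- cor(geno)^2
  d <- abs(outer(posn, posn, "-"))
  ut <- upper.tri(r2)
  near <- d[ut] < 0.05; far <- d[ut] > 0.4
  expect_gt(mean(r2[ut][near]), mean(r2[ut][far]))
})

test_that("SNP panel selection respects bins and the MAF floor", {
  pop <- simulate_population(100, 50, n_snp_loci = 200, n_qtl = 5, seed = 57)
  idx <- select_snp_panel(pop, n_bins = 40, min_maf = 0.05)
  f <- colMeans(pop$haplotypes[, idx, drop = FALSE])
  expect_true(all(pmin(f, 1 - f) > 0.05))
  expect_true(all(!pop$is_qtl[idx]))
  bins <- floor(pop$positions[idx] / pop$map$length * 40)
  expect_false(any(duplicated(bins)))   # at most one SNP per bin
  # all-monomorphic panel yields a warning and empty selection
  pop0 <- pop
  pop0$haplotypes[] <- 0L
  expect_warning(res <- select_snp_panel(pop0, 40), "empty")
  expect_length(res, 0)
})

test_that("realistic pipeline produces an analysis-ready cohort", {
  suppressMessages(
    sim <- simulate_realistic(n_base = 120, generations = 40,
                              n_snp_loci = 300, n_qtl = 8, n_train = 50,
                              n_bins = 100, h2 = 0.5, dist = "gamma",
                              seed = 58))
  expect_s3_class(sim$genotypes, "genotype_matrix")
  expect_equal(nrow(sim$genotypes$codes), 50)
  expect_equal(length(sim$traits$y), 50)
  expect_equal(var(sim$tbv), 1, tolerance = 1e-10)  # h2 = 0.5 target
  expect_true(is.na(sim$true_pi))                   # QTL not in the panel
})
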