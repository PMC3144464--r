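# engine-level behaviour of the four samplers

make_fit_inputs <- function(n = 60, K = 10, n_qtl = 2, h2 = 0.5, seed = 1) {
  pop <- simulate_ideal(n, K, n_qtl, h2 = h2, seed = seed)
  prior <- build_prior_config("bayesCpi", target_va_from_h2(h2),
                              allele_freqs(pop$genotypes),
                              sigma2_e_prior = 1)
  list(pop = pop, prior = prior)
}

batch_se <- function(x, n_batch = 40) {
  b <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(n_batch)
}

test_that("BayesA keeps every marker in the model at every iteration", {
  inp <- make_fit_inputs(seed = 31)
  prior <- build_prior_config("bayesA", 1, allele_freqs(inp$pop$genotypes),
                              sigma2_e_prior = 1)
  fit <- run_mcmc(inp$pop$genotypes, inp$pop$traits, prior,
                  chain_config(600, 100, seed = 5))
  expect_true(all(fit$snp_effects$model_freq == 1))
  expect_true(all(fit$chains$nsnp == fit$K))
  expect_equal(fit$nsnp_sd, 0)
})

test_that("identical seed and config give bit-identical results", {
  inp <- make_fit_inputs(seed = 32)
  run <- function() run_mcmc(inp$pop$genotypes, inp$pop$traits, inp$prior,
                             chain_config(400, 100, seed = 77))
  f1 <- run(); f2 <- run()
  expect_identical(f1$snp_effects, f2$snp_effects)
  expect_identical(f1$chains, f2$chains)
})

test_that("the adjusted-phenotype reconstruction invariant holds", {
  inp <- make_fit_inputs(n = 120, K = 40, seed = 33)
  for (method in c("bayesB", "bayesCpi", "bayesDpi")) {
    prior <- build_prior_config(method, 1, allele_freqs(inp$pop$genotypes),
                                sigma2_e_prior = 1)
    fit <- run_mcmc(inp$pop$genotypes, inp$pop$traits, prior,
                    chain_config(500, 100, seed = 6),
                    control = mcmc_control(check_every = 50))
    expect_lt(fit$recon_max_rel, 1e-8)
  }
})

test_that("BayesCpi on pure-noise data keeps pi above one half", {
  set.seed(34)
  g <- random_genotypes(200, 100, freq = runif(100, 0.2, 0.8))
  tr <- trait_data(g$individual_ids, rnorm(200))
  prior <- build_prior_config("bayesCpi", 0.2, allele_freqs(g),
                              sigma2_e_prior = 1)
  fit <- run_mcmc(g, tr, prior, chain_config(3000, 1000, seed = 8))
  expect_gt(fit$pi_mean, 0.5)
})

test_that("Cpi Gibbs inclusion frequencies match exact 2^3 enumeration", {
  set.seed(35)
  n <- 12
  Zraw <- vapply(rep(0.5, 3), function(p) rbinom(n, 2, p), integer(n))
  Z <- scale(Zraw, scale = FALSE)
  s2a <- 0.5; s2e <- 1; piv <- 0.6
  a_true <- c(0.8, 0, -0.5)
  y <- as.numeric(Z %*% a_true) + rnorm(n, 0, sqrt(s2e))
  exact <- enumerate_inclusion(Z, y, s2a, s2e, piv)

  g <- genotype_matrix(Zraw)
  prior <- build_prior_config("bayesCpi", 1, allele_freqs(g), pi0 = piv,
                              sigma2_e_prior = 1)
  fit <- run_mcmc(g, trait_data(g$individual_ids, y), prior,
                  chain_config(60000, 2000, seed = 9),
                  control = mcmc_control(fix_mu = TRUE, mu_value = 0,
                                         fix_sigma2_e = TRUE,
                                         sigma2_e_value = s2e,
                                         fix_sigma2_a = TRUE,
                                         sigma2_a_value = s2a,
                                         fix_pi = TRUE))
  freq <- fit$snp_effects$model_freq
  # generous Monte-Carlo band for 58,000 correlated indicator draws
  expect_lt(max(abs(freq - exact)), 0.03)
})

test_that("MH inclusion frequencies match enumeration at concentrated prior", {
  # with very large nu_a the locus-variance prior degenerates at its mean,
  # making the Metropolis-Hastings update comparable to fixed-variance
  # enumeration
  set.seed(36)
  n <- 12
  Zraw <- vapply(rep(0.5, 3), function(p) rbinom(n, 2, p), integer(n))
  Z <- scale(Zraw, scale = FALSE)
  s2a <- 0.5; s2e <- 1; piv <- 0.6
  y <- as.numeric(Z %*% c(0.8, 0, -0.5)) + rnorm(n, 0, 1)
  exact <- enumerate_inclusion(Z, y, s2a, s2e, piv)

  nu_big <- 1e6
  g <- genotype_matrix(Zraw)
  prior <- build_prior_config("bayesB", 1, allele_freqs(g), pi = piv,
                              nu_a = nu_big, sigma2_e_prior = 1)
  prior$S2_a <- scale_from_mean(s2a, nu_big)
  fit <- run_mcmc(g, trait_data(g$individual_ids, y), prior,
                  chain_config(60000, 2000, seed = 10),
                  control = mcmc_control(fix_mu = TRUE, mu_value = 0,
                                         fix_sigma2_e = TRUE,
                                         sigma2_e_value = s2e))
  freq <- fit$snp_effects$model_freq
  # wider band than the Gibbs case: MH mixes more slowly and nu_a is large
  # but finite
  expect_lt(max(abs(freq - exact)), 0.05)
})

test_that("locus-variance posterior gains one degree of freedom", {
  # BayesA, single marker: given the sampled effect a, the conditional of the
  # locus variance is scinvchisq(nu+1, (a^2 + nu S2)/(nu+1)), so
  # (a^2 + nu S2) / sigma2_k ~ chi-square(nu + 1) marginally over the chain
  set.seed(37)
  n <- 40
  z <- rbinom(n, 2, 0.5)
  y <- 0.6 * (z - mean(z)) + rnorm(n)
  g <- genotype_matrix(cbind(z))
  prior <- build_prior_config("bayesA", 0.3, allele_freqs(g),
                              sigma2_e_prior = 1)
  fit <- run_mcmc(g, trait_data(g$individual_ids, y), prior,
                  chain_config(30000, 2000, seed = 11),
                  control = mcmc_control(fix_mu = TRUE, mu_value = mean(y)))
  nu <- prior$nu_a; S2 <- prior$S2_a
  # effect draws are not stored per iteration; reconstruct the implied
  # statistic from the stored locus-variance chain and its known conditional:
  # E[(a^2 + nu S2)/sigma2_k] = nu + 1 under the joint posterior. Use the
  # posterior-mean identity via a second, direct simulation of a | sigma2_k.
  s2k <- fit$chains$sigma2_k1
  c_k <- sum((z - mean(z))^2)  # zWz for the centered column
  # draw a | sigma2_k, y for each kept iteration and form the statistic
  r <- sum((z - mean(z)) * (y - mean(y)))
  s2e <- fit$chains$sigma2_e
  ck <- c_k + s2e / s2k
  a_draw <- rnorm(length(s2k), r / ck, sqrt(s2e / ck))
  q <- (a_draw^2 + nu * S2) / s2k
  se <- batch_se(q)
  expect_lt(abs(mean(q) - (nu + 1)), 4 * se)
})

test_that("BayesCpi with pi near zero and rigid prior matches ridge regression", {
  set.seed(38)
  n <- 50; K <- 20
  Zraw <- vapply(runif(K, 0.2, 0.8), function(p) rbinom(n, 2, p), integer(n))
  Z <- scale(Zraw, scale = FALSE)
  a_true <- rnorm(K, 0, 0.3)
  y <- as.numeric(Z %*% a_true + rnorm(n))
  s2m <- 0.09; s2e <- 1
  ridge <- solve(crossprod(Z) + diag(s2e / s2m, K), crossprod(Z, y))

  g <- genotype_matrix(Zraw)
  # pi clamped essentially at zero: every marker stays in the model, and with
  # the common variance clamped too the posterior mean is the ridge solution
  prior <- build_prior_config("bayesCpi", 1, allele_freqs(g), pi0 = 1e-9,
                              sigma2_e_prior = 1)
  fit <- run_mcmc(g, trait_data(g$individual_ids, y - mean(y)), prior,
                  chain_config(40000, 2000, seed = 12),
                  control = mcmc_control(fix_mu = TRUE, mu_value = 0,
                                         fix_sigma2_e = TRUE,
                                         sigma2_e_value = s2e,
                                         fix_sigma2_a = TRUE,
                                         sigma2_a_value = s2m,
                                         fix_pi = TRUE))
  expect_true(all(fit$snp_effects$model_freq > 0.999))
  est <- fit$snp_effects$posterior_mean
  expect_lt(sqrt(sum((est - ridge)^2) / sum(ridge^2)), 0.01)
})
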