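# small programmatic fixtures shared across the suite

random_genotypes <- function(n, K, freq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freq)) freq <- runif(K, 0.1, 0.9)
  codes <- vapply(freq, function(p) rbinom(n, 2, p), integer(n))
  genotype_matrix(codes)
}

# exact posterior inclusion probabilities for a K-SNP model by enumerating
# all 2^K inclusion patterns, with fixed variances and pi and mu = 0.
# Marginal likelihood of y given the included set S (effects integrated out):
#   y ~ N(0, Z_S Z_S' s2a + I s2e)
enumerate_inclusion <- function(Z, y, s2a, s2e, pi) {
  K <- ncol(Z)
  patterns <- as.matrix(expand.grid(rep(list(0:1), K)))
  logw <- apply(patterns, 1, function(d) {
    S <- which(d == 1)
    V <- diag(s2e, length(y))
    if (length(S) > 0)
      V <- V + Z[, S, drop = FALSE] %*% t(Z[, S, drop = FALSE]) * s2a
    mvn_logdens(y, V) + sum(d) * log(1 - pi) + (K - sum(d)) * log(pi)
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(colSums(patterns * w))
}

mvn_logdens <- function(y, V) {
  R <- chol(V)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) -
    0.5 * sum(backsolve(R, y, transpose = TRUE)^2)
}

# gene-dropping estimate of the numerator relationship matrix: founders get
# unique allele labels, alleles descend with fair Mendelian sampling, and
# a_ij is estimated as twice the mean fraction of allele pairs identical by
# descent across replicates (all matrices vectorized over replicates)
gene_drop_A <- function(ped, n_rep = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  next_label <- 1L
  for (j in seq_len(n)) {
    s <- ped$sire[j]; d <- ped$dam[j]
    if (s == "0") {
      al1[, j] <- next_label; next_label <- next_label + 1L
    } else {
      js <- idx[[s]]
      pick <- runif(n_rep) < 0.5
      al1[, j] <- ifelse(pick, al1[, js], al2[, js])
    }
    if (d == "0") {
      al2[, j] <- next_label; next_label <- next_label + 1L
    } else {
      jd <- idx[[d]]
      pick <- runif(n_rep) < 0.5
      al2[, j] <- ifelse(pick, al1[, jd], al2[, jd])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
      (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])
    A[i, j] <- A[j, i] <- 2 * mean(ibd / 4)
  }
  A
}
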