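#' Genotype quality-control thresholds
#'
#' @param min_maf minimum minor allele frequency a SNP must exceed (default
#'   0.03, i.e. MAF > 3%).
#' @param max_missing maximum tolerated fraction of missing genotypes
#'   (default 0.05).
#' @param hwe_p_min minimum Hardy-Weinberg chi-square p-value (default
#'   1e-10); SNPs with p below this are dropped.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_maf = 0.03, max_missing = 0.05,
                          hwe_p_min = 1e-10) {
  for (v in c(min_maf, max_missing, hwe_p_min))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("all QC thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(min_maf = min_maf, max_missing = max_missing,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

# 1-df chi-square HWE test on the three genotype-class counts
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  exp_counts <- n * c(q^2, 2 * p * q, p^2)
  obs <- c(n0, n1, n2)
  if (any(exp_counts == 0)) {
    # monomorphic: observed equals expected, no HWE evidence
    if (all(obs[exp_counts == 0] == 0)) return(list(stat = 0, p = 1))
    return(list(stat = Inf, p = 0))
  }
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Filter SNPs on MAF, missingness and Hardy-Weinberg equilibrium
#'
#' Applies the three marker filters in order (MAF, missing fraction, HWE) and
#' reports, for each dropped SNP, the first rule it failed. Surviving SNPs
#' have their remaining missing genotypes mean-imputed to `2 * p_k`, where
#' `p_k` is the allele frequency among observed genotypes, so that the
#' post-imputation column mean is unchanged.
#'
#' @param g a [genotype_matrix()], possibly with `NA` codes.
#' @param thresholds a [qc_thresholds()].
#' @return a list with `genotypes` (the filtered, imputed
#'   [genotype_matrix()]) and `report`, a tibble with columns `snp_id`,
#'   `reason` (`"maf"`, `"missing"` or `"hwe"`) and `value` for every dropped
#'   SNP.
#' @export
qc_filter <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  codes <- g$codes
  n <- nrow(codes)
  miss_frac <- colMeans(is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(codes)), function(k) {
    x <- codes[, k]
    x <- x[!is.na(x)]
    # integer genotype classes; imputed dosages count toward the nearest class
    hwe_chisq_p(sum(x < 0.5), sum(x >= 0.5 & x < 1.5), sum(x >= 1.5))$p
  }, 0)
  reason <- rep(NA_character_, ncol(codes))
  value <- rep(NA_real_, ncol(codes))
  fail_maf <- !(maf > thresholds$min_maf)
  fail_missing <- !(miss_frac < thresholds$max_missing)
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  reason[fail_hwe] <- "hwe"; value[fail_hwe] <- hwe_p[fail_hwe]
  reason[fail_missing] <- "missing"; value[fail_missing] <- miss_frac[fail_missing]
  reason[fail_maf] <- "maf"; value[fail_maf] <- maf[fail_maf]
  keep <- is.na(reason)
  if (!any(keep))
    stop("QC dropped every SNP; no marker panel remains", call. = FALSE)
  report <- tibble::tibble(snp_id = g$snp_ids[!keep],
                           reason = reason[!keep],
                           value = value[!keep])
  kept <- codes[, keep, drop = FALSE]
  for (k in seq_len(ncol(kept))) {
    na <- is.na(kept[, k])
    if (any(na)) kept[na, k] <- mean(kept[!na, k])
  }
  list(genotypes = genotype_matrix(kept,
                                   individual_ids = g$individual_ids,
                                   snp_ids = g$snp_ids[keep]),
       report = report)
}
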