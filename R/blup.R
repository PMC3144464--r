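#' Genomic relationship matrix
#'
#' `G = M M' / (2 sum p_k (1 - p_k))` with `M` the column-centered genotype
#' matrix (`codes - 2 p_k`), so that under Hardy-Weinberg the average
#' diagonal tends to 1. G-BLUP with this matrix is equivalent to ridge
#' regression on the markers. Allele frequencies come from the supplied
#' genotyped set.
#'
#' @param g a [genotype_matrix()] without missing codes.
#' @return a `relationship_matrix` of kind `"genomic"`.
#' @export
build_G <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$codes)) stop("impute missing genotypes before build_G",
                           call. = FALSE)
  p <- g$allele_freqs
  M <- sweep(g$codes, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers fixed; G undefined", call. = FALSE)
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(g$individual_ids, g$individual_ids)
  structure(list(ids = g$individual_ids, mat = G, kind = "genomic"),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> %s, %d individuals\n", x$kind,
              length(x$ids)))
  invisible(x)
}

#' Solve the animal model for estimated breeding values
#'
#' Mixed-model equations for `y = 1 mu + Z g + e` with `g ~ N(0, rel *
#' sigma2_g)` and `var(e_i) = sigma2_e / w_i`. Individuals in `rel` without a
#' phenotype receive predicted breeding values through their relationships.
#'
#' @param rel a `relationship_matrix` ([build_A()] or [build_G()]).
#' @param traits a [trait_data()]; every phenotyped id must be in `rel`.
#' @param h2 heritability used to derive the variance ratio when explicit
#'   variances are not given.
#' @param sigma2_g,sigma2_e genetic and residual variances (override `h2`).
#' @param ridge added to the diagonal of a numerically singular relationship
#'   matrix, with a warning (default 1e-6).
#' @return a tibble with columns `id` and `ebv`, ordered as `rel$ids`.
#' @export
solve_animal_model <- function(rel, traits, h2 = NULL, sigma2_g = NULL,
                               sigma2_e = NULL, ridge = 1e-6) {
  stopifnot(inherits(rel, "relationship_matrix"))
  if (is.null(sigma2_g) || is.null(sigma2_e)) {
    if (is.null(h2)) stop("supply h2 or both variances", call. = FALSE)
    sigma2_g <- h2
    sigma2_e <- 1 - h2
  }
  idx <- match(traits$id, rel$ids)
  if (anyNA(idx))
    stop("phenotyped individuals missing from relationship matrix",
         call. = FALSE)
  # variance form: V = sigma2_g K_oo + W^-1 sigma2_e on the phenotyped set,
  # mu by GLS, breeding values by the BLUP projection sigma2_g K_.o V^-1 e.
  # This never inverts K, so a singular genomic matrix (G always has the
  # 1-vector in its null space when frequencies come from the same
  # individuals) is handled without regularisation.
  w <- traits$weight
  V <- sigma2_g * rel$mat[idx, idx, drop = FALSE] +
    diag(sigma2_e / w, length(idx))
  R <- tryCatch(chol(V), error = function(e) {
    warning("phenotypic covariance numerically singular; adding ridge ",
            ridge, call. = FALSE)
    chol(V + diag(ridge, length(idx)))
  })
  Vinv_solve <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
  one <- rep(1, length(idx))
  Vi1 <- Vinv_solve(one)
  mu_hat <- sum(Vi1 * traits$y) / sum(Vi1 * one)
  alpha <- Vinv_solve(traits$y - mu_hat)
  ebv <- sigma2_g * as.numeric(rel$mat[, idx, drop = FALSE] %*% alpha)
  tibble::tibble(id = rel$ids, ebv = ebv)
}

#' Genomic BLUP
#'
#' Builds `G` from the genotypes and solves the animal model; equivalent to
#' ridge regression on the markers.
#'
#' @inheritParams solve_animal_model
#' @param g a [genotype_matrix()].
#' @return a tibble `id`, `ebv` for every genotyped individual.
#' @export
gblup <- function(g, traits, h2 = NULL, sigma2_g = NULL, sigma2_e = NULL,
                  ridge = 1e-6) {
  solve_animal_model(build_G(g), traits, h2 = h2, sigma2_g = sigma2_g,
                     sigma2_e = sigma2_e, ridge = ridge)
}

#' Pedigree BLUP
#'
#' Builds the numerator relationship matrix and solves the animal model.
#'
#' @inheritParams solve_animal_model
#' @param ped a [pedigree()].
#' @return a tibble `id`, `ebv` for every pedigree individual.
#' @export
pblup <- function(ped, traits, h2 = NULL, sigma2_g = NULL, sigma2_e = NULL) {
  solve_animal_model(build_A(ped), traits, h2 = h2, sigma2_g = sigma2_g,
                     sigma2_e = sigma2_e)
}
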