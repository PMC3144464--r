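#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds SNP genotypes for a set of individuals, coded as
#' the number of copies of one of the two SNP alleles (0, 1 or 2). Missing
#' genotypes may be present as `NA` until [qc_filter()] imputes them; after
#' imputation codes are real-valued dosages in `[0, 2]`.
#'
#' @param codes numeric matrix, individuals in rows and SNPs in columns, with
#'   entries in `{0, 1, 2}` (or `[0, 2]` for imputed dosages) and `NA` for
#'   missing.
#' @param individual_ids character vector of row identifiers.
#' @param snp_ids character vector of column identifiers.
#' @return an object of class `genotype_matrix` with fields `codes`,
#'   `individual_ids`, `snp_ids` and `allele_freqs` (column mean / 2, computed
#'   over observed genotypes).
#' @export
genotype_matrix <- function(codes,
                            individual_ids = rownames(codes),
                            snp_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  if (length(individual_ids) != nrow(codes))
    stop("individual_ids must match the number of rows", call. = FALSE)
  if (length(snp_ids) != ncol(codes))
    stop("snp_ids must match the number of columns", call. = FALSE)
  ok <- is.na(codes) | (codes >= 0 & codes <= 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype code outside [0, 2] at individual %s, SNP %s",
                 individual_ids[bad[1]], snp_ids[bad[2]]), call. = FALSE)
  }
  dimnames(codes) <- list(individual_ids, snp_ids)
  structure(
    list(individual_ids = as.character(individual_ids),
         snp_ids = as.character(snp_ids),
         codes = codes,
         allele_freqs = colMeans(codes, na.rm = TRUE) / 2),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs\n",
              nrow(x$codes), ncol(x$codes)))
  nm <- sum(is.na(x$codes))
  if (nm > 0) cat(sprintf("  %d missing genotypes (pre-QC)\n", nm))
  cat(sprintf("  allele frequency range: %.3f - %.3f\n",
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Allele frequencies of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector `p_k`, one entry per SNP, equal to the column mean
#'   of the genotype codes divided by 2 (observed genotypes only).
#' @export
allele_freqs <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  g$allele_freqs
}

#' Read genotypes from a delimited file
#'
#' Two dialects are supported. `"matrix"`: an optional header line of SNP ids,
#' then one row per individual consisting of the individual id followed by K
#' genotype codes, whitespace- or comma-separated; `NA` or `-9` denote a
#' missing genotype. `"plink_raw"`: the PLINK `.raw` additive-dosage format
#' with the FID IID PAT MAT SEX PHENOTYPE leading columns followed by per-SNP
#' allele counts.
#'
#' @param path file path.
#' @param dialect `"matrix"` or `"plink_raw"`.
#' @return a [genotype_matrix()]; missing codes are retained as `NA` until QC.
#' @export
read_genotypes <- function(path, dialect = c("matrix", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty genotype file: ", path, call. = FALSE)
  split_fields <- function(x) strsplit(trimws(x), "[,[:space:]]+")
  if (dialect == "plink_raw") {
    header <- split_fields(lines[1])[[1]]
    if (length(header) < 7 || header[1] != "FID")
      stop("not a PLINK .raw header in ", path, call. = FALSE)
    snp_ids <- sub("_[A-Za-z0-9]+$", "", header[-(1:6)])
    body <- split_fields(lines[-1])
    K <- length(snp_ids)
    parse_row <- function(f, line_no) {
      if (length(f) != K + 6)
        stop(sprintf("line %d: expected %d fields, found %d",
                     line_no, K + 6, length(f)), call. = FALSE)
      list(id = f[2], codes = parse_codes(f[-(1:6)], line_no))
    }
    rows <- Map(parse_row, body, seq_along(body) + 1L)
  } else {
    fields <- split_fields(lines)
    has_header <- is.na(suppressWarnings(as.numeric(fields[[1]][2]))) &&
      !fields[[1]][2] %in% c("NA", "-9")
    snp_ids <- NULL
    if (has_header) {
      hd <- fields[[1]]
      snp_ids <- if (length(hd) > 1 &&
                     length(hd) == length(fields[[2]]) - 1) hd else hd[-1]
      fields <- fields[-1]
    }
    if (length(fields) == 0) stop("empty genotype file: ", path, call. = FALSE)
    K <- length(fields[[1]]) - 1L
    if (K < 1) stop("line 1: no genotype codes found", call. = FALSE)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(K))
    if (length(snp_ids) != K)
      stop("header has ", length(snp_ids), " SNP ids but rows have ", K,
           " codes", call. = FALSE)
    rows <- Map(function(f, line_no) {
      if (length(f) != K + 1)
        stop(sprintf("line %d: expected %d fields, found %d",
                     line_no, K + 1, length(f)), call. = FALSE)
      list(id = f[1], codes = parse_codes(f[-1], line_no))
    }, fields, seq_along(fields) + has_header)
  }
  codes <- do.call(rbind, lapply(rows, `[[`, "codes"))
  genotype_matrix(codes,
                  individual_ids = vapply(rows, `[[`, "", "id"),
                  snp_ids = snp_ids)
}

parse_codes <- function(x, line_no) {
  x[x %in% c("NA", "-9")] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & (is.na(v) | !v %in% c(0, 1, 2)))
  if (length(bad) > 0)
    stop(sprintf("line %d: unknown genotype code '%s'", line_no, x[bad[1]]),
         call. = FALSE)
  v
}

#' Write genotypes in the matrix dialect
#'
#' Writes a header line of SNP ids then one row per individual (id followed by
#' codes, space separated, `NA` for missing). [read_genotypes()] on the result
#' round-trips.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  header <- paste(c("id", g$snp_ids), collapse = " ")
  body <- vapply(seq_along(g$individual_ids), function(i)
    paste(c(g$individual_ids[i], format(g$codes[i, ], trim = TRUE)),
          collapse = " "), "")
  writeLines(c(header, body), path)
  invisible(path)
}
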