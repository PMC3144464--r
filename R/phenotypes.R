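#' Construct a trait-data table
#'
#' Phenotypes (or de-regressed-proof-style pseudo-phenotypes) with optional
#' residual weights. Under the model the residual variance of record i is
#' `sigma2_e / weight_i`; the default weight 1 gives homogeneous residuals.
#' The only fixed effect fitted throughout the package is the overall mean.
#'
#' @param individual_ids character vector of ids.
#' @param y numeric phenotype vector.
#' @param weights strictly positive residual weights (default 1).
#' @return a tibble of class `trait_data` with columns `id`, `y`, `weight`.
#' @export
trait_data <- function(individual_ids, y, weights = 1) {
  individual_ids <- as.character(individual_ids)
  y <- as.numeric(y)
  weights <- rep_len(as.numeric(weights), length(y))
  if (length(individual_ids) != length(y))
    stop("individual_ids and y must have the same length", call. = FALSE)
  if (anyNA(y)) stop("phenotypes contain missing values", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  out <- tibble::tibble(id = individual_ids, y = y, weight = weights)
  class(out) <- c("trait_data", class(out))
  out
}

#' Read phenotypes from a CSV file
#'
#' Expected columns: `individual,value[,weight]` with an optional header.
#'
#' @param path file path.
#' @return a [trait_data()] tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][2])))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype file needs at least 2 columns", call. = FALSE)
  trait_data(df[[1]], df[[2]],
             weights = if (ncol(df) >= 3) df[[3]] else 1)
}

#' Write phenotypes as CSV
#'
#' @param tr a [trait_data()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(tr, path) {
  utils::write.csv(as.data.frame(tr)[c("id", "y", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
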