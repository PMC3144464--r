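#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers are returned numeric. Recognised keys include
#' `method, sigma2_a, sigma2_e, sigma2_u, nu_a, pi, pi0, chain_length,
#' burn_in, seed, mh_reps`.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib bayesalphabet, .registration = TRUE
NULL
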