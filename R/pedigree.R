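#' Construct a pedigree
#'
#' Records of (individual, sire, dam) with `"0"` (or `NA`) meaning an unknown
#' parent. The records must be topologically ordered: every parent appears as
#' an individual on an earlier row (founders first). No individual may be its
#' own ancestor.
#'
#' @param individual,sire,dam character vectors of equal length.
#' @return a tibble of class `pedigree` with columns `id`, `sire`, `dam`.
#' @export
pedigree <- function(individual, sire, dam) {
  id <- as.character(individual)
  sire <- as.character(sire); dam <- as.character(dam)
  sire[is.na(sire)] <- "0"; dam[is.na(dam)] <- "0"
  if (anyDuplicated(id))
    stop("duplicated individual id in pedigree: ",
         id[duplicated(id)][1], call. = FALSE)
  seen <- character(0)
  for (i in seq_along(id)) {
    for (par in c(sire[i], dam[i])) {
      if (par == "0") next
      if (par == id[i])
        stop("individual ", id[i], " is its own parent", call. = FALSE)
      if (!par %in% seen)
        stop("pedigree not topologically ordered: parent ", par,
             " of ", id[i], " not previously defined", call. = FALSE)
    }
    seen <- c(seen, id[i])
  }
  out <- tibble::tibble(id = id, sire = sire, dam = dam)
  class(out) <- c("pedigree", class(out))
  out
}

#' Read a pedigree CSV (individual,sire,dam; 0 = unknown parent)
#'
#' @param path file path.
#' @return a [pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("sire|individual|id", first, ignore.case = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 3) stop("pedigree file needs 3 columns", call. = FALSE)
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree as CSV
#'
#' @param ped a [pedigree()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped)[c("id", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular (recursive) method: `a_ij = (a_{i,sire(j)} + a_{i,dam(j)}) / 2` for
#' `i < j` and `a_jj = 1 + a_{sire(j),dam(j)} / 2`; unknown parents contribute
#' zero. Inbreeding accumulates through the diagonal term.
#'
#' @param ped a [pedigree()].
#' @return a `relationship_matrix` (list with `ids`, dense symmetric `mat`,
#'   `kind = "numerator"`).
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1) {
      prev <- seq_len(j - 1)
      as_ <- if (s > 0) A[prev, s] else rep(0, j - 1)
      ad_ <- if (d > 0) A[prev, d] else rep(0, j - 1)
      A[prev, j] <- A[j, prev] <- (as_ + ad_) / 2
    }
    A[j, j] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  structure(list(ids = ped$id, mat = A, kind = "numerator"),
            class = "relationship_matrix")
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Builds `A^-1` directly from the pedigree using Henderson's contribution
#' rules without the inbreeding adjustment: the Mendelian-sampling precision
#' is 2 with both parents known, 4/3 with one, and 1 with none.
#'
#' @param ped a [pedigree()].
#' @return a dense matrix with dimnames equal to the pedigree ids.
#' @export
build_Ainv <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  Ainv <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- if (ped$sire[j] == "0") 0L else idx[[ped$sire[j]]]
    d <- if (ped$dam[j] == "0") 0L else idx[[ped$dam[j]]]
    np <- (s > 0) + (d > 0)
    alpha <- c(1, 4 / 3, 2)[np + 1]
    Ainv[j, j] <- Ainv[j, j] + alpha
    for (p in c(s, d)[c(s, d) > 0]) {
      Ainv[p, j] <- Ainv[p, j] - alpha / 2
      Ainv[j, p] <- Ainv[j, p] - alpha / 2
      for (q in c(s, d)[c(s, d) > 0])
        Ainv[p, q] <- Ainv[p, q] + alpha / 4
    }
  }
  Ainv
}
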