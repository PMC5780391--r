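# Pedigree handling and the additive (numerator) relationship matrix.

.normalise_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

#' Construct a pedigree
#'
#' A pedigree is a data frame of parentage records with columns `animal`,
#' `sire` and `dam` (plus optional `sex` and `generation`). Unknown parents
#' are encoded as `NA`; the strings `""` and `"0"` are accepted as synonyms
#' on input. Animals that appear only as parents are inserted as founder
#' records with a warning, so that every parent reference resolves.
#'
#' @param animal character vector of unique animal identifiers.
#' @param sire,dam parent identifiers (`NA`, `""` or `"0"` = unknown).
#' @param sex optional per-animal sex, `"M"` or `"F"`.
#' @param generation optional non-negative integer per animal.
#' @return A `pedigree` object (a classed data frame).
#' @examples
#' ped <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"))
#' @export
pedigree <- function(animal, sire = NA, dam = NA, sex = NULL, generation = NULL) {
  animal <- as.character(animal)
  n <- length(animal)
  if (n == 0L) stop("pedigree must contain at least one record")
  sire <- .normalise_parent(rep_len(as.character(sire), n))
  dam <- .normalise_parent(rep_len(as.character(dam), n))
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  self <- (!is.na(sire) & sire == animal) | (!is.na(dam) & dam == animal)
  if (any(self)) {
    stop("animal listed as its own parent: ", animal[which(self)[1]])
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) ped$sex <- rep_len(as.character(sex), n)
  if (!is.null(generation)) ped$generation <- rep_len(as.integer(generation), n)
  missing_parents <- setdiff(stats::na.omit(unique(c(sire, dam))), animal)
  if (length(missing_parents)) {
    warning(length(missing_parents),
            " parent id(s) not listed as animals; inserted as founders: ",
            paste(utils::head(missing_parents, 5), collapse = ", "))
    add <- data.frame(animal = missing_parents, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    for (col in setdiff(names(ped), names(add))) add[[col]] <- NA
    ped <- rbind(add[, names(ped)], ped)
  }
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Validate a pedigree and sort parents before offspring
#'
#' Checks that every parent reference resolves, that no animal is its own
#' ancestor, and returns the records in a topological order (every parent
#' precedes its offspring). The relative order of records is otherwise
#' preserved, so a founders-only pedigree comes back unchanged.
#'
#' @param ped a [pedigree()] object or data frame with columns
#'   `animal`, `sire`, `dam`.
#' @return The same records, topologically sorted, with attribute
#'   `sorted = TRUE`.
#' @export
validate_and_sort <- function(ped) {
  if (!all(c("animal", "sire", "dam") %in% names(ped))) {
    stop("pedigree needs columns animal, sire, dam")
  }
  if (nrow(ped) == 0L) stop("pedigree must contain at least one record")
  animal <- as.character(ped$animal)
  sire <- .normalise_parent(ped$sire)
  dam <- .normalise_parent(ped$dam)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  dangling <- setdiff(stats::na.omit(unique(c(sire, dam))), animal)
  if (length(dangling)) {
    stop("parent id(s) not present in pedigree: ",
         paste(dangling, collapse = ", "))
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(si) | placed[si]) &
      (is.na(di) | placed[di])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree contains a parentage cycle involving animal ",
         animal[which(!placed)[1]])
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

.assert_sorted <- function(ped) {
  animal <- as.character(ped$animal)
  si <- match(.normalise_parent(ped$sire), animal)
  di <- match(.normalise_parent(ped$dam), animal)
  pos <- seq_along(animal)
  ok <- (is.na(si) | si < pos) & (is.na(di) | di < pos)
  if (!all(ok)) {
    stop("pedigree is not sorted parents-first; run validate_and_sort() first")
  }
  list(animal = animal, si = si, di = di)
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds the matrix A of expected additive genetic relationships (twice the
#' kinship coefficient) by the classic tabular recursion: processing animals
#' parents-first, `a_ii = 1 + 0.5 a_sd` and, for every earlier animal j,
#' `a_ij = 0.5 (a_js + a_jd)`, with unknown parents contributing zero.
#' Diagonal entries are `1 + F_i` where `F_i` is the inbreeding coefficient.
#'
#' @param ped a sorted pedigree (see [validate_and_sort()]).
#' @return A dense symmetric numeric matrix with animal ids as dimnames.
#' @export
additive_relationship <- function(ped) {
  idx <- .assert_sorted(ped)
  n <- length(idx$animal)
  A <- matrix(0, n, n, dimnames = list(idx$animal, idx$animal))
  for (i in seq_len(n)) {
    s <- idx$si[i]
    d <- idx$di[i]
    if (i > 1L && (!is.na(s) || !is.na(d))) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else 0
      ad_ <- if (!is.na(d)) A[j, d] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Invert a relationship matrix
#'
#' Dense inverse via Cholesky decomposition; at colony scale (a few hundred
#' to a few thousand animals) this is exact and avoids bookkeeping for
#' Henderson-style sparse rules.
#'
#' @param A positive-definite relationship matrix.
#' @return The inverse, with the same dimnames.
#' @export
inverse_relationship <- function(A) {
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    stop(sprintf(
      "relationship matrix is singular or ill-conditioned (rcond = %.3e)", rc))
  }
  ch <- tryCatch(chol(A), error = function(e) {
    stop("Cholesky factorization failed: ", conditionMessage(e))
  })
  Ainv <- chol2inv(ch)
  dimnames(Ainv) <- dimnames(A)
  Ainv
}

#' Read a pedigree from CSV
#'
#' Expects a comma-separated file with a header containing at least the
#' columns `animal`, `sire`, `dam` (optional `sex`, `generation`). An empty
#' field or the sentinel `"0"` marks an unknown parent.
#'
#' @param path file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(fields) < 2L) stop("pedigree file has no data rows: ", path)
  bad <- which(fields != fields[1])
  if (length(bad)) {
    stop("malformed pedigree row (wrong field count) at line ", bad[1] + 0L,
         " of ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(raw))) {
    stop("pedigree file must have header columns animal, sire, dam")
  }
  pedigree(raw$animal, raw$sire, raw$dam,
           sex = if ("sex" %in% names(raw)) raw$sex else NULL,
           generation = if ("generation" %in% names(raw)) {
             suppressWarnings(as.integer(raw$generation))
           } else NULL)
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `"0"`; `read_pedigree()` of the result
#' reproduces the pedigree.
#'
#' @param ped a pedigree.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
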