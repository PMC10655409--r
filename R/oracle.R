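# Brute-force reference implementations. These define correctness for the
# fast nibble-table search on small instances; performance is irrelevant here.

#' Reference pairwise-AND bicluster enumeration (bit level)
#'
#' Direct, unencoded implementation of the same contract as [bitclust()]:
#' whole-row bitwise AND over every seed pair, explicit containment scans, no
#' nibble table. Used as the correctness oracle for set-equality tests.
#'
#' @param x binary matrix.
#' @param r_min,c_min minimum bicluster dimensions.
#' @param max_dim refuse inputs with more than `max_dim` rows or columns
#'   (oracle runtime is quadratic-times-linear and unoptimized).
#' @return list of biclusters (`list(rows =, cols =)`), in canonical order
#'   (sorted by row-set key then column-set key).
#' @export
reference_pairwise_and <- function(x, r_min = 2L, c_min = 2L, max_dim = 64L) {
  x <- as_binary_matrix(x)
  n <- nrow(x)
  if (n > max_dim || ncol(x) > max_dim) {
    stop(sprintf("oracle size cap exceeded (%d x %d > %d); raise max_dim explicitly if intended",
                 n, ncol(x), max_dim))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tmpl <- x[i, ] & x[j, ]
        key <- paste(as.integer(tmpl), collapse = "")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        J <- unname(which(tmpl))
        if (length(J) < c_min) next
        hits <- unname(which(rowSums(x[, J, drop = FALSE]) == length(J)))
        I <- sort(unique(c(i, j, hits)))
        if (length(I) >= r_min) {
          out[[length(out) + 1L]] <- list(rows = I, cols = J)
        }
      }
    }
  }
  canonical_order(out)
}

# deterministic ordering decoupled from discovery order
canonical_order <- function(bics) {
  if (!length(bics)) return(bics)
  keys <- vapply(bics, function(b) {
    paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","), sep = "|")
  }, character(1))
  bics[order(keys)]
}

#' Canonical string keys of a bicluster collection
#'
#' Sorted `"rows|cols"` keys, decoupled from discovery order; two collections
#' are set-equal iff their key vectors are identical.
#'
#' @param x bicluster collection (anything accepted by [as_bicluster_list()]).
#' @return sorted character vector.
#' @export
bicluster_keys <- function(x) {
  bics <- as_bicluster_list(x)
  sort(vapply(bics, function(b) {
    paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","), sep = "|")
  }, character(1)))
}

#' Verify that a bicluster is maximal
#'
#' A bicluster `(I, J)` is maximal when no row outside `I` is 1 on every
#' column of `J` and no column outside `J` is 1 on every row of `I`. Errors
#' if the candidate is not an all-ones submatrix.
#'
#' @param b bicluster (`list(rows =, cols =)`).
#' @param x the source binary matrix.
#' @return `TRUE` or `FALSE`.
#' @export
verify_maximal <- function(b, x) {
  x <- as_binary_matrix(x)
  I <- sort(as.integer(b$rows)); J <- sort(as.integer(b$cols))
  sub <- x[I, J, drop = FALSE]
  if (any(sub != 1L)) stop("candidate is not an all-ones submatrix")
  other_rows <- setdiff(seq_len(nrow(x)), I)
  if (length(other_rows) &&
      any(rowSums(x[other_rows, J, drop = FALSE]) == length(J))) {
    return(FALSE)
  }
  other_cols <- setdiff(seq_len(ncol(x)), J)
  if (length(other_cols) &&
      any(colSums(x[I, other_cols, drop = FALSE]) == length(I))) {
    return(FALSE)
  }
  TRUE
}

#' Exhaustive closed-pattern enumeration
#'
#' Enumerates every maximal all-ones submatrix meeting the size minimums by
#' closing over all non-empty row subsets: for each subset, take the columns
#' that are 1 across it, then re-collect every row covering those columns,
#' and keep the distinct maximal closures. Exponential in the row count —
#' used only to characterize, on small instances, which maximal biclusters
#' the pairwise-AND strategy can miss.
#'
#' @param x binary matrix.
#' @param min_rows,min_cols minimum dimensions.
#' @param max_dim refuse inputs larger than `max_dim` in either dimension.
#' @return canonical-ordered list of biclusters.
#' @export
enumerate_closed <- function(x, min_rows = 2L, min_cols = 2L, max_dim = 20L) {
  x <- as_binary_matrix(x)
  n <- nrow(x)
  if (n > max_dim || ncol(x) > max_dim) {
    stop(sprintf("closed-pattern enumeration capped at %d x %d", max_dim, max_dim))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    I0 <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    J <- unname(which(colSums(x[I0, , drop = FALSE]) == length(I0)))
    if (length(J) < min_cols) next
    I <- unname(which(rowSums(x[, J, drop = FALSE]) == length(J)))
    if (length(I) < min_rows) next
    key <- paste(paste(I, collapse = ","), paste(J, collapse = ","), sep = "|")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- list(rows = I, cols = J)
    }
  }
  canonical_order(out)
}
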