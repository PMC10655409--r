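#' Encode a binary matrix into 4-bit nibble rows
#'
#' Each row of the 0/1 matrix is packed into `P = ceiling(M/4)` nibbles, each a
#' decimal value in 0..15. Within a nibble the leftmost column is the most
#' significant bit, so the bit row `0101 1100` encodes to nibbles `(5, 12)`.
#' When the column count is not a multiple of 4 the final nibble is zero-padded
#' on the right; padded bits are always 0 and never contribute to template
#' widths.
#'
#' @param x a binary matrix (anything accepted by [as_binary_matrix()]).
#' @return an object of class `encoded_matrix`: a list with `nibbles` (N x P
#'   integer matrix), `n_col` (original column count M), `pad_bits`,
#'   `row_labels` and `col_labels`.
#' @seealso [decode_matrix()] for the exact inverse.
#' @examples
#' enc <- encode_matrix(matrix(c(0, 1, 0, 1, 1, 1, 0, 0), 1, byrow = TRUE))
#' enc$nibbles  # 5 12
#' @export
encode_matrix <- function(x) {
  x <- as_binary_matrix(x)
  m <- ncol(x)
  p <- as.integer(ceiling(m / 4))
  pad <- 4L * p - m
  if (pad > 0L) {
    x_pad <- cbind(x, matrix(0L, nrow(x), pad))
  } else {
    x_pad <- x
  }
  nib <- matrix(0L, nrow(x), p)
  for (k in seq_len(p)) {
    j <- 4L * (k - 1L)
    nib[, k] <- 8L * x_pad[, j + 1L] + 4L * x_pad[, j + 2L] +
      2L * x_pad[, j + 3L] + x_pad[, j + 4L]
  }
  rownames(nib) <- rownames(x)
  structure(
    list(nibbles = nib, n_col = m, pad_bits = pad,
         row_labels = rownames(x), col_labels = colnames(x)),
    class = "encoded_matrix"
  )
}

#' Decode a nibble-encoded matrix back to 0/1 form
#'
#' Exact inverse of [encode_matrix()]: expands every nibble to four bits
#' (most significant first) and drops the padded trailing bits.
#'
#' @param enc an `encoded_matrix`.
#' @return the original integer 0/1 matrix with its labels.
#' @export
decode_matrix <- function(enc) {
  stopifnot(inherits(enc, "encoded_matrix"))
  nib <- enc$nibbles
  p <- ncol(nib)
  out <- matrix(0L, nrow(nib), 4L * p)
  for (k in seq_len(p)) {
    j <- 4L * (k - 1L)
    out[, j + 1L] <- nib[, k] %/% 8L
    out[, j + 2L] <- (nib[, k] %/% 4L) %% 2L
    out[, j + 3L] <- (nib[, k] %/% 2L) %% 2L
    out[, j + 4L] <- nib[, k] %% 2L
  }
  out <- out[, seq_len(enc$n_col), drop = FALSE]
  rownames(out) <- enc$row_labels
  colnames(out) <- enc$col_labels
  out
}

#' @method print encoded_matrix
#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("Nibble-encoded binary matrix: %d rows, %d columns (%d nibbles/row, %d pad bits)\n",
              nrow(x$nibbles), x$n_col, ncol(x$nibbles), x$pad_bits))
  invisible(x)
}

#' Submask lookup table for nibble containment queries
#'
#' Builds the 16 submask sets `V_0..V_15`. `V_0 = {0}` and, for `i >= 1`,
#' `V_i` holds the nonzero values `x` with `bitwAnd(i, x) == x` — i.e. the
#' nonzero submasks of `i`. The table also carries, for each value `i`, the
#' probability `P_i` that a uniformly drawn set `V_j` contains `i` (the
#' success probability of a column-wise row-inclusion lookup under uniform
#' nibbles). Total membership over all sets is 66, so the mean per-lookup
#' success probability is 66/256, roughly one quarter — the constant behind
#' the algorithm's average-case geometric decay of surviving rows.
#'
#' The membership predicate used by the search extends the set definition: a
#' template nibble of 0 is contained in every row nibble (0 is a submask of
#' everything), so all-zero template positions never reject a row.
#'
#' @return an object of class `submask_table`: list with `members` (list of 16
#'   integer vectors, named "0".."15"), `grid` (16 x 16 logical lookup,
#'   `grid[t+1, r+1]` = "template nibble t admits row nibble r"), and `probs`
#'   (numeric, `P_i` for i = 0..15).
#' @examples
#' v <- submask_table()
#' v$members[["5"]]  # 1 4 5
#' sum(lengths(v$members))  # 66
#' @export
submask_table <- function() {
  members <- vector("list", 16L)
  names(members) <- as.character(0:15)
  members[["0"]] <- 0L
  for (i in 1:15) {
    x <- 1:15
    members[[as.character(i)]] <- x[bitwAnd(i, x) == x]
  }
  grid <- outer(0:15, 0:15, function(t, r) bitwAnd(r, t) == t)
  dimnames(grid) <- list(template = 0:15, row = 0:15)
  probs <- vapply(0:15, function(i) {
    mean(vapply(members, function(v) i %in% v, logical(1)))
  }, numeric(1))
  names(probs) <- 0:15
  structure(list(members = members, grid = grid, probs = probs),
            class = "submask_table")
}

#' @method print submask_table
#' @export
print.submask_table <- function(x, ...) {
  cat("Submask lookup table V_0..V_15\n")
  cat(sprintf("  total membership: %d;  mean search probability: %.6f\n",
              sum(lengths(x$members)), mean(x$probs)))
  invisible(x)
}

#' Nibble containment predicate
#'
#' Answers whether a template nibble is admitted by a row nibble: `TRUE` iff
#' `bitwAnd(row_nibble, template_nibble) == template_nibble`, i.e. the row has
#' a 1 wherever the template does. A template nibble of 0 is admitted by every
#' row nibble. Vectorized over both arguments.
#'
#' @param template_nibble,row_nibble integer values in 0..15.
#' @param table a [submask_table()] (built on the fly if omitted).
#' @return logical vector.
#' @export
submask_contains <- function(template_nibble, row_nibble, table = submask_table()) {
  if (any(template_nibble < 0L | template_nibble > 15L) ||
      any(row_nibble < 0L | row_nibble > 15L)) {
    stop("nibble values must lie in 0..15")
  }
  table$grid[cbind(template_nibble + 1L, row_nibble + 1L)]
}
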