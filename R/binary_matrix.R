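#' Coerce and validate a binary matrix
#'
#' The algorithm's substrate is a dense labeled 0/1 matrix. This helper
#' coerces data frames and unlabeled matrices, attaches default labels
#' (`r1..rN`, `c1..cM`) where missing, and rejects anything that is not
#' exactly 0/1 with a cell-addressed error.
#'
#' @param x matrix or data frame of 0/1 values.
#' @param row_labels,col_labels optional character vectors overriding dimnames;
#'   must be unique within their axis.
#' @return an integer matrix with complete, unique dimnames.
#' @examples
#' as_binary_matrix(matrix(c(1, 0, 0, 1), 2))
#' @export
as_binary_matrix <- function(x, row_labels = NULL, col_labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("matrix must have at least one row and one column")
  bad <- which(is.na(x) | (x != 0 & x != 1))  # validate before integer coercion
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-binary value at cell (%d, %d): %s", i, j,
                 deparse(x[[i, j]])), call. = FALSE)
  }
  storage.mode(x) <- "integer"
  if (!is.null(row_labels)) rownames(x) <- row_labels
  if (!is.null(col_labels)) colnames(x) <- col_labels
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("row labels must be unique")
  if (anyDuplicated(colnames(x))) stop("column labels must be unique")
  x
}

is_binary_matrix <- function(x) {
  is.matrix(x) && !anyNA(x) && all(x == 0L | x == 1L)
}
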