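#' Enumerate maximal biclusters from a binary matrix
#'
#' The fitting function of the package. Every ordered pair of seed rows
#' `(i, j)`, `i < j`, produces a candidate template: the nibble-wise bitwise
#' AND of the two encoded rows. A template is scanned only the first time it
#' appears and only when its width (number of 1-columns) reaches `c_min`; all
#' remaining rows are then tested column-wise against the template through the
#' submask lookup table, stopping at the first failing position. A row that
#' passes every position joins the row set, and the bicluster
#' `(rows, template columns)` is emitted when it has at least `r_min` rows.
#' Every emitted bicluster is an all-ones submatrix, maximal in both
#' directions, and the result contains no duplicate (rows, cols) pair.
#'
#' Two modes are offered. `base` mode fixes `r_min = c_min = 2` (values passed
#' by the user are coerced back with a warning) and yields the complete set of
#' maximal biclusters reachable by pairwise AND. `flex` mode honours stricter
#' user minimums and optionally removes transpose-duplicate ("symmetric")
#' clusters on square symmetric inputs and/or truncates to the `top_k` largest
#' clusters by area.
#'
#' @param x binary matrix (anything accepted by [as_binary_matrix()]).
#' @param r_min minimum number of rows per bicluster (>= 2; seeds are pairs,
#'   so single-row biclusters are never produced).
#' @param c_min minimum number of columns per bicluster (>= 1).
#' @param mode `"base"` or `"flex"`.
#' @param remove_symmetric in flex mode, drop one member of each
#'   transpose-duplicate pair (see [remove_symmetric()]).
#' @param top_k in flex mode, keep only the `top_k` largest biclusters by
#'   `nrow * ncol` area (ties broken by discovery order). `NULL` keeps all.
#' @param collect_stats also record per-template K-sequences (exclusion counts
#'   per nibble position), retrievable via [comparison_stats()]. Per-template
#'   check totals are always recorded.
#' @param skip_sparse_seeds skip seed pairs in which either row carries fewer
#'   than `c_min` ones; provably output-equivalent, on by default.
#' @return an object of class `bitclust`: list with `biclusters` (each a list
#'   with sorted integer `rows` and `cols`), `row_labels`, `col_labels`,
#'   `params`, `stats`, `n` (bicluster count) and the matched `call`.
#' @examples
#' m <- matrix(0L, 6, 6)
#' m[1:3, 1:3] <- 1L; m[4:6, 4:6] <- 1L
#' fit <- bitclust(m)
#' fit$n  # 2 blocks
#' @export
bitclust <- function(x, r_min = 2L, c_min = 2L, mode = c("base", "flex"),
                     remove_symmetric = FALSE, top_k = NULL,
                     collect_stats = FALSE, skip_sparse_seeds = TRUE) {
  cl <- match.call()
  mode <- match.arg(mode)
  x <- as_binary_matrix(x)
  if (mode == "base") {
    if (r_min != 2L || c_min != 2L) {
      warning("base mode fixes r_min = c_min = 2; supplied values ignored")
    }
    r_min <- 2L
    c_min <- 2L
  }
  r_min <- as.integer(r_min)
  c_min <- as.integer(c_min)
  if (r_min < 2L) stop("r_min must be >= 2 (seed rows come in pairs)")
  if (c_min < 1L) stop("c_min must be >= 1")

  enc <- encode_matrix(x)
  res <- .cpp_enumerate(enc$nibbles, enc$n_col, r_min, c_min,
                        isTRUE(skip_sparse_seeds), isTRUE(collect_stats))
  bics <- lapply(seq_along(res$rows), function(b) {
    list(rows = res$rows[[b]], cols = res$cols[[b]],
         seed_pair = res$seed_pairs[b, ])
  })
  stats <- res$stats
  stats$n_rows <- nrow(x)
  stats$n_cols <- ncol(x)
  stats$n_nibbles <- ncol(enc$nibbles)
  class(stats) <- "comparison_stats"

  fit <- structure(
    list(biclusters = bics, row_labels = rownames(x), col_labels = colnames(x),
         params = list(r_min = r_min, c_min = c_min, mode = mode,
                       remove_symmetric = isTRUE(remove_symmetric),
                       top_k = top_k),
         stats = stats, n = length(bics), call = cl),
    class = "bitclust"
  )
  if (mode == "flex") {
    if (isTRUE(remove_symmetric)) fit <- remove_symmetric(fit)
    if (!is.null(top_k) && fit$n > top_k) {
      area <- vapply(fit$biclusters,
                     function(b) length(b$rows) * length(b$cols), numeric(1))
      keep <- sort(order(-area)[seq_len(top_k)])
      fit$biclusters <- fit$biclusters[keep]
      fit$n <- length(fit$biclusters)
    }
  }
  fit
}

#' Build a pairwise-AND template from two encoded seed rows
#'
#' @param enc an [encode_matrix()] result.
#' @param i,j distinct row indices, `i < j`.
#' @return object of class `bic_template`: list with `nibbles`, `width`
#'   (1-bit count over non-padded columns), `columns` (original column
#'   indices of the 1-bits) and `seed_pair`.
#' @export
make_template <- function(enc, i, j) {
  stopifnot(inherits(enc, "encoded_matrix"))
  n <- nrow(enc$nibbles)
  if (i == j || i < 1L || j < 1L || i > n || j > n) {
    stop("seed indices must be two distinct valid rows")
  }
  if (i > j) stop("seed pair must satisfy i < j")
  nib <- bitwAnd(enc$nibbles[i, ], enc$nibbles[j, ])
  cols <- nibbles_to_columns(nib, enc$n_col)
  structure(list(nibbles = as.integer(nib), width = length(cols),
                 columns = cols, seed_pair = c(i, j)),
            class = "bic_template")
}

# expand nibble vector to the original column indices of its 1-bits
nibbles_to_columns <- function(nib, n_col) {
  p <- length(nib)
  bits <- integer(4L * p)
  idx <- 4L * (seq_len(p) - 1L)
  bits[idx + 1L] <- nib %/% 8L
  bits[idx + 2L] <- (nib %/% 4L) %% 2L
  bits[idx + 3L] <- (nib %/% 2L) %% 2L
  bits[idx + 4L] <- nib %% 2L
  which(bits[seq_len(n_col)] == 1L)
}

#' Test one encoded row against a template
#'
#' Column-wise (nibble-granularity) inclusion test with early exit: the row is
#' rejected at the first position whose template nibble is not a submask of
#' the row nibble. `checks_used` reports how many positions were examined —
#' the comparison count of the complexity accounting.
#'
#' @param enc_row integer vector of nibble values (one encoded row).
#' @param template a [make_template()] result.
#' @param table a [submask_table()]; built on the fly if omitted.
#' @return list with `match` (logical) and `checks_used` (integer).
#' @export
row_matches_template <- function(enc_row, template, table = submask_table()) {
  stopifnot(inherits(template, "bic_template"))
  if (length(enc_row) != length(template$nibbles)) {
    stop("encoded row length does not match template length")
  }
  for (k in seq_along(enc_row)) {
    if (!submask_contains(template$nibbles[k], enc_row[k], table)) {
      return(list(match = FALSE, checks_used = k))
    }
  }
  list(match = TRUE, checks_used = length(enc_row))
}

#' Remove transpose-duplicate biclusters from symmetric inputs
#'
#' On a square matrix whose rows and columns index the same label space (an
#' adjacency matrix), every bicluster `(I, J)` has a mirror `(J, I)`. This
#' filter keeps, from each transpose pair, only the member with the
#' lexicographically smallest (rows, cols) key; self-symmetric clusters
#' (`I == J`) are kept. On non-square inputs, or when row and column label
#' spaces differ, the filter is an identity pass with a warning.
#'
#' @param fit a `bitclust` object.
#' @return the filtered `bitclust` object.
#' @export
remove_symmetric <- function(fit) {
  stopifnot(inherits(fit, "bitclust"))
  if (length(fit$row_labels) != length(fit$col_labels) ||
      !identical(fit$row_labels, fit$col_labels)) {
    warning("symmetric removal requires a square matrix with shared row/column labels; returning input unchanged")
    return(fit)
  }
  key <- function(rows, cols) {
    paste(paste(rows, collapse = ","), paste(cols, collapse = ","), sep = "|")
  }
  keys <- vapply(fit$biclusters, function(b) key(b$rows, b$cols), character(1))
  tkeys <- vapply(fit$biclusters, function(b) key(b$cols, b$rows), character(1))
  drop <- logical(length(keys))
  idx <- match(tkeys, keys)
  for (b in seq_along(keys)) {
    p <- idx[b]
    if (is.na(p) || p == b) next  # no mirror present / self-symmetric
    # keep only the lexicographically smaller key of the pair
    if (keys[b] > keys[p]) drop[b] <- TRUE
  }
  fit$biclusters <- fit$biclusters[!drop]
  fit$n <- length(fit$biclusters)
  fit
}

#' Retrieve search instrumentation
#'
#' Exact comparison counts recorded during [bitclust()]: one comparison is one
#' nibble containment lookup. `per_template_checks` never exceeds
#' `(N - 2) * P` for an N-row input with P nibbles per row (the worst case, in
#' which every position of every row is examined); the best case examines all
#' rows at the first position only. With `collect_stats = TRUE` the object
#' also carries `k_sequences`: per template, the number of rows excluded at
#' each nibble position — the K-sequence of the comparison-count bookkeeping.
#'
#' @param fit a `bitclust` object.
#' @return the `comparison_stats` object.
#' @export
comparison_stats <- function(fit) {
  stopifnot(inherits(fit, "bitclust"))
  fit$stats
}

#' @method print comparison_stats
#' @export
print.comparison_stats <- function(x, ...) {
  cat("Search comparison statistics\n")
  cat(sprintf("  seed pairs: %.0f; templates scanned: %.0f (duplicates %.0f, below c_min %.0f)\n",
              x$n_seed_pairs, x$n_templates_scanned,
              x$n_duplicate_templates, x$n_below_cmin))
  cat(sprintf("  total comparisons: %.0f; ceiling per template: %d\n",
              x$total_checks, (x$n_rows - 2L) * x$n_nibbles))
  invisible(x)
}

#' Survivor-ratio profile across successive template columns
#'
#' Empirical counterpart of the average-case analysis: for seed-pair
#' templates, walk the template's 1-columns in order and record how many
#' non-seed rows still satisfy every column seen so far. The ratio of
#' consecutive survivor counts estimates the per-column retention rate; on an
#' i.i.d. Bernoulli(p) matrix it concentrates around p, producing the
#' geometric decay (N, Np, Np^2, ...) of rows examined per column. With
#' uniform nibble contents the submask-table analysis gives a mean lookup
#' success of 66/256, about one quarter, so density-0.25 backgrounds reproduce
#' the canonical N, N/4, N/16, ... pattern.
#'
#' @param x binary matrix.
#' @param max_templates cap on the number of seed-pair templates examined
#'   (pairs are taken in lexicographic order).
#' @param positions number of leading template columns profiled.
#' @return list with `survivors` (templates x positions+1 matrix of pooled
#'   counts, column 1 = rows scanned), `ratios` (pooled survivor ratio per
#'   step) and `overall` (pooled across steps).
#' @export
retention_profile <- function(x, max_templates = 2000L, positions = 4L) {
  x <- as_binary_matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 rows")
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_templates) pairs <- pairs[, seq_len(max_templates), drop = FALSE]
  surv <- matrix(NA_real_, ncol(pairs), positions + 1L)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    jcols <- which(x[i, ] == 1L & x[j, ] == 1L)
    if (!length(jcols)) next
    jcols <- jcols[seq_len(min(length(jcols), positions))]
    sub <- x[-c(i, j), jcols, drop = FALSE]
    alive <- rep(TRUE, nrow(sub))
    surv[q, 1L] <- nrow(sub)
    for (k in seq_along(jcols)) {
      alive <- alive & (sub[, k] == 1L)
      surv[q, k + 1L] <- sum(alive)
    }
  }
  # pool each step only over templates observed at both endpoints, so short
  # templates do not bias the ratio
  num <- den <- numeric(positions)
  for (k in seq_len(positions)) {
    ok <- !is.na(surv[, k]) & !is.na(surv[, k + 1L])
    den[k] <- sum(surv[ok, k])
    num[k] <- sum(surv[ok, k + 1L])
  }
  ratios <- ifelse(den > 0, num / den, NA_real_)
  list(survivors = surv, ratios = ratios, overall = sum(num) / sum(den))
}
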