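# --- bicluster collection coercion -----------------------------------------

#' Coerce to a plain list of biclusters
#'
#' Accepts a `bitclust` fit, a list of `list(rows =, cols =)` pairs, or a
#' single such pair, and returns the canonical list form with sorted integer
#' index vectors.
#'
#' @param x object to coerce.
#' @return list of biclusters.
#' @export
as_bicluster_list <- function(x) {
  if (inherits(x, "bitclust")) return(x$biclusters)
  if (is.list(x) && !is.null(x$rows) && !is.null(x$cols)) x <- list(x)
  if (!is.list(x)) stop("cannot interpret object as a bicluster collection")
  lapply(x, function(b) {
    if (is.null(b$rows) || is.null(b$cols)) {
      stop("each bicluster needs `rows` and `cols`")
    }
    list(rows = sort(as.integer(b$rows)), cols = sort(as.integer(b$cols)))
  })
}

#' Jaccard similarity between two biclusters
#'
#' `scope = "rows"`: Jaccard index of the two row sets (the gene-level match
#' primitive). `scope = "rows_and_cols"`: Jaccard index of the two cell sets
#' `I x J`, computed as `|I1 n I2| * |J1 n J2|` over the union cell count.
#'
#' @param b1,b2 biclusters (`list(rows =, cols =)`).
#' @param scope `"rows"` or `"rows_and_cols"`.
#' @return value in `[0, 1]`.
#' @examples
#' bicluster_jaccard(list(rows = 1:3, cols = 1:2), list(rows = 2:4, cols = 1:2))
#' @export
bicluster_jaccard <- function(b1, b2, scope = c("rows", "rows_and_cols")) {
  scope <- match.arg(scope)
  if (!length(b1$rows) || !length(b1$cols) || !length(b2$rows) || !length(b2$cols)) {
    stop("biclusters must be non-empty")
  }
  ri <- length(intersect(b1$rows, b2$rows))
  if (scope == "rows") {
    return(ri / length(union(b1$rows, b2$rows)))
  }
  ci <- length(intersect(b1$cols, b2$cols))
  inter <- ri * ci
  uni <- length(b1$rows) * length(b1$cols) + length(b2$rows) * length(b2$cols) - inter
  inter / uni
}

# All pairwise Jaccard similarities between two collections, via incidence
# matrices (one row per bicluster): intersection counts come from a single
# cross-product, so scoring stays fast for large collections. Same math as
# bicluster_jaccard(), which the tests hold as the scalar reference.
pairwise_jaccard <- function(a, b, scope) {
  n_r <- max(vapply(c(a, b), function(x) max(x$rows), integer(1)))
  inc <- function(bs, field, n) {
    m <- matrix(0L, length(bs), n)
    for (i in seq_along(bs)) m[i, bs[[i]][[field]]] <- 1L
    m
  }
  ra <- inc(a, "rows", n_r); rb <- inc(b, "rows", n_r)
  ri <- ra %*% t(rb)
  sa <- rowSums(ra); sb <- rowSums(rb)
  if (scope == "rows") {
    return(ri / (outer(sa, sb, "+") - ri))
  }
  n_c <- max(vapply(c(a, b), function(x) max(x$cols), integer(1)))
  ca <- inc(a, "cols", n_c); cb <- inc(b, "cols", n_c)
  ci <- ca %*% t(cb)
  cells_a <- sa * rowSums(ca); cells_b <- sb * rowSums(cb)
  inter <- ri * ci
  inter / (outer(cells_a, cells_b, "+") - inter)
}

#' Match score between two bicluster collections
#'
#' Mean, over the `found` collection, of each bicluster's best Jaccard
#' similarity against the `reference` collection. Not symmetric: the two
#' directions against a ground truth are the relevance (found vs truth) and
#' the recovery (truth vs found). Collections are treated as sets: exact
#' duplicates are collapsed before averaging, so duplicating an entry never
#' moves the score. An empty `found` collection scores 0.
#'
#' @param found,reference bicluster collections (anything accepted by
#'   [as_bicluster_list()]).
#' @inheritParams bicluster_jaccard
#' @return value in `[0, 1]`.
#' @export
match_score <- function(found, reference, scope = c("rows", "rows_and_cols")) {
  scope <- match.arg(scope)
  found <- as_bicluster_list(found)
  reference <- as_bicluster_list(reference)
  found <- unique(found)
  reference <- unique(reference)
  if (!length(found) || !length(reference)) return(0)
  if (any(vapply(c(found, reference), function(b)
    !length(b$rows) || !length(b$cols), logical(1)))) {
    stop("biclusters must be non-empty")
  }
  mean(apply(pairwise_jaccard(found, reference, scope), 1L, max))
}

#' Relevance and recovery against a ground truth
#'
#' Average bicluster relevance (how well found biclusters represent true
#' ones: match score of found vs truth) and average module recovery (how well
#' true biclusters are recovered: match score of truth vs found). Both lie in
#' `[0, 1]`; 1 means the collections coincide, 0 that they are disjoint.
#'
#' @param found bicluster collection under evaluation.
#' @param truth ground-truth collection (must be non-empty).
#' @inheritParams bicluster_jaccard
#' @return object of class `metric_report`: list with `relevance`,
#'   `recovery`, `match_score_ab`, `match_score_ba`, `scope`, and
#'   `best_matches` — a data frame giving, per found bicluster, the index of
#'   its best ground-truth partner and the Jaccard achieved.
#' @export
relevance_recovery <- function(found, truth, scope = c("rows", "rows_and_cols")) {
  scope <- match.arg(scope)
  found <- as_bicluster_list(found)
  truth <- as_bicluster_list(truth)
  if (!length(truth)) stop("ground truth must be non-empty")
  found <- unique(found)
  truth <- unique(truth)
  rel <- match_score(found, truth, scope)
  rec <- match_score(truth, found, scope)
  best <- if (length(found)) {
    jm <- pairwise_jaccard(found, truth, scope)
    data.frame(found = seq_along(found),
               best_truth = apply(jm, 1L, which.max),
               jaccard = apply(jm, 1L, max))
  } else {
    data.frame(found = integer(), best_truth = integer(), jaccard = numeric())
  }
  structure(list(relevance = rel, recovery = rec,
                 match_score_ab = rel, match_score_ba = rec,
                 scope = scope, best_matches = best),
            class = "metric_report")
}

#' @method print metric_report
#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Bicluster evaluation (scope: %s)\n", x$scope))
  cat(sprintf("  average bicluster relevance: %.6f\n", x$relevance))
  cat(sprintf("  average module recovery:     %.6f\n", x$recovery))
  invisible(x)
}
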