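#' @method print bitclust
#' @export
print.bitclust <- function(x, ...) {
  cat(sprintf("Bit-pattern bicluster enumeration (%s mode)\n", x$params$mode))
  cat(sprintf("  input: %d x %d; r_min = %d, c_min = %d\n",
              length(x$row_labels), length(x$col_labels),
              x$params$r_min, x$params$c_min))
  cat(sprintf("  biclusters found: %d\n", x$n))
  invisible(x)
}

#' Summarize a bicluster enumeration
#'
#' @param object a `bitclust` object.
#' @param ... unused.
#' @return a `summary.bitclust` list with size distributions and search
#'   instrumentation totals.
#' @method summary bitclust
#' @export
summary.bitclust <- function(object, ...) {
  nr <- vapply(object$biclusters, function(b) length(b$rows), integer(1))
  nc <- vapply(object$biclusters, function(b) length(b$cols), integer(1))
  out <- list(
    n = object$n,
    params = object$params,
    dim = c(length(object$row_labels), length(object$col_labels)),
    rows_summary = if (object$n) summary(nr) else NULL,
    cols_summary = if (object$n) summary(nc) else NULL,
    area_total = sum(as.numeric(nr) * nc),
    stats = object$stats
  )
  class(out) <- "summary.bitclust"
  out
}

#' @method print summary.bitclust
#' @export
print.summary.bitclust <- function(x, ...) {
  cat(sprintf("Bicluster enumeration summary (%s mode, r_min = %d, c_min = %d)\n",
              x$params$mode, x$params$r_min, x$params$c_min))
  cat(sprintf("  input: %d x %d; biclusters: %d; total covered area: %.0f cells\n",
              x$dim[1], x$dim[2], x$n, x$area_total))
  if (x$n) {
    cat("  rows per bicluster:\n"); print(x$rows_summary)
    cat("  cols per bicluster:\n"); print(x$cols_summary)
  }
  cat(sprintf("  comparisons: %.0f over %.0f scanned templates\n",
              x$stats$total_checks, x$stats$n_templates_scanned))
  invisible(x)
}

#' Tabulate biclusters
#'
#' One row per bicluster: id, sizes, area, seed pair, and semicolon-joined
#' sorted row/column labels.
#'
#' @param x a `bitclust` object.
#' @param ... unused.
#' @return a data frame.
#' @method as.data.frame bitclust
#' @export
as.data.frame.bitclust <- function(x, ...) {
  if (!x$n) {
    return(data.frame(id = integer(), n_rows = integer(), n_cols = integer(),
                      area = integer(), rows = character(), cols = character(),
                      stringsAsFactors = FALSE))
  }
  nr <- vapply(x$biclusters, function(b) length(b$rows), integer(1))
  nc <- vapply(x$biclusters, function(b) length(b$cols), integer(1))
  data.frame(
    id = seq_len(x$n),
    n_rows = nr,
    n_cols = nc,
    area = nr * nc,
    rows = vapply(x$biclusters, function(b)
      paste(sort(x$row_labels[b$rows]), collapse = ";"), character(1)),
    cols = vapply(x$biclusters, function(b)
      paste(sort(x$col_labels[b$cols]), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Plot bicluster size distribution
#'
#' Scatter of rows vs columns per bicluster, point area proportional to the
#' number of coincident biclusters.
#'
#' @param x a `bitclust` object.
#' @param ... passed to [graphics::plot()].
#' @method plot bitclust
#' @export
plot.bitclust <- function(x, ...) {
  if (!x$n) {
    warning("no biclusters to plot")
    return(invisible(x))
  }
  nr <- vapply(x$biclusters, function(b) length(b$rows), integer(1))
  nc <- vapply(x$biclusters, function(b) length(b$cols), integer(1))
  tab <- table(nr, nc)
  d <- as.data.frame(tab, stringsAsFactors = FALSE)
  d <- d[d$Freq > 0, ]
  graphics::plot(as.integer(d$nr), as.integer(d$nc),
                 cex = 0.5 + 2 * sqrt(d$Freq / max(d$Freq)),
                 xlab = "rows per bicluster", ylab = "columns per bicluster",
                 main = sprintf("%d biclusters", x$n), ...)
  invisible(x)
}
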