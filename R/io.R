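# File formats: CSV/TSV dense matrices, Matrix Market sparse, two-column
# edge lists, bicluster TSV/JSON, ground-truth JSON.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
         edges = "edgelist", edgelist = "edgelist",
         stop(sprintf("cannot infer format from extension '.%s'; pass `format`", ext)))
}

# Sniff whether the first row/column look like labels. Overridable: pass
# header/row_names as TRUE/FALSE to force.
read_table_matrix <- function(path, sep, header = NA, row_names = NA) {
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (is.na(header)) {
    header <- any(is.na(suppressWarnings(as.numeric(first[-1L]))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.na(row_names)) {
    row_names <- ncol(df) > 1L &&
      any(is.na(suppressWarnings(as.numeric(df[[1L]]))))
  }
  if (row_names) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
    rownames(m) <- NULL
  }
  if (!header) colnames(m) <- NULL
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop(sprintf("non-numeric or missing cells in %s", path))
  m
}

#' Read a binary matrix from CSV/TSV or Matrix Market file
#'
#' CSV/TSV: header row and label column are autodetected (non-numeric first
#' row/column) but can be forced with `header`/`row_names`. MTX: Matrix
#' Market coordinate format, densified with absent entries 0; stored values
#' other than 1 are rejected rather than coerced.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param header,row_names logical or `NA` (autodetect); CSV/TSV only.
#' @return labeled integer binary matrix.
#' @export
read_binary_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                               header = NA, row_names = NA) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    vals <- unique(as.vector(m))
    if (!all(vals %in% c(0, 1))) {
      stop("MTX entries other than 1 are not valid for a binary matrix")
    }
    return(as_binary_matrix(m))
  }
  sep <- if (format == "csv") "," else "\t"
  m <- read_table_matrix(path, sep, header, row_names)
  as_binary_matrix(m)
}

#' Read a real-valued expression matrix from CSV/TSV
#'
#' @inheritParams read_binary_matrix
#' @return numeric matrix (genes x conditions) with labels when present.
#' @export
read_expression_matrix <- function(path, format = c("auto", "csv", "tsv"),
                                   header = NA, row_names = NA) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  sep <- if (format == "csv") "," else "\t"
  m <- read_table_matrix(path, sep, header, row_names)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

#' Write a binary matrix as labeled CSV
#'
#' Round-trips exactly through [read_binary_matrix()].
#'
#' @param x binary matrix.
#' @param path output path.
#' @export
write_binary_matrix <- function(x, path) {
  x <- as_binary_matrix(x)
  utils::write.table(x, path, sep = ",", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a two-column edge list
#'
#' @param path TSV (or whitespace-separated) file of node-label pairs;
#'   lines starting with `#` are skipped.
#' @return data frame with columns `from`, `to`.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#",
                          col.names = c("from", "to"),
                          colClasses = "character")
  if (!nrow(df)) stop("empty edge list")
  df
}

#' Convert an undirected edge list to a binary adjacency matrix
#'
#' Builds a square symmetric 0/1 matrix over the sorted set of unique node
#' labels. Self-interactions are removed (their count is kept in the
#' `n_self_loops` attribute), duplicate and reversed edges collapse to a
#' single symmetric pair, and the diagonal is all zero.
#'
#' @param edges data frame or 2-column matrix of node-label pairs.
#' @return labeled integer adjacency matrix with attributes `n_self_loops`
#'   and `n_edges` (undirected interactions retained).
#' @export
edges_to_adjacency <- function(edges) {
  if (is.matrix(edges)) edges <- data.frame(from = edges[, 1L], to = edges[, 2L],
                                            stringsAsFactors = FALSE)
  if (!nrow(edges)) stop("empty edge list")
  from <- as.character(edges[[1L]]); to <- as.character(edges[[2L]])
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]
  if (!length(from)) stop("edge list contains only self-interactions")
  labs <- sort(unique(c(from, to)))
  adj <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  i <- match(from, labs); j <- match(to, labs)
  adj[cbind(i, j)] <- 1L
  adj[cbind(j, i)] <- 1L
  structure(as_binary_matrix(adj),
            n_self_loops = n_self, n_edges = sum(adj) %/% 2L)
}

pkg_version <- function() {
  as.character(utils::packageVersion("bitclust"))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write biclusters to TSV or JSON
#'
#' TSV: one record per line (`id`, sizes, area, seed pair, sorted
#' semicolon-joined labels) under a commented provenance header. JSON: object
#' with a `provenance` block (tool version, config hash, parameters) and a
#' `biclusters` array carrying labels and 0-based integer indices.
#' Ordering is deterministic (discovery order).
#'
#' @param fit a `bitclust` object.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_biclusters <- function(fit, path, format = c("tsv", "json")) {
  stopifnot(inherits(fit, "bitclust"))
  format <- match.arg(format)
  prov <- list(tool = "bitclust", version = pkg_version(),
               params = fit$params,
               n_rows = length(fit$row_labels), n_cols = length(fit$col_labels))
  prov$config_hash <- config_hash(prov)
  if (format == "tsv") {
    d <- as.data.frame(fit)
    d$seed_row_i <- vapply(fit$biclusters, function(b)
      if (is.null(b$seed_pair)) NA_integer_ else b$seed_pair[1L], integer(1))
    d$seed_row_j <- vapply(fit$biclusters, function(b)
      if (is.null(b$seed_pair)) NA_integer_ else b$seed_pair[2L], integer(1))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# bitclust %s mode=%s r_min=%d c_min=%d config=%s",
                       prov$version, fit$params$mode, fit$params$r_min,
                       fit$params$c_min, prov$config_hash), con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    recs <- lapply(seq_along(fit$biclusters), function(b) {
      bc <- fit$biclusters[[b]]
      list(id = b,
           rows = fit$row_labels[bc$rows],
           cols = fit$col_labels[bc$cols],
           rows_idx0 = bc$rows - 1L,
           cols_idx0 = bc$cols - 1L,
           n_rows = length(bc$rows), n_cols = length(bc$cols),
           area = length(bc$rows) * length(bc$cols),
           seed_pair = if (is.null(bc$seed_pair)) NULL else bc$seed_pair,
           mode = fit$params$mode)
    })
    jsonlite::write_json(list(provenance = prov, biclusters = recs), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read biclusters written by [write_biclusters()]
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return list of biclusters; JSON inputs carry 1-based integer `rows`/`cols`
#'   plus `row_labels`/`col_labels`, TSV inputs carry sorted label vectors.
#' @export
read_biclusters <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    recs <- obj$biclusters
    if (!length(recs)) return(list())
    return(lapply(seq_len(nrow(recs)), function(b) {
      list(rows = sort(as.integer(recs$rows_idx0[[b]]) + 1L),
           cols = sort(as.integer(recs$cols_idx0[[b]]) + 1L),
           row_labels = recs$rows[[b]], col_labels = recs$cols[[b]])
    }))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(d)), function(b) {
    list(rows = strsplit(d$rows[b], ";", fixed = TRUE)[[1L]],
         cols = strsplit(d$cols[b], ";", fixed = TRUE)[[1L]])
  })
}

#' Write generator ground truth as JSON
#'
#' @param truth a `ground_truth` object from [gen_implanted()].
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  recs <- lapply(truth$biclusters, function(b) {
    list(rows_idx0 = b$rows - 1L, cols_idx0 = b$cols - 1L)
  })
  jsonlite::write_json(
    list(seed = truth$seed, spec = truth$spec,
         degenerate_nesting = truth$degenerate_nesting, biclusters = recs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path JSON path.
#' @return list of biclusters with 1-based integer `rows`/`cols`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- obj$biclusters
  lapply(seq_len(nrow(recs)), function(b) {
    list(rows = as.integer(recs$rows_idx0[[b]]) + 1L,
         cols = as.integer(recs$cols_idx0[[b]]) + 1L)
  })
}
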