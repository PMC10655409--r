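# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# per-element stream seed derived from a master seed (kept below 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483629)
}

#' Random Bernoulli binary matrix
#'
#' i.i.d. Bernoulli(density) 0/1 cells; reproducible given `seed`.
#'
#' @param n,m dimensions.
#' @param density probability of a 1, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return labeled integer binary matrix.
#' @export
gen_density_matrix <- function(n, m, density, seed = 1L) {
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0 || density > 1) {
    stop("density must be a single value in [0, 1]")
  }
  vals <- with_seed(seed, as.integer(stats::runif(n * m) < density))
  as_binary_matrix(matrix(vals, n, m))
}

#' Scaling benchmark suite
#'
#' Groups of square matrices of growing size; group `g` holds one matrix per
#' density. The defaults mirror the standard scalability layout: sizes 50 to
#' 500 in steps of 50, densities 10% to 100% in steps of 10%, giving 10
#' groups of 10 matrices. Each matrix draws from its own RNG stream derived
#' from the master seed, so suites regenerate element-wise.
#'
#' @param sizes square dimensions, one group per size.
#' @param densities 1-densities used within every group.
#' @param seed master integer seed.
#' @return list of groups; each group is a list with `size` and `matrices`
#'   (one labeled binary matrix per density, density stored as an attribute).
#' @export
gen_scaling_suite <- function(sizes = seq(50L, 500L, by = 50L),
                              densities = seq(0.1, 1, by = 0.1),
                              seed = 1L) {
  idx <- 0L
  lapply(sizes, function(s) {
    mats <- lapply(densities, function(d) {
      idx <<- idx + 1L
      m <- gen_density_matrix(s, s, d, seed = derive_seed(seed, idx))
      attr(m, "density") <- d
      m
    })
    list(size = s, matrices = mats)
  })
}

#' Binary matrix with implanted all-ones biclusters
#'
#' Places `n_implants` all-ones blocks along the main diagonal; consecutive
#' blocks share `shared` rows and columns (overlapping corners). Background
#' cells are i.i.d. Bernoulli(`background_density`). The ground truth lists
#' the exact index sets of every implant.
#'
#' `shared` defaults to `floor(overlap_degree/100 * min(adjacent sizes))`.
#' At 100% overlap consecutive implants share every row and column of the
#' smaller block (degenerate nesting, flagged in the ground truth).
#'
#' @param size square matrix dimension.
#' @param n_implants number of implanted biclusters.
#' @param implant_rows,implant_cols implant dimensions; scalars or vectors of
#'   length `n_implants` (typical benchmark range 10-20).
#' @param overlap_degree percentage in 0..100 controlling shared rows/columns
#'   between consecutive implants.
#' @param background_density Bernoulli density of non-implant cells.
#' @param seed integer RNG seed.
#' @param shared explicit shared row/column count overriding the
#'   `overlap_degree` derivation.
#' @return list with `matrix` (labeled binary matrix) and `truth` — class
#'   `ground_truth`: list of implanted biclusters plus the generator echo.
#' @examples
#' g <- gen_implanted(size = 30, n_implants = 3, implant_rows = 10,
#'                    implant_cols = 10, overlap_degree = 0, seed = 1)
#' length(g$truth$biclusters)  # 3
#' @export
gen_implanted <- function(size = 100L, n_implants = 10L,
                          implant_rows = 10L, implant_cols = 10L,
                          overlap_degree = 0, background_density = 0,
                          seed = 1L, shared = NULL) {
  if (overlap_degree < 0 || overlap_degree > 100) {
    stop("overlap_degree must lie in 0..100")
  }
  rows <- rep_len(as.integer(implant_rows), n_implants)
  cols <- rep_len(as.integer(implant_cols), n_implants)
  if (n_implants > 1L) {
    adj_min <- pmin(pmin(rows[-n_implants], rows[-1L]),
                    pmin(cols[-n_implants], cols[-1L]))
    sh <- if (is.null(shared)) {
      as.integer(floor(overlap_degree / 100 * adj_min))
    } else {
      rep_len(as.integer(shared), n_implants - 1L)
    }
    if (any(sh > adj_min)) stop("shared count exceeds adjacent implant size")
  } else {
    sh <- integer(0)
  }
  start_r <- cumsum(c(1L, rows[-n_implants] - sh))
  start_c <- cumsum(c(1L, cols[-n_implants] - sh))
  if (any(start_r + rows - 1L > size) || any(start_c + cols - 1L > size)) {
    stop("implants exceed matrix bounds; enlarge `size` or reduce implants")
  }
  mat <- if (background_density > 0) {
    gen_density_matrix(size, size, background_density, seed = seed)
  } else {
    as_binary_matrix(matrix(0L, size, size))
  }
  truth <- vector("list", n_implants)
  for (t in seq_len(n_implants)) {
    I <- start_r[t]:(start_r[t] + rows[t] - 1L)
    J <- start_c[t]:(start_c[t] + cols[t] - 1L)
    mat[I, J] <- 1L
    truth[[t]] <- list(rows = I, cols = J)
  }
  nested <- n_implants > 1L && any(sh == adj_min)
  gt <- structure(
    list(biclusters = truth, seed = seed, degenerate_nesting = nested,
         spec = list(size = size, n_implants = n_implants,
                     implant_rows = rows, implant_cols = cols,
                     overlap_degree = overlap_degree, shared = sh,
                     background_density = background_density)),
    class = "ground_truth"
  )
  list(matrix = mat, truth = gt)
}

#' @method print ground_truth
#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d implanted biclusters (overlap %d%%, background %.2f)\n",
              length(x$biclusters), x$spec$overlap_degree,
              x$spec$background_density))
  invisible(x)
}

#' Implanted-bicluster benchmark suite across overlap degrees
#'
#' One matrix per overlap degree d in `overlap_degrees`: 10 square implants
#' of side `10 + d/10`, consecutive implants sharing `d/10` rows and columns,
#' zero background. This reproduces the canonical benchmark dimensions — the
#' matrix at degree d is `(100 + d/10)` square, so the 11 default degrees
#' span 100x100 through 110x110.
#'
#' @param overlap_degrees overlap percentages (multiples of 10 in 0..100).
#' @param background_density Bernoulli density of non-implant cells.
#' @param seed master integer seed (one derived stream per matrix).
#' @return list, one element per degree: `overlap_degree`, `matrix`, `truth`.
#' @export
gen_implant_suite <- function(overlap_degrees = seq(0L, 100L, by = 10L),
                              background_density = 0, seed = 1L) {
  stopifnot(all(overlap_degrees %in% seq(0L, 100L, by = 10L)))
  lapply(seq_along(overlap_degrees), function(q) {
    d <- overlap_degrees[q]
    s <- 10L + d %/% 10L
    g <- gen_implanted(size = 10L * s - 9L * (d %/% 10L), n_implants = 10L,
                       implant_rows = s, implant_cols = s,
                       overlap_degree = d, shared = d %/% 10L,
                       background_density = background_density,
                       seed = derive_seed(seed, q))
    c(list(overlap_degree = d), g)
  })
}
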