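#' Discretize a real-valued expression matrix into binary form
#'
#' Converts a genes x conditions expression matrix into the 0/1 substrate the
#' bicluster search operates on. Three methods:
#'
#' * `threshold` — cell is 1 iff its value exceeds `threshold` (global cutoff).
#' * `quantile` — per-gene cutoff at quantile `q`; cell is 1 iff it exceeds
#'   its gene's cutoff.
#' * `ltmg` — simplified per-gene two-component Gaussian mixture, a
#'   lightweight stand-in for left-truncated mixture discretization: values
#'   below a detection floor are censored at the floor (approximating left
#'   truncation of dropout mass), a two-component mixture is fitted by EM with
#'   a deterministic median-split initialisation, and the cell is 1 iff the
#'   posterior probability of the higher-mean component exceeds 0.5. Genes
#'   with degenerate variance or failed fits fall back to the quantile rule
#'   (recorded in provenance).
#'
#' @param expr numeric matrix (genes x conditions); finite entries.
#' @param method `"threshold"`, `"quantile"` or `"ltmg"`.
#' @param threshold global cutoff for `method = "threshold"`.
#' @param q per-gene quantile in (0, 1) for `method = "quantile"` and for
#'   mixture fallbacks.
#' @param floor detection floor for `method = "ltmg"`; defaults per gene to
#'   its minimum positive value (all values censored upward to the floor).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param seed recorded in provenance; the median-split initialisation makes
#'   the fit deterministic, so no randomness is consumed.
#' @return integer binary matrix with the input's labels and a `binarize`
#'   attribute: list with `method`, `params` and `fallback_genes` (indices
#'   that used the quantile fallback under the mixture method).
#' @examples
#' e <- rbind(gene1 = c(0.1, 0.2, 5, 6), gene2 = c(2, 3, 0.1, 0.2))
#' binarize(e, method = "quantile", q = 0.5)
#' @export
binarize <- function(expr, method = c("threshold", "quantile", "ltmg"),
                     threshold = 0, q = 0.5, floor = NULL,
                     max_iter = 100L, tol = 1e-6, seed = NULL) {
  method <- match.arg(method)
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr)) stop("`expr` must be a numeric matrix")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("s", seq_len(ncol(expr)))

  fallback <- integer(0)
  out <- switch(
    method,
    threshold = (expr > threshold) + 0L,
    quantile = t(apply(expr, 1L, function(v) as.integer(v > stats::quantile(v, q)))),
    ltmg = {
      res <- matrix(0L, nrow(expr), ncol(expr))
      for (g in seq_len(nrow(expr))) {
        v <- expr[g, ]
        fit <- fit_censored_mixture(v, floor = floor, max_iter = max_iter, tol = tol)
        if (is.null(fit)) {
          fallback <- c(fallback, g)
          res[g, ] <- as.integer(v > stats::quantile(v, q))
        } else {
          res[g, ] <- as.integer(fit$posterior_upper > 0.5)
        }
      }
      res
    }
  )
  dimnames(out) <- dimnames(expr)
  storage.mode(out) <- "integer"
  attr(out, "binarize") <- list(
    method = method,
    params = list(threshold = threshold, q = q, floor = floor,
                  max_iter = max_iter, tol = tol, seed = seed),
    fallback_genes = fallback
  )
  out
}

#' Two-component censored Gaussian mixture fit for one gene
#'
#' EM on values censored upward at a detection floor. Deterministic
#' initialisation: split at the median, component statistics from the two
#' halves. Returns `NULL` on degenerate inputs (near-zero spread, collapsed
#' component, or non-finite likelihood), signalling the caller to fall back.
#'
#' @param v numeric vector of one gene's expression values.
#' @param floor detection floor; default: smallest positive value of `v`
#'   (if none, the minimum).
#' @param max_iter,tol EM controls.
#' @return `NULL`, or a list with `mu` (sorted ascending), `sigma`, `lambda`
#'   (mixing weights, same order), `posterior_upper` (per value), `loglik`,
#'   and `iterations`.
#' @export
fit_censored_mixture <- function(v, floor = NULL, max_iter = 100L, tol = 1e-6) {
  if (length(v) < 4L) return(NULL)
  if (is.null(floor)) {
    pos <- v[v > 0]
    floor <- if (length(pos)) min(pos) else min(v)
  }
  x <- pmax(v, floor)
  if (stats::sd(x) < 1e-10) return(NULL)

  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(lo) < 2L || length(hi) < 2L) return(NULL)
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-4 * stats::sd(x), 1e-8)
  lam <- c(length(lo), length(hi)) / length(x)

  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- lam[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- lam[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    z2 <- d2 / tot
    z1 <- 1 - z2
    n1 <- sum(z1); n2 <- sum(z2)
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(z1 * x) / n1, sum(z2 * x) / n2)
    sg <- sqrt(c(sum(z1 * (x - mu[1])^2) / n1, sum(z2 * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-8)
    lam <- c(n1, n2) / length(x)
    if (abs(ll - ll_old) < tol || it >= max_iter) break
    ll_old <- ll
  }
  if (mu[2] < mu[1]) {  # keep the upper component second
    mu <- rev(mu); sg <- rev(sg); lam <- rev(lam); z2 <- 1 - z2
  }
  list(mu = mu, sigma = sg, lambda = lam, posterior_upper = z2,
       loglik = ll, iterations = it)
}
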