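#' REML fit of the null kinship model
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma2_g * K)` and `e ~ N(0,
#' sigma2_e * I)` by restricted maximum likelihood. The covariance is
#' parameterized through the variance ratio `delta = sigma2_e / sigma2_g`;
#' after one eigendecomposition `K = U D U'` the restricted log-likelihood
#' is a cheap one-dimensional function of `delta`, which is maximized by a
#' coarse log-spaced grid followed by local refinement with
#' [stats::optimize()]. The returned spectral cache (`U`, `d`, rotated
#' response and intercept) makes per-marker generalized least squares tests
#' a set of closed-form operations.
#'
#' @param y numeric phenotype vector (finite; aligned to `K` rows).
#' @param K symmetric positive semi-definite kinship matrix.
#' @param X optional fixed-effect design (default intercept only).
#' @param log10_delta_range search range for `log10(delta)`.
#' @param n_grid number of coarse grid points.
#' @return list of class `"null_lmm"`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `loglik` (restricted), `boundary` (TRUE when the genetic variance hits
#'   its zero boundary, i.e. `delta` at the upper search edge), and the
#'   spectral cache `U`, `d`, `ystar`, `Xstar`.
#' @export
fit_null_lmm <- function(y, K, X = NULL,
                         log10_delta_range = c(-8, 8), n_grid = 64L) {
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  n <- length(y)
  K <- unclass(K)
  if (nrow(K) != n) stop("phenotype and kinship dimensions disagree")
  if (is.null(X)) X <- matrix(1, n, 1L)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ystar <- crossprod(U, y)[, 1L]
  Xstar <- crossprod(U, X)

  obj <- function(log10_delta) {
    reml_loglik(10^log10_delta, ystar, Xstar, d)
  }
  grid <- seq(log10_delta_range[1L], log10_delta_range[2L], length.out = n_grid)
  ll <- vapply(grid, obj, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  best_log10 <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  best_ll <- max(opt$objective, ll[i])
  delta <- 10^best_log10

  p <- ncol(X)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xstar, Xstar * w)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  r <- ystar - Xstar %*% beta
  sigma2_g <- sum(w * r^2) / (n - p)
  boundary <- best_log10 >= log10_delta_range[2L] - 1e-6
  structure(list(
    sigma2_g = sigma2_g,
    sigma2_e = sigma2_g * delta,
    delta = delta,
    loglik = best_ll,
    boundary = boundary,
    U = U, d = d, ystar = ystar, Xstar = Xstar, n = n
  ), class = "null_lmm")
}

#' Restricted log-likelihood of the variance ratio
#'
#' Profile REML log-likelihood of `delta = sigma2_e / sigma2_g` given the
#' spectral rotation of the kinship. Exposed so that the optimum can be
#' checked against grid searches.
#'
#' @param delta variance ratio (> 0).
#' @param ystar rotated response `U' y`.
#' @param Xstar rotated fixed-effect design `U' X`.
#' @param d kinship eigenvalues.
#' @return restricted log-likelihood (up to the usual REML constant).
#' @export
reml_loglik <- function(delta, ystar, Xstar, d) {
  n <- length(ystar)
  p <- ncol(Xstar)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xstar, Xstar * w)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  r <- ystar - Xstar %*% beta
  rss <- sum(w * r^2)
  sigma2 <- rss / (n - p)
  ldet_H <- sum(log(d + delta))
  ldet_XtWX <- determinant(XtWX, logarithm = TRUE)$modulus[1L]
  ldet_XtX <- determinant(crossprod(Xstar), logarithm = TRUE)$modulus[1L]
  -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
            ldet_H + ldet_XtWX - ldet_XtX)
}

#' Kinship-corrected single-marker association scan
#'
#' Tests each marker as a fixed effect in the mixed model, holding the
#' variance ratio `delta` at the null-model REML estimate (the P3D/EMMAX
#' strategy: one REML fit per trait, generalized least squares per marker).
#' The residual scale is re-estimated per marker from the GLS residual sum
#' of squares, so with `K = I` the Wald statistic reduces exactly to the
#' squared OLS t statistic. Significance is assessed against a chi-squared
#' reference with one degree of freedom.
#'
#' The per-marker explained variance is the squared correlation between the
#' fitted marker term and the phenotype, i.e. the marginal `r^2` between
#' marker scores and trait values.
#'
#' @param scores accession-by-marker score matrix (QC-passed).
#' @param y phenotype vector aligned to `scores` rows.
#' @param null_fit a `"null_lmm"` fit of `y` (see [fit_null_lmm()]); pass a
#'   fit on the identity kinship for a simple (uncorrected) scan.
#' @param meta optional marker metadata (adds `scaffold`, `position`).
#' @param threshold optional significance threshold (a list from
#'   [significance_threshold()] or a `-log10 p` scalar) used to set
#'   `pass_threshold`.
#' @return data.frame of class `"association_scan"` with one row per
#'   marker: `marker_id`, `effect`, `se`, `wald`, `p`, `neglog10p`,
#'   `expl_var`, `pass_threshold`; scan-level values (`sigma2_g`,
#'   `sigma2_e`, `delta`, `threshold`) are attached as attributes.
#' @export
scan_markers <- function(scores, y, null_fit, meta = NULL, threshold = NULL) {
  n <- nrow(scores)
  stopifnot(length(y) == n)
  sds <- matrixStats_colSds(scores)
  if (any(sds == 0)) stop("constant marker columns present; run QC first")
  w <- 1 / (null_fit$d + null_fit$delta)
  x0 <- null_fit$Xstar[, 1L]
  ys <- null_fit$ystar
  G <- crossprod(null_fit$U, scores)

  a11 <- sum(w * x0^2)
  a12 <- colSums(G * (w * x0))
  a22 <- colSums(G^2 * w)
  b1 <- sum(w * x0 * ys)
  b2 <- colSums(G * (w * ys))
  det <- a11 * a22 - a12^2
  beta0 <- (a22 * b1 - a12 * b2) / det
  alpha <- (a11 * b2 - a12 * b1) / det
  yty <- sum(w * ys^2)
  rss <- yty - (b1 * beta0 + b2 * alpha)
  rss <- pmax(rss, 0)
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 * a11 / det)
  wald <- (alpha / se)^2
  lp <- stats::pchisq(wald, df = 1L, lower.tail = FALSE, log.p = TRUE)
  p <- pmax(exp(lp), .Machine$double.xmin)
  neglog10p <- -lp / log(10)
  expl_var <- drop(stats::cor(scores, y))^2

  out <- data.frame(marker_id = colnames(scores),
                    effect = alpha, se = se, wald = wald, p = p,
                    neglog10p = neglog10p, expl_var = expl_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(meta)) {
    m <- match(out$marker_id, meta$marker_id)
    out$scaffold <- meta$scaffold[m]
    out$position <- meta$position[m]
    out <- out[, c("marker_id", "scaffold", "position", "effect", "se",
                   "wald", "p", "neglog10p", "expl_var")]
  }
  thr <- if (is.list(threshold)) threshold$neglog10p else threshold
  out$pass_threshold <- if (is.null(thr)) NA else out$neglog10p >= thr
  structure(out,
            sigma2_g = null_fit$sigma2_g, sigma2_e = null_fit$sigma2_e,
            delta = null_fit$delta, threshold = thr,
            class = c("association_scan", "data.frame"))
}

matrixStats_colSds <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m^2) - mu^2, 0) * nrow(m) / (nrow(m) - 1L))
}

#' A null fit on the identity kinship (simple regression scan)
#'
#' Convenience wrapper producing a `"null_lmm"` cache in which the
#' covariance is proportional to the identity, so [scan_markers()] performs
#' classical per-marker ordinary least squares.
#'
#' @param y phenotype vector.
#' @return a `"null_lmm"` object.
#' @export
fit_null_ols <- function(y) {
  n <- length(y)
  structure(list(
    sigma2_g = 0, sigma2_e = stats::var(y), delta = 1, loglik = NA_real_,
    boundary = TRUE,
    U = diag(n), d = rep(0, n), ystar = y, Xstar = matrix(1, n, 1L), n = n
  ), class = "null_lmm")
}

#' Effective number of independent tests
#'
#' Li-Ji style eigenvalue-based count: within each block the eigenvalues
#' `lambda_i` of the marker correlation matrix are mapped through
#' `f(lambda) = I(lambda >= 1) + (lambda - floor(lambda))` and summed; the
#' panel-wide `M_eff` is the sum over blocks. Blocks default to scaffolds -
#' the natural unit of linkage in a fragmented assembly - and a block with a
#' single marker contributes exactly 1.
#'
#' @param scores accession-by-marker score matrix.
#' @param meta marker metadata (needed for scaffold blocking).
#' @param blocks either `"scaffold"`, `"none"` (one global block), or a
#'   vector of block labels aligned to markers.
#' @return list with `m_eff`, `m` (marker count) and `per_block`.
#' @export
effective_tests <- function(scores, meta = NULL, blocks = "scaffold") {
  m <- ncol(scores)
  if (identical(blocks, "scaffold")) {
    if (is.null(meta)) stop("scaffold blocking requires marker metadata")
    labels <- meta$scaffold[match(colnames(scores), meta$marker_id)]
  } else if (identical(blocks, "none")) {
    labels <- rep("all", m)
  } else {
    stopifnot(length(blocks) == m)
    labels <- blocks
  }
  per_block <- vapply(split(seq_len(m), labels), function(idx) {
    if (length(idx) == 1L) return(1)
    C <- stats::cor(scores[, idx, drop = FALSE])
    lambda <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    # round before flooring: an eigenvalue numerically just below an
    # integer must not contribute an extra fractional unit
    lambda <- round(pmax(lambda, 0), 8L)
    sum((lambda >= 1) + (lambda - floor(lambda)))
  }, numeric(1))
  m_eff <- min(sum(per_block), m)
  list(m_eff = m_eff, m = m, per_block = per_block)
}

#' Bonferroni threshold on the effective number of tests
#'
#' @param alpha genome-wide type-I error rate.
#' @param m_eff effective number of independent tests (a number or the list
#'   returned by [effective_tests()]).
#' @return list `alpha`, `m_eff`, `p_threshold`, `neglog10p`.
#' @export
significance_threshold <- function(alpha = 0.05, m_eff) {
  if (is.list(m_eff)) m_eff <- m_eff$m_eff
  stopifnot(alpha > 0, alpha < 1, m_eff >= 1)
  list(alpha = alpha, m_eff = m_eff,
       p_threshold = alpha / m_eff,
       neglog10p = -log10(alpha / m_eff))
}

#' Observed versus expected p-values with and without kinship correction
#'
#' Draws a random subset of markers and scans them twice: with the kinship
#' mixed model and with simple per-marker regression. Expected quantiles
#' assume markers unlinked to the trait polymorphisms (uniform p-values).
#' The inflation statistic is the median observed Wald chi-square divided by
#' the null median `qchisq(0.5, 1)`; values near 1 indicate well-calibrated
#' tests, values well above 1 indicate confounding by structure.
#'
#' @param scores accession-by-marker score matrix.
#' @param y phenotype vector.
#' @param K kinship matrix.
#' @param n_sample number of markers to sample (default 3000; all markers
#'   when fewer are available).
#' @param seed RNG seed for the marker subsample.
#' @return list with `marker_ids`, sorted `observed_kinship`,
#'   `observed_simple`, `expected` (-log10 scale), `inflation_kinship`,
#'   `inflation_simple`.
#' @export
cumulative_p_diagnostic <- function(scores, y, K, n_sample = 3000L,
                                    seed = 1L) {
  m <- ncol(scores)
  n_sample <- min(n_sample, m)
  idx <- with_local_seed(seed, sample.int(m, n_sample))
  sub <- scores[, idx, drop = FALSE]
  fit_k <- fit_null_lmm(y, K)
  scan_k <- scan_markers(sub, y, fit_k)
  scan_s <- scan_markers(sub, y, fit_null_ols(y))
  expected <- -log10((seq_len(n_sample) - 0.5) / n_sample)
  list(
    marker_ids = colnames(sub),
    observed_kinship = sort(scan_k$neglog10p, decreasing = TRUE),
    observed_simple = sort(scan_s$neglog10p, decreasing = TRUE),
    expected = expected,
    inflation_kinship = stats::median(scan_k$wald) / stats::qchisq(0.5, 1L),
    inflation_simple = stats::median(scan_s$wald) / stats::qchisq(0.5, 1L)
  )
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
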