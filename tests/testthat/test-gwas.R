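test_that("with identity kinship the scan reproduces OLS squared-t exactly", {
  set.seed(101)
  n <- 30L; m <- 100L
  scores <- matrix(round(runif(n * m) * 16) / 16, n, m,
                   dimnames = list(sprintf("a%02d", 1:n),
                                   sprintf("s%d_%d", 1:m, 1:m)))
  y <- rnorm(n) + scores[, 1] * 2
  scan <- scan_markers(scores, y, fit_null_ols(y))
  for (j in c(1L, 2L, 17L, 50L, 100L)) {
    fit <- stats::lm(y ~ scores[, j])
    tval <- summary(fit)$coefficients[2L, "t value"]
    est <- summary(fit)$coefficients[2L, "Estimate"]
    se <- summary(fit)$coefficients[2L, "Std. Error"]
    expect_equal(scan$effect[j], unname(est), tolerance = 1e-8)
    expect_equal(scan$se[j], unname(se), tolerance = 1e-8)
    expect_equal(scan$wald[j], unname(tval^2), tolerance = 1e-8)
    expect_equal(scan$p[j],
                 stats::pchisq(tval^2, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
  expect_true(all(scan$p > 0 & scan$p <= 1))
  expect_true(all(scan$wald >= 0))
  # -log10 p consistent with p
  idx <- scan$p > 1e-300
  expect_equal(scan$neglog10p[idx], -log10(scan$p[idx]), tolerance = 1e-6)
})

test_that("scan equals a brute-force GLS oracle at fixed variance ratio", {
  panel <- small_panel(seed = 55L, n_accessions = 30L, n_scaffolds = 20L,
                       markers_per_scaffold = 5L)
  scores <- panel$scores
  K <- unclass(vanraden_kinship(scores))
  ph <- panel$phenotypes
  y <- ph$value[ph$trait == "trait1" & ph$location == "CRA"]
  fit <- fit_null_lmm(y, K)
  scan <- scan_markers(scores, y, fit)

  # brute force: V = K + delta I; GLS via explicit solve, marker by marker
  V <- K + diag(fit$delta, nrow(K))
  Vi <- solve(V)
  n <- length(y)
  for (j in seq_len(ncol(scores))) {
    X <- cbind(1, scores[, j])
    XtVi <- t(X) %*% Vi
    cov_u <- solve(XtVi %*% X)
    b <- cov_u %*% XtVi %*% y
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(s2 * cov_u[2, 2])
    expect_equal(scan$effect[j], b[2, 1], tolerance = 1e-8)
    expect_equal(scan$wald[j], (b[2, 1] / se)^2, tolerance = 1e-6)
  }
})

test_that("REML optimum beats a 100-point grid on random toys", {
  set.seed(606)
  for (rep in 1:20) {
    n <- 50L
    W <- matrix(rnorm(n * 60), n, 60)
    K <- tcrossprod(scale(W, scale = FALSE)) / 60
    h2 <- runif(1, 0.2, 0.8)
    g <- drop(crossprod(chol(K + diag(1e-8, n)), rnorm(n)))
    y <- sqrt(h2) * g / sd(g) + sqrt(1 - h2) * rnorm(n)
    fit <- fit_null_lmm(y, K)
    grid <- 10^seq(-6, 6, length.out = 100L)
    ll_grid <- vapply(grid, function(d) {
      reml_loglik(d, fit$ystar, fit$Xstar, fit$d)
    }, numeric(1))
    expect_gte(fit$loglik, max(ll_grid) - 1e-6)
  }
})

test_that("variance components are recovered in a Monte-Carlo experiment", {
  # known (sigma2_g, sigma2_e) = (2, 1); median estimates near truth
  set.seed(77)
  n <- 50L
  W <- matrix(rnorm(n * 200), n, 200)
  K <- tcrossprod(scale(W, scale = FALSE)) / 200
  L <- chol(K + diag(1e-8, n))
  est_g <- est_e <- numeric(60)
  for (r in seq_len(60)) {
    y <- sqrt(2) * drop(crossprod(L, rnorm(n))) + rnorm(n)
    fit <- fit_null_lmm(y, K)
    est_g[r] <- fit$sigma2_g
    est_e[r] <- fit$sigma2_e
  }
  expect_lt(abs(median(est_g) - 2) / 2, 0.2)
  expect_lt(abs(median(est_e) - 1) / 1, 0.25)
})

test_that("sigma2_g shrinks to the boundary for an unstructured phenotype", {
  set.seed(88)
  n <- 60L
  W <- matrix(rnorm(n * 100), n, 100)
  K <- tcrossprod(scale(W, scale = FALSE)) / 100
  y <- rnorm(n)  # no genetic component
  fit <- fit_null_lmm(y, K)
  # sigma2_g * max eigenvalue is negligible next to sigma2_e
  expect_lt(fit$sigma2_g * max(fit$d), 0.3 * fit$sigma2_e)
})

test_that("a perfect marker signal yields an extreme association", {
  panel <- small_panel(seed = 66L, n_accessions = 40L, n_scaffolds = 10L,
                       markers_per_scaffold = 5L)
  scores <- panel$scores
  y <- 3 + 5 * scores[, 7]  # exact linear function, sigma2_g = 0
  scan <- scan_markers(scores, y, fit_null_ols(y))
  expect_lt(scan$p[7], 1e-12)
  expect_equal(scan$expl_var[7], 1, tolerance = 1e-9)
})

test_that("p-values are uniform under a permuted phenotype", {
  # mutually independent markers so the KS sampling assumptions hold;
  # the phenotype carries kinship structure until the permutation breaks it
  set.seed(91)
  n <- 80L
  scores <- matrix(round(runif(n * 2000L) * 16) / 16, n, 2000L,
                   dimnames = list(sprintf("a%02d", 1:n),
                                   sprintf("s%d_1", 1:2000L)))
  K <- vanraden_kinship(scores)
  g <- drop(crossprod(chol(unclass(K) + diag(1e-6, n)), rnorm(n)))
  y <- g + rnorm(n, sd = 0.5)
  yp <- sample(y)  # breaks any genotype-phenotype link
  fit <- fit_null_lmm(yp, K)
  scan <- scan_markers(scores, yp, fit)
  ks <- stats::ks.test(scan$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("effective test count follows the Li-Ji eigenvalue rule", {
  set.seed(33)
  n <- 50L
  # orthogonal markers: m_eff = m
  Q <- qr.Q(qr(matrix(rnorm(n * 8L), n, 8L)))
  scores <- 0.5 + 0.1 * Q
  colnames(scores) <- sprintf("s%d_1", 1:8)
  rownames(scores) <- sprintf("a%02d", 1:n)
  meta <- data.frame(marker_id = colnames(scores),
                     scaffold = "s1", position = 1:8)
  expect_equal(effective_tests(scores, meta)$m_eff, 8, tolerance = 1e-8)

  # one marker duplicated 10x: block m_eff = 1
  dup <- scores[, rep(1L, 10L)]
  colnames(dup) <- sprintf("d%d_1", 1:10)
  meta_dup <- data.frame(marker_id = colnames(dup),
                         scaffold = "d", position = 1:10)
  expect_equal(effective_tests(dup, meta_dup)$m_eff, 1, tolerance = 1e-8)

  # compound symmetric block, r = 0.5: eigenvalues (2, .5, .5) ->
  # f(2) = 1, f(.5) = .5 each => m_eff = 2
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  Z <- matrix(rnorm(3 * 20000L), 20000L, 3L) %*% L
  Z <- scale(Z)
  # exact correlation via construction: replace empirical cor with target
  # by orthogonalization trick - here assert the formula directly instead
  lam <- round(eigen(S, only.values = TRUE)$values, 8)
  meff_formula <- sum((lam >= 1) + (lam - floor(lam)))
  expect_equal(meff_formula, 2)

  # blocks sum across scaffolds and a single-marker block contributes 1
  both <- cbind(scores[, 1:3], dup[, 1:2])
  meta_b <- data.frame(marker_id = colnames(both),
                       scaffold = c("s1", "s1", "s1", "d", "d"),
                       position = 1:5)
  me <- effective_tests(both, meta_b)
  expect_equal(unname(me$per_block["d"]), 1, tolerance = 1e-8)
  expect_lte(me$m_eff, me$m)

  one <- effective_tests(scores[, 1, drop = FALSE],
                         meta[1, , drop = FALSE])
  expect_equal(one$m_eff, 1)
})

test_that("threshold encodes alpha over the effective tests", {
  thr <- significance_threshold(alpha = 0.05, m_eff = 557)
  expect_equal(thr$neglog10p, -log10(0.05 / 557))
  expect_error(significance_threshold(alpha = 0, m_eff = 10))
})

test_that("the p-value diagnostic contrasts corrected and naive scans", {
  # structured panel, purely polygenic trait
  cfg <- sim_config(n_accessions = 100L, n_subpops = 5L, fst_target = 0.05,
                    n_scaffolds = 60L, markers_per_scaffold = 15L,
                    traits = list(default_trait(n_qtl = 0L,
                                                qtl_var = numeric(0),
                                                h2 = 0.7)),
                    seed = 12L)
  panel <- simulate_panel(cfg)
  qc <- qc_score_matrix(panel$scores, panel$meta)
  K <- vanraden_kinship(qc$scores)
  ph <- panel$phenotypes
  y <- ph$value[ph$trait == "trait1" & ph$location == "CRA"]
  diag1 <- cumulative_p_diagnostic(qc$scores, y, K, n_sample = 600L,
                                   seed = 5L)
  expect_gt(diag1$inflation_simple, diag1$inflation_kinship)
  expect_lt(abs(diag1$inflation_kinship - 1), 0.25)

  # determinism of the subsample
  diag2 <- cumulative_p_diagnostic(qc$scores, y, K, n_sample = 600L,
                                   seed = 5L)
  expect_identical(diag1$marker_ids, diag2$marker_ids)
  expect_equal(diag1$observed_kinship, diag2$observed_kinship)

  # unstructured panel, pure-noise trait: both models calibrated
  cfg0 <- sim_config(n_accessions = 100L, n_subpops = 1L, fst_target = 0,
                     n_scaffolds = 60L, markers_per_scaffold = 15L,
                     accession_f = 0,
                     traits = list(default_trait(n_qtl = 0L,
                                                 qtl_var = numeric(0),
                                                 h2 = 0)),
                     seed = 13L)
  panel0 <- simulate_panel(cfg0)
  qc0 <- qc_score_matrix(panel0$scores, panel0$meta)
  K0 <- vanraden_kinship(qc0$scores)
  ph0 <- panel0$phenotypes
  y0 <- ph0$value[ph0$trait == "trait1" & ph0$location == "CRA"]
  diag0 <- cumulative_p_diagnostic(qc0$scores, y0, K0, n_sample = 600L,
                                   seed = 6L)
  expect_lt(abs(diag0$inflation_simple - 1), 0.3)
  expect_lt(abs(diag0$inflation_kinship - 1), 0.3)
})
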