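test_that("configuration invariants are enforced", {
  expect_error(sim_config(fst_target = 1), "FST")
  expect_error(sim_config(pool_size = 0), "pool_size")
  expect_error(sim_config(traits = list(default_trait(n_qtl = 2L,
                                                      qtl_var = c(0.4, 0.4),
                                                      h2 = 0.5))),
               "exceed")
  expect_error(sim_config(traits = list(default_trait(n_qtl = 1L,
                                                      qtl_var = c(0.1, 0.1),
                                                      h2 = 0.5))),
               "n_qtl")
})

test_that("zero drift makes all subpopulations equal the ancestral pool", {
  cfg <- sim_config(n_subpops = 3L, fst_target = 0, seed = 2L,
                    traits = list(default_trait(n_qtl = 1L, qtl_var = 0.2,
                                                h2 = 0.4)))
  sp <- simulate_subpop_frequencies(cfg, n_markers = 500L, seed = 2L)
  for (i in 1:3) expect_equal(sp$freq[i, ], sp$ancestral, tolerance = 1e-12)
})

test_that("realized FST hits the target within Monte-Carlo tolerance", {
  cfg <- sim_config(n_subpops = 2L, fst_target = 0.05, seed = 8L)
  sp <- simulate_subpop_frequencies(cfg, n_markers = 50000L, seed = 8L)
  realized <- fst_from_frequencies(sp$freq)[1, 2]
  expect_lt(abs(realized - 0.05), 0.01)

  # matrix targets, five subpopulations in the weak-structure regime
  k <- 5L
  Tm <- matrix(0.04, k, k)
  Tm[1, 2] <- Tm[2, 1] <- 0.02
  Tm[4, 5] <- Tm[5, 4] <- 0.06
  diag(Tm) <- 0
  cfg2 <- sim_config(n_subpops = k, fst_target = Tm, seed = 9L)
  sp2 <- simulate_subpop_frequencies(cfg2, n_markers = 30000L, seed = 9L)
  R <- fst_from_frequencies(sp2$freq)
  expect_lt(abs(R[1, 2] - 0.02), 0.01)
  expect_lt(abs(R[4, 5] - 0.06), 0.01)
  expect_lt(max(abs(R[upper.tri(R)] - Tm[upper.tri(Tm)])), 0.015)
})

test_that("generators are reproducible given config and seed", {
  cfg <- sim_config(n_accessions = 30L, n_scaffolds = 8L,
                    markers_per_scaffold = 5L, seed = 123L,
                    traits = list(default_trait(n_qtl = 1L, qtl_var = 0.2,
                                                h2 = 0.5)))
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$phenotypes$value, p2$phenotypes$value)
  expect_identical(p1$truth$trait1$causal, p2$truth$trait1$causal)
})

test_that("pooled scores lie exactly on the allele-count grid", {
  for (ps in c(1L, 4L, 8L)) {
    cfg <- sim_config(n_accessions = 20L, n_scaffolds = 5L,
                      markers_per_scaffold = 4L, pool_size = ps,
                      seed = 5L,
                      traits = list(default_trait(n_qtl = 1L, qtl_var = 0.2,
                                                  h2 = 0.5)))
    set.seed(5)
    geno <- simulate_pooled_genotypes(simulate_subpop_frequencies(cfg), cfg)
    counts <- geno$scores * 2 * ps
    expect_equal(counts, round(counts), tolerance = 1e-12)
    expect_true(all(geno$scores >= 0 & geno$scores <= 1))
    # polarized to the panel major allele
    expect_true(all(colMeans(geno$scores) >= 0.5))
  }
})

test_that("long-range duplicated markers are strongly correlated", {
  cfg <- sim_config(n_accessions = 80L, n_scaffolds = 30L,
                    markers_per_scaffold = 10L,
                    long_range_fraction = 0.05, long_range_flip = 0.05,
                    seed = 44L,
                    traits = list(default_trait(n_qtl = 1L, qtl_var = 0.2,
                                                h2 = 0.5)))
  set.seed(44)
  geno <- simulate_pooled_genotypes(simulate_subpop_frequencies(cfg), cfg)
  lr <- geno$long_range_pairs
  expect_gt(nrow(lr), 5L)
  r2 <- mapply(function(a, b) marker_r2(geno$scores, a, b),
               lr$target, lr$source)
  expect_gt(median(r2), 0.5)
  # and they sit on different scaffolds
  sc <- geno$meta$scaffold[match(lr$target, geno$meta$marker_id)]
  sc2 <- geno$meta$scaffold[match(lr$source, geno$meta$marker_id)]
  expect_true(all(sc != sc2))
})

test_that("a planted QTL explains its configured variance share", {
  # one QTL at 50% of variance, h2 = 0.5: regression R2 ~ 0.5
  r2 <- replicate(20, {
    cfg <- sim_config(n_accessions = 100L, n_scaffolds = 20L,
                      markers_per_scaffold = 5L,
                      traits = list(default_trait(n_qtl = 1L, qtl_var = 0.5,
                                                  h2 = 0.5)),
                      seed = sample.int(1e6, 1))
    panel <- simulate_panel(cfg)
    causal <- panel$truth$trait1$causal$marker_id
    ph <- panel$phenotypes
    y <- ph$value[ph$trait == "trait1" & ph$location == "CRA"]
    summary(stats::lm(y ~ panel$scores[, causal]))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.5), 0.05)
})

test_that("realized heritability matches its target across replicates", {
  h2 <- replicate(20, {
    cfg <- sim_config(n_accessions = 80L, n_scaffolds = 15L,
                      markers_per_scaffold = 6L,
                      traits = list(default_trait(n_qtl = 2L,
                                                  qtl_var = c(0.2, 0.1),
                                                  h2 = 0.6)),
                      seed = sample.int(1e6, 1))
    panel <- simulate_panel(cfg)
    tr <- panel$truth$trait1
    # cross-check the recorded realized components against the raw data
    ph <- panel$phenotypes
    y <- ph$value[ph$trait == "trait1" & ph$location == "FNPC"]
    g <- drop(panel$scores[, tr$causal$marker_id] %*% tr$causal[, "FNPC"])
    i <- which(tr$components$location == "FNPC")
    expect_equal(tr$components$var_qtl[i], var(g), tolerance = 1e-8)
    expect_equal(tr$components$var_total[i], var(y), tolerance = 1e-8)
    tr$components$h2_realized[i]
  })
  expect_lt(abs(mean(h2) - 0.6), 0.05)
})

test_that("null trait on an unstructured panel shows no inflation", {
  cfg <- sim_config(n_accessions = 100L, n_subpops = 1L, fst_target = 0,
                    n_scaffolds = 40L, markers_per_scaffold = 10L,
                    accession_f = 0,
                    traits = list(default_trait(n_qtl = 0L,
                                                qtl_var = numeric(0),
                                                h2 = 0)),
                    seed = 3L)
  panel <- simulate_panel(cfg)
  qc <- qc_score_matrix(panel$scores, panel$meta)
  ph <- panel$phenotypes
  y <- ph$value[ph$trait == "trait1" & ph$location == "CRA"]
  scan <- scan_markers(qc$scores, y, fit_null_ols(y))
  infl <- median(scan$wald) / qchisq(0.5, 1)
  expect_lt(abs(infl - 1), 0.2)
})

test_that("full G-by-E correlation gives identical effects across locations", {
  cfg <- sim_config(n_accessions = 40L, n_scaffolds = 10L,
                    markers_per_scaffold = 5L,
                    traits = list(default_trait(n_qtl = 3L,
                                                qtl_var = rep(0.1, 3),
                                                h2 = 0.5, gxe_cor = 1)),
                    seed = 21L)
  panel <- simulate_panel(cfg)
  eff <- panel$truth$trait1$causal
  expect_identical(eff$CRA, eff$FNPC)
  expect_identical(eff$CRA, eff$VDS)
})

test_that("recovery scoring counts hits and false discoveries correctly", {
  scores <- toy_scores(n = 30L, seed = 9L)
  # truth: causal = m1; model detects m2 (collinear with m1) and m3 (not)
  truth <- list(causal = data.frame(marker_id = "m1", CRA = 1))
  expect_gt(abs(cor(scores[, "m1"], scores[, "m2"])), 0.3)
  expect_lt(abs(cor(scores[, "m1"], scores[, "m3"])), 0.3)
  model <- structure(list(
    trait = "t", location = "CRA",
    qtls = list(list(representative = "m2", members = "m2"),
                list(representative = "m3", members = "m3")),
    n_qtl = 2L), class = "multiqtl_model")
  rec <- score_recovery(model, truth, scores)
  expect_equal(rec$power, 1)            # m1 tagged via m2
  expect_equal(rec$fdp, 0.5)            # m3 spurious
  expect_equal(rec$n_detected, 2L)

  # representative identical to the causal marker is a trivial hit
  model1 <- structure(list(trait = "t", location = "CRA",
                           qtls = list(list(representative = "m1",
                                            members = "m1")),
                           n_qtl = 1L), class = "multiqtl_model")
  expect_equal(score_recovery(model1, truth, scores)$power, 1)

  # zero detections on a null trait: FDP undefined, 0 detections reported
  empty <- structure(list(trait = "t", location = "CRA", qtls = list(),
                          n_qtl = 0L), class = "multiqtl_model")
  rec0 <- score_recovery(empty, truth, scores)
  expect_equal(rec0$n_detected, 0L)
  expect_true(is.na(rec0$fdp))

  # 5 planted, 3 recovered, 1 spurious: power 0.6, FDP 0.25
  set.seed(10)
  ind <- matrix(round(runif(40 * 6) * 16) / 16, 40, 6,
                dimnames = list(NULL, paste0("c", 1:6)))
  truth5 <- list(causal = data.frame(marker_id = paste0("c", 1:5), CRA = 1))
  model5 <- structure(list(
    trait = "t", location = "CRA",
    qtls = lapply(c("c1", "c2", "c3", "c6"), function(id) {
      list(representative = id, members = id)
    }),
    n_qtl = 4L), class = "multiqtl_model")
  rec5 <- score_recovery(model5, truth5, ind)
  expect_equal(rec5$power, 0.6)
  expect_equal(rec5$fdp, 0.25)
})
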