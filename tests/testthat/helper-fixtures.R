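# Fixtures shared across the suite. Everything is generated in code; sizes
# are kept small so the whole suite runs in minutes.

# long-format frequency table for a hand-checkable toy panel
toy_freq_table <- function() {
  rows <- list(
    # m1: clean biallelic A/G, varies across accessions
    list("s1_10", "s1", 10L, "a1", 0.50, 0.00, 0.50, 0.00),
    list("s1_10", "s1", 10L, "a2", 1.00, 0.00, 0.00, 0.00),
    list("s1_10", "s1", 10L, "a3", 0.75, 0.00, 0.25, 0.00),
    # m2: near-fixed (major 0.99 panel-wide)
    list("s1_20", "s1", 20L, "a1", 0.98, 0.02, 0.00, 0.00),
    list("s1_20", "s1", 20L, "a2", 1.00, 0.00, 0.00, 0.00),
    list("s1_20", "s1", 20L, "a3", 0.99, 0.01, 0.00, 0.00),
    # m3: three alleles, top-two sum 0.90 < 0.95
    list("s2_5",  "s2", 5L,  "a1", 0.50, 0.40, 0.10, 0.00),
    list("s2_5",  "s2", 5L,  "a2", 0.40, 0.50, 0.10, 0.00),
    list("s2_5",  "s2", 5L,  "a3", 0.45, 0.45, 0.10, 0.00),
    # m4: biallelic but constant 0.55 everywhere (SD 0)
    list("s2_9",  "s2", 9L,  "a1", 0.55, 0.45, 0.00, 0.00),
    list("s2_9",  "s2", 9L,  "a2", 0.55, 0.45, 0.00, 0.00),
    list("s2_9",  "s2", 9L,  "a3", 0.55, 0.45, 0.00, 0.00),
    # m5: missing call for a3
    list("s3_7",  "s3", 7L,  "a1", 0.30, 0.70, 0.00, 0.00),
    list("s3_7",  "s3", 7L,  "a2", 0.80, 0.20, 0.00, 0.00)
  )
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(marker_id = r[[1]], scaffold = r[[2]], position = r[[3]],
               accession = r[[4]], A = r[[5]], C = r[[6]], G = r[[7]],
               T = r[[8]], stringsAsFactors = FALSE)
  }))
  as_freq_table(tab)
}

# random valid frequency tables for property tests: biallelic-ish markers
# with occasional missing calls and third alleles
random_freq_table <- function(n_acc = 8L, n_marker = 12L) {
  acc <- sprintf("a%02d", seq_len(n_acc))
  rows <- list()
  for (j in seq_len(n_marker)) {
    pair <- sample(c("A", "C", "G", "T"), 2L)
    p <- runif(1, 0.02, 0.98)
    miss <- runif(n_acc) < 0.1
    for (i in seq_len(n_acc)) {
      if (miss[i]) next
      third <- if (runif(1) < 0.15) runif(1, 0, 0.15) else 0
      f1 <- pmin(pmax(rnorm(1, p, 0.2), 0), 1) * (1 - third)
      freqs <- c(A = 0, C = 0, G = 0, T = 0)
      freqs[pair[1]] <- f1
      freqs[pair[2]] <- (1 - third) - f1
      if (third > 0) {
        rest <- setdiff(c("A", "C", "G", "T"), pair)
        freqs[rest[1]] <- third
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = sprintf("sc%d_%d", j, j * 10L),
        scaffold = sprintf("sc%d", j), position = j * 10L,
        accession = acc[i], A = freqs[["A"]], C = freqs[["C"]],
        G = freqs[["G"]], T = freqs[["T"]], stringsAsFactors = FALSE)
    }
  }
  as_freq_table(do.call(rbind, rows))
}

# small structured panel reused by several analysis tests
small_panel <- function(seed = 42L, n_accessions = 80L, n_scaffolds = 30L,
                        markers_per_scaffold = 15L, traits = NULL) {
  if (is.null(traits)) {
    # tiny panels cannot host many mutually non-collinear QTLs
    traits <- list(default_trait(n_qtl = 2L, qtl_var = c(0.2, 0.15),
                                 h2 = 0.5))
  }
  args <- list(n_accessions = n_accessions, n_scaffolds = n_scaffolds,
               markers_per_scaffold = markers_per_scaffold, seed = seed,
               traits = traits)
  simulate_panel(do.call(sim_config, args))
}

# deterministic score matrix with known correlation structure
toy_scores <- function(n = 20L, seed = 11L) {
  set.seed(seed)
  x <- round(runif(n, 0, 16)) / 16
  y <- round(pmin(pmax(x + rnorm(n, 0, 0.15), 0), 1) * 16) / 16
  z <- round(runif(n, 0, 16)) / 16
  m <- cbind(m1 = x, m2 = y, m3 = z, m4 = 1 - x)
  rownames(m) <- sprintf("acc%02d", seq_len(n))
  m
}
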