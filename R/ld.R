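#' Squared allele-frequency correlation between two markers
#'
#' Squared Pearson correlation of two score columns across accessions.
#' Because columns are polarized by the panel major allele, negative
#' correlations are physically meaningful linkage and `r^2` is invariant to
#' polarity (a column and its complement give `r^2 = 1`).
#'
#' @param scores accession-by-marker score matrix.
#' @param a,b marker ids or column indices.
#' @return squared Pearson correlation, or `NA` if either column has zero
#'   variance (cannot occur after QC).
#' @export
marker_r2 <- function(scores, a, b) {
  x <- scores[, a]
  y <- scores[, b]
  if (length(x) < 3L) stop("need at least 3 accessions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Within-scaffold LD profiles
#'
#' Computes `r^2` for all marker pairs on each selected scaffold together
#' with their physical distance `|pos_a - pos_b|` (positions are 1-based;
#' two markers at the same position yield a distance-0 pair, which is
#' retained). Scaffolds can be selected explicitly or by rank of their
#' length in a scaffold index (the field practice is to profile the largest
#' scaffolds that are well covered with markers).
#'
#' @param scores accession-by-marker score matrix.
#' @param meta marker metadata aligned to `scores` columns.
#' @param scaffolds explicit character vector of scaffold names, or `NULL`.
#' @param scaffold_index optional index used with `n_largest`.
#' @param n_largest when `scaffolds` is `NULL`, profile the `n_largest`
#'   longest indexed scaffolds that carry at least `min_markers` markers
#'   (default 24, mirroring standard practice on draft assemblies).
#' @param min_markers scaffolds with fewer markers are skipped with a
#'   warning.
#' @return list of per-scaffold data.frames (`id_a`, `id_b`, `distance`,
#'   `r2`), named by scaffold, of class `"ld_profiles"`.
#' @export
scaffold_ld_profile <- function(scores, meta, scaffolds = NULL,
                                scaffold_index = NULL, n_largest = 24L,
                                min_markers = 2L) {
  min_markers <- max(2L, min_markers)
  counts <- table(meta$scaffold)
  if (is.null(scaffolds)) {
    if (!is.null(scaffold_index)) {
      eligible <- names(counts)[counts >= min_markers]
      idx <- scaffold_index[scaffold_index$scaffold %in% eligible, ]
      idx <- idx[order(idx$length_bp, decreasing = TRUE), ]
      scaffolds <- utils::head(idx$scaffold, n_largest)
    } else {
      scaffolds <- names(sort(counts, decreasing = TRUE))
      scaffolds <- utils::head(scaffolds[counts[scaffolds] >= min_markers],
                               n_largest)
    }
  }
  profiles <- list()
  for (sc in scaffolds) {
    on_sc <- which(meta$scaffold == sc)
    if (length(on_sc) < min_markers) {
      warning("scaffold ", sc, " has fewer than ", min_markers,
              " markers; skipped")
      next
    }
    pos <- meta$position[on_sc]
    ids <- meta$marker_id[on_sc]
    C <- stats::cor(scores[, on_sc, drop = FALSE])
    pair <- which(upper.tri(C), arr.ind = TRUE)
    profiles[[sc]] <- data.frame(
      id_a = ids[pair[, 1L]],
      id_b = ids[pair[, 2L]],
      distance = abs(pos[pair[, 1L]] - pos[pair[, 2L]]),
      r2 = C[pair]^2,
      stringsAsFactors = FALSE
    )
  }
  structure(profiles, class = c("ld_profiles", "list"))
}

#' Binned LD-decay summary
#'
#' Median `r^2` per log-spaced distance bin, pooled over scaffolds; the raw
#' pairs are kept by [scaffold_ld_profile()] for scatter-style plots.
#'
#' @param profiles an `"ld_profiles"` list.
#' @param n_bins number of log-spaced distance bins.
#' @return data.frame `bin_lo`, `bin_hi`, `n_pairs`, `median_r2`.
#' @export
ld_decay_summary <- function(profiles, n_bins = 12L) {
  all_pairs <- do.call(rbind, lapply(unname(profiles), identity))
  d <- pmax(all_pairs$distance, 1)
  breaks <- exp(seq(log(min(d)), log(max(d) + 1), length.out = n_bins + 1L))
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  agg <- split(all_pairs$r2, bin)
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1L],
    n_pairs = vapply(agg, length, integer(1)),
    median_r2 = vapply(agg, function(v) {
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
}

#' Baseline r-squared and the collinearity threshold
#'
#' The long-range floor of the decay curve is estimated as the median `r^2`
#' among the most distal `distal_fraction` of pairs on each scaffold,
#' averaged over scaffolds. The recommended collinearity threshold is the
#' larger of this baseline and the configured floor (0.1 on the `r^2`
#' scale, i.e. `|r| >= 0.3` up to rounding), so a panel with very weak
#' long-range correlation still uses the conventional threshold.
#'
#' @param profiles an `"ld_profiles"` list.
#' @param distal_fraction fraction of most-distant pairs per scaffold used
#'   for the baseline (default 0.25).
#' @param floor_r2 configured floor on the `r^2` scale (default 0.1).
#' @return list with `baseline_r2`, `threshold_r2`, `threshold_r`
#'   (`sqrt(threshold_r2)`), `per_scaffold` baselines.
#' @export
estimate_baseline_r2 <- function(profiles, distal_fraction = 0.25,
                                 floor_r2 = 0.1) {
  per_scaffold <- vapply(profiles, function(p) {
    if (nrow(p) == 0L) return(NA_real_)
    q <- stats::quantile(p$distance, 1 - distal_fraction, names = FALSE)
    distal <- p$r2[p$distance >= q]
    if (length(distal) == 0L) distal <- p$r2
    stats::median(distal)
  }, numeric(1))
  per_scaffold <- per_scaffold[is.finite(per_scaffold)]
  if (length(per_scaffold) == 0L) {
    warning("no distal pairs available; falling back to the configured floor")
    baseline <- NA_real_
    threshold <- floor_r2
  } else {
    baseline <- mean(per_scaffold)
    threshold <- max(baseline, floor_r2)
  }
  list(baseline_r2 = baseline,
       threshold_r2 = threshold,
       threshold_r = sqrt(threshold),
       per_scaffold = per_scaffold)
}

#' Flatten LD profiles into a single table
#' @param profiles an `"ld_profiles"` list.
#' @export
ld_pairs_table <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(sc) {
    cbind(scaffold = sc, profiles[[sc]], stringsAsFactors = FALSE)
  }))
}
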