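#' Panel-level allele statistics
#'
#' For every marker, the panel frequency of each nucleotide is the mean of
#' the per-accession frequencies over accessions with a call, and the call
#' rate is the fraction of panel accessions with a call. The panel-wide
#' major allele is the nucleotide with the highest panel frequency; ties at
#' exactly equal frequency are broken lexicographically (A < C < G < T) so
#' scoring is deterministic.
#'
#' @param tab a `freq_table` (see [read_frequency_table()]).
#' @param accessions optional character vector fixing the panel; defaults to
#'   the accessions present anywhere in `tab`.
#' @return data.frame with one row per marker: `marker_id`, `scaffold`,
#'   `position`, panel frequencies `A`,`C`,`G`,`T`, `call_rate`,
#'   `major_allele`, `minor_allele`, `major_freq`, `minor_freq` (the
#'   second-largest panel frequency), `top2_sum`, `major_sd` (sample SD of
#'   the per-accession major-allele frequency).
#' @export
panel_allele_stats <- function(tab, accessions = NULL) {
  if (is.null(accessions)) accessions <- unique(tab$accession)
  n_panel <- length(accessions)
  if (n_panel == 0L) stop("panel contains zero accessions")
  tab <- tab[tab$accession %in% accessions, , drop = FALSE]
  freqs <- as.matrix(tab[, NUCLEOTIDES])
  called <- stats::complete.cases(freqs)
  tab <- tab[called, , drop = FALSE]
  freqs <- freqs[called, , drop = FALSE]

  f <- factor(tab$marker_id, levels = unique(tab$marker_id))
  n_calls <- as.vector(table(f))
  panel_freq <- rowsum(freqs, f, reorder = FALSE) / n_calls

  # lexicographic tie-break: max.col(ties.method = "first") on A,C,G,T order
  major_idx <- max.col(panel_freq, ties.method = "first")
  sorted2 <- apply(panel_freq, 1L, function(v) sort(v, decreasing = TRUE)[1:2])
  minor_idx <- apply(panel_freq, 1L, function(v) {
    order(v, decreasing = TRUE)[2L]
  })

  major_acc_freq <- freqs[cbind(seq_len(nrow(freqs)), major_idx[as.integer(f)])]
  grp_n <- n_calls[as.integer(f)]
  mu <- (panel_freq[cbind(seq_along(major_idx), major_idx)])[as.integer(f)]
  ss <- rowsum((major_acc_freq - mu)^2, f, reorder = FALSE)[, 1]
  major_sd <- ifelse(n_calls > 1L, sqrt(ss / (n_calls - 1L)), 0)

  first <- !duplicated(tab$marker_id)
  data.frame(
    marker_id = tab$marker_id[first],
    scaffold = tab$scaffold[first],
    position = tab$position[first],
    panel_freq,
    call_rate = n_calls / n_panel,
    major_allele = NUCLEOTIDES[major_idx],
    minor_allele = NUCLEOTIDES[minor_idx],
    major_freq = sorted2[1L, ],
    minor_freq = sorted2[2L, ],
    top2_sum = sorted2[1L, ] + sorted2[2L, ],
    major_sd = major_sd,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

QC_RULES <- c("call_rate", "maf", "biallelic", "sd")

#' Informative-marker selection and major-allele scoring
#'
#' Applies the four selection rules, in order, to pooled nucleotide
#' frequencies and scores each surviving marker as the per-accession
#' frequency of the panel-wide major allele:
#'
#' 1. **call_rate** - the marker must be called in 100% of the panel
#'    accessions (configurable via `call_rate_min`);
#' 2. **maf** - markers whose panel minor (second-largest) allele frequency
#'    is below `maf_min` (2%) or whose major allele frequency exceeds
#'    `major_max` (98%) are removed;
#' 3. **biallelic** - the panel frequencies of the two major alleles must sum
#'    to at least `biallelic_min` (95%);
#' 4. **sd** - the sample standard deviation of the per-accession
#'    major-allele frequency must be at least `sd_min` (0.1), ensuring
#'    allelic variation across the panel.
#'
#' The rejection report records, for each removed marker, the first rule it
#' violated in the order above.
#'
#' @param tab a `freq_table`.
#' @param thresholds named list overriding `maf_min`, `major_max`,
#'   `biallelic_min`, `sd_min`, `call_rate_min`.
#' @param accessions optional fixed panel (see [panel_allele_stats()]).
#' @return list of class `"marker_panel"` with elements `scores`
#'   (accession-by-marker matrix), `meta` (marker metadata), `rejections`
#'   (data.frame `marker_id`, `rule`), `rule_counts`, and `stats` (the panel
#'   allele statistics of all input markers).
#' @export
select_markers <- function(tab, thresholds = list(), accessions = NULL) {
  th <- utils::modifyList(
    list(maf_min = 0.02, major_max = 0.98, biallelic_min = 0.95,
         sd_min = 0.1, call_rate_min = 1.0),
    thresholds
  )
  if (is.null(accessions)) accessions <- unique(tab$accession)
  stats <- panel_allele_stats(tab, accessions = accessions)

  rule <- rep(NA_character_, nrow(stats))
  rule[is.na(rule) & stats$call_rate < th$call_rate_min] <- "call_rate"
  rule[is.na(rule) &
         (stats$minor_freq < th$maf_min | stats$major_freq > th$major_max)] <- "maf"
  rule[is.na(rule) & stats$top2_sum < th$biallelic_min] <- "biallelic"
  rule[is.na(rule) & stats$major_sd < th$sd_min] <- "sd"

  keep <- is.na(rule)
  rejections <- data.frame(marker_id = stats$marker_id[!keep],
                           rule = rule[!keep], stringsAsFactors = FALSE)
  rule_counts <- vapply(QC_RULES, function(r) sum(rule == r, na.rm = TRUE),
                        integer(1))

  kept_ids <- stats$marker_id[keep]
  if (length(kept_ids) == 0L) {
    warning("no marker survived QC; returning an empty panel")
    scores <- matrix(numeric(0), nrow = length(accessions), ncol = 0,
                     dimnames = list(accessions, character(0)))
  } else {
    sub <- tab[tab$marker_id %in% kept_ids & tab$accession %in% accessions, ,
               drop = FALSE]
    major <- stats$major_allele[match(sub$marker_id, stats$marker_id)]
    val <- as.matrix(sub[, NUCLEOTIDES])[cbind(seq_len(nrow(sub)),
                                               match(major, NUCLEOTIDES))]
    scores <- matrix(NA_real_, nrow = length(accessions),
                     ncol = length(kept_ids),
                     dimnames = list(accessions, kept_ids))
    scores[cbind(match(sub$accession, accessions),
                 match(sub$marker_id, kept_ids))] <- val
    if (anyNA(scores)) {
      stop("missing scores after QC despite the call-rate rule")
    }
  }
  meta <- stats[keep, c("marker_id", "scaffold", "position",
                        "major_allele", "minor_allele"), drop = FALSE]
  rownames(meta) <- NULL
  if (ncol(scores) > 0L) {
    # canonical polarity: among the two retained alleles the tracked one has
    # panel score >= 0.5 (lexicographic on an exact tie), so rescoring the
    # scored output reproduces it
    mu <- colMeans(scores)
    flip <- mu < 0.5 | (mu == 0.5 & meta$minor_allele < meta$major_allele)
    if (any(flip)) {
      scores[, flip] <- 1 - scores[, flip]
      tmp <- meta$major_allele[flip]
      meta$major_allele[flip] <- meta$minor_allele[flip]
      meta$minor_allele[flip] <- tmp
    }
  }
  new_marker_panel(scores, meta,
                   rejections = rejections, rule_counts = rule_counts,
                   stats = stats, thresholds = th)
}

new_marker_panel <- function(scores, meta, ...) {
  structure(list(scores = scores, meta = meta, ...),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d accessions x %d markers on %d scaffolds\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$meta$scaffold))))
  if (!is.null(x$rule_counts)) {
    cat("QC rejections:",
        paste(names(x$rule_counts), x$rule_counts, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Apply the QC rules directly to a score matrix
#'
#' Fast path for panels already scored as major-allele proportions (for
#' instance the output of the synthetic generator, or a rerun of QC on its
#' own output). The call-rate rule requires complete columns; the maf and sd
#' rules are applied to the column mean and sample SD of the scores; the
#' biallelic rule is satisfied by construction (a score column carries two
#' alleles). Polarity is never flipped, which makes the operation idempotent.
#'
#' @param scores accession-by-marker score matrix.
#' @param meta marker metadata aligned to `scores` columns.
#' @inheritParams select_markers
#' @return a `"marker_panel"` (same shape of result as [select_markers()]).
#' @export
qc_score_matrix <- function(scores, meta, thresholds = list()) {
  th <- utils::modifyList(
    list(maf_min = 0.02, major_max = 0.98, sd_min = 0.1, call_rate_min = 1.0),
    thresholds
  )
  stopifnot(ncol(scores) == nrow(meta))
  call_rate <- colMeans(!is.na(scores))
  p_major <- colMeans(scores, na.rm = TRUE)
  # columns are polarized to the major allele, so the minor frequency is 1 - p
  sd_col <- apply(scores, 2L, stats::sd, na.rm = TRUE)

  rule <- rep(NA_character_, ncol(scores))
  rule[is.na(rule) & call_rate < th$call_rate_min] <- "call_rate"
  rule[is.na(rule) &
         (pmin(p_major, 1 - p_major) < th$maf_min |
            pmax(p_major, 1 - p_major) > th$major_max)] <- "maf"
  rule[is.na(rule) & sd_col < th$sd_min] <- "sd"

  keep <- is.na(rule)
  rejections <- data.frame(marker_id = meta$marker_id[!keep],
                           rule = rule[!keep], stringsAsFactors = FALSE)
  rule_counts <- vapply(QC_RULES, function(r) sum(rule == r, na.rm = TRUE),
                        integer(1))
  new_marker_panel(scores[, keep, drop = FALSE],
                   meta[keep, , drop = FALSE],
                   rejections = rejections, rule_counts = rule_counts,
                   thresholds = th)
}

#' Expand a score matrix back into a nucleotide frequency table
#'
#' The inverse of scoring for biallelic markers: the major-allele column of
#' each accession gets the score and the minor allele gets `1 - score`; the
#' two remaining nucleotides get frequency zero.
#'
#' @param scores accession-by-marker score matrix.
#' @param meta marker metadata with `major_allele` / `minor_allele` columns.
#' @return a `freq_table`.
#' @export
freq_table_from_scores <- function(scores, meta) {
  stopifnot(ncol(scores) == nrow(meta))
  n_acc <- nrow(scores)
  n_mk <- ncol(scores)
  acc <- rep(rownames(scores), times = n_mk)
  mk <- rep(seq_len(n_mk), each = n_acc)
  s <- as.vector(scores)
  freqs <- matrix(0, nrow = n_acc * n_mk, ncol = 4L,
                  dimnames = list(NULL, NUCLEOTIDES))
  freqs[cbind(seq_along(s), match(meta$major_allele, NUCLEOTIDES)[mk])] <- s
  freqs[cbind(seq_along(s), match(meta$minor_allele, NUCLEOTIDES)[mk])] <- 1 - s
  tab <- data.frame(marker_id = meta$marker_id[mk],
                    scaffold = meta$scaffold[mk],
                    position = meta$position[mk],
                    accession = acc,
                    freqs,
                    stringsAsFactors = FALSE)
  as_freq_table(tab)
}

#' Summarize genome coverage of a selected marker panel
#'
#' @param panel a `"marker_panel"`.
#' @param scaffold_index data.frame `scaffold`, `length_bp` (see
#'   [read_scaffold_index()]); markers on scaffolds absent from the index are
#'   counted as unplaced and excluded from the length sum.
#' @param genome_size_bp haploid genome size used for the covered fraction;
#'   defaults to the total length in the index.
#' @return list with `n_markers`, `n_scaffolds`, `covered_bp`,
#'   `genome_fraction`, `unplaced_scaffolds`.
#' @export
qc_summary <- function(panel, scaffold_index, genome_size_bp = NULL) {
  if (is.null(genome_size_bp)) genome_size_bp <- sum(scaffold_index$length_bp)
  covered <- unique(panel$meta$scaffold)
  placed <- covered[covered %in% scaffold_index$scaffold]
  unplaced <- setdiff(covered, placed)
  covered_bp <- sum(scaffold_index$length_bp[
    match(placed, scaffold_index$scaffold)])
  list(
    n_markers = ncol(panel$scores),
    n_scaffolds = length(covered),
    covered_bp = covered_bp,
    genome_fraction = if (genome_size_bp > 0) covered_bp / genome_size_bp else 0,
    unplaced_scaffolds = unplaced
  )
}
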