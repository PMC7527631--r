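#' Forward-selection MultiQTL model
#'
#' Builds a multi-locus model from the markers that pass the genome-wide
#' significance threshold of an association scan. A QTL is a group of
#' significant, mutually collinear markers represented by the member that
#' explains the largest phenotypic variance. The procedure iterates:
#'
#' 1. among the remaining significant candidates, select the marker with
#'    the largest explained variance conditional on the representatives
#'    already in the model (marginal `r^2` at the first step); ties are
#'    broken by smaller scan p-value, then lexicographic marker id;
#' 2. assign every remaining candidate correlated at `|r| >= r_collinear`
#'    with the new representative to its group (collinearity is evaluated
#'    against the representative only);
#' 3. continue with the markers still unassigned.
#'
#' In `mode = "conditional"` (the default) selection stops as soon as the
#' best candidate's conditional test - the t-test of the candidate in a
#' least-squares model containing the selected representatives - no longer
#' passes the same genome-wide p threshold used by the scan. In
#' `mode = "marginal"` candidates keep entering (ordered by conditional
#' explained variance) until all significant markers are grouped, which
#' mirrors procedures that rank markers without conditional re-testing.
#'
#' The model explained variance is the squared correlation between the
#' fitted values of the least-squares regression of the phenotype on all
#' representatives and the observed phenotype (no kinship re-correction);
#' an adjusted version accounting for the number of representatives is also
#' reported.
#'
#' @param scan an `"association_scan"` for one trait and location.
#' @param scores accession-by-marker score matrix (all scanned markers).
#' @param y phenotype vector used in the scan.
#' @param r_collinear collinearity threshold on `|r|` (default 0.3).
#' @param threshold significance threshold: a list from
#'   [significance_threshold()], a `-log10 p` scalar, or `NULL` to reuse the
#'   threshold stored in the scan.
#' @param mode `"conditional"` or `"marginal"` (see Details).
#' @param trait,location labels carried into the model object.
#' @return list of class `"multiqtl_model"`: `trait`, `location`, `qtls`
#'   (ordered list with `representative`, `members`, `stats`, i.e. the
#'   representative's scan row, and `conditional_expl_var`), `n_qtl`,
#'   `expl_var`, `expl_var_adj`, `cumulative_expl_var`, `n_significant`,
#'   `n_unselected`, `r_collinear`, `mode`.
#' @export
forward_select <- function(scan, scores, y, r_collinear = 0.3,
                           threshold = NULL, mode = c("conditional", "marginal"),
                           trait = NA_character_, location = NA_character_) {
  mode <- match.arg(mode)
  thr <- if (is.list(threshold)) threshold$neglog10p else threshold
  if (is.null(thr)) thr <- attr(scan, "threshold")
  if (is.null(thr)) stop("no significance threshold available")
  p_thr <- 10^(-thr)

  sig <- scan$marker_id[scan$neglog10p >= thr]
  empty <- list(trait = trait, location = location, qtls = list(),
                n_qtl = 0L, expl_var = 0, expl_var_adj = 0,
                cumulative_expl_var = numeric(0),
                n_significant = length(sig), n_unselected = length(sig),
                r_collinear = r_collinear, mode = mode)
  class(empty) <- "multiqtl_model"
  if (length(sig) == 0L) return(empty)

  y <- as.numeric(y)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  candidates <- sig
  reps <- character(0)
  qtls <- list()
  cum_r2 <- numeric(0)
  X_sel <- matrix(1, n, 1L)
  rss_sel <- tss

  scan_p <- stats::setNames(scan$p, scan$marker_id)

  repeat {
    if (length(candidates) == 0L) break
    if (ncol(X_sel) >= n - 1L) break  # design saturated
    Xc <- scores[, candidates, drop = FALSE]
    # conditional RSS when adding each candidate to the selected design
    q <- qr(X_sel)
    Rc <- Xc - qr.fitted(q, Xc)
    ry <- y - qr.fitted(q, y)
    cxy <- colSums(Rc * ry)
    cxx <- colSums(Rc^2)
    ok <- cxx > 1e-12
    rss_new <- rss_sel - ifelse(ok, cxy^2 / cxx, 0)
    cond_r2 <- (rss_sel - rss_new) / tss

    df_resid <- n - (ncol(X_sel) + 1L)
    tstat2 <- ifelse(ok & rss_new > 0,
                     (cxy^2 / cxx) / (rss_new / df_resid), Inf)
    cond_p <- stats::pf(tstat2, 1L, df_resid, lower.tail = FALSE)

    ord <- order(-cond_r2, scan_p[candidates], candidates)
    best <- ord[1L]
    if (mode == "conditional" && cond_p[best] > p_thr) break

    rep_id <- candidates[best]
    r_to_rep <- drop(stats::cor(scores[, candidates, drop = FALSE],
                                scores[, rep_id]))
    members <- candidates[abs(r_to_rep) >= r_collinear]
    members <- union(rep_id, members)

    reps <- c(reps, rep_id)
    X_sel <- cbind(X_sel, scores[, rep_id])
    rss_sel <- rss_new[best]
    fit_r2 <- 1 - rss_sel / tss
    cum_r2 <- c(cum_r2, fit_r2)
    qtls[[length(qtls) + 1L]] <- list(
      representative = rep_id,
      members = sort(members),
      stats = scan[scan$marker_id == rep_id, , drop = FALSE],
      conditional_expl_var = cond_r2[best]
    )
    candidates <- setdiff(candidates, members)
  }

  if (length(reps) == 0L) return(empty)
  fitted <- qr.fitted(qr(X_sel), y)
  r2 <- stats::cor(fitted, y)^2
  k <- length(reps)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  structure(list(
    trait = trait, location = location, qtls = qtls,
    n_qtl = length(qtls),
    expl_var = r2, expl_var_adj = r2_adj,
    cumulative_expl_var = cum_r2,
    n_significant = length(sig),
    n_unselected = length(candidates),
    r_collinear = r_collinear, mode = mode
  ), class = "multiqtl_model")
}

#' @export
print.multiqtl_model <- function(x, ...) {
  cat(sprintf("MultiQTL model [%s / %s]: %d QTLs, explained variance %.3f (%d significant markers, %d unselected)\n",
              x$trait, x$location, x$n_qtl, x$expl_var,
              x$n_significant, x$n_unselected))
  for (q in x$qtls) {
    cat(sprintf("  %s (%d members)\n", q$representative, length(q$members)))
  }
  invisible(x)
}

#' Representative markers of a MultiQTL model
#' @param model a `"multiqtl_model"`.
#' @return character vector of representative marker ids.
#' @export
representative_markers <- function(model) {
  vapply(model$qtls, `[[`, character(1), "representative")
}

#' Sensitivity of the MultiQTL model to the collinearity threshold
#'
#' Re-runs the forward selection over a grid of `r` thresholds and tabulates
#' the number of QTLs and the model explained variance at each value. Run in
#' marginal mode by default: the scan probes how the grouping granularity -
#' not the conditional stop rule - reshapes the model, which is what makes
#' the over-fragmentation beyond the calibrated threshold visible.
#'
#' @inheritParams forward_select
#' @param r_grid vector of `|r|` thresholds (default 0.1 to 0.9).
#' @return data.frame `r`, `n_qtl`, `expl_var`.
#' @export
collinearity_scan <- function(scan, scores, y,
                              r_grid = seq(0.1, 0.9, by = 0.1),
                              threshold = NULL, mode = "marginal") {
  rows <- lapply(r_grid, function(r) {
    m <- forward_select(scan, scores, y, r_collinear = r,
                        threshold = threshold, mode = mode)
    data.frame(r = r, n_qtl = m$n_qtl, expl_var = m$expl_var)
  })
  do.call(rbind, rows)
}

#' PCA of significant-marker allele-frequency profiles
#'
#' Principal component analysis in which the significant markers are the
#' observations and the accession frequencies the variables, so markers with
#' similar frequency profiles - collinear markers tagging the same locus -
#' cluster together. Plotting (PC1, PC2, -log10 p) reproduces the peak-top
#' view of a Manhattan plot when no chromosome coordinates exist.
#'
#' @param scores accession-by-marker score matrix restricted (by the caller
#'   or via `marker_ids`) to significant markers, typically the union across
#'   locations.
#' @param scan_stats data.frame with `marker_id` and `neglog10p` (rows for
#'   markers from several scans may be stacked; a `location` column is
#'   carried through when present).
#' @param marker_ids optional subset of markers to use.
#' @return list with `coords` (per marker: `marker_id`, `PC1`, `PC2`,
#'   `neglog10p`, and `location` when supplied) and `percent_variance`.
#' @export
significant_marker_pca <- function(scores, scan_stats, marker_ids = NULL) {
  if (!is.null(marker_ids)) scores <- scores[, marker_ids, drop = FALSE]
  if (ncol(scores) < 2L) stop("PCA needs at least two significant markers")
  X <- t(scores)  # markers as observations
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- data.frame(marker_id = rownames(pc$x),
                       PC1 = pc$x[, 1L],
                       PC2 = if (k >= 2L) pc$x[, 2L] else 0,
                       stringsAsFactors = FALSE, row.names = NULL)
  m <- match(coords$marker_id, scan_stats$marker_id)
  coords$neglog10p <- scan_stats$neglog10p[m]
  if ("location" %in% names(scan_stats)) {
    coords$location <- scan_stats$location[m]
  }
  list(coords = coords, percent_variance = pct)
}

#' Serialize MultiQTL models to JSON
#'
#' @param models a `"multiqtl_model"` or list of them.
#' @param path output JSON path.
#' @export
write_multiqtl_json <- function(models, path) {
  if (inherits(models, "multiqtl_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(trait = m$trait, location = m$location, n_qtl = m$n_qtl,
         expl_var = m$expl_var, expl_var_adj = m$expl_var_adj,
         qtls = lapply(m$qtls, function(q) {
           list(representative = q$representative,
                members = q$members,
                neglog10p = q$stats$neglog10p,
                effect = q$stats$effect,
                expl_var = q$stats$expl_var,
                conditional_expl_var = q$conditional_expl_var)
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
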