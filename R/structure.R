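#' VanRaden genomic relationship matrix on the allele-frequency scale
#'
#' Accession "genotypes" here are pooled major-allele proportions in
#' `[0, 1]` rather than 0/1/2 dosages, so the classical VanRaden scaling
#' `2 * sum(p * (1 - p))` is replaced by its frequency-scale analogue:
#' `K = Z Z' / s` with `Z` the column-centred score matrix and
#' `s = sum_j pbar_j * (1 - pbar_j)`, `pbar_j` the panel mean score of
#' marker `j`. Constant columns contribute nothing to `Z`.
#'
#' @param scores accession-by-marker score matrix (QC-passed; no missing
#'   values are allowed).
#' @return symmetric accession-by-accession matrix of class
#'   `"kinship_matrix"` with attributes `method`, `centering` (the column
#'   means) and `scale` (the denominator `s`).
#' @export
vanraden_kinship <- function(scores) {
  if (anyNA(scores)) stop("missing scores: kinship requires a QC-passed matrix")
  if (ncol(scores) < 1L) stop("no markers")
  pbar <- colMeans(scores)
  Z <- sweep(scores, 2L, pbar, "-")
  s <- sum(pbar * (1 - pbar))
  if (s <= 0) stop("all markers are fixed; kinship undefined")
  K <- tcrossprod(Z) / s
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(scores), rownames(scores))
  structure(K, method = "vanraden_freq", centering = pbar, scale = s,
            class = c("kinship_matrix", "matrix", "array"))
}

#' Principal coordinate analysis of a kinship matrix
#'
#' Eigendecomposition of the double-centred kinship. Axes are ordered by
#' eigenvalue; per-axis percent variance is the eigenvalue divided by the sum
#' of positive eigenvalues, times 100.
#'
#' @param K symmetric kinship matrix.
#' @param n_axes number of axes to return (default all positive).
#' @return list with `coords` (accessions x axes, scaled by sqrt
#'   eigenvalue), `eigenvalues`, `percent_variance`.
#' @export
pcoa_kinship <- function(K, n_axes = NULL) {
  K <- unclass(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship must be symmetric")
  if (all(abs(K) < 1e-12)) stop("all-zero kinship matrix")
  n <- nrow(K)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% K %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  total <- sum(e$values[pos])
  if (is.null(n_axes)) n_axes <- sum(pos)
  n_axes <- min(n_axes, sum(pos))
  idx <- seq_len(n_axes)
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[idx], 0)), n_axes, n_axes)
  dimnames(coords) <- list(rownames(K), paste0("PCo", idx))
  list(coords = coords,
       eigenvalues = e$values,
       percent_variance = 100 * e$values[idx] / total)
}

#' Dendrogram of a kinship matrix with a k-cluster cut
#'
#' Converts the kinship similarity into a distance and clusters it
#' hierarchically (average linkage by default, which also drives the
#' reported cluster cut). The default conversion is the Gram-induced
#' distance `d(i, j) = K_ii + K_jj - 2 K_ij`, under which two accessions
#' with identical marker profiles are at distance zero and merge first;
#' `"max_minus"` (`d = max(K) - K_ij`) is available as an alternative.
#' Tie-breaking follows `stats::hclust`, which is deterministic in the
#' input label order.
#'
#' @param K symmetric kinship matrix with accession dimnames.
#' @param k number of clusters to cut (default 5); must be `<= n`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param distance similarity-to-distance conversion, `"gram"` (default) or
#'   `"max_minus"`.
#' @return list with `hclust`, `clusters` (named integer vector), `newick`.
#' @export
kinship_dendrogram <- function(K, k = 5L, linkage = "average",
                               distance = c("gram", "max_minus")) {
  distance <- match.arg(distance)
  K <- unclass(K)
  n <- nrow(K)
  if (k > n) stop("cannot cut ", n, " accessions into ", k, " clusters")
  D <- if (distance == "gram") {
    outer(diag(K), diag(K), "+") - 2 * K
  } else {
    max(K) - K
  }
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  clusters <- stats::cutree(hc, k = k)
  list(hclust = hc, clusters = clusters, newick = write_newick(hc))
}

#' Pairwise Wright's FST between accession clusters
#'
#' For each marker, `p_i` is the mean accession score within cluster `i`,
#' `c_i` the fraction of accessions in cluster `i`, and `pbar = sum(c_i *
#' p_i)`. Per marker, `FST = (pbar * (1 - pbar) - sum(c_i * p_i * (1 -
#' p_i))) / (pbar * (1 - pbar))`. The multi-marker value for a cluster pair
#' is the ratio of the summed numerators to the summed denominators
#' (Weir-style averaging, stable when single markers carry little
#' information); monomorphic markers (`pbar` 0 or 1) are skipped. Per-marker
#' ratios are returned as well.
#'
#' @param scores accession-by-marker score matrix.
#' @param clusters named vector mapping accessions to cluster labels (at
#'   least two non-empty clusters).
#' @return data.frame of class `"fst_result"`: `cluster_a`, `cluster_b`,
#'   `fst`, `n_markers`; per-marker ratios in attribute `"per_marker"`, and a
#'   square matrix form in attribute `"matrix"`.
#' @export
pairwise_fst <- function(scores, clusters) {
  clusters <- clusters[rownames(scores)]
  if (anyNA(clusters)) stop("every accession needs a cluster assignment")
  labs <- sort(unique(as.character(clusters)))
  if (length(labs) < 2L) stop("need at least two clusters")
  sizes <- table(factor(as.character(clusters), levels = labs))
  if (any(sizes == 0L)) stop("empty cluster")
  # cluster-mean allele frequencies, clusters x markers
  P <- rowsum(scores, group = as.character(clusters), reorder = TRUE) /
    as.vector(sizes)

  pairs <- utils::combn(labs, 2L)
  per_marker <- list()
  out <- data.frame(cluster_a = pairs[1L, ], cluster_b = pairs[2L, ],
                    fst = NA_real_, n_markers = NA_integer_,
                    stringsAsFactors = FALSE)
  M <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ca <- sizes[[a]] / (sizes[[a]] + sizes[[b]])
    cb <- 1 - ca
    pa <- P[a, ]; pb <- P[b, ]
    pbar <- ca * pa + cb * pb
    keep <- pbar > 0 & pbar < 1
    num <- pbar * (1 - pbar) - (ca * pa * (1 - pa) + cb * pb * (1 - pb))
    den <- pbar * (1 - pbar)
    out$fst[j] <- sum(num[keep]) / sum(den[keep])
    out$n_markers[j] <- sum(keep)
    per_marker[[paste(a, b, sep = "|")]] <- ifelse(keep, num / den, NA_real_)
    M[a, b] <- M[b, a] <- out$fst[j]
  }
  structure(out, per_marker = per_marker, matrix = M,
            class = c("fst_result", "data.frame"))
}

#' Write an FST result as a lower-triangle matrix table
#' @param fst an `"fst_result"`.
#' @param path output TSV path.
#' @export
write_fst_matrix <- function(fst, path) {
  M <- attr(fst, "matrix")
  M[upper.tri(M)] <- NA
  out <- data.frame(cluster = rownames(M), signif(M, 6), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
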