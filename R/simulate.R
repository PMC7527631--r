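#' Configuration for the synthetic pooled-accession panel
#'
#' The generator emulates the statistical structure of a pooled-accession
#' association panel: a handful of weakly differentiated subpopulations
#' (pairwise FST of a few percent), a fragmented genome of scaffolds whose
#' within-scaffold marker correlation decays with physical distance toward a
#' long-range floor, pooled genotyping in which every accession is scored as
#' an allele count over `2 * pool_size` haplotypes, and multi-location
#' quantitative traits with planted QTLs, a polygenic background drawn from
#' the realized kinship, and genotype-by-environment interaction.
#'
#' @param n_accessions number of pooled accessions (default 150).
#' @param n_subpops number of subpopulations (default 5).
#' @param fst_target scalar or symmetric matrix of target pairwise FST
#'   values in `[0, 1)` (default 0.04, within the low-differentiation regime
#'   typical of crop panels).
#' @param n_scaffolds,markers_per_scaffold genome shape (default 200 x 25 =
#'   5000 markers).
#' @param scaffold_length_range scaffold lengths in bp, drawn log-uniform
#'   (default 20 kb - 600 kb, a draft-assembly profile).
#' @param ld_decay_bp e-folding distance of the distance-decaying part of
#'   the latent haplotype correlation (default 50 kb).
#' @param ld_floor_r2 long-range floor of the pairwise `r^2` within a
#'   scaffold (default 0.1).
#' @param long_range_fraction fraction of markers whose haplotypes are
#'   copied (with flips) from a marker on another scaffold, creating the
#'   minority of strongly correlated long-range pairs (default 0.02).
#' @param long_range_flip per-haplotype flip probability for those copies
#'   (default 0.05, i.e. copies correlate at roughly `r^2 = 0.8`).
#' @param pool_size diploid individuals pooled per accession (default 8,
#'   hence scores on the `1/16` grid).
#' @param accession_f within-accession homogeneity in `[0, 1)`: the weight
#'   of a latent founder haplotype shared by all haplotypes of an accession.
#'   0 makes accessions random draws from their subpopulation; larger values
#'   make seed lots internally similar and increase the between-accession
#'   variance (default 0.2).
#' @param ancestral_range range of ancestral allele frequencies, uniform
#'   (default 0.05 - 0.95 so marker QC retains most of the panel).
#' @param locations location labels (default the three-trial layout
#'   `"CRA"`, `"FNPC"`, `"VDS"`).
#' @param traits list of trait configurations; each a list with `name`,
#'   `n_qtl`, `qtl_var` (vector of per-QTL fractions of phenotypic
#'   variance), `h2` (broad-sense heritability per location; the polygenic
#'   fraction is `h2 - sum(qtl_var)`), `gxe_cor` (latent correlation of QTL
#'   effects across locations; 1 means identical effects), and optional
#'   `mean`. The default is a single architecture of 5 QTLs at 11%
#'   phenotypic variance each with `h2 = 0.6` and no G-by-E.
#' @param seed RNG seed.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_accessions = 150L,
                       n_subpops = 5L,
                       fst_target = 0.04,
                       n_scaffolds = 200L,
                       markers_per_scaffold = 25L,
                       scaffold_length_range = c(2e4, 6e5),
                       ld_decay_bp = 5e4,
                       ld_floor_r2 = 0.1,
                       long_range_fraction = 0.02,
                       long_range_flip = 0.05,
                       pool_size = 8L,
                       accession_f = 0.2,
                       ancestral_range = c(0.05, 0.95),
                       locations = c("CRA", "FNPC", "VDS"),
                       traits = list(default_trait()),
                       seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_subpops = as.integer(n_subpops),
              fst_target = fst_target,
              n_scaffolds = as.integer(n_scaffolds),
              markers_per_scaffold = as.integer(markers_per_scaffold),
              scaffold_length_range = scaffold_length_range,
              ld_decay_bp = ld_decay_bp,
              ld_floor_r2 = ld_floor_r2,
              long_range_fraction = long_range_fraction,
              long_range_flip = long_range_flip,
              pool_size = as.integer(pool_size),
              accession_f = accession_f,
              ancestral_range = ancestral_range,
              locations = locations,
              traits = traits,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param name,n_qtl,qtl_var,h2,gxe_cor,mean trait architecture fields.
#' @export
default_trait <- function(name = "trait1", n_qtl = 5L,
                          qtl_var = rep(0.11, 5L), h2 = 0.6,
                          gxe_cor = 1, mean = 0) {
  list(name = name, n_qtl = as.integer(n_qtl), qtl_var = qtl_var,
       h2 = h2, gxe_cor = gxe_cor, mean = mean)
}

validate_sim_config <- function(cfg) {
  Fm <- fst_target_matrix(cfg)
  if (any(Fm < 0) || any(Fm >= 1)) {
    stop("target FST values must lie in [0, 1)")
  }
  if (cfg$pool_size < 1L) stop("pool_size must be >= 1")
  if (cfg$accession_f < 0 || cfg$accession_f >= 1) {
    stop("accession_f must lie in [0, 1)")
  }
  if (cfg$ld_floor_r2 < 0 || cfg$ld_floor_r2 >= 1) {
    stop("ld_floor_r2 must lie in [0, 1)")
  }
  for (tr in cfg$traits) {
    if (length(tr$qtl_var) != tr$n_qtl) {
      stop("trait '", tr$name, "': qtl_var must have n_qtl entries")
    }
    if (any(tr$qtl_var < 0) || tr$h2 < 0 || tr$h2 > 1) {
      stop("trait '", tr$name, "': variance fractions must be in [0, 1]")
    }
    if (sum(tr$qtl_var) > tr$h2 + 1e-9) {
      stop("trait '", tr$name,
           "': per-QTL variance fractions exceed the heritability")
    }
    if (tr$gxe_cor < 0 || tr$gxe_cor > 1) {
      stop("trait '", tr$name, "': gxe_cor must lie in [0, 1]")
    }
  }
  structure(cfg, class = c("sim_config", "list"))
}

fst_target_matrix <- function(cfg) {
  k <- cfg$n_subpops
  t <- cfg$fst_target
  if (is.matrix(t)) {
    stopifnot(nrow(t) == k, ncol(t) == k)
    Fm <- (t + t(t)) / 2
  } else {
    Fm <- matrix(t, k, k)
  }
  diag(Fm) <- 0
  Fm
}

# per-subpopulation Balding-Nichols F parameters hitting the pairwise
# targets in expectation: FST_ij ~ a / (1 - a) with a = (F_i + F_j) / 4,
# solved in least squares over all pairs
subpop_bn_f <- function(cfg) {
  k <- cfg$n_subpops
  Fm <- fst_target_matrix(cfg)
  if (k == 1L) return(0)
  pairs <- utils::combn(k, 2L)
  a <- Fm[t(pairs)] / (1 + Fm[t(pairs)])
  A <- matrix(0, ncol(pairs), k)
  A[cbind(seq_len(ncol(pairs)), pairs[1L, ])] <- 1
  A[cbind(seq_len(ncol(pairs)), pairs[2L, ])] <- 1
  f <- qr.solve(A, 4 * a)
  pmin(pmax(f, 0), 0.999)
}

#' Subpopulation allele frequencies under a Balding-Nichols model
#'
#' Ancestral frequencies are uniform on `ancestral_range`; each
#' subpopulation then draws its frequency from
#' `Beta(p (1 - F_i) / F_i, (1 - p)(1 - F_i) / F_i)`, with the
#' per-subpopulation drift parameters `F_i` solved so that the pairwise
#' FST targets are met in expectation. A target of exactly zero reduces to
#' all subpopulations sharing the ancestral frequency.
#'
#' @param cfg a `"sim_config"`.
#' @param n_markers number of markers (defaults to the configured genome).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `ancestral` (length-M vector), `freq`
#'   (subpopulations x markers matrix) and `bn_f` (per-subpopulation drift).
#' @export
simulate_subpop_frequencies <- function(cfg, n_markers = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_markers)) {
    n_markers <- cfg$n_scaffolds * cfg$markers_per_scaffold
  }
  p <- stats::runif(n_markers, cfg$ancestral_range[1L], cfg$ancestral_range[2L])
  f <- subpop_bn_f(cfg)
  freq <- matrix(NA_real_, cfg$n_subpops, n_markers)
  for (i in seq_len(cfg$n_subpops)) {
    if (f[i] < 1e-9) {
      freq[i, ] <- p
    } else {
      shape_scale <- (1 - f[i]) / f[i]
      freq[i, ] <- stats::rbeta(n_markers, p * shape_scale,
                                (1 - p) * shape_scale)
    }
  }
  # keep frequencies polymorphic so thresholds stay finite
  freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  list(ancestral = p, freq = freq, bn_f = f)
}

#' Wright's FST between subpopulations from a frequency matrix
#'
#' Direct multi-marker evaluation (ratio of summed numerators to summed
#' denominators) of the same formula used by [pairwise_fst()], applied to
#' known subpopulation frequencies with equal weights. Used to verify that
#' the generator hits its differentiation targets.
#'
#' @param freq subpopulations-by-markers frequency matrix.
#' @return symmetric matrix of pairwise FST values.
#' @export
fst_from_frequencies <- function(freq) {
  k <- nrow(freq)
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      pbar <- (freq[i, ] + freq[j, ]) / 2
      keep <- pbar > 0 & pbar < 1
      num <- pbar * (1 - pbar) -
        (freq[i, ] * (1 - freq[i, ]) + freq[j, ] * (1 - freq[j, ])) / 2
      den <- pbar * (1 - pbar)
      M[i, j] <- M[j, i] <- sum(num[keep]) / sum(den[keep])
    }
  }
  M
}

simulate_marker_map <- function(cfg) {
  lr <- log(cfg$scaffold_length_range)
  lengths <- round(exp(stats::runif(cfg$n_scaffolds, lr[1L], lr[2L])))
  scaffold <- sprintf("scaffold%d", seq_len(cfg$n_scaffolds))
  meta <- do.call(rbind, lapply(seq_len(cfg$n_scaffolds), function(s) {
    pos <- sort(sample.int(lengths[s], cfg$markers_per_scaffold))
    data.frame(scaffold = scaffold[s], position = pos,
               stringsAsFactors = FALSE)
  }))
  meta$marker_id <- paste0(meta$scaffold, "_", meta$position)
  alleles <- t(vapply(seq_len(nrow(meta)),
                      function(i) sample(NUCLEOTIDES, 2L),
                      character(2)))
  meta$major_allele <- alleles[, 1L]
  meta$minor_allele <- alleles[, 2L]
  index <- data.frame(scaffold = scaffold, length_bp = lengths,
                      stringsAsFactors = FALSE)
  list(meta = meta[, c("marker_id", "scaffold", "position",
                       "major_allele", "minor_allele")],
       index = index)
}

# correlation of two Bernoulli indicators obtained by thresholding a
# bivariate standard normal with latent correlation rho at frequencies p1, p2
binary_threshold_cor <- function(rho, p1, p2) {
  if (rho <= 0) return(0)
  t1 <- stats::qnorm(p1)
  t2 <- stats::qnorm(p2)
  p11 <- stats::integrate(function(z) {
    stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  }, -Inf, t1, rel.tol = 1e-9)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# latent weight of the scaffold-wide component producing an allele-level
# r^2 floor of `floor_r2`: solves, by quadrature over the ancestral
# frequency distribution, for the latent correlation whose median
# thresholded r^2 across frequency pairs equals the target
latent_floor_weight <- function(floor_r2, ancestral_range = c(0.05, 0.95)) {
  if (floor_r2 <= 0) return(0)
  probs <- seq(0.1, 0.9, length.out = 5L)
  p_grid <- ancestral_range[1L] + probs * diff(ancestral_range)
  pairs <- expand.grid(p1 = p_grid, p2 = p_grid)
  med_r2 <- function(rho) {
    stats::median(mapply(binary_threshold_cor, rho,
                         pairs$p1, pairs$p2)^2)
  }
  stats::uniroot(function(rho) med_r2(rho) - floor_r2,
                 interval = c(1e-4, 0.995), tol = 1e-4)$root
}

#' Pooled accession genotypes with within-scaffold LD
#'
#' For every scaffold, `2 * pool_size` haplotypes per accession (plus one
#' latent founder path per accession, weighted by `accession_f`) are
#' generated from a Gaussian copula whose correlation between two markers at
#' distance `d` is `(1 - c) * exp(-d / ld_decay_bp) + c`, with `c` chosen so
#' the allele-level `r^2` floors at `ld_floor_r2`. Alleles are obtained by
#' thresholding at the subpopulation frequency, and the accession score is
#' the fraction of its haplotypes carrying the tracked allele - hence scores
#' lie exactly on the `1 / (2 * pool_size)` grid. A configured minority of
#' markers has its haplotypes copied (with random flips) from a marker on a
#' different scaffold, planting strong long-range correlations. Finally,
#' each column is polarized so the tracked allele is the panel-wide major
#' one.
#'
#' @param subpop result of [simulate_subpop_frequencies()].
#' @param cfg a `"sim_config"`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `scores` (accessions x markers, on the allele-count
#'   grid), `meta`, `scaffold_index`, `assignment` (accession subpop),
#'   `long_range_pairs` (data.frame `target`, `source`).
#' @export
simulate_pooled_genotypes <- function(subpop, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- simulate_marker_map(cfg)
  meta <- map$meta
  M <- nrow(meta)
  n <- cfg$n_accessions
  H <- 2L * cfg$pool_size
  assignment <- rep(seq_len(cfg$n_subpops), length.out = n)
  acc <- sprintf("acc%03d", seq_len(n))

  # choose long-range duplications up front (targets get copied haplotypes)
  n_lr <- round(cfg$long_range_fraction * M)
  lr_pairs <- NULL
  if (n_lr > 0L) {
    target <- sample.int(M, n_lr)
    source <- vapply(target, function(t) {
      off <- which(meta$scaffold != meta$scaffold[t])
      off[sample.int(length(off), 1L)]
    }, integer(1))
    lr_pairs <- data.frame(target = target, source = source)
  }
  need_alleles <- unique(lr_pairs$source)

  c_floor <- latent_floor_weight(cfg$ld_floor_r2, cfg$ancestral_range)
  fa <- cfg$accession_f
  n_paths <- n * (H + 1L)  # H haplotypes + 1 founder path per accession
  hap_of_acc <- rep(seq_len(n), each = H)
  hap_rows <- as.vector(vapply(seq_len(n), function(a) {
    (a - 1L) * (H + 1L) + seq_len(H)
  }, integer(H)))
  founder_rows <- rep((seq_len(n) - 1L) * (H + 1L) + H + 1L, each = H)

  scores <- matrix(NA_real_, n, M, dimnames = list(acc, meta$marker_id))
  allele_cache <- list()

  for (sc in unique(meta$scaffold)) {
    idx <- which(meta$scaffold == sc)
    m_s <- length(idx)
    pos <- meta$position[idx]
    phi <- exp(-diff(pos) / cfg$ld_decay_bp)

    Z <- matrix(NA_real_, n_paths, m_s)
    Z[, 1L] <- stats::rnorm(n_paths)
    if (m_s > 1L) {
      for (k in 2L:m_s) {
        Z[, k] <- phi[k - 1L] * Z[, k - 1L] +
          sqrt(1 - phi[k - 1L]^2) * stats::rnorm(n_paths)
      }
    }
    U <- stats::rnorm(n_paths)  # scaffold-wide component per path
    Z <- sqrt(1 - c_floor) * Z + sqrt(c_floor) * U
    # blend each haplotype with its accession's founder path
    Zh <- sqrt(1 - fa) * Z[hap_rows, , drop = FALSE] +
      sqrt(fa) * Z[founder_rows, , drop = FALSE]

    thr <- stats::qnorm(subpop$freq[, idx, drop = FALSE])  # subpop x m_s
    thr_h <- thr[assignment[hap_of_acc], , drop = FALSE]
    alleles <- Zh < thr_h  # haplotype carries the tracked allele
    grp <- factor(hap_of_acc, levels = seq_len(n))
    scores[, idx] <- rowsum(alleles + 0, grp, reorder = TRUE) / H
    keep <- idx %in% need_alleles
    if (any(keep)) {
      for (j in idx[keep]) {
        allele_cache[[as.character(j)]] <- alleles[, match(j, idx)]
      }
    }
  }

  if (!is.null(lr_pairs)) {
    for (r in seq_len(nrow(lr_pairs))) {
      src <- allele_cache[[as.character(lr_pairs$source[r])]]
      flip <- stats::runif(length(src)) < cfg$long_range_flip
      dup <- xor(src, flip)
      scores[, lr_pairs$target[r]] <-
        rowsum(dup + 0, factor(hap_of_acc, levels = seq_len(cfg$n_accessions)),
               reorder = TRUE)[, 1L] / H
    }
  }

  # polarize every column to the panel-wide major allele (lexicographic on
  # an exact tie, matching the scoring convention of marker QC)
  mu <- colMeans(scores)
  flip_col <- mu < 0.5 | (mu == 0.5 & meta$minor_allele < meta$major_allele)
  scores[, flip_col] <- 1 - scores[, flip_col]
  swap <- meta$major_allele[flip_col]
  meta$major_allele[flip_col] <- meta$minor_allele[flip_col]
  meta$minor_allele[flip_col] <- swap

  list(scores = scores, meta = meta, scaffold_index = map$index,
       assignment = stats::setNames(assignment, acc),
       long_range_pairs = if (is.null(lr_pairs)) {
         data.frame(target = integer(0), source = integer(0))
       } else {
         data.frame(target = meta$marker_id[lr_pairs$target],
                    source = meta$marker_id[lr_pairs$source],
                    stringsAsFactors = FALSE)
       })
}

#' Multi-location phenotypes with planted QTLs and ground truth
#'
#' For each configured trait, causal markers are drawn from the QC-eligible
#' part of the panel (panel minor-allele frequency at least 2%, score SD at
#' least 0.1) under the constraint of mutual non-collinearity
#' (`|r| < 0.3`). Per location, each QTL contributes an effect scaled so it
#' explains exactly its configured fraction of the phenotypic variance; the
#' polygenic background (fraction `h2 - sum(qtl_var)`) is drawn with
#' covariance proportional to the realized kinship of the simulated panel,
#' and the residual is scaled so the realized per-location broad-sense
#' heritability equals `h2`. Genotype-by-environment interaction is
#' controlled by `gxe_cor`, the latent correlation of per-location QTL
#' effect directions (and of the polygenic draws): at 1, genetic effects
#' are identical across locations.
#'
#' @param geno result of [simulate_pooled_genotypes()] (or any list with
#'   `scores` and `meta`).
#' @param cfg a `"sim_config"`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return list with `phenotypes` (long data.frame: `accession`, `trait`,
#'   `location`, `value`) and `truth` (class `"truth_table"`): per trait a
#'   list with `causal` (data.frame `marker_id` and per-location effect
#'   columns), `qtl_var`, `polygenic_var`, `h2`, `gxe_cor`, `components`
#'   (realized variance components per location), and `collinear_members`
#'   (markers at `|r| >= 0.3` with each causal marker).
#' @export
simulate_phenotypes <- function(geno, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores <- geno$scores
  n <- nrow(scores)
  locs <- cfg$locations

  p_col <- colMeans(scores)
  sd_col <- apply(scores, 2L, stats::sd)
  eligible <- which(pmin(p_col, 1 - p_col) >= 0.02 & sd_col >= 0.1)

  K <- vanraden_kinship(scores)
  L <- chol(unclass(K) + diag(1e-6, n))

  pheno <- list()
  truth <- list()
  for (tr in cfg$traits) {
    causal <- select_noncollinear(scores, eligible, tr$n_qtl)
    Xc <- scores[, causal, drop = FALSE]
    sdc <- apply(Xc, 2L, stats::sd)

    # latent effect directions, correlated across locations at gxe_cor
    g0 <- stats::rnorm(tr$n_qtl)
    eff <- matrix(NA_real_, tr$n_qtl, length(locs),
                  dimnames = list(causal, locs))
    for (l in seq_along(locs)) {
      u <- sqrt(tr$gxe_cor) * g0 +
        sqrt(1 - tr$gxe_cor) * stats::rnorm(tr$n_qtl)
      s <- ifelse(u >= 0, 1, -1)
      eff[, l] <- s * sqrt(tr$qtl_var) / sdc
    }

    v_poly <- max(tr$h2 - sum(tr$qtl_var), 0)
    xi0 <- stats::rnorm(n)
    vals <- matrix(NA_real_, n, length(locs))
    comp <- data.frame(location = locs, var_qtl = NA_real_,
                       var_polygenic = NA_real_, var_genetic = NA_real_,
                       var_total = NA_real_, h2_realized = NA_real_)
    for (l in seq_along(locs)) {
      qtl_part <- drop(Xc %*% eff[, l])
      if (v_poly > 0) {
        xi <- sqrt(tr$gxe_cor) * xi0 + sqrt(1 - tr$gxe_cor) * stats::rnorm(n)
        g <- drop(crossprod(L, xi))
        g <- g / stats::sd(g) * sqrt(v_poly)
      } else {
        g <- numeric(n)
      }
      genetic <- qtl_part + g
      var_g <- stats::var(genetic)
      # residual orthogonal to the genetic component and standardized, so
      # the realized per-location heritability equals the target exactly
      e <- stats::rnorm(n)
      e <- e - mean(e)
      gc <- genetic - mean(genetic)
      if (sum(gc^2) > 0) e <- e - gc * sum(e * gc) / sum(gc^2)
      e <- e / stats::sd(e)
      noise_sd <- if (tr$h2 > 0) sqrt(var_g * (1 - tr$h2) / tr$h2) else 1
      vals[, l] <- tr$mean + genetic + noise_sd * e
      comp$var_qtl[l] <- stats::var(qtl_part)
      comp$var_polygenic[l] <- stats::var(g)
      comp$var_genetic[l] <- var_g
      comp$var_total[l] <- stats::var(vals[, l])
      comp$h2_realized[l] <- var_g / stats::var(vals[, l])
    }
    pheno[[tr$name]] <- data.frame(
      accession = rep(rownames(scores), times = length(locs)),
      trait = tr$name,
      location = rep(locs, each = n),
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )

    Cc <- abs(stats::cor(scores, Xc))
    members <- lapply(seq_along(causal), function(q) {
      colnames(scores)[Cc[, q] >= 0.3]
    })
    names(members) <- causal
    truth[[tr$name]] <- list(
      causal = data.frame(marker_id = causal, eff,
                          stringsAsFactors = FALSE, row.names = NULL),
      qtl_var = tr$qtl_var,
      polygenic_var = v_poly,
      h2 = tr$h2,
      gxe_cor = tr$gxe_cor,
      components = comp,
      collinear_members = members
    )
  }
  list(phenotypes = do.call(rbind, unname(pheno)),
       truth = structure(truth, class = "truth_table"))
}

select_noncollinear <- function(scores, eligible, n_qtl, r_max = 0.3,
                                max_tries = 2000L) {
  if (length(eligible) < n_qtl) stop("not enough QC-eligible markers")
  chosen <- integer(0)
  tries <- 0L
  pool <- sample(eligible)
  i <- 1L
  while (length(chosen) < n_qtl && tries < max_tries) {
    if (i > length(pool)) {
      pool <- sample(eligible)
      i <- 1L
    }
    cand <- pool[i]
    i <- i + 1L
    tries <- tries + 1L
    if (cand %in% chosen) next
    if (length(chosen) == 0L ||
        all(abs(stats::cor(scores[, chosen, drop = FALSE],
                           scores[, cand])) < r_max)) {
      chosen <- c(chosen, cand)
    }
  }
  if (length(chosen) < n_qtl) {
    stop("could not place ", n_qtl, " mutually non-collinear QTLs")
  }
  colnames(scores)[chosen]
}

#' Simulate a complete panel: genotypes, phenotypes and truth
#'
#' Convenience wrapper seeding the RNG once and chaining
#' [simulate_subpop_frequencies()], [simulate_pooled_genotypes()] and
#' [simulate_phenotypes()].
#'
#' @param cfg a `"sim_config"`.
#' @return list with `scores`, `meta`, `scaffold_index`, `assignment`,
#'   `subpop` (frequency draw), `long_range_pairs`, `phenotypes`, `truth`,
#'   `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  subpop <- simulate_subpop_frequencies(cfg)
  geno <- simulate_pooled_genotypes(subpop, cfg)
  ph <- simulate_phenotypes(geno, cfg)
  c(geno, list(subpop = subpop, phenotypes = ph$phenotypes,
               truth = ph$truth, config = cfg))
}

#' Score QTL recovery of MultiQTL models against the planted truth
#'
#' A detected QTL counts as a true positive if its representative or any
#' member marker is collinear (`|r| >= r_threshold`) with a causal marker of
#' the trait. Power is the fraction of planted QTLs recovered - when models
#' from several locations are supplied, a planted QTL counts as recovered if
#' any location's model detects it. The false-discovery proportion pools
#' detections over the supplied models; with zero detections it is
#' undefined and reported as `NA` alongside `n_detected = 0`.
#'
#' @param models a `"multiqtl_model"` or list of them (e.g. one per
#'   location) for a single trait.
#' @param truth a `"truth_table"` entry or the table itself (then `trait`
#'   selects the entry).
#' @param scores accession-by-marker score matrix of the same panel.
#' @param r_threshold collinearity threshold (default 0.3).
#' @param trait trait name when `truth` is a full table.
#' @return list with `power`, `fdp`, `n_causal`, `n_recovered`,
#'   `n_detected`, `n_true_detections`, `recovered` (named logical per
#'   causal marker).
#' @export
score_recovery <- function(models, truth, scores, r_threshold = 0.3,
                           trait = NULL) {
  if (inherits(models, "multiqtl_model")) models <- list(models)
  if (inherits(truth, "truth_table")) {
    if (is.null(trait)) trait <- models[[1L]]$trait
    truth <- truth[[trait]]
  }
  causal <- truth$causal$marker_id
  Cc <- abs(stats::cor(scores, scores[, causal, drop = FALSE]))
  recovered <- stats::setNames(rep(FALSE, length(causal)), causal)
  n_detected <- 0L
  n_true <- 0L
  for (m in models) {
    for (q in m$qtls) {
      n_detected <- n_detected + 1L
      grp <- union(q$representative, q$members)
      hit <- Cc[grp, , drop = FALSE] >= r_threshold
      if (any(hit)) {
        n_true <- n_true + 1L
        recovered[colSums(hit) > 0] <- TRUE
      }
    }
  }
  list(power = mean(recovered),
       fdp = if (n_detected > 0L) (n_detected - n_true) / n_detected
             else NA_real_,
       n_causal = length(causal),
       n_recovered = sum(recovered),
       n_detected = n_detected,
       n_true_detections = n_true,
       recovered = recovered)
}
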