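#' Run the full analysis pipeline
#'
#' Chains the pipeline stages on either a simulated panel (when the
#' configuration has a `sim` block) or on-disk inputs (`score_matrix` +
#' `marker_meta` + `phenotypes`, optionally `scaffold_index`): marker QC,
#' kinship, structure (PCoA, dendrogram, cluster FST), within-scaffold LD
#' profiling with baseline calibration, per trait-location mixed-model
#' scans, MultiQTL forward selection, and cross-location region matching.
#' Every stage writes its table under `out_dir` and appends a log line with
#' parameter provenance; outputs are deterministic given the configuration
#' and seed.
#'
#' @param config a `"run_config"` (see [load_run_config()]) or path to one.
#' @param stages subset of stages to run, in pipeline order. Subsequent
#'   stages read the outputs of earlier ones from `out_dir`, so stages can
#'   be re-run standalone.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "kinship", "structure",
                                    "ld", "gwas", "multiqtl", "crossloc")) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "pipeline.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  th <- config$thresholds
  set.seed(config$seed)
  res <- list(config = config)

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages && length(config$sim) > 0) {
    run_stage("simulate", function() {
      sim_args <- config$sim
      sim_args$seed <- config$seed
      cfg <- do.call(sim_config, sim_args)
      panel <- simulate_panel(cfg)
      write_score_matrix(panel$scores, file.path(out, "scores_raw.tsv"))
      write_marker_meta(panel$meta, file.path(out, "marker_meta.tsv"))
      write_scaffold_index(panel$scaffold_index,
                           file.path(out, "scaffold_index.tsv"))
      write_phenotypes(panel$phenotypes, file.path(out, "phenotypes.csv"))
      jsonlite::write_json(lapply(panel$truth, function(t) {
        t$collinear_members <- NULL  # bulky; regenerable from the scores
        t
      }), file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
      log_line("simulate", sprintf("seed=%d accessions=%d markers=%d",
                                   config$seed, nrow(panel$scores),
                                   ncol(panel$scores)))
      res$panel <<- panel
    })
  }

  read_inputs <- function() {
    if (!is.null(res$panel)) {
      list(scores = res$panel$scores, meta = res$panel$meta,
           index = res$panel$scaffold_index,
           phenotypes = res$panel$phenotypes)
    } else {
      list(
        scores = read_score_matrix(config$score_matrix %||%
                                     file.path(out, "scores_raw.tsv")),
        meta = read_marker_meta(config$marker_meta %||%
                                  file.path(out, "marker_meta.tsv")),
        index = read_scaffold_index(config$scaffold_index %||%
                                      file.path(out, "scaffold_index.tsv")),
        phenotypes = read_phenotypes(config$phenotypes %||%
                                       file.path(out, "phenotypes.csv"))
      )
    }
  }

  if ("qc" %in% stages) {
    run_stage("qc", function() {
      inp <- read_inputs()
      panel <- qc_score_matrix(inp$scores, inp$meta, thresholds = th)
      summ <- qc_summary(panel, inp$index,
                         genome_size_bp = config$genome_size_bp)
      write_score_matrix(panel$scores, file.path(out, "scores_qc.tsv"))
      write_marker_meta(panel$meta, file.path(out, "marker_meta_qc.tsv"))
      write_tsv(panel$rejections, file.path(out, "qc_rejections.tsv"))
      jsonlite::write_json(summ[c("n_markers", "n_scaffolds", "covered_bp",
                                  "genome_fraction")],
                           file.path(out, "qc_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("qc", sprintf("kept=%d rejected=%d (maf=%d sd=%d)",
                             ncol(panel$scores), nrow(panel$rejections),
                             panel$rule_counts[["maf"]],
                             panel$rule_counts[["sd"]]))
      res$qc <<- panel
    })
  }

  qc_scores <- function() {
    if (!is.null(res$qc)) res$qc$scores
    else read_score_matrix(file.path(out, "scores_qc.tsv"))
  }
  qc_meta <- function() {
    if (!is.null(res$qc)) res$qc$meta
    else read_marker_meta(file.path(out, "marker_meta_qc.tsv"))
  }

  if ("kinship" %in% stages) {
    run_stage("kinship", function() {
      K <- vanraden_kinship(qc_scores())
      write_kinship(K, file.path(out, "kinship.tsv"))
      log_line("kinship", sprintf("method=vanraden_freq markers=%d",
                                  ncol(qc_scores())))
      res$kinship <<- K
    })
  }

  get_K <- function() {
    if (!is.null(res$kinship)) res$kinship
    else read_kinship(file.path(out, "kinship.tsv"))
  }

  if ("structure" %in% stages) {
    run_stage("structure", function() {
      K <- get_K()
      pc <- pcoa_kinship(K, n_axes = min(10L, nrow(K) - 1L))
      coords <- data.frame(accession = rownames(K), pc$coords,
                           check.names = FALSE)
      write_tsv(coords, file.path(out, "pcoa.tsv"))
      dend <- kinship_dendrogram(K, k = config$n_clusters)
      write_newick(dend$hclust, file.path(out, "dendrogram.nwk"))
      fst <- pairwise_fst(qc_scores(), dend$clusters)
      write_fst_matrix(fst, file.path(out, "fst.tsv"))
      log_line("structure", sprintf(
        "k=%d pco1_pct=%.2f fst_range=[%.4f, %.4f]",
        config$n_clusters, pc$percent_variance[1L],
        min(fst$fst), max(fst$fst)))
      res$structure <<- list(pcoa = pc, dendrogram = dend, fst = fst)
    })
  }

  if ("ld" %in% stages) {
    run_stage("ld", function() {
      inp_index <- if (!is.null(res$panel)) res$panel$scaffold_index
        else read_scaffold_index(file.path(out, "scaffold_index.tsv"))
      prof <- scaffold_ld_profile(qc_scores(), qc_meta(),
                                  scaffold_index = inp_index)
      base <- estimate_baseline_r2(prof, floor_r2 = th$r_collinear^2)
      write_tsv(ld_pairs_table(prof), file.path(out, "ld_pairs.tsv"))
      write_tsv(ld_decay_summary(prof), file.path(out, "ld_decay.tsv"))
      jsonlite::write_json(base[c("baseline_r2", "threshold_r2",
                                  "threshold_r")],
                           file.path(out, "ld_baseline.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("ld", sprintf("scaffolds=%d baseline_r2=%.4f",
                             length(prof), base$baseline_r2))
      res$ld <<- list(profiles = prof, baseline = base)
    })
  }

  if (any(c("gwas", "multiqtl", "crossloc") %in% stages)) {
    inp <- read_inputs()
    scores <- qc_scores()
    meta <- qc_meta()
    K <- get_K()
    pheno <- inp$phenotypes
    meff <- effective_tests(scores, meta, blocks = "scaffold")
    thr <- significance_threshold(alpha = th$alpha, m_eff = meff)
    combos <- unique(pheno[, c("trait", "location")])

    if ("gwas" %in% stages) {
      run_stage("gwas", function() {
        scans <- list()
        for (i in seq_len(nrow(combos))) {
          tr <- combos$trait[i]; lc <- combos$location[i]
          y <- aligned_phenotype(pheno, tr, lc, rownames(scores))
          fit <- fit_null_lmm(y$values, K[y$accessions, y$accessions])
          scan <- scan_markers(scores[y$accessions, , drop = FALSE],
                               y$values, fit, meta = meta, threshold = thr)
          tag <- paste(tr, lc, sep = "_")
          write_tsv(as.data.frame(scan),
                    file.path(out, sprintf("scan_%s.tsv", tag)))
          jsonlite::write_json(
            list(trait = tr, location = lc,
                 sigma2_g = attr(scan, "sigma2_g"),
                 sigma2_e = attr(scan, "sigma2_e"),
                 m_eff = thr$m_eff, alpha = thr$alpha,
                 threshold_neglog10p = thr$neglog10p),
            file.path(out, sprintf("scan_%s.json", tag)),
            auto_unbox = TRUE, digits = NA)
          scans[[tag]] <- scan
          log_line("gwas", sprintf("%s hits=%d m_eff=%.1f", tag,
                                   sum(scan$pass_threshold), thr$m_eff))
        }
        res$scans <<- scans
        res$threshold <<- thr
      })
    }

    load_scan <- function(tag) {
      if (!is.null(res$scans[[tag]])) return(res$scans[[tag]])
      scan <- utils::read.delim(file.path(out, sprintf("scan_%s.tsv", tag)),
                                stringsAsFactors = FALSE)
      side <- jsonlite::read_json(file.path(out, sprintf("scan_%s.json", tag)),
                                  simplifyVector = TRUE)
      structure(scan, threshold = side$threshold_neglog10p,
                class = c("association_scan", "data.frame"))
    }

    if ("multiqtl" %in% stages) {
      run_stage("multiqtl", function() {
        models <- list()
        for (i in seq_len(nrow(combos))) {
          tr <- combos$trait[i]; lc <- combos$location[i]
          tag <- paste(tr, lc, sep = "_")
          scan <- load_scan(tag)
          y <- aligned_phenotype(pheno, tr, lc, rownames(scores))
          models[[tag]] <- forward_select(
            scan, scores[y$accessions, , drop = FALSE], y$values,
            r_collinear = th$r_collinear, threshold = thr,
            trait = tr, location = lc)
          log_line("multiqtl", sprintf("%s qtls=%d expl_var=%.3f", tag,
                                       models[[tag]]$n_qtl,
                                       models[[tag]]$expl_var))
        }
        write_multiqtl_json(models, file.path(out, "multiqtl_models.json"))
        res$models <<- models
      })
    }

    if ("crossloc" %in% stages) {
      run_stage("crossloc", function() {
        if (is.null(res$models)) {
          raw <- jsonlite::read_json(file.path(out, "multiqtl_models.json"))
          res$models <<- lapply(raw, function(m) {
            structure(list(
              trait = m$trait, location = m$location,
              qtls = lapply(m$qtls, function(q) {
                list(representative = q$representative,
                     members = unlist(q$members))
              }),
              n_qtl = m$n_qtl, expl_var = m$expl_var
            ), class = "multiqtl_model")
          })
        }
        region_sets <- list()
        for (tr in unique(combos$trait)) {
          models_tr <- Filter(function(m) m$trait == tr, res$models)
          if (length(models_tr) < 2L) next
          region_sets[[tr]] <- match_regions(models_tr, scores,
                                             r_collinear = th$r_collinear)
          write_regions(region_sets[[tr]],
                        json_path = file.path(out,
                                              sprintf("regions_%s.json", tr)),
                        tsv_path = file.path(out,
                                             sprintf("regions_%s.tsv", tr)))
          log_line("crossloc", sprintf("%s regions=%d", tr,
                                       nrow(region_sets[[tr]]$regions)))
        }
        if (length(region_sets) >= 2L) {
          overlap <- cross_trait_overlap(region_sets)
          write_tsv(overlap, file.path(out, "cross_trait_overlap.tsv"))
          res$overlap <<- overlap
        }
        res$regions <<- region_sets
      })
    }
  }
  invisible(res)
}

# phenotype vector for one trait x location, aligned to the accession order
# of the score matrix; missing cells dropped pairwise
aligned_phenotype <- function(pheno, trait, location, accessions) {
  sub <- pheno[pheno$trait == trait & pheno$location == location, ]
  sub <- sub[sub$accession %in% accessions & is.finite(sub$value), ]
  sub <- sub[match(intersect(accessions, sub$accession), sub$accession), ]
  list(accessions = sub$accession, values = sub$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
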