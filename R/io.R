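#' @keywords internal
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Read a per-accession nucleotide frequency table
#'
#' The canonical on-disk layout is a long, tab-separated table with one row
#' per (marker, accession) call and columns `marker_id`, `scaffold`,
#' `position`, `accession`, `A`, `C`, `G`, `T`. The four nucleotide columns
#' hold the within-accession allele frequencies (proportions in `[0, 1]`)
#' observed in the pooled sample. Accessions without a call at a marker are
#' simply absent (or carry `NA` frequencies); call rate is accounted for
#' during marker QC.
#'
#' Rows whose four frequencies do not sum to 1 within `sum_tol` are kept but
#' flagged; the flagged subset is attached as attribute `"flagged"` so that a
#' validation report can be written alongside downstream outputs.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param sum_tol Tolerance on `|A + C + G + T - 1|` before a row is flagged.
#' @return A `data.frame` of class `"freq_table"` with attribute `"flagged"`
#'   (a data.frame of offending rows, possibly empty).
#' @export
read_frequency_table <- function(path, sum_tol = 0.01) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_freq_table(tab, sum_tol = sum_tol)
}

#' Validate an in-memory frequency table
#'
#' @param tab data.frame in the long layout of [read_frequency_table()].
#' @param sum_tol tolerance for the frequency-sum invariant.
#' @return the validated table with class `"freq_table"`.
#' @export
as_freq_table <- function(tab, sum_tol = 0.01) {
  required <- c("marker_id", "scaffold", "position", "accession", NUCLEOTIDES)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("frequency table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  freqs <- as.matrix(tab[, NUCLEOTIDES])
  if (any(freqs < 0, na.rm = TRUE)) {
    stop("negative nucleotide frequency encountered")
  }
  if (any(freqs > 1 + 1e-9, na.rm = TRUE)) {
    stop("nucleotide frequency above 1 encountered")
  }
  if (any(tab$position < 1, na.rm = TRUE)) {
    stop("marker positions must be >= 1 (1-based coordinates)")
  }
  sums <- rowSums(freqs)
  bad <- which(is.finite(sums) & abs(sums - 1) > sum_tol)
  flagged <- tab[bad, , drop = FALSE]
  structure(tab, flagged = flagged, class = c("freq_table", "data.frame"))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Nucleotide frequency table: %d calls, %d markers, %d accessions (%d flagged rows)\n",
              nrow(x), length(unique(x$marker_id)),
              length(unique(x$accession)), nrow(attr(x, "flagged"))))
  invisible(x)
}

#' Write a frequency table to disk
#' @param tab a `freq_table`.
#' @param path output path (TSV).
#' @export
write_frequency_table <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
}

#' Read a scaffold-length index
#'
#' Accepts either a two-column `scaffold<TAB>length_bp` table or a standard
#' five-column FAI index, in which case only the first two columns are used.
#'
#' @param path path to the index file (no header).
#' @return data.frame with columns `scaffold`, `length_bp`.
#' @export
read_scaffold_index <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  idx <- data.frame(scaffold = as.character(tab[[1]]),
                    length_bp = as.integer(tab[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(idx$scaffold)) stop("duplicate scaffold names in index")
  if (any(idx$length_bp <= 0)) stop("scaffold lengths must be positive")
  idx
}

#' @rdname read_scaffold_index
#' @param index data.frame with columns `scaffold`, `length_bp`.
#' @export
write_scaffold_index <- function(index, path) {
  utils::write.table(index[, c("scaffold", "length_bp")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read / write an accession-by-marker score matrix
#'
#' Scores are major-allele proportions in `[0, 1]`. On disk the matrix is a
#' TSV with accessions in rows; the first column is named `accession` and the
#' remaining columns are marker ids. Marker metadata (scaffold, position,
#' major/minor allele) travels in a separate TSV, see [write_marker_meta()].
#'
#' @param path path to the TSV.
#' @return numeric matrix with accession rownames and marker colnames.
#' @export
read_score_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "accession") stop("first column must be 'accession'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$accession
  storage.mode(m) <- "double"
  m
}

#' @rdname read_score_matrix
#' @param scores accession-by-marker numeric matrix.
#' @export
write_score_matrix <- function(scores, path) {
  out <- data.frame(accession = rownames(scores),
                    signif(scores, 6), check.names = FALSE)
  write_tsv(out, path)
}

#' Read / write marker metadata
#'
#' Columns: `marker_id` (scaffoldNAME_POS convention), `scaffold`, `position`
#' (1-based bp), `major_allele`, `minor_allele`.
#' @param path path to the TSV.
#' @export
read_marker_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_marker_meta(meta)
  meta
}

#' @rdname read_marker_meta
#' @param meta marker metadata data.frame.
#' @export
write_marker_meta <- function(meta, path) {
  write_tsv(meta, path)
}

validate_marker_meta <- function(meta) {
  required <- c("marker_id", "scaffold", "position")
  if (!all(required %in% names(meta))) {
    stop("marker metadata needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(meta$marker_id)) stop("marker ids must be unique panel-wide")
  if (any(meta$position < 1)) stop("positions are 1-based and must be >= 1")
  invisible(meta)
}

#' Read / write a phenotype table
#'
#' Long format, comma-separated: `accession`, `trait`, `location`, `value`.
#' One value per (accession, trait, location); missing cells are simply
#' absent and are dropped pairwise per trait-location analysis.
#' @param path path to the CSV.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("accession", "trait", "location", "value")
  if (!all(required %in% names(tab))) {
    stop("phenotype table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(!is.finite(tab$value))) stop("non-finite phenotype values")
  key <- paste(tab$accession, tab$trait, tab$location, sep = "\r")
  if (anyDuplicated(key)) stop("more than one value per (accession, trait, location)")
  tab
}

#' @rdname read_phenotypes
#' @param tab phenotype data.frame.
#' @export
write_phenotypes <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
}

#' Read / write a square labelled kinship matrix
#' @param path path to the TSV.
#' @export
read_kinship <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_kinship
#' @param K square kinship matrix with dimnames.
#' @export
write_kinship <- function(K, path) {
  out <- data.frame(accession = rownames(K), signif(K, 6), check.names = FALSE)
  write_tsv(out, path)
}

#' Serialize a hierarchical clustering as newick
#'
#' Writes a single-line newick string (terminated by `";"`) for an `hclust`
#' tree over accession labels. Branch lengths follow the usual convention for
#' ultrametric trees built from a distance: a pair merged at height `h` gets
#' two branches of length `h / 2`. A single-leaf "tree" may be given as a
#' character label and is serialized as `"label;"`.
#'
#' @param tree an `hclust` object, an `ape::phylo` tree, or a single label.
#' @param path optional output file; when `NULL` the string is returned only.
#' @return the newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    nwk <- paste0(tree, ";")
  } else {
    if (inherits(tree, "hclust")) {
      if (anyDuplicated(tree$labels)) stop("duplicate leaf labels")
      tree <- ape::as.phylo(tree)
    }
    if (!inherits(tree, "phylo")) stop("unsupported tree object")
    if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
    nwk <- ape::write.tree(tree)
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) mappings with at least a `seed`, a
#' `thresholds` block and an `out_dir`. Threshold defaults mirror the package
#' defaults used throughout: `maf_min = 0.02`, `major_max = 0.98`,
#' `biallelic_min = 0.95`, `sd_min = 0.1`, `r_collinear = 0.3`,
#' `alpha = 0.05`.
#'
#' @param path path to a YAML/JSON configuration file.
#' @param config alternatively, a named list.
#' @return validated configuration list of class `"run_config"`.
#' @export
load_run_config <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    config <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  defaults <- list(
    seed = 1L,
    out_dir = "scafqtl_out",
    thresholds = list(maf_min = 0.02, major_max = 0.98, biallelic_min = 0.95,
                      sd_min = 0.1, r_collinear = 0.3, alpha = 0.05),
    genome_size_bp = NULL,
    n_clusters = 5L,
    sim = list()
  )
  config <- utils::modifyList(defaults, config)
  th <- config$thresholds
  for (nm in c("maf_min", "major_max", "biallelic_min", "sd_min", "r_collinear")) {
    v <- th[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("threshold '", nm, "' must lie in [0, 1]")
    }
  }
  if (!is.numeric(th$alpha) || th$alpha <= 0 || th$alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  config$seed <- as.integer(config$seed)
  class(config) <- c("run_config", "list")
  config
}
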