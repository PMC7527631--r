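#' QTL regions shared across locations
#'
#' Representative QTL-markers from the per-location MultiQTL models of one
#' trait are joined into a graph with an edge between every pair of markers
#' from *different* locations correlated at `|r| >= r_collinear` (the same
#' marker id appearing in two locations is trivially connected). Regions
#' are the connected components that touch at least two locations. Within a
#' location representatives are non-collinear by construction, so no
#' within-location edges exist at the default threshold.
#'
#' Connected components are a single-linkage construction: two markers can
#' end up in one region through a chain even when their direct correlation
#' is below the threshold. Such regions are flagged (`chained = TRUE`) so
#' the report surfaces them.
#'
#' @param models list of `"multiqtl_model"` objects for one trait, one per
#'   location (at least two).
#' @param scores accession-by-marker score matrix containing all
#'   representative markers.
#' @param r_collinear threshold on `|r|` (default 0.3).
#' @param trait trait label; defaults to the models' common trait.
#' @return list of class `"qtl_regions"`: data.frame `regions`
#'   (`region_id`, `trait`, `n_locations`, `n_markers`, `scaffolds`,
#'   `chained`, plus one column per location listing its marker ids,
#'   `;`-separated) and list `members` (per region: data.frame `marker_id`,
#'   `location`).
#' @export
match_regions <- function(models, scores, r_collinear = 0.3, trait = NULL) {
  if (length(models) < 2L) stop("need MultiQTL models from at least two locations")
  locs <- vapply(models, `[[`, character(1), "location")
  if (anyDuplicated(locs)) stop("one model per location expected")
  if (is.null(trait)) trait <- models[[1L]]$trait

  nodes <- do.call(rbind, lapply(models, function(m) {
    reps <- representative_markers(m)
    if (length(reps) == 0L) return(NULL)
    data.frame(marker_id = reps, location = m$location,
               stringsAsFactors = FALSE)
  }))
  out <- structure(list(regions = data.frame(), members = list(),
                        trait = trait, r_collinear = r_collinear),
                   class = "qtl_regions")
  if (is.null(nodes) || nrow(nodes) < 2L) return(out)
  nodes$node <- paste(nodes$marker_id, nodes$location, sep = "@")

  C <- stats::cor(scores[, unique(nodes$marker_id), drop = FALSE])
  pair_idx <- utils::combn(nrow(nodes), 2L)
  ia <- pair_idx[1L, ]; ib <- pair_idx[2L, ]
  cross <- nodes$location[ia] != nodes$location[ib]
  r_ab <- abs(C[cbind(match(nodes$marker_id[ia], rownames(C)),
                      match(nodes$marker_id[ib], rownames(C)))])
  same_id <- nodes$marker_id[ia] == nodes$marker_id[ib]
  edge <- cross & (same_id | r_ab >= r_collinear)

  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes$node[ia][edge], to = nodes$node[ib][edge]),
    directed = FALSE,
    vertices = nodes$node
  )
  comp <- igraph::components(g)$membership[nodes$node]

  regions <- list()
  members <- list()
  for (cid in unique(comp)) {
    sel <- nodes[comp == cid, , drop = FALSE]
    if (length(unique(sel$location)) < 2L) next
    # chaining check: some cross-location pair connected but directly below r
    pi <- utils::combn(nrow(sel), 2L)
    ca <- pi[1L, ]; cb <- pi[2L, ]
    xl <- sel$location[ca] != sel$location[cb]
    direct <- abs(C[cbind(match(sel$marker_id[ca], rownames(C)),
                          match(sel$marker_id[cb], rownames(C)))])
    sameid <- sel$marker_id[ca] == sel$marker_id[cb]
    chained <- any(xl & !sameid & direct < r_collinear)
    regions[[length(regions) + 1L]] <- sel
    members[[length(members) + 1L]] <- list(sel = sel, chained = chained)
  }
  if (length(regions) == 0L) return(out)

  # stable naming: order by location span (desc), then first marker id
  ord <- order(-vapply(regions, function(s) length(unique(s$location)),
                       integer(1)),
               vapply(regions, function(s) min(s$marker_id), character(1)))
  members <- members[ord]
  all_locs <- sort(unique(nodes$location))
  rows <- lapply(seq_along(members), function(i) {
    sel <- members[[i]]$sel
    per_loc <- vapply(all_locs, function(l) {
      ids <- sel$marker_id[sel$location == l]
      if (length(ids) == 0L) "" else paste(sort(ids), collapse = ";")
    }, character(1))
    scaffolds <- unique(sub("_[0-9]+$", "", sel$marker_id))
    df <- data.frame(region_id = sprintf("QTL_%s%d", trait, i),
                     trait = trait,
                     n_locations = length(unique(sel$location)),
                     n_markers = nrow(sel),
                     scaffolds = paste(sort(scaffolds), collapse = ";"),
                     chained = members[[i]]$chained,
                     stringsAsFactors = FALSE)
    for (l in all_locs) df[[l]] <- per_loc[[l]]
    df
  })
  out$regions <- do.call(rbind, rows)
  out$members <- stats::setNames(
    lapply(members, function(m) m$sel[, c("marker_id", "location")]),
    out$regions$region_id
  )
  out
}

#' @export
print.qtl_regions <- function(x, ...) {
  cat(sprintf("QTL regions [%s]: %d regions across locations\n",
              x$trait, nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions[, c("region_id", "n_locations",
                                           "n_markers", "chained")])
  invisible(x)
}

#' Representative markers shared between traits' QTL regions
#'
#' Lists, for every pair of traits, the region pairs that share at least one
#' representative marker id (and separately any shared scaffold), an
#' indication that QTLs for correlated traits co-localize.
#'
#' @param region_sets named list of `"qtl_regions"`, one per trait.
#' @return data.frame `trait_a`, `trait_b`, `region_a`, `region_b`,
#'   `shared_markers`, `shared_scaffolds` (both `;`-separated, possibly
#'   empty for scaffold-only overlap).
#' @export
cross_trait_overlap <- function(region_sets) {
  traits <- names(region_sets)
  if (is.null(traits) || length(traits) < 2L) {
    stop("need region sets for at least two traits, as a named list")
  }
  rows <- list()
  for (i in seq_len(length(traits) - 1L)) {
    for (j in seq((i + 1L), length(traits))) {
      ra <- region_sets[[i]]; rb <- region_sets[[j]]
      if (nrow(ra$regions) == 0L || nrow(rb$regions) == 0L) next
      for (ka in names(ra$members)) {
        for (kb in names(rb$members)) {
          ma <- ra$members[[ka]]$marker_id
          mb <- rb$members[[kb]]$marker_id
          shared <- sort(unique(intersect(ma, mb)))
          sca <- unique(sub("_[0-9]+$", "", ma))
          scb <- unique(sub("_[0-9]+$", "", mb))
          shared_sc <- sort(unique(intersect(sca, scb)))
          if (length(shared) == 0L && length(shared_sc) == 0L) next
          rows[[length(rows) + 1L]] <- data.frame(
            trait_a = traits[i], trait_b = traits[j],
            region_a = ka, region_b = kb,
            shared_markers = paste(shared, collapse = ";"),
            shared_scaffolds = paste(shared_sc, collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(trait_a = character(0), trait_b = character(0),
                      region_a = character(0), region_b = character(0),
                      shared_markers = character(0),
                      shared_scaffolds = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write QTL regions as JSON and as a per-location table
#' @param regions a `"qtl_regions"` object.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_regions <- function(regions, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(trait = regions$trait,
                    r_collinear = regions$r_collinear,
                    regions = regions$regions,
                    members = regions$members)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path) && nrow(regions$regions)) {
    write_tsv(regions$regions, tsv_path)
  }
  invisible(regions)
}
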