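#' Niche points of a taxon within one ecosystem
#'
#' Collects the predictor vectors of the grid cells that are both
#' predicted present for the taxon and inside the ecosystem, and projects
#' them onto the first two PCA axes. An empty result (taxon absent from
#' the ecosystem) is returned as a 0-row matrix, not an error.
#'
#' @param binary a `binary_map` for the taxon.
#' @param eco an `ecosystem_map` with the same geometry.
#' @param ecosystem_id ecosystem class label.
#' @param space a `pca_space` fitted on the background cells.
#' @param stack the `predictor_stack` the maps were built from.
#' @return numeric matrix of 2-D points (one row per qualifying cell).
#' @export
taxon_niche_points <- function(binary, eco, ecosystem_id, space, stack) {
  stopifnot(identical(binary$geom$n_rows, eco$geom$n_rows),
            identical(binary$geom$n_cols, eco$geom$n_cols))
  cells <- intersect(which(!is.na(binary$values) & binary$values == 1),
                     ecosystem_cells(eco, ecosystem_id))
  cells <- cells[stack$mask[cells]]
  if (length(cells) == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  project_pca(space, predictor_matrix(stack, cells))[, 1:2, drop = FALSE]
}

#' Niche points from raw occurrence records
#'
#' Alternative to [taxon_niche_points()] using the occupied cells of the
#' raw records instead of a modelled binary map (both conventions are in
#' use for hull-based niche estimates; a switch between them is provided
#' throughout).
#'
#' @param occ occurrence data frame (needs `cell_id` or `lon`/`lat`).
#' @param space a `pca_space`.
#' @param stack a `predictor_stack`.
#' @param eco,ecosystem_id optional restriction to one ecosystem.
#' @return numeric matrix of 2-D points (one row per occupied cell).
#' @export
occurrence_niche_points <- function(occ, space, stack, eco = NULL,
                                    ecosystem_id = NULL) {
  if (is.null(occ$cell_id)) occ$cell_id <- locate_cells(occ$lon, occ$lat, stack$geom)
  cells <- unique(occ$cell_id)
  cells <- cells[!is.na(cells) & stack$mask[cells]]
  if (!is.null(eco) && !is.null(ecosystem_id)) {
    cells <- intersect(cells, ecosystem_cells(eco, ecosystem_id))
  }
  if (length(cells) == 0) return(matrix(numeric(0), 0, 2))
  project_pca(space, predictor_matrix(stack, cells))[, 1:2, drop = FALSE]
}

#' Tick-by-host Jaccard overlap matrix for one ecosystem
#'
#' Builds each taxon's niche hull inside the ecosystem and fills the full
#' tick x host table of pairwise Jaccard overlap percentages. Taxa with no
#' qualifying cells in the ecosystem give undefined (`NA`) cells, flagged
#' and excluded from row means; taxa with too few or collinear points give
#' degenerate hulls scoring 0.
#'
#' @param tick_maps,host_maps named lists of `binary_map`s.
#' @param eco an `ecosystem_map`.
#' @param ecosystem_id ecosystem class label.
#' @param space a `pca_space`.
#' @param stack the shared `predictor_stack`.
#' @return an `overlap_matrix`: list with `ecosystem_id`, `values`
#'   (ticks x hosts, `[0,100]` or `NA`), `defined` (logical matrix) and
#'   the per-taxon `hulls`.
#' @export
ecosystem_overlap_matrix <- function(tick_maps, host_maps, eco, ecosystem_id,
                                     space, stack) {
  hull_of <- function(map) {
    pts <- taxon_niche_points(map, eco, ecosystem_id, space, stack)
    if (nrow(pts) == 0) NULL else convex_hull(pts)
  }
  th <- lapply(tick_maps, hull_of)
  hh <- lapply(host_maps, hull_of)
  defined_t <- !vapply(th, is.null, TRUE)
  defined_h <- !vapply(hh, is.null, TRUE)
  if (!any(defined_t) || !any(defined_h)) {
    stop("ecosystem ", ecosystem_id,
         ": no tick or no host with a defined niche hull")
  }
  vals <- matrix(NA_real_, length(th), length(hh),
                 dimnames = list(names(tick_maps), names(host_maps)))
  for (i in seq_along(th)) for (j in seq_along(hh)) {
    if (defined_t[i] && defined_h[j]) {
      vals[i, j] <- jaccard_overlap(th[[i]], hh[[j]])
    }
  }
  structure(list(ecosystem_id = ecosystem_id, values = vals,
                 defined = !is.na(vals), hulls = c(th, hh)),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> ecosystem %s: %d ticks x %d hosts, %d undefined cells\n",
              as.character(x$ecosystem_id), nrow(x$values), ncol(x$values),
              sum(!x$defined)))
  invisible(x)
}

#' Mean host niche overlap of one tick (biotic suitability)
#'
#' The arithmetic mean of the defined Jaccard values in the tick's row of
#' the ecosystem overlap matrix — the average niche sharing between the
#' tick and the hosts that colonise the same ecosystem, in `[0, 100]`.
#'
#' @param om an `overlap_matrix`.
#' @param tick_id tick row name.
#' @return mean overlap, or `NA` when every host cell is undefined.
#' @export
biotic_suitability <- function(om, tick_id) {
  if (!tick_id %in% rownames(om$values)) stop("unknown tick ", tick_id)
  row <- om$values[tick_id, ]
  if (all(is.na(row))) return(NA_real_)
  mean(row, na.rm = TRUE)
}

#' Write / read an overlap matrix as CSV (ticks as rows, hosts as columns,
#' empty cell = undefined)
#' @param om an `overlap_matrix`.
#' @param path CSV path.
#' @export
write_overlap_matrix <- function(om, path) {
  df <- data.frame(tick_id = rownames(om$values), om$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_overlap_matrix
#' @param ecosystem_id id to attach to the object read back.
#' @export
read_overlap_matrix <- function(path, ecosystem_id = NA) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$tick_id
  structure(list(ecosystem_id = ecosystem_id, values = vals,
                 defined = !is.na(vals), hulls = NULL),
            class = "overlap_matrix")
}

#' Write niche hulls as polygon records (JSON)
#' @param hulls named list of `niche_hull`s.
#' @param path output JSON path.
#' @export
write_hulls <- function(hulls, path) {
  rec <- lapply(hulls, function(h) {
    if (is.null(h)) return(NULL)
    list(type = "Polygon", degenerate = h$degenerate, area = h$area,
         coordinates = if (nrow(h$vertices)) {
           lapply(seq_len(nrow(h$vertices)), function(i) unname(h$vertices[i, ]))
         } else list())
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
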