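#' Partition a climate grid into ecosystems
#'
#' Assigns every grid cell to exactly one of `k` ecosystem classes, either
#' as contiguous latitudinal bands or by k-means clustering of the cells'
#' harmonic climate coefficients (the same 9 predictors used for
#' modelling, standardised before clustering).
#'
#' @param grid a `climate_grid`.
#' @param k number of ecosystems, `2 <= k <=` number of cells.
#' @param scheme `"latitudinal_bands"` or `"kmeans_on_climate"`.
#' @param seed integer seed (used by the k-means scheme).
#' @return an `ecosystem_map`: list with `geom`, integer `labels`
#'   (length `n_cells`, values `1..k`), `k` and a `legend` naming each class.
#' @export
make_ecosystem_map <- function(grid, k,
                               scheme = c("latitudinal_bands", "kmeans_on_climate"),
                               seed = 1L) {
  validate_climate_grid(grid)
  scheme <- match.arg(scheme)
  nc <- n_cells(grid$geom)
  if (k < 2) stop("k must be at least 2")
  if (k > nc) stop("k exceeds the number of cells")
  labels <- switch(scheme,
    latitudinal_bands = {
      if (k > grid$geom$n_rows) stop("more bands than rows")
      sizes <- diff(floor(seq(0, grid$geom$n_rows, length.out = k + 1)))
      row_lab <- rep(seq_len(k), times = sizes)
      row_lab[cell_centers(grid$geom)$row]
    },
    kmeans_on_climate = {
      x <- scale(predictor_matrix(build_predictors(grid)))
      km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 10, iter.max = 50))
      as.integer(km$cluster)
    }
  )
  stopifnot(length(unique(labels)) == k)
  structure(list(geom = grid$geom, labels = as.integer(labels), k = as.integer(k),
                 legend = stats::setNames(paste0("ecosystem_", seq_len(k)),
                                          seq_len(k)),
                 scheme = scheme),
            class = "ecosystem_map")
}

#' @export
print.ecosystem_map <- function(x, ...) {
  cat(sprintf("<ecosystem_map> %d classes over %d cells (%s)\n",
              x$k, length(x$labels), x$scheme))
  print(table(x$labels))
  invisible(x)
}

#' Cells belonging to one ecosystem
#' @param eco an `ecosystem_map`.
#' @param ecosystem_id integer class label.
#' @return integer vector of cell ids.
#' @export
ecosystem_cells <- function(eco, ecosystem_id) {
  if (!ecosystem_id %in% eco$labels) stop("ecosystem ", ecosystem_id, " not present")
  which(eco$labels == ecosystem_id)
}

#' Write an ecosystem map (integer grid + JSON legend sidecar)
#' @param eco an `ecosystem_map`.
#' @param path grid file path; the legend goes to `<path>.legend.json`.
#' @export
write_ecosystem_map <- function(eco, path) {
  write_text_grid(list(ecosystem = as.numeric(eco$labels)), eco$geom, path)
  jsonlite::write_json(as.list(eco$legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an ecosystem map written by [write_ecosystem_map()]
#' @param path grid file path.
#' @return an `ecosystem_map`.
#' @export
read_ecosystem_map <- function(path) {
  g <- read_text_grid(path)
  labels <- as.integer(g$layers$ecosystem)
  legend_path <- paste0(path, ".legend.json")
  legend <- if (file.exists(legend_path)) {
    unlist(jsonlite::read_json(legend_path))
  } else stats::setNames(paste0("ecosystem_", sort(unique(labels))), sort(unique(labels)))
  structure(list(geom = g$geom, labels = labels, k = length(unique(labels)),
                 legend = legend, scheme = "file"),
            class = "ecosystem_map")
}
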