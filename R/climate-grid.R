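new_grid_geometry <- function(n_rows, n_cols, origin = c(0, 40), cellsize = 0.1) {
  stopifnot(n_rows >= 2, n_cols >= 2, cellsize > 0, length(origin) == 2,
            all(is.finite(origin)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin = as.numeric(origin), cellsize = as.numeric(cellsize)),
            class = "grid_geometry")
}

n_cells <- function(geom) geom$n_rows * geom$n_cols

#' Cell-center coordinates of a grid
#'
#' Cells are stored in row-major order with row 1 the northernmost row;
#' `origin` is the lower-left corner of the grid.
#'
#' @param geom a `grid_geometry` (or an object carrying one in `$geom`).
#' @return data frame with columns `cell_id`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(geom) {
  if (!inherits(geom, "grid_geometry")) geom <- geom$geom
  row <- rep(seq_len(geom$n_rows), each = geom$n_cols)
  col <- rep(seq_len(geom$n_cols), times = geom$n_rows)
  data.frame(
    cell_id = seq_len(n_cells(geom)),
    row = row, col = col,
    lon = geom$origin[1] + (col - 0.5) * geom$cellsize,
    lat = geom$origin[2] + (geom$n_rows - row + 0.5) * geom$cellsize
  )
}

#' Default regional harmonic parameters for the synthetic climate field
#'
#' Two latitudinal bands (south, north), each holding an annual-cycle triple
#' `(a0, a1, b1)` per climate variable: maximum temperature (degrees C),
#' minimum temperature (degrees C) and vapour pressure deficit (kPa).
#' `a0` is the annual mean level, `a1`/`b1` the cosine/sine amplitudes of
#' the annual harmonic evaluated at month positions 1..12.
#'
#' @return a list of bands; each band is a list with elements `tmax`,
#'   `tmin`, `vpd`, each a numeric triple `c(a0, a1, b1)`.
#' @export
default_harmonics <- function() {
  list(
    south = list(tmax = c(24, 7, -2.5), tmin = c(12, 6, -2), vpd = c(1.6, 0.6, -0.2)),
    north = list(tmax = c(12, 10, -3.5), tmin = c(2, 9, -3), vpd = c(0.7, 0.3, -0.1))
  )
}

harmonic_basis <- function(months = 1:12) {
  cbind(1, cos(2 * pi * months / 12), sin(2 * pi * months / 12))
}

#' Generate a synthetic monthly climate grid
#'
#' Builds a gridded monthly climatology for maximum temperature, minimum
#' temperature and vapour pressure deficit. Each variable's 12 monthly
#' values per cell follow `a0 + a1*cos(2*pi*m/12) + b1*sin(2*pi*m/12)` plus
#' i.i.d. Gaussian noise, with the harmonic triple set per latitudinal band
#' (`regional_harmonics`) and the mean level `a0` additionally tilted
#' east-to-west by a linear continentality gradient.
#'
#' @param n_rows,n_cols grid dimensions (each at least 2).
#' @param seed integer seed; the same seed reproduces the grid exactly.
#' @param regional_harmonics list of latitudinal bands (northernmost rows get
#'   the last band); see [default_harmonics()]. A single band gives a
#'   spatially uniform harmonic field.
#' @param noise_sd per-variable Gaussian noise standard deviation. `NULL`
#'   (default) uses 5\% of each variable's mean seasonal amplitude
#'   `sqrt(a1^2 + b1^2)`; a single number is recycled across variables.
#' @param continentality total west-to-east span added to `a0`
#'   (named per variable); the gradient is linear in column and centred.
#' @param origin,cellsize grid geometry (lower-left corner, degrees).
#' @return a `climate_grid`: list with `geom` and `values`, the latter a
#'   list of `n_cells x 12` matrices named `tmax`, `tmin`, `vpd`.
#' @export
make_climate_grid <- function(n_rows, n_cols, seed,
                              regional_harmonics = default_harmonics(),
                              noise_sd = NULL,
                              continentality = c(tmax = 3, tmin = 3, vpd = 0.3),
                              origin = c(0, 40), cellsize = 0.1) {
  geom <- new_grid_geometry(n_rows, n_cols, origin, cellsize)
  vars <- c("tmax", "tmin", "vpd")
  bands <- regional_harmonics
  if (!is.list(bands) || length(bands) < 1) stop("regional_harmonics must be a non-empty list of bands")
  for (b in bands) {
    for (v in vars) {
      p <- b[[v]]
      if (is.null(p) || length(p) != 3 || !all(is.finite(p))) {
        stop("each band needs a finite (a0, a1, b1) triple for ", v)
      }
    }
  }
  if (!all(is.finite(unlist(continentality)))) stop("non-finite continentality")
  if (length(bands) > n_rows) stop("more bands than grid rows")

  if (is.null(noise_sd)) {
    noise_sd <- vapply(vars, function(v) {
      amps <- vapply(bands, function(b) sqrt(b[[v]][2]^2 + b[[v]][3]^2), 0)
      0.05 * mean(amps)
    }, 0)
  } else {
    noise_sd <- rep_len(as.numeric(noise_sd), 3)
    names(noise_sd) <- vars
    if (any(noise_sd < 0) || any(!is.finite(noise_sd))) stop("invalid noise_sd")
  }

  cc <- cell_centers(geom)
  # band index per row: bands are listed south to north; row 1 is north
  sizes <- diff(floor(seq(0, n_rows, length.out = length(bands) + 1)))
  south_to_north <- rep(seq_along(bands), times = sizes)
  row_band <- south_to_north[n_rows - seq_len(n_rows) + 1]
  basis <- harmonic_basis()

  values <- with_seed(seed, {
    out <- list()
    for (v in vars) {
      par_mat <- t(vapply(bands, function(b) b[[v]], numeric(3)))
      cell_par <- par_mat[row_band[cc$row], , drop = FALSE]
      cont <- continentality[[v]] %||% 0
      cell_par[, 1] <- cell_par[, 1] +
        cont * ((cc$col - 0.5) / geom$n_cols - 0.5)
      mu <- cell_par %*% t(basis)            # n_cells x 12
      eps <- if (noise_sd[[v]] > 0) {
        matrix(stats::rnorm(length(mu), 0, noise_sd[[v]]), nrow(mu))
      } else 0
      out[[v]] <- mu + eps
    }
    out
  })
  values$vpd <- pmax(values$vpd, 0)
  values$tmin <- pmin(values$tmin, values$tmax)   # physical constraint
  for (v in vars) colnames(values[[v]]) <- sprintf("m%02d", 1:12)
  structure(list(geom = geom, values = values,
                 bands = row_band, noise_sd = noise_sd),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells, variables: %s\n",
              x$geom$n_rows, x$geom$n_cols,
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

validate_climate_grid <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  for (v in names(grid$values)) {
    m <- grid$values[[v]]
    if (ncol(m) != 12) stop("variable ", v, " must have 12 monthly columns")
    if (nrow(m) != n_cells(grid$geom)) stop("variable ", v, " has wrong cell count")
  }
  invisible(grid)
}

# ---- plain-text grid dialect -------------------------------------------
# header: nrows, ncols, cellsize, xorigin, yorigin, layers; then for each
# layer a "layer <name>" line followed by n_rows lines of n_cols values
# (row-major, row 1 = north).

#' Write layers to the plain-text grid format
#'
#' @param layers named list of numeric vectors (length `n_cells`, row-major).
#' @param geom a `grid_geometry`.
#' @param path output file path.
#' @export
write_text_grid <- function(layers, geom, path) {
  stopifnot(inherits(geom, "grid_geometry"), length(layers) >= 1,
            !is.null(names(layers)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("nrows", geom$n_rows), paste("ncols", geom$n_cols),
    paste("cellsize", format(geom$cellsize, digits = 15)),
    paste("xorigin", format(geom$origin[1], digits = 15)),
    paste("yorigin", format(geom$origin[2], digits = 15)),
    paste("layers", length(layers))
  ), con)
  for (nm in names(layers)) {
    v <- layers[[nm]]
    if (length(v) != n_cells(geom)) stop("layer ", nm, " has wrong length")
    writeLines(paste("layer", nm), con)
    m <- matrix(v, nrow = geom$n_rows, byrow = TRUE)
    writeLines(apply(m, 1, function(r) paste(format(r, digits = 15), collapse = " ")), con)
  }
  invisible(path)
}

#' Read layers from the plain-text grid format
#'
#' @param path file written by [write_text_grid()].
#' @return list with `geom` and named list `layers` of row-major vectors.
#' @export
read_text_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- vapply(hdr, `[`, "", 2)
  h <- stats::setNames(as.numeric(val), key)
  geom <- new_grid_geometry(h[["nrows"]], h[["ncols"]],
                            c(h[["xorigin"]], h[["yorigin"]]), h[["cellsize"]])
  n_layers <- as.integer(h[["layers"]])
  layers <- list()
  pos <- 7L
  for (i in seq_len(n_layers)) {
    lay <- strsplit(lines[pos], "\\s+")[[1]]
    if (lay[1] != "layer") stop("malformed grid file at line ", pos)
    nm <- lay[2]
    block <- lines[pos + seq_len(geom$n_rows)]
    vals <- as.numeric(unlist(strsplit(trimws(block), "\\s+")))
    if (length(vals) != n_cells(geom)) stop("layer ", nm, ": wrong value count")
    layers[[nm]] <- vals
    pos <- pos + geom$n_rows + 1L
  }
  list(geom = geom, layers = layers)
}

#' Write a climate grid as a 36-layer plain-text grid
#' @param grid a `climate_grid`.
#' @param path output path.
#' @export
write_climate_grid <- function(grid, path) {
  validate_climate_grid(grid)
  layers <- list()
  for (v in names(grid$values)) {
    for (m in 1:12) layers[[sprintf("%s_m%02d", v, m)]] <- grid$values[[v]][, m]
  }
  write_text_grid(layers, grid$geom, path)
}

#' Read a climate grid written by [write_climate_grid()]
#' @param path file path.
#' @return a `climate_grid`.
#' @export
read_climate_grid <- function(path) {
  g <- read_text_grid(path)
  vars <- unique(sub("_m\\d\\d$", "", names(g$layers)))
  values <- lapply(vars, function(v) {
    m <- sapply(1:12, function(i) g$layers[[sprintf("%s_m%02d", v, i)]])
    colnames(m) <- sprintf("m%02d", 1:12)
    m
  })
  names(values) <- vars
  structure(list(geom = g$geom, values = values), class = "climate_grid")
}
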