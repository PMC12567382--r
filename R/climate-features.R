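#' Monthly climatology from per-year monthly observations
#'
#' Averages observations by calendar month over years, giving the 12-value
#' climatological series that the harmonic fit consumes.
#'
#' @param values numeric vector of observations.
#' @param month integer month index (1..12) per observation.
#' @return numeric vector of 12 monthly means.
#' @export
monthly_climatology <- function(values, month) {
  stopifnot(length(values) == length(month))
  month <- as.integer(month)
  if (any(month < 1 | month > 12)) stop("month indices must be in 1..12")
  out <- numeric(12)
  for (m in 1:12) {
    idx <- month == m
    if (!any(idx)) stop("no observations for month ", m)
    out[m] <- mean(values[idx])
  }
  out
}

#' Fit the annual harmonic to a 12-month series
#'
#' Least-squares fit of `y_m = a0 + a1*cos(2*pi*m/12) + b1*sin(2*pi*m/12)`
#' for months `m = 1..12`. Over a full cycle the basis is orthogonal, so the
#' coefficients have the closed form `a0 = mean(y)`,
#' `a1 = (2/12) * sum(y * cos)`, `b1 = (2/12) * sum(y * sin)`; this equals
#' the normal-equations solution exactly.
#'
#' @param monthly numeric vector of 12 finite values (January..December).
#' @return named numeric vector `c(a0, a1, b1)`.
#' @export
fit_harmonics <- function(monthly) {
  if (length(monthly) != 12 || !all(is.finite(monthly))) {
    stop("fit_harmonics needs 12 finite monthly values")
  }
  m <- 1:12
  c(a0 = mean(monthly),
    a1 = sum(monthly * cos(2 * pi * m / 12)) / 6,
    b1 = sum(monthly * sin(2 * pi * m / 12)) / 6)
}

#' Build the 9-layer harmonic predictor stack from a climate grid
#'
#' Applies [fit_harmonics()] cell-wise to each of the three climate
#' variables, yielding nine predictors per cell in the fixed order
#' `tmax_a0, tmax_a1, tmax_b1, tmin_a0, tmin_a1, tmin_b1, vpd_a0, vpd_a1,
#' vpd_b1`. Cells with any missing monthly value are masked out of all nine
#' layers.
#'
#' @param grid a `climate_grid`.
#' @return a `predictor_stack`: list with `geom`, `coef` (`n_cells x 9`
#'   matrix, `NA` rows where masked) and logical `mask` (`TRUE` = valid).
#' @export
build_predictors <- function(grid) {
  validate_climate_grid(grid)
  vars <- names(grid$values)
  nc <- n_cells(grid$geom)
  basis <- harmonic_basis()
  coef <- matrix(NA_real_, nc, 3 * length(vars))
  colnames(coef) <- as.vector(t(outer(vars, c("a0", "a1", "b1"), paste, sep = "_")))
  mask <- rep(TRUE, nc)
  for (j in seq_along(vars)) {
    y <- grid$values[[vars[j]]]
    bad <- rowSums(!is.finite(y)) > 0
    mask[bad] <- FALSE
    ok <- !bad
    if (any(ok)) {
      # closed form via the orthogonal basis, vectorised over cells
      coef[ok, 3 * j - 2] <- rowMeans(y[ok, , drop = FALSE])
      coef[ok, 3 * j - 1] <- (y[ok, , drop = FALSE] %*% basis[, 2]) / 6
      coef[ok, 3 * j]     <- (y[ok, , drop = FALSE] %*% basis[, 3]) / 6
    }
  }
  coef[!mask, ] <- NA_real_
  structure(list(geom = grid$geom, coef = coef, mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d cells x %d predictors (%d masked)\n",
              nrow(x$coef), ncol(x$coef), sum(!x$mask)))
  invisible(x)
}

#' Predictor matrix of the valid cells
#' @param stack a `predictor_stack`.
#' @param cells optional cell ids to extract (default all).
#' @return numeric matrix of predictors (rows = requested cells).
#' @export
predictor_matrix <- function(stack, cells = NULL) {
  if (is.null(cells)) stack$coef else stack$coef[cells, , drop = FALSE]
}

#' Write a predictor stack (9-layer text grid and companion CSV)
#' @param stack a `predictor_stack`.
#' @param path grid file path; a CSV with `cell_id` + coefficients is
#'   written to `<path>.csv`.
#' @export
write_predictors <- function(stack, path) {
  layers <- lapply(seq_len(ncol(stack$coef)), function(j) stack$coef[, j])
  names(layers) <- colnames(stack$coef)
  write_text_grid(layers, stack$geom, path)
  utils::write.csv(
    data.frame(cell_id = seq_len(nrow(stack$coef)), stack$coef,
               check.names = FALSE),
    paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Read a predictor stack written by [write_predictors()]
#' @param path grid file path.
#' @return a `predictor_stack`.
#' @export
read_predictors <- function(path) {
  g <- read_text_grid(path)
  coef <- do.call(cbind, g$layers)
  structure(list(geom = g$geom, coef = coef,
                 mask = rowSums(!is.finite(coef)) == 0),
            class = "predictor_stack")
}
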