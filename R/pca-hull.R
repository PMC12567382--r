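#' Fit the common PCA climate space
#'
#' Centred, unit-variance PCA of the cell-by-predictor table. All taxa are
#' later projected into this shared space, which is what makes cross-taxon
#' hull overlap comparable. Axis signs follow a fixed convention (the
#' largest-magnitude loading on each axis is positive) so results are
#' reproducible across platforms.
#'
#' @param x numeric matrix (rows = cells/background points, columns =
#'   predictors); needs at least `k + 1` rows.
#' @param k number of axes to keep (default 2).
#' @return a `pca_space`: list with `loadings` (p x k, orthonormal),
#'   `center`, `scale`, `explained` (variance fractions, nonincreasing)
#'   and `dropped` (names of zero-variance columns removed).
#' @export
fit_pca <- function(x, k = 2) {
  x <- as.matrix(x)
  if (k < 1) stop("k must be >= 1")
  if (nrow(x) < k + 1) stop("need at least k + 1 rows")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds <= 1e-12]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
    x <- x[, sds > 1e-12, drop = FALSE]
  }
  if (ncol(x) < k) stop("fewer informative columns than requested axes")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = load, center = p$center, scale = p$scale,
                 explained = expl[seq_len(k)], explained_all = expl,
                 dropped = dropped),
            class = "pca_space")
}

#' Project predictor vectors into a fitted PCA space
#' @param space a `pca_space`.
#' @param x matrix of predictor vectors (columns matching the fit, minus
#'   any dropped ones).
#' @return matrix of scores (rows x k axes).
#' @export
project_pca <- function(space, x) {
  x <- as.matrix(x)
  keep <- names(space$center)
  x <- x[, keep, drop = FALSE]
  scale(x, center = space$center, scale = space$scale) %*% space$loadings
}

shoelace_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

#' Convex hull of a 2-D point set
#'
#' Returns the hull with vertices ordered counter-clockwise and its area
#' by the shoelace formula. Fewer than 3 distinct points, or a collinear
#' set, yields a degenerate hull (area 0, `degenerate = TRUE`): an
#' unresolvable niche that scores zero overlap downstream.
#'
#' @param points numeric matrix or data frame with 2 columns.
#' @return a `niche_hull`: list with `vertices` (CCW, not repeated),
#'   `area`, `n_source_points`, `degenerate`.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  n_src <- nrow(points)
  pts <- unique(points)
  if (nrow(pts) < 3) {
    return(structure(list(vertices = pts, area = 0,
                          n_source_points = n_src, degenerate = TRUE),
                     class = "niche_hull"))
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[idx, , drop = FALSE]
  a <- shoelace_area(v)
  if (a < 0) {          # enforce counter-clockwise orientation
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    a <- -a
  }
  if (a <= 1e-14 || nrow(v) < 3) {
    return(structure(list(vertices = v, area = 0,
                          n_source_points = n_src, degenerate = TRUE),
                     class = "niche_hull"))
  }
  structure(list(vertices = unname(v), area = a, n_source_points = n_src,
                 degenerate = FALSE),
            class = "niche_hull")
}

#' @export
print.niche_hull <- function(x, ...) {
  cat(sprintf("<niche_hull> %d vertices, area %.4g%s\n", nrow(x$vertices),
              x$area, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Clip convex polygon `subject` (CCW matrix) by the half-plane left of the
# directed edge a -> b (Sutherland-Hodgman step).
clip_halfplane <- function(subject, a, b) {
  if (is.null(subject) || nrow(subject) == 0) return(subject)
  inside <- function(p) {
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
  }
  intersect_pt <- function(p, q) {
    # segment p-q with line a-b
    d1 <- c(q[1] - p[1], q[2] - p[2])
    d2 <- c(b[1] - a[1], b[2] - a[2])
    denom <- d1[1] * d2[2] - d1[2] * d2[1]
    t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
    p + t * d1
  }
  out <- list()
  n <- nrow(subject)
  for (i in seq_len(n)) {
    p <- subject[i, ]; q <- subject[if (i == n) 1 else i + 1, ]
    pin <- inside(p); qin <- inside(q)
    if (pin) {
      out[[length(out) + 1]] <- p
      if (!qin) out[[length(out) + 1]] <- intersect_pt(p, q)
    } else if (qin) {
      out[[length(out) + 1]] <- intersect_pt(p, q)
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Intersection area of two convex hulls
#'
#' Convex polygon clipping (Sutherland-Hodgman): the first hull is clipped
#' successively by each edge of the second, and the area of the remaining
#' polygon is returned. Disjoint or degenerate hulls give 0.
#'
#' @param h1,h2 `niche_hull` objects.
#' @return nonnegative intersection area.
#' @export
hull_intersection_area <- function(h1, h2) {
  if (h1$degenerate || h2$degenerate) return(0)
  poly <- h1$vertices
  v2 <- h2$vertices
  n2 <- nrow(v2)
  for (i in seq_len(n2)) {
    poly <- clip_halfplane(poly, v2[i, ], v2[if (i == n2) 1 else i + 1, ])
    if (is.null(poly) || nrow(poly) < 3) return(0)
  }
  abs(shoelace_area(poly))
}

#' Jaccard overlap of two niche hulls, in percent
#'
#' `100 * area(intersection) / area(union)` with
#' `area(union) = A1 + A2 - area(intersection)`. A degenerate hull scores
#' 0 against any defined hull; two degenerate hulls are undefined (`NA`).
#'
#' @param h1,h2 `niche_hull` objects.
#' @return a value in `[0, 100]`, or `NA` when undefined.
#' @export
jaccard_overlap <- function(h1, h2) {
  if (h1$degenerate && h2$degenerate) return(NA_real_)
  if (h1$degenerate || h2$degenerate) return(0)
  inter <- hull_intersection_area(h1, h2)
  union <- h1$area + h2$area - inter
  if (union <= 0) return(NA_real_)
  min(max(100 * inter / union, 0), 100)
}
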