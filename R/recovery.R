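#' Convex hull after Mahalanobis outlier trimming
#'
#' Convex hulls are sensitive to single outlying points; dropping points
#' above a Mahalanobis-distance quantile (97.5th percentile by default)
#' before taking the hull yields a range estimate whose population
#' analogue is the same-mass Mahalanobis level set of the sampling
#' distribution (see [true_trimmed_hull()]).
#'
#' @param points 2-D point matrix (repeated points allowed and meaningful:
#'   the trim quantile is taken over points, i.e. over sampling mass).
#' @param q quantile of squared Mahalanobis distance retained.
#' @return a `niche_hull`.
#' @export
trimmed_convex_hull <- function(points, q = 0.975) {
  points <- as.matrix(points)
  if (nrow(points) > 10) {
    d2 <- stats::mahalanobis(points, colMeans(points), stats::cov(points))
    points <- points[d2 <= stats::quantile(d2, q), , drop = FALSE]
  }
  convex_hull(points)
}

#' Population analogue of the trimmed occurrence hull
#'
#' The exact hull a trimmed occurrence sample estimates: grid cells are
#' weighted by true suitability (the occurrence sampling measure), the
#' suitability-weighted mean and covariance define a Mahalanobis distance
#' in the projected plane, and the hull is taken over the cells inside
#' the weighted `q`-quantile of that distance — the true-suitability
#' level set at the same presence threshold the estimator applies to its
#' sample.
#'
#' @param truth a `synthetic_truth`.
#' @param taxon_id taxon column name.
#' @param space a `pca_space`.
#' @param stack the `predictor_stack`.
#' @param q retained suitability mass (default 0.975).
#' @return a `niche_hull`.
#' @export
true_trimmed_hull <- function(truth, taxon_id, space, stack, q = 0.975) {
  s <- truth$suitability[, taxon_id]
  s[is.na(s)] <- 0
  pts <- project_pca(space, predictor_matrix(stack))[, 1:2, drop = FALSE]
  w <- s / sum(s)
  mu <- colSums(pts * w)
  xc <- sweep(pts, 2, mu)
  S <- t(xc) %*% (xc * w)
  d2 <- stats::mahalanobis(pts, mu, S)
  o <- order(d2)
  cutoff <- d2[o][which(cumsum(w[o]) >= q)[1]]
  convex_hull(pts[d2 <= cutoff & s > 0, , drop = FALSE])
}

#' Niche-overlap recovery experiment against generator truth
#'
#' Builds a climate grid, anchors a virtual tick and a sweep of virtual
#' hosts with a shared diagonal Gaussian breadth at the grid's central
#' climate, shifting each host's niche center by a growing multiple of
#' the per-predictor spatial s.d. For every taxon, `n_rep` seeded samples
#' of `n_occ` occurrence records are pooled and turned into a trimmed
#' occurrence hull in the common PCA plane; the estimated tick-host
#' Jaccard overlap is compared with the truth computed from the
#' true-suitability level sets at the same presence threshold
#' ([true_trimmed_hull()]). Under the generator, overlap decreases
#' strictly as the centers separate.
#'
#' @param seed integer seed (drives the grid and all occurrence draws).
#' @param n_side grid side length (default 30).
#' @param n_occ occurrence records per taxon per replicate (default 500).
#' @param separations center shifts in s.d. units (default 6 values,
#'   0.07-0.42).
#' @param n_rep replicate occurrence samples pooled per taxon (default 8).
#' @param breadth_scale shared niche s.d. as a multiple of predictor s.d.
#' @param trim Mahalanobis trim quantile / retained mass (default 0.975).
#' @return data frame with `separation`, `estimated`, `truth`, `error`.
#' @export
overlap_recovery_experiment <- function(seed = 1, n_side = 30, n_occ = 500,
                                        separations = seq(0.07, 0.42, by = 0.07),
                                        n_rep = 8, breadth_scale = 0.4,
                                        trim = 0.975) {
  stack <- build_predictors(make_climate_grid(n_side, n_side,
                                              child_seed(seed, "climate")))
  sds <- apply(stack$coef, 2, stats::sd)
  center_cell <- (ceiling(n_side / 2) - 1) * n_side + ceiling(n_side / 2)
  base <- predictor_matrix(stack)[center_cell, ]
  breadth <- (breadth_scale * pmax(sds, 1e-8))^2
  tick <- virtual_taxon("tick", "tick", base, breadth, 0.8)
  hosts <- lapply(seq_along(separations), function(i) {
    virtual_taxon(paste0("host_", i), "host", base + separations[i] * sds,
                  breadth, 0.8)
  })
  truth <- synthetic_truth(c(list(tick), hosts), stack)
  space <- fit_pca(predictor_matrix(stack), k = 2)
  pooled_hull <- function(tx, seeds) {
    occ <- do.call(rbind, lapply(seeds, function(s) {
      sample_occurrences(tx, truth, n_occ, seed = s)
    }))
    pts <- project_pca(space, predictor_matrix(stack, occ$cell_id))[, 1:2]
    trimmed_convex_hull(pts, q = trim)
  }
  rep_seeds <- function(i) {
    vapply(seq_len(n_rep), function(r) {
      child_seed(seed + 7919 * r + 97 * i, "occurrences")
    }, 0L)
  }
  tick_est <- pooled_hull(tick, rep_seeds(0))
  tick_true <- true_trimmed_hull(truth, "tick", space, stack, trim)
  rows <- lapply(seq_along(separations), function(i) {
    est <- jaccard_overlap(tick_est, pooled_hull(hosts[[i]], rep_seeds(i)))
    tru <- jaccard_overlap(
      tick_true,
      true_trimmed_hull(truth, paste0("host_", i), space, stack, trim))
    data.frame(separation = separations[i], estimated = est, truth = tru)
  })
  out <- do.call(rbind, rows)
  out$error <- out$estimated - out$truth
  out
}
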