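#' Distance matrix over (tick, ecosystem) overlap profiles
#'
#' Each item is one tick within one ecosystem, described by its profile of
#' Jaccard overlaps with the union host set (undefined overlaps enter as
#' 0). The default dissimilarity is the root-mean-square difference
#' between profiles, which maps identical profiles to 0 and fully
#' antipodal profiles (e.g. `(100, 0)` vs `(0, 100)`) to 100 — a bounded
#' complement-style "inverse" of habitat sharing. `mode = "reciprocal"`
#' instead transforms each profile value through `100 / (1 + v)` before
#' taking the RMS difference, for users who read "inverse" literally.
#'
#' @param matrices named list of `overlap_matrix` objects (name = ecosystem).
#' @param mode `"complement"` (default) or `"reciprocal"`.
#' @return list with `d` (square symmetric matrix, zero diagonal),
#'   `items` (data frame `tick_id`, `ecosystem_id`) and `profiles`.
#' @export
overlap_to_distance <- function(matrices, mode = c("complement", "reciprocal")) {
  mode <- match.arg(mode)
  hosts <- sort(unique(unlist(lapply(matrices, function(m) colnames(m$values)))))
  items <- do.call(rbind, lapply(names(matrices), function(e) {
    v <- matrices[[e]]$values
    keep <- rowSums(!is.na(v)) > 0   # ticks absent from the ecosystem drop out
    data.frame(tick_id = rownames(v)[keep], ecosystem_id = e,
               stringsAsFactors = FALSE)
  }))
  if (nrow(items) < 3) stop("need at least 3 (tick, ecosystem) items")
  prof <- matrix(0, nrow(items), length(hosts),
                 dimnames = list(paste(items$tick_id, items$ecosystem_id, sep = "|"),
                                 hosts))
  for (r in seq_len(nrow(items))) {
    v <- matrices[[items$ecosystem_id[r]]]$values
    row <- v[items$tick_id[r], ]
    row[is.na(row)] <- 0
    prof[r, colnames(v)] <- row
  }
  if (mode == "reciprocal") prof <- 100 / (1 + prof)
  n <- nrow(prof)
  d <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sqrt(mean((prof[i, ] - prof[j, ])^2))
  }
  list(d = d, items = items, profiles = prof)
}

#' Non-metric multidimensional scaling with seeded restarts
#'
#' Kruskal's stress-1 NMDS (monotone regression, via
#' [vegan::monoMDS()]), run from a classical-scaling start plus
#' `n_starts - 1` seeded random starts; the lowest-stress configuration is
#' returned with coordinates centred at the origin.
#'
#' @param d square distance matrix (or `dist`).
#' @param dim embedding dimension (default 2, must be < n - 1).
#' @param seed integer seed.
#' @param n_starts total starts (default 8).
#' @param maxit iteration cap per start (default 300).
#' @return an `ordination_result`: list with `coordinates` (centred),
#'   `stress` (Kruskal stress-1, in `[0, 1]`), `converged`, `items`,
#'   `seed`. All-zero input distances return a flagged degenerate result.
#' @export
nmds <- function(d, dim = 2, seed = 1L, n_starts = 8, maxit = 300) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (dim >= n - 1) stop("dim must be smaller than n - 1")
  if (all(dm <= 1e-15)) {
    return(structure(list(coordinates = matrix(0, n, dim,
                                               dimnames = list(rownames(dm), NULL)),
                          stress = 0, converged = FALSE, degenerate = TRUE,
                          items = rownames(dm), seed = seed),
                     class = "ordination_result"))
  }
  dd <- stats::as.dist(dm)
  inits <- with_seed(seed, {
    out <- list(suppressWarnings(stats::cmdscale(dd, k = dim)))
    for (i in seq_len(max(0, n_starts - 1))) {
      out[[i + 1]] <- matrix(stats::rnorm(n * dim), n, dim)
    }
    out
  })
  best <- NULL
  for (y in inits) {
    if (ncol(y) < dim) y <- cbind(y, matrix(0, n, dim - ncol(y)))
    fit <- vegan::monoMDS(dd, y = y, k = dim, model = "global",
                          maxit = maxit, smin = 1e-7, sfgrmin = 1e-8)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- rownames(dm)
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$icause %in% c(2L, 3L) || best$stress < 1e-6,
                 degenerate = FALSE, items = rownames(dm), seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d items in %d-D, stress %.4g%s\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Is the ordination stress acceptably low?
#'
#' Strict comparison: stress must be below the threshold (0.05 by
#' default, the conventional bar for a reliable reduction); a stress
#' exactly at the threshold fails.
#'
#' @param result an `ordination_result`.
#' @param threshold stress bound (default 0.05).
#' @return logical flag.
#' @export
stress_check <- function(result, threshold = 0.05) {
  result$stress < threshold
}

#' Permutation test for group separation in a distance matrix
#'
#' A distance-based check that between-group dissimilarities exceed
#' within-group ones: the statistic is
#' `mean(between-group d) - mean(within-group d)` and group labels are
#' permuted. This is this package's own construction for asking whether
#' overlap profiles are structured by ecosystem; it is a generic
#' separation test, not a reproduction of any published procedure.
#'
#' @param d square distance matrix.
#' @param groups group label per item.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n_perm`.
#' @export
group_separation_test <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dm))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  ut <- upper.tri(dm)
  stat <- function(g) {
    same <- outer(g, g, "==")[ut]
    mean(dm[ut][!same]) - mean(dm[ut][same])
  }
  s_obs <- stat(groups)
  hits <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(groups)) >= s_obs - 1e-12, TRUE)
  })
  list(statistic = s_obs, p_value = (1 + sum(hits)) / (n_perm + 1),
       n_perm = n_perm)
}
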