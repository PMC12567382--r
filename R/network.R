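#' Build the overlap-weighted tick-host network of one ecosystem
#'
#' Directed bipartite network tick -> host with one edge per defined
#' overlap cell exceeding `edge_threshold`; edge weight equals the Jaccard
#' overlap percentage. Nodes with no edges are retained.
#'
#' @param om an `overlap_matrix`.
#' @param edge_threshold minimum overlap for an edge (default 0,
#'   exclusive).
#' @return a `tick_host_network`: list with `ecosystem_id`, `ticks`,
#'   `hosts`, `edges` (data frame `tick_id`, `host_id`, `weight`) and the
#'   weighted `incidence` matrix (0 where no edge).
#' @export
build_network <- function(om, edge_threshold = 0) {
  vals <- om$values
  if (length(vals) == 0) stop("empty overlap matrix")
  inc <- ifelse(!is.na(vals) & vals > edge_threshold, vals, 0)
  idx <- which(inc > 0, arr.ind = TRUE)
  edges <- data.frame(tick_id = rownames(vals)[idx[, 1]],
                      host_id = colnames(vals)[idx[, 2]],
                      weight = inc[idx], stringsAsFactors = FALSE)
  structure(list(ecosystem_id = om$ecosystem_id, ticks = rownames(vals),
                 hosts = colnames(vals), edges = edges, incidence = inc,
                 edge_threshold = edge_threshold),
            class = "tick_host_network")
}

#' @export
print.tick_host_network <- function(x, ...) {
  cat(sprintf("<tick_host_network> ecosystem %s: %d ticks, %d hosts, %d edges\n",
              as.character(x$ecosystem_id), length(x$ticks), length(x$hosts),
              nrow(x$edges)))
  invisible(x)
}

# Drop all-zero rows/columns and sort by decreasing marginal totals.
prepare_nested <- function(m) {
  m <- as.matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(NULL)
  m[order(rowSums(m), decreasing = TRUE),
    order(colSums(m), decreasing = TRUE), drop = FALSE]
}

#' Nestedness by overlap and decreasing fill (NODF)
#'
#' For every ordered pair of rows (and of columns) with strictly
#' decreasing fills, the paired overlap is the percentage of the sparser
#' line's presences that also occur in the denser line; pairs with equal
#' fills contribute 0. NODF is the mean paired overlap across all row
#' pairs and column pairs, in `[0, 100]`.
#'
#' @param m incidence matrix (any positive entry counts as a presence).
#' @return NODF, or `NA` when fewer than 2 non-empty rows or columns
#'   remain.
#' @export
nodf <- function(m) {
  b <- prepare_nested((as.matrix(m) > 0) * 1)
  if (is.null(b)) return(NA_real_)
  pair_sum <- function(mat) {
    fills <- rowSums(mat)
    n <- nrow(mat)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (fills[i] > fills[j]) {
        tot <- tot + 100 * sum(mat[i, ] * mat[j, ]) / fills[j]
      }
    }
    tot
  }
  n_pairs <- choose(nrow(b), 2) + choose(ncol(b), 2)
  as.numeric(pair_sum(b) + pair_sum(t(b))) / n_pairs
}

#' Weighted NODF
#'
#' Weighted analogue of [nodf()]: for a pair of lines with strictly
#' decreasing marginal totals, a cell of the sparser line qualifies when
#' it is nonzero, nonzero in the denser line, and strictly smaller than
#' the denser line's weight in that position; the paired term is the
#' percentage of qualifying cells among the sparser line's nonzero cells.
#' Uniform equal weights therefore score 0 (no strict inequality).
#'
#' @param m nonnegative weighted incidence matrix.
#' @return weighted NODF in `[0, 100]`, or `NA` as in [nodf()].
#' @export
wnodf <- function(m) {
  w <- prepare_nested(as.matrix(m))
  if (is.null(w)) return(NA_real_)
  pair_sum <- function(mat) {
    tot_w <- rowSums(mat)
    n <- nrow(mat)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (tot_w[i] > tot_w[j]) {
        nz <- mat[j, ] > 0
        if (any(nz)) {
          qual <- mat[i, nz] > mat[j, nz]   # implies mat[i, ] > 0 too
          tot <- tot + 100 * sum(qual) / sum(nz)
        }
      }
    }
    tot
  }
  n_pairs <- choose(nrow(w), 2) + choose(ncol(w), 2)
  as.numeric(pair_sum(w) + pair_sum(t(w))) / n_pairs
}

#' Barber bipartite modularity of a given module assignment
#'
#' `Q = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(g_i, h_j)` over
#' tick x host pairs, with `m` the total edge weight and `k`, `d` the
#' weighted degrees.
#'
#' @param incidence weighted ticks x hosts matrix.
#' @param row_modules,col_modules integer module labels for rows/columns.
#' @return modularity Q.
#' @export
barber_q <- function(incidence, row_modules, col_modules) {
  A <- as.matrix(incidence)
  m <- sum(A)
  if (m <= 0) stop("network has no edges")
  k <- rowSums(A); d <- colSums(A)
  B <- A - outer(k, d) / m
  delta <- outer(row_modules, col_modules, "==")
  sum(B * delta) / m
}

#' Maximise Barber bipartite modularity by label moves
#'
#' Greedy label optimisation: nodes are visited in a fixed order and moved
#' to the module that maximises Q (lowest label wins on ties) until no
#' move improves Q, repeated over `n_restarts` seeded random initial
#' assignments plus one deterministic start; the best partition found is
#' returned. Reproducibility is favoured over global optimality.
#'
#' @param net a `tick_host_network` with at least one edge.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @param max_iter sweep limit per restart (default 100).
#' @return list with `q`, `row_modules`, `col_modules`.
#' @export
bipartite_modularity <- function(net, seed = 1L, n_restarts = 10, max_iter = 100) {
  A <- net$incidence
  m <- sum(A)
  if (m <= 0) stop("network has no edges; modularity undefined")
  R <- nrow(A); C <- ncol(A)
  k <- rowSums(A); d <- colSums(A)
  B <- A - outer(k, d) / m

  refine <- function(g, h) {
    for (iter in seq_len(max_iter)) {
      changed <- FALSE
      mods <- sort(unique(c(g, h)))
      for (i in seq_len(R)) {        # move rows to best column-module
        gains <- vapply(mods, function(c_) sum(B[i, h == c_]), 0)
        best <- mods[which.max(gains)]
        if (best != g[i] && max(gains) > gains[match(g[i], mods)] + 1e-12) {
          g[i] <- best; changed <- TRUE
        }
      }
      mods <- sort(unique(c(g, h)))
      for (j in seq_len(C)) {
        gains <- vapply(mods, function(c_) sum(B[g == c_, j]), 0)
        best <- mods[which.max(gains)]
        if (best != h[j] && max(gains) > gains[match(h[j], mods)] + 1e-12) {
          h[j] <- best; changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(g = g, h = h, q = barber_q(A, g, h))
  }

  best <- refine(seq_len(R), R + seq_len(C))   # deterministic start
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      n_mod <- max(2L, min(R, C))
      cand <- refine(sample.int(n_mod, R, replace = TRUE),
                     sample.int(n_mod, C, replace = TRUE))
      if (cand$q > best$q + 1e-12) best <- cand
    }
  })
  list(q = best$q,
       row_modules = stats::setNames(best$g, net$ticks),
       col_modules = stats::setNames(best$h, net$hosts))
}

#' Null-model significance of a network metric
#'
#' Proportional (degree-informed probabilistic) null model: each cell of
#' the binary incidence is filled independently with probability
#' `p_ij = (r_i / C + c_j / R) / 2`, where `r_i`, `c_j` are the observed
#' row/column incidence counts. For weighted metrics the observed positive
#' weights are resampled onto the filled cells. The upper-tail p-value
#' uses the add-one correction `p = (1 + #[null >= obs]) / (n_valid + 1)`,
#' so p is never 0.
#'
#' @param m observed (weighted or binary) incidence matrix.
#' @param metric `"nodf"`, `"wnodf"` or `"modularity"`.
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed.
#' @param model only `"proportional"`.
#' @param p_matrix optional known cell-fill probability matrix; by default
#'   the proportional probabilities are estimated from the observed
#'   margins (supply the generating probabilities in calibration studies,
#'   where estimating them from each draw is conservative).
#' @return list with `observed`, `null_mean`, `null_sd`, `z` (`NA` when
#'   the null distribution is degenerate), `p_value`, `n_valid`, `seed`.
#' @export
null_significance <- function(m, metric = c("nodf", "wnodf", "modularity"),
                              n_null = 999, seed = 1L,
                              model = "proportional", p_matrix = NULL) {
  metric <- match.arg(metric)
  model <- match.arg(model, "proportional")
  if (n_null < 99) stop("n_null must be at least 99")
  m <- as.matrix(m)
  b <- (m > 0) * 1
  R <- nrow(b); C <- ncol(b)
  p_ij <- if (is.null(p_matrix)) {
    (outer(rowSums(b) / C, rep(1, C)) +
     outer(rep(1, R), colSums(b) / R)) / 2
  } else {
    stopifnot(all(dim(p_matrix) == c(R, C)), all(p_matrix >= 0 & p_matrix <= 1))
    p_matrix
  }
  weights_pool <- m[m > 0]
  eval_metric <- function(x) {
    switch(metric,
      nodf = nodf(x),
      wnodf = wnodf(x),
      modularity = {
        net <- structure(list(incidence = x, ticks = rownames(x) %||% as.character(seq_len(nrow(x))),
                              hosts = colnames(x) %||% as.character(seq_len(ncol(x)))),
                         class = "tick_host_network")
        if (sum(x) <= 0) NA_real_ else bipartite_modularity(net, seed = 1L, n_restarts = 5)$q
      })
  }
  observed <- eval_metric(m)
  if (is.na(observed)) stop("observed metric undefined for this matrix")
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      fill <- matrix(stats::runif(R * C) < p_ij, R, C) * 1
      x <- fill
      if (metric != "nodf" && sum(fill) > 0) {
        x[fill > 0] <- sample(weights_pool, sum(fill), replace = TRUE)
      }
      tryCatch(eval_metric(x), error = function(e) NA_real_)
    }, 0)
  })
  valid <- nulls[!is.na(nulls)]
  n_valid <- length(valid)
  if (n_valid < 1) stop("all null replicates degenerate")
  null_sd <- stats::sd(valid)
  list(observed = observed, null_mean = mean(valid), null_sd = null_sd,
       z = if (null_sd > 0) (observed - mean(valid)) / null_sd else NA_real_,
       p_value = (1 + sum(valid >= observed)) / (n_valid + 1),
       n_valid = n_valid, metric = metric, seed = seed)
}
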