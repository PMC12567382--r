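# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately naive (normal equations, O(n^3) scans, exhaustive
# enumeration) and never call the implementation paths they check.

quiet_fit_sdm <- function(...) suppressWarnings(fit_sdm_ensemble(...))

small_grid <- function(n = 20, seed = 42, noise_sd = NULL) {
  make_climate_grid(n, n, seed = seed, noise_sd = noise_sd)
}

small_system <- function(n = 20, seed = 42, n_ticks = 2, n_hosts = 4,
                         breadth_scale = 0.6) {
  grid <- small_grid(n, seed)
  stack <- build_predictors(grid)
  taxa <- make_virtual_taxa(stack, n_ticks, n_hosts, seed = seed + 1,
                            breadth_scale = breadth_scale)
  truth <- synthetic_truth(taxa, stack)
  list(grid = grid, stack = stack, taxa = taxa, truth = truth)
}

# --- harmonic regression oracle: explicit normal equations -------------
oracle_harmonics <- function(y) {
  m <- 1:12
  X <- cbind(1, cos(2 * pi * m / 12), sin(2 * pi * m / 12))
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# --- convex hull oracle: O(n^3) hull-edge scan -------------------------
# Directed pair (i, j) is a hull edge iff every other point lies on its
# left; the union of endpoints of hull edges is the extreme-point set.
oracle_extreme_points <- function(pts) {
  n <- nrow(pts)
  extreme <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    side <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
            (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(side[-c(i, j)] >= -1e-9)) {
      extreme[i] <- TRUE
      extreme[j] <- TRUE
    }
  }
  extreme
}

# --- Monte-Carlo polygon intersection area -----------------------------
mc_intersection_area <- function(h1, h2, n_pts = 1e5, seed = 1) {
  v <- rbind(h1$vertices, h2$vertices)
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  box <- prod(hi - lo)
  set.seed(seed)
  x <- runif(n_pts, lo[1], hi[1]); y <- runif(n_pts, lo[2], hi[2])
  inside <- function(h, x, y) {
    vv <- h$vertices; n <- nrow(vv); ok <- rep(TRUE, length(x))
    for (i in seq_len(n)) {
      a <- vv[i, ]; b <- vv[if (i == n) 1 else i + 1, ]
      ok <- ok & ((b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1]) >= -1e-12)
    }
    ok
  }
  hit <- inside(h1, x, y) & inside(h2, x, y)
  p <- mean(hit)
  list(area = box * p, se = box * sqrt(p * (1 - p) / n_pts))
}

# --- NODF oracle: literal paired-overlap definition --------------------
oracle_nodf <- function(m) {
  m <- (as.matrix(m) > 0) * 1
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(NA_real_)
  m <- m[order(rowSums(m), decreasing = TRUE),
         order(colSums(m), decreasing = TRUE), drop = FALSE]
  terms <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    terms <- c(terms,
               if (sum(m[i, ]) > sum(m[j, ]))
                 100 * sum(m[i, ] & m[j, ]) / sum(m[j, ]) else 0)
  }
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    terms <- c(terms,
               if (sum(m[, i]) > sum(m[, j]))
                 100 * sum(m[, i] & m[, j]) / sum(m[, j]) else 0)
  }
  mean(terms)
}

# --- exhaustive Barber modularity oracle -------------------------------
# Enumerates every partition of the R + C nodes (restricted growth
# strings) and returns the maximal Q.
oracle_max_modularity <- function(A) {
  R <- nrow(A); C <- ncol(A); n <- R + C
  m <- sum(A); k <- rowSums(A); d <- colSums(A)
  B <- A - outer(k, d) / m
  best <- -Inf
  assign_next <- function(labels, pos, n_used) {
    if (pos > n) {
      g <- labels[seq_len(R)]; h <- labels[R + seq_len(C)]
      q <- sum(B * outer(g, h, "==")) / m
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(n_used + 1)) {
      labels[pos] <- lab
      assign_next(labels, pos + 1, max(n_used, lab))
    }
  }
  assign_next(integer(n), 1, 0)
  best
}

# --- exhaustive Mantel enumeration -------------------------------------
oracle_mantel_p <- function(d1, d2) {
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut])
  perms <- nicheweave:::all_permutations(nrow(d1))
  hits <- vapply(perms, function(p) {
    abs(cor(d1[ut], d2[p, p][ut])) >= abs(r_obs) - 1e-12
  }, TRUE)
  mean(hits)
}

# Kruskal stress-1 of a configuration against target distances, using
# isotonic regression of configuration distances on target ranks.
stress1 <- function(coords, d) {
  dhat <- as.matrix(dist(coords))
  ut <- upper.tri(d)
  dv <- d[ut]; cv <- dhat[ut]
  ord <- order(dv)
  fit <- isoreg(cv[ord])$yf
  sqrt(sum((cv[ord] - fit)^2) / sum(cv^2))
}
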