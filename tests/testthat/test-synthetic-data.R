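test_that("zero-noise climate grid reproduces its generating harmonic exactly", {
  bands <- list(only = list(tmax = c(20, 5, -2), tmin = c(8, 4, -1),
                            vpd = c(1.2, 0.5, -0.1)))
  g <- make_climate_grid(4, 4, seed = 1, regional_harmonics = bands,
                         noise_sd = 0, continentality = c(tmax = 0, tmin = 0, vpd = 0))
  m <- 1:12
  expected <- 20 + 5 * cos(2 * pi * m / 12) - 2 * sin(2 * pi * m / 12)
  for (cell in c(1, 7, 16)) {
    expect_equal(unname(g$values$tmax[cell, ]), expected, tolerance = 1e-12)
  }
})

test_that("climate grids are bit-identical under the same seed", {
  g1 <- make_climate_grid(10, 12, seed = 7)
  g2 <- make_climate_grid(10, 12, seed = 7)
  expect_identical(g1$values, g2$values)
  g3 <- make_climate_grid(10, 12, seed = 8)
  expect_false(identical(g1$values, g3$values))
})

test_that("band-mean a0 difference matches the configured band difference", {
  bands <- default_harmonics()
  g <- make_climate_grid(50, 50, seed = 3, regional_harmonics = bands)
  st <- build_predictors(g)
  north_rows <- cell_centers(g$geom)$row <= 25
  a0 <- st$coef[, "tmax_a0"]
  observed <- mean(a0[!north_rows]) - mean(a0[north_rows])
  configured <- bands$south$tmax[1] - bands$north$tmax[1]
  # noise SE of a band mean of fitted a0 over 1250 cells
  se <- g$noise_sd[["tmax"]] / sqrt(12) * sqrt(2 / 1250)
  expect_lt(abs(observed - configured), 3 * se + 1e-9)
})

test_that("non-finite harmonic parameters are rejected", {
  bad <- list(b = list(tmax = c(NA, 1, 1), tmin = c(1, 1, 1), vpd = c(1, 1, 1)))
  expect_error(make_climate_grid(4, 4, 1, regional_harmonics = bad), "finite")
})

test_that("ecosystem maps partition the grid", {
  g <- small_grid(4)
  expect_error(make_ecosystem_map(g, 1), "at least 2")
  expect_error(make_ecosystem_map(g, 17), "exceeds")
  eco <- make_ecosystem_map(g, 2, "latitudinal_bands")
  expect_equal(as.integer(table(eco$labels)), c(8L, 8L))
  eco5 <- make_ecosystem_map(small_grid(10), 5, "latitudinal_bands")
  expect_equal(sum(table(eco5$labels)), 100)
  expect_true(all(table(eco5$labels) > 0))
})

test_that("kmeans ecosystems recover well-separated latitudinal bands", {
  bands <- default_harmonics()
  g <- make_climate_grid(20, 20, seed = 5, regional_harmonics = bands,
                         noise_sd = 0.05,
                         continentality = c(tmax = 0, tmin = 0, vpd = 0))
  truth_lab <- make_ecosystem_map(g, 2, "latitudinal_bands")$labels
  km_lab <- make_ecosystem_map(g, 2, "kmeans_on_climate", seed = 9)$labels
  agreement <- max(mean(km_lab == truth_lab), mean(km_lab == 3 - truth_lab))
  expect_gte(agreement, 0.95)
})

test_that("occurrence sampling has degenerate, deterministic and CLT behaviour", {
  sys <- small_system(40, seed = 11)
  stack <- sys$stack
  # degenerate support: suitability positive on exactly one cell
  t1 <- sys$taxa[[1]]
  tr <- sys$truth
  one_cell <- which.max(tr$suitability[, t1$taxon_id])
  tr1 <- tr
  tr1$suitability[, t1$taxon_id] <- 0
  tr1$suitability[one_cell, t1$taxon_id] <- 1
  occ1 <- sample_occurrences(t1, tr1, 25, seed = 2)
  expect_true(all(occ1$cell_id == one_cell))
  # all-zero suitability rejected
  tr0 <- tr
  tr0$suitability[, t1$taxon_id] <- 0
  expect_error(sample_occurrences(t1, tr0, 5, seed = 2), "all-zero")
  # determinism
  oa <- sample_occurrences(t1, tr, 100, seed = 31)
  ob <- sample_occurrences(t1, tr, 100, seed = 31)
  expect_identical(oa, ob)
  expect_false(identical(oa, sample_occurrences(t1, tr, 100, seed = 32)))
  # records lie inside the grid extent
  geom <- stack$geom
  expect_true(all(oa$lon > geom$origin[1] &
                  oa$lon < geom$origin[1] + geom$n_cols * geom$cellsize))
  expect_true(all(oa$lat > geom$origin[2] &
                  oa$lat < geom$origin[2] + geom$n_rows * geom$cellsize))
  # CLT: the sample mean of the records' predictor vectors converges to
  # the generator's sampling expectation sum(x * s) / sum(s)
  centered <- virtual_taxon("centered", "tick",
                            predictor_matrix(stack)[800, ],
                            (0.35 * apply(stack$coef, 2, sd))^2, 1)
  trc <- synthetic_truth(c(sys$taxa, list(centered)), stack)
  occ <- sample_occurrences(centered, trc, 500, seed = 13)
  x <- predictor_matrix(stack, occ$cell_id)
  s <- trc$suitability[, "centered"]
  expected <- colSums(predictor_matrix(stack) * s) / sum(s)
  for (j in c("tmax_a0", "tmin_a0", "vpd_a0")) {
    se <- sd(x[, j]) / sqrt(nrow(x))
    expect_lt(abs(mean(x[, j]) - expected[[j]]), 3 * se + 1e-8)
  }
  # and the expectation itself sits close to the niche center, relative
  # to the niche breadth in that predictor
  for (j in c("tmax_a0", "tmin_a0", "vpd_a0")) {
    k <- match(j, colnames(x))
    expect_lt(abs(expected[[j]] - centered$niche_center[k]),
              sqrt(centered$niche_breadth[k, k]))
  }
})

test_that("virtual taxon invariants hold", {
  expect_error(virtual_taxon("a", "tick", 1:3, c(1, -1, 1)), "positive")
  expect_error(virtual_taxon("a", "tick", 1:3, c(1, 1, 1), 0), "max_prevalence")
  sys <- small_system()
  expect_true(all(sys$truth$suitability >= 0 & sys$truth$suitability <= 1,
                  na.rm = TRUE))
})

test_that("true overlap is 100 for identical niches and decreases with separation", {
  stack <- build_predictors(small_grid(30, seed = 21))
  sds <- apply(stack$coef, 2, sd)
  base <- predictor_matrix(stack)[435, ]
  breadth <- (0.4 * pmax(sds, 1e-8))^2
  tick <- virtual_taxon("t", "tick", base, breadth, 0.8)
  twin <- virtual_taxon("h0", "host", base, breadth, 0.5)  # different prevalence
  seps <- seq(0.05, 0.35, by = 0.05)
  hosts <- lapply(seq_along(seps), function(i) {
    virtual_taxon(paste0("h", i), "host", base + seps[i] * sds, breadth, 0.8)
  })
  tr <- synthetic_truth(c(list(tick, twin), hosts), stack)
  ov <- tr$true_pairwise_overlap["t", ]
  expect_equal(unname(ov["h0"]), 100)
  expect_true(all(diff(ov[paste0("h", seq_along(seps))]) < 0))
})

test_that("Yule phylogenies have the forced shape and round-trip via Newick", {
  expect_error(make_phylogeny(c("a", "a"), 1), "duplicate")
  expect_error(make_phylogeny("a", 1), "at least 2")
  cherry <- make_phylogeny(c("a", "b"), seed = 4)
  expect_equal(ape::Ntip(cherry), 2)
  expect_equal(cherry$Nnode, 1)
  expect_true(all(cherry$edge.length > 0))
  for (n in c(5, 17)) {
    tr <- make_phylogeny(paste0("t", seq_len(n)), seed = n)
    expect_equal(tr$Nnode, n - 1)  # binary rooted
  }
  for (i in 1:20) {
    tr <- make_phylogeny(paste0("x", 1:8), seed = 100 + i)
    back <- parse_newick(write_newick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(back)
    expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
  }
})

test_that("lambda-scaled trait simulation matches its covariance contract", {
  tree <- make_phylogeny(paste0("s", 1:12), seed = 2)
  expect_error(simulate_bm_trait(tree, 1.2, 1, 1), "lambda")
  expect_error(simulate_bm_trait(tree, 0.5, 0, 1), "sigma2")
  a <- simulate_bm_trait(tree, 0.7, 1, seed = 5)
  expect_identical(a, simulate_bm_trait(tree, 0.7, 1, seed = 5))
  # lambda 0: tips i.i.d.; mean inter-tip sample covariance shrinks to 0
  reps <- t(sapply(1:300, function(i) simulate_bm_trait(tree, 0, 1, seed = i)))
  cv <- cov(reps)
  off <- cv[upper.tri(cv)]
  expect_lt(mean(abs(off)), 3 * mean(diag(cv)) / sqrt(300))
})
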