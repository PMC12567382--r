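square_hull <- function(x0 = 0, y0 = 0, side = 1) {
  convex_hull(rbind(c(x0, y0), c(x0 + side, y0),
                    c(x0 + side, y0 + side), c(x0, y0 + side)))
}

test_that("PCA space matches a brute-force eigendecomposition", {
  set.seed(31)
  x <- matrix(rnorm(200 * 9), ncol = 9,
              dimnames = list(NULL, paste0("p", 1:9)))
  x[, 5] <- x[, 1] * 2 + rnorm(200, sd = 0.3)
  sp <- fit_pca(x, k = 9)
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(sp$explained_all, ev / sum(ev), tolerance = 1e-8)
  expect_equal(crossprod(sp$loadings), diag(9), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank projection and back-projection reproduce the scaled data
  z <- project_pca(sp, x)
  back <- z %*% t(sp$loadings)
  expect_equal(back, scale(x), tolerance = 1e-8, ignore_attr = TRUE)
  # explained fractions nonincreasing and summing to <= 1
  expect_true(all(diff(sp$explained_all) <= 1e-12))
  expect_lte(sum(sp$explained), 1 + 1e-12)
})

test_that("PCA handles rank-1 data and zero-variance columns", {
  t_lin <- seq(-2, 2, length.out = 50)
  x <- outer(t_lin, c(1, -2, 0.5, 3, 1, 1, -1, 2, 0.1))
  colnames(x) <- paste0("p", 1:9)
  sp <- fit_pca(x + 0, k = 2)
  expect_equal(sp$explained[1], 1, tolerance = 1e-10)
  x2 <- x
  x2[, 3] <- 7  # constant column
  expect_warning(fit_pca(x2, k = 2), "zero-variance")
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(sp$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
})

test_that("convex hulls match known polygons and the O(n^3) oracle", {
  set.seed(32)
  sq <- convex_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                          matrix(runif(20, 0.2, 0.8), ncol = 2)))
  expect_false(sq$degenerate)
  expect_equal(sq$area, 1)
  expect_equal(nrow(sq$vertices), 4)
  expect_equal(sq$n_source_points, 14)
  # shoelace consistency on the stored vertices
  expect_equal(abs(nicheweave:::shoelace_area(sq$vertices)), sq$area)
  # degenerate cases
  expect_true(convex_hull(rbind(c(0, 0), c(1, 1)))$degenerate)
  expect_true(convex_hull(cbind(1:5, 2 * (1:5)))$degenerate)
  # rotation invariance
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- matrix(rnorm(60), ncol = 2)
  expect_equal(convex_hull(pts %*% R)$area, convex_hull(pts)$area,
               tolerance = 1e-9)
  # extreme-point oracle on random clouds
  for (i in 1:5) {
    pts <- matrix(rnorm(200), ncol = 2)
    h <- convex_hull(pts)
    ext <- oracle_extreme_points(pts)
    hull_set <- apply(h$vertices, 1, paste, collapse = ",")
    oracle_set <- apply(pts[ext, , drop = FALSE], 1, paste, collapse = ",")
    expect_setequal(hull_set, oracle_set)
  }
})

test_that("hull intersection agrees with analytic clipping and Monte Carlo", {
  a <- square_hull(0, 0)
  b <- square_hull(0.5, 0.5)
  expect_equal(hull_intersection_area(a, a), 1, tolerance = 1e-12)
  expect_equal(hull_intersection_area(a, b), 0.25, tolerance = 1e-12)
  far <- square_hull(5, 5)
  expect_equal(hull_intersection_area(a, far), 0)
  # random hull pairs vs Monte-Carlo point-in-polygon
  set.seed(33)
  for (i in 1:10) {
    h1 <- convex_hull(matrix(rnorm(40), ncol = 2))
    h2 <- convex_hull(matrix(rnorm(40, mean = 0.5), ncol = 2))
    mc <- mc_intersection_area(h1, h2, n_pts = 1e5, seed = i)
    expect_lt(abs(hull_intersection_area(h1, h2) - mc$area),
              3 * mc$se + 1e-6)
  }
})

test_that("Jaccard overlap handles identity, disjoint and shifted squares", {
  a <- square_hull(0, 0)
  expect_equal(jaccard_overlap(a, a), 100)
  expect_equal(jaccard_overlap(a, square_hull(3, 3)), 0)
  expect_equal(jaccard_overlap(a, square_hull(0.5, 0.5)),
               100 * 0.25 / 1.75, tolerance = 1e-9)
  deg <- convex_hull(rbind(c(0, 0), c(1, 1)))
  expect_equal(jaccard_overlap(a, deg), 0)
  expect_true(is.na(jaccard_overlap(deg, deg)))
  # symmetry over random pairs
  set.seed(34)
  for (i in 1:10) {
    h1 <- convex_hull(matrix(rnorm(30), ncol = 2))
    h2 <- convex_hull(matrix(rnorm(30, 0.3), ncol = 2))
    expect_equal(jaccard_overlap(h1, h2), jaccard_overlap(h2, h1),
                 tolerance = 1e-9)
    expect_true(jaccard_overlap(h1, h2) >= 0 && jaccard_overlap(h1, h2) <= 100)
  }
  # growing one hull toward covering the other never decreases overlap
  inner <- lapply(seq(0.2, 1, by = 0.2), function(s) {
    convex_hull(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  })
  ov <- vapply(inner, jaccard_overlap, 0, h2 = a)
  expect_true(all(diff(ov) >= -1e-12))
})

test_that("niche points honour the presence-and-ecosystem intersection", {
  sys <- small_system(15, seed = 41)
  eco <- make_ecosystem_map(sys$grid, 2)
  space <- fit_pca(predictor_matrix(sys$stack), k = 2)
  nc <- n_cells(sys$stack$geom)
  bm <- structure(list(geom = sys$stack$geom, values = rep(1, nc),
                       taxon_id = "t"), class = "binary_map")
  # all present, one ecosystem -> all that ecosystem's cells
  pts <- taxon_niche_points(bm, eco, 1, space, sys$stack)
  expect_equal(nrow(pts), length(ecosystem_cells(eco, 1)))
  # absent taxon -> empty set
  bm0 <- bm; bm0$values[] <- 0
  expect_equal(nrow(taxon_niche_points(bm0, eco, 1, space, sys$stack)), 0)
  # brute-force cell scan
  set.seed(42)
  bm$values <- rbinom(nc, 1, 0.4)
  expected <- sum(bm$values == 1 & eco$labels == 2)
  expect_equal(nrow(taxon_niche_points(bm, eco, 2, space, sys$stack)), expected)
})

test_that("ecosystem overlap matrices compose pairwise Jaccard calls", {
  sys <- small_system(20, seed = 43, n_ticks = 2, n_hosts = 3,
                      breadth_scale = 0.45)
  eco <- make_ecosystem_map(sys$grid, 2)
  space <- fit_pca(predictor_matrix(sys$stack), k = 2)
  nc <- n_cells(sys$stack$geom)
  mk_bm <- function(cells) {
    v <- rep(0, nc); v[cells] <- 1
    structure(list(geom = sys$stack$geom, values = v), class = "binary_map")
  }
  set.seed(44)
  ticks <- list(tA = mk_bm(sample(nc, 150)), tB = mk_bm(sample(nc, 150)))
  hosts <- list(hA = mk_bm(sample(nc, 150)), hB = mk_bm(sample(nc, 150)),
                hC = mk_bm(integer(0)))   # absent host
  om <- ecosystem_overlap_matrix(ticks, hosts, eco, 1, space, sys$stack)
  expect_true(all(is.na(om$values[, "hC"])))
  for (t in names(ticks)) for (h in c("hA", "hB")) {
    h1 <- convex_hull(taxon_niche_points(ticks[[t]], eco, 1, space, sys$stack))
    h2 <- convex_hull(taxon_niche_points(hosts[[h]], eco, 1, space, sys$stack))
    expect_equal(om$values[t, h], jaccard_overlap(h1, h2), tolerance = 1e-9)
  }
  # identical tick and host niches give exactly 100
  om_id <- ecosystem_overlap_matrix(list(t1 = ticks$tA), list(h1 = ticks$tA),
                                    eco, 1, space, sys$stack)
  expect_equal(unname(om_id$values[1, 1]), 100)
  # all hosts absent -> error naming the ecosystem
  expect_error(
    ecosystem_overlap_matrix(ticks, list(h = mk_bm(integer(0))), eco, 1,
                             space, sys$stack),
    "ecosystem 1")
})

test_that("biotic suitability averages only the defined row cells", {
  om <- structure(list(
    ecosystem_id = 1,
    values = matrix(c(100, 0, 40, NA), 2, 2, byrow = TRUE,
                    dimnames = list(c("t1", "t2"), c("h1", "h2")))),
    class = "overlap_matrix")
  om$defined <- !is.na(om$values)
  expect_equal(biotic_suitability(om, "t1"), 50)
  expect_equal(biotic_suitability(om, "t2"), 40)
  om$values["t2", ] <- NA
  expect_true(is.na(biotic_suitability(om, "t2")))
  expect_error(biotic_suitability(om, "zz"), "unknown tick")
})

test_that("overlap matrices round-trip through CSV with undefined cells", {
  vals <- matrix(c(12.5, NA, 88, 3), 2, 2,
                 dimnames = list(c("t1", "t2"), c("h1", "h2")))
  om <- structure(list(ecosystem_id = 2, values = vals, defined = !is.na(vals)),
                  class = "overlap_matrix")
  p <- tempfile(fileext = ".csv")
  write_overlap_matrix(om, p)
  back <- read_overlap_matrix(p, ecosystem_id = 2)
  expect_equal(back$values, vals)
  unlink(p)
})
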