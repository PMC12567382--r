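make_labelled <- function(n_per = 60, sep = 3, seed = 1) {
  # separable along the first predictor, noise elsewhere
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * 9), ncol = 9)
  colnames(x) <- paste0("p", 1:9)
  x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + sep
  out <- data.frame(cell_id = seq_len(2 * n_per), x,
                    label = rep(c(1L, 0L), each = n_per),
                    partition = NA_character_, check.names = FALSE)
  class(out) <- c("labelled_points", class(out))
  out
}

test_that("pseudo-absences pair presences one to one and never collide", {
  sys <- small_system(15, seed = 3)
  occ <- sample_occurrences(sys$taxa[[1]], sys$truth, 50, seed = 4)
  pts <- generate_pseudo_absences(occ, sys$stack, seed = 5)
  expect_equal(sum(pts$label == 0), 50)
  expect_equal(sum(pts$label == 1), 50)
  for (s in c(5, 6, 99)) {
    p <- generate_pseudo_absences(occ, sys$stack, seed = s)
    expect_length(intersect(p$cell_id[p$label == 0], occ$cell_id), 0)
  }
  expect_identical(generate_pseudo_absences(occ, sys$stack, 5),
                   generate_pseudo_absences(occ, sys$stack, 5))
  # grid fully occupied -> no candidates
  occ_all <- data.frame(taxon_id = "t", role = "tick",
                        lon = NA, lat = NA,
                        cell_id = seq_len(n_cells(sys$stack$geom)))
  expect_error(generate_pseudo_absences(occ_all, sys$stack, 1), "insufficient")
})

test_that("train/test split is stratified, exact and a true partition", {
  pts <- make_labelled(100)
  sp <- split_records(pts, 0.7, seed = 2)
  for (lab in 0:1) {
    expect_equal(sum(sp$partition == "train" & sp$label == lab), 70)
    expect_equal(sum(sp$partition == "test" & sp$label == lab), 30)
  }
  expect_setequal(which(sp$partition == "train"),
                  setdiff(seq_len(nrow(sp)), which(sp$partition == "test")))
  expect_error(split_records(pts, 1.0), "strictly inside")
  expect_error(split_records(pts, 0), "strictly inside")
  one <- pts[c(1, 101, 102), ]
  expect_error(split_records(one, 0.7), "fewer than 2")
})

test_that("every learner separates a separable fixture and respects [0,1]", {
  pts <- split_records(make_labelled(80, sep = 6), 0.7, seed = 3)
  train <- pts[pts$partition == "train", ]
  test <- pts[pts$partition == "test", ]
  cols <- setdiff(names(pts), c("cell_id", "label", "partition"))
  set.seed(10)
  queries <- matrix(rnorm(1000 * 9, sd = 3), ncol = 9,
                    dimnames = list(NULL, cols))
  for (lr in c("smooth_additive", "adaptive_hinge", "kernel_margin")) {
    fit <- suppressWarnings(fit_learner(train, lr, seed = 6))
    m <- confusion_metrics(predict(fit, test[, cols]), test$label, 0.5)
    expect_gte(m[["sensitivity"]], 0.95)
    expect_gte(m[["specificity"]], 0.95)
    q <- predict(fit, queries)
    expect_true(all(q >= 0 & q <= 1))
  }
  const <- train
  const$label <- 1L
  expect_error(fit_learner(const, "smooth_additive"), "both labels")
  degen <- train
  for (cc in cols) degen[[cc]] <- 1
  expect_error(suppressWarnings(fit_learner(degen, "smooth_additive")), "degenerate")
})

test_that("confusion metrics follow the stated formulas", {
  perfect <- confusion_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect[["sensitivity"]], 1)
  expect_equal(perfect[["specificity"]], 1)
  expect_equal(perfect[["kappa"]], 1)
  # TP=40, FN=10, FP=5, TN=45
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 5), rep(0.1, 45))
  labels <- c(rep(1, 50), rep(0, 50))
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.9)
  expect_equal(m[["omission_rate"]], 0.2)
  expect_equal(m[["proportion_correct"]], 0.85)
  expect_equal(m[["kappa"]], 0.7)
  expect_equal(m[["omission_rate"]], 1 - m[["sensitivity"]])
  expect_error(confusion_metrics(numeric(0), numeric(0), 0.5), "no records")
})

test_that("confusion metrics agree with a brute-force count on random fixtures", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    scores <- runif(n)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    th <- runif(1)
    m <- confusion_metrics(scores, labels, th)
    pred <- scores >= th
    expect_equal(m[["tp"]], sum(pred & labels == 1))
    expect_equal(m[["tn"]], sum(!pred & labels == 0))
    expect_equal(m[["sensitivity"]], sum(pred & labels == 1) / sum(labels == 1))
    expect_equal(m[["proportion_correct"]],
                 mean(pred == (labels == 1)))
  }
})

test_that("label-independent scores give kappa near zero", {
  set.seed(15)
  ks <- replicate(200, {
    n <- 400
    confusion_metrics(runif(n), rbinom(n, 1, 0.5), 0.5)[["kappa"]]
  })
  expect_lt(abs(mean(ks)), 3 / sqrt(200 * 400) * 20)  # generous CLT bound
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("kappa-weighted ensembling is a convex weighted mean", {
  sys <- small_system(10, seed = 8)
  mk_member <- function(score, kappa) {
    fake <- structure(list(learner = "fake", fit = score,
                           columns = colnames(sys$stack$coef)),
                      class = c("fake_learner", "sdm_learner"))
    list(model = fake, metrics = c(kappa = kappa))
  }
  # local predict for the fake constant-score learner
  assign("predict.fake_learner",
         function(object, newdata, ...) rep(object$fit, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.fake_learner", envir = globalenv()))
  one <- ensemble_suitability(list(mk_member(0.8, 0.6)), sys$stack)
  expect_equal(unique(one$values[sys$stack$mask]), 0.8)
  two <- ensemble_suitability(list(mk_member(0.8, 0.6), mk_member(0.4, 0.2)),
                              sys$stack, retain_kappa = 0.1)
  expect_equal(unique(two$values[sys$stack$mask]),
               (0.8 * 0.6 + 0.4 * 0.2) / 0.8)
  expect_true(all(two$values[sys$stack$mask] >= 0.4 &
                  two$values[sys$stack$mask] <= 0.8))
  expect_error(ensemble_suitability(list(mk_member(0.8, 0.1)), sys$stack),
               "no member retained")
})

test_that("max-TSS binarisation picks the midpoint threshold", {
  sys <- small_system(10, seed = 9)
  map <- structure(list(geom = sys$stack$geom,
                        values = rep(0.5, n_cells(sys$stack$geom)),
                        taxon_id = "t"),
                   class = "suitability_map")
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.6)
  map$values[1:6] <- scores
  test_pts <- data.frame(cell_id = 1:6, label = c(1, 1, 1, 0, 0, 0))
  bm <- binarize(map, test_pts)
  expect_equal(bm$threshold, 0.65)
  expect_equal(bm$tss, 1)
  # shifting all scores shifts the threshold, TSS unchanged
  map2 <- map
  map2$values <- map$values + 0.05
  bm2 <- binarize(map2, test_pts)
  expect_equal(bm2$threshold, 0.70)
  expect_equal(bm2$tss, 1)
  map3 <- map
  map3$values[] <- 0.4
  expect_error(binarize(map3, test_pts), "all test scores equal")
})

test_that("max TSS is near zero when labels are shuffled", {
  sys <- small_system(10, seed = 10)
  map <- structure(list(geom = sys$stack$geom,
                        values = runif(n_cells(sys$stack$geom)),
                        taxon_id = "t"),
                   class = "suitability_map")
  set.seed(44)
  tss <- replicate(100, {
    pts <- data.frame(cell_id = sample(n_cells(sys$stack$geom), 60),
                      label = rep(c(0, 1), 30))
    binarize(map, pts)$tss
  })
  # null expectation of a maximum over thresholds is positive but small
  expect_lt(mean(tss), 0.45)
  expect_gt(mean(tss), 0.05)
})

test_that("abiotic suitability is the percentage mean over ecosystem cells", {
  g <- small_grid(4)
  eco <- make_ecosystem_map(g, 2)
  st <- build_predictors(g)
  map <- structure(list(geom = g$geom, values = rep(0, 16), taxon_id = "t"),
                   class = "suitability_map")
  cells <- ecosystem_cells(eco, 1)
  expect_equal(abiotic_suitability(map, eco, 1), 0)
  map$values[] <- 1
  expect_equal(abiotic_suitability(map, eco, 1), 100)
  map$values[] <- 0
  map$values[cells[1:2]] <- c(0.1, 0.3)
  # restrict the ecosystem to exactly those two cells
  eco2 <- eco
  eco2$labels[] <- 2L
  eco2$labels[cells[1:2]] <- 1L
  expect_equal(abiotic_suitability(map, eco2, 1), 20)
  expect_error(abiotic_suitability(map, eco, 99), "not present")
})

test_that("the full per-taxon ensemble is deterministic under one seed", {
  sys <- small_system(15, seed = 12)
  occ <- sample_occurrences(sys$taxa[[1]], sys$truth, 80, seed = 3)
  f1 <- quiet_fit_sdm(occ, sys$stack, seed = 21)
  f2 <- quiet_fit_sdm(occ, sys$stack, seed = 21)
  expect_identical(f1$suitability$values, f2$suitability$values)
  expect_identical(f1$binary$values, f2$binary$values)
  expect_identical(f1$points$partition, f2$points$partition)
})
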