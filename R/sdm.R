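#' Pair presences with uniformly drawn pseudo-absences
#'
#' Draws exactly one pseudo-absence cell per presence record, uniformly
#' and without replacement from the grid cells holding no presence record
#' of the taxon, so presence and background classes are balanced one to
#' one.
#'
#' @param occ occurrence data frame for one taxon (needs `cell_id`).
#' @param stack a `predictor_stack`.
#' @param seed integer seed.
#' @return a `labelled_points` data frame: `cell_id`, the nine predictor
#'   columns, `label` (1 presence / 0 pseudo-absence) and `partition`
#'   (`NA` until [split_records()]).
#' @export
generate_pseudo_absences <- function(occ, stack, seed) {
  if (nrow(occ) < 1) stop("need at least one presence")
  if (is.null(occ$cell_id)) occ$cell_id <- locate_cells(occ$lon, occ$lat, stack$geom)
  keep <- !is.na(occ$cell_id) & stack$mask[occ$cell_id]
  if (!all(keep)) {
    warning(sum(!keep), " presence record(s) off-grid or on masked cells dropped")
    occ <- occ[keep, , drop = FALSE]
  }
  n_pres <- nrow(occ)
  if (n_pres < 1) stop("no usable presence records")
  candidates <- setdiff(which(stack$mask), unique(occ$cell_id))
  if (length(candidates) < n_pres) {
    stop("insufficient candidate cells for ", n_pres, " pseudo-absences")
  }
  absence_cells <- with_seed(seed, sample(candidates, n_pres, replace = FALSE))
  cells <- c(occ$cell_id, absence_cells)
  out <- data.frame(cell_id = cells, predictor_matrix(stack, cells),
                    label = rep(c(1L, 0L), each = n_pres),
                    partition = NA_character_, check.names = FALSE)
  class(out) <- c("labelled_points", class(out))
  out
}

#' Stratified train/test split of labelled points
#'
#' @param points a `labelled_points` data frame.
#' @param train_fraction fraction used for training, in `(0, 1)`;
#'   `round(train_fraction * n)` points per label go to training.
#' @param seed integer seed.
#' @return the input with `partition` set to `"train"` or `"test"`.
#' @export
split_records <- function(points, train_fraction = 0.7, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly inside (0, 1)")
  }
  for (lab in c(0L, 1L)) {
    if (sum(points$label == lab) < 2) stop("label ", lab, " has fewer than 2 records")
  }
  points$partition <- NA_character_
  with_seed(seed, {
    for (lab in unique(points$label)) {
      idx <- which(points$label == lab)
      n_train <- round(train_fraction * length(idx))
      tr <- sample(idx, n_train)
      points$partition[tr] <- "train"
      points$partition[setdiff(idx, tr)] <- "test"
    }
  })
  points
}

predictor_cols <- function(points) {
  setdiff(names(points), c("cell_id", "label", "partition"))
}

#' Fit one suitability learner
#'
#' All learners honour the same contract: a fitted object whose
#' [predict()] method maps a matrix of predictor vectors to suitability
#' scores in `[0, 1]`. Three learners are provided: `smooth_additive`
#' (penalised additive logistic model via \pkg{mgcv}), `adaptive_hinge`
#' (lasso-selected logistic regression on a MARS-style hinge basis via
#' \pkg{glmnet}) and `kernel_margin` (radial-kernel SVM via \pkg{e1071},
#' with the decision value recalibrated to probability scale by a
#' logistic link).
#'
#' @param train `labelled_points` rows used for fitting (both labels
#'   required; predictors with zero variance are dropped internally, and
#'   fitting fails if all predictors are degenerate).
#' @param learner one of `"smooth_additive"`, `"adaptive_hinge"`,
#'   `"kernel_margin"`.
#' @param seed integer seed for the learners' internal randomness.
#' @param settings optional list: `epsilon` (convergence tolerance,
#'   default `1e-8`), `maxit` (default 500), `n_folds` (hinge-basis
#'   cross-validation folds, default 3), `n_knots` (hinge knots per
#'   predictor, default 3), `gam_k` (spline basis size, default 4).
#' @return an `sdm_learner`.
#' @export
fit_learner <- function(train,
                        learner = c("smooth_additive", "adaptive_hinge", "kernel_margin"),
                        seed = 1L, settings = list()) {
  learner <- match.arg(learner)
  if (length(unique(train$label)) < 2) stop("training data must contain both labels")
  cols <- predictor_cols(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  keep <- apply(x, 2, function(v) stats::sd(v) > 1e-12)
  if (!any(keep)) stop("all predictors are degenerate (zero variance)")
  x <- x[, keep, drop = FALSE]
  y <- train$label
  s <- utils::modifyList(list(epsilon = 1e-8, maxit = 500, n_folds = 3,
                              n_knots = 3, gam_k = 4), settings)

  fit <- with_seed(seed, switch(learner,
    smooth_additive = {
      df <- data.frame(y = y, x, check.names = FALSE)
      terms <- paste(sprintf("s(`%s`, k = %d)", colnames(x), s$gam_k),
                     collapse = " + ")
      mgcv::gam(stats::as.formula(paste("y ~", terms)), data = df,
                family = stats::binomial(),
                control = mgcv::gam.control(epsilon = s$epsilon,
                                            maxit = s$maxit))
    },
    adaptive_hinge = {
      hb <- hinge_basis(x, n_knots = s$n_knots)
      # near-separable fits trip glmnet's small-lambda convergence warnings;
      # those lambdas are never selected, so the warnings are benign
      cv <- suppressWarnings(
        glmnet::cv.glmnet(hb$basis, y, family = "binomial",
                          nfolds = s$n_folds, thresh = 1e-7,
                          maxit = max(s$maxit * 200, 1e5)))
      list(cv = cv, knots = hb$knots)
    },
    kernel_margin = {
      m <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                      scale = TRUE)
      dv <- attr(stats::predict(m, x, decision.values = TRUE),
                 "decision.values")[, 1]
      calib <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial()))
      list(svm = m, calib = calib)
    }
  ))
  structure(list(learner = learner, fit = fit, columns = colnames(x)),
            class = "sdm_learner")
}

# MARS-style hinge features max(0, x - knot) and max(0, knot - x) at
# per-predictor quantile knots.
hinge_basis <- function(x, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    probs <- seq_len(n_knots) / (n_knots + 1)
    knots <- lapply(seq_len(ncol(x)), function(j) {
      unique(stats::quantile(x[, j], probs, names = FALSE))
    })
    names(knots) <- colnames(x)
  }
  out <- list()
  for (j in seq_len(ncol(x))) {
    for (kn in knots[[j]]) {
      out[[paste0(colnames(x)[j], "_p", format(kn, digits = 6))]] <- pmax(0, x[, j] - kn)
      out[[paste0(colnames(x)[j], "_n", format(kn, digits = 6))]] <- pmax(0, kn - x[, j])
    }
  }
  list(basis = do.call(cbind, out), knots = knots)
}

#' @export
predict.sdm_learner <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$columns, drop = FALSE]
  p <- switch(object$learner,
    smooth_additive = as.numeric(
      mgcv::predict.gam(object$fit, newdata = as.data.frame(x), type = "response")),
    adaptive_hinge = {
      hb <- hinge_basis(x, knots = object$fit$knots)
      as.numeric(stats::predict(object$fit$cv, hb$basis, s = "lambda.min",
                                type = "response"))
    },
    kernel_margin = {
      dv <- attr(stats::predict(object$fit$svm, x, decision.values = TRUE),
                 "decision.values")[, 1]
      as.numeric(stats::predict(object$fit$calib,
                                newdata = data.frame(dv = dv),
                                type = "response"))
    }
  )
  pmin(pmax(p, 0), 1)
}

#' Confusion-matrix evaluation metrics
#'
#' Scores at or above `threshold` are predicted presences. Reports
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, omission rate
#' `FN/(TP+FN)`, proportion correct `(TP+TN)/n` and Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with `p_e` from the marginal products.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 observed labels (both classes required).
#' @param threshold decision threshold in `[0, 1]`.
#' @return named numeric vector (`kappa` is `NA` when `p_e = 1`).
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  n <- length(scores)
  if (n == 0) stop("no records")
  stopifnot(length(labels) == n, all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("both labels must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    omission_rate = fn / (tp + fn), proportion_correct = p_o,
    kappa = kappa, threshold = threshold,
    tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Kappa-weighted ensemble of fitted learners
#'
#' Retains the member models whose test kappa reaches `retain_kappa`
#' ("moderate agreement" floor of 0.4 by default) and averages their
#' per-cell scores with weights proportional to kappa.
#'
#' @param members list of members, each a list with elements `model`
#'   (an `sdm_learner`) and `metrics` (from [confusion_metrics()] on the
#'   held-out test records at threshold 0.5).
#' @param stack a `predictor_stack` to score over.
#' @param retain_kappa minimum test kappa for inclusion (default 0.4).
#' @param taxon_id optional id stored in the result.
#' @return a `suitability_map`: list with `geom`, per-cell `values` in
#'   `[0,1]` (`NA` on masked cells), `members` (name, kappa, weight) and
#'   `taxon_id`.
#' @export
ensemble_suitability <- function(members, stack, retain_kappa = 0.4,
                                 taxon_id = NA_character_) {
  kappas <- vapply(members, function(m) unname(m$metrics["kappa"]), 0)
  retained <- which(!is.na(kappas) & kappas >= retain_kappa)
  if (length(retained) == 0) {
    stop("no member retained under rule kappa >= ", retain_kappa)
  }
  w <- pmax(kappas[retained], 0)
  w <- w / sum(w)
  x <- predictor_matrix(stack)[stack$mask, , drop = FALSE]
  scores <- vapply(members[retained], function(m) predict(m$model, x),
                   numeric(nrow(x)))
  vals <- rep(NA_real_, nrow(stack$coef))
  vals[stack$mask] <- as.numeric(scores %*% w)
  member_info <- lapply(seq_along(retained), function(i) {
    m <- members[[retained[i]]]
    list(learner = m$model$learner, kappa = unname(kappas[retained[i]]),
         weight = unname(w[i]), metrics = m$metrics)
  })
  structure(list(geom = stack$geom, values = vals, members = member_info,
                 taxon_id = taxon_id, retain_kappa = retain_kappa),
            class = "suitability_map")
}

#' Threshold a suitability map by maximising the true skill statistic
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' test scores) and keeps the one maximising `TSS = sensitivity +
#' specificity - 1`, breaking ties toward the lower threshold.
#'
#' @param map a `suitability_map`.
#' @param test `labelled_points` rows with `partition == "test"` (both
#'   labels required); scores are read off the map at the test cells.
#' @param rule currently only `"max_tss"`.
#' @return a `binary_map`: list with `geom`, 0/1 `values` (`NA` masked),
#'   `threshold`, `rule` and achieved `tss`.
#' @export
binarize <- function(map, test, rule = "max_tss") {
  rule <- match.arg(rule, "max_tss")
  if (length(unique(test$label)) < 2) stop("test data must contain both labels")
  scores <- map$values[test$cell_id]
  if (anyNA(scores)) stop("test records fall on masked cells")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all test scores equal; threshold undefined")
  cand <- (u[-1] + u[-length(u)]) / 2
  tss <- vapply(cand, function(th) {
    m <- confusion_metrics(scores, test$label, th)
    unname(m["sensitivity"] + m["specificity"] - 1)
  }, 0)
  best <- cand[which.max(tss)]   # which.max takes the first (lowest) on ties
  structure(list(geom = map$geom,
                 values = ifelse(is.na(map$values), NA_real_,
                                 as.numeric(map$values >= best)),
                 threshold = best, rule = rule, tss = max(tss),
                 taxon_id = map$taxon_id),
            class = "binary_map")
}

#' Mean climate suitability of an ecosystem, as a percentage
#'
#' `100 *` the mean continuous suitability over the ecosystem's (unmasked)
#' cells; values below 20 are conventionally read as insufficient for
#' population persistence.
#'
#' @param map a `suitability_map`.
#' @param eco an `ecosystem_map` sharing the map's geometry.
#' @param ecosystem_id ecosystem class label.
#' @return a number in `[0, 100]`.
#' @export
abiotic_suitability <- function(map, eco, ecosystem_id) {
  cells <- ecosystem_cells(eco, ecosystem_id)
  v <- map$values[cells]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("ecosystem ", ecosystem_id, " has no scored cells")
  100 * mean(v)
}

#' Fit the full per-taxon ensemble distribution model
#'
#' Convenience wrapper running pseudo-absence generation, the stratified
#' 70/30 split, the three learners, held-out evaluation, kappa-weighted
#' ensembling and max-TSS binarisation for one taxon.
#'
#' @param occ occurrence records of one taxon.
#' @param stack a `predictor_stack`.
#' @param seed integer seed driving every stochastic step.
#' @param train_fraction fraction of records used for training.
#' @param retain_kappa ensemble retention floor (see
#'   [ensemble_suitability()]); if no learner reaches it the floor is not
#'   relaxed — an error is raised.
#' @param learners learner names to fit.
#' @param settings passed to [fit_learner()].
#' @return list with `suitability` (`suitability_map`), `binary`
#'   (`binary_map`), `points` (split `labelled_points`) and `members`.
#' @export
fit_sdm_ensemble <- function(occ, stack, seed, train_fraction = 0.7,
                             retain_kappa = 0.4,
                             learners = c("smooth_additive", "adaptive_hinge",
                                          "kernel_margin"),
                             settings = list()) {
  taxon_id <- unique(occ$taxon_id)
  if (length(taxon_id) != 1) stop("fit_sdm_ensemble expects a single taxon")
  pts <- generate_pseudo_absences(occ, stack, child_seed(seed, "pseudo_absence"))
  pts <- split_records(pts, train_fraction, child_seed(seed, "split"))
  train <- pts[pts$partition == "train", ]
  test <- pts[pts$partition == "test", ]
  cols <- predictor_cols(pts)
  members <- lapply(seq_along(learners), function(i) {
    model <- fit_learner(train, learners[i],
                         seed = child_seed(seed + i, "learner"),
                         settings = settings)
    scores <- predict(model, test[, cols, drop = FALSE])
    list(model = model, metrics = confusion_metrics(scores, test$label, 0.5))
  })
  smap <- ensemble_suitability(members, stack, retain_kappa, taxon_id)
  bmap <- binarize(smap, test)
  list(suitability = smap, binary = bmap, points = pts, members = members)
}

#' Write a suitability or binary map as a single-layer text grid
#' @param map a `suitability_map` or `binary_map`.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  write_text_grid(list(value = map$values), map$geom, path)
}
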