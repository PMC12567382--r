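#' Build a validated pipeline configuration
#'
#' Central configuration for [run_all()]. Unknown keys are rejected;
#' every parameter is range-checked here rather than deep inside a stage.
#'
#' @param seed global seed; each stage derives its own seed via
#'   [child_seed()].
#' @param synthetic list describing the synthetic study system:
#'   `n_rows`, `n_cols` (grid), `n_ticks`, `n_hosts`, `k_ecosystems`,
#'   `n_occurrences` per taxon, `structure` (`"random"` or `"nested"`),
#'   `level_set_tau`, `noise_sd` (`NULL` = generator default),
#'   `breadth_scale`.
#' @param train_fraction,retain_kappa,edge_threshold,n_null,n_perm,k_pcs,
#'   distance_mode,nmds_starts stage parameters (documented with their
#'   stages).
#' @param on_taxon_error `"abort"` (default) stops the run when a taxon's
#'   ensemble cannot be built; `"skip"` drops the taxon and marks it in
#'   the report.
#' @param out_dir optional directory for all intermediate artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       synthetic = list(),
                       train_fraction = 0.7, retain_kappa = 0.4,
                       edge_threshold = 0, n_null = 199, n_perm = 199,
                       k_pcs = 2, distance_mode = "complement",
                       nmds_starts = 8,
                       on_taxon_error = c("abort", "skip"),
                       out_dir = NULL) {
  syn_defaults <- list(n_rows = 30, n_cols = 30, n_ticks = 3, n_hosts = 8,
                       k_ecosystems = 3, n_occurrences = 150,
                       structure = "random", level_set_tau = 0.05,
                       noise_sd = NULL, breadth_scale = 0.6)
  extra <- setdiff(names(synthetic), names(syn_defaults))
  if (length(extra)) stop("unknown synthetic keys: ", paste(extra, collapse = ", "))
  synthetic <- utils::modifyList(syn_defaults, synthetic)
  stopifnot(train_fraction > 0, train_fraction < 1,
            retain_kappa >= -1, retain_kappa <= 1,
            edge_threshold >= 0, edge_threshold < 100,
            n_null >= 99, n_perm >= 99, k_pcs >= 2,
            synthetic$n_ticks >= 1, synthetic$n_hosts >= 2,
            synthetic$k_ecosystems >= 2)
  distance_mode <- match.arg(distance_mode, c("complement", "reciprocal"))
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 train_fraction = train_fraction, retain_kappa = retain_kappa,
                 edge_threshold = edge_threshold, n_null = n_null,
                 n_perm = n_perm, k_pcs = k_pcs,
                 distance_mode = distance_mode, nmds_starts = nmds_starts,
                 on_taxon_error = match.arg(on_taxon_error),
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(paste(deparse(cfg), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic pipeline end to end
#'
#' Executes every stage in dependency order: synthetic climate grid ->
#' harmonic predictors -> ecosystem map -> virtual taxa and ground truth
#' -> occurrence sampling -> per-taxon ensemble distribution models ->
#' PCA niche hulls and per-ecosystem overlap matrices -> host phylogeny
#' metrics -> overlap-weighted networks with null-model significance ->
#' NMDS ordination. Fully deterministic given `config$seed`. When
#' `config$out_dir` is set, every intermediate artifact is written there
#' in the package's plain-text formats.
#'
#' @param config a `run_config`.
#' @return a `run_report` list with sections `suitability`
#'   (per tick x ecosystem: abiotic %, biotic mean Jaccard, Faith PD,
#'   Pagel's lambda), `networks` (per ecosystem: NODF, WNODF, Q, null
#'   p-values), `ordination` (coordinates, stress, grouping p),
#'   `members` (per-taxon model metrics), `truth`, and provenance
#'   (`seed`, `config_hash`, `version`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  syn <- config$synthetic
  seed <- config$seed
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  grid <- stage_try("climate", make_climate_grid(
    syn$n_rows, syn$n_cols, child_seed(seed, "climate"),
    noise_sd = syn$noise_sd))
  note("climate: %dx%d grid, seed %d", syn$n_rows, syn$n_cols,
       child_seed(seed, "climate"))
  stack <- stage_try("features", build_predictors(grid))
  eco <- stage_try("ecosystem", make_ecosystem_map(
    grid, syn$k_ecosystems, "latitudinal_bands", child_seed(seed, "ecosystem")))
  taxa <- stage_try("taxa", make_virtual_taxa(
    stack, syn$n_ticks, syn$n_hosts, child_seed(seed, "taxa"),
    breadth_scale = syn$breadth_scale, structure = syn$structure))
  truth <- stage_try("truth", synthetic_truth(taxa, stack, syn$level_set_tau))
  ids <- names(truth$taxa)
  roles <- vapply(truth$taxa, `[[`, "", "role")

  occs <- stage_try("occurrences", {
    out <- lapply(seq_along(ids), function(i) {
      sample_occurrences(truth$taxa[[i]], truth, syn$n_occurrences,
                         child_seed(seed + i, "occurrences"))
    })
    names(out) <- ids
    out
  })
  tree <- stage_try("tree", make_phylogeny(ids[roles == "host"],
                                           child_seed(seed, "tree")))

  fits <- list()
  skipped <- character()
  for (i in seq_along(ids)) {
    res <- tryCatch(
      fit_sdm_ensemble(occs[[ids[i]]], stack, seed + i,
                       train_fraction = config$train_fraction,
                       retain_kappa = config$retain_kappa),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (config$on_taxon_error == "abort") {
        stop("pipeline stage 'sdm' failed for ", ids[i], ": ",
             conditionMessage(res), call. = FALSE)
      }
      skipped <- c(skipped, ids[i])
      note("sdm: skipped %s (%s)", ids[i], conditionMessage(res))
    } else {
      fits[[ids[i]]] <- res
      note("sdm: %s ensemble kappa-weighted over %d member(s), TSS threshold %.3f",
           ids[i], length(res$suitability$members), res$binary$threshold)
    }
  }
  tick_ids <- intersect(ids[roles == "tick"], names(fits))
  host_ids <- intersect(ids[roles == "host"], names(fits))
  if (length(tick_ids) == 0 || length(host_ids) == 0) {
    stop("pipeline stage 'sdm' failed: no usable tick or host models")
  }

  space <- stage_try("pca", fit_pca(
    predictor_matrix(stack)[stack$mask, , drop = FALSE], k = config$k_pcs))

  tick_maps <- lapply(fits[tick_ids], `[[`, "binary")
  host_maps <- lapply(fits[host_ids], `[[`, "binary")
  eco_ids <- sort(unique(eco$labels))
  overlaps <- list()
  for (e in eco_ids) {
    om <- tryCatch(
      ecosystem_overlap_matrix(tick_maps, host_maps, eco, e, space, stack),
      error = function(err) NULL)
    if (!is.null(om)) overlaps[[as.character(e)]] <- om
    note("niche: ecosystem %d %s", e,
         if (is.null(om)) "skipped (no defined hulls)" else "overlap matrix built")
  }
  if (length(overlaps) == 0) stop("pipeline stage 'niche' failed: no ecosystem with defined hulls")

  # per tick x ecosystem suitability / diversity table
  suit_rows <- list()
  for (e in names(overlaps)) {
    om <- overlaps[[e]]
    for (t in tick_ids) {
      hosts_def <- colnames(om$values)[om$defined[t, ]]
      pd <- if (length(hosts_def) >= 1) faith_pd(tree, hosts_def) else NA_real_
      lam <- NA_real_
      if (length(hosts_def) >= 4) {
        fit <- pagels_lambda(tree, om$values[t, hosts_def])
        lam <- fit$lambda
      }
      suit_rows[[length(suit_rows) + 1]] <- data.frame(
        tick_id = t, ecosystem_id = as.integer(e),
        abiotic_suitability = abiotic_suitability(fits[[t]]$suitability, eco,
                                                  as.integer(e)),
        biotic_suitability = biotic_suitability(om, t),
        n_hosts = length(hosts_def), faith_pd = pd, pagels_lambda = lam,
        stringsAsFactors = FALSE)
    }
  }
  suitability <- do.call(rbind, suit_rows)

  networks <- list()
  for (e in names(overlaps)) {
    net <- build_network(overlaps[[e]], config$edge_threshold)
    stats_e <- list(ecosystem_id = as.integer(e),
                    n_edges = nrow(net$edges),
                    nodf = nodf(net$incidence),
                    wnodf = wnodf(net$incidence))
    stats_e$modularity_q <- if (nrow(net$edges) > 0) {
      bipartite_modularity(net, child_seed(seed, "null_model"))$q
    } else NA_real_
    if (!is.na(stats_e$nodf)) {
      ns <- null_significance(net$incidence, "nodf", config$n_null,
                              child_seed(seed + as.integer(e), "null_model"))
      stats_e$nodf_null_mean <- ns$null_mean
      stats_e$nodf_z <- ns$z
      stats_e$nodf_p <- ns$p_value
    }
    networks[[e]] <- list(network = net, stats = stats_e)
    note("networks: ecosystem %s NODF %.2f, Q %.3f", e, stats_e$nodf %||% NA,
         stats_e$modularity_q)
  }

  ord <- stage_try("ordination", {
    od <- overlap_to_distance(overlaps, mode = config$distance_mode)
    fit <- nmds(od$d, dim = 2, seed = child_seed(seed, "nmds"),
                n_starts = config$nmds_starts)
    grp <- group_separation_test(od$d, od$items$ecosystem_id,
                                 n_perm = config$n_perm,
                                 seed = child_seed(seed, "mantel"))
    list(distance = od, fit = fit, grouping = grp)
  })
  note("ordination: stress %.4f (reliable: %s), grouping p %.4f",
       ord$fit$stress, stress_check(ord$fit), ord$grouping$p_value)

  report <- structure(list(
    suitability = suitability,
    networks = lapply(networks, `[[`, "stats"),
    ordination = list(
      coordinates = data.frame(ord$distance$items,
                               x = ord$fit$coordinates[, 1],
                               y = ord$fit$coordinates[, 2]),
      stress = ord$fit$stress,
      reliable = stress_check(ord$fit),
      grouping_statistic = ord$grouping$statistic,
      grouping_p = ord$grouping$p_value),
    members = lapply(fits, function(f) {
      lapply(f$suitability$members, function(m) {
        list(learner = m$learner, kappa = m$kappa, weight = m$weight)
      })
    }),
    skipped_taxa = skipped,
    seed = seed, config_hash = config_hash(config),
    version = as.character(utils::packageVersion("nicheweave")),
    log = log_lines),
    class = "run_report")

  attr(report, "objects") <- list(grid = grid, stack = stack, eco = eco,
                                  truth = truth, occurrences = occs,
                                  tree = tree, fits = fits, space = space,
                                  overlaps = overlaps, networks = networks,
                                  ordination = ord)
  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat("  suitability rows:", nrow(x$suitability), "\n")
  cat("  ecosystems with networks:", length(x$networks), "\n")
  cat(sprintf("  ordination stress: %.4f\n", x$ordination$stress))
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' Emits the climate grid, predictor stack, ecosystem map, occurrence
#' CSVs, per-taxon suitability and binary maps, per-ecosystem overlap
#' CSVs, edge-list TSVs, the network statistics JSON, ordination
#' coordinates CSV, the host tree (Newick), the stage log and the report
#' JSON — so that every reported number can be recomputed from files.
#'
#' @param report a `run_report` (with its attached stage objects).
#' @param dir output directory (created if needed).
#' @export
write_report_artifacts <- function(report, dir) {
  obj <- attr(report, "objects")
  if (is.null(obj)) stop("report carries no stage objects")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_climate_grid(obj$grid, file.path(dir, "climate.grid"))
  write_predictors(obj$stack, file.path(dir, "predictors.grid"))
  write_ecosystem_map(obj$eco, file.path(dir, "ecosystems.grid"))
  write_occurrences(do.call(rbind, obj$occurrences),
                    file.path(dir, "occurrences.csv"))
  write_newick(obj$tree, file.path(dir, "hosts.nwk"))
  for (id in names(obj$fits)) {
    write_map(obj$fits[[id]]$suitability,
              file.path(dir, paste0("suitability_", id, ".grid")))
    write_map(obj$fits[[id]]$binary,
              file.path(dir, paste0("binary_", id, ".grid")))
  }
  for (e in names(obj$overlaps)) {
    write_overlap_matrix(obj$overlaps[[e]],
                         file.path(dir, paste0("overlap_eco", e, ".csv")))
    net <- obj$networks[[e]]$network
    utils::write.table(cbind(net$edges, ecosystem = e),
                       file.path(dir, paste0("edges_eco", e, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(report$networks, file.path(dir, "network_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(cbind(report$ordination$coordinates,
                         stress = report$ordination$stress),
                   file.path(dir, "ordination.csv"), row.names = FALSE)
  utils::write.csv(report$suitability, file.path(dir, "suitability.csv"),
                   row.names = FALSE)
  writeLines(report$log, file.path(dir, "stages.log"))
  clean <- report
  attr(clean, "objects") <- NULL
  jsonlite::write_json(unclass(clean), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
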