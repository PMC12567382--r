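#' Define a virtual taxon with a Gaussian climate niche
#'
#' A virtual taxon's suitability over predictor space is bell-shaped:
#' `s(x) = max_prevalence * exp(-Mahalanobis^2(x; center, breadth) / 2)`.
#' The Gaussian response is the standard virtual-species construction; it
#' makes true niches ellipsoidal, so overlap between taxa is controlled
#' analytically by the distance between niche centers.
#'
#' @param taxon_id character id.
#' @param role `"tick"` or `"host"`.
#' @param niche_center numeric vector in predictor space (length 9 for the
#'   harmonic predictor stack).
#' @param niche_breadth either a vector of positive variances (diagonal
#'   scale) or a symmetric positive-definite scale matrix.
#' @param max_prevalence suitability at the niche center, in `(0, 1]`.
#' @return a `virtual_taxon`.
#' @export
virtual_taxon <- function(taxon_id, role = c("tick", "host"),
                          niche_center, niche_breadth, max_prevalence = 1) {
  role <- match.arg(role)
  stopifnot(is.character(taxon_id), length(taxon_id) == 1,
            all(is.finite(niche_center)))
  if (!(max_prevalence > 0 && max_prevalence <= 1)) {
    stop("max_prevalence must be in (0, 1]")
  }
  d <- length(niche_center)
  if (is.matrix(niche_breadth)) {
    if (!isSymmetric(unname(niche_breadth)) ||
        any(eigen(niche_breadth, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("niche_breadth matrix must be symmetric positive definite")
    }
    if (nrow(niche_breadth) != d) stop("breadth dimension mismatch")
    B <- niche_breadth
  } else {
    if (length(niche_breadth) != d || any(niche_breadth <= 0)) {
      stop("diagonal niche_breadth needs ", d, " positive variances")
    }
    B <- diag(as.numeric(niche_breadth), d)
  }
  structure(list(taxon_id = taxon_id, role = role,
                 niche_center = as.numeric(niche_center),
                 niche_breadth = B, max_prevalence = max_prevalence),
            class = "virtual_taxon")
}

#' True suitability of a virtual taxon over a predictor stack
#' @param taxon a `virtual_taxon`.
#' @param stack a `predictor_stack`.
#' @return numeric vector in `[0,1]` per cell (`NA` for masked cells).
#' @export
true_suitability <- function(taxon, stack) {
  x <- predictor_matrix(stack)
  s <- rep(NA_real_, nrow(x))
  ok <- stack$mask
  d2 <- stats::mahalanobis(x[ok, , drop = FALSE], taxon$niche_center,
                           taxon$niche_breadth)
  s[ok] <- taxon$max_prevalence * exp(-d2 / 2)
  s
}

#' Assemble the synthetic ground truth for a set of virtual taxa
#'
#' Computes per-cell true suitability for every taxon and the tick-by-host
#' true overlap matrix, defined as the cell-set Jaccard index (x100)
#' between the taxa's niche level sets
#' `{cells : suitability / max_prevalence >= level_set_tau}`. Identical
#' `(center, breadth)` pairs score exactly 100, and the score decreases as
#' niche centers separate; the definition involves no hull or PCA
#' machinery, so it can serve as an independent target for recovery tests.
#'
#' @param taxa list of `virtual_taxon` objects (ids must be unique).
#' @param stack a `predictor_stack`.
#' @param level_set_tau threshold on prevalence-normalised suitability
#'   defining each taxon's true range (default 0.05).
#' @return a `synthetic_truth`: list with `taxa`, `suitability`
#'   (`n_cells x n_taxa` matrix), `level_sets` (logical matrix) and
#'   `true_pairwise_overlap` (ticks x hosts, in `[0,100]`).
#' @export
synthetic_truth <- function(taxa, stack, level_set_tau = 0.05) {
  ids <- vapply(taxa, `[[`, "", "taxon_id")
  if (anyDuplicated(ids)) stop("duplicate taxon ids")
  roles <- vapply(taxa, `[[`, "", "role")
  suit <- vapply(taxa, true_suitability, numeric(nrow(stack$coef)), stack = stack)
  colnames(suit) <- ids
  norm <- sweep(suit, 2, vapply(taxa, `[[`, 0, "max_prevalence"), `/`)
  level <- !is.na(norm) & norm >= level_set_tau
  ticks <- ids[roles == "tick"]; hosts <- ids[roles == "host"]
  ov <- matrix(NA_real_, length(ticks), length(hosts),
               dimnames = list(ticks, hosts))
  for (ti in ticks) for (hj in hosts) {
    a <- level[, ti]; b <- level[, hj]
    u <- sum(a | b)
    ov[ti, hj] <- if (u == 0) 0 else 100 * sum(a & b) / u
  }
  structure(list(taxa = stats::setNames(taxa, ids), suitability = suit,
                 level_sets = level, true_pairwise_overlap = ov,
                 level_set_tau = level_set_tau, geom = stack$geom),
            class = "synthetic_truth")
}

#' Generate a community of virtual taxa anchored to the realized climate
#'
#' Niche centers are taken from the predictor vectors of randomly chosen
#' grid cells (optionally jittered), so every niche lies on the manifold of
#' climates that actually occur on the grid; niche breadths are diagonal,
#' proportional to the per-predictor standard deviation across cells.
#'
#' @param stack a `predictor_stack`.
#' @param n_ticks,n_hosts how many taxa of each role.
#' @param seed integer seed.
#' @param breadth_scale niche s.d. as a multiple of each predictor's
#'   spatial s.d. (default 0.6); scalar or per-taxon vector.
#' @param structure `"random"` draws all centers independently;
#'   `"nested"` gives hosts a shared center with geometrically increasing
#'   breadths and spreads tick centers away from it, so host ranges are
#'   nested subsets by construction (the extreme-climate community used in
#'   directional nestedness checks).
#' @return list of `virtual_taxon` objects (ticks first).
#' @export
make_virtual_taxa <- function(stack, n_ticks, n_hosts, seed,
                              breadth_scale = 0.6,
                              structure = c("random", "nested")) {
  structure_mode <- match.arg(structure)
  x <- predictor_matrix(stack)[stack$mask, , drop = FALSE]
  sds <- pmax(apply(x, 2, stats::sd), 1e-8)
  n <- n_ticks + n_hosts
  bs <- rep_len(breadth_scale, n)
  with_seed(seed, {
    taxa <- vector("list", n)
    if (structure_mode == "random") {
      rows <- sample(nrow(x), n, replace = TRUE)
      for (i in seq_len(n)) {
        center <- x[rows[i], ] + stats::rnorm(ncol(x), 0, 0.1 * sds)
        taxa[[i]] <- virtual_taxon(
          taxon_id = if (i <= n_ticks) sprintf("tick_%02d", i)
                     else sprintf("host_%02d", i - n_ticks),
          role = if (i <= n_ticks) "tick" else "host",
          niche_center = center,
          niche_breadth = (bs[i] * sds)^2,
          max_prevalence = stats::runif(1, 0.6, 1))
      }
    } else {
      anchor <- x[sample(nrow(x), 1), ]
      for (i in seq_len(n)) {
        if (i <= n_ticks) {
          # ticks displaced progressively from the anchor
          shift <- (i - 1) / max(1, n_ticks - 1)
          center <- anchor + shift * 1.5 * sds * sign(stats::rnorm(ncol(x)))
          taxa[[i]] <- virtual_taxon(sprintf("tick_%02d", i), "tick",
                                     center, (bs[i] * sds)^2, 0.9)
        } else {
          j <- i - n_ticks
          # concentric hosts: same center, geometrically growing breadth
          taxa[[i]] <- virtual_taxon(sprintf("host_%02d", j), "host",
                                     anchor,
                                     (bs[i] * sds * 0.35 * 1.45^(j - 1))^2,
                                     0.9)
        }
      }
    }
    taxa
  })
}

#' Sample occurrence records for a virtual taxon
#'
#' Draws `n` cells with replacement, with probability proportional to the
#' taxon's true suitability (repeat draws emulate repeated records at one
#' locality, as in real tick datasets). Records carry the cell-center
#' coordinates.
#'
#' @param taxon a `virtual_taxon`.
#' @param truth a `synthetic_truth` containing the taxon.
#' @param n number of records (>= 1).
#' @param seed integer seed; the same seed reproduces the records.
#' @return data frame with columns `taxon_id`, `role`, `lon`, `lat`,
#'   `cell_id`.
#' @export
sample_occurrences <- function(taxon, truth, n, seed) {
  stopifnot(n >= 1)
  s <- truth$suitability[, taxon$taxon_id]
  s[is.na(s)] <- 0
  if (sum(s) <= 0) stop("taxon ", taxon$taxon_id, " has all-zero suitability")
  cc <- cell_centers(truth$geom)
  cells <- with_seed(seed, sample.int(length(s), n, replace = TRUE, prob = s))
  data.frame(taxon_id = taxon$taxon_id, role = taxon$role,
             lon = cc$lon[cells], lat = cc$lat[cells], cell_id = cells,
             stringsAsFactors = FALSE)
}

#' Write / read occurrence records as CSV (`taxon_id,role,lon,lat`)
#' @param occ occurrence data frame.
#' @param path CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("taxon_id", "role", "lon", "lat")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @param geom optional `grid_geometry`; when given, `cell_id` is
#'   reconstructed from the coordinates.
#' @export
read_occurrences <- function(path, geom = NULL) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(geom)) occ$cell_id <- locate_cells(occ$lon, occ$lat, geom)
  occ
}

#' Map coordinates to row-major cell ids
#' @param lon,lat coordinates.
#' @param geom a `grid_geometry`.
#' @return integer cell ids (`NA` outside the grid extent).
#' @export
locate_cells <- function(lon, lat, geom) {
  col <- floor((lon - geom$origin[1]) / geom$cellsize) + 1
  row_from_bottom <- floor((lat - geom$origin[2]) / geom$cellsize) + 1
  row <- geom$n_rows - row_from_bottom + 1
  ok <- col >= 1 & col <= geom$n_cols & row >= 1 & row <= geom$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- (row[ok] - 1L) * geom$n_cols + col[ok]
  out
}
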