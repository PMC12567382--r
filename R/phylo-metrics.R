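#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]: every branch must
#' carry a length and tip labels must be unique.
#'
#' @param text Newick string (or a length-1 character path-free string).
#' @return an `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  # ape warns (and returns NULL) on truncated strings; fold both failure
  # modes into one parse error
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: unreadable string")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree must have a branch length on every edge")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Serialize a phylogeny to Newick
#' @param tree a `phylo`.
#' @param path optional file; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Faith's phylogenetic diversity of a tip subset
#'
#' Sum of branch lengths of the minimal subtree connecting the tips,
#' rooted at their most recent common ancestor; the path from the MRCA up
#' to the tree root is excluded by default, so PD is a pure among-host
#' diversity measure: a single tip has PD 0, and PD is monotone under
#' adding tips. Set `include_root = TRUE` for the convention that also
#' counts the MRCA-to-root path.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tips character tip labels (at least 1, all present in the tree).
#' @param include_root count the MRCA-to-root branches too (default FALSE).
#' @return nonnegative phylogenetic diversity.
#' @export
faith_pd <- function(tree, tips, include_root = FALSE) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(tips) < 1) stop("need at least one tip")
  tips <- unique(tips)
  if (length(tips) == 1 && !include_root) return(0)
  if (length(tips) == 1) {
    # single tip with root path: sum of edges from tip to root
    node <- match(tips, tree$tip.label)
    pd <- 0
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      pd <- pd + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    return(pd)
  }
  sub <- ape::keep.tip(tree, tips)   # rooted at the subset's MRCA
  pd <- sum(sub$edge.length)
  if (include_root) {
    mrca <- ape::getMRCA(tree, tips)
    root <- ape::Ntip(tree) + 1L
    node <- mrca
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      pd <- pd + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    if (!is.null(sub$root.edge)) pd <- pd + sub$root.edge
  }
  pd
}

# Profile log-likelihood of lambda under the lambda-transformed Brownian
# model: mean and rate are profiled out in closed form.
lambda_loglik <- function(lambda, C, y) {
  V <- lambda * C
  diag(V) <- diag(C)
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Phylogenetic signal of a continuous tip trait: the off-diagonal entries
#' of the Brownian covariance are scaled by `lambda` (diagonal preserved)
#' and `lambda` is estimated by maximising the likelihood over `[0, 1]`,
#' with the ancestral mean and Brownian rate profiled out analytically.
#' The bounded optimisation is golden-section search (tolerance `1e-6`),
#' which cannot leave the admissible interval.
#'
#' @param tree a `phylo` with branch lengths (>= 4 tips carrying values).
#' @param trait named numeric vector of tip values.
#' @return list with `lambda` (in `[0,1]`), `loglik`, and `flag`
#'   (`"ok"`, `"constant_trait"` or `"star_tree"`, the latter two with
#'   `lambda = NA`).
#' @export
pagels_lambda <- function(tree, trait) {
  trait <- trait[!is.na(trait)]
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < 4) stop("need at least 4 tips with trait values")
  if (length(common) < ape::Ntip(tree)) tree <- ape::keep.tip(tree, common)
  y <- as.numeric(trait[tree$tip.label])
  if (stats::sd(y) <= 1e-12) {
    return(list(lambda = NA_real_, loglik = NA_real_, flag = "constant_trait"))
  }
  C <- ape::vcv(tree)
  off <- C[upper.tri(C)]
  if (all(abs(off) <= 1e-12 * max(diag(C)))) {
    return(list(lambda = NA_real_, loglik = NA_real_, flag = "star_tree"))
  }
  f <- function(l) lambda_loglik(l, C, y)
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
  # the optimum can sit on a boundary; golden-section never quite reaches it
  cand <- rbind(c(0, f(0)), c(opt$maximum, opt$objective), c(1, f(1)))
  best <- cand[which.max(cand[, 2]), ]
  list(lambda = unname(best[1]), loglik = unname(best[2]), flag = "ok")
}
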