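#' Simulate a host phylogeny under a Yule (pure-birth) process
#'
#' @param taxon_ids character tip labels (unique, at least 2).
#' @param seed integer seed.
#' @param model currently only `"yule"`.
#' @param birth speciation rate of the pure-birth process (default 1).
#' @return an [ape::rphylo()]-style binary rooted `phylo` object with
#'   positive branch lengths and tips labelled by `taxon_ids`.
#' @export
make_phylogeny <- function(taxon_ids, seed, model = "yule", birth = 1) {
  model <- match.arg(model, "yule")
  if (length(taxon_ids) < 2) stop("need at least 2 taxa")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon_ids")
  tree <- with_seed(seed, ape::rphylo(length(taxon_ids), birth = birth, death = 0))
  tree$tip.label <- as.character(taxon_ids)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  tree
}

#' Simulate a tip trait under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait vector whose covariance is the
#' phylogenetic (Brownian) covariance with all off-diagonal entries scaled
#' by `lambda_true` and the diagonal left unchanged — Pagel's lambda
#' transformation. `lambda_true = 1` is plain Brownian motion;
#' `lambda_true = 0` gives independent tips.
#'
#' @param tree a `phylo` with branch lengths.
#' @param lambda_true phylogenetic-signal parameter in `[0, 1]`.
#' @param sigma2 Brownian rate (> 0).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_trait <- function(tree, lambda_true, sigma2, seed) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.finite(lambda_true) || lambda_true < 0 || lambda_true > 1) {
    stop("lambda_true must be in [0, 1]")
  }
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  C <- ape::vcv(tree)
  Cl <- lambda_true * C
  diag(Cl) <- diag(C)
  x <- with_seed(seed, MASS::mvrnorm(1, mu = rep(0, nrow(Cl)), Sigma = sigma2 * Cl))
  stats::setNames(as.numeric(x), rownames(C))
}
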