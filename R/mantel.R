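#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance by
#' simultaneous row-and-column permutation of the second matrix. The
#' default two-sided p-value uses the add-one correction
#' `p = (1 + #[|r_perm| >= |r_obs|]) / (n_perm + 1)`; with
#' `exhaustive = TRUE` all `n!` relabelings are enumerated and the p-value
#' is the exact fraction (the identity permutation included).
#'
#' @param d1,d2 square symmetric matrices with zero diagonals, same size
#'   (n >= 4). `dist` objects are accepted.
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param exhaustive enumerate every permutation (feasible for small n).
#' @return list with `r`, `p_value`, `n_perm`, `flag` (`"ok"` or
#'   `"constant"`, the latter with `r = NA`).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L,
                        alternative = c("two.sided", "greater"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4 || any(dim(d1) != n) || any(dim(d2) != n)) {
    stop("matrices must be square, same size, n >= 4")
  }
  if (!isSymmetric(unname(d1)) || !isSymmetric(unname(d2)) ||
      any(abs(diag(d1)) > 1e-12) || any(abs(diag(d2)) > 1e-12)) {
    stop("matrices must be symmetric with zero diagonals")
  }
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (stats::sd(v1) <= 1e-15 || stats::sd(d2[ut]) <= 1e-15) {
    return(list(r = NA_real_, p_value = NA_real_, n_perm = 0, flag = "constant"))
  }
  r_obs <- stats::cor(v1, d2[ut])
  stat <- function(perm) stats::cor(v1, d2[perm, perm][ut])
  compare <- function(r_perm) {
    if (alternative == "two.sided") abs(r_perm) >= abs(r_obs) - 1e-12
    else r_perm >= r_obs - 1e-12
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    hits <- vapply(perms, function(p) compare(stat(p)), TRUE)
    p <- mean(hits)
    n_used <- length(perms)
  } else {
    hits <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) compare(stat(sample.int(n))), TRUE)
    })
    p <- (1 + sum(hits)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = r_obs, p_value = p, n_perm = n_used, flag = "ok")
}

# All permutations of 1..n as a list (n! entries; intended for small n).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1)
    for (p in rest) {
      q <- integer(n)
      q[1] <- i
      q[-1] <- setdiff(seq_len(n), i)[p]
      out[[length(out) + 1]] <- q
    }
  }
  out
}
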