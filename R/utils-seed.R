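#' Derive a per-stage child seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own RNG seed from the
#' single user-supplied seed through this fixed rule, so any stage can be
#' re-run in isolation and reproduce its part of a full pipeline run.
#' The rule is `(seed * 1009 + offset(stage)) mod (2^31 - 1)`, with a fixed
#' integer offset per stage name.
#'
#' @param seed integer global seed.
#' @param stage character, one of the stage names listed in `Details`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @details Recognized stages, in pipeline order: `climate`, `ecosystem`,
#'   `taxa`, `occurrences`, `tree`, `trait`, `pseudo_absence`, `split`,
#'   `learner`, `null_model`, `mantel`, `nmds`.
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(
    climate = 11L, ecosystem = 23L, taxa = 37L, occurrences = 53L,
    tree = 71L, trait = 89L, pseudo_absence = 107L, split = 127L,
    learner = 149L, null_model = 173L, mantel = 197L, nmds = 223L
  )
  stage <- match.arg(stage, names(offsets))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 1009 + offsets[[stage]]) %% (2^31 - 1))
}

# Evaluate `expr` under a temporary RNG state set from `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
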