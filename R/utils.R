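# Internal helpers: seeded RNG streams and small validators.

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Every stochastic operation in a pipeline run draws its randomness from an
#' independent stream keyed by the stage name, so that changing the number of
#' iterations in one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"rarefy"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  # deterministic integer hash, kept in double precision (< 2^53) throughout
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((h + (master %% 2147483647) * 69069) %% 2147483647)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# permutation Monte-Carlo p-value, (b + 1) / (B + 1) convention
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vegan::rrarefy without its "observed counts" heuristic warning, which
# fires on any valid table whose smallest positive count exceeds one
rrarefy_quiet <- function(m, depth) {
  withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}
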