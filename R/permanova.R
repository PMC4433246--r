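# Distance-based permutational MANOVA (one-factor) computed directly from
# the squared distance matrix, with significance by label permutation, and
# the level-wise battery of multivariate tests across taxonomic ranks.

#' One-factor permutational MANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances (`SS_T = sum d_ij^2 / n`
#' over all pairs) into among- and within-group components; the pseudo-F is
#' `(SS_A / (a - 1)) / (SS_W / (n - a))` and `R^2 = SS_A / SS_T`.
#' Significance is one-sided (large F) by permuting group labels with the
#' `(b + 1) / (B + 1)` rule.
#'
#' @param dm a `dist` or square symmetric distance matrix with labels.
#' @param groups group label per sample (at least two groups).
#' @param permutations number of label permutations B.
#' @param seed integer seed.
#' @return An object of class `permanova_result`: list with `f`, `r2`, `p`,
#'   `permutations`, `n`, `n_groups`, `df`, and a `constant_distances` flag
#'   set when every off-diagonal distance is identical (F is then invariant
#'   under permutation and p is 1 by construction).
#' @export
permanova <- function(dm, groups, permutations = 999, seed = NULL) {
  D2 <- as.matrix(dm)^2
  n <- nrow(D2)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must have one label per sample")
  a <- length(unique(groups))
  if (a < 2) stop("need at least two groups")
  if (n - a < 1) stop("no residual degrees of freedom")
  sst <- sum(D2[upper.tri(D2)]) / n
  f_stat <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      if (length(i) > 1) {
        sub <- D2[i, i, drop = FALSE]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
      }
    }
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  null <- with_seed(seed, {
    vapply(seq_len(permutations),
           function(b) f_stat(groups[sample.int(n)]), numeric(1))
  })
  ssw <- 0
  for (lev in unique(groups)) {
    i <- which(groups == lev)
    if (length(i) > 1) {
      sub <- D2[i, i, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
    }
  }
  off <- D2[upper.tri(D2)]
  structure(list(f = f_obs,
                 r2 = (sst - ssw) / sst,
                 p = perm_pvalue(sum(null >= f_obs), permutations),
                 permutations = permutations,
                 n = n, n_groups = a,
                 df = c(among = a - 1, within = n - a),
                 constant_distances = length(unique(round(off, 12))) == 1,
                 null = null),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.3f, R^2 = %.3f, p = %.4g (%d permutations)\n",
    x$df[["among"]], x$df[["within"]], x$f, x$r2, x$p, x$permutations))
  if (x$constant_distances) {
    cat("note: all pairwise distances are equal; F is permutation-invariant\n")
  }
  invisible(x)
}

#' Level-wise multivariate tests of a host grouping factor
#'
#' For each taxonomic level, aggregates the table, converts to relative
#' abundance, applies the arcsine square-root transform, computes Manhattan
#' distances and runs a PERMANOVA on the chosen metadata factor. At the OTU
#' level a presence/absence binary-Jaccard PERMANOVA is run as well.
#'
#' @param x an [otu_table] at OTU level.
#' @param tax a `taxonomy_map`.
#' @param meta a `sample_metadata`.
#' @param factor_name metadata column to test (`"host_species"`,
#'   `"host_tribe"`, `"diet"`, ...).
#' @param levels taxonomic levels; `"otu"` plus any of the canonical ranks.
#' @param permutations label permutations per test.
#' @param seed integer master seed; each level derives its own stream.
#' @return Data frame `level`, `distance`, `f`, `r2`, `p`.
#' @export
levelwise_group_tests <- function(x, tax, meta, factor_name,
                                  levels = c("otu", "genus", "family",
                                             "order", "class", "phylum"),
                                  permutations = 999, seed = NULL) {
  meta <- align_metadata(meta, x)
  if (!factor_name %in% names(meta)) {
    stop("unknown metadata factor: ", factor_name)
  }
  groups <- meta[[factor_name]]
  if (length(unique(groups)) < 2) {
    stop("factor '", factor_name, "' has a single level")
  }
  rows <- list()
  for (lev in levels) {
    tab <- if (identical(lev, "otu")) x else aggregate_by_rank(x, tax, lev)
    d <- manhattan_distance(arcsin_sqrt(to_relative(tab)))
    pr <- permanova(d, groups, permutations = permutations,
                    seed = if (is.null(seed)) NULL
                           else derive_seed(seed, paste0("permanova_", lev)))
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev, distance = "manhattan_arcsin",
      f = pr$f, r2 = pr$r2, p = pr$p, stringsAsFactors = FALSE)
    if (identical(lev, "otu")) {
      pj <- permanova(binary_jaccard(tab), groups,
                      permutations = permutations,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, "permanova_otu_jaccard"))
      rows[[length(rows) + 1L]] <- data.frame(
        level = lev, distance = "binary_jaccard",
        f = pj$f, r2 = pj$r2, p = pj$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
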