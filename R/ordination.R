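# Ordination and ordination comparison: principal coordinates analysis,
# Procrustes superimposition with Monte Carlo significance, jackknifed UPGMA
# clustering, and the simple two-sample / concordance statistics used to
# compare the two markers.

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-centres `-d^2 / 2` and eigendecomposes
#' it. Axes are ordered by decreasing eigenvalue; only axes with positive
#' eigenvalues are returned as coordinates, while negative eigenvalues are
#' reported untouched (no correction is applied).
#'
#' @param dm a `dist` or square symmetric distance matrix with labels.
#' @return An object of class `pcoa_result`: list with `coords` (samples x
#'   axes), `eigenvalues` (all, sorted), `prop_explained` (over positive
#'   eigenvalues), `n_negative` and `min_eigenvalue`.
#' @export
pcoa <- function(dm) {
  D <- as.matrix(dm)
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coords = coords,
                 eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos]),
                 n_negative = sum(e$values < -tol),
                 min_eigenvalue = min(e$values)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coords), ncol(x$coords), x$n_negative))
  cat("first axes explain:",
      paste0(round(100 * utils::head(x$prop_explained, 3), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Procrustes comparison of two ordinations with Monte Carlo significance
#'
#' Both configurations are centred and scaled to unit sum of squares, then
#' the second is optimally rotated (and scaled) onto the first. The
#' concordance statistic is the symmetric `M^2`, the normalised residual sum
#' of squares in `[0, 1]`; significance comes from permuting the row labels
#' of the second configuration and counting permuted `M^2` values at or
#' below the observed one, with the `(b + 1) / (B + 1)` rule.
#'
#' @param a,b numeric coordinate matrices with matching rownames (sample
#'   ids); columns may differ and are zero-padded to a common width.
#'   `pcoa_result` objects are accepted.
#' @param permutations number of row permutations.
#' @param seed integer seed.
#' @return An object of class `procrustes_test`: list with `m2`, `p`,
#'   `permutations`, `null` (permuted `M^2` values).
#' @export
procrustes_test <- function(a, b, permutations = 1000, seed = NULL) {
  if (inherits(a, "pcoa_result")) a <- a$coords
  if (inherits(b, "pcoa_result")) b <- b$coords
  if (is.null(rownames(a)) || is.null(rownames(b))) {
    stop("configurations must carry sample ids as rownames")
  }
  if (!setequal(rownames(a), rownames(b))) {
    stop("configurations must share the same sample ids")
  }
  b <- b[rownames(a), , drop = FALSE]
  k <- max(ncol(a), ncol(b))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  X <- normalize_config(pad(a))
  Y <- normalize_config(pad(b))
  m2_obs <- procrustes_m2(X, Y)
  null <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      procrustes_m2(X, Y[sample(nrow(Y)), , drop = FALSE])
    }, numeric(1))
  })
  structure(list(m2 = m2_obs,
                 p = perm_pvalue(sum(null <= m2_obs), permutations),
                 permutations = permutations,
                 null = null),
            class = "procrustes_test")
}

# centre columns and scale to unit total sum of squares
normalize_config <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  ss <- sqrt(sum(m^2))
  if (ss == 0) stop("degenerate configuration: all points identical")
  m / ss
}

# symmetric Procrustes statistic for unit-normalised centred configurations
procrustes_m2 <- function(X, Y) {
  s <- svd(crossprod(X, Y))$d
  max(0, 1 - sum(s)^2)
}

#' @export
print.procrustes_test <- function(x, ...) {
  cat(sprintf("Procrustes M^2 = %.4f, p = %.4g (%d permutations)\n",
              x$m2, x$p, x$permutations))
  invisible(x)
}

#' Jackknifed beta-diversity clustering with UPGMA support values
#'
#' The full table is clustered by UPGMA on the chosen distance; each
#' jackknife replicate rarefies the table to `depth` reads, recomputes the
#' distance and re-clusters. Support of every internal node of the reference
#' tree is the fraction of replicate trees containing the same sample
#' bipartition.
#'
#' @param x an [otu_table].
#' @param distance distance function of one [otu_table] argument, e.g.
#'   `binary_jaccard` or `function(t) unweighted_unifrac(t, tree)`.
#' @param depth jackknife rarefaction depth.
#' @param replicates number of jackknife replicates.
#' @param seed integer seed.
#' @return List with `tree` (reference UPGMA as `ape::phylo`), `support`
#'   (fraction per internal node, ordered as `ape::prop.clades`),
#'   `replicates`.
#' @export
jackknife_beta <- function(x, distance = binary_jaccard, depth,
                           replicates = 100, seed = NULL) {
  ref <- upgma_tree(distance(x))
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      upgma_tree(distance(rarefy(x, depth)))
    })
  })
  cnt <- ape::prop.clades(ref, reps, rooted = TRUE)
  cnt[is.na(cnt)] <- 0
  list(tree = ref, support = cnt / replicates, replicates = replicates)
}

upgma_tree <- function(dm) {
  ape::as.phylo(stats::hclust(stats::as.dist(dm), method = "average"))
}

#' Mann-Whitney U test
#'
#' Thin wrapper over [stats::wilcox.test()] reporting the U statistic: exact
#' enumeration for small tie-free samples, normal approximation with tie
#' correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative as in [stats::wilcox.test()].
#' @return List with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  wt <- stats::wilcox.test(x, y, alternative = alternative)
  list(U = unname(wt$statistic), p = wt$p.value, method = wt$method)
}

#' Rank-sum test with continuity correction
#'
#' The normal-approximation Wilcoxon rank-sum test with continuity
#' correction, reporting the W statistic as used for large unbalanced
#' comparisons of shared-OTU proportions.
#'
#' @param x,y numeric samples.
#' @param alternative as in [stats::wilcox.test()].
#' @return List with `W`, `p`, `method`.
#' @export
rank_sum_continuity <- function(x, y, alternative = "two.sided") {
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = FALSE, correct = TRUE)
  list(W = unname(wt$statistic), p = wt$p.value, method = wt$method)
}

#' Between-marker agreement of alpha diversity estimates
#'
#' Ordinary least-squares R-squared of paired values (typically per-species
#' mean alpha diversity from the two markers).
#'
#' @param values_a,values_b paired numeric vectors.
#' @return The regression R-squared in `[0, 1]`.
#' @export
marker_concordance_r2 <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  summary(stats::lm(values_b ~ values_a))$r.squared
}
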