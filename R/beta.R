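# Beta diversity: binary Jaccard, unweighted/weighted UniFrac, Manhattan on
# arcsine-transformed relative abundances, and distance-matrix group
# summaries and tests.

#' Binary Jaccard distance between samples
#'
#' `1 - |A intersect B| / |A union B|` on presence sets.
#'
#' @param x an [otu_table] (or numeric matrix).
#' @return A `dist` object over samples.
#' @export
binary_jaccard <- function(x) {
  m <- if (inherits(x, "otu_table")) otu_counts(x) else as.matrix(x)
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Unweighted UniFrac distance
#'
#' Fraction of the branch length leading to tips observed in either of two
#' samples that is unique to one of them; branches are taken relative to the
#' root, and tips absent from both samples contribute nothing.
#'
#' @param x an [otu_table]; every OTU must be a tip of `tree`.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @return A `dist` object with values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(x, tree) {
  m <- otu_counts(x)
  idx <- tree_edge_index(tree)
  present <- edge_mass(otu_presence(m) * 1, idx) > 0  # samples x edges
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  len <- idx$length
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      either <- present[i, ] | present[j, ]
      uniq <- xor(present[i, ], present[j, ])
      tot <- sum(len[either])
      d[i, j] <- d[j, i] <- if (tot == 0) 0 else sum(len[uniq]) / tot
    }
  }
  stats::as.dist(d)
}

#' Weighted UniFrac distance
#'
#' Abundance-weighted branch-length difference between two samples:
#' `sum_e b_e |p_A(e) - p_B(e)|`, where `p_X(e)` is the relative abundance of
#' sample X descending from edge e. The normalised variant (default) divides
#' by `sum_e b_e (p_A(e) + p_B(e))` so values lie in `[0, 1]`.
#'
#' @param x an [otu_table]; every OTU must be a tip of `tree`.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param normalized logical; return the normalised variant.
#' @return A `dist` object.
#' @export
weighted_unifrac <- function(x, tree, normalized = TRUE) {
  rel <- to_relative(x)
  idx <- tree_edge_index(tree)
  p <- edge_mass(rel, idx)  # samples x edges relative mass
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  len <- idx$length
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      num <- sum(len * abs(p[i, ] - p[j, ]))
      if (normalized) {
        den <- sum(len * (p[i, ] + p[j, ]))
        d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  }
  stats::as.dist(d)
}

#' Manhattan distance between sample profiles
#'
#' `sum_i |x_i - y_i|` across taxa; applied to arcsine-transformed relative
#' abundances in the multivariate pipeline. On raw relative abundances the
#' Manhattan distance equals twice the Bray-Curtis dissimilarity.
#'
#' @param m numeric matrix (samples x taxa), typically from [arcsin_sqrt()].
#' @return A `dist` object.
#' @export
manhattan_distance <- function(m) {
  if (inherits(m, "otu_table")) m <- otu_counts(m)
  stats::dist(m, method = "manhattan")
}

#' Per-group-pair mean and standard deviation of distances
#'
#' For every unordered pair of groups (including within-group pairs), the
#' mean and SD of the distances between members. Within-group entries of
#' single-member groups have no distances and are flagged with `NA`.
#'
#' @param dm a `dist` or square symmetric matrix with labels.
#' @param groups group label per sample (aligned to the matrix labels).
#' @return Data frame `group1`, `group2`, `n_distances`, `mean`, `sd`.
#' @export
distance_group_stats <- function(dm, groups) {
  sets <- distance_group_distributions(dm, groups)
  out <- data.frame(
    group1 = vapply(sets, function(s) s$g1, character(1)),
    group2 = vapply(sets, function(s) s$g2, character(1)),
    n_distances = vapply(sets, function(s) length(s$values), integer(1)),
    mean = vapply(sets, function(s) {
      if (length(s$values)) mean(s$values) else NA_real_
    }, numeric(1)),
    sd = vapply(sets, function(s) {
      if (length(s$values) > 1) stats::sd(s$values) else NA_real_
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

# list of distance distributions, one per unordered group pair
distance_group_distributions <- function(dm, groups) {
  D <- as.matrix(dm)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must have one label per sample")
  lev <- unique(groups)
  sets <- list()
  for (a in seq_along(lev)) {
    for (b in seq.int(a, length(lev))) {
      ia <- which(groups == lev[a])
      ib <- which(groups == lev[b])
      if (a == b) {
        vals <- D[ia, ib, drop = FALSE][upper.tri(D[ia, ib, drop = FALSE])]
      } else {
        vals <- as.vector(D[ia, ib, drop = FALSE])
      }
      sets[[paste(lev[a], lev[b], sep = " vs ")]] <-
        list(g1 = lev[a], g2 = lev[b], values = vals)
    }
  }
  sets
}

#' Pairwise t-tests between distance-boxplot distributions
#'
#' Builds the distance distribution of every group pair (the boxplots) and
#' compares all pairs of distributions with Welch two-sample t-tests,
#' Bonferroni-adjusting the p-values over the number of comparisons.
#'
#' @param dm a `dist` or square symmetric matrix with labels.
#' @param groups group label per sample.
#' @return Data frame `comparison1`, `comparison2`, `t`, `df`, `p`,
#'   `p_bonferroni` (capped at 1).
#' @export
distance_boxplot_tests <- function(dm, groups) {
  sets <- distance_group_distributions(dm, groups)
  sets <- Filter(function(s) length(s$values) >= 2, sets)
  nm <- names(sets)
  if (length(sets) < 2) stop("fewer than two usable distance distributions")
  combs <- utils::combn(length(sets), 2)
  res <- apply(combs, 2, function(ij) {
    tt <- stats::t.test(sets[[ij[1]]]$values, sets[[ij[2]]]$values)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  })
  k <- ncol(combs)
  data.frame(comparison1 = nm[combs[1, ]], comparison2 = nm[combs[2, ]],
             t = res["t", ], df = res["df", ], p = res["p", ],
             p_bonferroni = pmin(1, res["p", ] * k),
             row.names = NULL, stringsAsFactors = FALSE)
}
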