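# Indicator value (IndVal) analysis in the original Dufrene-Legendre form:
# specificity (relative mean abundance concentrated in a cluster) times
# fidelity (fraction of the cluster's samples containing the taxon), with
# permutation significance and a cross-marker concordance filter.

#' Indicator values of taxa with respect to sample clusters
#'
#' For taxon i and cluster j, specificity `A_ij` is the mean abundance of i
#' in j divided by the sum of its mean abundances over all clusters, and
#' fidelity `B_ij` is the fraction of cluster-j samples containing i; the
#' indicator value is `A_ij * B_ij`. A value of 1 means the taxon is
#' exclusive to one cluster and present in all of its members. By default
#' abundances are per-sample relative abundances (library-size robust); raw
#' counts are available via `mode = "raw"`.
#'
#' @param x an [otu_table] (OTU level or rank-aggregated).
#' @param clusters cluster label per sample (character or factor), e.g. host
#'   species, genus, tribe or diet.
#' @param mode `"relative"` (default) or `"raw"` abundances.
#' @return An object of class `indval_result`: list with matrices `A`, `B`,
#'   `indval` (clusters x taxa) and `summary`, a data frame per taxon with
#'   the assigned (argmax) cluster, its indicator value, and a tie flag.
#'   Taxa absent everywhere score 0 and get no assigned cluster.
#' @export
indval <- function(x, clusters, mode = c("relative", "raw")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "otu_table")) otu_counts(x) else as.matrix(x)
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(m)) {
    stop("clusters must have one label per sample")
  }
  if (any(table(clusters) == 0)) stop("empty cluster")
  if (mode == "relative") m <- to_relative(m)
  iv <- indval_matrices(m, clusters)
  lev <- rownames(iv$indval)
  mx <- apply(iv$indval, 2, max)
  arg <- apply(iv$indval, 2, function(v) {
    w <- which(v == max(v))
    lev[min(w)]  # lexicographic tie-break: levels kept sorted
  })
  tie <- apply(iv$indval, 2, function(v) sum(v == max(v)) > 1) & mx > 0
  arg[mx == 0] <- NA_character_
  structure(list(A = iv$A, B = iv$B, indval = iv$indval,
                 mode = mode,
                 summary = data.frame(taxon = colnames(m), cluster = arg,
                                      indval = mx, tie = tie,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "indval_result")
}

# clusters x taxa matrices of A, B and indval for an abundance matrix
indval_matrices <- function(m, clusters) {
  lev <- sort(unique(clusters))
  meanab <- rowsum(m, group = clusters) /
    as.vector(table(factor(clusters, levels = sort(unique(clusters)))))
  meanab <- meanab[lev, , drop = FALSE]
  colsum <- colSums(meanab)
  A <- sweep(meanab, 2, ifelse(colsum > 0, colsum, 1), "/")
  A[, colsum == 0] <- 0
  B <- rowsum((m > 0) * 1, group = clusters) /
    as.vector(table(factor(clusters, levels = lev)))
  B <- B[lev, , drop = FALSE]
  list(A = A, B = B, indval = A * B)
}

#' @export
print.indval_result <- function(x, ...) {
  cat(sprintf("indval_result (%s abundances): %d taxa x %d clusters\n",
              x$mode, ncol(x$indval), nrow(x$indval)))
  top <- x$summary[order(-x$summary$indval), ]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Permutation significance of indicator values
#'
#' Permutes cluster labels over samples and compares each taxon's maximum
#' indicator value with its permutation distribution; `p = (number of
#' permuted max-IndVal >= observed + 1) / (B + 1)`.
#'
#' @inheritParams indval
#' @param permutations number of label permutations B.
#' @param seed integer seed.
#' @return Data frame `taxon`, `cluster` (assigned), `indval` (observed
#'   max), `p`.
#' @export
indval_significance <- function(x, clusters, permutations = 999,
                                seed = NULL, mode = c("relative", "raw")) {
  mode <- match.arg(mode)
  obs <- indval(x, clusters, mode = mode)
  m <- if (inherits(x, "otu_table")) otu_counts(x) else as.matrix(x)
  if (mode == "relative") m <- to_relative(m)
  clusters <- as.character(clusters)
  obs_max <- obs$summary$indval
  count <- numeric(length(obs_max))
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      perm <- clusters[sample.int(length(clusters))]
      pm <- apply(indval_matrices(m, perm)$indval, 2, max)
      count <- count + (pm >= obs_max)
    }
  })
  data.frame(taxon = obs$summary$taxon,
             cluster = obs$summary$cluster,
             indval = obs_max,
             p = perm_pvalue(count, permutations),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-marker concordant indicator taxa
#'
#' Retains taxa (matched by name) that are significant in both markers,
#' assigned to the same cluster in both, and reach the indicator-value
#' threshold in at least one marker — the filter used to exclude
#' marker-specific methodological artefacts before reporting indicators.
#'
#' @param recs_a,recs_b data frames from [indval_significance()] for the two
#'   markers.
#' @param alpha significance level applied to both markers.
#' @param min_indval indicator-value threshold required of at least one
#'   marker.
#' @return Data frame `taxon`, `cluster`, `indval_a`, `indval_b`, `p_a`,
#'   `p_b`, sorted by decreasing combined indicator value.
#' @export
concordant_indicators <- function(recs_a, recs_b, alpha = 0.05,
                                  min_indval = 0.6) {
  clean <- function(d) d[!is.na(d$cluster) & nzchar(d$taxon) &
                           d$taxon != "unassigned", ]
  mg <- merge(clean(recs_a), clean(recs_b), by = "taxon",
              suffixes = c("_a", "_b"))
  keep <- mg$p_a < alpha & mg$p_b < alpha &
    mg$cluster_a == mg$cluster_b &
    (mg$indval_a >= min_indval | mg$indval_b >= min_indval)
  out <- mg[keep, c("taxon", "cluster_a", "indval_a", "indval_b",
                    "p_a", "p_b")]
  names(out)[2] <- "cluster"
  out <- out[order(-(out$indval_a + out$indval_b)), ]
  rownames(out) <- NULL
  out
}
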