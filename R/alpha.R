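# Alpha diversity: Chao1 richness, Shannon entropy and Faith's phylogenetic
# diversity, plus rarefaction-averaged estimation and rarefaction curves.

#' Chao1 richness estimate
#'
#' Bias-corrected by default: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1
#' and F2 are the singleton and doubleton counts; the correction keeps the
#' estimator finite when no doubletons occur. The classic form
#' `S_obs + F1^2 / (2 F2)` is available for comparison.
#'
#' @param counts non-negative integer abundance vector.
#' @param bias_corrected logical; use the bias-corrected estimator.
#' @return The estimated richness (always `>=` observed richness for the
#'   bias-corrected form).
#' @examples
#' chao1(c(5, 5, 5))      # no rare OTUs: estimate equals observed (3)
#' chao1(c(1, 1, 2, 5))   # 4 + 2*1/(2*2) = 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  stopifnot(is.numeric(counts), all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero abundance vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0 && f1 > 0) {
      warning("classic Chao1 undefined with singletons but no doubletons; ",
              "returning bias-corrected value")
      return(s_obs + f1 * (f1 - 1) / 2)
    }
    s_obs + if (f1 == 0) 0 else f1^2 / (2 * f2)
  }
}

#' Shannon diversity index
#'
#' Entropy of the relative-abundance distribution, in base-2 (bits) by
#' default to match the classic amplicon toolchain.
#'
#' @param counts non-negative abundance vector with positive sum.
#' @param base logarithm base.
#' @return Shannon entropy, `>= 0`.
#' @export
shannon <- function(counts, base = 2) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero abundance vector")
  as.numeric(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                              base = base))
}

#' Faith's phylogenetic diversity (whole-tree convention)
#'
#' Total branch length of the minimal subtree connecting the present tips to
#' the root, i.e. the root path is always included ("PD whole tree").
#'
#' @param present character vector of present OTU ids (tips), or a logical /
#'   numeric abundance vector named by tip.
#' @param tree rooted `ape::phylo` whose tips include all present OTUs.
#' @return Summed branch length, in the tree's branch-length units.
#' @export
faith_pd <- function(present, tree) {
  if (!is.character(present)) {
    if (is.null(names(present))) stop("abundance vector must be named by tip")
    present <- names(present)[present > 0]
  }
  if (length(present) == 0) stop("empty presence set")
  idx <- tree_edge_index(tree)
  faith_pd_idx(present, idx)
}

# PD given a precomputed tree_edge_index (hot path for rarefaction averaging)
faith_pd_idx <- function(present, idx) {
  pos <- match(present, idx$tips)
  if (anyNA(pos)) {
    stop("tips missing from tree: ",
         paste(present[is.na(pos)], collapse = ", "))
  }
  on_path <- colSums(idx$desc[pos, , drop = FALSE]) > 0
  sum(idx$length[on_path])
}

#' Rarefaction-averaged alpha diversity
#'
#' Computes each requested metric on independently rarefied tables and
#' reports the per-sample mean across iterations, the procedure used when
#' sequencing effort differs among libraries. Samples below the rarefaction
#' depth are excluded with a warning.
#'
#' @param x an [otu_table].
#' @param metrics subset of `"chao1"`, `"shannon"`, `"faith_pd"`.
#' @param depth rarefaction depth (reads per sample).
#' @param iterations number of independent rarefactions averaged.
#' @param tree rooted `ape::phylo`; required when `"faith_pd"` is requested.
#' @param seed integer seed.
#' @param base logarithm base for Shannon.
#' @return Data frame `sample_id`, `metric`, `value` (mean over iterations),
#'   `sd`, `n_iterations`; per-iteration values are attached as attribute
#'   `"iterations"` (sample x iteration x metric array).
#' @export
alpha_with_rarefaction <- function(x, metrics = c("chao1", "shannon",
                                                  "faith_pd"),
                                   depth = 500, iterations = 10,
                                   tree = NULL, seed = NULL, base = 2) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if ("faith_pd" %in% metrics && is.null(tree)) {
    stop("faith_pd requires a tree")
  }
  m <- otu_counts(x)
  keep <- rowSums(m) >= depth
  if (!any(keep)) stop("all samples fall below rarefaction depth ", depth)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(m)[!keep], collapse = ", "))
  }
  m <- m[keep, , drop = FALSE]
  idx <- if ("faith_pd" %in% metrics) tree_edge_index(tree) else NULL
  vals <- array(NA_real_, c(nrow(m), iterations, length(metrics)),
                dimnames = list(rownames(m), NULL, metrics))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      r <- rrarefy_quiet(m, depth)
      for (mt in metrics) {
        vals[, it, mt] <- switch(
          mt,
          chao1 = apply(r, 1, chao1),
          shannon = apply(r, 1, shannon, base = base),
          faith_pd = apply(r, 1, function(v) {
            faith_pd_idx(colnames(r)[v > 0], idx)
          }))
      }
    }
  })
  out <- expand.grid(sample_id = rownames(m), metric = metrics,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- mapply(function(s, mt) mean(vals[s, , mt]),
                      out$sample_id, out$metric)
  out$sd <- mapply(function(s, mt) stats::sd(vals[s, , mt]),
                   out$sample_id, out$metric)
  out$n_iterations <- iterations
  attr(out, "iterations") <- vals
  out
}

#' Rarefaction curves of observed OTU richness
#'
#' Mean observed OTU count per sample at each depth, averaged over
#' independent subsamples; the mean curve is monotone non-decreasing in depth
#' up to Monte Carlo noise and plateaus at the observed richness.
#'
#' @param x an [otu_table].
#' @param depths increasing vector of rarefaction depths.
#' @param iterations subsamples averaged per depth.
#' @param seed integer seed.
#' @return Data frame `sample_id`, `depth`, `mean_observed`, `sd`; depths
#'   exceeding a sample's library size yield no row for that sample.
#' @export
rarefaction_curve <- function(x, depths, iterations = 10, seed = NULL) {
  m <- otu_counts(x)
  res <- list()
  with_seed(seed, {
    for (d in sort(depths)) {
      keep <- rowSums(m) >= d
      if (!any(keep)) next
      sub <- m[keep, , drop = FALSE]
      obs <- replicate(iterations, rowSums(rrarefy_quiet(sub, d) > 0))
      if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1,
                                           dimnames = list(rownames(sub)))
      res[[length(res) + 1L]] <- data.frame(
        sample_id = rownames(sub), depth = d,
        mean_observed = rowMeans(obs),
        sd = apply(obs, 1, stats::sd),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}
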