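# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately use different code paths from the package internals
# (explicit loops, ape::extract.clade, enumeration).

# small labelled count matrix, samples x OTUs
toy_counts <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  if (is.null(otus)) otus <- paste0("otu", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  m
}

# naive per-edge UniFrac: walks every edge, resolving its descendant tip set
# through ape::extract.clade, and accumulates shared/unique branch length
oracle_unifrac <- function(tree, abund_a, abund_b, weighted = FALSE,
                           normalized = TRUE) {
  ntip <- length(tree$tip.label)
  pa <- abund_a / sum(abund_a)
  pb <- abund_b / sum(abund_b)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) tree$tip.label[child]
            else ape::extract.clade(tree, child)$tip.label
    len <- tree$edge.length[e]
    if (weighted) {
      ma <- sum(pa[tips]); mb <- sum(pb[tips])
      num <- num + len * abs(ma - mb)
      den <- den + len * (ma + mb)
    } else {
      ina <- any(abund_a[tips] > 0); inb <- any(abund_b[tips] > 0)
      if (ina || inb) den <- den + len
      if (xor(ina, inb)) num <- num + len
    }
  }
  if (weighted && !normalized) return(num)
  if (den == 0) 0 else num / den
}

# brute-force Dufrene-Legendre indicator values on an abundance matrix
# (relative abundances expected when comparing to mode = "relative")
oracle_indval <- function(m, clusters) {
  lev <- sort(unique(clusters))
  taxa <- colnames(m)
  iv <- matrix(0, length(lev), length(taxa), dimnames = list(lev, taxa))
  for (tx in taxa) {
    means <- sapply(lev, function(cl) mean(m[clusters == cl, tx]))
    for (cl in lev) {
      A <- if (sum(means) == 0) 0 else means[cl] / sum(means)
      members <- which(clusters == cl)
      B <- mean(m[members, tx] > 0)
      iv[cl, tx] <- A * B
    }
  }
  iv
}

# all permutations of 1..n (n small), as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# worked 4-tip tree used in hand calculations:
# ((A:1,B:2):1,(C:3,D:1):2);  total length 10
worked_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
}

# deterministic small two-marker indval fixture: one exclusive taxon
exclusive_cluster_table <- function() {
  m <- matrix(0, 10, 3)
  m[1:5, 1] <- c(4, 9, 2, 7, 5)    # present in all of cluster 1 only
  m[, 2] <- rpois(10, 5) + 1       # ubiquitous
  m[6:10, 3] <- c(1, 0, 3, 2, 1)   # mostly cluster 2
  toy_counts(m, otus = c("excl", "ubiq", "other"))
}

# fresh temp file path (auto-cleaned by R's tempdir)
withr_tempfile <- function(ext = "") tempfile(fileext = ext)
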