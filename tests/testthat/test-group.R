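# PERMANOVA, indicator values, permutation significance, concordance
# filtering and the level-wise test battery.

test_that("PERMANOVA F and R2 match vegan::adonis2", {
  set.seed(41)
  for (i in 1:5) {
    x <- matrix(rnorm(30), 10, 3)
    d <- dist(x)
    g <- sample(rep(c("a", "b", "c"), c(4, 3, 3)))
    pr <- permanova(d, g, permutations = 99, seed = 1)
    ad <- vegan::adonis2(d ~ g, permutations = 10)
    expect_equal(pr$f, ad$F[1], tolerance = 1e-10)
    expect_equal(pr$r2, ad$R2[1], tolerance = 1e-10)
    expect_equal(pr$r2 + (1 - pr$r2), 1)
  }
})

test_that("PERMANOVA on equal distances is permutation-invariant, p = 1", {
  D <- matrix(1, 6, 6) - diag(6)
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  pr <- permanova(D, rep(c("a", "b"), each = 3), permutations = 50, seed = 1)
  expect_true(pr$constant_distances)
  expect_equal(pr$p, 1)
})

test_that("PERMANOVA p is uniform under exchangeable labels", {
  set.seed(42)
  ps <- replicate(200, {
    d <- dist(matrix(rnorm(24), 8, 3))
    permanova(d, rep(c("a", "b"), each = 4), permutations = 59)$p
  })
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
  expect_lt(abs(mean(ps <= 0.25) - 0.25), 0.1)
})

test_that("planted separation is detected at high significance", {
  set.seed(43)
  pts <- rbind(matrix(rnorm(12), 4, 3), matrix(rnorm(12, 8), 4, 3))
  pr <- permanova(dist(pts), rep(c("a", "b"), each = 4),
                  permutations = 199, seed = 9)
  # label permutations that reproduce the original partition tie with the
  # observed F (2 of 70 distinct assignments for a balanced 4+4 design), so
  # the attainable minimum exceeds 1/(B+1); 0.05 is still far above it
  expect_lt(pr$p, 0.05)
  expect_gt(pr$r2, 0.8)
})

test_that("indval matches the brute-force A x B oracle on random tables", {
  set.seed(44)
  for (i in 1:20) {
    m <- toy_counts(matrix(rpois(80, 2), 10, 8))
    m[, 1] <- m[, 1] + 1  # no empty samples
    k <- sample(2:3, 1)
    cl <- sample(letters[1:k], 10, replace = TRUE)
    while (length(unique(cl)) < k) cl <- sample(letters[1:k], 10,
                                                replace = TRUE)
    iv <- indval(otu_table(m), cl, mode = "relative")
    rel <- m / rowSums(m)
    expect_equal(iv$indval, oracle_indval(rel, cl), tolerance = 1e-12)
    iv_raw <- indval(otu_table(m), cl, mode = "raw")
    expect_equal(iv_raw$indval, oracle_indval(m, cl), tolerance = 1e-12)
    # invariants: A columns sum to 1 for present taxa; indval in [0, 1]
    present <- colSums(m) > 0
    expect_equal(unname(colSums(iv$A)[present]),
                 rep(1, sum(present)), tolerance = 1e-12)
    expect_true(all(iv$indval >= 0 & iv$indval <= 1))
  }
})

test_that("exclusive ubiquitous taxon scores exactly 1; symmetry gives 1/k", {
  set.seed(45)
  m <- exclusive_cluster_table()
  cl <- rep(c("c1", "c2"), each = 5)
  iv <- indval(otu_table(m), cl)
  expect_identical(iv$indval["c1", "excl"], 1)
  expect_identical(iv$summary$cluster[iv$summary$taxon == "excl"], "c1")
  # equal abundance in all clusters, present everywhere -> 1/k each
  m2 <- toy_counts(matrix(5L, 8, 2))
  iv2 <- indval(otu_table(m2), rep(c("a", "b"), each = 4))
  expect_equal(unname(iv2$indval[, 1]), c(0.5, 0.5))
  # absent taxon: all zero, no assigned cluster
  m3 <- toy_counts(cbind(rep(1L, 4), 0L))
  iv3 <- indval(otu_table(m3), rep(c("a", "b"), each = 2))
  expect_true(all(iv3$indval[, 2] == 0))
  expect_true(is.na(iv3$summary$cluster[2]))
})

test_that("indval significance: exclusive taxa reject, null calibrates", {
  set.seed(46)
  m <- exclusive_cluster_table()
  cl <- rep(c("c1", "c2"), each = 5)
  sig <- indval_significance(otu_table(m), cl, permutations = 199, seed = 1)
  expect_lt(sig$p[sig$taxon == "excl"], 0.05)
  sig2 <- indval_significance(otu_table(m), cl, permutations = 199, seed = 1)
  expect_identical(sig$p, sig2$p)  # seeded determinism
  # null calibration: shuffled labels -> ~5% rejections at alpha = 0.05
  rej <- replicate(150, {
    mm <- toy_counts(matrix(rpois(60, 3) + 1, 6, 10))
    cc <- sample(rep(c("a", "b"), each = 3))
    s <- indval_significance(otu_table(mm), cc, permutations = 39)
    mean(s$p <= 0.05)
  })
  expect_lt(mean(rej), 0.10)
})

test_that("concordance filter keeps same-cluster taxa significant twice", {
  recs_a <- data.frame(
    taxon = c("t1", "t2", "t3", "t4", "unassigned"),
    cluster = c("X", "X", "X", "Y", "X"),
    indval = c(0.9, 0.7, 0.95, 0.45, 0.99),
    p = c(0.001, 0.001, 0.2, 0.01, 0.001))
  recs_b <- data.frame(
    taxon = c("t1", "t2", "t3", "t4", "unassigned"),
    cluster = c("X", "Y", "X", "Y", "X"),
    indval = c(0.5, 0.8, 0.9, 0.3, 0.99),
    p = c(0.01, 0.001, 0.001, 0.04, 0.001))
  out <- concordant_indicators(recs_a, recs_b)
  # t1: significant both, same cluster, indval >= 0.6 in marker A -> kept
  # t2: different clusters -> dropped; t3: not significant in A -> dropped
  # t4: same cluster + significant but indval < 0.6 in both -> dropped
  # unassigned: never matched
  expect_identical(out$taxon, "t1")
  expect_identical(out$cluster, "X")
  out2 <- concordant_indicators(recs_a, recs_b, min_indval = 0.3)
  expect_setequal(out2$taxon, c("t1", "t4"))
})

test_that("level-wise tests detect a planted tribe effect", {
  ds <- generate_dataset(simulation_design(), seed = 51)
  lw <- levelwise_group_tests(ds$v12, ds$taxonomy, ds$metadata,
                              "host_tribe",
                              levels = c("otu", "genus", "phylum"),
                              permutations = 99, seed = 5)
  # outgroup-exclusive taxa make the tribe split detectable at otu/genus
  expect_lt(lw$p[lw$level == "otu" & lw$distance == "manhattan_arcsin"],
            0.05)
  expect_lt(lw$p[lw$level == "genus"], 0.05)
  expect_true("binary_jaccard" %in% lw$distance)
  expect_error(levelwise_group_tests(ds$v12, ds$taxonomy, ds$metadata,
                                     "origin_not_a_column"),
               "unknown metadata factor")
  one_level <- ds$metadata
  one_level$host_tribe <- "same"
  expect_error(levelwise_group_tests(ds$v12, ds$taxonomy, one_level,
                                     "host_tribe"),
               "single level")
})

test_that("PERMANOVA on diet rejects at the nominal rate when exchangeable", {
  # enrichment, species cores and outgroup-exclusive taxa off: every form
  # of host-specific structure removed, so diet labels are exchangeable
  design <- simulation_design(diet_fold = 1, species_core_n = 0L,
                              n_outgroup_exclusive = 0L, n_lab = 0L)
  set.seed(47)
  rej <- replicate(120, {
    ds <- generate_dataset(design, seed = sample.int(2^30, 1),
                           with_taxonomy = FALSE, with_tree = FALSE)
    rel <- arcsin_sqrt(to_relative(ds$v12))
    p <- permanova(manhattan_distance(rel), ds$metadata$diet,
                   permutations = 99)$p
    p <= 0.05
  })
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
})

test_that("diet enrichment at 3-fold is detectable on enriched taxa", {
  ds <- generate_dataset(simulation_design(), seed = 52,
                         with_taxonomy = FALSE, with_tree = FALSE)
  enriched <- ds$truth$diet_enriched$V12
  rel <- to_relative(ds$v12)
  is_se <- ds$metadata$diet == "scale-eater"
  ratio <- colMeans(rel[is_se, enriched, drop = FALSE]) /
    colMeans(rel[!is_se, enriched, drop = FALSE])
  expect_gt(stats::median(ratio), 1.5)
})
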