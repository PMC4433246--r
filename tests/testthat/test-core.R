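# Core microbiota: membership criteria, relative core length, the
# permutation test, and shared-OTU comparisons.

make_meta <- function(species, origin = NULL, ids = NULL) {
  n <- length(species)
  if (is.null(origin)) origin <- rep("wild", n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  sample_metadata(data.frame(
    sample_id = ids, host_species = species,
    host_genus = paste0("g_", species), host_tribe = "T",
    diet = "omnivore", origin = origin, stringsAsFactors = FALSE))
}

test_that("core membership applies prevalence and every-species criteria", {
  # 5 individuals, 2 species; threshold ceil(0.8*5) = 4
  m <- toy_counts(rbind(c(1, 1, 1, 0),
                        c(1, 1, 0, 1),
                        c(1, 1, 1, 1),
                        c(1, 0, 1, 1),
                        c(1, 0, 1, 1)),
                  otus = c("ubiq", "spA_only", "four", "four_b"))
  meta <- make_meta(c("A", "A", "A", "B", "B"))
  x <- otu_table(m)
  cs <- core_members(x, meta, prevalence = 0.8)
  expect_true("ubiq" %in% cs$members)          # everywhere
  expect_identical(cs$threshold_count, 4)
  # spA_only: 3/5 occurrences -> below threshold
  expect_false("spA_only" %in% cs$members)
  # four, four_b: in 4/5 and both species -> core
  expect_setequal(cs$members, c("ubiq", "four", "four_b"))

  # an OTU above the prevalence threshold but absent from one entire
  # species: 4 of 5 individuals, all conspecific
  meta2 <- make_meta(c("A", "A", "A", "A", "B"))
  m2 <- m; m2[, "four"] <- c(1, 1, 1, 1, 0)
  cs2 <- core_members(otu_table(m2), meta2, prevalence = 0.8)
  expect_false("four" %in% cs2$members)
  cs3 <- core_members(otu_table(m2), meta2, prevalence = 0.8,
                      require_every_species = FALSE)
  expect_true("four" %in% cs3$members)
})

test_that("prevalence threshold uses the ceiling: 20 of 25 meets 80%", {
  n <- 25
  m <- matrix(0L, n, 2, dimnames = list(paste0("s", 1:n), c("in20", "in19")))
  sp <- rep(c("A", "B", "C", "D", "E"), each = 5)
  # both OTUs cover every species; they differ only in total prevalence
  m[c(1:16, 21:24), "in20"] <- 1L          # 20 of 25 individuals
  m[c(1:15, 16:18, 21), "in19"] <- 1L      # 19 of 25 individuals
  meta <- make_meta(sp)
  cs <- core_members(otu_table(m), meta, prevalence = 0.8)
  expect_identical(cs$threshold_count, 20)
  expect_true("in20" %in% cs$members)
  expect_false("in19" %in% cs$members)
})

test_that("lab samples are excluded from the wild-scope core", {
  m <- toy_counts(rbind(1, 1, 1, 1, 0), otus = "o")
  # the lab population carries its own host label, like a captive strain
  meta <- make_meta(c("A", "A", "B", "B", "BLAB"),
                    origin = c(rep("wild", 4), "lab"))
  cs <- core_members(otu_table(m), meta, prevalence = 1)
  expect_true("o" %in% cs$members)   # absent only from the lab sample
  expect_identical(cs$n_samples, 4L)
  cs_all <- core_members(otu_table(m), meta, prevalence = 1, scope = "all")
  expect_false("o" %in% cs_all$members)
})

test_that("core membership is monotone in threshold and criteria", {
  set.seed(32)
  for (i in 1:10) {
    m <- toy_counts(matrix(rbinom(150, 1, runif(1, 0.3, 0.9)), 10, 15))
    meta <- make_meta(rep(c("A", "B"), each = 5))
    x <- otu_table(m)
    prev <- c(0.5, 0.7, 0.8, 0.9, 1)
    sizes <- sapply(prev, function(p) {
      length(core_members(x, meta, prevalence = p)$members)
    })
    expect_true(all(diff(sizes) <= 0))
    with_crit <- core_members(x, meta, prevalence = 0.6)$members
    without <- core_members(x, meta, prevalence = 0.6,
                            require_every_species = FALSE)$members
    expect_true(all(with_crit %in% without))
  }
})

test_that("cross-marker core intersects taxon names, never OTUs", {
  a <- core_members(otu_table(toy_counts(rbind(c(1, 1, 1), c(1, 1, 1)),
                                         otus = c("Firmicutes",
                                                  "Fusobacteria", "TM7"))),
                    make_meta(c("A", "B")), prevalence = 0.8,
                    level = "phylum")
  b <- core_members(otu_table(toy_counts(rbind(c(1, 1), c(1, 1)),
                                         otus = c("Firmicutes",
                                                  "Fusobacteria"))),
                    make_meta(c("A", "B")), prevalence = 0.8,
                    level = "phylum")
  both <- cross_marker_core(a, b)
  expect_setequal(both$members, c("Firmicutes", "Fusobacteria"))
  expect_true(both$criteria[["cross_marker"]])
  a_otu <- a; a_otu$level <- "otu"
  b_otu <- b; b_otu$level <- "otu"
  expect_error(cross_marker_core(a_otu, b_otu), "taxonomic ranks")
  mismatch <- b; mismatch$level <- "genus"
  expect_error(cross_marker_core(a, mismatch), "different levels")
})

test_that("relative core length: endpoints and a worked 5-individual table", {
  ident <- otu_table(toy_counts(matrix(1L, 5, 6)))
  expect_equal(relative_core_length(ident, 1:5), 1)
  disjoint <- otu_table(toy_counts(diag(5L) * 3L))
  expect_equal(relative_core_length(disjoint, 1:5), 0)
  # worked table: 8 OTUs, occupancy 5,5,4,4,3,2,1,1 -> threshold ceil(4)=4
  occ <- c(5, 5, 4, 4, 3, 2, 1, 1)
  m <- sapply(occ, function(k) c(rep(1L, k), rep(0L, 5 - k)))
  x <- otu_table(toy_counts(m))
  expect_equal(relative_core_length(x, 1:5, prevalence = 0.8), 4 / 8)
})

test_that("core-length permutation null matches exhaustive draws of 5 of 6", {
  set.seed(33)
  m <- toy_counts(matrix(rbinom(6 * 30, 1, 0.5) * rpois(180, 8), 6, 30))
  meta <- make_meta(rep(c("A", "B", "C"), each = 2))
  x <- otu_table(m)
  # exhaustive oracle: all choose(6,5) = 6 leave-one-out draws
  exhaustive <- apply(utils::combn(6, 5), 2, function(rows) {
    relative_core_length(x, rows, prevalence = 0.8)
  })
  res <- core_length_permutation_test(x, meta, draw = 5,
                                      permutations = 600, seed = 4)
  # every Monte-Carlo null value must be one of the 6 possible values
  expect_true(all(res$null %in% exhaustive))
  # frequencies approximate the uniform distribution over the 6 draws
  vals <- sort(unique(round(exhaustive, 12)))
  obs_freq <- as.vector(table(factor(round(res$null, 12),
                                     levels = vals))) / length(res$null)
  exp_freq <- as.vector(table(factor(round(exhaustive, 12),
                                     levels = vals))) / length(exhaustive)
  expect_true(all(abs(obs_freq - exp_freq) < 0.12))
})

test_that("species with one individual are excluded from the test", {
  set.seed(34)
  m <- toy_counts(matrix(rpois(7 * 20, 3), 7, 20))
  meta <- make_meta(c("A", "A", "A", "B", "B", "B", "solo"))
  res <- core_length_permutation_test(otu_table(m), meta, draw = 3,
                                      permutations = 50, seed = 1)
  expect_identical(res$excluded, "solo")
  expect_setequal(res$results$species, c("A", "B"))
  expect_true(all(res$results$p >= 1 / 51 & res$results$p <= 1))
})

test_that("identical individuals give relative core length 1 and p = 1", {
  m <- toy_counts(matrix(rep(c(2L, 0L, 5L, 1L), each = 6), 6, 4))
  meta <- make_meta(rep(c("A", "B"), each = 3))
  res <- core_length_permutation_test(otu_table(m), meta, draw = 5,
                                      permutations = 100, seed = 1)
  expect_true(all(res$null == 1))
  expect_true(all(res$results$observed == 1))
  expect_true(all(res$results$p == 1))
})

test_that("shared-OTU proportions separate planted intra/inter structure", {
  set.seed(35)
  ds <- generate_dataset(simulation_design(), seed = 21,
                         with_taxonomy = FALSE, with_tree = FALSE)
  sp <- shared_otu_proportions(ds$v12, ds$metadata)
  med_intra <- stats::median(sp$pairs$shared[sp$pairs$type == "intraspecific"])
  med_inter <- stats::median(sp$pairs$shared[sp$pairs$type == "interspecific"])
  expect_gt(med_intra, med_inter)
  expect_lt(sp$p, 0.05)
  # endpoints
  ident <- otu_table(toy_counts(matrix(1L, 4, 5)))
  meta <- make_meta(c("A", "A", "B", "B"))
  si <- suppressWarnings(shared_otu_proportions(ident, meta))
  expect_true(all(si$pairs$shared == 1))
  disj <- otu_table(toy_counts(diag(4L)))
  sd_ <- suppressWarnings(shared_otu_proportions(disj, meta))
  expect_true(all(sd_$pairs$shared == 0))
})
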