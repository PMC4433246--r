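# The synthetic-community generator: determinism, planted structure, and
# the contracts downstream analyses rely on.

test_that("generate_tree produces valid deterministic coalescent trees", {
  t2 <- generate_tree(2, seed = 1)
  expect_identical(length(t2$tip.label), 2L)
  expect_true(all(t2$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(10, seed = 7)),
                   ape::write.tree(generate_tree(10, seed = 7)))
  t50 <- generate_tree(50, seed = 3)
  expect_identical(length(t50$tip.label), 50L)
  expect_identical(t50$Nnode, 49L)  # binary rooted: n - 1 internal nodes
  expect_error(generate_tree(1), "at least 2")
})

test_that("generated datasets are pure functions of (design, seed)", {
  d1 <- generate_dataset(simulation_design(), seed = 5)
  d2 <- generate_dataset(simulation_design(), seed = 5)
  expect_identical(otu_counts(d1$v12), otu_counts(d2$v12))
  expect_identical(otu_counts(d1$v34), otu_counts(d2$v34))
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  d3 <- generate_dataset(simulation_design(), seed = 6)
  expect_false(identical(otu_counts(d1$v12), otu_counts(d3$v12)))
})

test_that("row sums equal the drawn library sizes exactly", {
  ds <- generate_dataset(simulation_design(), seed = 8,
                         with_taxonomy = FALSE, with_tree = FALSE)
  expect_identical(unname(rowSums(otu_counts(ds$v12))),
                   unname(as.numeric(ds$truth$lib_sizes[, "V12"])))
  expect_identical(unname(rowSums(otu_counts(ds$v34))),
                   unname(as.numeric(ds$truth$lib_sizes[, "V34"])))
})

test_that("truth ids resolve in the emitted tables, taxonomy and tree", {
  ds <- generate_dataset(simulation_design(), seed = 9)
  expect_true(all(ds$truth$family_core$V12 %in% otu_ids(ds$v12)))
  expect_true(all(ds$truth$family_core$V34 %in% otu_ids(ds$v34)))
  expect_true(all(unlist(lapply(ds$truth$species_core, `[[`, "V12")) %in%
                    otu_ids(ds$v12)))
  all_ids <- c(otu_ids(ds$v12), otu_ids(ds$v34))
  expect_true(all(all_ids %in% ds$taxonomy$otu_id))
  expect_true(all(all_ids %in% ds$tree$tip.label))
  expect_true(all(ds$tree$edge.length >= 0))
  # markers share taxonomy at species rank: the dominant OTU matches
  sp12 <- ds$taxonomy$species[ds$taxonomy$otu_id == ds$truth$dominant$V12]
  sp34 <- ds$taxonomy$species[ds$taxonomy$otu_id == ds$truth$dominant$V34]
  expect_identical(sp12, sp34)
})

test_that("dominant OTU holds ~30% of pooled reads across replicates", {
  shares <- sapply(1:20, function(s) {
    ds <- generate_dataset(simulation_design(), seed = 100 + s,
                           with_taxonomy = FALSE, with_tree = FALSE)
    m <- otu_counts(ds$v12)
    sum(m[, ds$truth$dominant$V12]) / sum(m)
  })
  expect_lt(abs(mean(shares) - 0.30), 0.05)
})

test_that("planted species cores reach 80% conspecific prevalence", {
  hits <- c(); total <- c()
  for (s in 1:15) {
    ds <- generate_dataset(simulation_design(), seed = 200 + s,
                           with_taxonomy = FALSE, with_tree = FALSE)
    meta <- ds$metadata
    pres <- otu_presence(ds$v12)
    for (sp in names(ds$truth$species_core)) {
      rows <- meta$sample_id[meta$host_species == sp & meta$origin == "wild"]
      if (length(rows) < 2) next
      ids <- ds$truth$species_core[[sp]]$V12
      prev <- colSums(pres[rows, ids, drop = FALSE]) / length(rows)
      hits <- c(hits, sum(prev >= 0.8))
      total <- c(total, length(ids))
    }
  }
  expect_gte(sum(hits) / sum(total), 0.95)
})

test_that("degenerate design: full recovery gives identical taxon sets", {
  design <- simulation_design(noise_per_sample = 0, diet_fold = 1,
                              n_diet_enriched = 0L, recovery_prob = 1)
  ds <- generate_dataset(design, seed = 10)
  sp12 <- sort(ds$taxonomy$species[match(otu_ids(ds$v12),
                                         ds$taxonomy$otu_id)])
  sp34 <- sort(ds$taxonomy$species[match(otu_ids(ds$v34),
                                         ds$taxonomy$otu_id)])
  expect_identical(sp12, sp34)
})

test_that("outgroup-exclusive taxa are absent from other host species", {
  ds <- generate_dataset(simulation_design(), seed = 11,
                         with_taxonomy = FALSE, with_tree = FALSE)
  meta <- ds$metadata
  out_sp <- ds$truth$outgroup_species
  other <- meta$sample_id[!startsWith(meta$host_species, out_sp)]
  ids <- intersect(ds$truth$outgroup_exclusive$V12, otu_ids(ds$v12))
  expect_true(all(otu_counts(ds$v12)[other, ids] == 0))
})

test_that("lab population is a diversity-depleted subset of the outgroup", {
  ds <- generate_dataset(simulation_design(), seed = 12,
                         with_taxonomy = FALSE, with_tree = FALSE)
  meta <- ds$metadata
  pres <- otu_presence(ds$v12)
  wild <- meta$sample_id[meta$host_species == ds$truth$outgroup_species &
                           meta$origin == "wild"]
  lab <- meta$sample_id[meta$origin == "lab"]
  rich_wild <- mean(rowSums(pres[wild, ]))
  rich_lab <- mean(rowSums(pres[lab, ]))
  expect_lt(rich_lab, rich_wild)
  # family-core OTUs are retained by the lab population
  fam <- ds$truth$family_core$V12
  expect_true(all(colSums(pres[lab, fam, drop = FALSE]) > 0))
})

test_that("datasets round-trip through write_dataset and the readers", {
  ds <- generate_dataset(simulation_design(), seed = 13)
  dir <- file.path(tempdir(), "synthds")
  write_dataset(ds, dir)
  v12 <- read_otu_table(file.path(dir, "otu_table_V12.tsv"), marker = "V12")
  expect_identical(otu_counts(v12), otu_counts(ds$v12))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tax$species, ds$taxonomy$species)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(meta$host_species, ds$metadata$host_species)
  tree <- read_tree(file.path(dir, "tree.nwk"),
                    otu_ids = otu_ids(ds$v12))
  expect_identical(sort(tree$tip.label), sort(ds$tree$tip.label))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
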