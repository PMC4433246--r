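# Synthetic paired-marker community generator. Emulates the structure of a
# two-amplicon gut-microbiota survey of several related host species: one
# dominant shared OTU, a family-wide core, per-species cores, taxa exclusive
# to a phylogenetically distant outgroup host, diet-associated enrichment,
# environmental singleton noise, variable library sizes, and two markers
# with overlapping but non-identical taxon recovery. Ground truth about
# every planted feature is returned for parameter-recovery tests.

#' Default host species table for the simulation design
#'
#' Six host species: two zooplanktivorous and three scale-eating species of
#' one tribe (three genera), plus an omnivorous outgroup species of a
#' distant tribe; 25 wild individuals in total, one species contributing a
#' single individual.
#'
#' @return Data frame `species`, `genus`, `tribe`, `diet`, `n_wild`.
#' @export
default_species_table <- function() {
  data.frame(
    species = c("Hapmic", "Haptri", "Plestr", "Permic", "Perecc", "Astbur"),
    genus = c("Haplotaxodon", "Haplotaxodon", "Plecodus", "Perissodus",
              "Perissodus", "Astatotilapia"),
    tribe = c("Perissodini", "Perissodini", "Perissodini", "Perissodini",
              "Perissodini", "Tropheini"),
    diet = c("zooplanktivore", "zooplanktivore", "scale-eater",
             "scale-eater", "scale-eater", "omnivore"),
    n_wild = c(5L, 5L, 5L, 4L, 1L, 5L),
    stringsAsFactors = FALSE)
}

#' Simulation design for the synthetic paired-marker survey
#'
#' Parameters of [generate_dataset()]. Defaults emulate the magnitudes of a
#' desk-scale two-amplicon survey: a dominant OTU holding ~30% of reads, a
#' family-wide core of 20 OTUs, per-species cores sized so that roughly
#' 13-15% of each species' observed OTUs are core at 80% conspecific
#' prevalence, tribe-exclusive taxa in the outgroup species, a 3-fold
#' diet enrichment of designated taxa in scale-eaters, sparse environmental
#' singleton noise, log-normal library sizes with median 8000 reads, and a
#' 90% per-marker OTU recovery probability.
#'
#' @param species data frame as [default_species_table()].
#' @param n_lab individuals of the laboratory population (a
#'   diversity-depleted strain of the outgroup species).
#' @param lab_retention fraction of the outgroup's non-core pool retained by
#'   the laboratory population.
#' @param n_family_core family-wide core OTUs (includes the dominant OTU).
#' @param family_core_prob per-individual presence probability of a
#'   family-core OTU; the default models the family-wide core as obligate
#'   (present in every gut before sequencing noise), the way the most
#'   prevalent shared symbionts behave, so that the prevalence machinery is
#'   exercised by the species cores and the common pool instead.
#' @param dominant_mean mean relative abundance of the dominant OTU.
#' @param dominant_conc concentration (a + b) of the Beta distribution of
#'   the dominant OTU's per-sample share.
#' @param species_core_n per-species core OTUs planted for every species.
#' @param species_core_prob presence probability of a species-core OTU in a
#'   conspecific individual; chosen so that a planted core clears the 80%
#'   prevalence criterion in at least 95% of draws even for the smallest
#'   multi-individual species (n = 4 requires presence in all four, i.e.
#'   `p^4 >= 0.95` up to detection noise).
#' @param species_core_cross_prob presence probability of a species-core OTU
#'   in individuals of other species (microbial promiscuity).
#' @param n_common shared non-core OTU pool size.
#' @param common_prob per-individual presence probability of a common-pool
#'   OTU.
#' @param n_outgroup_exclusive OTUs exclusive to the outgroup species.
#' @param outgroup_prob their per-individual presence probability.
#' @param n_diet_enriched taxa whose abundance is multiplied in the enriched
#'   diet class.
#' @param diet_fold multiplicative enrichment (1 disables the effect).
#' @param diet_class diet class receiving the enrichment.
#' @param noise_per_sample expected environmental singleton OTUs per sample.
#' @param noise_weight pre-normalisation abundance weight of one noise OTU,
#'   on the same scale as the log-normal common-pool weights (the default
#'   yields a few reads per library, i.e. singleton-like occurrences).
#' @param lib_median median library size (reads); sizes are log-normal.
#' @param lib_sdlog log-scale SD of library sizes.
#' @param recovery_prob probability that a marker recovers an OTU at all
#'   (the dominant OTU is always recovered by both markers).
#' @param core_weight,species_core_weight abundance weight multipliers of
#'   family-core and species-core OTUs relative to common-pool OTUs.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(species = default_species_table(),
                              n_lab = 5L, lab_retention = 0.5,
                              n_family_core = 20L, family_core_prob = 1,
                              dominant_mean = 0.30, dominant_conc = 20,
                              species_core_n = 12L, species_core_prob = 0.97,
                              species_core_cross_prob = 0.1,
                              n_common = 200L, common_prob = 0.3,
                              n_outgroup_exclusive = 25L,
                              outgroup_prob = 0.7,
                              n_diet_enriched = 8L, diet_fold = 3,
                              diet_class = "scale-eater",
                              noise_per_sample = 2, noise_weight = 0.3,
                              lib_median = 8000, lib_sdlog = 0.4,
                              recovery_prob = 0.9,
                              core_weight = 10, species_core_weight = 6) {
  d <- as.list(environment())
  stopifnot(nrow(species) >= 2, all(species$n_wild >= 0),
            dominant_mean > 0, dominant_mean < 1,
            family_core_prob >= 0, family_core_prob <= 1,
            species_core_prob >= 0, species_core_prob <= 1,
            common_prob >= 0, common_prob <= 1,
            recovery_prob > 0, recovery_prob <= 1,
            diet_fold >= 1, lab_retention >= 0, lab_retention <= 1,
            n_family_core >= 1)
  if (n_diet_enriched > n_common) {
    stop("more diet-enriched taxa than common-pool taxa")
  }
  class(d) <- "simulation_design"
  d
}

# total base taxa implied by a design (noise pool scales with samples)
design_pool_sizes <- function(design) {
  n_samples <- sum(design$species$n_wild) + design$n_lab
  n_noise <- round(design$noise_per_sample * n_samples)
  list(n_samples = n_samples,
       n_species = nrow(design$species),
       n_noise = n_noise,
       n_taxa = design$n_family_core +
         design$species_core_n * nrow(design$species) +
         design$n_common + design$n_outgroup_exclusive + n_noise)
}

#' Generate a random rooted phylogeny for simulated OTUs
#'
#' Random coalescent tree with positive branch lengths and tips named
#' `otu_0001 ...`; deterministic given the seed.
#'
#' @param n_otus number of tips (`>= 2`).
#' @param seed integer seed.
#' @return A rooted `ape::phylo`.
#' @export
generate_tree <- function(n_otus, seed = NULL) {
  if (n_otus < 2) stop("need at least 2 OTUs for a tree")
  with_seed(seed, {
    tr <- ape::rcoal(n_otus,
                     tip.label = sprintf("otu_%04d", seq_len(n_otus)))
    tr
  })
}

#' Generate a synthetic paired-marker dataset with ground truth
#'
#' Per sample, a relative-abundance vector is assembled: the dominant OTU's
#' share is Beta-distributed around its mean; planted core, common-pool,
#' outgroup-exclusive and noise OTUs are switched on by Bernoulli presence
#' draws at their design probabilities and weighted by fixed log-normal
#' per-OTU weights; diet-enriched taxa are multiplied by the fold in the
#' enriched diet class; the vector is renormalised. Counts are then drawn by
#' a multinomial at the sample's log-normal library size, independently per
#' marker after marker-level OTU dropout (the markers share the composition
#' but use disjoint OTU id spaces joined only through taxonomy). The
#' laboratory population re-uses the outgroup species' pool with a
#' retention-subsampled non-core component.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; the full dataset is a pure function of
#'   `(design, seed)`.
#' @param with_taxonomy,with_tree logical; skip building the taxonomy map
#'   and/or the phylogeny (the slowest components) when a replication study
#'   only needs count tables and metadata. Skipping does not change the
#'   random draws behind the tables.
#' @return List with `v12`, `v34` ([otu_table]s), `taxonomy`
#'   (`taxonomy_map` over both markers' OTU ids), `tree` (tips cover both
#'   markers' OTU ids), `metadata` (`sample_metadata`), and `truth`: planted
#'   family-core / species-core / diet-enriched / outgroup-exclusive / noise
#'   ids (base taxa and their per-marker OTU ids), the dominant OTU, and the
#'   drawn library sizes.
#' @export
generate_dataset <- function(design = simulation_design(), seed = 1,
                             with_taxonomy = TRUE, with_tree = TRUE) {
  stopifnot(inherits(design, "simulation_design"))
  ps <- design_pool_sizes(design)
  with_seed(seed, generate_dataset_impl(design, ps, with_taxonomy, with_tree))
}

generate_dataset_impl <- function(design, ps, with_taxonomy = TRUE,
                                  with_tree = TRUE) {
  sp <- design$species
  n_sp <- nrow(sp)

  # ---- base taxa and their roles -------------------------------------------
  n_taxa <- ps$n_taxa
  taxa <- sprintf("taxon_%04d", seq_len(n_taxa))
  cursor <- 0
  take <- function(k) {
    out <- taxa[cursor + seq_len(k)]
    cursor <<- cursor + k
    out
  }
  family_core <- take(design$n_family_core)
  dominant <- family_core[1]
  species_core <- lapply(seq_len(n_sp), function(i) take(design$species_core_n))
  names(species_core) <- sp$species
  common <- take(design$n_common)
  outgroup_excl <- take(design$n_outgroup_exclusive)
  noise <- take(ps$n_noise)
  diet_enriched <- if (design$n_diet_enriched > 0) {
    common[seq_len(design$n_diet_enriched)]
  } else character(0)

  # fixed per-taxon abundance weights (log-normal), role multipliers applied
  w <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1)
  names(w) <- taxa
  w[family_core] <- w[family_core] * design$core_weight
  w[unlist(species_core)] <- w[unlist(species_core)] *
    design$species_core_weight
  w[noise] <- design$noise_weight  # tiny fixed weight, reads ~ singletons

  # ---- samples and metadata ------------------------------------------------
  outgroup_species <- sp$species[which(sp$tribe != sp$tribe[1])[1] %||% n_sp]
  if (is.na(outgroup_species)) outgroup_species <- sp$species[n_sp]
  meta_rows <- list()
  for (i in seq_len(n_sp)) {
    if (sp$n_wild[i] == 0) next
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%d", sp$species[i], seq_len(sp$n_wild[i])),
      host_species = sp$species[i], host_genus = sp$genus[i],
      host_tribe = sp$tribe[i], diet = sp$diet[i], origin = "wild",
      stringsAsFactors = FALSE)
  }
  if (design$n_lab > 0) {
    i <- match(outgroup_species, sp$species)
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = sprintf("%sLAB_%d", sp$species[i], seq_len(design$n_lab)),
      host_species = paste0(sp$species[i], "LAB"), host_genus = sp$genus[i],
      host_tribe = sp$tribe[i], diet = sp$diet[i], origin = "lab",
      stringsAsFactors = FALSE)
  }
  meta <- sample_metadata(do.call(rbind, meta_rows))
  n_samples <- nrow(meta)

  # lab pool: cores always retained, non-core component subsampled
  lab_nonCore_pool <- c(common, outgroup_excl)
  lab_retained <- lab_nonCore_pool[
    stats::runif(length(lab_nonCore_pool)) < design$lab_retention]

  # noise OTUs: each appears in exactly one (random) sample
  noise_host <- sample.int(n_samples, length(noise), replace = TRUE)

  # ---- per-sample composition ----------------------------------------------
  ab <- matrix(0, n_samples, n_taxa,
               dimnames = list(meta$sample_id, taxa))
  dom_a <- design$dominant_mean * design$dominant_conc
  dom_b <- (1 - design$dominant_mean) * design$dominant_conc
  for (s in seq_len(n_samples)) {
    sp_s <- sub("LAB$", "", meta$host_species[s])
    is_lab <- meta$origin[s] == "lab"
    present <- stats::setNames(rep(FALSE, n_taxa), taxa)
    present[family_core] <-
      stats::runif(length(family_core)) < design$family_core_prob
    present[dominant] <- TRUE
    for (spn in names(species_core)) {
      p <- if (spn == sp_s) design$species_core_prob
           else design$species_core_cross_prob
      present[species_core[[spn]]] <-
        stats::runif(design$species_core_n) < p
    }
    pool_common <- if (is_lab) intersect(common, lab_retained) else common
    present[pool_common] <-
      stats::runif(length(pool_common)) < design$common_prob
    if (sp_s == outgroup_species) {
      pool_out <- if (is_lab) intersect(outgroup_excl, lab_retained)
                  else outgroup_excl
      present[pool_out] <- stats::runif(length(pool_out)) < design$outgroup_prob
    }
    present[noise[noise_host == s]] <- TRUE

    wt <- w * present
    wt[dominant] <- 0
    if (design$diet_fold > 1 && meta$diet[s] == design$diet_class) {
      wt[diet_enriched] <- wt[diet_enriched] * design$diet_fold
    }
    dom_share <- stats::rbeta(1, dom_a, dom_b)
    rest <- sum(wt)
    if (rest > 0) wt <- wt / rest * (1 - dom_share)
    wt[dominant] <- dom_share
    ab[s, ] <- wt / sum(wt)
  }

  # ---- marker recovery and count draws -------------------------------------
  markers <- c("V12", "V34")
  recovered <- lapply(markers, function(mk) {
    keep <- stats::runif(n_taxa) < design$recovery_prob
    keep[match(dominant, taxa)] <- TRUE
    taxa[keep]
  })
  names(recovered) <- markers
  lib_sizes <- matrix(
    round(stats::rlnorm(n_samples * 2, meanlog = log(design$lib_median),
                        sdlog = design$lib_sdlog)),
    n_samples, 2, dimnames = list(meta$sample_id, markers))
  lib_sizes[lib_sizes < 1] <- 1

  otu_ids_of <- function(mk, base) {
    sprintf("%s_OTU_%04d", mk, match(base, taxa))
  }
  tables <- lapply(markers, function(mk) {
    base <- recovered[[mk]]
    comp <- ab[, base, drop = FALSE]
    counts <- matrix(0L, n_samples, length(base),
                     dimnames = list(meta$sample_id, otu_ids_of(mk, base)))
    for (s in seq_len(n_samples)) {
      p <- comp[s, ]
      if (sum(p) == 0) next
      counts[s, ] <- as.integer(
        stats::rmultinom(1, lib_sizes[s, mk], p / sum(p)))
    }
    otu_table(counts, marker = mk)
  })
  names(tables) <- markers

  # ---- taxonomy over both markers' OTU ids ---------------------------------
  tax <- NULL
  if (with_taxonomy) {
    lineages <- synth_lineages(taxa, family_core, dominant, species_core,
                               diet_enriched, outgroup_excl, noise)
    all_ids <- c(otu_ids_of("V12", recovered$V12),
                 otu_ids_of("V34", recovered$V34))
    all_base <- c(recovered$V12, recovered$V34)
    tax <- taxonomy_map(stats::setNames(lineages[all_base], all_ids))
  }

  # ---- tree: base coalescent, each recovered taxon expanded into its
  #      marker-specific tips ------------------------------------------------
  tree <- NULL
  if (with_tree) {
    base_tree <- ape::rcoal(n_taxa, tip.label = taxa)
    tree <- expand_marker_tips(base_tree, taxa, recovered, otu_ids_of)
  }

  truth <- list(
    dominant = list(base = dominant,
                    V12 = otu_ids_of("V12", dominant),
                    V34 = otu_ids_of("V34", dominant)),
    family_core = marker_ids(family_core, recovered, otu_ids_of),
    species_core = lapply(species_core, marker_ids, recovered, otu_ids_of),
    diet_enriched = c(marker_ids(diet_enriched, recovered, otu_ids_of),
                      list(fold = design$diet_fold,
                           diet_class = design$diet_class)),
    outgroup_exclusive = marker_ids(outgroup_excl, recovered, otu_ids_of),
    noise = marker_ids(noise, recovered, otu_ids_of),
    outgroup_species = outgroup_species,
    lab_retained = lab_retained,
    lib_sizes = lib_sizes)

  list(v12 = tables$V12, v34 = tables$V34, taxonomy = tax, tree = tree,
       metadata = meta, truth = truth)
}

marker_ids <- function(base, recovered, otu_ids_of) {
  list(base = base,
       V12 = otu_ids_of("V12", intersect(base, recovered$V12)),
       V34 = otu_ids_of("V34", intersect(base, recovered$V34)))
}

# plausible 7-rank lineages; species rank is unique per base taxon so taxa
# can be matched across markers at every rank
synth_lineages <- function(taxa, family_core, dominant, species_core,
                           diet_enriched, outgroup_excl, noise) {
  frames <- list(
    fuso = c("k__Bacteria", "p__Fusobacteria", "c__Fusobacteriia",
             "o__Fusobacteriales", "f__Fusobacteriaceae", "g__Cetobacterium"),
    clost = c("k__Bacteria", "p__Firmicutes", "c__Clostridia",
              "o__Clostridiales", "f__Clostridiaceae", "g__Clostridium"),
    bacilli = c("k__Bacteria", "p__Firmicutes", "c__Bacilli",
                "o__Lactobacillales", "f__Streptococcaceae", "g__Lactococcus"),
    gamma = c("k__Bacteria", "p__Proteobacteria", "c__Gammaproteobacteria",
              "o__Enterobacteriales", "f__Enterobacteriaceae",
              "g__Plesiomonas"),
    beta = c("k__Bacteria", "p__Proteobacteria", "c__Betaproteobacteria",
             "o__Neisseriales", "f__Neisseriaceae", "g__Deefgea"),
    bact = c("k__Bacteria", "p__Bacteroidetes", "c__Bacteroidia",
             "o__Bacteroidales", "f__Bacteroidaceae", "g__Bacteroides"),
    planct = c("k__Bacteria", "p__Planctomycetes", "c__Planctomycetia",
               "o__Pirellulales", "f__Pirellulaceae", "g__Pirellula"),
    verruco = c("k__Bacteria", "p__Verrucomicrobia", "c__Verrucomicrobiae",
                "o__Verrucomicrobiales", "f__Verrucomicrobiaceae",
                "g__Luteolibacter"),
    tm7 = c("k__Bacteria", "p__TM7", "c__TM7-3", "o__CW040", "f__F16", "g__"),
    melaina = c("k__Bacteria", "p__Cyanobacteria", "c__4C0d-2", "o__YS2",
                "f__", "g__"),
    chloroplast = c("k__Bacteria", "p__Cyanobacteria", "c__Chloroplast",
                    "o__Streptophyta", "f__", "g__"))
  pick <- stats::setNames(rep("clost", length(taxa)), taxa)
  base_cycle <- c("fuso", "clost", "bacilli", "gamma", "beta", "bact",
                  "planct", "verruco")
  pick[taxa] <- base_cycle[(seq_along(taxa) - 1) %% length(base_cycle) + 1]
  pick[dominant] <- "fuso"
  pick[diet_enriched] <- "clost"
  # outgroup-exclusive pool mixes distinctive lineages, incl. gut
  # Cyanobacteria (order YS2) that survive the taxon filter
  og_cycle <- c("tm7", "melaina", "bacilli", "beta")
  pick[outgroup_excl] <-
    og_cycle[(seq_along(outgroup_excl) - 1) %% length(og_cycle) + 1]
  # part of the noise pool is chloroplast material that the filter removes
  noise_cycle <- c("chloroplast", "planct", "gamma")
  pick[noise] <- noise_cycle[(seq_along(noise) - 1) %% length(noise_cycle) + 1]
  out <- vapply(taxa, function(tn) {
    fr <- frames[[pick[tn]]]
    paste(c(fr, paste0("s__", tn)), collapse = "; ")
  }, character(1))
  names(out) <- taxa
  out
}

# replace each base-taxon tip by a cherry of its marker-specific OTU ids
# (or rename it when only one marker recovered it); operates on the Newick
# string, tip labels are fixed-width so matches are unambiguous
expand_marker_tips <- function(base_tree, taxa, recovered, otu_ids_of) {
  nwk <- ape::write.tree(base_tree)
  eps <- 0.005
  for (tn in taxa) {
    in12 <- tn %in% recovered$V12
    in34 <- tn %in% recovered$V34
    if (!in12 && !in34) next
    ids <- c(if (in12) otu_ids_of("V12", tn),
             if (in34) otu_ids_of("V34", tn))
    repl <- if (length(ids) == 2) {
      sprintf("(%s:%g,%s:%g)", ids[1], eps, ids[2], eps)
    } else {
      ids
    }
    nwk <- sub(paste0("([(,])", tn, ":"),
               paste0("\\1", repl, ":"), nwk)
  }
  tree <- ape::read.tree(text = nwk)
  # drop base-taxon tips recovered by neither marker
  orphan <- intersect(tree$tip.label, taxa)
  if (length(orphan) > 0) tree <- ape::drop.tip(tree, orphan)
  tree
}

#' Write a generated dataset to a directory in standard formats
#'
#' Writes `otu_table_V12.tsv`, `otu_table_V34.tsv`, `taxonomy.tsv`,
#' `tree.nwk`, `metadata.tsv` and `truth.json`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$v12, file.path(dir, "otu_table_V12.tsv"))
  write_otu_table(dataset$v34, file.path(dir, "otu_table_V34.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- dataset$truth
  truth$lib_sizes <- as.data.frame(truth$lib_sizes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
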