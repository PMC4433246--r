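# Analysis configuration and end-to-end pipeline orchestration. A run is a
# pure function of (inputs, config, master seed): every stochastic stage
# draws from its own seed stream and all outputs are plain text tables.

#' Analysis configuration
#'
#' Collects the tunable parameters of the full pipeline with validation.
#'
#' @param depth rarefaction depth in reads per sample.
#' @param iterations rarefaction iterations for alpha diversity.
#' @param prevalence core prevalence threshold, in `(0, 1]`.
#' @param permutations permutations for all permutation tests.
#' @param draw individuals per null draw of the core-length test.
#' @param alpha significance level for indicator filtering.
#' @param min_indval indicator-value threshold of the concordance filter.
#' @param seed master seed; stage seeds are derived from it.
#' @param min_samples,singleton_min_reads retention-filter parameters.
#' @param exclude,exceptions taxon-exclusion patterns.
#' @param below_depth `"drop"` or `"error"` for samples under `depth`.
#' @param indval_rank taxonomic rank of the indicator analysis.
#' @param core_ranks ranks at which cross-marker core taxa are computed.
#' @param factors metadata factors tested by PERMANOVA.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(depth = 500, iterations = 10, prevalence = 0.8,
                            permutations = 1000, draw = 5, alpha = 0.05,
                            min_indval = 0.6, seed = 1,
                            min_samples = 2, singleton_min_reads = 4,
                            exclude = "p__Cyanobacteria",
                            exceptions = c("Melainabacteria", "YS2",
                                           "4C0d-2"),
                            below_depth = c("drop", "error"),
                            indval_rank = "genus",
                            core_ranks = c("phylum", "class", "order",
                                           "family", "genus", "species"),
                            factors = c("host_species", "host_tribe",
                                        "diet")) {
  below_depth <- match.arg(below_depth)
  cfg <- as.list(environment())
  if (!(prevalence > 0 && prevalence <= 1)) {
    stop("prevalence must lie in (0, 1], got ", prevalence)
  }
  if (depth < 1) stop("depth must be >= 1")
  if (permutations < 1) stop("permutations must be >= 1")
  if (iterations < 1) stop("iterations must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full two-marker analysis pipeline
#'
#' Executes preprocessing (retention filter, taxon exclusion), alpha
#' diversity with rarefaction averaging and between-marker concordance,
#' beta diversity (binary Jaccard, both UniFrac variants, Manhattan on
#' arcsine-transformed genus profiles), PCoA and Procrustes comparison of
#' the markers, core OTUs and cross-marker core taxa, the core-length
#' permutation test, shared-OTU proportions, level-wise PERMANOVA, and
#' indicator analysis with the concordance filter. All results are written
#' as tab-separated text plus a deterministic log; identical inputs, config
#' and seed give byte-identical outputs.
#'
#' @param v12,v34 [otu_table]s of the two markers.
#' @param taxonomy a `taxonomy_map` covering both tables.
#' @param tree rooted `ape::phylo` covering both tables' OTUs (or `NULL` to
#'   skip phylogenetic metrics).
#' @param metadata a `sample_metadata`.
#' @param config an [analysis_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with all in-memory results; side effect: result
#'   files under `out_dir`.
#' @export
run_pipeline <- function(v12, v34, taxonomy, tree = NULL, metadata,
                         config = analysis_config(), out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("microcore pipeline log",
                 paste0("master seed: ", config$seed),
                 paste0("R version: ", R.version.string),
                 paste0("config: depth=", config$depth,
                        " iterations=", config$iterations,
                        " prevalence=", config$prevalence,
                        " permutations=", config$permutations,
                        " draw=", config$draw))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(config = config)
  markers <- list(V12 = v12, V34 = v34)

  # ---- preprocess ----------------------------------------------------------
  pre <- stage("preprocess", lapply(names(markers), function(mk) {
    f1 <- filter_low_occurrence(markers[[mk]], config$min_samples,
                                config$singleton_min_reads)
    f2 <- filter_taxa(f1$table, taxonomy, config$exclude, config$exceptions)
    list(table = f2$table, reports = list(f1$report, f2$report))
  }))
  names(pre) <- names(markers)
  results$tables <- lapply(pre, `[[`, "table")
  filt <- do.call(rbind, lapply(names(pre), function(mk) {
    do.call(rbind, lapply(pre[[mk]]$reports, function(r) {
      data.frame(marker = mk, rule = r$rule, n_input = r$n_input,
                 n_removed = r$n_removed, n_retained = r$n_retained)
    }))
  }))
  write_tsv(filt, file.path(out_dir, "filter_report.tsv"))

  # ---- alpha diversity -----------------------------------------------------
  metrics <- c("chao1", "shannon", if (!is.null(tree)) "faith_pd")
  alpha_res <- stage("alpha", lapply(names(pre), function(mk) {
    suppressWarnings(alpha_with_rarefaction(
      results$tables[[mk]], metrics = metrics, depth = config$depth,
      iterations = config$iterations, tree = tree,
      seed = derive_seed(config$seed, paste0("alpha_", mk))))
  }))
  names(alpha_res) <- names(pre)
  results$alpha <- alpha_res
  for (mk in names(alpha_res)) {
    write_tsv(alpha_res[[mk]], file.path(out_dir,
                                         paste0("alpha_", mk, ".tsv")))
  }
  results$alpha_concordance <- stage("alpha_concordance", {
    species_of <- stats::setNames(metadata$host_species, metadata$sample_id)
    species_means <- lapply(alpha_res, function(a) {
      a$species <- species_of[a$sample_id]
      stats::aggregate(value ~ metric + species, data = a, FUN = mean)
    })
    mg <- merge(species_means$V12, species_means$V34,
                by = c("metric", "species"), suffixes = c("_V12", "_V34"))
    do.call(rbind, lapply(split(mg, mg$metric), function(d) {
      data.frame(metric = d$metric[1],
                 r2 = marker_concordance_r2(d$value_V12, d$value_V34))
    }))
  })
  write_tsv(results$alpha_concordance,
            file.path(out_dir, "alpha_concordance.tsv"))

  # ---- beta diversity, ordination, Procrustes ------------------------------
  beta_res <- stage("beta", lapply(names(pre), function(mk) {
    tab <- results$tables[[mk]]
    out <- list(jaccard = binary_jaccard(tab))
    if (!is.null(tree)) {
      out$unweighted_unifrac <- unweighted_unifrac(tab, tree)
      out$weighted_unifrac <- weighted_unifrac(tab, tree)
    }
    gen <- aggregate_by_rank(tab, taxonomy, "genus")
    out$manhattan_genus <- manhattan_distance(arcsin_sqrt(to_relative(gen)))
    out
  }))
  names(beta_res) <- names(pre)
  results$beta <- beta_res
  for (mk in names(beta_res)) {
    for (metric in names(beta_res[[mk]])) {
      write_tsv(dist_to_df(beta_res[[mk]][[metric]]),
                file.path(out_dir, paste0("beta_", metric, "_", mk, ".tsv")))
    }
  }
  results$procrustes <- stage("procrustes", {
    metric <- if (!is.null(tree)) "unweighted_unifrac" else "jaccard"
    pa <- pcoa(beta_res$V12[[metric]])
    pb <- pcoa(beta_res$V34[[metric]])
    pt <- procrustes_test(pa, pb, permutations = config$permutations,
                          seed = derive_seed(config$seed, "procrustes"))
    data.frame(metric = metric, m2 = pt$m2, p = pt$p,
               permutations = pt$permutations)
  })
  write_tsv(results$procrustes, file.path(out_dir, "procrustes.tsv"))

  # ---- core ----------------------------------------------------------------
  results$core_otus <- stage("core_otus", lapply(names(pre), function(mk) {
    core_members(results$tables[[mk]], metadata,
                 prevalence = config$prevalence, level = "otu")
  }))
  names(results$core_otus) <- names(pre)
  core_otu_df <- do.call(rbind, lapply(names(results$core_otus), function(mk) {
    cs <- results$core_otus[[mk]]
    if (length(cs$members) == 0) return(NULL)
    data.frame(marker = mk, otu_id = cs$members,
               threshold = cs$threshold_count, n = cs$n_samples)
  }))
  write_tsv(core_otu_df %||%
              data.frame(marker = character(0), otu_id = character(0)),
            file.path(out_dir, "core_otus.tsv"))

  results$core_taxa <- stage("core_taxa", {
    do.call(rbind, lapply(config$core_ranks, function(rk) {
      cores <- lapply(names(pre), function(mk) {
        core_members(aggregate_by_rank(results$tables[[mk]], taxonomy, rk),
                     metadata, prevalence = config$prevalence, level = rk)
      })
      both <- cross_marker_core(cores[[1]], cores[[2]])
      if (length(both$members) == 0) return(NULL)
      data.frame(rank = rk, taxon = both$members)
    }))
  })
  write_tsv(results$core_taxa %||% data.frame(rank = character(0),
                                              taxon = character(0)),
            file.path(out_dir, "core_taxa.tsv"))

  results$core_length <- stage("core_length", lapply(names(pre),
                                                     function(mk) {
    core_length_permutation_test(
      results$tables[[mk]], metadata, draw = config$draw,
      permutations = config$permutations, prevalence = config$prevalence,
      seed = derive_seed(config$seed, paste0("core_length_", mk)))
  }))
  names(results$core_length) <- names(pre)
  write_tsv(do.call(rbind, lapply(names(results$core_length), function(mk) {
    cbind(marker = mk, results$core_length[[mk]]$results)
  })), file.path(out_dir, "core_length_test.tsv"))

  results$shared_otus <- stage("shared_otus", lapply(names(pre),
                                                     function(mk) {
    s <- shared_otu_proportions(results$tables[[mk]], metadata)
    data.frame(marker = mk, W = s$W, p = s$p)
  }))
  write_tsv(do.call(rbind, results$shared_otus),
            file.path(out_dir, "shared_otu_test.tsv"))

  # ---- group tests and indicators ------------------------------------------
  results$permanova <- stage("permanova", {
    do.call(rbind, lapply(names(pre), function(mk) {
      do.call(rbind, lapply(config$factors, function(fc) {
        lw <- levelwise_group_tests(
          results$tables[[mk]], taxonomy, metadata, fc,
          permutations = config$permutations,
          seed = derive_seed(config$seed, paste0("lw_", mk, "_", fc)))
        cbind(marker = mk, factor = fc, lw)
      }))
    }))
  })
  write_tsv(results$permanova, file.path(out_dir, "permanova.tsv"))

  results$indicators <- stage("indval", {
    recs <- lapply(names(pre), function(mk) {
      tab <- aggregate_by_rank(results$tables[[mk]], taxonomy,
                               config$indval_rank)
      cl <- align_metadata(metadata, tab)$host_species
      indval_significance(tab, cl, permutations = config$permutations,
                          seed = derive_seed(config$seed,
                                             paste0("indval_", mk)))
    })
    names(recs) <- names(pre)
    list(per_marker = recs,
         concordant = concordant_indicators(recs$V12, recs$V34,
                                            alpha = config$alpha,
                                            min_indval = config$min_indval))
  })
  for (mk in names(results$indicators$per_marker)) {
    write_tsv(results$indicators$per_marker[[mk]],
              file.path(out_dir, paste0("indval_", mk, ".tsv")))
  }
  write_tsv(results$indicators$concordant,
            file.path(out_dir, "indval_concordant.tsv"))

  writeLines(c(log_lines, "status: complete"),
             file.path(out_dir, "pipeline.log"))
  invisible(results)
}

# deterministic TSV writer: fixed significant digits, no quoting
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

dist_to_df <- function(d) {
  m <- as.matrix(d)
  data.frame(sample_id = rownames(m), m, check.names = FALSE,
             stringsAsFactors = FALSE)
}
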