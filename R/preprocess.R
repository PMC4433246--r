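# OTU/taxon filtering rules, rarefaction, rank aggregation and abundance
# transforms applied to a per-marker combined OTU table before any diversity
# or core computation.

new_filter_report <- function(rule, removed_ids, n_input) {
  structure(list(rule = rule, removed_ids = removed_ids,
                 n_input = n_input, n_removed = length(removed_ids),
                 n_retained = n_input - length(removed_ids)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter '%s': %d of %d OTUs removed, %d retained\n",
              x$rule, x$n_removed, x$n_input, x$n_retained))
  invisible(x)
}

#' Drop low-occurrence OTUs
#'
#' Retains an OTU iff it occurs in at least `min_samples` samples, or occurs
#' in exactly one sample with a total of at least `singleton_min_reads`
#' reads. The defaults keep OTUs shared across two or more samples plus all
#' single-sample OTUs backed by more than three reads; all-zero columns are
#' always removed.
#'
#' @param x an [otu_table].
#' @param min_samples minimum number of samples for multi-sample retention.
#' @param singleton_min_reads minimum total reads for single-sample OTUs.
#' @return List with elements `table` (filtered [otu_table]) and `report`
#'   (a `filter_report`).
#' @export
filter_low_occurrence <- function(x, min_samples = 2, singleton_min_reads = 4) {
  m <- otu_counts(x)
  n_occ <- colSums(m > 0)
  total <- colSums(m)
  keep <- n_occ >= min_samples | (n_occ == 1 & total >= singleton_min_reads)
  out <- subset_otu_table(x, otus = which(keep))
  list(table = out,
       report = new_filter_report("low_occurrence",
                                  colnames(m)[!keep], ncol(m)))
}

#' Remove OTUs matching a taxon-exclusion pattern
#'
#' Removes OTUs whose lineage string matches `exclude` unless it also matches
#' any of the `exceptions`. The defaults remove the phylum Cyanobacteria —
#' treated as derived from ingested plant or environmental material — while
#' keeping the gut-associated Melainabacteria lineages (class 4C0d-2, order
#' YS2).
#'
#' @param x an [otu_table].
#' @param tax a `taxonomy_map` covering every OTU in `x`.
#' @param exclude regular expression matched against the formatted lineage.
#' @param exceptions character vector of patterns that override `exclude`.
#' @return List with elements `table` and `report`, as in
#'   [filter_low_occurrence()].
#' @export
filter_taxa <- function(x, tax, exclude = "p__Cyanobacteria",
                        exceptions = c("Melainabacteria", "YS2", "4C0d-2")) {
  lin <- lineage_strings(tax, otu_ids(x))
  hit <- tryCatch(grepl(exclude, lin),
                  error = function(e) stop("malformed exclude pattern: ",
                                           conditionMessage(e)))
  if (length(exceptions) > 0) {
    keep_back <- Reduce(`|`, lapply(exceptions, function(p) grepl(p, lin)))
    hit <- hit & !keep_back
  }
  out <- subset_otu_table(x, otus = which(!hit))
  list(table = out,
       report = new_filter_report("taxon_exclusion",
                                  otu_ids(x)[hit], length(lin)))
}

#' Rarefy every sample to a fixed depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (per-sample multivariate hypergeometric draw, via
#' [vegan::rrarefy()]). Samples with fewer reads than `depth` are dropped
#' with a warning by default, or raise an error.
#'
#' @param x an [otu_table].
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param below_depth `"drop"` (default) or `"error"` for samples whose
#'   library is smaller than `depth`.
#' @return A rarefied [otu_table]; OTU columns are retained even if all-zero
#'   after rarefaction.
#' @export
rarefy <- function(x, depth = 500, seed = NULL,
                   below_depth = c("drop", "error")) {
  below_depth <- match.arg(below_depth)
  stopifnot(depth >= 1)
  m <- otu_counts(x)
  tot <- rowSums(m)
  low <- tot < depth
  if (any(low)) {
    if (below_depth == "error") {
      stop("samples below rarefaction depth ", depth, ": ",
           paste(rownames(m)[low], collapse = ", "))
    }
    warning("dropping ", sum(low), " sample(s) below rarefaction depth ",
            depth, ": ", paste(rownames(m)[low], collapse = ", "))
    m <- m[!low, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("all samples fall below rarefaction depth ", depth)
  r <- with_seed(seed, rrarefy_quiet(m, depth))
  otu_table(r, marker = otu_marker(x))
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums counts of OTUs carrying the same taxon label at `rank`; OTUs
#' unassigned at that rank are pooled into an explicit `"unassigned"`
#' column. Row sums are preserved exactly.
#'
#' @param x an [otu_table].
#' @param tax a `taxonomy_map` covering every OTU in `x`.
#' @param rank one of `kingdom`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return An [otu_table] whose columns are taxon labels at `rank`.
#' @export
aggregate_by_rank <- function(x, tax, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  labels <- rank_labels(tax, otu_ids(x), rank)
  labels[is.na(labels) | !nzchar(labels)] <- "unassigned"
  m <- otu_counts(x)
  agg <- t(rowsum(t(m), group = labels))
  otu_table(agg, marker = otu_marker(x))
}

#' Convert counts to relative abundances
#'
#' @param x an [otu_table] (or numeric matrix) with positive row sums.
#' @return Numeric matrix of per-sample fractions summing to one per row.
#' @export
to_relative <- function(x) {
  m <- if (inherits(x, "otu_table")) otu_counts(x) else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("empty sample(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  }
  m / tot
}

#' Arcsine square-root transform of fractional data
#'
#' The variance-stabilising transform x -> arcsin(sqrt(x)), mapping `[0, 1]`
#' onto `[0, pi/2]`. Applied to relative abundances before Manhattan-distance
#' ordination so that both rare and dominant taxa gain weight.
#'
#' @param m numeric matrix or vector of values in `[0, 1]`.
#' @return Transformed object of the same shape.
#' @export
arcsin_sqrt <- function(m) {
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("arcsin_sqrt expects fractional data in [0, 1]")
  }
  asin(sqrt(m))
}
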