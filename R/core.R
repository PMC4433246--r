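# Core microbiota: multi-criterion core membership, relative core length,
# the species-label permutation test, and intra- vs inter-specific
# shared-OTU comparisons. These are the survey's bespoke statistics.

#' Multi-criterion core membership
#'
#' A member (OTU, or taxon after rank aggregation) belongs to the core iff it
#' is present in at least `ceiling(prevalence * N)` of the N in-scope
#' individuals, and — when `require_every_species` — in at least one
#' individual of every in-scope host species. The scope defaults to wild
#' individuals only, so laboratory populations never influence the wild
#' core. Prevalence uses a ceiling so that "at least 80%" is a hard lower
#' bound (e.g. 20 of 25 individuals).
#'
#' @param x an [otu_table] (at OTU level or rank-aggregated via
#'   [aggregate_by_rank()]).
#' @param meta a `sample_metadata` covering the table's samples.
#' @param prevalence fraction in `(0, 1]`.
#' @param require_every_species logical; demand one representative per
#'   species.
#' @param scope `"wild"` (default) or `"all"`.
#' @param level descriptive label recorded in the result (e.g. `"otu"`,
#'   `"genus"`).
#' @param rounding `"ceiling"` (default) or `"floor"` for the prevalence
#'   count threshold.
#' @return An object of class `core_set`: list with `members`, `level`,
#'   `prevalence`, `threshold_count`, `n_samples`, `criteria`, `scope`.
#' @export
core_members <- function(x, meta, prevalence = 0.8,
                         require_every_species = TRUE,
                         scope = c("wild", "all"), level = "otu",
                         rounding = c("ceiling", "floor")) {
  scope <- match.arg(scope)
  rounding <- match.arg(rounding)
  stopifnot(prevalence > 0, prevalence <= 1)
  meta <- align_metadata(meta, x)
  keep <- if (scope == "wild") meta$origin == "wild" else rep(TRUE, nrow(meta))
  if (!any(keep)) stop("no samples in scope")
  pres <- otu_presence(x)[keep, , drop = FALSE]
  species <- meta$host_species[keep]
  n <- nrow(pres)
  thr <- if (rounding == "ceiling") ceiling(prevalence * n)
         else max(1, floor(prevalence * n))
  occ <- colSums(pres)
  member <- occ >= thr
  if (require_every_species) {
    by_sp <- rowsum(pres * 1, group = species)  # species x members
    member <- member & colSums(by_sp > 0) == nrow(by_sp)
  }
  members <- colnames(pres)[member]
  members <- setdiff(members, "unassigned")
  structure(list(members = members, level = level,
                 prevalence = prevalence, threshold_count = thr,
                 n_samples = n,
                 criteria = c(overall_prevalence = TRUE,
                              every_species = require_every_species,
                              cross_marker = FALSE),
                 scope = scope),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(
    "core_set [%s, %s scope]: %d members at prevalence >= %.0f%% (>= %d of %d individuals)%s\n",
    x$level, x$scope, length(x$members), 100 * x$prevalence,
    x$threshold_count, x$n_samples,
    if (x$criteria[["every_species"]]) ", every species represented" else ""))
  invisible(x)
}

#' Cross-marker concordant core
#'
#' Intersects two rank-level cores by taxon name. OTU identifiers are
#' marker-specific, so concordance is only meaningful at taxonomic ranks;
#' unassigned or blank names never match.
#'
#' @param core_a,core_b `core_set` objects at the same taxonomic rank.
#' @return A `core_set` whose members are the shared taxon names and whose
#'   `cross_marker` criterion flag is set.
#' @export
cross_marker_core <- function(core_a, core_b) {
  stopifnot(inherits(core_a, "core_set"), inherits(core_b, "core_set"))
  if (!identical(core_a$level, core_b$level)) {
    stop("cores computed at different levels: ", core_a$level, " vs ",
         core_b$level)
  }
  if (identical(core_a$level, "otu")) {
    stop("cross-marker concordance applies to taxonomic ranks, not OTUs")
  }
  clean <- function(v) setdiff(v[nzchar(v)], "unassigned")
  out <- core_a
  out$members <- sort(intersect(clean(core_a$members), clean(core_b$members)))
  out$criteria["cross_marker"] <- TRUE
  out
}

#' Relative core length of a set of individuals
#'
#' The fraction of the OTUs observed in a set of n individuals that are
#' present in at least `ceiling(prevalence * n)` of them: core OTUs over
#' total OTUs for the set.
#'
#' @param x an [otu_table].
#' @param individuals sample ids (or logical/integer row index).
#' @param prevalence fraction in `(0, 1]`.
#' @return A fraction in `[0, 1]`; 1 iff all individuals share identical
#'   presence sets, `NA` if the individuals carry no OTUs at all.
#' @export
relative_core_length <- function(x, individuals, prevalence = 0.8) {
  pres <- otu_presence(x)[individuals, , drop = FALSE]
  n <- nrow(pres)
  if (n == 0) stop("no individuals selected")
  occ <- colSums(pres)
  total <- sum(occ >= 1)
  if (total == 0) return(NA_real_)
  sum(occ >= ceiling(prevalence * n)) / total
}

#' Permutation test of species relative core length
#'
#' For every host species with at least two in-scope individuals, the
#' observed relative core length of its conspecifics is compared with a null
#' distribution obtained by ignoring species labels: `permutations` draws of
#' `draw` individuals sampled without replacement from all in-scope (wild)
#' individuals, each scored by [relative_core_length()]. The one-sided
#' p-value is `(number of null values >= observed + 1) / (B + 1)`. Species
#' represented by a single individual are excluded. Species whose own n
#' differs from `draw` are scored on their own n with the matching ceiling
#' threshold.
#'
#' @param x an [otu_table].
#' @param meta a `sample_metadata` covering the table's samples.
#' @param draw individuals per null draw.
#' @param permutations number of null draws B.
#' @param prevalence core prevalence threshold.
#' @param seed integer seed.
#' @param scope `"wild"` (default) or `"all"`.
#' @return An object of class `core_length_test`: list with `results` (data
#'   frame `species`, `n`, `observed`, `p`), `null` (B null values), `draw`,
#'   `permutations`, `prevalence`, `excluded` species.
#' @export
core_length_permutation_test <- function(x, meta, draw = 5,
                                         permutations = 1000,
                                         prevalence = 0.8, seed = NULL,
                                         scope = c("wild", "all")) {
  scope <- match.arg(scope)
  meta <- align_metadata(meta, x)
  keep <- if (scope == "wild") meta$origin == "wild" else rep(TRUE, nrow(meta))
  pres <- otu_presence(x)[keep, , drop = FALSE]
  species <- meta$host_species[keep]
  n_pool <- nrow(pres)
  if (n_pool < draw) stop("pooled individuals (", n_pool,
                          ") fewer than draw size ", draw)
  rcl <- function(rows) {
    occ <- colSums(pres[rows, , drop = FALSE])
    total <- sum(occ >= 1)
    if (total == 0) return(NA_real_)
    sum(occ >= ceiling(prevalence * length(rows))) / total
  }
  null <- with_seed(seed, {
    vapply(seq_len(permutations),
           function(b) rcl(sample.int(n_pool, draw)), numeric(1))
  })
  tab <- table(species)
  use <- names(tab)[tab >= 2]
  excluded <- names(tab)[tab < 2]
  res <- do.call(rbind, lapply(use, function(sp) {
    rows <- which(species == sp)
    obs <- rcl(rows)
    data.frame(species = sp, n = length(rows), observed = obs,
               p = perm_pvalue(sum(null >= obs), permutations),
               stringsAsFactors = FALSE)
  }))
  structure(list(results = res, null = null, draw = draw,
                 permutations = permutations, prevalence = prevalence,
                 excluded = excluded),
            class = "core_length_test")
}

#' @export
print.core_length_test <- function(x, ...) {
  cat(sprintf(
    "relative core length test: draw %d of pooled individuals, %d permutations\n",
    x$draw, x$permutations))
  print(x$results, row.names = FALSE)
  if (length(x$excluded)) {
    cat("excluded (single individual):", paste(x$excluded, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Intra- versus inter-specific shared-OTU proportions
#'
#' For every pair of individuals, the shared fraction is the Jaccard
#' similarity of their OTU presence sets, `|A int B| / |A un B|`. Pairs are
#' labelled intraspecific or interspecific and the two distributions are
#' compared with a continuity-corrected rank-sum test.
#'
#' @param x an [otu_table].
#' @param meta a `sample_metadata` covering the table's samples.
#' @param species_subset optional character vector restricting the analysis
#'   to some host species (e.g. a single tribe).
#' @param scope `"wild"` (default) or `"all"`.
#' @param alternative test alternative; `"greater"` asks whether
#'   intraspecific sharing exceeds interspecific sharing.
#' @return List with `pairs` (data frame `sample1`, `sample2`, `shared`,
#'   `type`), `W`, `p`, `alternative`.
#' @export
shared_otu_proportions <- function(x, meta, species_subset = NULL,
                                   scope = c("wild", "all"),
                                   alternative = "two.sided") {
  scope <- match.arg(scope)
  meta <- align_metadata(meta, x)
  keep <- if (scope == "wild") meta$origin == "wild" else rep(TRUE, nrow(meta))
  if (!is.null(species_subset)) {
    keep <- keep & meta$host_species %in% species_subset
  }
  pres <- otu_presence(x)[keep, , drop = FALSE]
  species <- meta$host_species[keep]
  ids <- rownames(pres)
  n <- nrow(pres)
  if (n < 3) stop("need at least three in-scope individuals")
  pairs <- utils::combn(n, 2)
  shared <- apply(pairs, 2, function(ij) {
    a <- pres[ij[1], ]
    b <- pres[ij[2], ]
    u <- sum(a | b)
    if (u == 0) 0 else sum(a & b) / u
  })
  type <- ifelse(species[pairs[1, ]] == species[pairs[2, ]],
                 "intraspecific", "interspecific")
  test <- rank_sum_continuity(shared[type == "intraspecific"],
                              shared[type == "interspecific"],
                              alternative = alternative)
  list(pairs = data.frame(sample1 = ids[pairs[1, ]],
                          sample2 = ids[pairs[2, ]],
                          shared = shared, type = type,
                          stringsAsFactors = FALSE),
       W = test$W, p = test$p, alternative = alternative)
}
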