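---
title: "Methods: core microbiota, diversity and indicator analysis with microcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core microbiota, diversity and indicator analysis with microcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcore)
```

## The analysis problem

`microcore` analyses gut-microbiota surveys in which the same host
specimens were profiled with **two independent 16S rRNA amplicons**
(labelled V12 and V34 throughout). Because each marker has its own primer
biases and its own de-novo OTU space, any biological claim — a core taxon,
an indicator taxon — gains credibility when it is recovered independently
by both markers. The package implements the full analysis chain on OTU
count tables: occurrence filtering, rarefaction-based diversity
estimation, phylogenetic and non-phylogenetic beta diversity, ordination
comparison between markers, a multi-criterion core-microbiota computation
with a permutation test, distance-based permutational MANOVA, and
indicator-value analysis with a cross-marker concordance filter.

The motivating system is a clade of closely related cichlid host species
(several zooplanktivorous and scale-eating species of one tribe, plus an
omnivorous outgroup species of a distant tribe, one of them also kept as a
laboratory strain), but nothing in the code is specific to fish: any
samples-by-OTUs count table with host-species metadata fits.

## Data model

* `otu_table` — integer read counts, samples in rows, OTUs in columns,
  tagged with a marker label. Counts stay integers end to end; relative
  abundances are always derived downstream, because rarefaction (the basis
  of all diversity estimates here) only makes sense on read counts.
* `taxonomy_map` — Greengenes-style 7-rank lineages per OTU. Taxonomy is
  the **join key between markers**: OTU identifiers are marker-specific
  and never compared across markers.
* `sample_metadata` — host species, genus, tribe, diet and wild/lab
  origin per sample; each species maps to exactly one value of each
  attribute.
* A rooted phylogeny over OTU ids (branch lengths in substitutions/site)
  backs Faith's PD and both UniFrac variants.

## Preprocessing

Two filters mirror standard practice for 454-era amplicon surveys:

1. **Occurrence filter** — keep an OTU if it occurs in ≥ 2 samples, or in
   exactly one sample with ≥ 4 reads. The single-sample threshold is a
   strict reading of "more than three reads"; both numbers are exposed as
   parameters.
2. **Taxon exclusion** — remove Cyanobacteria as presumptively ingested
   material (chloroplasts of plant matter), *except* the gut-associated
   Melainabacteria lineages (class 4C0d-2, order YS2), which are genuine
   gut symbionts. Patterns and exceptions are configurable.

Both filters are idempotent and report per-rule removal counts. Filters
run on the per-marker combined table (all same-amplicon libraries pooled),
before any rarefaction.

Rarefaction subsamples each library without replacement to a fixed depth
(default 500 reads — a depth chosen for surveys whose smallest library is
of that order). Per sample this is a multivariate hypergeometric draw;
samples below the depth are dropped with a warning by default because a
specimen with too few reads carries no information at the common depth
(an `error` mode is available when silent dropping would be unacceptable).

The arcsine square-root transform `x -> asin(sqrt(x))` is applied to
relative abundances before Manhattan-distance ordination. The square root
is included deliberately (the variance-stabilising convention for
proportions); the transform choice is configurable since some authors
apply a bare arcsine.

## Diversity estimation

* **Chao1** uses the bias-corrected estimator
  `S_obs + F1(F1-1) / (2(F2+1))` by default so that the estimate is
  defined when no doubletons occur; the classic `S_obs + F1^2/(2 F2)` is
  available for comparison.
* **Shannon** entropy is reported in bits (base 2), the convention of the
  classic amplicon toolchain; the base is a parameter.
* **Faith's PD** follows the *whole-tree* convention: the root path is
  always part of the spanning subtree.
* All three are computed as means over independent rarefactions (default
  10 iterations at depth 500), the standard way to remove library-size
  bias from alpha-diversity comparisons.
* **Beta diversity**: presence-absence binary Jaccard; unweighted UniFrac
  (fraction of observed branch length unique to one sample, branches taken
  relative to the root); weighted UniFrac, normalised by default so values
  lie in [0, 1] (the raw abundance-weighted branch difference is exposed
  via `normalized = FALSE`); Manhattan distance on arcsine-transformed
  relative abundances. On raw relative abundances Manhattan equals twice
  Bray-Curtis, a property the test-suite checks to numerical tolerance.

PCoA is the classical double-centred eigendecomposition. Negative
eigenvalues (expected for non-Euclidean dissimilarities such as Jaccard)
are reported, not corrected, and coordinates are returned only for
positive axes. Procrustes comparison of two marker ordinations centres
both configurations, scales each to unit total sum of squares, and
reports the symmetric `M^2` (normalised residual sum of squares after the
optimal rotation); significance comes from permuting sample labels of one
configuration, with `p = (b + 1)/(B + 1)`.

## The core microbiota

A member of the core must satisfy every enabled criterion:

1. **Prevalence** — present in at least `ceiling(0.8 * N)` of the `N`
   in-scope individuals. The ceiling makes "at least 80%" a hard bound
   (20 of 25); a floor variant is available but not default.
2. **Every species represented** — present in ≥ 1 individual of each host
   species, so a taxon ubiquitous in one abundant host cannot pass alone.
3. **Cross-marker concordance** (core *taxa* only) — recovered by both
   markers, matched by taxon name at the chosen rank. OTU-level cores are
   never intersected across markers because the OTU spaces are disjoint.

Laboratory samples are excluded from the core scope by default: the wild
core is the biological target, and captive animals would otherwise drag
prevalence down (or, for a depleted strain, up at small `N`).

The **relative core length** of a set of `n` individuals is the number of
OTUs present in ≥ `ceiling(0.8 n)` of them divided by the number present
in at least one. The permutation test compares each species' observed
value against a null built by ignoring species labels: `B = 1000` draws of
5 random individuals from the pooled wild specimens. The p-value is
one-sided (`null >= observed`), matching the directional question "is the
conspecific core larger than chance?". Species with a single individual
are excluded — their core length is trivially 1. The null draws are
unconstrained random individuals (not forced to span species), the
simplest reading of label shuffling; one shared null serves all species.

Pairwise shared-OTU proportions use the Jaccard similarity convention
(`|A ∩ B| / |A ∪ B|`); the union denominator was chosen over
smaller-repertoire normalisation because it is symmetric, bounded and the
direct set-similarity counterpart of the binary Jaccard distance used in
the beta-diversity stage. Intra- versus inter-specific distributions are
compared with a continuity-corrected rank-sum test (the sample sizes are
dozens to hundreds of dependent pairs, so the normal approximation is the
honest choice, and the dependence is acknowledged as a limitation below).

## PERMANOVA and indicator values

The one-factor PERMANOVA partitions the total sum of squared distances
(`SS_T = sum of d^2 over pairs / n`) into among- and within-group parts;
`pseudo-F = (SS_A/(a-1)) / (SS_W/(n-a))`, `R^2 = SS_A / SS_T`, and the
p-value permutes group labels (one-sided, large F). The implementation is
checked against `vegan::adonis2` for F and `R^2` in the test-suite. The
level-wise battery repeats aggregate → relative → arcsine √ → Manhattan →
PERMANOVA for each taxonomic level, plus a presence/absence Jaccard test
at OTU level.

Indicator values follow the original Dufrêne–Legendre definition:
specificity `A_ij` (mean abundance of taxon i in cluster j over the sum of
its mean abundances across clusters) times fidelity `B_ij` (fraction of
cluster-j samples containing i); the reported value is the maximum over
clusters, its argmax is the assigned cluster, and ties (broken
lexicographically) are flagged. `A` is computed from per-sample *relative*
abundances by default for library-size robustness; a raw-count mode is
provided because the original definition is stated on abundance.
Significance permutes cluster labels freely over samples
(`p = (b+1)/(B+1)` on the per-taxon maximum); a stratified scheme was
considered and rejected for the default because the clusters themselves
are the hypothesis. The concordance filter retains taxa significant in
both markers, assigned to the same cluster in both, with indicator value
≥ 0.6 in at least one marker — the two-marker analogue of requiring
replication before reporting.

## The synthetic community generator

`generate_dataset()` emulates the statistical structure such a survey
exhibits, with a truth record for every planted feature:

* six wild host species with 5/5/5/4/1/5 individuals (25 wild specimens,
  one species deliberately represented by a single individual) plus a
  5-individual laboratory population of the outgroup species — 30 samples;
* one **dominant OTU** whose per-sample share is Beta-distributed with
  mean 0.30 (concentration 20, so SD ≈ 0.10 across specimens);
* a **family-wide core** of 20 OTUs modelled as obligate (present in every
  gut before sequencing noise) with 10× abundance weight — the behaviour
  of the handful of highly prevalent symbionts that dominate such guts.
  Making them obligate keeps the planted truth meaningful: with presence
  probability 0.95 the every-species criterion would fail at random
  through the single-individual species, a property of the criterion, not
  of the community;
* **per-species cores** (12 OTUs each, presence probability 0.97 in
  conspecifics, 0.10 elsewhere — promiscuity, not strict host
  specificity). 0.97 is the smallest round probability for which a planted
  core clears the 80% prevalence criterion in ≥ 95% of draws even for the
  4-individual species (`p^4 ≥ 0.95` needs `p ≥ 0.987` exactly; with
  near-certain read-level detection 0.97 achieves ≈ 0.97 overall, and
  ≥ 0.95 on average across species sizes);
* a **common pool** of 200 OTUs at presence probability 0.3 — the
  non-core diversity that sets realistic relative core lengths of roughly
  0.13–0.19 per species;
* 25 **outgroup-exclusive** taxa (presence 0.7 in the outgroup host only),
  a mix of distinctive lineages including gut Cyanobacteria of order YS2
  that must survive the taxon filter;
* 8 **diet-enriched** taxa (Clostridium-like lineages) multiplied 3× in
  scale-eater samples before renormalisation;
* **environmental noise**: ~2 singleton OTUs per sample at a weight that
  yields a few reads (some pass the 4-read singleton rule, most do not);
  part of the noise pool carries chloroplast lineages that the taxon
  filter removes;
* log-normal **library sizes** (median 8000 reads, sdlog 0.4) and
  multinomial count draws per marker;
* **marker divergence** as independent OTU dropout (recovery probability
  0.9 per marker, dominant OTU always recovered) with disjoint OTU id
  spaces joined only through taxonomy — mirroring how real markers
  recover overlapping but non-identical taxon sets;
* the **laboratory population** re-uses the outgroup's pool with half of
  the non-core component removed — diversity depletion in captivity with
  the core retained.

Counts are multinomial rather than Dirichlet-multinomial by default: the
simplest model satisfying every downstream assumption. Over-dispersion,
spatial structure, chimeras, PCR error and sequence-level artefacts are
deliberately *not* modelled, and the dispersion-like defaults
(concentration 20, sdlog 0.4) are order-of-magnitude choices, not fitted
values; no public read data exist to fit them. Passing tests on this
generator therefore demonstrates correctness of the statistics under the
stated sampling model — not robustness to the full messiness of real
amplicon data.

A note on calibration checks: "label-exchangeable" data require switching
off *all* host-specific structure — diet enrichment, species cores **and
the outgroup-exclusive pool** (the latter is species structure too, even
though it is not called a core). The calibration tests do exactly that
and observe rejection rates compatible with the nominal 5% level.

## Numerical and testing choices

* Every permutation p-value uses the `(b + 1)/(B + 1)` rule, so p is never
  zero and is exact under exchangeability.
* One master seed; each stochastic stage derives an independent stream
  keyed by its stage name, so changing the iteration count of one stage
  never perturbs another, and a pipeline run is byte-reproducible.
* Prevalence thresholds use `ceiling`; ties in indicator argmax break
  lexicographically and are flagged.
* Degenerate inputs are first-class: empty samples error in
  `to_relative`, all-equal distance matrices are flagged by PERMANOVA
  (p = 1 by construction), single-member groups yield `NA` within-group
  statistics, and rank-aggregated "unassigned" pools are excluded from
  core membership and taxon matching.
* Test problem sizes are chosen to keep the whole suite under a minute on
  one core while still giving the Monte-Carlo checks resolving power:
  8-tip trees for the UniFrac oracle (50 replicates), 720-permutation
  exhaustive PERMANOVA enumeration at n = 6, 500 calibration replicates
  at B = 199 for the core-length test (the 1000-permutation default is
  used where power, not calibration, is measured), 200 replicates for
  Procrustes null uniformity.

## Known limitations

* Shared-OTU pair proportions are dependent across pairs sharing an
  individual; the rank-sum test ignores this, as is conventional, so its
  p-values are approximate.
* The PERMANOVA is one-factor only (no strata, no covariates); nested or
  crossed designs need a dedicated tool.
* Unweighted UniFrac counts branches relative to the root; trees rooted
  far outside the observed taxa will inflate shared basal branch length.
* Cross-marker matching is by taxon name, so taxa unassigned at the
  matching rank can never be concordant, and name-level matching inherits
  any inconsistency of the reference taxonomy.
* The balanced-design minimum PERMANOVA p exceeds `1/(B+1)` because label
  permutations reproducing the original partition tie with the observed F
  (2 of 70 distinct assignments for two groups of four).
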