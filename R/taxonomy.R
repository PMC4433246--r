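# Greengenes-style taxonomy handling: OTU id -> ranked lineage. The seven
# canonical ranks are kingdom..species with "k__".."s__" prefixes; lineages
# may be truncated at any depth but never skip a rank.

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse a Greengenes-style lineage string
#'
#' @param lineage character string such as
#'   `"k__Bacteria; p__Firmicutes; c__Clostridia"`.
#' @return Named character vector over the seven canonical ranks; unassigned
#'   ranks are `NA`.
#' @examples
#' parse_lineage("k__Bacteria; p__Firmicutes")
#' @export
parse_lineage <- function(lineage) {
  out <- stats::setNames(rep(NA_character_, 7L), TAX_RANKS)
  if (is.na(lineage) || !nzchar(trimws(lineage))) return(out)
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts) | seq_along(parts) <= length(parts)]
  last <- 0L
  for (p in parts) {
    if (!nzchar(p)) next
    hit <- which(vapply(TAX_PREFIXES, function(pre) startsWith(p, pre),
                        logical(1)))
    if (length(hit) != 1L) stop("unrecognised rank token: '", p, "'")
    if (hit <= last) {
      stop("rank prefixes out of canonical order near '", p, "'")
    }
    if (hit > last + 1L) {
      # explicit empty tokens for skipped ranks are required upstream; a
      # silent gap means the lineage is malformed unless the skipped tokens
      # were present-but-empty, which strsplit preserved as "" and we skipped
      gap <- seq.int(last + 1L, hit - 1L)
      out[gap] <- NA_character_
    }
    val <- substring(p, 4L)
    out[hit] <- if (nzchar(val)) val else NA_character_
    last <- hit
  }
  out
}

#' Format a ranked lineage back into a Greengenes-style string
#'
#' The inverse of [parse_lineage()] on fully specified prefixes: assigned
#' ranks are rendered as `x__name`, trailing unassigned ranks as bare
#' prefixes, so a full 7-rank lineage round-trips exactly.
#'
#' @param lineage named character vector over the seven canonical ranks.
#' @return A single lineage string.
#' @export
format_lineage <- function(lineage) {
  stopifnot(length(lineage) == 7L)
  toks <- paste0(TAX_PREFIXES,
                 ifelse(is.na(lineage) | !nzchar(lineage), "", lineage))
  paste(toks, collapse = "; ")
}

#' Read a two-column OTU -> lineage taxonomy map
#'
#' @param path tab-separated file with columns `otu_id` and `lineage` (header
#'   optional).
#' @param otu_ids optional character vector; OTUs missing from the file are
#'   added as fully unassigned entries with a warning.
#' @return A `taxonomy_map`: data frame with `otu_id` plus one column per
#'   canonical rank (`NA` where unassigned).
#' @export
read_taxonomy <- function(path, otu_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "otu_id")) df <- df[-1, , drop = FALSE]
  taxonomy_map(stats::setNames(as.character(df[[2]]), as.character(df[[1]])),
               otu_ids = otu_ids)
}

#' Build a taxonomy map from named lineage strings
#'
#' @param lineages named character vector, names are OTU ids and values
#'   Greengenes-style lineage strings.
#' @param otu_ids optional full id universe; missing entries are filled as
#'   unassigned with a warning.
#' @return A `taxonomy_map` data frame.
#' @export
taxonomy_map <- function(lineages, otu_ids = NULL) {
  if (anyDuplicated(names(lineages))) stop("duplicate OTU ids in taxonomy")
  if (!is.null(otu_ids)) {
    missing <- setdiff(otu_ids, names(lineages))
    if (length(missing) > 0) {
      warning(length(missing),
              " OTU(s) missing from taxonomy; recorded as unassigned")
      lineages <- c(lineages, stats::setNames(rep("", length(missing)),
                                              missing))
    }
  }
  parsed <- t(vapply(lineages, parse_lineage, character(7)))
  out <- data.frame(otu_id = names(lineages), parsed,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Write a taxonomy map as tab-separated text
#'
#' @param tax a `taxonomy_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  strings <- apply(as.matrix(tax[, TAX_RANKS]), 1, format_lineage)
  utils::write.table(data.frame(tax$otu_id, strings),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# lineage strings (for pattern filters) for a set of otu ids, in order
lineage_strings <- function(tax, ids) {
  idx <- match(ids, tax$otu_id)
  if (anyNA(idx)) {
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  apply(as.matrix(tax[idx, TAX_RANKS]), 1, format_lineage)
}

# rank labels for a set of otu ids; NA where unassigned at that rank
rank_labels <- function(tax, ids, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  idx <- match(ids, tax$otu_id)
  if (anyNA(idx)) {
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  tax[[rank]][idx]
}
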