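# Sample metadata: host species / genus / tribe / diet / origin labels.
# These are the grouping factors behind every comparison in the pipeline.

DIET_LEVELS <- c("zooplanktivore", "scale-eater", "omnivore")
ORIGIN_LEVELS <- c("wild", "lab")

#' Construct and validate sample metadata
#'
#' Each sample carries its host species and the species-level attributes
#' (genus, tribe, diet, origin). A species must map to exactly one value of
#' each attribute; duplicated sample ids are rejected.
#'
#' @param df data frame with columns `sample_id`, `host_species`,
#'   `host_genus`, `host_tribe`, `diet`, `origin`.
#' @return A validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "host_species", "host_genus", "host_tribe",
            "diet", "origin")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$diet %in% DIET_LEVELS)) {
    stop("diet must be one of: ", paste(DIET_LEVELS, collapse = ", "))
  }
  if (!all(df$origin %in% ORIGIN_LEVELS)) {
    stop("origin must be one of: ", paste(ORIGIN_LEVELS, collapse = ", "))
  }
  for (attr in c("host_genus", "host_tribe", "diet", "origin")) {
    k <- tapply(df[[attr]], df$host_species, function(v) length(unique(v)))
    if (any(k > 1)) {
      stop("host_species maps to multiple values of ", attr, ": ",
           paste(names(k)[k > 1], collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from tab-separated text
#'
#' @param path TSV file with a header naming the required columns.
#' @return A `sample_metadata` data frame (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(utils::read.table(path, header = TRUE, sep = "\t",
                                    comment.char = "",
                                    stringsAsFactors = FALSE))
}

#' Write sample metadata as tab-separated text
#'
#' @param meta a `sample_metadata` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# check that every sample of a table has a metadata row; return meta rows
# aligned to the table's samples
align_metadata <- function(meta, x) {
  ids <- sample_ids(x)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}
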