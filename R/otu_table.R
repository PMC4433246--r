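# OTU count table: the central container every analysis stage consumes.
# Counts are stored as integers (samples x OTUs); relative abundances are
# always computed downstream, never stored, because rarefaction needs reads.

#' Construct an OTU count table
#'
#' An `otu_table` holds non-negative integer read counts with samples as rows
#' and OTUs as columns, tagged with the amplicon marker it came from (e.g.
#' `"V12"` or `"V34"`). Identifiers must be unique in both dimensions.
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows, OTUs in columns, with both dimnames set.
#' @param marker character label of the 16S fragment the table derives from.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `marker`.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' otu_table(m, marker = "V12")
#' @export
otu_table <- function(counts, marker = "unknown") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample rownames and OTU colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell sample '%s', OTU '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, marker = as.character(marker)[1]),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table [marker %s]: %d samples x %d OTUs, %s reads\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Accessors for OTU tables
#'
#' @param x an [otu_table].
#' @return `otu_counts()` the integer count matrix; `sample_ids()` and
#'   `otu_ids()` the identifier vectors; `otu_marker()` the marker label.
#' @export
otu_counts <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$counts
}

#' @rdname otu_counts
#' @export
sample_ids <- function(x) rownames(otu_counts(x))

#' @rdname otu_counts
#' @export
otu_ids <- function(x) colnames(otu_counts(x))

#' @rdname otu_counts
#' @export
otu_marker <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$marker
}

# subset an otu_table, keeping class and marker; drops all-absent nothing
subset_otu_table <- function(x, samples = NULL, otus = NULL) {
  m <- otu_counts(x)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  otu_table(m, marker = otu_marker(x))
}

#' Read an OTU table from TSV or dense-JSON BIOM
#'
#' Tab-separated tables follow the classic convention of OTU rows by sample
#' columns (first column holds OTU ids; a leading `#OTU ID` header is
#' accepted). Orientation is normalised to samples x OTUs on return. When
#' `sample_ids` is supplied the orientation is auto-detected by matching the
#' ids against row and column names; an ambiguous or impossible match is an
#' error, never a guess. Files ending in `.biom` (or starting with `{`) are
#' parsed as dense-JSON BIOM via the biomformat package.
#'
#' @param path file path.
#' @param marker marker label to tag the table with.
#' @param sample_ids optional character vector of known sample ids used to
#'   auto-detect orientation.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, marker = "unknown", sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\\.biom$", path) || grepl("^\\s*\\{", first)) {
    m <- read_biom_dense(path)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "", check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                   arr.ind = TRUE)
      stop(sprintf("non-numeric cell in row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    rownames(m) <- ids
    m <- t(m)  # classic layout is OTU rows x sample columns
  }
  m <- orient_counts(m, sample_ids)
  otu_table(m, marker = marker)
}

# normalise orientation to samples x OTUs using known sample ids if provided
orient_counts <- function(m, sample_ids = NULL) {
  if (is.null(sample_ids)) return(m)
  in_rows <- all(rownames(m) %in% sample_ids)
  in_cols <- all(colnames(m) %in% sample_ids)
  if (in_rows && !in_cols) return(m)
  if (in_cols && !in_rows) return(t(m))
  if (in_rows && in_cols) {
    stop("table orientation ambiguous: both dimensions match the sample ids")
  }
  stop("table orientation undetermined: neither dimension matches the supplied sample ids")
}

read_biom_dense <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  t(m)
}

#' Write an OTU table as tab-separated text
#'
#' Writes the classic layout (OTU rows x sample columns) with a `#OTU ID`
#' header, the exact inverse of [read_otu_table()].
#'
#' @param x an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  m <- t(otu_counts(x))
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Presence/absence view of an OTU table
#'
#' @param x an [otu_table] or a count matrix.
#' @return Logical matrix, `TRUE` where the count is positive.
#' @export
otu_presence <- function(x) {
  m <- if (inherits(x, "otu_table")) otu_counts(x) else as.matrix(x)
  m > 0
}
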