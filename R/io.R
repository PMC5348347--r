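# Readers/writers for the plain-text formats used across the pipeline.
# Internal coordinates are 0-based half-open everywhere; BED shares that
# convention natively, while SEG files are 1-based inclusive and are
# converted on read/write.

#' Read/write BED intervals
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate conversion is applied. Extra columns beyond the first three
#' are preserved.
#'
#' @param path file path.
#' @param x data.frame with `chrom`, `start`, `end` (+ optional extras).
#' @return `read_bed`: data.frame with `chrom`, `start`, `end` and any
#'   extra columns.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("malformed BED: need at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  bad <- which(!is.numeric(df$start) | !is.numeric(df$end) |
                 df$start >= df$end | df$start < 0)
  if (length(bad)) {
    stop("malformed BED intervals at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  .validate_intervals(x)
  first <- c("chrom", "start", "end")
  x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write SEG-like segment tables
#'
#' Tab-separated with a header (`sample`, `chrom`, `start`, `end`,
#' `mean_log2`, `n_markers`). On disk coordinates are 1-based inclusive
#' (the SEG dialect); internally they are 0-based half-open; conversion
#' happens on read/write.
#'
#' @param path file path.
#' @param x data.frame of segments (internal coordinates) with at least
#'   `sample`, `chrom`, `start`, `end`, `mean_log2`, `n_markers`.
#' @return `read_seg`: data.frame in internal coordinates.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "mean_log2", "n_markers")
  if (!all(need %in% names(df))) {
    stop("malformed SEG: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(df$start > df$end | df$start < 1)
  if (length(bad)) {
    stop("malformed SEG coordinates at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df$start <- df$start - 1 # 1-based inclusive -> 0-based half-open
  df
}

#' @rdname read_seg
#' @export
write_seg <- function(x, path) {
  out <- x
  out$start <- out$start + 1 # 0-based half-open -> 1-based inclusive
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write keyed TSV matrices
#'
#' Tab-separated with a header; the first column holds the row key
#' (probe or gene id).
#'
#' @param path file path.
#' @param x numeric matrix with rownames.
#' @param key name for the key column (default "id").
#' @return `read_matrix`: numeric matrix with rownames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate row ids in matrix file")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("ragged or non-numeric matrix file")
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @export
write_matrix <- function(x, path, key = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene`, `chrom`, `strand`, `tss`,
#' `start`, `end` (0-based half-open span).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(df))) {
    stop("malformed annotation: missing ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in annotation")
  df
}

#' Read a sample sheet and derive the pairing
#'
#' The sheet is tab-separated with columns `sample_id`, `patient_id`,
#' `timepoint` ("diagnosis"/"relapse") and `batch`. Every patient with
#' both timepoints forms a pair.
#'
#' @param path file path.
#' @return list with `sheet` (the data.frame) and `pairs` (data.frame:
#'   pair_id, diagnosis, relapse, batch).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "timepoint", "batch")
  if (!all(need %in% names(df))) {
    stop("malformed sample sheet: missing ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df[, c("patient_id", "timepoint")])) {
    stop("sample sheet: (patient_id, timepoint) must be unique")
  }
  d <- df[df$timepoint == "diagnosis", ]
  r <- df[df$timepoint == "relapse", ]
  common <- intersect(d$patient_id, r$patient_id)
  pairs <- data.frame(
    pair_id = common,
    diagnosis = d$sample_id[match(common, d$patient_id)],
    relapse = r$sample_id[match(common, r$patient_id)],
    batch = d$batch[match(common, d$patient_id)],
    stringsAsFactors = FALSE)
  list(sheet = df, pairs = pairs)
}
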