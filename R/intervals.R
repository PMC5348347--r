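#' @importFrom methods is
#' @importFrom stats median mad sd var quantile wilcox.test pchisq pnorm
#'   p.adjust rnorm runif rbinom cor cor.test dist hclust cutree cmdscale
#'   phyper setNames complete.cases aggregate
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

# Genomic intervals are plain data.frames with columns chrom, start, end,
# 0-based half-open. GRanges (1-based closed) is used internally for the
# set operations; conversion is confined to the two helpers below.

.validate_intervals <- function(x) {
  if (is.null(x) || nrow(x) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end)) {
    stop("invalid interval: start must be < end (0-based half-open)")
  }
  if (any(x$start < 0)) stop("invalid interval: negative start")
  x
}

.to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

.from_granges <- function(gr) {
  if (length(gr) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Union of genomic intervals
#'
#' Collapses a set of (possibly overlapping) genomic intervals into the
#' minimal sorted disjoint cover, per chromosome.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open coordinates).
#' @return data.frame of disjoint sorted intervals with the same columns.
#' @export
interval_union <- function(x) {
  x <- .validate_intervals(x)
  if (nrow(x) == 0L) return(x)
  out <- .from_granges(GenomicRanges::reduce(.to_granges(x)))
  rownames(out) <- NULL
  out
}

#' Subtraction of genomic intervals
#'
#' Returns the parts of `a` not covered by `b` (exact set difference on
#' base pairs).
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame of disjoint sorted intervals.
#' @export
interval_subtract <- function(a, b) {
  a <- .validate_intervals(a)
  b <- .validate_intervals(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(interval_union(a))
  ga <- .to_granges(a)
  gb <- .to_granges(b)
  GenomeInfoDb_levels <- union(
    as.character(unique(GenomicRanges::seqnames(ga))),
    as.character(unique(GenomicRanges::seqnames(gb)))
  )
  GenomeInfoDb::seqlevels(ga) <- GenomeInfoDb_levels
  GenomeInfoDb::seqlevels(gb) <- GenomeInfoDb_levels
  out <- .from_granges(GenomicRanges::setdiff(ga, gb))
  rownames(out) <- NULL
  out
}

#' Total genomic length covered by a set of intervals
#'
#' Length in bp of the union of `x` (overlaps counted once).
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @return numeric scalar, base pairs.
#' @export
total_length <- function(x) {
  u <- interval_union(x)
  if (nrow(u) == 0L) return(0)
  sum(u$end - u$start)
}

#' Base pairs of overlap between two interval sets
#'
#' @param a,b interval data.frames.
#' @return numeric scalar: bp in the intersection of union(a) and union(b).
#' @export
interval_overlap_bp <- function(a, b) {
  a <- interval_union(a)
  total_length(a) - total_length(interval_subtract(a, b))
}
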