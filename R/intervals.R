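#' Construct a set of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` everywhere inside the
#' package; conversion to and from 1-based coordinates happens only at the
#' VCF boundary. BED files share this convention natively.
#'
#' @param chrom Character vector of contig names.
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("interval chrom must be a non-empty string")
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing")
  if (any(start < 0L)) stop("negative interval coordinates are not allowed")
  if (any(start >= end)) stop("intervals require 0 <= start < end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_intervals <- function() genomic_intervals()

#' Sort intervals by (chrom, start, end)
#' @param x Interval data.frame.
#' @return Sorted interval data.frame.
#' @export
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

# Convert between the internal interval frame and GRanges (1-based closed).
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

gr_to_intervals <- function(gr) {
  if (length(gr) == 0L) return(empty_intervals())
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr))
}

#' Merge (union) a set of intervals into maximal disjoint intervals
#' @param x Interval data.frame.
#' @return Sorted, disjoint interval data.frame covering the same bases.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(empty_intervals())
  sort_intervals(gr_to_intervals(GenomicRanges::reduce(intervals_to_gr(x))))
}

#' Intersect two interval sets
#' @param x,y Interval data.frames.
#' @return Sorted disjoint intervals covering bases present in both sets.
#' @export
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(empty_intervals())
  gr <- GenomicRanges::intersect(intervals_to_gr(x), intervals_to_gr(y))
  sort_intervals(gr_to_intervals(gr))
}

#' Subtract one interval set from another
#' @param x,y Interval data.frames; bases of `y` are removed from `x`.
#' @return Sorted disjoint intervals covering bases in `x` but not `y`.
#' @export
subtract_intervals <- function(x, y) {
  if (nrow(x) == 0L) return(empty_intervals())
  if (nrow(y) == 0L) return(merge_intervals(x))
  gr <- GenomicRanges::setdiff(intervals_to_gr(x), intervals_to_gr(y))
  sort_intervals(gr_to_intervals(gr))
}

#' Test whether points fall inside any interval
#'
#' Half-open semantics: a point `p` is inside `[start, end)` iff
#' `start <= p < end`.
#'
#' @param chrom,pos Vectors naming the query points (0-based).
#' @param intervals Interval data.frame.
#' @return Logical vector.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  if (length(pos) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  IRanges::overlapsAny(q, intervals_to_gr(intervals))
}

#' Read a BED3 file
#'
#' @param path Path to a BED file (0-based half-open, as BED defines).
#' @return Interval data.frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  ln <- readLines(path, warn = FALSE)
  if (!any(nzchar(ln))) return(empty_intervals())
  gr <- rtracklayer::import(path, format = "bed")
  gr_to_intervals(gr)
}

#' Write intervals as BED3, sorted by (chrom, start)
#'
#' @param intervals Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- sort_intervals(intervals)
  writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a known-variant database table (DGV-like)
#'
#' Tab-separated columns `chrom`, `start`, `end`, `type`, `sample`
#' (0-based half-open intervals; `type` is a free-text class such as
#' "loss", "deletion", "gain", "insertion").
#'
#' @param path Path to the TSV/BED-like file. A header line is optional.
#' @return data.frame with the five columns above.
#' @export
read_known_db <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      sample = character(), stringsAsFactors = FALSE))
  if (grepl("^chrom\t", ln[1])) ln <- ln[-1]
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) < 5L)) stop("known-db rows need 5 tab-separated fields")
  data.frame(chrom = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 2L)),
             end = as.integer(vapply(f, `[`, "", 3L)),
             type = vapply(f, `[`, "", 4L),
             sample = vapply(f, `[`, "", 5L),
             stringsAsFactors = FALSE)
}
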