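#' NSVR construction parameters
#'
#' "No structural variant regions" are built from reads that align
#' end-to-end (no soft/hard clips), uniquely (MAPQ at or above
#' `min_mapq`), with low edit distance (`NM / aligned length` at or below
#' `max_edit_frac`). "Multiple" such reads means per-base depth of at
#' least `min_reads`, and any mapped read *failing* the conditions poisons
#' the bases it spans — NSVR bases must be covered *only* by clean reads.
#'
#' @param min_reads Minimum qualifying-read depth.
#' @param max_edit_frac Maximum edit-distance fraction.
#' @param min_mapq Minimum mapping quality for "uniquely aligned".
#' @param min_region_len Minimum reported region length (bp).
#' @param max_del_op Largest in-read deletion (`D`) op that does not
#'   disqualify; a `D` of SV scale is itself SV evidence.
#' @return list with class `nsvr_params`.
#' @export
nsvr_params <- function(min_reads = 2L, max_edit_frac = 0.02,
                        min_mapq = 40L, min_region_len = 100L,
                        max_del_op = 49L) {
  stopifnot(min_reads >= 1L, max_edit_frac >= 0, min_mapq >= 0L,
            min_region_len >= 1L)
  structure(list(min_reads = as.integer(min_reads),
                 max_edit_frac = max_edit_frac,
                 min_mapq = as.integer(min_mapq),
                 min_region_len = as.integer(min_region_len),
                 max_del_op = as.integer(max_del_op)),
            class = "nsvr_params")
}

#' Classify reads as qualifying / disqualifying / ignored for NSVR
#'
#' @param reads Aligned-read data.frame.
#' @param params An [nsvr_params()].
#' @return Character vector: "QUALIFYING", "DISQUALIFYING" or "IGNORED".
#' @export
qualify_read <- function(reads, params = nsvr_params()) {
  n <- nrow(reads)
  if (n == 0L) return(character(0))
  out <- rep("DISQUALIFYING", n)
  ignored <- reads$is_secondary | is.na(reads$cigar) | reads$cigar == "*"
  out[ignored] <- "IGNORED"
  cand <- which(!ignored)
  if (length(cand) == 0L) return(out)
  sub <- reads[cand, , drop = FALSE]
  clipped <- cigar_has_clip(sub$cigar)
  dlens <- GenomicAlignments::explodeCigarOpLengths(sub$cigar, ops = "D")
  bigdel <- vapply(dlens, function(d) any(d > params$max_del_op),
                   logical(1))
  alens <- GenomicAlignments::explodeCigarOpLengths(
    sub$cigar, ops = c("M", "I", "=", "X"))
  alen <- vapply(alens, sum, integer(1))
  nm_missing <- is.na(sub$nm)
  if (any(nm_missing))
    warning(sum(nm_missing),
            " read(s) without an NM tag treated as disqualifying")
  edit_ok <- !nm_missing & alen > 0L & sub$nm / alen <= params$max_edit_frac
  good <- !clipped & !bigdel & !sub$is_supplementary &
    sub$mapq >= params$min_mapq & edit_ok
  out[cand[good]] <- "QUALIFYING"
  out
}

#' Build the no-structural-variant regions from alignments
#'
#' NSVR = maximal intervals where the qualifying-read depth is at least
#' `min_reads` and no disqualifying read covers any base, filtered to
#' `min_region_len`.
#'
#' @param reads Aligned-read data.frame (or a SAM/BAM path).
#' @param params An [nsvr_params()].
#' @return An `nsvr_set`: list(`intervals`, `params`).
#' @export
build_nsvr <- function(reads, params = nsvr_params()) {
  if (is.character(reads)) reads <- read_alignments(reads, keep_seq = FALSE)
  mk <- function(iv) structure(list(intervals = iv, params = params),
                               class = "nsvr_set")
  if (nrow(reads) == 0L) return(mk(empty_intervals()))
  status <- qualify_read(reads, params)
  spans <- cigar_ref_span(reads$cigar)
  spans[is.na(spans)] <- 0L
  keepq <- status == "QUALIFYING"
  keepd <- status == "DISQUALIFYING" & spans > 0L
  out <- list()
  for (chrom in sort(unique(reads$chrom))) {
    onq <- keepq & reads$chrom == chrom
    if (!any(onq)) next
    qr <- IRanges::IRanges(start = reads$start[onq] + 1L,
                           width = spans[onq])
    cov <- IRanges::coverage(qr)
    good <- IRanges::slice(cov, lower = params$min_reads,
                           rangesOnly = TRUE)
    if (length(good) == 0L) next
    ond <- keepd & reads$chrom == chrom
    if (any(ond)) {
      dr <- IRanges::reduce(IRanges::IRanges(start = reads$start[ond] + 1L,
                                             width = spans[ond]))
      good <- IRanges::setdiff(good, dr)
    }
    good <- good[IRanges::width(good) >= params$min_region_len]
    if (length(good) == 0L) next
    out[[length(out) + 1L]] <-
      genomic_intervals(chrom, IRanges::start(good) - 1L,
                        IRanges::end(good))
  }
  if (length(out) == 0L) return(mk(empty_intervals()))
  mk(sort_intervals(do.call(rbind, out)))
}

#' Do both breakpoints of an SV lie inside an NSVR?
#'
#' Point-in-half-open-interval tests on `start` and `end` (for an INS, the
#' single anchor point).
#'
#' @param svs SV data.frame.
#' @param nsvr An `nsvr_set` (or a bare interval data.frame).
#' @return Logical vector.
#' @export
both_breakpoints_in_nsvr <- function(svs, nsvr) {
  iv <- if (inherits(nsvr, "nsvr_set")) nsvr$intervals else nsvr
  if (nrow(svs) == 0L) return(logical(0))
  s_in <- points_in_intervals(svs$chrom, svs$start, iv)
  e_in <- points_in_intervals(svs$chrom, svs$end, iv)
  ifelse(svs$svtype == "INS", s_in, s_in & e_in)
}

#' Write an NSVR set as BED plus a JSON parameter sidecar
#' @param nsvr An `nsvr_set`.
#' @param path BED output path; the sidecar is written at `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_nsvr <- function(nsvr, path) {
  write_bed(nsvr$intervals, path)
  jsonlite::write_json(unclass(nsvr$params), paste0(path, ".params.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
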