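#' Matching criteria for SV evaluation
#'
#' A call matches a gold deletion when they overlap reciprocally by at
#' least `del_reciprocal_min` *or* both breakpoints agree within
#' `breakpoint_tolerance`; an insertion matches when the anchors agree
#' within the tolerance and the size ratio is at least `ins_size_ratio_min`
#' (the ratio test is skipped when either size is unknown). `min_size`
#' (at least 50 bp; 100 bp for the deletion benchmark, which excludes the
#' range some callers cannot report) filters both calls and gold records
#' before any counting.
#'
#' @param del_reciprocal_min Minimum reciprocal overlap for deletions.
#' @param breakpoint_tolerance Breakpoint distance tolerance (bp).
#' @param ins_size_ratio_min Minimum insertion size ratio.
#' @param min_size Evaluation size floor (bp).
#' @return list with class `match_criteria`.
#' @export
match_criteria <- function(del_reciprocal_min = 0.5,
                           breakpoint_tolerance = 100L,
                           ins_size_ratio_min = 0.5, min_size = 50L) {
  stopifnot(del_reciprocal_min > 0, del_reciprocal_min <= 1,
            breakpoint_tolerance >= 0L, ins_size_ratio_min > 0,
            ins_size_ratio_min <= 1, min_size >= 50L)
  structure(list(del_reciprocal_min = del_reciprocal_min,
                 breakpoint_tolerance = as.integer(breakpoint_tolerance),
                 ins_size_ratio_min = ins_size_ratio_min,
                 min_size = as.integer(min_size)),
            class = "match_criteria")
}

#' Does a call match a gold SV?
#'
#' @param call,gold One-row SV data.frames.
#' @param criteria A [match_criteria()].
#' @return `TRUE`/`FALSE` (type mismatch is `FALSE`, not an error).
#' @export
match_sv <- function(call, gold, criteria = match_criteria()) {
  if (call$svtype != gold$svtype || call$chrom != gold$chrom) return(FALSE)
  tol <- criteria$breakpoint_tolerance
  if (call$svtype == "DEL") {
    ro <- reciprocal_overlap(call$start, call$end, gold$start, gold$end)
    ro >= criteria$del_reciprocal_min ||
      (abs(call$start - gold$start) <= tol &&
         abs(call$end - gold$end) <= tol)
  } else {
    if (abs(call$start - gold$start) > tol) return(FALSE)
    if (is.na(call$size) || is.na(gold$size)) return(TRUE)
    min(call$size, gold$size) / max(call$size, gold$size) >=
      criteria$ins_size_ratio_min
  }
}

#' Compute TPR, NSVR-FDR and F1 from counts
#'
#' `TPR = TP / n_gold`; `NSVR_FDR = NSVR_FP / (TP + NSVR_FP)` (0 when the
#' denominator is 0); precision is `1 - NSVR_FDR`; F1 is the harmonic mean
#' of precision and TPR, and 0 when TP is 0. Values are exact; rounding to
#' 4 decimals happens only at report time.
#'
#' @param TP Gold records recovered by at least one call.
#' @param NSVR_FP Unmatched calls with both breakpoints inside NSVR.
#' @param n_gold Gold records after the size filter.
#' @return list(TPR=, NSVR_FDR=, precision=, F1=).
#' @export
f1_from_counts <- function(TP, NSVR_FP, n_gold) {
  if (TP < 0 || NSVR_FP < 0 || n_gold <= 0)
    stop("counts must be non-negative and n_gold positive")
  TPR <- TP / n_gold
  NSVR_FDR <- if (TP + NSVR_FP > 0) NSVR_FP / (TP + NSVR_FP) else 0
  precision <- 1 - NSVR_FDR
  F1 <- if (TP == 0) 0 else 2 * precision * TPR / (precision + TPR)
  list(TPR = TPR, NSVR_FDR = NSVR_FDR, precision = precision, F1 = F1)
}

#' Evaluate a callset against a gold SV set with NSVR-based FDR
#'
#' Calls and gold are filtered to one `svtype` and to `min_size` first.
#' Each call is matched to at most one gold record (largest reciprocal
#' overlap for deletions, nearest anchor for insertions; ties broken by
#' smaller gold start); a gold record matched by any number of calls
#' counts once. Unmatched calls with both breakpoints inside the NSVR are
#' NSVR false positives; unmatched calls outside are labelled UNKNOWN and
#' enter no metric — the NSVR-FDR definition is conditional on NSVR
#' placement.
#'
#' @param calls,gold SV data.frames.
#' @param nsvr An `nsvr_set` or interval data.frame.
#' @param criteria A [match_criteria()].
#' @param svtype `"DEL"` or `"INS"`.
#' @return list with class `eval_result`: counts, rates and per-call
#'   labels.
#' @export
evaluate_sv <- function(calls, gold, nsvr, criteria = match_criteria(),
                        svtype = "DEL") {
  gold <- filter_sv_size(gold[gold$svtype == svtype, , drop = FALSE],
                         criteria$min_size)
  calls <- filter_sv_size(calls[calls$svtype == svtype, , drop = FALSE],
                          criteria$min_size)
  if (nrow(gold) == 0L)
    stop("empty gold set after filtering: metrics undefined")
  gold <- sort_svs(gold)
  calls <- sort_svs(calls)
  matched_gold <- rep(FALSE, nrow(gold))
  labels <- rep("UNKNOWN", nrow(calls))
  in_nsvr <- both_breakpoints_in_nsvr(calls, nsvr)
  for (i in seq_len(nrow(calls))) {
    best <- NA_integer_; best_score <- -Inf
    for (g in seq_len(nrow(gold))) {
      if (gold$chrom[g] != calls$chrom[i]) next
      if (gold$start[g] - calls$end[i] > criteria$breakpoint_tolerance) break
      if (!match_sv(calls[i, ], gold[g, ], criteria)) next
      score <- if (svtype == "DEL") {
        reciprocal_overlap(calls$start[i], calls$end[i],
                           gold$start[g], gold$end[g])
      } else {
        -abs(calls$start[i] - gold$start[g])
      }
      if (score > best_score) { best_score <- score; best <- g }
    }
    if (!is.na(best)) {
      matched_gold[best] <- TRUE
      labels[i] <- "TP_MATCH"
    } else if (in_nsvr[i]) {
      labels[i] <- "NSVR_FP"
    }
  }
  TP <- sum(matched_gold)
  NSVR_FP <- sum(labels == "NSVR_FP")
  m <- f1_from_counts(TP, NSVR_FP, nrow(gold))
  structure(list(n_gold = nrow(gold), TP = TP, TPR = m$TPR,
                 NSVR_FP = NSVR_FP, NSVR_FDR = m$NSVR_FDR,
                 precision = m$precision, F1 = m$F1,
                 per_call_labels = data.frame(id = calls$id, label = labels,
                                              stringsAsFactors = FALSE)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "SV evaluation: n_gold=%d TP=%d TPR=%.4f NSVR-FP=%d NSVR-FDR=%.4f F1=%.4f\n",
    x$n_gold, x$TP, x$TPR, x$NSVR_FP, x$NSVR_FDR, x$F1))
  invisible(x)
}

#' Histogram of variant sizes over power-of-two bins
#'
#' A record of size `s` falls in the smallest bin whose upper bound is at
#' least `s`; bin names are the upper bounds (1, 2, 4, ..., 131072 by
#' default). Sizes above the largest bound go to an `overflow` bin with a
#' warning. Counts always sum to the number of records.
#'
#' @param sizes Integer vector of sizes (>= 1), e.g. `svs$size` or
#'   `abs(nchar(ref) - nchar(alt))`.
#' @param max_exp Largest exponent: bins run to `2^max_exp`.
#' @return Named integer vector of counts.
#' @export
size_histogram <- function(sizes, max_exp = 17L) {
  stopifnot(all(sizes >= 1))
  bounds <- 2^(0:max_exp)
  counts <- stats::setNames(integer(length(bounds) + 1L),
                            c(as.character(bounds), "overflow"))
  if (length(sizes) == 0L) return(counts)
  bin <- findInterval(sizes - 1, bounds) + 1L   # smallest bound >= size
  over <- bin > length(bounds)
  if (any(over)) warning(sum(over), " size(s) above the largest bin")
  tb <- table(factor(names(counts)[pmin(bin, length(bounds) + 1L)],
                     levels = names(counts)))
  counts[] <- as.integer(tb)
  counts
}

#' Repeat-element overlap report for an SV set
#'
#' An SV intersects a repeat class when its span (DEL) or its anchor point
#' +/- 1 bp (INS) overlaps a repeat interval of that class by at least one
#' base. Reports per-class SV counts, the fraction of SVs hitting any
#' repeat, and (when `genome_length` is given) the fraction of the genome
#' covered by repeats, for the enrichment comparison.
#'
#' @param svs SV data.frame.
#' @param repeats data.frame with columns `chrom`, `start`, `end`, `class`.
#' @param genome_length Optional total genome length (bp).
#' @return list(per_class=, n=, n_in_repeat=, fraction=,
#'   genome_repeat_fraction=).
#' @export
repeat_overlap_report <- function(svs, repeats, genome_length = NULL) {
  n <- nrow(svs)
  if (n == 0L || nrow(repeats) == 0L) {
    gf <- if (!is.null(genome_length) && nrow(repeats) > 0L) {
      sum(merge_intervals(repeats)$end -
            merge_intervals(repeats)$start) / genome_length
    } else 0
    return(list(per_class = stats::setNames(integer(0), character(0)),
                n = n, n_in_repeat = 0L, fraction = 0,
                genome_repeat_fraction = gf))
  }
  qs <- ifelse(svs$svtype == "DEL", svs$start, pmax(0L, svs$start - 1L))
  qe <- ifelse(svs$svtype == "DEL", svs$end, svs$start + 1L)
  q <- GenomicRanges::GRanges(svs$chrom, IRanges::IRanges(qs + 1L, qe))
  r <- GenomicRanges::GRanges(repeats$chrom,
                              IRanges::IRanges(repeats$start + 1L,
                                               repeats$end))
  hits <- GenomicRanges::findOverlaps(q, r)
  cls <- repeats$class[S4Vectors::subjectHits(hits)]
  sv_i <- S4Vectors::queryHits(hits)
  per_class <- vapply(split(sv_i, cls), function(ix) length(unique(ix)),
                      integer(1))
  n_in <- length(unique(sv_i))
  gf <- if (!is.null(genome_length)) {
    mi <- merge_intervals(repeats[c("chrom", "start", "end")])
    sum(mi$end - mi$start) / genome_length
  } else NA_real_
  list(per_class = per_class, n = n, n_in_repeat = n_in,
       fraction = n_in / n, genome_repeat_fraction = gf)
}

#' Format a Table-style metrics row for one or more callsets
#'
#' @param results Named list of `eval_result` objects.
#' @return data.frame with columns Method, TP, TPR, NSVR_FP, NSVR_FDR, F1
#'   (rates rounded to 4 decimals, as reported).
#' @export
metrics_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(Method = nm, TP = r$TP, TPR = round(r$TPR, 4),
               NSVR_FP = r$NSVR_FP, NSVR_FDR = round(r$NSVR_FDR, 4),
               F1 = round(r$F1, 4), stringsAsFactors = FALSE)
  }))
}
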