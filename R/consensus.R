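#' Consensus configuration: declared platforms and callers
#'
#' The gold-set criteria need at least two platforms to be meaningful
#' (criterion 1 requires a call on *every* declared platform); a warning is
#' emitted for a single-platform configuration.
#'
#' @param platforms Character vector of platform identifiers.
#' @param callers Character vector of caller identifiers.
#' @return list with class `consensus_config`.
#' @export
consensus_config <- function(platforms = c("sanger", "illumina"),
                             callers = c("gatk_hc", "freebayes", "samtools")) {
  platforms <- unique(as.character(platforms))
  callers <- unique(as.character(callers))
  if (length(platforms) < 2L)
    warning("fewer than 2 platforms: the cross-platform criterion is trivial")
  structure(list(platforms = platforms, callers = callers),
            class = "consensus_config")
}

origin_label <- function(platform, caller) paste(platform, caller, sep = "|")

check_origins <- function(platform, caller, cfg) {
  if (any(!platform %in% cfg$platforms))
    stop("undeclared platform: ",
         paste(setdiff(platform, cfg$platforms), collapse = ", "))
  if (any(!caller %in% cfg$callers))
    stop("undeclared caller: ",
         paste(setdiff(caller, cfg$callers), collapse = ", "))
}

#' Build an evidence map from per-origin callsets
#'
#' Every callset is normalized (left-aligned, minimal) before keying so
#' that the same indel reported in different representations by different
#' callers collapses onto one key.
#'
#' @param callsets List of entries `list(platform=, caller=, variants=)`,
#'   each `variants` a small-variant data.frame.
#' @param reference Named character vector of contig sequences.
#' @param cfg A [consensus_config()].
#' @param exclude Optional interval data.frame; variants whose position
#'   falls inside are dropped before classification.
#' @return An `evidence_map`: named list mapping normalized variant keys to
#'   character matrices of origins (columns `platform`, `caller`).
#' @export
build_evidence_map <- function(callsets, reference, cfg = consensus_config(),
                               exclude = NULL) {
  seen <- character(0)
  entries <- new.env(parent = emptyenv())
  for (cs in callsets) {
    check_origins(cs$platform, cs$caller, cfg)
    lab <- origin_label(cs$platform, cs$caller)
    if (lab %in% seen) stop("duplicate callset origin: ", lab)
    seen <- c(seen, lab)
    v <- normalize_variants(cs$variants, reference)
    if (!is.null(exclude) && nrow(v) > 0L) {
      v <- v[!points_in_intervals(v$chrom, v$pos, exclude), , drop = FALSE]
    }
    for (k in unique(variant_key(v))) {
      cur <- if (!is.null(entries[[k]])) entries[[k]] else character(0)
      entries[[k]] <- unique(c(cur, lab))
    }
  }
  out <- as.list(entries)
  structure(out, class = "evidence_map", cfg = cfg)
}

#' Classify an origin set against the two consensus criteria
#'
#' Criterion 1 (cross-platform): the variant is called by at least one
#' caller on *each* declared platform. Criterion 2 (cross-caller): it is
#' called by at least two *distinct* callers, regardless of platform — the
#' same caller on both platforms does not satisfy it. A variant satisfying
#' both goes to the gold set; exactly one, to the complete set only.
#'
#' @param platform,caller Parallel character vectors: one entry per call
#'   origin that reported the variant.
#' @param cfg A [consensus_config()].
#' @return `"GOLD"`, `"COMPLETE_ONLY"` or `"NONE"`.
#' @export
classify_variant <- function(platform, caller, cfg = consensus_config()) {
  if (length(platform) == 0L) stop("origin set must be non-empty")
  check_origins(platform, caller, cfg)
  c1 <- all(cfg$platforms %in% platform)
  c2 <- length(unique(caller)) >= 2L
  if (c1 && c2) "GOLD" else if (c1 || c2) "COMPLETE_ONLY" else "NONE"
}

em_origins <- function(em, key) {
  labs <- em[[key]]
  f <- strsplit(labs, "|", fixed = TRUE)
  list(platform = vapply(f, `[`, "", 1L), caller = vapply(f, `[`, "", 2L))
}

#' Build the gold and complete small-variant sets from an evidence map
#'
#' @param em Evidence map from [build_evidence_map()].
#' @param cfg A [consensus_config()].
#' @return list(gold=, complete=): small-variant data.frames sorted by
#'   (chrom, pos); the gold set is a subset of the complete set.
#' @export
build_small_gold <- function(em, cfg = attr(em, "cfg")) {
  keys <- setdiff(names(em), "cfg")
  cls <- vapply(keys, function(k) {
    o <- em_origins(em, k)
    classify_variant(o$platform, o$caller, cfg)
  }, character(1))
  gold <- key_to_variants(keys[cls == "GOLD"])
  complete <- key_to_variants(keys[cls %in% c("GOLD", "COMPLETE_ONLY")])
  list(gold = gold[order(gold$chrom, gold$pos), , drop = FALSE],
       complete = complete[order(complete$chrom, complete$pos), ,
                           drop = FALSE])
}

#' Consensus homozygous-reference call regions
#'
#' Applies the same two criteria per base: a base belongs to the output iff
#' the set of origins whose reference-call regions cover it satisfies both
#' the cross-platform and the cross-caller criterion. Implemented on
#' disjoint elementary segments, then reassembled into maximal intervals.
#'
#' @param region_sets List of entries `list(platform=, caller=, regions=)`,
#'   each `regions` an interval data.frame of homozygous-reference calls.
#' @param cfg A [consensus_config()].
#' @return Sorted disjoint interval data.frame.
#' @export
consensus_reference_regions <- function(region_sets,
                                        cfg = consensus_config()) {
  if (length(region_sets) == 0L) return(empty_intervals())
  grl <- list(); plat <- character(0); call <- character(0)
  for (rs in region_sets) {
    check_origins(rs$platform, rs$caller, cfg)
    grl[[length(grl) + 1L]] <-
      GenomicRanges::reduce(intervals_to_gr(rs$regions))
    plat <- c(plat, rs$platform)
    call <- c(call, rs$caller)
  }
  all_gr <- suppressWarnings(do.call(c, grl))
  if (length(all_gr) == 0L) return(empty_intervals())
  seg <- GenomicRanges::disjoin(all_gr)
  cov <- vapply(grl, function(g) IRanges::overlapsAny(seg, g),
                logical(length(seg)))
  cov <- matrix(cov, nrow = length(seg))
  keep <- vapply(seq_len(length(seg)), function(i) {
    on <- cov[i, ]
    all(cfg$platforms %in% plat[on]) && length(unique(call[on])) >= 2L
  }, logical(1))
  if (!any(keep)) return(empty_intervals())
  merge_intervals(gr_to_intervals(seg[keep]))
}
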