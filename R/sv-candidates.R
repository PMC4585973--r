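#' Extract candidate SVs from gapped and split long-read alignments
#'
#' Two extraction routes, both labelled with source `"split_read"`:
#' \itemize{
#' \item intra-alignment: a `D` cigar operation of at least `min_size`
#'   becomes a deletion over its reference span; an `I` operation of at
#'   least `min_size` becomes an insertion whose sequence is lifted from
#'   the read.
#' \item split-read: a primary + supplementary alignment pair of the same
#'   read on the same contig and strand whose query intervals are adjacent
#'   within `slack` bp becomes a deletion when the reference gap between
#'   the two segments is at least `min_size`, or an insertion when the
#'   reference gap is within `slack` and the unaligned query middle is at
#'   least `min_size` long.
#' }
#'
#' @param reads Aligned-read data.frame (secondary alignments are ignored).
#' @param min_size Minimum event size (bp), 50 by default.
#' @param slack Query-adjacency slack for split-read reconstruction (bp).
#' @return SV data.frame with `sources = "split_read"`.
#' @export
extract_sv_from_alignments <- function(reads, min_size = 50L, slack = 10L) {
  out <- list()
  reads <- reads[!reads$is_secondary, , drop = FALSE]
  nocig <- is.na(reads$cigar) | reads$cigar == "*"
  if (any(nocig)) {
    warning(sum(nocig), " read(s) without a CIGAR skipped")
    reads <- reads[!nocig, , drop = FALSE]
  }
  if (nrow(reads) == 0L) return(empty_svs())
  parsed <- parse_cigar(reads$cigar)

  emit <- function(chrom, start, end, svtype, size, seq) {
    out[[length(out) + 1L]] <<-
      sv_records(chrom, start, end, svtype, size, seq,
                 sources = "split_read")
  }

  # intra-alignment I/D operations
  for (i in seq_len(nrow(reads))) {
    p <- parsed[[i]]
    refpos <- reads$start[i]
    qpos <- 0L
    for (j in seq_len(nrow(p))) {
      op <- p$op[j]; len <- p$len[j]
      if (op == "D" && len >= min_size) {
        emit(reads$chrom[i], refpos, refpos + len, "DEL", len, NA_character_)
      }
      if (op == "I" && len >= min_size) {
        seq <- NA_character_
        if (!is.na(reads$seq[i]))
          seq <- substr(reads$seq[i], qpos + 1L, qpos + len)
        emit(reads$chrom[i], refpos, refpos, "INS", len, seq)
      }
      if (op %in% c("M", "D", "=", "X")) refpos <- refpos + len
      if (op %in% c("M", "I", "S", "=", "X")) qpos <- qpos + len
    }
  }

  # split-read reconstruction across primary/supplementary segments
  grp <- split(seq_len(nrow(reads)), reads$name)
  for (idx in grp) {
    if (length(idx) < 2L) next
    sub <- reads[idx, , drop = FALSE]
    psub <- parsed[idx]
    qs <- t(vapply(seq_along(idx), function(k) {
      cigar_query_span(psub[[k]], sub$is_reverse[k])
    }, numeric(3)))
    ord <- order(qs[, 1L])
    for (k in seq_len(length(ord) - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      if (sub$chrom[a] != sub$chrom[b]) next
      if (sub$is_reverse[a] != sub$is_reverse[b]) next
      qgap <- qs[b, 1L] - qs[a, 2L]
      a_ref_end <- sub$start[a] + cigar_ref_span(sub$cigar[a])
      rgap <- sub$start[b] - a_ref_end
      if (sub$is_reverse[a]) {
        # in read orientation the later query segment is the *left*
        # reference segment for reverse-strand alignments
        b_ref_end <- sub$start[b] + cigar_ref_span(sub$cigar[b])
        rgap <- sub$start[a] - b_ref_end
        a_ref_end <- b_ref_end
      }
      if (abs(qgap) <= slack && rgap >= min_size) {
        emit(sub$chrom[a], a_ref_end, a_ref_end + rgap, "DEL", rgap,
             NA_character_)
      } else if (abs(rgap) <= slack && qgap >= min_size) {
        seq <- NA_character_
        prim <- which(!sub$is_supplementary)
        if (length(prim) >= 1L && !is.na(sub$seq[prim[1L]]) &&
            !sub$is_reverse[a] && !grepl("H", sub$cigar[prim[1L]])) {
          seq <- substr(sub$seq[prim[1L]], qs[a, 2L] + 1L, qs[b, 1L])
        }
        emit(sub$chrom[a], a_ref_end, a_ref_end, "INS", qgap, seq)
      }
    }
  }
  if (length(out) == 0L) return(empty_svs())
  unique(sort_svs(do.call(rbind, out)))
}

sv_pair_mergeable <- function(a, b, tolerance, reciprocal_min) {
  if (a$chrom != b$chrom || a$svtype != b$svtype) return(FALSE)
  if (a$svtype == "DEL") {
    ro <- reciprocal_overlap(a$start, a$end, b$start, b$end)
    ro >= reciprocal_min && abs(a$start - b$start) <= tolerance &&
      abs(a$end - b$end) <= tolerance
  } else {
    sr <- min(a$size, b$size) / max(a$size, b$size)
    abs(a$start - b$start) <= tolerance && sr >= reciprocal_min
  }
}

#' Merge SV callsets from multiple sources into one candidate set
#'
#' Deletions merge when they overlap reciprocally by at least
#' `reciprocal_min` *and* both breakpoints agree within `tolerance`;
#' insertions merge when their anchors agree within `tolerance` and their
#' size ratio (smaller/larger) is at least `reciprocal_min`. Clustering is
#' a greedy sweep over records sorted by coordinate (a record joins the
#' first cluster whose seed it matches), so the result does not depend on
#' input order. The merged record keeps the breakpoints of the member from
#' the highest-priority source (sources are prioritised in the order the
#' callsets are listed) and unions all source labels.
#'
#' @param callsets List of entries `list(source=, svs=)`.
#' @param tolerance Breakpoint tolerance in bp (default 10).
#' @param reciprocal_min Minimum reciprocal overlap / size ratio (default
#'   0.5).
#' @return A `candidate_set`: list with `records` (SV data.frame),
#'   `merge_tolerance`, `reciprocal_overlap_min`.
#' @export
merge_sv_callsets <- function(callsets, tolerance = 10L,
                              reciprocal_min = 0.5) {
  stopifnot(reciprocal_min > 0, reciprocal_min <= 1)
  recs <- list()
  for (pri in seq_along(callsets)) {
    cs <- callsets[[pri]]
    svs <- cs$svs
    if (nrow(svs) == 0L) next
    if (any(!svs$svtype %in% c("DEL", "INS"))) stop("unknown svtype")
    svs$sources <- cs$source
    svs$priority <- pri
    recs[[length(recs) + 1L]] <- svs
  }
  if (length(recs) == 0L) {
    return(structure(list(records = empty_svs(), merge_tolerance = tolerance,
                          reciprocal_overlap_min = reciprocal_min),
                     class = "candidate_set"))
  }
  all <- do.call(rbind, recs)
  all <- all[order(all$chrom, all$start, all$end, all$svtype, all$priority), ,
             drop = FALSE]
  cluster <- rep(NA_integer_, nrow(all))
  seeds <- integer(0)
  for (i in seq_len(nrow(all))) {
    assigned <- FALSE
    for (ci in seq_along(seeds)) {
      s <- seeds[ci]
      if (all$chrom[s] != all$chrom[i]) next
      if (all$start[i] - all$end[s] > tolerance + 1L) next
      if (sv_pair_mergeable(all[s, ], all[i, ], tolerance, reciprocal_min)) {
        cluster[i] <- ci; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      seeds <- c(seeds, i)
      cluster[i] <- length(seeds)
    }
  }
  merged <- lapply(seq_along(seeds), function(ci) {
    m <- all[cluster == ci, , drop = FALSE]
    rep_i <- order(m$priority, m$start, m$end)[1L]
    rec <- m[rep_i, , drop = FALSE]
    rec$sources <- join_labels(unlist(lapply(m$sources, split_labels)))
    # prefer a known inserted sequence from any member
    if (rec$svtype == "INS" && is.na(rec$inserted_seq)) {
      known <- m$inserted_seq[!is.na(m$inserted_seq)]
      if (length(known) > 0L && nchar(known[1L]) == rec$size)
        rec$inserted_seq <- known[1L]
    }
    rec$priority <- NULL
    rec
  })
  out <- sort_svs(do.call(rbind, merged))
  rownames(out) <- NULL
  structure(list(records = out, merge_tolerance = tolerance,
                 reciprocal_overlap_min = reciprocal_min),
            class = "candidate_set")
}
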