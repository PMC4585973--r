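#' Validation parameters
#'
#' Defaults: 500 bp of flank either side of a junction, 20 bp minimum
#' overhang across it, 5% mismatch budget for a gapless placement, 2
#' supporting reads / discordant pairs to set a flag, 50% reciprocal
#' overlap against the known-variant database, and a 3-sigma insert-size
#' discordance threshold. All are configurable; the validation *sources*
#' (KNOWN_DB, JUNCTION, READPAIR) are fixed.
#'
#' @param flank Junction flank length (bp).
#' @param min_overhang Minimum aligned bases on each side of the junction.
#' @param max_mismatch_frac Mismatch budget for junction re-alignment.
#' @param min_junction_reads Reads needed to set the JUNCTION flag.
#' @param min_discordant_pairs Pairs needed to set the READPAIR flag.
#' @param db_reciprocal_min Reciprocal overlap (DEL) / size ratio (INS)
#'   against database records.
#' @param db_ins_tolerance Anchor distance tolerance for INS database hits
#'   (bp).
#' @param db_exclude_samples Sample labels removed from the database before
#'   validation (e.g. the benchmarked individual itself).
#' @return list with class `validation_config`.
#' @export
validation_config <- function(flank = 500L, min_overhang = 20L,
                              max_mismatch_frac = 0.05,
                              min_junction_reads = 2L,
                              min_discordant_pairs = 2L,
                              db_reciprocal_min = 0.5,
                              db_ins_tolerance = 100L,
                              db_exclude_samples = character()) {
  stopifnot(flank > 0L, min_overhang > 0L, min_overhang < flank,
            max_mismatch_frac > 0, min_junction_reads > 0L,
            min_discordant_pairs > 0L, db_reciprocal_min > 0,
            db_ins_tolerance > 0L)
  structure(list(flank = flank, min_overhang = min_overhang,
                 max_mismatch_frac = max_mismatch_frac,
                 min_junction_reads = min_junction_reads,
                 min_discordant_pairs = min_discordant_pairs,
                 db_reciprocal_min = db_reciprocal_min,
                 db_ins_tolerance = db_ins_tolerance,
                 db_exclude_samples = db_exclude_samples),
            class = "validation_config")
}

#' Insert-size model for discordant-pair analysis
#'
#' Describes the *inner* mate distance (right-mate start minus left-mate
#' end on the reference) of a concordant pair; a pair is discordant when
#' its apparent insert deviates from `mean` by more than `k * sd`.
#'
#' @param mean,sd Library insert mean and standard deviation (bp).
#' @param k Discordance multiplier.
#' @return list with class `insert_size_model`.
#' @export
insert_size_model <- function(mean, sd, k = 3) {
  stopifnot(sd > 0, k > 0)
  structure(list(mean = mean, sd = sd, k = k), class = "insert_size_model")
}

#' Build the breakpoint-junction sequence for one SV
#'
#' For a deletion the junction is the novel adjacency formed by joining the
#' two flanks; for an insertion (with a known inserted sequence) the flanks
#' embrace the insert, giving two junction offsets. Flanks are truncated at
#' contig edges and the truncation recorded.
#'
#' @param sv One-row SV data.frame.
#' @param reference Named character vector of contig sequences.
#' @param flank Requested flank (bp) each side.
#' @return list(`sv_id`, `seq`, `offsets`, `flank`, `left_truncated`,
#'   `right_truncated`), or `NULL` for an INS without sequence (junction
#'   validation inapplicable, as opposed to failed).
#' @export
build_junction <- function(sv, reference, flank = 500L) {
  stopifnot(nrow(sv) == 1L)
  clen <- ref_len(reference, sv$chrom)
  if (sv$svtype == "INS" && is.na(sv$inserted_seq)) return(NULL)
  ltrunc <- max(0L, flank - sv$start)
  lstart <- sv$start - (flank - ltrunc)
  if (sv$svtype == "DEL") {
    rtrunc <- max(0L, sv$end + flank - clen)
    seq <- paste0(ref_fetch(reference, sv$chrom, lstart, sv$start),
                  ref_fetch(reference, sv$chrom, sv$end,
                            sv$end + flank - rtrunc))
    offsets <- flank - ltrunc
  } else {
    rtrunc <- max(0L, sv$start + flank - clen)
    seq <- paste0(ref_fetch(reference, sv$chrom, lstart, sv$start),
                  sv$inserted_seq,
                  ref_fetch(reference, sv$chrom, sv$start,
                            sv$start + flank - rtrunc))
    offsets <- c(flank - ltrunc, flank - ltrunc + sv$size)
  }
  list(sv_id = sv$id, seq = seq, offsets = offsets, flank = flank,
       left_truncated = ltrunc, right_truncated = rtrunc)
}

#' Count reads supporting a breakpoint junction
#'
#' A read supports the junction when it has a gapless placement on the
#' junction sequence (either orientation) whose mismatch fraction is within
#' `max_mismatch_frac` and which covers a junction offset with at least
#' `min_overhang` aligned bases on each side. Duplicate read names count
#' once.
#'
#' @param junction A junction from [build_junction()].
#' @param reads Character vector of read sequences; names (if present) are
#'   used to deduplicate.
#' @param cfg A [validation_config()].
#' @return list(count=, validated=): supporting-read count and whether it
#'   reaches `min_junction_reads`.
#' @export
junction_support <- function(junction, reads, cfg = validation_config()) {
  if (is.null(junction)) return(list(count = 0L, validated = NA))
  if (length(reads) == 0L) return(list(count = 0L, validated = FALSE))
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- paste0("r", seq_along(reads))
  reads <- reads[!duplicated(names(reads))]
  slen <- nchar(junction$seq)
  moh <- cfg$min_overhang
  jraw <- charToRaw(junction$seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(reads))))
  supports <- vapply(seq_along(reads), function(i) {
    L <- nchar(reads[[i]])
    if (L > slen || L < 2L * moh) return(FALSE)
    budget <- floor(L * cfg$max_mismatch_frac)
    for (rs in c(reads[[i]], rc[i])) {
      rraw <- charToRaw(rs)
      for (off in junction$offsets) {
        # a supporting placement covers the offset with min_overhang on
        # each side: start in [off - L + moh, off - moh]
        lo <- max(0L, off - L + moh)
        hi <- min(slen - L, off - moh)
        if (hi < lo) next
        for (st in lo:hi) {
          if (sum(jraw[(st + 1L):(st + L)] != rraw) <= budget)
            return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  count <- sum(supports)
  list(count = as.integer(count), validated = count >= cfg$min_junction_reads)
}

#' Count discordant read pairs supporting an SV
#'
#' For a deletion, a pair supports when its apparent insert (inner mate
#' distance) exceeds `mean + k*sd`, the pair brackets the deletion, and the
#' apparent insert minus the deletion size falls back inside
#' `mean +/- k*sd`. For an insertion, a pair supports when the apparent
#' insert is below `mean - k*sd` and the pair brackets the anchor point.
#'
#' @param sv One-row SV data.frame.
#' @param pairs data.frame with columns `chrom`, `left_end`, `right_start`
#'   (0-based; see [mate_pairs()] to derive it from alignments).
#' @param model An [insert_size_model()].
#' @param cfg A [validation_config()].
#' @return list(count=, validated=).
#' @export
discordant_pair_support <- function(sv, pairs, model,
                                    cfg = validation_config()) {
  stopifnot(nrow(sv) == 1L)
  if (nrow(pairs) == 0L) return(list(count = 0L, validated = FALSE))
  pairs <- pairs[pairs$chrom == sv$chrom, , drop = FALSE]
  ins <- pairs$right_start - pairs$left_end
  lo <- model$mean - model$k * model$sd
  hi <- model$mean + model$k * model$sd
  if (sv$svtype == "DEL") {
    ok <- ins > hi &
      pairs$left_end <= sv$start & pairs$right_start >= sv$end &
      (ins - sv$size) >= lo & (ins - sv$size) <= hi
  } else {
    ok <- ins < lo &
      pairs$left_end <= sv$start & pairs$right_start >= sv$start
  }
  count <- sum(ok)
  list(count = as.integer(count),
       validated = count >= cfg$min_discordant_pairs)
}

#' Derive mate-pair spans from an alignment table
#'
#' Keeps primary paired records whose mates map to the same contig, and
#' reports per pair the end of the left mate and the start of the right
#' mate (the apparent-insert endpoints used by
#' [discordant_pair_support()]).
#'
#' @param reads Aligned-read data.frame.
#' @return data.frame with columns `name`, `chrom`, `left_end`,
#'   `right_start`.
#' @export
mate_pairs <- function(reads) {
  r <- reads[reads$is_paired & !reads$is_secondary &
             !reads$is_supplementary & !is.na(reads$mate_chrom) &
             reads$mate_chrom == reads$chrom, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(name = character(), chrom = character(),
                      left_end = integer(), right_start = integer(),
                      stringsAsFactors = FALSE))
  base <- sub("/[12]$", "", r$name)
  if (is.null(r$.span)) r$.span <- cigar_ref_span(r$cigar)
  ends <- r$start + r$.span
  o <- order(base, r$start)
  b <- base[o]
  runs <- rle(b)
  stops <- cumsum(runs$lengths)
  two <- runs$lengths == 2L
  i <- o[stops[two] - 1L]   # left mate (smaller start within the pair)
  j <- o[stops[two]]
  same <- r$chrom[i] == r$chrom[j]
  i <- i[same]; j <- j[same]
  out <- data.frame(name = base[i], chrom = r$chrom[i],
                    left_end = ends[i], right_start = r$start[j],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate an SV against a known-variant database
#'
#' A DEL is validated by a type-compatible record ("loss"/"deletion"/"DEL")
#' with reciprocal overlap of at least `db_reciprocal_min`; an INS by a
#' type-compatible record ("gain"/"insertion"/"INS") whose interval lies
#' within `db_ins_tolerance` of the anchor and whose length ratio to the
#' insertion size is at least `db_reciprocal_min` (skipped when the
#' database record has no usable length). Database records whose sample
#' label is in `db_exclude_samples` are removed first — a gold set must not
#' validate an individual's SVs against entries derived from that same
#' individual.
#'
#' @param sv One-row SV data.frame.
#' @param db data.frame from [read_known_db()].
#' @param cfg A [validation_config()].
#' @return `TRUE` if validated.
#' @export
known_db_validate <- function(sv, db, cfg = validation_config()) {
  stopifnot(nrow(sv) == 1L)
  if (nrow(db) == 0L) return(FALSE)
  db <- db[!db$sample %in% cfg$db_exclude_samples, , drop = FALSE]
  db <- db[db$chrom == sv$chrom, , drop = FALSE]
  if (nrow(db) == 0L) return(FALSE)
  type <- tolower(db$type)
  if (sv$svtype == "DEL") {
    db <- db[type %in% c("loss", "deletion", "del"), , drop = FALSE]
    if (nrow(db) == 0L) return(FALSE)
    ro <- reciprocal_overlap(sv$start, sv$end, db$start, db$end)
    any(ro >= cfg$db_reciprocal_min)
  } else {
    db <- db[type %in% c("gain", "insertion", "ins", "duplication"), ,
             drop = FALSE]
    if (nrow(db) == 0L) return(FALSE)
    near <- abs(db$start - sv$start) <= cfg$db_ins_tolerance
    dblen <- db$end - db$start
    ratio_ok <- dblen <= 1L |
      pmin(dblen, sv$size) / pmax(dblen, sv$size) >= cfg$db_reciprocal_min
    any(near & ratio_ok)
  }
}

#' Assign Gold/Pass/Notval tiers from validation sources
#'
#' Gold: at least two independent validation sources; Pass: exactly one;
#' Notval: none. A pure function of the validation set, so re-running the
#' validators and re-tiering is idempotent.
#'
#' @param svs SV data.frame with `validations` populated.
#' @return The same data.frame with `tier` set.
#' @export
assign_tier <- function(svs) {
  nv <- n_labels(svs$validations)
  svs$tier <- ifelse(nv >= 2L, "GOLD", ifelse(nv == 1L, "PASS", "NOTVAL"))
  svs
}

#' Run all three validators over a candidate set and tier the records
#'
#' @param svs SV data.frame (candidates).
#' @param reference Named character vector of contig sequences.
#' @param reads Aligned-read data.frame used for junction mapping and
#'   discordant pairs (may be `NULL` to skip either analysis).
#' @param db Known-variant database data.frame (or `NULL`).
#' @param model An [insert_size_model()] (or `NULL` to skip pairs).
#' @param cfg A [validation_config()].
#' @return SV data.frame with `validations` and `tier` populated.
#' @export
validate_svs <- function(svs, reference, reads = NULL, db = NULL,
                         model = NULL, cfg = validation_config()) {
  if (nrow(svs) == 0L) return(svs)
  if (!is.null(reads)) reads$.span <- cigar_ref_span(reads$cigar)
  pairs <- if (!is.null(reads) && !is.null(model)) mate_pairs(reads)
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, , drop = FALSE]
    val <- character(0)
    if (!is.null(db) && known_db_validate(sv, db, cfg))
      val <- c(val, "KNOWN_DB")
    if (!is.null(reads)) {
      j <- build_junction(sv, reference, cfg$flank)
      if (!is.null(j)) {
        rs <- reads_near(reads, sv$chrom,
                         sv$start - cfg$flank,
                         max(sv$end, sv$start) + cfg$flank)
        js <- junction_support(j, rs, cfg)
        if (isTRUE(js$validated)) val <- c(val, "JUNCTION")
      }
    }
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      ds <- discordant_pair_support(sv, pairs, model, cfg)
      if (isTRUE(ds$validated)) val <- c(val, "READPAIR")
    }
    svs$validations[i] <- join_labels(val)
  }
  assign_tier(svs)
}

#' Fetch read sequences overlapping a region
#'
#' @param reads Aligned-read data.frame with sequences.
#' @param chrom,start,end Region (0-based half-open).
#' @return Named character vector of read sequences.
#' @export
reads_near <- function(reads, chrom, start, end) {
  if (is.null(reads$.span)) reads$.span <- cigar_ref_span(reads$cigar)
  r <- reads[reads$chrom == chrom & !is.na(reads$seq) &
             !reads$is_secondary, , drop = FALSE]
  if (nrow(r) == 0L) return(stats::setNames(character(0), character(0)))
  spans <- r$.span
  keep <- r$start < end & (r$start + spans) > start
  stats::setNames(r$seq[keep], r$name[keep])
}
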