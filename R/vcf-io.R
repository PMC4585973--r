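#' Read a VCF file as small variants or SV records
#'
#' Coordinates are converted from the VCF's 1-based `POS` to the internal
#' 0-based convention. Multi-allelic records are split into biallelic rows.
#'
#' In `"SV"` mode, symbolic `<DEL>`/`<INS>` alleles are resolved through the
#' `END`/`SVLEN`/`SEQ` INFO keys: a DEL spans `[POS-1, END)` (size
#' `END - POS + 1`), an INS is anchored at `POS` with size `|SVLEN|` or the
#' length of `SEQ`. Sequence-resolved alleles are interpreted as
#' left-anchored (the shorter allele is a prefix of the longer). Symbolic
#' records with neither `END` nor `SVLEN` (nor `SEQ` for INS) are skipped
#' with a warning; records below `min_size` are dropped.
#'
#' @param path VCF path.
#' @param mode `"SMALL"` or `"SV"`.
#' @param min_size Minimum SV size kept in SV mode (bp).
#' @return A small-variant data.frame (`"SMALL"`) or SV data.frame (`"SV"`).
#' @export
read_vcf <- function(path, mode = c("SMALL", "SV"), min_size = 50L) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  n <- length(vcf)
  if (n == 0L) {
    return(if (mode == "SMALL") small_variants() else empty_svs())
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  if (methods::is(alts, "DNAStringSetList")) {
    alts <- methods::as(alts, "CharacterList")
  }
  alts <- as.list(alts)
  inf <- VariantAnnotation::info(vcf)
  getinfo <- function(key, i) {
    if (!key %in% colnames(inf)) return(NA)
    val <- inf[[key]][i]
    if (methods::is(inf[[key]], "List") || is.list(inf[[key]])) {
      val <- unlist(val)
      if (length(val) == 0L) return(NA)
      if (key %in% c("SOURCES", "VALID")) return(paste(val, collapse = ","))
      val <- val[1L]
    }
    if (length(val) == 0L || is.na(val)) NA else val
  }
  gts <- NULL
  if (mode == "SMALL" && "GT" %in% names(VariantAnnotation::geno(vcf)) &&
      ncol(vcf) >= 1L) {
    gts <- VariantAnnotation::geno(vcf)$GT[, 1L]
  }

  small <- list(); svs <- list(); skipped <- 0L
  for (i in seq_len(n)) {
    for (a in alts[[i]]) {
      if (!nzchar(a)) next
      symbolic <- startsWith(a, "<")
      if (mode == "SMALL") {
        if (symbolic) next
        gt <- if (!is.null(gts) && length(alts[[i]]) == 1L) gts[i] else NA
        small[[length(small) + 1L]] <-
          small_variants(chrom[i], pos1[i] - 1L, refs[i], a, gt)
        next
      }
      # SV mode
      if (symbolic) {
        svt <- sub("^<(DEL|INS)>$", "\\1", a)
        if (!svt %in% c("DEL", "INS")) next   # BND etc: out of scope
        svlen <- suppressWarnings(as.integer(getinfo("SVLEN", i)))
        endv <- suppressWarnings(as.integer(getinfo("END", i)))
        seqv <- getinfo("SEQ", i)
        if (svt == "DEL") {
          start <- pos1[i] - 1L
          if (!is.na(endv)) {
            end <- endv
          } else if (!is.na(svlen)) {
            end <- start + abs(svlen)
          } else { skipped <- skipped + 1L; next }
          size <- end - start
          rec <- list(chrom = chrom[i], start = start, end = end,
                      svtype = "DEL", size = size, seq = NA_character_)
        } else {
          start <- pos1[i]
          size <- if (!is.na(svlen)) abs(svlen)
                  else if (!is.na(seqv) && !is.na(nchar(seqv))) nchar(seqv)
                  else NA_integer_
          if (is.na(size)) { skipped <- skipped + 1L; next }
          rec <- list(chrom = chrom[i], start = start, end = start,
                      svtype = "INS", size = size,
                      seq = if (is.na(seqv)) NA_character_
                            else as.character(seqv))
        }
      } else {
        rl <- nchar(refs[i]); al <- nchar(a)
        if (rl == al) next                    # SNV/MNV: not an SV
        if (rl > al) {
          start <- pos1[i] - 1L + al
          rec <- list(chrom = chrom[i], start = start, end = start + rl - al,
                      svtype = "DEL", size = rl - al, seq = NA_character_)
        } else {
          start <- pos1[i] - 1L + rl
          rec <- list(chrom = chrom[i], start = start, end = start,
                      svtype = "INS", size = al - rl,
                      seq = substr(a, rl + 1L, al))
        }
      }
      if (rec$size < min_size) next
      src <- getinfo("SOURCES", i); val <- getinfo("VALID", i)
      tier <- getinfo("TIER", i)
      svs[[length(svs) + 1L]] <-
        sv_records(rec$chrom, rec$start, rec$end, rec$svtype, rec$size,
                   rec$seq,
                   sources = if (is.na(src)) "" else src,
                   validations = if (is.na(val)) "" else val,
                   tier = if (is.na(tier)) "UNSET" else tier)
    }
  }
  if (skipped > 0L)
    warning(skipped, " symbolic SV record(s) without END/SVLEN/SEQ skipped")
  if (mode == "SMALL") {
    if (length(small) == 0L) return(small_variants())
    do.call(rbind, small)
  } else {
    if (length(svs) == 0L) return(empty_svs())
    do.call(rbind, svs)
  }
}

vcf_header <- function(contigs = NULL, info_lines = character(),
                       format_lines = character(), sample = NULL,
                       timestamp = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         sprintf("##source=goldset-%s",
                 as.character(utils::packageVersion("goldset"))))
  if (timestamp)
    h <- c(h, sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")))
  if (!is.null(contigs))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      unname(contigs)))
  h <- c(h, info_lines, format_lines)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) cols <- c(cols, "FORMAT", sample)
  c(h, paste(cols, collapse = "\t"))
}

#' Write small variants as a VCF file
#'
#' @param v Small-variant data.frame (0-based `pos`; written as 1-based).
#' @param path Output path.
#' @param reference Optional named character vector, used to emit `##contig`
#'   header lines.
#' @param timestamp Include a `##fileDate` header line?
#' @return `path`, invisibly.
#' @export
write_small_vcf <- function(v, path, reference = NULL, timestamp = TRUE) {
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  has_gt <- nrow(v) > 0L && any(!is.na(v$gt))
  contigs <- if (!is.null(reference)) {
    stats::setNames(as.integer(nchar(reference)), names(reference))
  }
  fmt <- if (has_gt)
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  h <- vcf_header(contigs, format_lines = if (has_gt) fmt else character(),
                  sample = if (has_gt) "SAMPLE", timestamp = timestamp)
  body <- character(0)
  if (nrow(v) > 0L) {
    body <- paste(v$chrom, v$pos + 1L, ".", v$ref, v$alt, ".", ".", ".",
                  sep = "\t")
    if (has_gt)
      body <- paste(body, "GT", ifelse(is.na(v$gt), "./.", v$gt), sep = "\t")
  }
  writeLines(c(h, body), path)
  invisible(path)
}

sv_info_header <- function() {
  c('##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of the event (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed event length">',
    '##INFO=<ID=SEQ,Number=1,Type=String,Description="Inserted sequence">',
    '##INFO=<ID=SOURCES,Number=.,Type=String,Description="Provenance labels">',
    '##INFO=<ID=VALID,Number=.,Type=String,Description="Validation sources">',
    '##INFO=<ID=TIER,Number=1,Type=String,Description="GOLD, PASS, NOTVAL or UNSET">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">')
}

#' Write SV records as a symbolic-allele VCF file
#'
#' DELs are written with `POS = start + 1` and `END = end` so that the
#' half-open internal span round-trips; INSs with `POS = start` (the base
#' before the insertion point). Provenance, validation sources and tier go
#' to the INFO keys `SOURCES`, `VALID` and `TIER`.
#'
#' @param svs SV data.frame.
#' @param path Output path.
#' @param reference Optional named character vector; provides `##contig`
#'   lines and the anchor REF base (otherwise "N").
#' @param timestamp Include a `##fileDate` header line?
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, reference = NULL, timestamp = TRUE) {
  svs <- sort_svs(svs)
  contigs <- if (!is.null(reference)) {
    stats::setNames(as.integer(nchar(reference)), names(reference))
  }
  h <- vcf_header(contigs, info_lines = sv_info_header(),
                  timestamp = timestamp)
  body <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    del <- svs$svtype[i] == "DEL"
    pos1 <- if (del) svs$start[i] + 1L else svs$start[i]
    refb <- "N"
    if (!is.null(reference) && pos1 >= 1L) {
      refb <- ref_fetch(reference, svs$chrom[i], pos1 - 1L, pos1)
    }
    info <- c(sprintf("SVTYPE=%s", svs$svtype[i]),
              sprintf("END=%d", svs$end[i]),
              sprintf("SVLEN=%d", if (del) -svs$size[i] else svs$size[i]))
    if (!del && !is.na(svs$inserted_seq[i]))
      info <- c(info, sprintf("SEQ=%s", svs$inserted_seq[i]))
    if (nzchar(svs$sources[i]))
      info <- c(info, sprintf("SOURCES=%s", svs$sources[i]))
    if (nzchar(svs$validations[i]))
      info <- c(info, sprintf("VALID=%s", svs$validations[i]))
    if (svs$tier[i] != "UNSET")
      info <- c(info, sprintf("TIER=%s", svs$tier[i]))
    body[i] <- paste(svs$chrom[i], pos1, svs$id[i], refb,
                     sprintf("<%s>", svs$svtype[i]), ".", ".",
                     paste(info, collapse = ";"), sep = "\t")
  }
  writeLines(c(h, body), path)
  invisible(path)
}
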