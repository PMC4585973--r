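#' Construct a table of aligned reads
#'
#' The in-memory alignment record used throughout the package. `start` is
#' 0-based; `cigar` uses the M/I/D/S/H operations; `nm` is the edit distance
#' (NM tag, `NA` when absent); `mate_*`/`insert_size` are populated for
#' paired reads. `seq` may be `NA` when sequences are not needed.
#'
#' @param name,chrom,start,cigar,mapq,nm Parallel vectors of core fields.
#' @param is_secondary,is_supplementary,is_reverse Flag vectors.
#' @param is_paired,mate_chrom,mate_start,mate_reverse,insert_size Pairing.
#' @param seq Read sequences (reference orientation, as in SAM).
#' @return data.frame of aligned reads.
#' @export
aligned_reads <- function(name = character(), chrom = character(),
                          start = integer(), cigar = character(),
                          mapq = integer(), nm = NA_integer_,
                          is_secondary = FALSE, is_supplementary = FALSE,
                          is_reverse = FALSE, is_paired = FALSE,
                          mate_chrom = NA_character_, mate_start = NA_integer_,
                          mate_reverse = FALSE, insert_size = NA_integer_,
                          seq = NA_character_) {
  n <- length(name)
  data.frame(name = as.character(name), chrom = as.character(chrom),
             start = as.integer(start), cigar = as.character(cigar),
             mapq = as.integer(mapq), nm = rep_len(as.integer(nm), n),
             is_secondary = rep_len(is_secondary, n),
             is_supplementary = rep_len(is_supplementary, n),
             is_reverse = rep_len(is_reverse, n),
             is_paired = rep_len(is_paired, n),
             mate_chrom = rep_len(as.character(mate_chrom), n),
             mate_start = rep_len(as.integer(mate_start), n),
             mate_reverse = rep_len(mate_reverse, n),
             insert_size = rep_len(as.integer(insert_size), n),
             seq = rep_len(as.character(seq), n),
             stringsAsFactors = FALSE)
}

# --- cigar helpers ----------------------------------------------------------

#' Parse CIGAR strings into operation/length pairs
#' @param cigar Character vector of CIGAR strings.
#' @return List of data.frames with columns `op`, `len`.
#' @export
parse_cigar <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(data.frame(op = character(),
                                                  len = integer()))
    m <- gregexpr("\\d+[MIDSH=X]", cg)[[1]]
    tok <- regmatches(cg, list(m))[[1]]
    if (sum(nchar(tok)) != nchar(cg)) stop("unparsable CIGAR: ", cg)
    data.frame(op = substr(tok, nchar(tok), nchar(tok)),
               len = as.integer(substr(tok, 1L, nchar(tok) - 1L)),
               stringsAsFactors = FALSE)
  })
}

#' Reference span of CIGAR strings (sum of M, D, =, X lengths)
#' @param cigar Character vector.
#' @return Integer vector of spans in bp.
#' @export
cigar_ref_span <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  out
}

#' Does a CIGAR contain soft or hard clips?
#' @param cigar Character vector.
#' @return Logical vector; `TRUE` means the read is not end-to-end.
#' @export
cigar_has_clip <- function(cigar) {
  grepl("[SH]", cigar)
}

# query-space interval of the aligned portion, in read orientation.
# Returns c(qstart, qend, qlen) 0-based half-open.
cigar_query_span <- function(p, is_reverse) {
  qlen <- sum(p$len[p$op %in% c("M", "I", "S", "=", "X")]) +
    sum(p$len[p$op == "H"])
  lead <- 0L
  for (i in seq_len(nrow(p))) {
    if (p$op[i] %in% c("S", "H")) lead <- lead + p$len[i] else break
  }
  trail <- 0L
  for (i in rev(seq_len(nrow(p)))) {
    if (p$op[i] %in% c("S", "H")) trail <- trail + p$len[i] else break
  }
  qs <- lead
  qe <- qlen - trail
  if (is_reverse) c(qlen - qe, qlen - qs, qlen) else c(qs, qe, qlen)
}

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted on the fly with [Rsamtools::asBam()]. The NM tag
#' is fetched when present (required downstream by the NSVR builder).
#'
#' @param path `.sam` or `.bam` path.
#' @param keep_seq Keep read sequences (needed for junction mapping and SV
#'   extraction of inserted sequence)?
#' @return Aligned-read data.frame (mapped records only).
#' @export
read_alignments <- function(path, keep_seq = TRUE) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize")
  if (keep_seq) what <- c(what, "seq")
  p <- Rsamtools::ScanBamParam(what = what, tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  out <- aligned_reads(
    name = res$qname, chrom = as.character(res$rname),
    start = res$pos - 1L, cigar = res$cigar, mapq = res$mapq, nm = nm,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    is_paired = bitwAnd(flag, 1L) > 0L,
    mate_chrom = as.character(res$mrnm), mate_start = res$mpos - 1L,
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    insert_size = res$isize,
    seq = if (keep_seq) as.character(res$seq) else NA_character_)
  out[mapped, , drop = FALSE]
}

#' Write aligned reads as a coordinate-sorted SAM file
#'
#' @param reads Aligned-read data.frame.
#' @param reference Named character vector of contig sequences (for `@SQ`).
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  hd <- c("@HD\tVN:1.6\tSO:coordinate",
          sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
  flag <- rep(0L, nrow(reads))
  flag <- flag + ifelse(reads$is_paired, 1L, 0L)
  flag <- flag + ifelse(reads$is_reverse, 16L, 0L)
  flag <- flag + ifelse(reads$is_paired & reads$mate_reverse, 32L, 0L)
  flag <- flag + ifelse(reads$is_secondary, 256L, 0L)
  flag <- flag + ifelse(reads$is_supplementary, 2048L, 0L)
  # first/second-in-pair bits from a trailing /1 or /2 naming convention
  flag <- flag + ifelse(reads$is_paired & grepl("/1$", reads$name), 64L, 0L)
  flag <- flag + ifelse(reads$is_paired & grepl("/2$", reads$name), 128L, 0L)
  qn <- sub("/[12]$", "", reads$name)
  rnext <- ifelse(reads$is_paired & !is.na(reads$mate_chrom),
                  ifelse(reads$mate_chrom == reads$chrom, "=",
                         reads$mate_chrom), "*")
  pnext <- ifelse(reads$is_paired & !is.na(reads$mate_start),
                  reads$mate_start + 1L, 0L)
  tlen <- ifelse(is.na(reads$insert_size), 0L, reads$insert_size)
  seq <- ifelse(is.na(reads$seq), "*", reads$seq)
  qual <- ifelse(is.na(reads$seq), "*",
                 vapply(nchar(seq), function(n) strrep("I", n), ""))
  body <- paste(qn, flag, reads$chrom, reads$start + 1L, reads$mapq,
                reads$cigar, rnext, pnext, tlen, seq, qual,
                ifelse(is.na(reads$nm), "", sprintf("NM:i:%d", reads$nm)),
                sep = "\t")
  body <- sub("\t$", "", body)
  writeLines(c(hd, body), path)
  invisible(path)
}
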