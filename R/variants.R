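#' Construct a table of small variants
#'
#' Positions are 0-based (first base of `ref`). `ref`/`alt` are non-empty
#' uppercase A/C/G/T strings; rows where either allele contains an ambiguity
#' code are rejected by [normalize_variants()] with a warning rather than
#' here, so callers can decide how strict to be.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the variants.
#' @param gt Optional genotype strings (e.g. "0/1", "1/1"); `NA` if unknown.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
small_variants <- function(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gt = NA_character_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   gt = rep_len(as.character(gt), n),
                   stringsAsFactors = FALSE)
  if (n > 0L) {
    if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
      stop("ref and alt must be non-empty")
    if (any(df$ref == df$alt)) stop("ref must differ from alt")
    if (any(df$pos < 0L)) stop("positions must be >= 0")
  }
  df
}

#' Classify small variants as SNV / insertion / deletion
#' @param v Small-variant data.frame.
#' @return Character vector "SNV", "INS", "DEL" or "MNV".
#' @export
variant_class <- function(v) {
  rl <- nchar(v$ref); al <- nchar(v$alt)
  ifelse(rl == 1L & al == 1L, "SNV",
         ifelse(al > rl, "INS", ifelse(rl > al, "DEL", "MNV")))
}

#' @keywords internal
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = "\t")
}

#' @keywords internal
key_to_variants <- function(keys) {
  if (length(keys) == 0L) return(small_variants())
  f <- strsplit(keys, "\t", fixed = TRUE)
  small_variants(vapply(f, `[`, "", 1L), as.integer(vapply(f, `[`, "", 2L)),
                 vapply(f, `[`, "", 3L), vapply(f, `[`, "", 4L))
}

# --- reference accessors ----------------------------------------------------
# A reference is a named character vector (one uppercase sequence per contig).

ref_fetch <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  substr(reference[[chrom]], start + 1L, end)
}

ref_len <- function(reference, chrom) {
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  nchar(reference[[chrom]])
}

#' Read a FASTA reference into a named character vector
#' @param path FASTA path.
#' @return Named character vector of uppercase contig sequences.
#' @export
read_fasta_ref <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param reference Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_ref <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

# --- normalization ----------------------------------------------------------

#' Normalize one small variant to its minimal left-aligned representation
#'
#' Implements the standard left-align-and-trim procedure: shared trailing
#' bases are trimmed (extending to the left with reference bases when an
#' allele empties), then shared leading bases beyond a single anchor are
#' trimmed. The result is the unique leftmost minimal representation of the
#' haplotype edit; applying the function twice is a no-op.
#'
#' @param chrom,pos,ref,alt A single variant (0-based `pos`).
#' @param reference Named character vector of contig sequences.
#' @return list(pos=, ref=, alt=).
#' @export
normalize_one <- function(chrom, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("empty allele")
  if (ref == alt) stop("ref equals alt: not a variant")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles restricted to A/C/G/T")
  obs <- ref_fetch(reference, chrom, pos, pos + nchar(ref))
  if (!identical(obs, ref))
    stop(sprintf("reference mismatch at %s:%d (have %s, VCF says %s)",
                 chrom, pos, obs, ref))
  last1 <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last1(ref) == last1(alt) &&
        (nchar(ref) > 1L || nchar(alt) > 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 0L) stop("cannot left-extend past contig start")
        pos <- pos - 1L
        b <- ref_fetch(reference, chrom, pos, pos + 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize a table of small variants
#'
#' Rows whose alleles contain ambiguity codes (anything outside A/C/G/T) are
#' dropped with a warning, since left-alignment is undefined over them.
#'
#' @param v Small-variant data.frame.
#' @param reference Named character vector of contig sequences.
#' @return Normalized small-variant data.frame (same row order).
#' @export
normalize_variants <- function(v, reference) {
  if (nrow(v) == 0L) return(v)
  bad <- grepl("[^ACGT]", v$ref) | grepl("[^ACGT]", v$alt)
  if (any(bad)) {
    warning(sum(bad), " variant(s) with non-ACGT alleles dropped")
    v <- v[!bad, , drop = FALSE]
    if (nrow(v) == 0L) return(v)
  }
  for (i in seq_len(nrow(v))) {
    nv <- normalize_one(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], reference)
    v$pos[i] <- nv$pos; v$ref[i] <- nv$ref; v$alt[i] <- nv$alt
  }
  v
}

#' Shift an indel to an equivalent right-aligned representation
#'
#' The dual of left alignment, used by the caller simulator to emit
#' representation variants that normalize back to the same key. SNVs are
#' returned unchanged.
#'
#' @param chrom,pos,ref,alt A single variant (0-based `pos`).
#' @param reference Named character vector of contig sequences.
#' @return list(pos=, ref=, alt=).
#' @export
right_shift_one <- function(chrom, pos, ref, alt, reference) {
  clen <- ref_len(reference, chrom)
  repeat {
    if (nchar(ref) == 0L || nchar(alt) == 0L) break
    if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) break
    if (nchar(ref) == 1L && nchar(alt) == 1L) break
    nxt <- pos + nchar(ref)          # reference base just past the ref span
    if (nxt >= clen) break
    b <- ref_fetch(reference, chrom, nxt, nxt + 1L)
    ref <- paste0(substr(ref, 2L, nchar(ref)), b)
    alt <- paste0(substr(alt, 2L, nchar(alt)), b)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
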