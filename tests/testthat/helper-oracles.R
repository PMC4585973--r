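# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Haplotype-equivalence normalization oracle: enumerate every (pos, ref, alt)
# in a +/-window whose haplotype edit equals the input's, then pick the
# minimal-length representation, leftmost on ties.
oracle_normalize <- function(refseq, pos, ref, alt, window = 20L) {
  n <- nchar(refseq)
  hap <- paste0(substr(refseq, 1L, pos), alt,
                substr(refseq, pos + nchar(ref) + 1L, n))
  hn <- nchar(hap)
  best <- NULL
  for (p in max(0L, pos - window):min(n - 1L, pos + window)) {
    if (substr(refseq, 1L, p) != substr(hap, 1L, p)) next
    for (rl in 1L:min(nchar(ref) + window, n - p)) {
      suffix_len <- n - p - rl
      al <- hn - p - suffix_len
      if (al < 1L) next
      if (substr(refseq, p + rl + 1L, n) != substr(hap, p + al + 1L, hn))
        next
      rc <- substr(refseq, p + 1L, p + rl)
      ac <- substr(hap, p + 1L, p + al)
      if (rc == ac) next
      cand <- list(pos = p, ref = rc, alt = ac, len = rl + al)
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$pos < best$pos)) {
        best <- cand
      }
    }
  }
  best
}

# Per-base boolean-mask oracle for interval set operations on one contig.
mask_from_intervals <- function(iv, contig_len) {
  m <- rep(FALSE, contig_len)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  }
  m
}

intervals_from_mask <- function(mask, chrom = "sim1") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(genomic_intervals())
  genomic_intervals(chrom, starts[keep], ends[keep])
}

# Per-base NSVR oracle: qualifying depth >= min_reads, zero disqualifying
# coverage, region length >= min_region_len. Reads are given as spans plus a
# qualifying flag (read-level qualification is tested separately).
oracle_nsvr <- function(spans, qualifying, contig_len, min_reads,
                        min_region_len, chrom = "sim1") {
  qd <- integer(contig_len)
  bad <- rep(FALSE, contig_len)
  for (i in seq_len(nrow(spans))) {
    ix <- (spans$start[i] + 1L):spans$end[i]
    if (qualifying[i]) qd[ix] <- qd[ix] + 1L else bad[ix] <- TRUE
  }
  mask <- qd >= min_reads & !bad
  iv <- intervals_from_mask(mask, chrom)
  iv[iv$end - iv$start >= min_region_len, , drop = FALSE]
}

# Closed-form P(C1 & C2) over independent per-origin presence probabilities.
# origins: data.frame(platform, caller); p: presence probability per origin.
oracle_p_consensus <- function(origins, p, platforms) {
  k <- nrow(origins)
  total <- 0
  for (bits in 0:(2^k - 1)) {
    on <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1L)))
    prob <- prod(ifelse(on, p, 1 - p))
    if (!any(on)) next
    c1 <- all(platforms %in% origins$platform[on])
    c2 <- length(unique(origins$caller[on])) >= 2L
    if (c1 && c2) total <- total + prob
  }
  total
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
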