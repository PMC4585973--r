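#' Simulate a reference contig
#'
#' Draws an i.i.d. base sequence at a target GC content and embeds
#' repeat-like cassettes: dispersed copies of a single SINE-length unit
#' (class `"SINE_like"`) and short tandem arrays (class
#' `"Simple_repeat"`), recording their spans so repeat-overlap reports can
#' be exercised. Deterministic for a fixed seed.
#'
#' @param length Contig length in bp (>= 10 kb).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param chrom Contig name.
#' @param n_sine,n_tandem Number of dispersed / tandem cassettes (defaults
#'   scale with length; 0 disables).
#' @return list with class `sim_genome`: `chrom`, `seq`, `repeats`
#'   (interval data.frame with a `class` column), `gc`, `seed`.
#' @export
simulate_genome <- function(length, gc = 0.41, seed = 1L, chrom = "sim1",
                            n_sine = NULL, n_tandem = NULL) {
  if (length < 10000L) stop("simulated contigs must be >= 10 kb")
  if (is.na(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  if (is.null(n_sine)) n_sine <- length %/% 20000L
  if (is.null(n_tandem)) n_tandem <- length %/% 25000L
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  reps <- list()
  place <- function(unit_len) {
    # non-overlapping placement away from contig edges
    for (try in 1:50) {
      s <- sample.int(length - unit_len - 2000L, 1L) + 1000L
      ok <- TRUE
      for (r in reps) if (s < r$end + 100L && s + unit_len > r$start - 100L) {
        ok <- FALSE; break
      }
      if (ok) return(s)
    }
    NA_integer_
  }
  if (n_sine > 0L) {
    unit <- sample(c("A", "C", "G", "T"), 300L, replace = TRUE)
    for (i in seq_len(n_sine)) {
      s <- place(300L)
      if (is.na(s)) next
      bases[(s + 1L):(s + 300L)] <- unit
      reps[[length(reps) + 1L]] <- list(start = s, end = s + 300L,
                                        class = "SINE_like")
    }
  }
  if (n_tandem > 0L) {
    for (i in seq_len(n_tandem)) {
      u <- sample(c("A", "C", "G", "T"), sample(2:6, 1L), replace = TRUE)
      arr <- rep(u, length.out = sample(60:150, 1L))
      s <- place(length(arr))
      if (is.na(s)) next
      bases[(s + 1L):(s + length(arr))] <- arr
      reps[[length(reps) + 1L]] <- list(start = s, end = s + length(arr),
                                        class = "Simple_repeat")
    }
  }
  repdf <- if (length(reps) == 0L) {
    cbind(empty_intervals(), data.frame(class = character()))
  } else {
    data.frame(chrom = chrom,
               start = vapply(reps, `[[`, 0L, "start"),
               end = vapply(reps, `[[`, 0L, "end"),
               class = vapply(reps, `[[`, "", "class"),
               stringsAsFactors = FALSE)
  }
  structure(list(chrom = chrom, seq = paste(bases, collapse = ""),
                 repeats = sort_intervals(repdf), gc = gc, seed = seed),
            class = "sim_genome")
}

# power-law-like SV size generator (Pareto tail above min_size)
rsv_size <- function(n, min_size = 50L, alpha = 1.2, cap = 20000L) {
  s <- floor(min_size * stats::runif(n)^(-1 / alpha))
  pmin(as.integer(s), cap)
}

#' Implant variants into a simulated reference, producing a diploid donor
#'
#' Events are placed pairwise non-overlapping with at least 200 bp of
#' separation; small indels are stored in normalized (minimal,
#' left-aligned) representation. Genotypes are homozygous with probability
#' 1/3, otherwise heterozygous on a random haplotype. Donor haplotype
#' sequences and per-haplotype reference-alignment block maps are built
#' alongside, so read simulation and recovery checks share one source of
#' truth.
#'
#' @param genome A [simulate_genome()] result.
#' @param n_snv,n_indel Number of SNVs and small (1-10 bp) indels.
#' @param n_sv_del,n_sv_ins Number of deletion / insertion SVs (sizes drawn
#'   from a power-law-like decay above `sv_min_size`).
#' @param sv_min_size,sv_max_size SV size range (bp).
#' @param seed Integer seed.
#' @return list with class `truth_set`: `reference` (named vector),
#'   `small` (+`small_hap`), `svs` (+`sv_hap`, `sv_gt`), `donor`
#'   (two haplotype sequences), `blocks` (per-haplotype alignment maps),
#'   `genome`, `seed`.
#' @export
implant_variants <- function(genome, n_snv = 1600L, n_indel = 400L,
                             n_sv_del = 120L, n_sv_ins = 80L,
                             sv_min_size = 50L, sv_max_size = 5000L,
                             seed = 1L) {
  set.seed(seed)
  chrom <- genome$chrom
  L <- nchar(genome$seq)
  reference <- stats::setNames(genome$seq, chrom)
  n <- n_snv + n_indel + n_sv_del + n_sv_ins
  types <- sample(c(rep("SNV", n_snv), rep("INDEL", n_indel),
                    rep("SVDEL", n_sv_del), rep("SVINS", n_sv_ins)))
  sizes <- integer(n)
  sizes[types == "SNV"] <- 1L
  sizes[types == "INDEL"] <- sample(1:10, sum(types == "INDEL"),
                                    replace = TRUE)
  nsv <- sum(types %in% c("SVDEL", "SVINS"))
  sizes[types %in% c("SVDEL", "SVINS")] <-
    pmin(rsv_size(nsv, sv_min_size), as.integer(sv_max_size))
  foot <- ifelse(types == "SVDEL", sizes,
                 ifelse(types == "INDEL", sizes + 2L, 2L))
  need <- sum(foot) + (n + 1L) * 200L + 2000L
  if (need > L)
    stop("infeasible implant spec: ", need, " bp of footprint+spacing on a ",
         L, " bp contig")
  slack <- L - need
  extra <- floor(diff(sort(c(0, stats::runif(n), 1))) * slack)
  pos <- integer(n)
  cur <- 1000L
  for (i in seq_len(n)) {
    cur <- cur + 200L + extra[i]
    pos[i] <- cur
    cur <- cur + foot[i]
  }

  base_at <- function(p) substr(genome$seq, p + 1L, p + 1L)
  rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                       replace = TRUE), collapse = "")
  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

  gt_draw <- function(k) {
    hom <- stats::runif(k) < 1 / 3
    hap <- ifelse(hom, 0L, sample(1:2, k, replace = TRUE))
    list(gt = ifelse(hom, "1/1", "0/1"), hap = hap)
  }

  small <- list(); small_hap <- integer(0)
  svs <- list(); sv_hap <- integer(0); sv_gt <- character(0)
  g_small <- gt_draw(n_snv + n_indel)
  g_sv <- gt_draw(nsv)
  i_small <- 0L; i_sv <- 0L
  for (i in seq_len(n)) {
    p <- pos[i]; s <- sizes[i]
    if (types[i] == "SNV") {
      i_small <- i_small + 1L
      b <- base_at(p)
      small[[length(small) + 1L]] <-
        small_variants(chrom, p, b, other_base(b), g_small$gt[i_small])
      small_hap <- c(small_hap, g_small$hap[i_small])
    } else if (types[i] == "INDEL") {
      i_small <- i_small + 1L
      anchor <- base_at(p)
      if (stats::runif(1) < 0.5) {        # insertion
        v <- small_variants(chrom, p, anchor, paste0(anchor, rand_seq(s)),
                            g_small$gt[i_small])
      } else {                            # deletion
        v <- small_variants(chrom, p,
                            substr(genome$seq, p + 1L, p + 1L + s),
                            anchor, g_small$gt[i_small])
      }
      nv <- normalize_one(chrom, v$pos, v$ref, v$alt, reference)
      v$pos <- nv$pos; v$ref <- nv$ref; v$alt <- nv$alt
      small[[length(small) + 1L]] <- v
      small_hap <- c(small_hap, g_small$hap[i_small])
    } else {
      i_sv <- i_sv + 1L
      if (types[i] == "SVDEL") {
        svs[[length(svs) + 1L]] <-
          sv_records(chrom, p, p + s, "DEL", s, sources = "truth")
      } else {
        svs[[length(svs) + 1L]] <-
          sv_records(chrom, p, p, "INS", s, rand_seq(s), sources = "truth")
      }
      sv_hap <- c(sv_hap, g_sv$hap[i_sv])
      sv_gt <- c(sv_gt, g_sv$gt[i_sv])
    }
  }
  small <- if (length(small) > 0L) do.call(rbind, small) else small_variants()
  svs <- if (length(svs) > 0L) do.call(rbind, svs) else empty_svs()
  ord <- order(small$pos); small <- small[ord, , drop = FALSE]
  small_hap <- small_hap[ord]
  ord <- order(svs$start); svs <- svs[ord, , drop = FALSE]
  sv_hap <- sv_hap[ord]; sv_gt <- sv_gt[ord]
  rownames(small) <- NULL; rownames(svs) <- NULL

  donor <- list(); blocks <- list()
  for (h in 1:2) {
    bl <- build_blocks(genome$seq, chrom,
                       small[small_hap %in% c(0L, h), , drop = FALSE],
                       svs[sv_hap %in% c(0L, h), , drop = FALSE])
    blocks[[h]] <- bl
    donor[[h]] <- blocks_to_donor(genome$seq, bl)
  }
  structure(list(reference = reference, small = small,
                 small_hap = small_hap, svs = svs, sv_hap = sv_hap,
                 sv_gt = sv_gt, donor = donor, blocks = blocks,
                 genome = genome, seed = seed),
            class = "truth_set")
}

# Alignment block map between reference and one donor haplotype.
# ops: M (identical run), X (substituted run), I (donor-only), D (ref-only).
build_blocks <- function(refseq, chrom, small, svs) {
  ev <- list()
  for (i in seq_len(nrow(small))) {
    v <- small[i, ]
    pre <- as.integer(substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L))
    rl <- nchar(v$ref) - pre; al <- nchar(v$alt) - pre
    if (rl == al && rl + pre == 1L) {       # SNV
      ev[[length(ev) + 1L]] <- list(pos = v$pos, ref_len = 1L,
                                    donor_len = 1L, op = "X",
                                    seq = v$alt, sv = FALSE)
    } else if (al > rl) {                   # insertion after anchor
      ev[[length(ev) + 1L]] <- list(pos = v$pos + pre, ref_len = 0L,
                                    donor_len = al - rl, op = "I",
                                    seq = substr(v$alt, pre + rl + 1L,
                                                 nchar(v$alt)),
                                    sv = FALSE)
    } else {                                # deletion after anchor
      ev[[length(ev) + 1L]] <- list(pos = v$pos + pre,
                                    ref_len = rl - al, donor_len = 0L,
                                    op = "D", seq = NA_character_,
                                    sv = FALSE)
    }
  }
  for (i in seq_len(nrow(svs))) {
    s <- svs[i, ]
    if (s$svtype == "DEL") {
      ev[[length(ev) + 1L]] <- list(pos = s$start, ref_len = s$size,
                                    donor_len = 0L, op = "D",
                                    seq = NA_character_, sv = TRUE)
    } else {
      ev[[length(ev) + 1L]] <- list(pos = s$start, ref_len = 0L,
                                    donor_len = s$size, op = "I",
                                    seq = s$inserted_seq, sv = TRUE)
    }
  }
  if (length(ev) > 0L) {
    ev <- ev[order(vapply(ev, `[[`, 0L, "pos"))]
  }
  L <- nchar(refseq)
  rows <- list()
  rpos <- 0L; dpos <- 0L
  add <- function(op, rl, dl, seq, sv) {
    rows[[length(rows) + 1L]] <<-
      data.frame(op = op, ref_start = rpos, donor_start = dpos,
                 ref_len = rl, donor_len = dl,
                 seq = if (is.null(seq)) NA_character_ else seq,
                 is_sv = sv, stringsAsFactors = FALSE)
    rpos <<- rpos + rl; dpos <<- dpos + dl
  }
  for (e in ev) {
    if (e$pos > rpos) add("M", e$pos - rpos, e$pos - rpos, NULL, FALSE)
    add(e$op, e$ref_len, e$donor_len, e$seq, e$sv)
  }
  if (rpos < L) add("M", L - rpos, L - rpos, NULL, FALSE)
  do.call(rbind, rows)
}

blocks_to_donor <- function(refseq, blocks) {
  parts <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    parts[i] <- switch(b$op,
      M = substr(refseq, b$ref_start + 1L, b$ref_start + b$ref_len),
      X = b$seq,
      I = b$seq,
      D = "")
  }
  paste(parts, collapse = "")
}

#' Read-simulation profiles
#'
#' @param read_len Read length (paired mode).
#' @param frag_mean,frag_sd Fragment (outer insert) distribution.
#' @param error_rate Per-base substitution error rate.
#' @name sim_profiles
#' @return Profile list for [simulate_reads()].
#' @export
paired_profile <- function(read_len = 100L, frag_mean = 400L,
                           frag_sd = 50L, error_rate = 0.001) {
  list(type = "paired", read_len = as.integer(read_len),
       frag_mean = frag_mean, frag_sd = frag_sd, error_rate = error_rate)
}

#' @rdname sim_profiles
#' @param len_mean,len_sd Read-length distribution (long mode).
#' @export
long_profile <- function(len_mean = 1000L, len_sd = 100L,
                         error_rate = 0.002) {
  list(type = "long", len_mean = len_mean, len_sd = len_sd,
       error_rate = error_rate)
}

# Align a donor-read [ds, de) back to the reference through the block map.
# Returns a list of alignment segments (first = primary); NULL if unmapped.
map_donor_read <- function(blocks, ds, de, keep_supplementary = TRUE) {
  b_op <- blocks$op; b_ds <- blocks$donor_start; b_dl <- blocks$donor_len
  b_rs <- blocks$ref_start; b_rl <- blocks$ref_len; b_sv <- blocks$is_sv
  segs <- list()
  cur <- NULL    # list(ref_start, ops(chr), lens(int), nm, qs, qe)
  open_seg <- function(ref_start, qpos) {
    list(ref_start = ref_start, ops = character(0), lens = integer(0),
         nm = 0L, qs = qpos, qe = qpos)
  }
  push <- function(seg, op, len) {
    k <- length(seg$ops)
    if (k > 0L && seg$ops[k] == op) {
      seg$lens[k] <- seg$lens[k] + len
    } else {
      seg$ops <- c(seg$ops, op); seg$lens <- c(seg$lens, len)
    }
    seg
  }
  close_seg <- function() {
    if (!is.null(cur) && length(cur$ops) > 0L)
      segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
  }
  db_end <- b_ds + b_dl
  first <- findInterval(ds, b_ds)
  for (bi in seq(max(1L, first), length(b_op))) {
    bs <- b_ds[bi]; be <- db_end[bi]
    if (b_op[bi] == "D") {
      if (bs > ds && bs < de) {           # read covers the junction
        if (b_sv[bi]) {
          close_seg()                      # split: remainder re-anchors
        } else if (!is.null(cur)) {
          cur <- push(cur, "D", b_rl[bi])
          cur$nm <- cur$nm + b_rl[bi]
        }
      }
      next
    }
    if (be <= ds) next
    if (bs >= de) break
    os <- max(ds, bs); oe <- min(de, be)
    if (oe <= os) next
    qpos <- os - ds
    if (b_op[bi] %in% c("M", "X")) {
      if (is.null(cur)) cur <- open_seg(b_rs[bi] + (os - bs), qpos)
      cur <- push(cur, "M", oe - os)
      if (b_op[bi] == "X") cur$nm <- cur$nm + (oe - os)
      cur$qe <- oe - ds
    } else {                               # I: donor-only bases
      covers_all <- bs >= ds && be <= de
      if (covers_all && !is.null(cur)) {
        cur <- push(cur, "I", oe - os)
        cur$nm <- cur$nm + (oe - os)
        cur$qe <- oe - ds
      } else {
        # read enters or leaves inside the insert: clip it
        close_seg()
      }
    }
  }
  close_seg()
  if (length(segs) == 0L) return(NULL)
  if (!keep_supplementary) segs <- segs[1L]
  segs
}

seg_to_cigar <- function(seg, read_len) {
  ops <- seg$ops; lens <- seg$lens
  if (seg$qs > 0L) { ops <- c("S", ops); lens <- c(seg$qs, lens) }
  if (seg$qe < read_len) { ops <- c(ops, "S"); lens <- c(lens, read_len - seg$qe) }
  paste0(lens, ops, collapse = "")
}

apply_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(list(seq = seq, idx = integer(0)))
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, error_rate)
  if (k == 0L) return(list(seq = seq, idx = integer(0)))
  idx <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), idx = idx)
}

#' Simulate reads from a diploid donor, with alignments by construction
#'
#' Reads are drawn from the donor haplotypes and given reference-space
#' alignment records directly from the truth block map (no aligner in the
#' loop): reads inside unchanged segments are end-to-end with NM from
#' substitution errors; reads crossing implanted SV breakpoints are
#' soft-clipped (and, for long reads over a deletion, emitted as
#' primary + supplementary split pairs); small indels appear as I/D cigar
#' operations. Paired mode fills mate fields with outer insert sizes drawn
#' from Normal(frag_mean, frag_sd).
#'
#' @param truth A `truth_set` from [implant_variants()].
#' @param profile A [paired_profile()] or [long_profile()].
#' @param depth Mean coverage.
#' @param seed Integer seed.
#' @return Aligned-read data.frame (coordinate-sorted); serialize with
#'   [write_sam()].
#' @export
simulate_reads <- function(truth, profile, depth = 10, seed = 1L) {
  set.seed(seed)
  chrom <- truth$genome$chrom
  acc <- list(name = character(0), start = integer(0), cigar = character(0),
              nm = integer(0), supp = logical(0), rev = logical(0),
              paired = logical(0), mstart = integer(0), mrev = logical(0),
              isize = integer(0), seq = character(0))
  k <- 0L
  add_read <- function(name, start, cigar, nm, seq, supp = FALSE,
                       rev = FALSE, paired = FALSE, mstart = NA_integer_,
                       mrev = FALSE, isize = NA_integer_) {
    k <<- k + 1L
    acc$name[k] <<- name; acc$start[k] <<- start; acc$cigar[k] <<- cigar
    acc$nm[k] <<- nm; acc$supp[k] <<- supp; acc$rev[k] <<- rev
    acc$paired[k] <<- paired; acc$mstart[k] <<- mstart
    acc$mrev[k] <<- mrev; acc$isize[k] <<- isize; acc$seq[k] <<- seq
  }
  for (h in 1:2) {
    dseq <- truth$donor[[h]]
    dlen <- nchar(dseq)
    blocks <- truth$blocks[[h]]
    if (profile$type == "long") {
      n_reads <- ceiling(depth * dlen / profile$len_mean / 2)
      for (i in seq_len(n_reads)) {
        rl <- max(200L, as.integer(round(stats::rnorm(1, profile$len_mean,
                                                      profile$len_sd))))
        rl <- min(rl, dlen)
        ds <- sample.int(dlen - rl + 1L, 1L) - 1L
        segs <- map_donor_read(blocks, ds, ds + rl)
        if (is.null(segs)) next
        err <- apply_errors(substr(dseq, ds + 1L, ds + rl),
                            profile$error_rate)
        next_name <- sprintf("simL_h%d_%d", h, i)
        for (si in seq_along(segs)) {
          seg <- segs[[si]]
          nerr <- sum(err$idx > seg$qs & err$idx <= seg$qe)
          add_read(next_name, seg$ref_start, seg_to_cigar(seg, rl),
                   seg$nm + nerr, err$seq, supp = si > 1L)
        }
      }
    } else {
      n_frags <- ceiling(depth * dlen / (2 * profile$read_len) / 2)
      rl <- profile$read_len
      for (i in seq_len(n_frags)) {
        f <- max(2L * rl, as.integer(round(stats::rnorm(1, profile$frag_mean,
                                                        profile$frag_sd))))
        if (f >= dlen) next
        ds <- sample.int(dlen - f + 1L, 1L) - 1L
        m1 <- map_donor_read(blocks, ds, ds + rl, keep_supplementary = FALSE)
        m2 <- map_donor_read(blocks, ds + f - rl, ds + f,
                             keep_supplementary = FALSE)
        if (is.null(m1) || is.null(m2)) next
        s1 <- m1[[1L]]; s2 <- m2[[1L]]
        e1 <- apply_errors(substr(dseq, ds + 1L, ds + rl),
                           profile$error_rate)
        e2 <- apply_errors(substr(dseq, ds + f - rl + 1L, ds + f),
                           profile$error_rate)
        nm1 <- s1$nm + sum(e1$idx > s1$qs & e1$idx <= s1$qe)
        nm2 <- s2$nm + sum(e2$idx > s2$qs & e2$idx <= s2$qe)
        ref_end2 <- s2$ref_start +
          sum(s2$lens[s2$ops %in% c("M", "D")])
        tlen <- ref_end2 - s1$ref_start
        base <- sprintf("simP_h%d_%d", h, i)
        add_read(paste0(base, "/1"), s1$ref_start, seg_to_cigar(s1, rl),
                 nm1, e1$seq, paired = TRUE, mstart = s2$ref_start,
                 mrev = TRUE, isize = tlen)
        add_read(paste0(base, "/2"), s2$ref_start, seg_to_cigar(s2, rl),
                 nm2, e2$seq, rev = TRUE, paired = TRUE,
                 mstart = s1$ref_start, isize = -tlen)
      }
    }
  }
  if (k == 0L) return(aligned_reads())
  reads <- aligned_reads(
    name = acc$name, chrom = chrom, start = acc$start, cigar = acc$cigar,
    mapq = 60L, nm = acc$nm, is_supplementary = acc$supp,
    is_reverse = acc$rev, is_paired = acc$paired,
    mate_chrom = ifelse(acc$paired, chrom, NA_character_),
    mate_start = acc$mstart, mate_reverse = acc$mrev,
    insert_size = acc$isize, seq = acc$seq)
  reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

#' Caller bias profile for callset simulation
#'
#' @param name Caller identifier.
#' @param fnr Per-variant false-negative rate.
#' @param fpr_per_mb Expected false calls per megabase.
#' @param breakpoint_jitter_sd Breakpoint jitter SD (bp) applied to SVs.
#' @param indel_repr_shift Emit right-aligned indel representations (the
#'   representational divergence the normalizer must cancel)?
#' @return list with class `caller_profile`.
#' @export
caller_profile <- function(name, fnr = 0.05, fpr_per_mb = 1,
                           breakpoint_jitter_sd = 0,
                           indel_repr_shift = FALSE) {
  stopifnot(fnr >= 0, fnr <= 1, fpr_per_mb >= 0, breakpoint_jitter_sd >= 0)
  structure(list(name = name, fnr = fnr, fpr_per_mb = fpr_per_mb,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 indel_repr_shift = indel_repr_shift),
            class = "caller_profile")
}

#' Simulate one caller's output from a truth set
#'
#' Drops each truth variant independently at the profile's false-negative
#' rate, adds Poisson false positives, jitters SV breakpoints, and
#' optionally emits right-aligned indel representations (which normalize
#' back to the truth keys). FP structural variants can be restricted to
#' lie inside provided NSVR intervals for FDR-calibration experiments.
#'
#' @param truth A `truth_set`.
#' @param profile A [caller_profile()].
#' @param seed Integer seed.
#' @param fp_regions Optional interval data.frame confining FP SVs.
#' @return list(small=, svs=).
#' @export
simulate_callset <- function(truth, profile, seed = 1L, fp_regions = NULL) {
  set.seed(seed)
  chrom <- truth$genome$chrom
  L <- nchar(truth$genome$seq)
  mb <- L / 1e6

  small <- truth$small
  keep <- stats::runif(nrow(small)) >= profile$fnr
  small <- small[keep, , drop = FALSE]
  if (profile$indel_repr_shift && nrow(small) > 0L) {
    ind <- which(nchar(small$ref) != nchar(small$alt))
    for (i in ind) {
      rv <- right_shift_one(chrom, small$pos[i], small$ref[i], small$alt[i],
                            truth$reference)
      small$pos[i] <- rv$pos; small$ref[i] <- rv$ref; small$alt[i] <- rv$alt
    }
  }
  n_fp <- stats::rpois(1L, profile$fpr_per_mb * mb)
  if (n_fp > 0L) {
    fp_pos <- sample.int(L - 2L, n_fp)
    fp <- do.call(rbind, lapply(fp_pos, function(p) {
      b <- substr(truth$genome$seq, p + 1L, p + 1L)
      small_variants(chrom, p, b,
                     sample(setdiff(c("A", "C", "G", "T"), b), 1L), "0/1")
    }))
    small <- rbind(small, fp)
  }
  small <- small[order(small$pos), , drop = FALSE]
  rownames(small) <- NULL

  svs <- truth$svs
  keep <- stats::runif(nrow(svs)) >= profile$fnr
  svs <- svs[keep, , drop = FALSE]
  if (profile$breakpoint_jitter_sd > 0 && nrow(svs) > 0L) {
    for (i in seq_len(nrow(svs))) {
      j1 <- as.integer(round(stats::rnorm(1, 0,
                                          profile$breakpoint_jitter_sd)))
      if (svs$svtype[i] == "DEL") {
        j2 <- as.integer(round(stats::rnorm(1, 0,
                                            profile$breakpoint_jitter_sd)))
        ns <- max(0L, svs$start[i] + j1)
        ne <- max(ns + 1L, svs$end[i] + j2)
        svs$start[i] <- ns; svs$end[i] <- ne
        svs$size[i] <- ne - ns
      } else {
        svs$start[i] <- max(0L, svs$start[i] + j1)
        svs$end[i] <- svs$start[i]
      }
    }
  }
  n_fp_sv <- stats::rpois(1L, profile$fpr_per_mb * mb)
  if (n_fp_sv > 0L) {
    fp <- list()
    for (i in seq_len(n_fp_sv)) {
      size <- rsv_size(1L, cap = 2000L)
      if (!is.null(fp_regions) && nrow(fp_regions) > 0L) {
        wide <- fp_regions[fp_regions$end - fp_regions$start >= size + 2L, ,
                           drop = FALSE]
        if (nrow(wide) == 0L) next
        r <- wide[sample.int(nrow(wide), 1L), ]
        s <- r$start + sample.int(r$end - r$start - size, 1L) - 1L
      } else {
        s <- sample.int(L - size - 1L, 1L)
      }
      fp[[length(fp) + 1L]] <-
        sv_records(chrom, s, s + size, "DEL", size,
                   sources = profile$name)
    }
    if (length(fp) > 0L) svs <- rbind(svs, do.call(rbind, fp))
  }
  if (nrow(svs) > 0L) svs$sources <- profile$name
  svs <- sort_svs(svs)
  rownames(svs) <- NULL
  list(small = small, svs = svs)
}
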