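test_that("genome simulation is deterministic and hits the GC target", {
  g1 <- simulate_genome(100000L, gc = 0.41, seed = 7L)
  g2 <- simulate_genome(100000L, gc = 0.41, seed = 7L)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$repeats, g2$repeats)
  obs_gc <- mean(strsplit(g1$seq, "")[[1]] %in% c("G", "C"))
  expect_gte(obs_gc, 0.39)
  expect_lte(obs_gc, 0.43)
  expect_error(simulate_genome(1000L), "10 kb")
  expect_error(simulate_genome(50000L, gc = 1.2), "gc")
  # repeat cassettes are recorded with classes
  expect_true(all(g1$repeats$class %in% c("SINE_like", "Simple_repeat")))
  expect_gt(nrow(g1$repeats), 0L)
})

test_that("implanting conserves donor length and respects spacing", {
  g <- simulate_genome(100000L, seed = 9L)
  tr <- implant_variants(g, n_snv = 0L, n_indel = 0L, n_sv_del = 1L,
                         n_sv_ins = 0L, sv_min_size = 1000L,
                         sv_max_size = 1000L, seed = 10L)
  expect_equal(nrow(tr$svs), 1L)
  expect_equal(tr$svs$size, 1000L)
  # homozygous deletion shortens both haplotypes by its size
  if (tr$sv_gt[1] == "1/1") {
    expect_equal(nchar(tr$donor[[1]]), 100000L - 1000L)
    expect_equal(nchar(tr$donor[[2]]), 100000L - 1000L)
  } else {
    h <- tr$sv_hap[1]
    expect_equal(nchar(tr$donor[[h]]), 100000L - 1000L)
    expect_equal(nchar(tr$donor[[3 - h]]), 100000L)
  }
  # general length bookkeeping per haplotype
  tr2 <- implant_variants(g, n_snv = 50L, n_indel = 30L, n_sv_del = 10L,
                          n_sv_ins = 10L, seed = 11L)
  for (h in 1:2) {
    on_h <- tr2$sv_hap %in% c(0L, h)
    sh <- tr2$small_hap %in% c(0L, h)
    delta <- sum(with(tr2$svs[on_h, ],
                      ifelse(svtype == "INS", size, -size))) +
      sum(nchar(tr2$small$alt[sh]) - nchar(tr2$small$ref[sh]))
    expect_equal(nchar(tr2$donor[[h]]), 100000L + delta)
  }
  # events are spaced: no two closer than 200 bp
  bks <- sort(c(tr2$small$pos, tr2$svs$start, tr2$svs$end))
  expect_true(all(diff(sort(c(tr2$small$pos, tr2$svs$start))) >= 100L))
  # infeasible specs fail loudly
  g_small <- simulate_genome(20000L, seed = 12L)
  expect_error(implant_variants(g_small, n_sv_del = 500L, seed = 1L),
               "infeasible")
})

test_that("truth sets round-trip through their VCF serialization", {
  g <- simulate_genome(50000L, seed = 13L)
  tr <- implant_variants(g, n_snv = 30L, n_indel = 20L, n_sv_del = 8L,
                         n_sv_ins = 6L, seed = 14L)
  tmp <- tempfile(fileext = ".vcf")
  write_sv_vcf(tr$svs, tmp, tr$reference, timestamp = FALSE)
  back <- read_vcf(tmp, "SV")
  expect_equal(back[c("chrom", "start", "end", "svtype", "size")],
               tr$svs[c("chrom", "start", "end", "svtype", "size")])
  tmp2 <- tempfile(fileext = ".vcf")
  write_small_vcf(tr$small, tmp2, tr$reference, timestamp = FALSE)
  back2 <- read_vcf(tmp2, "SMALL")
  expect_equal(back2[c("chrom", "pos", "ref", "alt")],
               tr$small[c("chrom", "pos", "ref", "alt")])
})

test_that("reads from a variant-free donor are end-to-end with NM = 0", {
  g <- simulate_genome(30000L, seed = 15L)
  tr <- implant_variants(g, n_snv = 0L, n_indel = 0L, n_sv_del = 0L,
                         n_sv_ins = 0L, seed = 16L)
  reads <- simulate_reads(tr, long_profile(error_rate = 0), depth = 4,
                          seed = 17L)
  expect_gt(nrow(reads), 0L)
  expect_false(any(cigar_has_clip(reads$cigar)))
  expect_true(all(reads$nm == 0L))
  # and the donor equals the reference
  expect_identical(tr$donor[[1]], g$seq)
})

test_that("reads crossing implanted SV breakpoints are disqualified for NSVR", {
  g <- simulate_genome(40000L, seed = 18L)
  tr <- implant_variants(g, n_snv = 10L, n_indel = 5L, n_sv_del = 4L,
                         n_sv_ins = 3L, seed = 19L)
  reads <- simulate_reads(tr, long_profile(error_rate = 0), depth = 10,
                          seed = 20L)
  status <- qualify_read(reads, nsvr_params())
  # find reads whose span straddles an implanted homozygous DEL start
  del <- tr$svs[tr$svs$svtype == "DEL" & tr$sv_gt == "1/1", , drop = FALSE]
  if (nrow(del) > 0L) {
    spans <- cigar_ref_span(reads$cigar)
    crossing <- reads$start < del$start[1] & reads$start + spans > del$start[1]
    expect_true(all(status[crossing] != "QUALIFYING"))
  }
})

test_that("paired-read insert sizes track the configured fragment model", {
  g <- simulate_genome(50000L, seed = 21L)
  tr <- implant_variants(g, n_snv = 0L, n_indel = 0L, n_sv_del = 0L,
                         n_sv_ins = 0L, seed = 22L)
  prof <- paired_profile(read_len = 100L, frag_mean = 400L, frag_sd = 50L,
                         error_rate = 0)
  reads <- simulate_reads(tr, prof, depth = 10, seed = 23L)
  tl <- reads$insert_size[!reads$is_reverse & reads$is_paired]
  n <- length(tl)
  expect_gt(n, 100L)
  expect_lt(abs(mean(tl) - 400), 3 * 50 / sqrt(n))
})

test_that("a noise-free caller profile reproduces the truth exactly", {
  g <- simulate_genome(40000L, seed = 25L)
  tr <- implant_variants(g, n_snv = 30L, n_indel = 15L, n_sv_del = 6L,
                         n_sv_ins = 4L, seed = 26L)
  prof <- caller_profile("perfect", fnr = 0, fpr_per_mb = 0,
                         breakpoint_jitter_sd = 0)
  cs <- simulate_callset(tr, prof, seed = 27L)
  expect_equal(cs$small[c("chrom", "pos", "ref", "alt")],
               tr$small[c("chrom", "pos", "ref", "alt")])
  expect_equal(cs$svs[c("chrom", "start", "end", "svtype", "size")],
               tr$svs[c("chrom", "start", "end", "svtype", "size")])
})

test_that("false-negative rates drop the expected fraction of truth variants", {
  g <- simulate_genome(120000L, seed = 28L)
  tr <- implant_variants(g, n_snv = 200L, n_indel = 0L, n_sv_del = 0L,
                         n_sv_ins = 0L, seed = 29L)
  prof <- caller_profile("lossy", fnr = 0.2, fpr_per_mb = 0)
  cs <- simulate_callset(tr, prof, seed = 30L)
  # 3 sigma around 160 of 200 retained
  sigma <- sqrt(200 * 0.2 * 0.8)
  expect_lt(abs(nrow(cs$small) - 160), 3 * sigma)
})

test_that("representation-shifted callsets normalize back to truth keys", {
  g <- simulate_genome(60000L, seed = 31L)
  tr <- implant_variants(g, n_snv = 0L, n_indel = 40L, n_sv_del = 0L,
                         n_sv_ins = 0L, seed = 32L)
  prof <- caller_profile("shifty", fnr = 0, fpr_per_mb = 0,
                         indel_repr_shift = TRUE)
  cs <- simulate_callset(tr, prof, seed = 33L)
  # at least some records differ textually from the truth
  expect_gt(sum(cs$small$pos != tr$small$pos), 0L)
  renorm <- normalize_variants(cs$small, tr$reference)
  expect_equal(sort(paste(renorm$chrom, renorm$pos, renorm$ref, renorm$alt)),
               sort(paste(tr$small$chrom, tr$small$pos, tr$small$ref,
                          tr$small$alt)))
})

test_that("FP SVs can be confined to supplied regions for FDR calibration", {
  g <- simulate_genome(200000L, seed = 34L)
  tr <- implant_variants(g, n_snv = 10L, n_indel = 0L, n_sv_del = 5L,
                         n_sv_ins = 0L, seed = 35L)
  regions <- genomic_intervals("sim1", c(10000L, 120000L),
                               c(60000L, 180000L))
  prof <- caller_profile("fp_heavy", fnr = 0, fpr_per_mb = 40)
  cs <- simulate_callset(tr, prof, seed = 36L, fp_regions = regions)
  fp <- cs$svs[!cs$svs$id %in% tr$svs$id, , drop = FALSE]
  expect_gt(nrow(fp), 0L)
  expect_true(all(both_breakpoints_in_nsvr(fp, regions)))
})

test_that("SAM round trip preserves alignment records", {
  g <- simulate_genome(30000L, seed = 37L)
  tr <- implant_variants(g, n_snv = 10L, n_indel = 5L, n_sv_del = 2L,
                         n_sv_ins = 2L, seed = 38L)
  reads <- simulate_reads(tr, paired_profile(), depth = 4, seed = 39L)
  tmp <- tempfile(fileext = ".sam")
  write_sam(reads, tr$reference, tmp)
  back <- read_alignments(tmp)
  expect_equal(nrow(back), nrow(reads))
  # same multiset of (start, cigar, nm)
  key <- function(df) sort(paste(df$start, df$cigar, df$nm))
  expect_equal(key(back), key(reads))
  # pairing data survives: mate_pairs finds pairs from both versions
  expect_equal(nrow(mate_pairs(back)), nrow(mate_pairs(reads)))
})
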