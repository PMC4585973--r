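cfg2x3 <- consensus_config(platforms = c("sanger", "illumina"),
                           callers = c("gatk_hc", "freebayes", "samtools"))

test_that("the two consensus criteria classify origin patterns correctly", {
  # same caller on both platforms: cross-platform holds, cross-caller fails
  expect_equal(classify_variant(c("sanger", "illumina"),
                                c("freebayes", "freebayes"), cfg2x3),
               "COMPLETE_ONLY")
  # both platforms, two callers: gold
  expect_equal(classify_variant(c("sanger", "illumina"),
                                c("gatk_hc", "freebayes"), cfg2x3),
               "GOLD")
  # one platform, two callers: cross-caller only
  expect_equal(classify_variant(c("illumina", "illumina"),
                                c("gatk_hc", "freebayes"), cfg2x3),
               "COMPLETE_ONLY")
  # single origin satisfies neither criterion
  expect_equal(classify_variant("illumina", "gatk_hc", cfg2x3), "NONE")
})

test_that("classification is invariant to origin order and duplication", {
  p <- c("sanger", "illumina", "illumina")
  k <- c("gatk_hc", "freebayes", "gatk_hc")
  base <- classify_variant(p, k, cfg2x3)
  set.seed(1)
  for (i in 1:5) {
    o <- sample(length(p))
    expect_equal(classify_variant(p[o], k[o], cfg2x3), base)
  }
  expect_equal(classify_variant(c(p, p), c(k, k), cfg2x3), base)
})

test_that("classification matches direct rule evaluation on all 2^6 patterns", {
  origins <- expand.grid(platform = c("sanger", "illumina"),
                         caller = c("gatk_hc", "freebayes", "samtools"),
                         stringsAsFactors = FALSE)
  for (bits in 1:63) {
    on <- as.logical(bitwAnd(bits, 2^(0:5)))
    c1 <- all(c("sanger", "illumina") %in% origins$platform[on])
    c2 <- length(unique(origins$caller[on])) >= 2L
    want <- if (c1 && c2) "GOLD" else if (c1 || c2) "COMPLETE_ONLY" else "NONE"
    expect_equal(classify_variant(origins$platform[on], origins$caller[on],
                                  cfg2x3),
                 want, info = paste("pattern", bits))
  }
})

test_that("classification rejects empty and undeclared origins", {
  expect_error(classify_variant(character(0), character(0), cfg2x3),
               "non-empty")
  expect_error(classify_variant("pacbio", "gatk_hc", cfg2x3), "undeclared")
  expect_error(classify_variant("sanger", "deepvariant", cfg2x3),
               "undeclared")
})

test_that("evidence map unifies representations and rejects duplicate origins", {
  ref <- c(sim1 = "GGATTTTCAA")
  # the same one-base deletion in the T run, two representations
  left <- small_variants("sim1", 2L, "AT", "A")
  right <- small_variants("sim1", 6L, "TC", "C")
  callsets <- list(
    list(platform = "sanger", caller = "gatk_hc", variants = left),
    list(platform = "illumina", caller = "freebayes", variants = right))
  em <- build_evidence_map(callsets, ref, cfg2x3)
  expect_equal(length(em), 1L)
  expect_setequal(em[[1]], c("sanger|gatk_hc", "illumina|freebayes"))

  expect_error(build_evidence_map(c(callsets, callsets[1]), ref, cfg2x3),
               "duplicate")
  expect_equal(length(build_evidence_map(list(), ref, cfg2x3)), 0L)
})

test_that("gold/complete sets follow the classification and input order does not matter", {
  set.seed(5)
  refseq <- random_dna(500L)
  ref <- c(sim1 = refseq)
  mkv <- function(pos) {
    b <- substr(refseq, pos + 1L, pos + 1L)
    small_variants("sim1", pos, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  v1 <- mkv(10L); v2 <- mkv(50L); v3 <- mkv(100L); v4 <- mkv(200L)
  callsets <- list(
    list(platform = "sanger", caller = "freebayes",
         variants = rbind(v1, v2)),
    list(platform = "illumina", caller = "freebayes",
         variants = rbind(v1, v3)),
    list(platform = "sanger", caller = "gatk_hc", variants = v2),
    list(platform = "illumina", caller = "gatk_hc",
         variants = rbind(v2, v3, v4)))
  # v1: freebayes on both platforms -> COMPLETE_ONLY
  # v2: both platforms, two callers -> GOLD
  # v3: illumina only, two callers -> COMPLETE_ONLY
  # v4: single origin -> NONE
  em <- build_evidence_map(callsets, ref, cfg2x3)
  sets <- build_small_gold(em, cfg2x3)
  expect_equal(sets$gold$pos, 50L)
  expect_equal(sets$complete$pos, c(10L, 50L, 100L))
  # gold is a subset of complete
  expect_true(all(sets$gold$pos %in% sets$complete$pos))
  # permuting callsets changes nothing
  em2 <- build_evidence_map(callsets[c(3, 1, 4, 2)], ref, cfg2x3)
  sets2 <- build_small_gold(em2, cfg2x3)
  expect_equal(sets2, sets)
  # adding an origin never demotes a variant out of gold/complete
  more <- c(callsets, list(list(platform = "illumina", caller = "samtools",
                                variants = rbind(v1, v4))))
  sets3 <- build_small_gold(build_evidence_map(more, ref, cfg2x3), cfg2x3)
  expect_true(all(sets$gold$pos %in% sets3$gold$pos))
  expect_true(all(sets$complete$pos %in% sets3$complete$pos))
})

test_that("consensus reference regions apply both criteria per base", {
  rs <- list(
    list(platform = "illumina", caller = "samtools",
         regions = genomic_intervals("sim1", 0L, 100L)),
    list(platform = "sanger", caller = "gatk_hc",
         regions = genomic_intervals("sim1", 50L, 150L)))
  out <- consensus_reference_regions(rs, cfg2x3)
  expect_equal(out, genomic_intervals("sim1", 50L, 100L),
               ignore_attr = TRUE)
  # same caller on both platforms: cross-caller criterion fails everywhere
  rs2 <- list(
    list(platform = "illumina", caller = "samtools",
         regions = genomic_intervals("sim1", 0L, 100L)),
    list(platform = "sanger", caller = "samtools",
         regions = genomic_intervals("sim1", 50L, 150L)))
  expect_equal(nrow(consensus_reference_regions(rs2, cfg2x3)), 0L)
  expect_equal(nrow(consensus_reference_regions(list(), cfg2x3)), 0L)
})

test_that("consensus reference regions agree with a per-base oracle", {
  set.seed(17)
  L <- 3000L
  origins <- expand.grid(platform = c("sanger", "illumina"),
                         caller = c("gatk_hc", "samtools"),
                         stringsAsFactors = FALSE)
  for (trial in 1:10) {
    rs <- lapply(seq_len(nrow(origins)), function(i) {
      n <- sample(1:5, 1L)
      s <- sample(0:(L - 200L), n)
      list(platform = origins$platform[i], caller = origins$caller[i],
           regions = genomic_intervals("sim1", s,
                                       s + sample(50:200, n, replace = TRUE)))
    })
    cfg <- consensus_config(platforms = c("sanger", "illumina"),
                            callers = c("gatk_hc", "samtools"))
    got <- consensus_reference_regions(rs, cfg)
    masks <- lapply(rs, function(r) mask_from_intervals(r$regions, L))
    want_mask <- vapply(seq_len(L), function(b) {
      on <- vapply(masks, `[`, logical(1), b)
      all(c("sanger", "illumina") %in% origins$platform[on]) &&
        length(unique(origins$caller[on])) >= 2L
    }, logical(1))
    expect_equal(got, intervals_from_mask(want_mask), ignore_attr = TRUE)
  }
})

test_that("no gold variant lies inside reference regions built from consistent inputs", {
  set.seed(23)
  refseq <- random_dna(2000L)
  ref <- c(sim1 = refseq)
  pos <- c(100L, 500L, 900L)
  vars <- do.call(rbind, lapply(pos, function(p) {
    b <- substr(refseq, p + 1L, p + 1L)
    small_variants("sim1", p, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }))
  # every origin calls all variants and calls reference elsewhere
  origins <- list(c("sanger", "gatk_hc"), c("illumina", "samtools"))
  callsets <- lapply(origins, function(o) {
    list(platform = o[1], caller = o[2], variants = vars)
  })
  refcalls <- lapply(origins, function(o) {
    iv <- subtract_intervals(genomic_intervals("sim1", 0L, 2000L),
                             genomic_intervals("sim1", pos, pos + 1L))
    list(platform = o[1], caller = o[2], regions = iv)
  })
  cfg <- consensus_config(platforms = c("sanger", "illumina"),
                          callers = c("gatk_hc", "samtools"))
  gold <- build_small_gold(build_evidence_map(callsets, ref, cfg), cfg)$gold
  rr <- consensus_reference_regions(refcalls, cfg)
  expect_equal(nrow(gold), 3L)
  expect_false(any(points_in_intervals(gold$chrom, gold$pos, rr)))
})
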