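test_that("junction sequences are assembled from the correct flanks", {
  set.seed(41)
  refseq <- random_dna(10000L)
  ref <- c(sim1 = refseq)
  del <- sv_records("sim1", 1000L, 2000L, "DEL")
  j <- build_junction(del, ref, flank = 500L)
  expect_equal(j$seq, paste0(substr(refseq, 501L, 1000L),
                             substr(refseq, 2001L, 2500L)))
  expect_equal(j$offsets, 500L)
  expect_equal(j$left_truncated, 0L)

  # flank truncated at the contig edge
  del2 <- sv_records("sim1", 100L, 200L, "DEL")
  j2 <- build_junction(del2, ref, flank = 500L)
  expect_equal(j2$left_truncated, 400L)
  expect_equal(j2$offsets, 100L)
  expect_equal(nchar(j2$seq), 100L + 500L)

  # insertion junction embraces the insert, two offsets
  ins <- sv_records("sim1", 1000L, 1000L, "INS", 80L,
                    strrep("ACGT", 20L))
  j3 <- build_junction(ins, ref, flank = 500L)
  expect_equal(nchar(j3$seq), 1080L)
  expect_equal(j3$offsets, c(500L, 580L))

  # INS without sequence: junction validation inapplicable, not failed
  ins2 <- sv_records("sim1", 1000L, 1000L, "INS", 80L)
  expect_null(build_junction(ins2, ref))
  expect_true(is.na(junction_support(NULL, character(0))$validated))
})

test_that("junction support requires overhang on both sides within the mismatch budget", {
  set.seed(43)
  refseq <- random_dna(10000L)
  ref <- c(sim1 = refseq)
  del <- sv_records("sim1", 1000L, 2000L, "DEL")
  j <- build_junction(del, ref, flank = 500L)
  cfg <- validation_config(min_overhang = 20L, min_junction_reads = 2L)
  # read covering [460, 560): overhangs 40 and 60 -> supports
  good <- substr(j$seq, 461L, 560L)
  # read covering [490, 515): left overhang 10 < 20 -> no support
  short <- substr(j$seq, 491L, 515L)
  expect_equal(junction_support(j, c(a = good, b = good), cfg)$count, 2L)
  expect_true(junction_support(j, c(a = good, b = good), cfg)$validated)
  expect_equal(junction_support(j, c(a = short), cfg)$count, 0L)
  # below the read-count threshold the flag stays unset
  one <- junction_support(j, c(a = good), cfg)
  expect_equal(one$count, 1L)
  expect_false(one$validated)
  # no reads at all
  expect_equal(junction_support(j, character(0), cfg)$count, 0L)
  # duplicate read names count once
  expect_equal(junction_support(j, c(a = good, a = good), cfg)$count, 1L)
  # too many mismatches: reject
  bad <- chartr("ACGT", "TGCA", good)
  expect_equal(junction_support(j, c(x = bad), cfg)$count, 0L)
  # reverse-complement placement is found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(good)))
  expect_equal(junction_support(j, c(r = rc), cfg)$count, 1L)
})

test_that("reference-allele reads do not support a deletion junction", {
  set.seed(47)
  refseq <- random_dna(10000L)
  ref <- c(sim1 = refseq)
  del <- sv_records("sim1", 1000L, 2000L, "DEL")
  j <- build_junction(del, ref, 500L)
  # a read straddling the left breakpoint on the reference allele
  refread <- substr(refseq, 951L, 1050L)
  expect_equal(junction_support(j, c(r = refread))$count, 0L)
})

test_that("discordant pairs support deletions by the insert-size arithmetic", {
  model <- insert_size_model(400, 50, k = 3)
  del <- sv_records("sim1", 5000L, 6000L, "DEL")
  cfg <- validation_config(min_discordant_pairs = 2L)
  # apparent insert 6300-4900=1400 > 550 and 1400-1000=400 inside [250,550]
  p1 <- data.frame(chrom = "sim1", left_end = 4900L, right_start = 6300L)
  expect_equal(discordant_pair_support(del, p1, model, cfg)$count, 1L)
  # concordant pair: apparent insert 420
  p2 <- data.frame(chrom = "sim1", left_end = 4900L, right_start = 5320L)
  expect_equal(discordant_pair_support(del, p2, model, cfg)$count, 0L)
  # one supporting pair is below min_discordant_pairs = 2
  expect_false(discordant_pair_support(del, p1, model, cfg)$validated)
  expect_true(discordant_pair_support(del, rbind(p1, p1), model,
                                      cfg)$validated)
  # pair must bracket the deletion
  p3 <- data.frame(chrom = "sim1", left_end = 5200L, right_start = 6600L)
  expect_equal(discordant_pair_support(del, p3, model, cfg)$count, 0L)
  # pairs on other contigs are ignored
  p4 <- p1; p4$chrom <- "sim2"
  expect_equal(discordant_pair_support(del, p4, model, cfg)$count, 0L)
})

test_that("short-insert pairs support insertions", {
  model <- insert_size_model(400, 50, k = 3)
  ins <- sv_records("sim1", 5000L, 5000L, "INS", 300L)
  p <- data.frame(chrom = "sim1", left_end = 4950L, right_start = 5050L)
  expect_equal(discordant_pair_support(ins, p, model)$count, 1L)
  p2 <- data.frame(chrom = "sim1", left_end = 4950L, right_start = 5350L)
  expect_equal(discordant_pair_support(ins, p2, model)$count, 0L)
})

test_that("known-database validation honours type, overlap and sample exclusion", {
  cfg <- validation_config(db_reciprocal_min = 0.5,
                           db_exclude_samples = "donor_self")
  del <- sv_records("sim1", 1000L, 2000L, "DEL")
  db <- data.frame(chrom = "sim1", start = 1100L, end = 2100L,
                   type = "loss", sample = "NA12878",
                   stringsAsFactors = FALSE)
  expect_true(known_db_validate(del, db, cfg))
  # same interval but from the excluded individual
  db_h <- db; db_h$sample <- "donor_self"
  expect_false(known_db_validate(del, db_h, cfg))
  # wrong type never validates a deletion
  db_g <- db; db_g$type <- "gain"
  expect_false(known_db_validate(del, db_g, cfg))
  # low reciprocal overlap
  db_far <- data.frame(chrom = "sim1", start = 1900L, end = 2900L,
                       type = "loss", sample = "x")
  expect_false(known_db_validate(del, db_far, cfg))
  # empty database
  expect_false(known_db_validate(del, db[0, ], cfg))
  # insertion: anchor within tolerance and compatible size
  ins <- sv_records("sim1", 5000L, 5000L, "INS", 200L)
  db_i <- data.frame(chrom = "sim1", start = 4950L, end = 5150L,
                     type = "insertion", sample = "y")
  expect_true(known_db_validate(ins, db_i, cfg))
})

test_that("tiers count validation sources: >=2 Gold, 1 Pass, 0 Notval", {
  svs <- sv_records(rep("sim1", 3), c(100L, 300L, 500L),
                    c(200L, 400L, 600L), "DEL",
                    validations = c("JUNCTION,KNOWN_DB", "READPAIR", ""))
  out <- assign_tier(svs)
  expect_equal(out$tier, c("GOLD", "PASS", "NOTVAL"))
  # idempotent: tier is a pure function of the validation set
  expect_equal(assign_tier(out), out)
})

test_that("decoy deletions are rarely junction-validated on simulated reads", {
  g <- simulate_genome(60000L, seed = 51L)
  tr <- implant_variants(g, n_snv = 30L, n_indel = 10L, n_sv_del = 8L,
                         n_sv_ins = 0L, seed = 52L)
  reads <- simulate_reads(tr, paired_profile(), depth = 20, seed = 53L)
  cfg <- validation_config()
  support_rate <- function(svs) {
    vapply(seq_len(nrow(svs)), function(i) {
      j <- build_junction(svs[i, ], tr$reference, cfg$flank)
      rs <- reads_near(reads, svs$chrom[i], svs$start[i] - cfg$flank,
                       svs$end[i] + cfg$flank)
      isTRUE(junction_support(j, rs, cfg)$validated)
    }, logical(1))
  }
  # homozygous implanted deletions with breakpoint-crossing reads validate
  hom <- tr$svs$svtype == "DEL" & tr$sv_gt == "1/1"
  if (any(hom)) expect_true(all(support_rate(tr$svs[hom, , drop = FALSE])))
  # decoys: shuffled intervals never implanted
  set.seed(54)
  n_decoy <- 40L
  dstart <- sample(seq(2000L, 50000L, by = 997L), n_decoy, replace = TRUE) +
    sample(0:500, n_decoy, replace = TRUE)
  sizes <- sample(100:400, n_decoy, replace = TRUE)
  decoys <- sv_records("sim1", dstart, dstart + sizes, "DEL")
  # drop decoys that collide with a real implanted deletion
  coll <- vapply(seq_len(n_decoy), function(i) {
    any(decoys$start[i] < tr$svs$end + 200L &
          decoys$end[i] > tr$svs$start - 200L)
  }, logical(1))
  decoys <- decoys[!coll, , drop = FALSE]
  expect_lt(mean(support_rate(decoys)), 0.05)
})

test_that("validate_svs combines the three validators into tiers", {
  g <- simulate_genome(50000L, seed = 61L)
  tr <- implant_variants(g, n_snv = 20L, n_indel = 5L, n_sv_del = 5L,
                         n_sv_ins = 3L, seed = 62L)
  reads <- simulate_reads(tr, paired_profile(), depth = 25, seed = 63L)
  db <- data.frame(chrom = tr$svs$chrom, start = tr$svs$start,
                   end = ifelse(tr$svs$svtype == "DEL", tr$svs$end,
                                tr$svs$start + tr$svs$size),
                   type = ifelse(tr$svs$svtype == "DEL", "loss", "gain"),
                   sample = "pop", stringsAsFactors = FALSE)
  model <- insert_size_model(200, 50, k = 3)
  out <- validate_svs(tr$svs, tr$reference, reads, db, model)
  expect_true(all(out$tier %in% c("GOLD", "PASS", "NOTVAL")))
  # every homozygous deletion has at least the database source plus junction
  hom_del <- out$svtype == "DEL" & tr$sv_gt == "1/1"
  if (any(hom_del)) {
    expect_true(all(grepl("KNOWN_DB", out$validations[hom_del])))
    expect_true(all(out$tier[hom_del] == "GOLD"))
  }
  # re-validation is idempotent
  out2 <- validate_svs(out, tr$reference, reads, db, model)
  expect_equal(out2$validations, out$validations)
  expect_equal(out2$tier, out$tier)
})
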