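test_that("planted exact arrays are recovered with zero error", {
  bg <- random_genome(5000, 0.5, seed = 60)
  pl <- plant_tandem_array(bg, pos = 2000, copies = 6, variant_spec = list())
  arr <- detect_tandem_arrays(pl$seq)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$start, pl$truth$start)
  expect_equal(arr$end, pl$truth$end)
  expect_equal(arr$unit_len, 42L)
  expect_equal(arr$copies, 6)
  expect_equal(arr$consensus_unit, phage_repeat_unit())
  expect_equal(nrow(arr$variants[[1L]]), 0L)
})

test_that("per-copy variants are reported against the consensus", {
  bg <- random_genome(3000, 0.5, seed = 61)
  # default variant: AAA -> CAG on copy 2 (differs at codon positions 1 and 3)
  pl <- plant_tandem_array(bg, pos = 1000, copies = 4)
  arr <- detect_tandem_arrays(pl$seq)
  v <- arr$variants[[1L]]
  expect_equal(unique(v$copy_index), 2L)
  expect_equal(v$offset, c(12L, 14L))
  expect_equal(v$consensus_base, c("A", "A"))
  expect_equal(v$observed_base, c("C", "G"))

  # a full three-base codon swap shows three deviations
  pl3 <- plant_tandem_array(bg, pos = 1000, copies = 4,
                            variant_spec = list(list(copy = 2L, codon = 5L,
                                                     replacement = "CGG")))
  v3 <- detect_tandem_arrays(pl3$seq)$variants[[1L]]
  expect_equal(nrow(v3), 3L)
  expect_equal(v3$copy_index, rep(2L, 3))
})

test_that("random constructions across the parameter space are exact", {
  withr::with_seed(62, {
    for (i in 1:50) {
      p <- sample(10:100, 1)
      n <- sample(2:10, 1)
      unit <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                    collapse = "")
      bg <- random_genome(3000, 0.5, seed = 6000 + i)
      pos <- sample(500:2000, 1)
      pl <- plant_tandem_array(bg, pos = pos, unit_seq = unit, copies = n,
                               variant_spec = list())
      arr <- detect_tandem_arrays(pl$seq)
      expect_equal(nrow(arr), 1L, info = sprintf("i=%d p=%d n=%d", i, p, n))
      expect_equal(arr$start, pl$truth$start)
      expect_equal(arr$end, pl$truth$end)
      expect_equal(arr$unit_len, p)
      expect_equal(arr$copies, n)
    }
  })
})

test_that("detector agrees with the exhaustive brute-force oracle", {
  cases <- list()
  withr::with_seed(63, {
    for (i in 1:6) cases[[i]] <- unname(random_genome(2000, 0.5,
                                                      seed = 630 + i))
    for (i in 1:4) {
      p <- sample(c(12, 21, 42, 60), 1)
      n <- sample(2:5, 1)
      unit <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                    collapse = "")
      pl <- plant_tandem_array(random_genome(1800, 0.5, seed = 640 + i),
                               pos = 600, unit_seq = unit, copies = n,
                               variant_spec = list())
      cases[[6 + i]] <- unname(pl$seq)
    }
  })
  for (s in cases) {
    got <- detect_tandem_arrays(s)
    want <- oracle_exact_arrays(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$unit_len, want$unit_len)
      expect_equal(got$copies, want$copies)
    }
  }
})

test_that("random sequence stays silent at the default match threshold", {
  for (i in 1:5) {
    expect_equal(nrow(detect_tandem_arrays(random_genome(5000, 0.5,
                                                         seed = 65 + i))),
                 0L)
  }
})

test_that("copy-number genotyping is exact on constructed amplicons", {
  u <- phage_repeat_unit()
  lf <- unname(random_genome(30, 0.5, seed = 70, id = "lf"))
  rf <- unname(random_genome(30, 0.5, seed = 71, id = "rf"))
  amp <- setNames(paste0(lf, strrep(u, 6), rf), "a6")
  gt <- genotype_copy_number(amp, lf, rf, 42)
  expect_equal(gt$calls$copies, 6L)
  expect_equal(gt$calls$residual, 0L)
  expect_equal(gt$calls$status, "ok")

  # planted {4, 6, 8} mixture: histogram support recovered exactly
  copies <- withr::with_seed(72, sample(rep(c(4L, 6L, 8L), each = 10)))
  amps <- setNames(vapply(copies, function(n) paste0(lf, strrep(u, n), rf),
                          character(1)),
                   sprintf("plaque%02d", seq_along(copies)))
  gt2 <- genotype_copy_number(amps, lf, rf, 42)
  expect_equal(sort(as.integer(names(gt2$histogram))), c(4L, 6L, 8L))
  expect_equal(unname(as.integer(gt2$histogram)), c(10L, 10L, 10L))
  expect_true(all(gt2$calls$residual == 0L))
  # near-exact flank matching survives two mismatches
  amp_mm <- amp
  substr(amp_mm, 3, 3) <- if (substr(amp_mm, 3, 3) == "A") "C" else "A"
  expect_equal(genotype_copy_number(amp_mm, lf, rf, 42)$calls$status, "ok")
})

test_that("genotyping reports per-source errors for bad flanks", {
  u <- phage_repeat_unit()
  lf <- unname(random_genome(30, 0.5, seed = 73))
  rf <- unname(random_genome(30, 0.5, seed = 74))
  missing_rf <- setNames(paste0(lf, strrep(u, 4)), "norf")
  gt <- genotype_copy_number(missing_rf, lf, rf, 42)
  expect_equal(gt$calls$status, "error")
  expect_match(gt$calls$message, "right flank not found")
  expect_equal(length(gt$histogram), 0L)

  dup_lf <- setNames(paste0(lf, strrep(u, 4), lf, strrep(u, 2), rf), "dup")
  expect_match(genotype_copy_number(dup_lf, lf, rf, 42)$calls$message,
               "left flank not unique")
  expect_error(genotype_copy_number(missing_rf, substr(lf, 1, 10), rf, 42),
               ">= 20")
})

test_that("partial-mapping flag fires on repeat-length conflicts only", {
  bg <- random_genome(5000, 0.5, seed = 75)
  ref4 <- plant_tandem_array(bg, pos = 2000, copies = 4)
  hap8 <- plant_tandem_array(bg, pos = 2000, copies = 8)
  region <- data.frame(seq_id = "ref", start = ref4$truth$start,
                       end = ref4$truth$end)

  rd8 <- simulate_reads(hap8$seq, 300, err_rate = 0, seed = 76)
  al8 <- align_reads_exact(c(rd8$r1, rd8$r2), ref4$seq, ref_id = "ref")
  fl8 <- flag_partial_mappings(al8, region)
  expect_true(fl8$flagged)
  expect_gt(fl8$partial_fraction, 0.2)

  rd4 <- simulate_reads(ref4$seq, 300, err_rate = 0, seed = 77)
  al4 <- align_reads_exact(c(rd4$r1, rd4$r2), ref4$seq, ref_id = "ref")
  fl4 <- flag_partial_mappings(al4, region)
  expect_false(fl4$flagged)
  expect_equal(fl4$partial_fraction, 0)

  # zero-depth region: NA partial fraction, never flagged
  far <- data.frame(seq_id = "elsewhere", start = 1, end = 100)
  flz <- flag_partial_mappings(al4, far)
  expect_true(is.na(flz$partial_fraction))
  expect_false(flz$flagged)

  # invariance to record order and duplication
  fl_shuf <- flag_partial_mappings(al8[sample(nrow(al8)), ], region)
  fl_dup <- flag_partial_mappings(rbind(al8, al8), region)
  expect_equal(fl_shuf$partial_fraction, fl8$partial_fraction)
  expect_equal(fl_dup$partial_fraction, fl8$partial_fraction)

  expect_error(flag_partial_mappings(al4, region,
                                     ref_lengths = c(ref = 2000)),
               "outside reference")
})

test_that("SAM alignment records carry positions and clipping", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref\tLN:1000",
    paste("r1", 0, "ref", 101, 60, "150M", "*", 0, 0,
          strrep("A", 150), strrep("I", 150), sep = "\t"),
    paste("r2", 0, "ref", 201, 60, "20S130M", "*", 0, 0,
          strrep("A", 150), strrep("I", 150), sep = "\t"),
    paste("r3", 0, "ref", 301, 60, "130M20S", "*", 0, 0,
          strrep("A", 150), strrep("I", 150), sep = "\t")
  ), sam)
  al <- read_alignments(sam)
  expect_equal(al$read_id, c("r1", "r2", "r3"))
  expect_equal(al$start, c(101L, 201L, 301L))
  expect_equal(al$end, c(250L, 330L, 430L))
  expect_equal(al$clipped_left, c(0L, 20L, 0L))
  expect_equal(al$clipped_right, c(0L, 0L, 20L))
})
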