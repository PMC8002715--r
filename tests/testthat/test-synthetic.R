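test_that("random_genome is seed-deterministic with calibrated GC", {
  expect_identical(random_genome(45000, 0.544, seed = 1),
                   random_genome(45000, 0.544, seed = 1))
  expect_false(identical(unname(random_genome(1000, 0.5, seed = 1)),
                         unname(random_genome(1000, 0.5, seed = 2))))
  # binomial SE at 100 kb is ~0.0016; 3 SE < 0.005
  g <- random_genome(100000, 0.5, seed = 7)
  expect_lt(abs(gc_content(g) - 0.5), 0.005)
  expect_error(random_genome(1000, 0, seed = 1), "strictly between")
  expect_error(random_genome(1000, 1, seed = 1), "strictly between")
})

test_that("mutate_genome hits the requested substitution rate", {
  g <- unname(random_genome(50000, 0.5, seed = 1))
  expect_identical(unname(mutate_genome(g, 0, seed = 2)), g)
  m <- unname(mutate_genome(g, 0.05, seed = 3))
  frac <- mean(strsplit(g, "")[[1L]] != strsplit(m, "")[[1L]])
  expect_lt(abs(frac - 0.05), 0.003)
  expect_identical(mutate_genome(g, 0.05, seed = 3),
                   mutate_genome(g, 0.05, seed = 3))
  expect_error(mutate_genome(g, 1, seed = 1), "sub_rate")
})

test_that("plant_tandem_array builds the exact requested array", {
  bg <- random_genome(2000, 0.5, seed = 4)
  u <- phage_repeat_unit()
  pl <- plant_tandem_array(bg, pos = 500, copies = 6, variant_spec = list())
  expect_equal(substr(unname(pl$seq), 500, 500 + 6 * 42 - 1), strrep(u, 6))
  expect_equal(pl$truth$end - pl$truth$start + 1L, 6L * 42L)

  # default variant: copy 2 carries the AAA -> CAG codon exchange
  pl2 <- plant_tandem_array(bg, pos = 500, copies = 4)
  copy2 <- substr(unname(pl2$seq), 500 + 42, 500 + 2 * 42 - 1)
  expect_equal(substr(copy2, 13, 15), "CAG")
  expect_equal(substr(u, 13, 15), "AAA")
  expect_equal(sum(strsplit(copy2, "")[[1L]] != strsplit(u, "")[[1L]]), 2L)

  expect_error(plant_tandem_array(bg, pos = 500, copies = 1), ">= 2")
  expect_error(plant_tandem_array(bg, pos = 99999, copies = 4), "outside")
})

test_that("simulated error-free reads map back to their recorded positions", {
  g <- unname(random_genome(4000, 0.5, seed = 5))
  rd <- simulate_reads(g, 60, err_rate = 0, seed = 6)
  gref <- Biostrings::DNAString(g)
  for (i in seq_len(60)) {
    hits <- Biostrings::start(Biostrings::matchPattern(rd$r1[[i]], gref))
    expect_true(rd$truth$frag_start[i] %in% hits)
    hits2 <- Biostrings::end(Biostrings::matchPattern(
      reverse_complement(rd$r2[[i]]), gref))
    expect_true(rd$truth$frag_end[i] %in% hits2)
  }
  expect_identical(simulate_reads(g, 10, seed = 9)$r1,
                   simulate_reads(g, 10, seed = 9)$r1)
  expect_error(simulate_reads(substr(g, 1, 100), 5, seed = 1),
               "shorter than read length")
})

test_that("read count tracks requested depth and FASTQ round-trips", {
  g <- unname(random_genome(30000, 0.5, seed = 8))
  depth <- 20
  n_pairs <- round(depth * nchar(g) / (2 * 150))
  realized <- n_pairs * 2 * 150 / nchar(g)
  expect_lt(abs(realized - depth) / depth, 0.05)

  rd <- simulate_reads(g, 20, seed = 10)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$r1, fq)
  expect_equal(read_fastq(fq), rd$r1)
})

test_that("domain corpus generator plants recoverable specific sets", {
  expect_error(simulate_domain_corpus(4, 4, n_specific_per_class = 0,
                                      seed = 1), "unclassifiable")
  expect_error(simulate_domain_corpus(4, 4, leakage = 1, seed = 1),
               "leakage")
  cp1 <- simulate_domain_corpus(5, 5, seed = 11)
  cp2 <- simulate_domain_corpus(5, 5, seed = 11)
  expect_identical(cp1$hits, cp2$hits)

  m <- build_model(cp1$hits, cp1$labels)
  expect_setequal(m$temperate_specific, cp1$truth$temperate_specific)
  expect_setequal(m$virulent_specific, cp1$truth$virulent_specific)

  # leaked domains are disqualified, so recovered sets shrink to subsets
  cpl <- simulate_domain_corpus(8, 8, leakage = 0.3, seed = 12)
  ml <- build_model(cpl$hits, cpl$labels)
  expect_true(all(ml$temperate_specific %in% cpl$truth$temperate_specific))
  expect_true(all(ml$virulent_specific %in% cpl$truth$virulent_specific))
})

test_that("count tables carry planted fold changes with NB noise", {
  expect_error(simulate_count_table(10, fold_changes = rep(1, 10),
                                    dispersion = -1, seed = 1),
               "dispersion")
  expect_error(simulate_count_table(10, fold_changes = rep(1, 5), seed = 1),
               "length")
  ct <- simulate_count_table(300, fold_changes = rep(1, 300), seed = 13)
  expect_identical(ct$counts,
                   simulate_count_table(300, fold_changes = rep(1, 300),
                                        seed = 13)$counts)
  mu <- rowMeans(ct$counts[, 1:2])
  mi <- rowMeans(ct$counts[, 3:4])
  fc <- fold_changes(mi, mu)
  expect_lt(mean(fc$flag != "none"), 0.05)

  fcs <- c(4, rep(1, 99))
  ct2 <- simulate_count_table(100, fold_changes = fcs, dispersion = 0.01,
                              seed = 14)
  fc2 <- fold_changes(rowMeans(ct2$counts[, 3:4]),
                      rowMeans(ct2$counts[, 1:2]))
  expect_equal(fc2$flag[1], "up")
})
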