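mini_corpus <- function() {
  hits <- data.frame(
    genome_id = c("t1", "t1", "t2", "v1", "v1", "v2", "t1", "v2"),
    domain_id = c("DT", "DS", "DT", "DV", "DS", "DV", "DB", "DB"),
    evalue = 1e-6, bitscore = 100,
    stringsAsFactors = FALSE)
  labels <- c(t1 = "temperate", t2 = "temperate",
              v1 = "virulent", v2 = "virulent")
  list(hits = hits, labels = labels)
}

test_that("build_model applies the exclusivity definition", {
  cp <- mini_corpus()
  m <- build_model(cp$hits, cp$labels)
  expect_equal(m$temperate_specific, "DT")
  expect_equal(m$virulent_specific, "DV")
  # DS and DB occur in both classes -> in neither set
  expect_false(any(c("DS", "DB") %in%
                   c(m$temperate_specific, m$virulent_specific)))
  expect_length(intersect(m$temperate_specific, m$virulent_specific), 0L)
})

test_that("build_model enforces corpus contracts and the e-value cutoff", {
  cp <- mini_corpus()
  expect_error(build_model(cp$hits, cp$labels[c("t1", "t2")]),
               "unlabelled|both lifestyles")
  expect_error(build_model(cp$hits[cp$hits$genome_id %in% c("t1", "t2"), ],
                           cp$labels[c("t1", "t2")]), "both lifestyles")
  # an above-cutoff hit must not create specificity
  h2 <- rbind(cp$hits, data.frame(genome_id = "v1", domain_id = "DT",
                                  evalue = 0.01, bitscore = 50))
  m2 <- build_model(h2, cp$labels)
  expect_true("DT" %in% m2$temperate_specific)
  # at the default cutoff 0 opposite-class genomes are allowed
  h3 <- rbind(cp$hits, data.frame(genome_id = "v1", domain_id = "DT",
                                  evalue = 1e-8, bitscore = 50))
  expect_false("DT" %in% build_model(h3, cp$labels)$temperate_specific)
  expect_true("DT" %in% build_model(h3, cp$labels,
                                    max_other_class_genomes = 1)$temperate_specific)
})

test_that("classify counts hits against the specific sets", {
  cp <- mini_corpus()
  m <- build_model(cp$hits, cp$labels)
  h <- data.frame(genome_id = "new", domain_id = c("DT", "DT", "DS"),
                  evalue = 1e-9, bitscore = 60, stringsAsFactors = FALSE)
  p <- classify(h, m)
  expect_equal(p$temperate_count, 2L)
  expect_equal(p$virulent_count, 0L)
  expect_equal(p$label, "temperate")

  tie <- data.frame(genome_id = "new",
                    domain_id = c("DT", "DT", "DT", "DV", "DV", "DV"),
                    evalue = 1e-9, bitscore = 60, stringsAsFactors = FALSE)
  expect_equal(classify(tie, m)$label, "ambiguous")

  empty <- classify(cp$hits[0, ], m, genome_id = "lonely")
  expect_equal(empty$temperate_count, 0L)
  expect_equal(empty$label, "ambiguous")

  # invariance to hit order; distinct mode collapses duplicates
  shuf <- tie[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(classify(shuf, m), classify(tie, m))
  expect_equal(classify(tie, m, count_mode = "distinct")$temperate_count, 1L)
})

test_that("planted corpora classify perfectly and leakage degrades accuracy", {
  cp <- simulate_domain_corpus(10, 10, seed = 50)
  m <- build_model(cp$hits, cp$labels)
  p <- classify(cp$hits, m)
  expect_equal(nrow(p), 20L)
  expect_equal(p$label, unname(cp$labels[p$genome_id]))

  expect_equal(evaluate_loocv(cp$hits, cp$labels)$accuracy, 1.0)

  mean_acc <- function(lk) {
    mean(vapply(1:5, function(s) {
      c2 <- simulate_domain_corpus(8, 8, leakage = lk, seed = 500 + s)
      evaluate_loocv(c2$hits, c2$labels)$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.2, 0.4), mean_acc, numeric(1))
  expect_equal(accs[1], 1.0)
  expect_true(all(diff(accs) <= 0))
})

test_that("label permutation drops LOOCV accuracy to chance", {
  cp <- simulate_domain_corpus(20, 20, seed = 51)
  perm <- withr::with_seed(52, setNames(sample(cp$labels), names(cp$labels)))
  acc <- evaluate_loocv(cp$hits, perm)$accuracy
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("an adversarially cross-paired corpus scores zero", {
  hits <- data.frame(
    genome_id = c("t1", "t2", "v1", "v2"),
    domain_id = c("X", "Y", "X", "Y"),
    evalue = 1e-9, bitscore = 60, stringsAsFactors = FALSE)
  labels <- c(t1 = "temperate", t2 = "temperate",
              v1 = "virulent", v2 = "virulent")
  expect_equal(evaluate_loocv(hits, labels)$accuracy, 0)
})

test_that("single-genome classes are skipped with a warning", {
  hits <- data.frame(genome_id = c("t1", "t2", "v1"),
                     domain_id = c("A", "A", "B"),
                     evalue = 1e-9, bitscore = 60, stringsAsFactors = FALSE)
  labels <- c(t1 = "temperate", t2 = "temperate", v1 = "virulent")
  expect_warning(cv <- evaluate_loocv(hits, labels), "skipping v1")
  expect_equal(nrow(cv$predictions), 2L)
})

test_that("removing a domain from the model never flips a label", {
  cp <- simulate_domain_corpus(6, 6, seed = 53)
  m <- build_model(cp$hits, cp$labels)
  p0 <- classify(cp$hits, m)
  for (d in c(m$temperate_specific[1], m$virulent_specific[1])) {
    m2 <- m
    m2$temperate_specific <- setdiff(m2$temperate_specific, d)
    m2$virulent_specific <- setdiff(m2$virulent_specific, d)
    p2 <- classify(cp$hits, m2)
    flipped <- (p0$label == "temperate" & p2$label == "virulent") |
               (p0$label == "virulent" & p2$label == "temperate")
    expect_false(any(flipped))
  }
})

test_that("models and hit tables round-trip through JSON and TSV", {
  cp <- simulate_domain_corpus(4, 4, seed = 54)
  m <- build_model(cp$hits, cp$labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_lifestyle_model(m, f)
  m2 <- read_lifestyle_model(f)
  expect_equal(m2$temperate_specific, m$temperate_specific)
  expect_equal(m2$virulent_specific, m$virulent_specific)

  ft <- withr::local_tempfile(fileext = ".tsv")
  write.table(cp$hits, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_domain_hits(ft)$domain_id, cp$hits$domain_id)
})
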