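test_that("genome positions map into CDS coordinates strand-aware", {
  cds <- random_cds(100L, seed = 80)
  plus <- new_gene_model("gp", 101L, 400L, "+", cds)
  expect_equal(genome_to_cds_pos(plus, 101L)$cds_pos, 1L)
  expect_equal(genome_to_cds_pos(plus, 400L)$cds_pos, 300L)

  minus <- new_gene_model("gm", 101L, 400L, "-", cds)
  mp <- genome_to_cds_pos(minus, 400L)
  expect_equal(mp$cds_pos, 1L)
  expect_equal(mp$cds_ref_base, substr(cds, 1, 1))

  expect_error(genome_to_cds_pos(plus, 100L), "outside gene")

  # round trip on both strands over every position
  for (g in list(plus, minus)) {
    for (pos in c(1L, 2L, 150L, 299L, 300L)) {
      expect_equal(genome_to_cds_pos(g, cds_to_genome_pos(g, pos))$cds_pos,
                   pos)
    }
  }
})

test_that("codon arithmetic reproduces the published substitutions", {
  # Gly350Asp via G->A at CDS position 1049 (codon 350 = GGC)
  cds1 <- make_cds(360L, fixed = list(`350` = "GGC"), seed = 81)
  a1 <- annotate_substitution(cds1, 1049L, "G", "A")
  expect_equal(a1$codon_index, 350L)
  expect_equal(a1$codon_pos, 2L)
  expect_equal(a1$ref_codon, "GGC")
  expect_equal(a1$alt_codon, "GAC")
  expect_equal(a1$aa_ref, "G")
  expect_equal(a1$aa_alt, "D")
  expect_equal(a1$effect, "missense")
  expect_equal(aa_change_string(a1$aa_ref, a1$aa_alt, a1$codon_index),
               "Gly350Asp")

  # Tyr886Asp via T->G at CDS position 2656 (codon 886 = TAT)
  cds2 <- make_cds(900L, fixed = list(`886` = "TAT"), seed = 82)
  a2 <- annotate_substitution(cds2, 2656L, "T", "G")
  expect_equal(a2$codon_index, 886L)
  expect_equal(a2$ref_codon, "TAT")
  expect_equal(a2$alt_codon, "GAT")
  expect_equal(aa_change_string(a2$aa_ref, a2$aa_alt, a2$codon_index),
               "Tyr886Asp")
})

test_that("effect classes cover the codon-change taxonomy", {
  cds <- make_cds(10L, fixed = list(`5` = "GGG", `7` = "TAC"), seed = 83)
  expect_equal(annotate_substitution(cds, 15L, "G", "A")$effect,
               "synonymous")  # GGG -> GGA, both Gly
  expect_equal(annotate_substitution(cds, 21L, "C", "A")$effect,
               "nonsense")    # TAC -> TAA
  # stop-lost at the terminal TAA
  last <- nchar(cds)
  expect_equal(annotate_substitution(cds, last - 2L, "T", "C")$effect,
               "stop-lost")
  # start-lost at codon 1 (ATG -> ACG)
  expect_equal(annotate_substitution(cds, 2L, "T", "C")$effect,
               "start-lost")

  expect_error(annotate_substitution(cds, 15L, "C", "A"),
               "reference discordance")
  expect_error(annotate_substitution(cds, 15L, "G", "G"), "must differ")
})

test_that("single-codon shortcut agrees with full re-translation everywhere", {
  cds <- random_cds(120L, seed = 84)
  prot <- translate_cds(cds)
  for (pos in seq_len(nchar(cds))) {
    ref <- substr(cds, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ann <- annotate_substitution(cds, pos, ref, alt, init_met = FALSE)
      mut <- cds
      substr(mut, pos, pos) <- alt
      prot_mut <- translate_cds(mut)
      expect_equal(substr(prot_mut, ann$codon_index, ann$codon_index),
                   ann$aa_alt)
      if (ann$effect == "synonymous") {
        expect_identical(prot_mut, prot)
      } else {
        expect_equal(which(strsplit(prot, "")[[1L]] !=
                           strsplit(prot_mut, "")[[1L]]),
                     ann$codon_index)
      }
    }
  }
})

test_that("summarize_snps reproduces the genome/gene coordinate duality", {
  # a minus-strand gene: genome-strand C->T equals gene-level G1049A
  cds <- make_cds(360L, fixed = list(`350` = "GGC"), seed = 85)
  genome_seq <- paste0(strrep("T", 200), reverse_complement(cds),
                       strrep("T", 200))
  gene <- new_gene_model("accD2_like", 201L, 200L + nchar(cds), "-", cds,
                         seqid = "chr")
  gpos <- cds_to_genome_pos(gene, 1049L)
  expect_equal(substr(genome_seq, gpos, gpos), "C")  # complement of G

  calls <- data.frame(strain = c("resistant1", "resistant1"),
                      ref_id = "chr",
                      genome_pos = c(gpos, 50L),
                      ref_base = c("C", "T"), alt_base = c("T", "G"),
                      frequency = c(0.977, 1),
                      stringsAsFactors = FALSE)
  tab <- summarize_snps(calls, gene)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$gene[1], "accD2_like")
  expect_equal(tab$base_change[1], "C -> T")
  expect_equal(tab$aa_change[1], "Gly350Asp")
  expect_equal(tab$effect[1], "missense")
  expect_equal(tab$effect[2], "intergenic")

  expect_equal(nrow(summarize_snps(calls[0, ], gene)), 0L)

  twice <- rbind(gene, new_gene_model("overlap", 150L, 200L + nchar(cds),
                                      "+", paste0(strrep("A", 51),
                                                  reverse_complement(cds)),
                                      seqid = "chr"))
  expect_error(summarize_snps(calls, twice), "multiple gene models")
})

test_that("substitution calls read from minimal VCF and TSV", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr\t1049\t.\tG\tA\t.\tPASS\t.",
               "chr\t2656\t.\tT\tG\t.\tPASS\t."), vcf)
  calls <- read_substitutions(vcf)
  expect_equal(calls$genome_pos, c(1049L, 2656L))
  expect_equal(calls$ref_base, c("G", "T"))
  expect_equal(calls$alt_base, c("A", "G"))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr\t10\t.\tGG\tA\t.\tPASS\t."), bad)
  expect_error(read_substitutions(bad), "single-nucleotide")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_substitutions(tsv), calls)
})
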