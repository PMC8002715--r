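# phagekit

Comparative genomics and infection-analysis building blocks for small
bacteriophage studies, written for the kind of work a corynephage genome
project needs after sequencing: placing a new phage among known genomes,
predicting its lifestyle, resolving repeat-length heterogeneity in its
assembly, annotating resistance SNPs in the host, and post-processing
infection transcriptomes.

## What it computes

* **k-mer genome signatures + Jensen–Shannon divergence** — genomes are
  summarized as tetranucleotide frequency vectors (both strands by
  default); pairs are compared with

  `JSD(P, Q) = H(M) − [H(P) + H(Q)]/2`, `M = (P + Q)/2`

  in base 2, so distances live in [0, 1] with 0 iff the signatures are
  identical. Matrices and per-group distance summaries (min/quartiles/
  median) support "one focal phage vs. labelled families" comparisons.
* **Fragment-based ANI (ANIb-style)** — the query is cut into 1,020-nt
  fragments; each fragment's best seeded local alignment against the
  subject (match +2, mismatch −3, gap open −5, gap extend −2) contributes
  its percent identity when it passes the classical 30 % identity / 70 %
  fragment-coverage filters; ANI is the unweighted fragment mean.
  `ani_matrix()` adds average-linkage ordering of the identity matrix.
* **Domain-count lifestyle classification** — from a corpus of
  conserved-domain hits labelled temperate/virulent, domains exclusive to
  one class form that class's specific set; a genome is labelled by
  whichever set collects more of its hits (ties are `ambiguous`).
  Leave-one-out cross-validation is built in.
* **Minisatellite tandem arrays** — detection via the shifted self-match
  indicator `m_p(i) = 1[s[i] = s[i+p]]` with smallest-period preference
  and per-copy variant calls; flagging of assembly-ambiguous regions from
  clipped read fractions; copy-number genotyping of spanning amplicons
  from flank-to-flank distances.
* **SNP effect annotation** — strand-aware genome→CDS coordinate mapping
  and codon arithmetic (`codon_index = ceil(cds_pos/3)`) under genetic
  code 11, classifying synonymous/missense/nonsense/stop-lost/start-lost;
  mismatching reference bases raise a reference-discordance error rather
  than annotating a wrong model.
* **Transcriptome arithmetic** — TPM, read-origin fractions
  (host / prophage / phage), inter-replicate means and relative
  differences (range/mean × 100 %), 2-fold flagging of fold changes, and
  Pearson correlation of log2(TPM + 1).
* **Synthetic data with planted truth** — seeded generators for genomes,
  divergent families, tandem arrays, paired-end reads, lifestyle-labelled
  domain corpora and two-condition count tables; every generator is a
  pure function of (parameters, seed).

## Worked example

```r
library(phagekit)

genome <- random_genome(45000, gc = 0.544, seed = 42, id = "phiSim")
genome_stats(genome)
#>       id length        gc n_orfs
#> 1 phiSim  45000 0.5442444    742

rel <- c(near  = unname(mutate_genome(genome, 0.02, seed = 43)),
         far   = unname(mutate_genome(genome, 0.20, seed = 44)),
         other = unname(random_genome(45000, 0.544, seed = 45)))
distance_matrix(kmer_profiles(c(phiSim = unname(genome), rel)))
#> DistanceMatrix (jsd) over 4 genomes
#>        phiSim  near    far  other
#> phiSim 0.0000 1e-04 0.0011 0.0009
#> near   0.0001 0e+00 0.0010 0.0009
#> far    0.0011 1e-03 0.0000 0.0016
#> other  0.0009 9e-04 0.0016 0.0000

ann <- annotate_substitution(paste0(strrep("GGC", 350), strrep("GCT", 10)),
                             1049, "G", "A")
aa_change_string(ann$aa_ref, ann$aa_alt, ann$codon_index)
#> [1] "Gly350Asp"

pl <- plant_tandem_array(random_genome(5000, 0.544, seed = 46),
                         pos = 2000, copies = 6)
detect_tandem_arrays(pl$seq)[, c("start", "end", "unit_len", "copies")]
#>   start  end unit_len copies
#> 1  2000 2251       42      6
```

The signature distances read as: a 2 %-diverged copy sits an order of
magnitude closer to the focal genome (1e-4) than a 20 %-diverged copy or
an unrelated genome of the same GC (~1e-3), which is exactly the
separation the boxplot-style `group_summary()` quantifies. The annotated
substitution reproduces the classic gene-level notation (G1049A →
Gly350Asp), and the repeat detector recovers the planted 6 × 42-nt array
with its exact boundaries.

A command-line front end wrapping the same functions lives at
`inst/exec/phagekit` (`phagekit {stats,jsd,ani,lifestyle,repeats,variant,
rnaseq,simulate,demo}`), and `run_pipeline(demo_config(dir, seed))`
executes an end-to-end synthetic demonstration whose outputs are
byte-identical across reruns.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the codon indices
reported by the substitution annotator for CDS positions 1049, 1022 and
2656 on their published codons (targets `t1`–`t3`) and the residue span
of a 42-nt repeat unit (`t4`), and writes them as a JSON object.
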