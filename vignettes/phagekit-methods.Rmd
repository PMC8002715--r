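---
title: "phagekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phagekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagekit)
```

phagekit re-implements, as reusable tested functions, the desk
computations of a small phage genomics study: genome-signature distances,
fragment-based average nucleotide identity, a domain-count lifestyle
classifier, minisatellite detection and genotyping, SNP effect
annotation, and post-mapping transcriptome arithmetic. This vignette
records the models, the tunable parameters, and the places where a design
decision was genuinely open — and why it was settled the way it was.

## Genome signatures and Jensen–Shannon divergence

A genome is summarized by its k-mer frequency vector over all overlapping
windows. Two conventions matter:

* **k = 4** (default). Tetranucleotide signatures are the standard
  compromise between resolution and sampling noise at the 10–100 kb scale
  of phage genomes; the choice is exposed (`k`, 1–8) because nothing in
  the method depends on it structurally.
* **Both-strand counting** (default). Adding reverse-complement windows
  makes the signature invariant to which strand a genome was deposited
  on, which is an arbitrary database convention. Single-strand mode is
  available for strand-asymmetry questions.

Windows containing N are skipped entirely (they are not informative and a
partial count would bias composition).

The divergence is

$$\mathrm{JSD}(P,Q) = H(M) - \tfrac12\,[H(P)+H(Q)],\qquad M=\tfrac12(P+Q),$$

with entropies in base 2, so values live in $[0,1]$, are symmetric, zero
iff $P=Q$, and finite in the presence of zeros ($0\log 0 := 0$) — hence
**no pseudocounts**. Raw JSD is reported (not its square root) because
that is what a divergence-based distance matrix means; `metric =
"sqrt-jsd"` yields the metric form, whose triangle inequality the test
suite verifies on random probability vectors.

`group_summary()` condenses the focal row of a distance matrix into
per-group five-number summaries sorted by median — the numerical content
of a "focal phage vs. labelled genome families" boxplot.

## Fragment-based ANI

The ANIb recipe is preserved exactly where it is load-bearing: 1,020-nt
consecutive fragments, a best local alignment per fragment, and the
30 % identity / 70 % fragment-coverage filters, with ANI the unweighted
mean identity of passing fragments and coverage the fraction of fragments
used. Terminal short fragments participate, with coverage judged against
their own length.

What is *not* reproduced bit-for-bit is the external BLASTn call inside
the classical implementation. The aligner here seeds on exact 15-mers
(sampled every 32 nt along the fragment, both subject strands), anchors
the best-supported diagonal, and runs a local alignment inside a
windowed band with BLASTn-like scores (match +2, mismatch −3, gap open
−5, gap extend −2). Identity is matches over alignment columns. On
synthetic families this recovers ANI ≈ 100(1 − substitution rate) within
1.5 points for rates up to 10 %, which is the property-level equivalence
the package claims; exact agreement with any particular BLAST version is
not claimed.

For matrix ordering, the two directed ANI values are averaged (ANIb is
only near-symmetric), undefined pairs are treated as 0 % identity so
unrelated genomes sort to maximal distance, and average-linkage
clustering on `100 − ANI` fixes the leaf order; ids are sorted before
clustering so ties break deterministically.

## Lifestyle classification from domain counts

The classifier consumes tabular conserved-domain hits (e.g. RPS-TBLASTN
vs. CDD, run upstream) for a corpus labelled temperate/virulent. After
filtering at e-value ≤ 0.001, a domain is **class-specific** when it
occurs in ≥ 1 genome of that class and 0 genomes of the other
(`max_other_class_genomes` relaxes the 0). A new genome is labelled by
whichever specific set collects more of its hits; `count_mode` chooses
between counting hit occurrences (default — the natural reading of
"total mapped domain counts") and distinct domains.

Two deliberate choices:

* **Ties are `ambiguous`, never a coin flip** — predictions must be
  deterministic. Consequently, leave-one-out accuracy scores an ambiguous
  prediction as 1/2, the expected accuracy of resolving the tie at
  random. This keeps the two calibration points coherent: a leakage-free
  planted corpus scores 1.0, and a label-permuted corpus — where no
  domain is exclusive to either class and every prediction collapses to
  a 0/0 tie — scores ≈ 0.5 rather than 0.
* **Exclusivity, not enrichment.** With no frequency threshold stated by
  the method, absolute exclusivity is the only parameter-free reading;
  the relaxation knob exists because real corpora of thousands of
  genomes will contain annotation noise.

## Minisatellite detection, ambiguity flags, genotyping

### Detection

For each candidate period $p$ (default 10–100 nt, ascending so the
smallest period explaining a locus wins), the detector computes the
shifted self-match indicator $m_p(i) = 1[s_i = s_{i+p}]$ and collects
dense runs: maximal exact runs, merged across gaps no longer than $p$
while the overall match fraction stays ≥ `min_match` (default 0.8) *and*
the neighbouring runs are at least as long as the gap they bridge (short
chance runs otherwise rotate the array frame). Candidates must span at
least `min_copies − 1` periods.

Three numerical guards make this behave on random sequence and at exact
planted arrays:

* **Significance for imperfect candidates.** At `min_match = 0.8` and
  small units, random sequence contains dense-enough windows at a rate of
  tens per 5 kb ($P(\text{match}) = 1/4$ under the null). Imperfect
  candidates therefore must pass a Bonferroni-corrected binomial test
  (`alpha = 0.001` familywise). Exact runs are exempt — their chance rate
  is $\sim 4^{-p}$ — and when a merged run fails the test its longest
  exact component is retried, so a perfect small array next to one chance
  match is not lost.
* **Fractional edge copies need ≥ 8 nt and an exact consensus match.**
  A flanking base continues the period with probability 1/4, so short
  overhangs are indistinguishable from chance; a genuine partial copy
  continues the consensus exactly.
* **Whole-copy frame scoring.** When a candidate's length is not a
  multiple of $p$, every frame shift within the remainder is scored by
  total disagreement with the column-majority consensus and the best
  frame wins; edge copies that still disagree with the consensus beyond
  `min_match` are trimmed.

The synthetic generator plants arrays with a **boundary guard**: the two
background bases flanking the array are adjusted not to continue the
period. Without the guard, one planted array in two would, by chance,
sit inside a genuinely larger periodic region whose boundary no detector
could place at the planted coordinate — the guard makes "exact recovery"
a well-posed claim. Consensus units are reported per column-majority,
and per-copy deviations from the consensus (0-based offsets within the
unit) give the variant calls.

### Ambiguity flags

`flag_partial_mappings()` computes, per region, the fraction of
overlapping alignments that are clipped (CIGAR soft/hard clips, or the
equivalent TSV columns), after de-duplicating identical records (paired
mates share a read id and are both kept). An aligner forced to stop
inside a region — reads from a longer repeat haplotype mapped onto a
shorter reference — surfaces as clipping; an unclipped alignment that
merely ends inside a region is ordinary and not counted, otherwise any
region wider than a read would flag itself on perfectly concordant data.
The default threshold 0.2 flags the planted 8-copy-reads-on-4-copy-
reference scenario robustly (observed fractions ≈ 0.4) while concordant
reads give 0.

### Genotyping

Copy number of a spanning sequence is the rounded inter-flank distance
divided by the unit length; flanks (≥ 20 nt) are located by near-exact
match (≤ 2 mismatches by default, so simulated read errors do not void a
source). Absent or non-unique flanks yield per-source error records,
excluded from the copy-number histogram. Residuals are reported; they are
0 for error-free constructions.

## Substitution effect annotation

All user-facing coordinates are 1-based inclusive, matching gene-level
`G1049A`-style notation. For minus-strand genes,
`cds_pos = genome_end − genome_pos + 1` and genome-strand bases are
complemented. Codon arithmetic is `codon_index = ⌈cds_pos/3⌉`,
`codon_pos = ((cds_pos−1) mod 3) + 1`; translation uses genetic code 11
with **explicit** initiator handling: a single codon is never treated as
an initiator implicitly (the underlying library's default would render
an interior GTG as Met), and GTG/TTG at codon 1 become Met only under
`init_met = TRUE`. Effects are classified synonymous / missense /
nonsense / stop-lost / start-lost; an exhaustive property test checks
every possible substitution of a random CDS against full re-translation.

A reference-base mismatch is an **error**, not a warning: it means the
gene model or strand is wrong, and silently annotating would produce
plausible-looking nonsense. This deliberately surfaces internally
inconsistent coordinate/base combinations in published SNP tables rather
than "fixing" them.

## Transcriptome arithmetic

TPM is computed per sample as $10^6 r_i / \sum_j r_j$ with
$r_i = c_i / L_i$; columns of non-degenerate samples sum to $10^6$ and
the unit is scale-invariant per sample. Origin fractions partition each
sample's counts by gene origin (host / prophage element / phage).

The inter-replicate "variance expressed as a percentage of the relative
difference" is ambiguous as stated; it is implemented as
**range/mean × 100**, which for two replicates $a,b$ is
$|a-b| / \frac{a+b}{2} \times 100$ (so (10, 20) → 66.67 %), undefined
(NA) at mean 0. Fold changes use a pseudocount (default 1 TPM unit, the
smallest value that guards zero means without dominating expressed
genes; exposed) and are flagged at |log2 FC| > 1. Sample correlations are
Pearson on log2(TPM + 1); constant samples get NA rows/columns.

The headline regulated-gene counts of a real infection experiment depend
on the actual libraries and are not reproduced by synthetic data; the
synthetic claims are structural (normalization, flag rates under the
null, replicate-vs-condition correlation contrast).

## Synthetic data: what it emulates, what it does not

Generators are pure functions of (parameters, seed) via an isolated RNG
scope; every dataset carries its planted truth. Defaults mirror the
stated world of the study they emulate: 45-kb genomes at 54.4 % GC,
2 × 150 bp read pairs, a 42-bp repeat unit at 4/6/8 copies whose second
copy carries an AAA→CAG codon exchange (the fixed 42-mer is a synthetic
stand-in — the real unit sequence is not public — with AAA at codon 5 so
the default variant applies; note AAA→CAG changes two of three codon
positions), temperate/virulent domain corpora, and two-replicate
count tables with log-normal baselines and NB (Poisson-gamma) noise.

Known simplifications, hence what a green test does *not* establish:
sequencing errors are substitutions only (no indels — this keeps repeat
genotyping truth exact); no quality-score model; domain corpora have
clean class structure (each shared domain occurs in ≥ 2 genomes per
class, each genome carries ≥ 1 own-class specific domain) rather than the
annotation noise of real phage databases; count noise is NB without
library-composition effects. Performance on real, messy inputs is a
weaker claim than the planted-recovery results.

## Determinism and the demo pipeline

`run_pipeline(demo_config(dir, seed))` regenerates every synthetic input
class and runs all stages in dependency order, writing TSV/JSON plus a
manifest of MD5 checksums; reruns with the same seed are byte-identical,
and a stage failure skips its dependents with a message instead of
cascading errors. The CLI (`inst/exec/phagekit`) is a thin dispatcher
over the same exported functions and exits non-zero on any error.

## Limitations

* The ORF finder is deliberately minimal (longest start-to-stop per
  stop-bounded segment, no RBS or coding statistics) and will not
  reproduce curated genome annotations; open-ended ORFs at contig edges
  are not reported.
* The ANI aligner's seeded banding assumes a dominant diagonal; genomes
  with large rearrangements inside a 1,020-nt fragment may under-align
  that fragment (it then simply fails the coverage filter).
* The repeat detector's fractional-copy rule suppresses genuine partial
  copies shorter than 8 nt by design.
* Lifestyle classification inherits all biases of the upstream domain
  search and the labelled corpus; no accuracy claim transfers beyond the
  synthetic corpus structure described above.
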