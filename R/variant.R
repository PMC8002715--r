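## Strand-aware annotation of single-nucleotide substitutions onto gene
## models.  All user-facing coordinates are 1-based inclusive, matching the
## gene-level "G1049A" style of notation; codon arithmetic is
## codon_index = ceiling(cds_pos / 3), codon_pos = ((cds_pos - 1) mod 3) + 1.

BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}

#' Map a genome position into CDS coordinates
#'
#' For a plus-strand gene `cds_pos = genome_pos - genome_start + 1`; for a
#' minus-strand gene `cds_pos = genome_end - genome_pos + 1` and the
#' reported CDS base is the complement of the genome-strand base.
#'
#' @param gene One gene model (single-row `data.frame` or list with
#'   `genome_start`, `genome_end`, `strand` and optionally `cds_seq`).
#' @param genome_pos 1-based genome position within the gene.
#' @return List with `cds_pos` and `cds_ref_base` (`NA` if the model
#'   carries no `cds_seq`).
#' @export
genome_to_cds_pos <- function(gene, genome_pos) {
  gs <- gene$genome_start
  ge <- gene$genome_end
  if (genome_pos < gs || genome_pos > ge)
    stop("position ", genome_pos, " outside gene [", gs, ", ", ge, "]")
  cds_pos <- if (gene$strand == "+") genome_pos - gs + 1L
             else ge - genome_pos + 1L
  base <- NA_character_
  if (!is.null(gene$cds_seq) && !is.na(gene$cds_seq))
    base <- substr(gene$cds_seq, cds_pos, cds_pos)
  list(cds_pos = as.integer(cds_pos), cds_ref_base = base)
}

#' Map a CDS position back to the genome
#'
#' Inverse of [genome_to_cds_pos()].
#'
#' @inheritParams genome_to_cds_pos
#' @param cds_pos 1-based CDS position.
#' @return 1-based genome position.
#' @export
cds_to_genome_pos <- function(gene, cds_pos) {
  len <- gene$genome_end - gene$genome_start + 1L
  if (cds_pos < 1L || cds_pos > len) stop("cds_pos outside gene")
  if (gene$strand == "+") gene$genome_start + cds_pos - 1L
  else gene$genome_end - cds_pos + 1L
}

#' Annotate the codon-level effect of a single-nucleotide substitution
#'
#' The reference base must match the CDS at `cds_pos` (coding strand); a
#' mismatch raises a reference-discordance error, which deliberately
#' surfaces inconsistent gene models or strand mix-ups rather than
#' annotating nonsense.
#'
#' @param cds_seq In-frame coding sequence (coding strand).
#' @param cds_pos 1-based position of the substitution within the CDS.
#' @param ref_base,alt_base Reference and alternate base on the coding
#'   strand (`ref_base != alt_base`).
#' @param init_met Render alternative start codons (GTG/TTG) at codon 1 as
#'   Met (bacterial convention).
#' @param gene_id Id recorded in the annotation.
#' @return `data.frame` with `gene_id`, `cds_pos`, `codon_index`,
#'   `codon_pos`, `ref_codon`, `alt_codon`, `aa_ref`, `aa_alt` and
#'   `effect` (`synonymous`, `missense`, `nonsense`, `stop-lost`,
#'   `start-lost`).
#' @export
annotate_substitution <- function(cds_seq, cds_pos, ref_base, alt_base,
                                  init_met = TRUE, gene_id = NA_character_) {
  s <- as_seq_char(cds_seq)
  if (!ref_base %in% BASES || !alt_base %in% BASES)
    stop("bases must be one of A/C/G/T")
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  if (cds_pos < 1L || cds_pos > nchar(s)) stop("cds_pos outside CDS")
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
  found <- substr(s, cds_pos, cds_pos)
  if (found != ref_base)
    stop("reference discordance at CDS position ", cds_pos, ": model has ",
         found, ", call claims ", ref_base,
         " (wrong gene model or strand?)")
  codon_index <- as.integer(ceiling(cds_pos / 3))
  codon_pos <- as.integer((cds_pos - 1L) %% 3L + 1L)
  a <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(s, a, a + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_base
  init <- init_met && codon_index == 1L
  aa_ref <- translate_cds(ref_codon, init_met = init)
  aa_alt <- translate_cds(alt_codon, init_met = init)
  effect <- if (codon_index == 1L && init_met &&
                ref_codon %in% c("ATG", "GTG", "TTG") &&
                !alt_codon %in% c("ATG", "GTG", "TTG")) "start-lost"
    else if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else if (aa_ref == "*") "stop-lost"
    else "missense"
  data.frame(gene_id = gene_id, cds_pos = as.integer(cds_pos),
             codon_index = codon_index, codon_pos = codon_pos,
             ref_codon = ref_codon, alt_codon = alt_codon,
             aa_ref = aa_ref, aa_alt = aa_alt, effect = effect,
             stringsAsFactors = FALSE)
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter", X = "Xaa")

#' Three-letter amino-acid change notation
#'
#' @param aa_ref,aa_alt One-letter amino acids.
#' @param codon_index 1-based codon index.
#' @return Strings like `"Gly350Asp"`.
#' @export
aa_change_string <- function(aa_ref, aa_alt, codon_index) {
  paste0(AA3[aa_ref], codon_index, AA3[aa_alt])
}

#' Tabulate SNP effects over gene models
#'
#' Maps each substitution call onto its containing gene model (strand-aware:
#' genome-strand ref/alt bases are complemented for minus-strand genes),
#' annotates the codon-level consequence and emits one row per call.
#' Intergenic calls are labelled as such.
#'
#' @param calls `data.frame` with `ref_id`, `genome_pos`, `ref_base`,
#'   `alt_base`, optionally `strain` and `frequency`.
#' @param genes Gene models (as from [read_gene_models()], with `cds_seq`).
#' @return `data.frame(strain, gene, base_change, aa_change, position,
#'   effect, frequency)`.
#' @export
summarize_snps <- function(calls, genes) {
  if (!nrow(calls)) {
    return(data.frame(strain = character(), gene = character(),
                      base_change = character(), aa_change = character(),
                      position = integer(), effect = character(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, , drop = FALSE]
    strain <- if ("strain" %in% names(cl)) cl$strain else NA_character_
    freq <- if ("frequency" %in% names(cl)) cl$frequency else NA_real_
    hit <- which(genes$seqid == cl$ref_id &
                 genes$genome_start <= cl$genome_pos &
                 genes$genome_end >= cl$genome_pos)
    if (length(hit) > 1L)
      stop("call at ", cl$genome_pos, " maps to multiple gene models")
    base_change <- paste0(cl$ref_base, " -> ", cl$alt_base)
    if (!length(hit)) {
      return(data.frame(strain = strain, gene = NA_character_,
                        base_change = base_change, aa_change = NA_character_,
                        position = cl$genome_pos, effect = "intergenic",
                        frequency = freq, stringsAsFactors = FALSE))
    }
    gene <- genes[hit, , drop = FALSE]
    mp <- genome_to_cds_pos(gene, cl$genome_pos)
    ref <- cl$ref_base
    alt <- cl$alt_base
    if (gene$strand == "-") {
      ref <- complement_base(ref)
      alt <- complement_base(alt)
    }
    ann <- annotate_substitution(gene$cds_seq, mp$cds_pos, ref, alt,
                                 gene_id = gene$id)
    data.frame(strain = strain, gene = gene$id, base_change = base_change,
               aa_change = aa_change_string(ann$aa_ref, ann$aa_alt,
                                            ann$codon_index),
               position = cl$genome_pos, effect = ann$effect,
               frequency = freq, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Read single-nucleotide substitution calls from a minimal VCF or TSV
#'
#' Only the CHROM/POS/REF/ALT columns are used; non-SNV records are
#' rejected.  TSV input expects a header with `ref_id`, `genome_pos`,
#' `ref_base`, `alt_base` (plus optional `strain`, `frequency`).
#'
#' @param path VCF (`.vcf`) or TSV path.
#' @return `data.frame(ref_id, genome_pos, ref_base, alt_base)`.
#' @export
read_substitutions <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(body)) {
      return(data.frame(ref_id = character(), genome_pos = integer(),
                        ref_base = character(), alt_base = character(),
                        stringsAsFactors = FALSE))
    }
    f <- strsplit(body, "\t", fixed = TRUE)
    df <- data.frame(
      ref_id = vapply(f, `[[`, character(1), 1L),
      genome_pos = as.integer(vapply(f, `[[`, character(1), 2L)),
      ref_base = toupper(vapply(f, `[[`, character(1), 4L)),
      alt_base = toupper(vapply(f, `[[`, character(1), 5L)),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  if (any(nchar(df$ref_base) != 1L | nchar(df$alt_base) != 1L))
    stop("only single-nucleotide substitutions are supported")
  if (any(!df$ref_base %in% BASES | !df$alt_base %in% BASES))
    stop("REF/ALT must be A/C/G/T")
  if (any(df$ref_base == df$alt_base)) stop("REF and ALT must differ")
  df
}
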