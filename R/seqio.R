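#' Read a multi-FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased on parse.  Characters outside the IUPAC
#' nucleotide alphabet are rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet]; names hold the record ids (first
#'   whitespace-delimited token of the header) and the `description` metadata
#'   column holds the remainder of the header line.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  .validate_fasta_lines(path)
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  x
}

.validate_fasta_lines <- function(path) {
  lines <- readLines(path)
  in_record <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      if (nchar(ln) < 2L || grepl("^>\\s", ln))
        stop("malformed FASTA header at line ", i, ": ", ln)
      in_record <- TRUE
    } else {
      if (!in_record)
        stop("sequence data before any FASTA header at line ", i)
      if (grepl("[^ACGTUMRWSYKVHDBNacgtumrwsykvhdbn-]", ln))
        stop("illegal sequence character at line ", i, ": ", ln)
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param x A [Biostrings::DNAStringSet] or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_dna_set(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

## Coerce character / DNAString / DNAStringSet to DNAStringSet.
as_dna_set <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (!is.null(names(x))) names(out) <- names(x)
    return(out)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as DNA sequences")
}

## Single sequence as plain uppercase character scalar.
as_seq_char <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L)
    stop("expected a single nucleotide sequence")
  toupper(seq)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Character scalar, `DNAString` or length-1 `DNAStringSet`.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_seq_char(seq))))
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T).  Ambiguous bases and N are excluded
#' from both numerator and denominator.
#'
#' @param seq Character scalar, `DNAString` or length-1 `DNAStringSet`.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  s <- Biostrings::DNAString(as_seq_char(seq))
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0L) stop("GC content undefined: no unambiguous A/C/G/T bases")
  unname((f[["G"]] + f[["C"]]) / tot)
}

#' AT content of a sequence
#'
#' Complement of [gc_content()] over unambiguous bases.
#' @inheritParams gc_content
#' @return Fraction in `[0, 1]`.
#' @export
at_content <- function(seq) 1 - gc_content(seq)

#' Translate a coding sequence with the bacterial genetic code (table 11)
#'
#' Internal stop codons are reported as `*` in the returned protein string,
#' never silently dropped.  Codons containing ambiguous bases translate to
#' `X` unless unambiguous.
#'
#' @param cds_seq In-frame coding sequence (length divisible by 3), coding
#'   strand.
#' @param init_met If `TRUE`, alternative initiation codons (GTG, TTG) at
#'   codon 1 are rendered as `M` per the bacterial convention.
#' @return Amino-acid string (possibly containing `*`).
#' @export
translate_cds <- function(cds_seq, init_met = FALSE) {
  s <- as_seq_char(cds_seq)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length ", nchar(s), " is not divisible by 3")
  if (nchar(s) == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,  # initiator handling is explicit via init_met
    if.fuzzy.codon = "solve"
  ))
  if (init_met && substr(s, 1L, 3L) %in% c("GTG", "TTG"))
    substr(aa, 1L, 1L) <- "M"
  aa
}

GENETIC_CODE_11 <- NULL  # resolved lazily; Biostrings owns the table

codon_to_aa <- function(codon, init = FALSE) {
  translate_cds(codon, init_met = init)
}

#' Find open reading frames
#'
#' Scans all six frames for start-to-stop ORFs.  Within each stop-bounded
#' frame segment the longest ORF (leftmost qualifying start codon through the
#' stop codon, inclusive) is reported when its length is at least `min_len`.
#' ORFs without a terminating stop codon inside the sequence are not
#' reported.  This is a deliberately minimal finder (no RBS or coding-score
#' model) and is not expected to reproduce curated genome annotations.
#'
#' @param seq Nucleotide sequence.
#' @param min_len Minimum ORF length in nucleotides, stop codon included.
#' @param starts Permitted start codons.
#' @return `data.frame(start, end, strand, frame, len)` with 1-based
#'   inclusive coordinates on the forward strand; `frame` in 1..3 is
#'   relative to the scanned strand.
#' @export
find_orfs <- function(seq, min_len = 75L, starts = c("ATG", "GTG", "TTG")) {
  s <- as_seq_char(seq)
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else reverse_complement(s)
    for (frame in 1:3) {
      n_codons <- (L - frame + 1L) %/% 3L
      if (n_codons < 1L) next
      pos <- frame + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(w, pos, pos + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_start <- codons %in% starts
      seg_start <- 1L
      for (j in which(is_stop)) {
        if (j > seg_start) {
          cand <- which(is_start[seg_start:(j - 1L)])
          if (length(cand)) {
            i0 <- seg_start + cand[[1L]] - 1L
            orf_len <- (j - i0 + 1L) * 3L
            if (orf_len >= min_len) {
              a <- pos[[i0]]
              b <- pos[[j]] + 2L
              if (strand == "+") {
                out[[length(out) + 1L]] <- data.frame(
                  start = a, end = b, strand = strand, frame = frame,
                  len = orf_len, stringsAsFactors = FALSE)
              } else {
                out[[length(out) + 1L]] <- data.frame(
                  start = L - b + 1L, end = L - a + 1L, strand = strand,
                  frame = frame, len = orf_len, stringsAsFactors = FALSE)
              }
            }
          }
        }
        seg_start <- j + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      len = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-genome summary statistics
#'
#' @param x `DNAStringSet` or named character vector of genomes.
#' @param orf_min_len Minimum ORF length passed to [find_orfs()].
#' @return `data.frame(id, length, gc, n_orfs)`.
#' @export
genome_stats <- function(x, orf_min_len = 75L) {
  x <- as_dna_set(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  data.frame(
    id = ids,
    length = Biostrings::width(x),
    gc = vapply(seq_along(x), function(i) gc_content(x[[i]]), numeric(1)),
    n_orfs = vapply(seq_along(x), function(i)
      nrow(find_orfs(x[[i]], min_len = orf_min_len)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Read gene models from GFF3
#'
#' Keeps `CDS` and `gene` features; coordinates are 1-based inclusive as in
#' GFF3.  When `genome` is supplied the coding-strand CDS sequence is
#' extracted (reverse-complemented for minus-strand models).
#'
#' @param path GFF3 file.
#' @param genome Optional genome sequences (`DNAStringSet` or named
#'   character) to extract `cds_seq` from.
#' @param feature_types GFF3 feature types to keep.
#' @return `data.frame(id, seqid, genome_start, genome_end, strand, cds_seq)`.
#' @export
read_gene_models <- function(path, genome = NULL,
                             feature_types = c("CDS", "gene")) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (anyNA(ids) && !is.null(gr$Name)) {
    nm <- as.character(gr$Name)
    ids[is.na(ids)] <- nm[is.na(ids)]
  }
  df <- data.frame(
    id = ids,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    genome_start = GenomicRanges::start(gr),
    genome_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$cds_seq <- NA_character_
  if (!is.null(genome)) {
    genome <- as_dna_set(genome)
    for (i in seq_len(nrow(df))) {
      g <- genome[[match(df$seqid[[i]], names(genome))]]
      sub <- as.character(Biostrings::subseq(g, df$genome_start[[i]],
                                             df$genome_end[[i]]))
      df$cds_seq[[i]] <- if (df$strand[[i]] == "-") reverse_complement(sub) else sub
    }
  }
  df
}

#' Write gene models to GFF3
#'
#' @param models Data frame as returned by [read_gene_models()] (the
#'   `cds_seq` column is optional and not serialized).
#' @param path Output GFF3 path.
#' @param feature_type Feature type to emit.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, feature_type = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = models$seqid,
    ranges = IRanges::IRanges(models$genome_start, models$genome_end),
    strand = models$strand
  )
  gr$type <- feature_type
  gr$ID <- models$id
  if (feature_type == "CDS") gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

new_gene_model <- function(id, genome_start, genome_end, strand, cds_seq,
                           seqid = "chr") {
  stopifnot(genome_start <= genome_end, strand %in% c("+", "-"))
  cds_seq <- as_seq_char(cds_seq)
  if (nchar(cds_seq) != genome_end - genome_start + 1L)
    stop("cds_seq length does not match coordinates for gene ", id)
  data.frame(id = id, seqid = seqid, genome_start = genome_start,
             genome_end = genome_end, strand = strand, cds_seq = cds_seq,
             stringsAsFactors = FALSE)
}
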