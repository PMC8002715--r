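## Fragment-based average nucleotide identity (ANIb-style).  The classical
## recipe: chop the query into 1,020-nt fragments, align each fragment
## locally against the subject, and average fragment identities over
## alignments passing 30% identity and 70% fragment-coverage filters.  The
## external BLASTn step is replaced by exact k-mer seeding plus a local
## Smith-Waterman restricted to a window around the seeded diagonal
## (BLASTn-like scores: match +2, mismatch -3, gap open -5, gap extend -2).

#' Split a genome into consecutive ANIb fragments
#'
#' @param seq Genome sequence.
#' @param frag_len Fragment length (default 1020, the ANIb convention).
#' @return `data.frame(start, end, short, seq)`; the terminal remainder is
#'   kept and flagged `short`.
#' @export
fragment_genome <- function(seq, frag_len = 1020L) {
  s <- as_seq_char(seq)
  L <- nchar(s)
  if (L < 1L) stop("empty sequence")
  starts <- seq(1L, L, by = frag_len)
  ends <- pmin(starts + frag_len - 1L, L)
  data.frame(start = starts, end = ends,
             short = (ends - starts + 1L) < frag_len,
             seq = substring(s, starts, ends),
             stringsAsFactors = FALSE)
}

seed_anchor <- function(frag, subject_char, k, stride = 32L) {
  flen <- nchar(frag)
  if (flen < k) return(NULL)
  offsets <- unique(c(seq(1L, flen - k + 1L, by = stride), flen - k + 1L))
  seeds <- substring(frag, offsets, offsets + k - 1L)
  keep <- !grepl("[^ACGT]", seeds)
  offsets <- offsets[keep]
  seeds <- seeds[keep]
  if (!length(seeds)) return(NULL)
  subj <- Biostrings::DNAString(subject_char)
  implied <- integer(0)
  for (i in seq_along(seeds)) {
    st <- Biostrings::start(Biostrings::matchPattern(seeds[[i]], subj))
    if (length(st)) implied <- c(implied, st - offsets[[i]] + 1L)
  }
  if (!length(implied)) return(NULL)
  bin <- round(implied / 30)
  tab <- table(bin)
  best_bin <- as.integer(names(tab)[which.max(tab)])
  anchor <- as.integer(round(stats::median(implied[bin == best_bin])))
  list(anchor = anchor, support = max(tab))
}

#' Locally align a fragment against a subject genome
#'
#' Exact k-mer seeds (default k = 15) anchor a diagonal; a local alignment
#' with fixed BLASTn-like scores (match +2, mismatch -3, gap open -5, gap
#' extend -2) is then computed inside a window around the anchor.  Both
#' subject strands are tried.  Without any seed no alignment is reported.
#'
#' @param frag Fragment sequence.
#' @param subject Subject genome sequence.
#' @param k Seed word size.
#' @param margin Window slack (nt) on each side of the anchored diagonal.
#' @return List with `identity_pct` (matches / alignment columns x 100, `NA`
#'   when unaligned), `alignment_len` (columns), `subject_start`,
#'   `subject_end` (forward-strand 1-based), `strand`.
#' @export
align_fragment <- function(frag, subject, k = 15L, margin = 150L) {
  frag <- as_seq_char(frag)
  subj <- as_seq_char(subject)
  L <- nchar(subj)
  flen <- nchar(frag)
  no_hit <- list(identity_pct = NA_real_, alignment_len = 0L,
                 subject_start = NA_integer_, subject_end = NA_integer_,
                 strand = NA_character_)
  if (flen < k || L < k) return(no_hit)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                      mismatch = -3)
  best <- NULL
  for (strand in c("+", "-")) {
    schar <- if (strand == "+") subj else reverse_complement(subj)
    anc <- seed_anchor(frag, schar, k = k)
    if (is.null(anc)) next
    ws <- max(1L, anc$anchor - margin)
    we <- min(L, anc$anchor + flen - 1L + margin)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(frag),
      Biostrings::DNAString(substring(schar, ws, we)),
      type = "local", substitutionMatrix = sub_mat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score)
      best <- list(aln = aln, score = sc, strand = strand, ws = ws)
  }
  if (is.null(best)) return(no_hit)
  aln <- best$aln
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  matches <- Biostrings::nmatch(aln)
  s_start <- best$ws + Biostrings::start(Biostrings::subject(aln)) - 1L
  s_end <- best$ws + Biostrings::end(Biostrings::subject(aln)) - 1L
  if (best$strand == "-") {
    tmp <- s_start
    s_start <- L - s_end + 1L
    s_end <- L - tmp + 1L
  }
  list(identity_pct = 100 * matches / cols, alignment_len = cols,
       subject_start = s_start, subject_end = s_end, strand = best$strand)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The query is fragmented ([fragment_genome()]); each fragment's best local
#' alignment against the subject is computed ([align_fragment()]); fragments
#' whose alignment reaches `min_identity` percent identity and covers at
#' least `min_coverage` percent of the fragment's own length contribute to
#' an unweighted mean identity.  Short terminal fragments participate with
#' coverage judged against their own length.
#'
#' @param query,subject Genome sequences (named character or `DNAString*`).
#' @param frag_len ANIb fragment length.
#' @param min_identity Identity filter (percent).
#' @param min_coverage Fragment-coverage filter (percent).
#' @param query_id,subject_id Ids recorded in the result.
#' @return Object of class `AniResult`: list with `query_id`, `subject_id`,
#'   `ani_pct` (`NA` when no fragment qualifies), `aligned_coverage_pct`,
#'   `n_fragments_total`, `n_fragments_used`.
#' @export
anib <- function(query, subject, frag_len = 1020L, min_identity = 30,
                 min_coverage = 70, query_id = NULL, subject_id = NULL) {
  if (is.null(query_id))
    query_id <- if (!is.null(names(query))) names(query)[[1L]] else "query"
  if (is.null(subject_id))
    subject_id <- if (!is.null(names(subject))) names(subject)[[1L]] else "subject"
  frags <- fragment_genome(query, frag_len = frag_len)
  subj <- as_seq_char(subject)
  ids <- numeric(0)
  used <- 0L
  for (i in seq_len(nrow(frags))) {
    a <- align_fragment(frags$seq[[i]], subj)
    flen_i <- nchar(frags$seq[[i]])
    if (!is.na(a$identity_pct) &&
        a$identity_pct >= min_identity &&
        a$alignment_len >= min_coverage / 100 * flen_i) {
      ids <- c(ids, a$identity_pct)
      used <- used + 1L
    }
  }
  structure(list(
    query_id = query_id, subject_id = subject_id,
    ani_pct = if (used) mean(ids) else NA_real_,
    aligned_coverage_pct = 100 * used / nrow(frags),
    n_fragments_total = nrow(frags), n_fragments_used = used
  ), class = "AniResult")
}

#' @export
print.AniResult <- function(x, ...) {
  cat(sprintf("ANIb %s vs %s: %s%% (%d/%d fragments, coverage %.1f%%)\n",
              x$query_id, x$subject_id,
              if (is.na(x$ani_pct)) "NA" else sprintf("%.2f", x$ani_pct),
              x$n_fragments_used, x$n_fragments_total,
              x$aligned_coverage_pct))
  invisible(x)
}

#' All-against-all ANI matrix with average-linkage leaf order
#'
#' Computes [anib()] for every ordered pair, then clusters genomes by
#' average linkage on the distance `100 - symmetrized ANI` (mean of the two
#' directions; `NA` treated as 0 identity, so unrelated pairs sort to
#' maximal distance).  Ids are sorted before clustering so the leaf order is
#' deterministic with ties broken by id.
#'
#' @param genomes `DNAStringSet` or named character vector (>= 2 genomes,
#'   unique ids).
#' @inheritParams anib
#' @return Object of class `AniMatrix`: list with `ids`, `values` (percent
#'   identities, diagonal 100, `NA` allowed), `linkage_order` (ids in
#'   dendrogram leaf order) and `hclust`.
#' @export
ani_matrix <- function(genomes, frag_len = 1020L, min_identity = 30,
                       min_coverage = 70) {
  genomes <- as_dna_set(genomes)
  ids <- names(genomes)
  if (is.null(ids)) ids <- paste0("g", seq_along(genomes))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  ord <- order(ids)
  genomes <- genomes[ord]
  ids <- ids[ord]
  n <- length(ids)
  seqs <- stats::setNames(as.character(genomes), ids)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(v) <- 100
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      v[i, j] <- anib(seqs[i], seqs[j], frag_len = frag_len,
                      min_identity = min_identity,
                      min_coverage = min_coverage)$ani_pct
    }
  }
  sym <- v
  sym[is.na(sym)] <- 0
  sym <- (sym + t(sym)) / 2
  hc <- stats::hclust(stats::as.dist(100 - sym), method = "average")
  structure(list(ids = ids, values = v, linkage_order = ids[hc$order],
                 hclust = hc),
            class = "AniMatrix")
}

#' @export
print.AniMatrix <- function(x, ...) {
  cat(sprintf("AniMatrix over %d genomes (leaf order: %s)\n",
              length(x$ids), paste(x$linkage_order, collapse = ", ")))
  print(round(x$values, 2))
  invisible(x)
}
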