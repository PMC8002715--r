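## Minisatellite tandem-array detection, assembly-ambiguity flagging from
## partial read mappings, and copy-number genotyping from spanning
## sequences.  The detector works on the shifted self-match indicator
## m_p(i) = 1[seq[i] == seq[i + p]]: a tandem array of period p is a long,
## dense run of matches in m_p.

#' Detect tandem repeat arrays
#'
#' For every candidate period `p` in `[unit_min, unit_max]` (ascending, so
#' the smallest period explaining a locus wins), maximal dense runs of the
#' shifted self-match indicator are collected: exact runs, and runs merged
#' across short gaps while the overall match fraction stays at least
#' `min_match`.  Imperfect candidates must additionally be significant
#' under a Bonferroni-corrected binomial null (P(match) = 1/4), which keeps
#' the detector silent on random sequence at permissive `min_match`.
#' Boundaries are refined to whole-copy frames; edge copies whose agreement
#' with the consensus falls below `min_match` are trimmed; a fractional
#' final copy is reported only when the partial segment is at least
#' `partial_min` nt (shorter overhangs are indistinguishable from chance
#' single-base period matches at the array edge).
#'
#' @param seq Sequence to scan.
#' @param unit_min,unit_max Period search range (nt).
#' @param min_copies Minimum (full) copies per reported array.
#' @param min_match Minimum per-position match fraction.
#' @param partial_min Minimum length (nt) of a reported fractional copy.
#' @param alpha Familywise significance level for imperfect candidates.
#' @param seq_id Id recorded in the output.
#' @return `data.frame(seq_id, start, end, unit_len, copies,
#'   consensus_unit)` with a list-column `variants` of per-copy deviations
#'   (`copy_index`, `offset` 0-based within the unit, `consensus_base`,
#'   `observed_base`).  Coordinates are 1-based inclusive.
#' @export
detect_tandem_arrays <- function(seq, unit_min = 10L, unit_max = 100L,
                                 min_copies = 2L, min_match = 0.8,
                                 partial_min = 8L, alpha = 0.001,
                                 seq_id = NULL) {
  s <- as_seq_char(seq)
  if (is.null(seq_id))
    seq_id <- if (!is.null(names(seq))) names(seq) else "seq"
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(v)
  if (L < 2L * unit_min) return(.empty_arrays())
  accepted <- list()
  n_tests <- as.numeric(L) * (unit_max - unit_min + 1)
  for (p in unit_min:min(unit_max, L %/% 2L)) {
    m <- v[seq_len(L - p)] == v[(p + 1L):L]
    runs <- .merged_runs(m, p, min_match)
    for (run in runs) {
      span_m <- run$end - run$start + 1L
      if (span_m < (min_copies - 1L) * p) next
      frac <- run$matches / span_m
      if (frac < min_match) next
      if (frac < 1) {
        pval <- stats::pbinom(run$matches - 1L, span_m, 0.25,
                              lower.tail = FALSE)
        if (pval > alpha / n_tests) {
          ## merged run not significant: retry its longest exact component
          ## (an exact run needs no significance test)
          rr <- rle(m[run$start:run$end])
          re <- cumsum(rr$lengths)
          ti <- which(rr$values)
          best <- ti[which.max(rr$lengths[ti])]
          run <- list(start = run$start + re[best] - rr$lengths[best],
                      end = run$start + re[best] - 1L,
                      matches = rr$lengths[best])
          span_m <- run$end - run$start + 1L
          if (span_m < (min_copies - 1L) * p) next
          frac <- 1
        }
      }
      cand_start <- run$start
      cand_end <- run$end + p
      if (.overlaps_accepted(cand_start, cand_end, accepted)) next
      arr <- .refine_array(v, cand_start, cand_end, p, min_match,
                           partial_min)
      if (is.null(arr) || arr$n_full < min_copies) next
      arr$seq_id <- seq_id
      accepted[[length(accepted) + 1L]] <- arr
    }
  }
  if (!length(accepted)) return(.empty_arrays())
  res <- data.frame(
    seq_id = vapply(accepted, `[[`, character(1), "seq_id"),
    start = vapply(accepted, `[[`, integer(1), "start"),
    end = vapply(accepted, `[[`, integer(1), "end"),
    unit_len = vapply(accepted, `[[`, integer(1), "unit_len"),
    copies = vapply(accepted, `[[`, numeric(1), "copies"),
    consensus_unit = vapply(accepted, `[[`, character(1), "consensus_unit"),
    stringsAsFactors = FALSE
  )
  res$variants <- lapply(accepted, `[[`, "variants")
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_arrays <- function() {
  out <- data.frame(seq_id = character(), start = integer(),
                    end = integer(), unit_len = integer(),
                    copies = numeric(), consensus_unit = character(),
                    stringsAsFactors = FALSE)
  out$variants <- list()
  out
}

## Maximal TRUE runs of m, greedily merged across gaps <= p while the
## overall match fraction stays >= min_match.
.merged_runs <- function(m, p, min_match) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ti <- which(r$values)
  if (!length(ti)) return(list())
  out <- list()
  cur <- list(start = starts[ti[1L]], end = ends[ti[1L]],
              matches = r$lengths[ti[1L]])
  for (i in ti[-1L]) {
    gap <- starts[i] - cur$end - 1L
    new_span <- ends[i] - cur$start + 1L
    new_matches <- cur$matches + r$lengths[i]
    ## a gap may only be bridged by neighbours at least as long as the gap;
    ## this stops short chance runs near an array from rotating its frame
    if (gap <= p && min(cur$matches, r$lengths[i]) >= gap &&
        new_matches / new_span >= min_match) {
      cur$end <- ends[i]
      cur$matches <- new_matches
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- list(start = starts[i], end = ends[i], matches = r$lengths[i])
    }
  }
  out[[length(out) + 1L]] <- cur
  out
}

.overlaps_accepted <- function(a, b, accepted) {
  for (x in accepted) {
    ov <- min(b, x$end) - max(a, x$start) + 1L
    if (ov > 0.5 * (b - a + 1L)) return(TRUE)
  }
  FALSE
}

.consensus_of <- function(blocks) {
  mat <- do.call(rbind, strsplit(blocks, "", fixed = TRUE))
  apply(mat, 2L, function(col) names(which.max(table(col))))
}

.block_strings <- function(v, start, n, p) {
  vapply(seq_len(n), function(j)
    paste(v[(start + (j - 1L) * p):(start + j * p - 1L)], collapse = ""),
    character(1))
}

.refine_array <- function(v, cand_start, cand_end, p, min_match,
                          partial_min) {
  S <- cand_end - cand_start + 1L
  full <- S %/% p
  rem <- S %% p
  if (full < 2L) return(NULL)
  start <- cand_start
  if (rem >= partial_min) {
    ## candidate fractional final copy: genuine partials continue the
    ## consensus exactly; chance periodic matches beyond the array do not
    blocks <- .block_strings(v, start, full, p)
    cons <- .consensus_of(blocks)
    tail_seq <- v[(start + full * p):(start + full * p + rem - 1L)]
    if (!all(tail_seq == cons[seq_len(rem)])) rem <- -rem  # force re-framing
  }
  if (rem < 0L || (rem > 0L && rem < partial_min)) {
    rem <- abs(rem)
    ## ambiguous short overhang: pick the whole-copy frame that minimizes
    ## total disagreement with the column consensus
    best <- NULL
    for (t in 0:rem) {
      x <- cand_start + t
      if (x + full * p - 1L > length(v)) next
      blocks <- .block_strings(v, x, full, p)
      cons <- .consensus_of(blocks)
      mism <- sum(vapply(blocks, function(b)
        sum(strsplit(b, "", fixed = TRUE)[[1L]] != cons), numeric(1)))
      if (is.null(best) || mism < best$mism) best <- list(t = t, mism = mism)
    }
    start <- cand_start + best$t
    rem <- 0L
  }
  ## trim edge copies disagreeing with the consensus (chance merges)
  repeat {
    blocks <- .block_strings(v, start, full, p)
    cons <- .consensus_of(blocks)
    agree <- vapply(blocks, function(b)
      mean(strsplit(b, "", fixed = TRUE)[[1L]] == cons), numeric(1))
    if (full > 2L && agree[[full]] < min_match) {
      full <- full - 1L
      rem <- 0L
    } else if (full > 2L && agree[[1L]] < min_match) {
      start <- start + p
      full <- full - 1L
    } else break
  }
  blocks <- .block_strings(v, start, full, p)
  cons <- .consensus_of(blocks)
  agree <- vapply(blocks, function(b)
    mean(strsplit(b, "", fixed = TRUE)[[1L]] == cons), numeric(1))
  if (mean(agree) < min_match) return(NULL)
  variants <- list()
  for (j in seq_len(full)) {
    bj <- strsplit(blocks[[j]], "", fixed = TRUE)[[1L]]
    off <- which(bj != cons)
    if (length(off)) {
      variants[[length(variants) + 1L]] <- data.frame(
        copy_index = j, offset = off - 1L, consensus_base = cons[off],
        observed_base = bj[off], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(copy_index = integer(), offset = integer(),
               consensus_base = character(), observed_base = character(),
               stringsAsFactors = FALSE)
  end <- start + full * p - 1L + rem
  list(start = as.integer(start), end = as.integer(end),
       unit_len = as.integer(p),
       copies = full + rem / p, n_full = full,
       consensus_unit = paste(cons, collapse = ""),
       variants = variants)
}

#' Flag regions with excess partial read mappings
#'
#' Per region, the partial fraction is the share of overlapping alignments
#' that are clipped (soft/hard clips from the CIGAR, or the equivalent TSV
#' columns), after de-duplication by read id.  An alignment forced to stop
#' inside a region (e.g. reads from a longer repeat haplotype mapped onto a
#' shorter reference) surfaces as clipping; unclipped alignments that merely
#' end inside a region are ordinary and not counted, so concordant reads
#' never trigger a flag.
#'
#' @param alignments `data.frame(read_id, ref_id, start, end, clipped_left,
#'   clipped_right)` as from [read_alignments()] or [align_reads_exact()].
#' @param regions `data.frame(seq_id, start, end)`.
#' @param threshold Partial fraction above which a region is flagged.
#' @param ref_lengths Optional named vector of reference lengths for region
#'   validation.
#' @return `data.frame(seq_id, start, end, n_reads, partial_fraction,
#'   depth, flagged)`; zero-depth regions get `NA` partial fraction and are
#'   not flagged.
#' @export
flag_partial_mappings <- function(alignments, regions, threshold = 0.2,
                                  ref_lengths = NULL) {
  need <- c("read_id", "ref_id", "start", "end", "clipped_left",
            "clipped_right")
  miss <- setdiff(need, names(alignments))
  if (length(miss))
    stop("alignment records lack columns: ", paste(miss, collapse = ", "))
  ## drop duplicated records (same read id AND placement); paired mates
  ## share a read id but differ in coordinates and are both kept
  key <- alignments[, c("read_id", "ref_id", "start", "end",
                        "clipped_left", "clipped_right")]
  a <- alignments[!duplicated(key), , drop = FALSE]
  out <- lapply(seq_len(nrow(regions)), function(i) {
    rs <- regions$start[[i]]
    re <- regions$end[[i]]
    rid <- regions$seq_id[[i]]
    if (rs < 1L || rs > re) stop("invalid region ", rid, ":", rs, "-", re)
    if (!is.null(ref_lengths)) {
      if (!rid %in% names(ref_lengths) || re > ref_lengths[[rid]])
        stop("region outside reference: ", rid, ":", rs, "-", re)
    }
    sel <- a$ref_id == rid & a$start <= re & a$end >= rs
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(seq_id = rid, start = rs, end = re, n_reads = 0L,
                        partial_fraction = NA_real_, depth = 0,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    sub <- a[sel, , drop = FALSE]
    partial <- sub$clipped_left > 0L | sub$clipped_right > 0L
    pf <- mean(partial)
    depth <- sum(pmin(sub$end, re) - pmax(sub$start, rs) + 1L) /
      (re - rs + 1L)
    data.frame(seq_id = rid, start = rs, end = re, n_reads = n,
               partial_fraction = pf, depth = depth,
               flagged = pf > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read alignment records from SAM or TSV
#'
#' SAM files are converted with `Rsamtools::asBam()` and read via
#' `GenomicAlignments::readGAlignments()`; clipping is taken from soft/hard
#' clip CIGAR operations.  The TSV fallback expects a header with columns
#' `read_id, ref_id, start, end, clipped_left, clipped_right`.
#'
#' @param path SAM (`.sam`) or TSV path.
#' @return `data.frame(read_id, ref_id, start, end, clipped_left,
#'   clipped_right)`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(what = "qname"))
    cig <- GenomicAlignments::cigar(ga)
    has_l <- grepl("^[0-9]+[SH]", cig)
    has_r <- grepl("[0-9]+[SH]$", cig)
    clip_l <- integer(length(cig))
    clip_r <- integer(length(cig))
    clip_l[has_l] <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cig[has_l]))
    clip_r[has_r] <- as.integer(sub("^.*?([0-9]+)[SH]$", "\\1", cig[has_r]))
    data.frame(
      read_id = S4Vectors::mcols(ga)$qname,
      ref_id = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga),
      end = GenomicAlignments::end(ga),
      clipped_left = clip_l, clipped_right = clip_r,
      stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
}

#' Exact-placement read aligner (synthetic-data helper)
#'
#' Places each read on the reference by exact matching: the full read if it
#' occurs verbatim (either orientation), otherwise its longest exactly
#' matching prefix or suffix (the remainder is reported as clipping).  This
#' deliberately simple aligner exists to validate ambiguity flagging on
#' simulated reads; it is not a general-purpose mapper.
#'
#' @param reads Named character vector of reads.
#' @param ref Reference sequence.
#' @param ref_id Reference id for the records.
#' @param min_aligned Minimum exactly matching length to report a placement.
#' @return Alignment `data.frame` as in [read_alignments()]; unplaceable
#'   reads are omitted.
#' @export
align_reads_exact <- function(reads, ref, ref_id = "ref", min_aligned = 20L) {
  refs <- Biostrings::DNAString(as_seq_char(ref))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  place_one <- function(r) {
    n <- nchar(r)
    hit <- Biostrings::matchPattern(r, refs)
    if (length(hit))
      return(list(start = Biostrings::start(hit)[1L],
                  end = Biostrings::end(hit)[1L], cl = 0L, cr = 0L))
    ## longest exact prefix
    lo <- min_aligned; hi <- n; best_p <- 0L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (length(Biostrings::matchPattern(substr(r, 1L, mid), refs))) {
        best_p <- mid; lo <- mid + 1L
      } else hi <- mid - 1L
    }
    ## longest exact suffix
    lo <- min_aligned; hi <- n; best_s <- 0L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (length(Biostrings::matchPattern(substr(r, n - mid + 1L, n), refs))) {
        best_s <- mid; lo <- mid + 1L
      } else hi <- mid - 1L
    }
    if (best_p == 0L && best_s == 0L) return(NULL)
    if (best_p >= best_s) {
      h <- Biostrings::matchPattern(substr(r, 1L, best_p), refs)
      list(start = Biostrings::start(h)[1L], end = Biostrings::end(h)[1L],
           cl = 0L, cr = n - best_p)
    } else {
      h <- Biostrings::matchPattern(substr(r, n - best_s + 1L, n), refs)
      list(start = Biostrings::start(h)[1L], end = Biostrings::end(h)[1L],
           cl = n - best_s, cr = 0L)
    }
  }
  rows <- list()
  for (i in seq_along(reads)) {
    r <- as_seq_char(reads[[i]])
    pl <- place_one(r)
    if (is.null(pl)) pl <- place_one(reverse_complement(r))
    if (is.null(pl)) next
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = ids[[i]], ref_id = ref_id, start = pl$start, end = pl$end,
      clipped_left = pl$cl, clipped_right = pl$cr, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      clipped_left = integer(), clipped_right = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genotype tandem-array copy number from spanning sequences
#'
#' Each spanning sequence (read, amplicon or assembled haplotype) is
#' genotyped by locating the unique left and right flanks (near-exact match
#' tolerating `flank_mm` mismatches) and dividing the inter-flank distance
#' by the unit length.  Sources whose flanks are absent or non-unique yield
#' per-source error records and are excluded from the histogram.
#'
#' @param spanning_seqs Named character vector of spanning sequences.
#' @param left_flank,right_flank Flanking anchor sequences (>= 20 nt).
#' @param unit_len Repeat unit length (nt).
#' @param flank_mm Mismatches tolerated when locating a flank.
#' @return List with `calls` (`data.frame(source_id, copies, residual,
#'   status, message)`) and `histogram` (table of copy numbers over
#'   successful calls).
#' @export
genotype_copy_number <- function(spanning_seqs, left_flank, right_flank,
                                 unit_len, flank_mm = 2L) {
  if (nchar(left_flank) < 20L || nchar(right_flank) < 20L)
    stop("flanks must be >= 20 nt")
  ids <- names(spanning_seqs)
  if (is.null(ids)) ids <- sprintf("src%03d", seq_along(spanning_seqs))
  lf <- Biostrings::DNAString(as_seq_char(left_flank))
  rf <- Biostrings::DNAString(as_seq_char(right_flank))
  rows <- lapply(seq_along(spanning_seqs), function(i) {
    s <- Biostrings::DNAString(as_seq_char(spanning_seqs[[i]]))
    err <- function(msg) data.frame(
      source_id = ids[[i]], copies = NA_integer_, residual = NA_integer_,
      status = "error", message = msg, stringsAsFactors = FALSE)
    hl <- Biostrings::matchPattern(lf, s, max.mismatch = flank_mm)
    if (length(hl) == 0L) return(err("left flank not found"))
    if (length(hl) > 1L) return(err("left flank not unique"))
    hr <- Biostrings::matchPattern(rf, s, max.mismatch = flank_mm)
    if (length(hr) == 0L) return(err("right flank not found"))
    if (length(hr) > 1L) return(err("right flank not unique"))
    d <- Biostrings::start(hr)[1L] - Biostrings::end(hl)[1L] - 1L
    if (d < 0L) return(err("flanks overlap or out of order"))
    copies <- as.integer(round(d / unit_len))
    data.frame(source_id = ids[[i]], copies = copies,
               residual = d - copies * unit_len, status = "ok",
               message = "", stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  list(calls = calls, histogram = table(calls$copies[calls$status == "ok"]))
}
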