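#' k-mer frequency profile of a genome
#'
#' Counts all overlapping k-mers (lexicographic index over A<C<G<T).
#' Windows containing N or other ambiguity codes are skipped.  In
#' `strand = "both"` mode (default) reverse-complement windows are added,
#' making the signature independent of which strand a genome was deposited
#' on.
#'
#' @param seq Genome sequence.
#' @param k Word size, 1..8 (default 4: tetranucleotide signature).
#' @param strand `"both"` or `"single"`.
#' @param id Genome id recorded in the profile.
#' @return An object of class `KmerProfile`: list with `genome_id`, `k`,
#'   `strand`, `counts` (named integer vector of length 4^k) and `total`.
#' @export
kmer_profile <- function(seq, k = 4L, strand = c("both", "single"),
                         id = NULL) {
  strand <- match.arg(strand)
  s <- Biostrings::DNAString(as_seq_char(seq))
  if (k < 1L || k > 8L) stop("k must be in 1..8")
  if (length(s) < k) stop("sequence shorter than k")
  counts <- Biostrings::oligonucleotideFrequency(s, width = k)
  if (strand == "both") {
    counts <- counts +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(s),
                                           width = k)
  }
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq) else "seq"
  structure(list(genome_id = id, k = as.integer(k), strand = strand,
                 counts = counts, total = sum(counts)),
            class = "KmerProfile")
}

#' @export
print.KmerProfile <- function(x, ...) {
  cat(sprintf("KmerProfile '%s': k=%d, strand=%s, %d windows\n",
              x$genome_id, x$k, x$strand, x$total))
  invisible(x)
}

#' k-mer profiles for a set of genomes
#'
#' @param x `DNAStringSet` or named character vector.
#' @inheritParams kmer_profile
#' @return List of `KmerProfile`.
#' @export
kmer_profiles <- function(x, k = 4L, strand = c("both", "single")) {
  strand <- match.arg(strand)
  x <- as_dna_set(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(x))
  lapply(seq_along(x), function(i)
    kmer_profile(x[[i]], k = k, strand = strand, id = ids[[i]]))
}

shannon_entropy <- function(p, log_base = 2) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = log_base))
}

#' Jensen-Shannon divergence between two frequency vectors
#'
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q) / 2` and
#' entropies in `log_base`.  With base 2 the value is bounded in `[0, 1]`,
#' is 0 iff `P = Q`, and is finite for vectors containing zeros (the
#' convention `0 log 0 = 0` applies), so no pseudocounts are used.
#'
#' @param p,q Normalized frequency vectors over the same index set.
#' @param log_base Logarithm base (default 2).
#' @return Non-negative divergence.
#' @export
jsd <- function(p, q, log_base = 2) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must each sum to 1 (tolerance 1e-9)")
  m <- (p + q) / 2
  d <- shannon_entropy(m, log_base) -
    (shannon_entropy(p, log_base) + shannon_entropy(q, log_base)) / 2
  max(d, 0)  # guard tiny negative rounding
}

profile_freq <- function(profile) {
  if (profile$total == 0) stop("empty profile")
  profile$counts / profile$total
}

#' Pairwise Jensen-Shannon distance matrix over k-mer profiles
#'
#' @param profiles List of `KmerProfile` sharing `k` and strand mode.
#' @param metric `"jsd"` (raw divergence, default) or `"sqrt-jsd"` (its
#'   square root, a metric).
#' @return Object of class `DistanceMatrix`: list with `ids`, `values`
#'   (symmetric matrix, zero diagonal) and `method`.
#' @export
distance_matrix <- function(profiles, metric = c("jsd", "sqrt-jsd")) {
  metric <- match.arg(metric)
  if (!length(profiles)) stop("no profiles")
  ks <- vapply(profiles, function(p) p$k, integer(1))
  st <- vapply(profiles, function(p) p$strand, character(1))
  if (length(unique(ks)) != 1L || length(unique(st)) != 1L)
    stop("profiles mix k or strand modes")
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  freqs <- lapply(profiles, profile_freq)
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- jsd(freqs[[i]], freqs[[j]])
        if (metric == "sqrt-jsd") d <- sqrt(d)
        m[i, j] <- m[j, i] <- d
      }
    }
  }
  structure(list(ids = ids, values = m, method = metric),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix (%s) over %d genomes\n", x$method,
              length(x$ids)))
  print(round(x$values, 4))
  invisible(x)
}

#' Summarize distances from a focal genome by group
#'
#' Distances from `focal_id` to every other genome are grouped by
#' `group_labels` and summarized (n, min, quartiles, median, max), sorted by
#' median.  This mirrors boxplot-style comparison of one genome against
#' labelled families of genomes.
#'
#' @param dm `DistanceMatrix`.
#' @param focal_id Id of the focal genome.
#' @param group_labels Named character vector labelling every non-focal id.
#' @return `data.frame(group, n, min, q1, median, q3, max)` sorted by
#'   median.
#' @export
group_summary <- function(dm, focal_id, group_labels) {
  stopifnot(is(dm, "DistanceMatrix"))
  if (!focal_id %in% dm$ids) stop("focal_id not in matrix")
  others <- setdiff(dm$ids, focal_id)
  missing <- setdiff(others, names(group_labels))
  if (length(missing))
    stop("unlabelled ids: ", paste(missing, collapse = ", "))
  d <- dm$values[focal_id, others]
  grp <- group_labels[others]
  res <- do.call(rbind, lapply(split(d, grp), function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(n = length(v), min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  }))
  res <- data.frame(group = rownames(res), res, stringsAsFactors = FALSE)
  res <- res[order(res$median), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a distance matrix as TSV
#'
#' Square form (ids in header and first column) plus optionally a
#' long-format table for plotting.
#'
#' @param dm `DistanceMatrix` or `AniMatrix`.
#' @param path Output TSV path.
#' @param long_path Optional long-format TSV path (id1, id2, value).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(dm, path, long_path = NULL) {
  m <- dm$values
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(m, diag = FALSE), arr.ind = TRUE)
    long <- data.frame(id1 = rownames(m)[idx[, 1]],
                       id2 = colnames(m)[idx[, 2]],
                       value = m[idx], stringsAsFactors = FALSE)
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
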