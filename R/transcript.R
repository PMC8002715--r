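## Post-mapping transcriptome arithmetic: TPM, read-origin fractions,
## inter-replicate statistics, fold-change flagging at 2-fold, and Pearson
## correlation of log2 TPM.  Read mapping itself is upstream; these
## functions start from a gene x sample count matrix.

#' Transcripts per million
#'
#' Per sample: `r_i = c_i / L_i`, `TPM_i = 1e6 * r_i / sum_j r_j`.  Columns
#' of samples with any counts sum to 1e6; an all-zero sample yields an
#' all-zero column with a warning.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param lengths Per-gene lengths in nt (positive, length `nrow(counts)`).
#' @return Matrix of TPM values with the axes of `counts`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lengths) != nrow(counts)) stop("one length per gene required")
  if (any(lengths <= 0)) stop("lengths must be positive")
  r <- counts / lengths
  tot <- colSums(r)
  if (any(tot == 0)) warning("all-zero sample(s): ",
                             paste(colnames(counts)[tot == 0], collapse = ", "))
  tot[tot == 0] <- NA_real_
  out <- sweep(r, 2L, tot, "/") * 1e6
  out[, is.na(tot)] <- 0
  out
}

#' Per-sample read-origin fractions
#'
#' Partitions each sample's counts by gene origin (e.g. host / CGP3
#' prophage / phage) and returns fractions summing to 1 per sample.
#'
#' @param counts Gene x sample count matrix.
#' @param origins Per-gene origin labels (length `nrow(counts)`).
#' @param levels Category order; defaults to the classic
#'   host/CGP3/phage partition when those are the labels present, else the
#'   sorted unique labels.
#' @return Origin x sample matrix of fractions (`NA` column for zero-total
#'   samples).
#' @export
origin_fractions <- function(counts, origins,
                             levels = NULL) {
  counts <- as.matrix(counts)
  if (length(origins) != nrow(counts))
    stop("one origin label per gene required")
  if (anyNA(origins)) stop("origin labels must cover all genes")
  if (is.null(levels)) {
    canonical <- c("host", "CGP3", "phage")
    levels <- if (all(unique(origins) %in% canonical)) canonical
              else sort(unique(origins))
  }
  sums <- rowsum(counts, group = factor(origins, levels = levels))
  m <- matrix(0, nrow = length(levels), ncol = ncol(counts),
              dimnames = list(levels, colnames(counts)))
  m[rownames(sums), ] <- sums
  tot <- colSums(m)
  frac <- sweep(m, 2L, tot, "/")
  frac[, tot == 0] <- NA_real_
  frac
}

#' Inter-replicate mean and relative difference
#'
#' For two replicates `a, b`: mean `(a + b) / 2` and relative difference
#' `|a - b| / mean * 100` percent; generalized to n replicates as
#' `range / mean * 100`.  The relative difference is `NA` where the mean is
#' 0.
#'
#' @param values Gene x replicate matrix (or vector of replicate values for
#'   a single gene).
#' @return `data.frame(mean, rel_diff_pct)` with one row per gene.
#' @export
replicate_stats <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  values <- as.matrix(values)
  mn <- rowMeans(values)
  rng <- apply(values, 1L, function(x) diff(range(x)))
  rel <- ifelse(mn == 0, NA_real_, rng / mn * 100)
  data.frame(mean = mn, rel_diff_pct = rel,
             row.names = rownames(values), stringsAsFactors = FALSE)
}

#' Fold changes between condition means, flagged at 2-fold
#'
#' `fc = (a + pseudocount) / (b + pseudocount)`; genes with
#' `log2(fc) > 1` are flagged `up`, `< -1` flagged `down`, otherwise
#' `none`.
#'
#' @param mean_infected,mean_uninfected Non-negative per-gene condition
#'   means (same length).
#' @param pseudocount Stabilizing offset added to both means (>= 0).
#' @return `data.frame(fc, log2fc, flag)`.
#' @export
fold_changes <- function(mean_infected, mean_uninfected, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(mean_infected) != length(mean_uninfected))
    stop("condition means must have equal length")
  if (any(mean_infected < 0) || any(mean_uninfected < 0))
    stop("means must be non-negative")
  fc <- (mean_infected + pseudocount) / (mean_uninfected + pseudocount)
  l2 <- log2(fc)
  data.frame(fc = fc, log2fc = l2,
             flag = ifelse(l2 > 1, "up", ifelse(l2 < -1, "down", "none")),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of log2-transformed TPM values
#'
#' Computes the sample x sample Pearson correlation of
#' `log2(TPM + pseudocount)`.  Samples with constant transformed values get
#' `NA` rows/columns; the diagonal is 1 elsewhere.
#'
#' @param tpm_mat Gene x sample TPM matrix.
#' @param pseudocount Offset inside the log (default 1 TPM unit).
#' @return Symmetric correlation matrix.
#' @export
pearson_log2 <- function(tpm_mat, pseudocount = 1) {
  tpm_mat <- as.matrix(tpm_mat)
  if (nrow(tpm_mat) < 2L) stop("need >= 2 genes")
  x <- log2(tpm_mat + pseudocount)
  sds <- apply(x, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(x, method = "pearson"))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' One-call transcriptome summary
#'
#' Convenience wrapper running the full post-mapping arithmetic: TPM,
#' origin fractions, per-condition replicate statistics on TPM, fold
#' changes between the two conditions, and the log2-TPM correlation matrix.
#'
#' @param counts Gene x sample count matrix.
#' @param genes `data.frame(id, length, origin)` aligned with the rows.
#' @param samples `data.frame(id, condition, replicate)` aligned with the
#'   columns; exactly two conditions are expected for fold changes, the
#'   second sorted condition treated as the baseline unless `baseline` is
#'   given.
#' @param baseline Condition name used as the fold-change denominator.
#' @param pseudocount Passed to [fold_changes()] and [pearson_log2()].
#' @return List with `tpm`, `origin_fractions`, `replicate_stats` (per
#'   condition), `fold_changes`, `correlation`.
#' @export
summarize_rnaseq <- function(counts, genes, samples, baseline = NULL,
                             pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(genes) == nrow(counts), nrow(samples) == ncol(counts))
  tp <- tpm(counts, genes$length)
  fr <- origin_fractions(counts, genes$origin)
  conds <- unique(samples$condition)
  rs <- lapply(stats::setNames(conds, conds), function(cn)
    replicate_stats(tp[, samples$condition == cn, drop = FALSE]))
  fc <- NULL
  if (length(conds) == 2L) {
    if (is.null(baseline)) baseline <- sort(conds)[[2L]]
    other <- setdiff(conds, baseline)
    fc <- fold_changes(rs[[other]]$mean, rs[[baseline]]$mean,
                       pseudocount = pseudocount)
    rownames(fc) <- rownames(counts)
  }
  list(tpm = tp, origin_fractions = fr, replicate_stats = rs,
       fold_changes = fc,
       correlation = pearson_log2(tp, pseudocount = pseudocount))
}
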