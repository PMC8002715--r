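# Shared helpers: independent brute-force oracles and fixture builders.

# Exhaustive exact tandem-array oracle: scans every (start, period) pair by
# direct substring comparison, extends copy by copy, prefers the smallest
# period explaining a locus (periods ascending, overlap-suppressed).  Kept
# deliberately naive and independent of the package's run-based detector.
oracle_exact_arrays <- function(s, unit_min = 10L, unit_max = 100L,
                                min_copies = 2L, partial_min = 8L) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(v)
  res <- list()
  covered <- function(a, b) {
    for (x in res) {
      ov <- min(b, x$end) - max(a, x$start) + 1L
      if (ov > 0.5 * (b - a + 1L)) return(TRUE)
    }
    FALSE
  }
  for (p in unit_min:min(unit_max, L %/% 2L)) {
    i <- 1L
    while (i + 2L * p - 1L <= L) {
      u <- substr(s, i, i + p - 1L)
      n <- 1L
      while (i + (n + 1L) * p - 1L <= L &&
             substr(s, i + n * p, i + (n + 1L) * p - 1L) == u) n <- n + 1L
      if (n >= min_copies && !covered(i, i + n * p - 1L)) {
        t <- 0L
        while (i + n * p + t <= L && t < p &&
               v[i + n * p + t] == v[i + t]) t <- t + 1L
        frac <- if (t >= partial_min) t else 0L
        res[[length(res) + 1L]] <- list(
          start = i, end = i + n * p - 1L + frac, unit_len = p,
          copies = n + frac / p)
        i <- i + n * p + t
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_len = integer(), copies = numeric()))
  }
  out <- do.call(rbind, lapply(res, as.data.frame))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random CDS with specified codons pinned at given 1-based codon indices.
make_cds <- function(n_codons, fixed = list(), seed = 1L) {
  s <- random_cds(n_codons, seed = seed)
  for (idx in names(fixed)) {
    i <- as.integer(idx)
    a <- (i - 1L) * 3L + 1L
    substr(s, a, a + 2L) <- fixed[[idx]]
  }
  s
}

# Random probability vector (normalized gamma draws).
rand_prob <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

base_complement <- c(A = "T", C = "G", G = "C", T = "A")
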