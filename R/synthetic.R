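## Seeded generators for every input class the pipeline consumes.  Each is a
## pure function of (parameters, seed) and returns planted ground truth
## alongside the data, so downstream stages can be validated by parameter
## recovery rather than by fixtures on disk.

#' Default 42-bp minisatellite repeat unit
#'
#' A fixed synthetic 42-mer of 14 distinct codons (no stops), with AAA at
#' codon 5 so that the default variant specification (an AAA to CAG codon
#' exchange on copy 2) can be applied.  This is a stand-in unit for tests and
#' demos; it is not a real phage repeat sequence.
#'
#' @return Character scalar of length 42.
#' @export
phage_repeat_unit <- function() {
  paste0("ATGGACCTGTTCAAAGGTACGCAGATCTGGTCAGAACGTTAC")
}

#' Default per-copy variant specification for planted repeat arrays
#'
#' Mimics a minisatellite whose second copy carries a single codon exchange
#' (AAA to CAG at codon 5 of [phage_repeat_unit()]).
#'
#' @return List of `list(copy, codon, replacement)`.
#' @export
default_repeat_variant <- function() {
  list(list(copy = 2L, codon = 5L, replacement = "CAG"))
}

#' Generate a random genome with a given GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length Genome length in nt.
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the generator is a pure function of
#'   `(length, gc, seed)`.
#' @param id Sequence id.
#' @return Named character scalar (name = `id`).
#' @export
random_genome <- function(length, gc, seed, id = "genome") {
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1)
    stop("gc must lie strictly between 0 and 1")
  if (length < 1L) stop("length must be >= 1")
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  stats::setNames(seq, id)
}

#' Introduce random substitutions into a genome
#'
#' Each site is substituted independently with probability `sub_rate` to a
#' uniformly chosen different base, so expected nucleotide identity to the
#' input is `1 - sub_rate`.
#'
#' @param seq Input sequence.
#' @param sub_rate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param id Output sequence id.
#' @return Named character scalar.
#' @export
mutate_genome <- function(seq, sub_rate, seed, id = "mutant") {
  if (sub_rate < 0 || sub_rate >= 1) stop("sub_rate must be in [0, 1)")
  s <- as_seq_char(seq)
  out <- withr::with_seed(seed, {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(v)) < sub_rate)
    for (i in hit) {
      v[[i]] <- sample(setdiff(c("A", "C", "G", "T"), v[[i]]), 1L)
    }
    paste(v, collapse = "")
  })
  stats::setNames(out, id)
}

#' Plant a tandem repeat array into a sequence
#'
#' Inserts `copies` concatenated copies of `unit_seq` so that the array
#' begins at position `pos` of the returned sequence.  `variant_spec` is a
#' list of `list(copy, codon, replacement)` entries applied to individual
#' copies (codon coordinates are 1-based within the unit, which must then be
#' divisible by 3).
#'
#' @param seq Background sequence.
#' @param pos 1-based position at which the array starts in the output.
#' @param unit_seq Repeat unit (default [phage_repeat_unit()]).
#' @param copies Number of copies (>= 2).
#' @param variant_spec Per-copy codon replacements; default mimics a single
#'   AAA-to-CAG exchange on copy 2 ([default_repeat_variant()]).  Use
#'   `list()` for a perfect array.
#' @param boundary_guard If `TRUE` (default), the background bases flanking
#'   the array are adjusted (deterministically) so they do not continue the
#'   repeat period.  Without the guard a flanking base continues the period
#'   with probability 1/4 per side, in which case the maximal periodic
#'   region genuinely extends beyond the planted array and its boundary is
#'   unrecoverable by any detector.
#' @return List with `seq` (named character), and `truth`: a list recording
#'   `pos`, `start`, `end`, `unit`, `copies` and `variant_spec`.
#' @export
plant_tandem_array <- function(seq, pos, unit_seq = phage_repeat_unit(),
                               copies, variant_spec = default_repeat_variant(),
                               boundary_guard = TRUE) {
  s <- as_seq_char(seq)
  unit <- as_seq_char(unit_seq)
  if (copies < 2L) stop("copies must be >= 2 (a single unit is not an array)")
  if (pos < 1L || pos > nchar(s) + 1L) stop("pos outside sequence")
  if (length(variant_spec) && nchar(unit) %% 3L != 0L)
    stop("unit length must be divisible by 3 for codon-coordinate variants")
  units <- rep(unit, copies)
  for (v in variant_spec) {
    if (v$copy > copies) stop("variant copy index exceeds copy number")
    if (v$codon > nchar(unit) %/% 3L) stop("variant codon index outside unit")
    a <- (v$codon - 1L) * 3L + 1L
    substr(units[[v$copy]], a, a + 2L) <- v$replacement
  }
  array_seq <- paste(units, collapse = "")
  out <- paste0(substr(s, 1L, pos - 1L), array_seq,
                substr(s, pos, nchar(s)))
  if (boundary_guard) {
    p <- nchar(unit)
    a <- pos
    b <- pos + nchar(array_seq) - 1L
    next_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[[1L]]
    if (a > 1L && substr(out, a - 1L, a - 1L) == substr(out, a - 1L + p, a - 1L + p))
      substr(out, a - 1L, a - 1L) <- next_base(substr(out, a - 1L + p, a - 1L + p))
    if (b < nchar(out) && substr(out, b + 1L, b + 1L) == substr(out, b + 1L - p, b + 1L - p))
      substr(out, b + 1L, b + 1L) <- next_base(substr(out, b + 1L - p, b + 1L - p))
  }
  nm <- if (!is.null(names(seq))) names(seq) else "planted"
  list(
    seq = stats::setNames(out, nm),
    truth = list(pos = pos, start = pos,
                 end = pos + nchar(array_seq) - 1L,
                 unit = unit, copies = copies, variant_spec = variant_spec)
  )
}

#' Simulate paired-end reads from a genome
#'
#' Fragments start uniformly on the forward strand; insert sizes are normal
#' (clamped to `[read_len, genome length]`); mates are FR-oriented; per-base
#' substitution errors occur at `err_rate` (no indels, so planted truth stays
#' exact for repeat genotyping).
#'
#' @param genome Genome sequence.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (default 150, i.e. 2 x 150 bp libraries).
#' @param insert_mean,insert_sd Insert-size distribution.
#' @param err_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#' @return List with `r1`, `r2` (named character vectors) and `truth`
#'   (`data.frame(read_id, frag_start, frag_end, insert)`).
#' @export
simulate_reads <- function(genome, n_pairs, read_len = 150L,
                           insert_mean = 400L, insert_sd = 40L,
                           err_rate = 0.001, seed, out_prefix = NULL) {
  g <- as_seq_char(genome)
  L <- nchar(g)
  if (L < read_len) stop("genome shorter than read length")
  if (insert_mean < 2L * read_len)
    warning("insert_mean < 2 * read_len: mates will overlap")
  sim <- withr::with_seed(seed, {
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                     read_len), L)
    start <- vapply(ins, function(x) sample.int(L - x + 1L, 1L), integer(1))
    r1 <- substring(g, start, start + read_len - 1L)
    frag_end <- start + ins - 1L
    r2 <- vapply(seq_len(n_pairs), function(i)
      reverse_complement(substring(g, frag_end[[i]] - read_len + 1L,
                                   frag_end[[i]])), character(1))
    add_err <- function(reads) {
      vapply(reads, function(r) {
        v <- strsplit(r, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(v)) < err_rate)
        for (i in hit) v[[i]] <- sample(setdiff(c("A", "C", "G", "T"), v[[i]]), 1L)
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    if (err_rate > 0) {
      r1 <- add_err(r1)
      r2 <- add_err(r2)
    }
    list(r1 = r1, r2 = r2, start = start, end = frag_end, insert = ins)
  })
  ids <- sprintf("read%06d", seq_len(n_pairs))
  r1 <- stats::setNames(sim$r1, ids)
  r2 <- stats::setNames(sim$r2, ids)
  truth <- data.frame(read_id = ids, frag_start = sim$start,
                      frag_end = sim$end, insert = sim$insert,
                      stringsAsFactors = FALSE)
  if (!is.null(out_prefix)) {
    write_fastq(r1, paste0(out_prefix, "_R1.fastq"))
    write_fastq(r2, paste0(out_prefix, "_R2.fastq"))
  }
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- as_dna_set(reads)
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate a lifestyle-labelled domain-hit corpus
#'
#' Generates `n_temp` temperate and `n_vir` virulent genomes.  Each genome's
#' hit list mixes shared domains with its class-specific domains; every
#' class-specific domain occurs in at least one genome of its class.  With
#' probability `leakage` a class-specific domain additionally appears in one
#' opposite-class genome (and is then, by construction, no longer recoverable
#' as specific).  A few decoy hits above the usual 0.001 e-value cutoff are
#' included to exercise e-value filtering.
#'
#' @param n_temp,n_vir Genomes per class.
#' @param n_shared_domains Size of the shared (uninformative) domain pool.
#' @param n_specific_per_class Class-specific domains per lifestyle.
#' @param hits_per_genome Approximate hits per genome.
#' @param leakage Per-domain probability of appearing in one opposite-class
#'   genome, in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `hits` (`data.frame(genome_id, domain_id, evalue,
#'   bitscore)`), `labels` (named character vector,
#'   `temperate`/`virulent`) and `truth` (planted specific sets and leaked
#'   domains).
#' @export
simulate_domain_corpus <- function(n_temp, n_vir, n_shared_domains = 30L,
                                   n_specific_per_class = 5L,
                                   hits_per_genome = 20L, leakage = 0,
                                   seed) {
  if (n_specific_per_class < 1L)
    stop("n_specific_per_class must be >= 1 (corpus otherwise unclassifiable)")
  if (leakage < 0 || leakage >= 1) stop("leakage must be in [0, 1)")
  shared <- sprintf("SHR%03d", seq_len(n_shared_domains))
  temp_spec <- sprintf("TSP%03d", seq_len(n_specific_per_class))
  vir_spec <- sprintf("VSP%03d", seq_len(n_specific_per_class))
  ids <- c(sprintf("temp%03d", seq_len(n_temp)),
           sprintf("vir%03d", seq_len(n_vir)))
  labels <- stats::setNames(rep(c("temperate", "virulent"), c(n_temp, n_vir)), ids)

  res <- withr::with_seed(seed, {
    rows <- list()
    emit <- function(genome, domains, max_e = 1e-4) {
      data.frame(genome_id = genome, domain_id = domains,
                 evalue = stats::runif(length(domains), 1e-12, max_e),
                 bitscore = round(stats::runif(length(domains), 40, 300), 1),
                 stringsAsFactors = FALSE)
    }
    for (g in ids) {
      spec <- if (labels[[g]] == "temperate") temp_spec else vir_spec
      own <- spec[stats::runif(length(spec)) < 0.8]
      if (!length(own)) own <- sample(spec, 1L)
      n_shared_hits <- max(hits_per_genome - length(own), 1L)
      dom <- c(own, sample(shared, n_shared_hits, replace = TRUE))
      rows[[g]] <- emit(g, dom)
      ## decoy above-cutoff hit from the opposite class's pool
      decoy <- if (labels[[g]] == "temperate") vir_spec else temp_spec
      rows[[paste0(g, "_decoy")]] <- emit(g, sample(decoy, 1L), max_e = 1)
      rows[[paste0(g, "_decoy")]]$evalue <- stats::runif(1, 0.01, 1)
    }
    hits <- do.call(rbind, rows)
    ## shared domains are shared by definition: ensure each occurs in at
    ## least two genomes of each class (when the class has two), so that it
    ## can never masquerade as class-specific, not even under leave-one-out
    for (d in shared) {
      for (cls in c("temperate", "virulent")) {
        cls_ids <- ids[labels == cls]
        want <- min(2L, length(cls_ids))
        carriers <- unique(hits$genome_id[hits$genome_id %in% cls_ids &
                                          hits$domain_id == d &
                                          hits$evalue <= 0.001])
        if (length(carriers) < want) {
          add_to <- sample(setdiff(cls_ids, carriers),
                           want - length(carriers))
          for (g2 in add_to) hits <- rbind(hits, emit(g2, d))
        }
      }
    }
    ## guarantee each specific domain is present in >= 1 own-class genome
    for (d in temp_spec) {
      if (!any(hits$domain_id == d & hits$evalue <= 0.001))
        hits <- rbind(hits, emit(sample(ids[labels == "temperate"], 1L), d))
    }
    for (d in vir_spec) {
      if (!any(hits$domain_id == d & hits$evalue <= 0.001))
        hits <- rbind(hits, emit(sample(ids[labels == "virulent"], 1L), d))
    }
    ## leakage: specific domain also in one opposite-class genome
    leaked <- character()
    for (d in c(temp_spec, vir_spec)) {
      if (stats::runif(1) < leakage) {
        opp <- if (d %in% temp_spec) "virulent" else "temperate"
        hits <- rbind(hits, emit(sample(ids[labels == opp], 1L), d))
        leaked <- c(leaked, d)
      }
    }
    list(hits = hits, leaked = leaked)
  })
  hits <- res$hits
  rownames(hits) <- NULL
  list(hits = hits, labels = labels,
       truth = list(seed = seed, temperate_specific = temp_spec,
                    virulent_specific = vir_spec, shared = shared,
                    leaked = res$leaked))
}

#' Simulate a two-condition count table with planted fold changes
#'
#' Counts are negative-binomial (Poisson-gamma): per-gene baseline means are
#' log-normal, the infected-condition mean is the baseline times the planted
#' fold change, and `dispersion` is the NB dispersion (0 gives Poisson
#' noise).  Gene origin labels (`host`, `CGP3`, `phage`) emulate
#' transcript-origin partitioning of an infection time course.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition (default 2).
#' @param fold_changes Planted infected/uninfected fold change per gene
#'   (length `n_genes`).
#' @param dispersion NB dispersion (>= 0).
#' @param origin_labels Optional character vector of per-gene origins;
#'   defaults to sampling host/CGP3/phage at 85/5/10 percent.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix), `genes`
#'   (`data.frame(id, length, origin)`), `samples`
#'   (`data.frame(id, condition, replicate)`) and `truth`.
#' @export
simulate_count_table <- function(n_genes, n_reps = 2L, fold_changes,
                                 dispersion = 0.05, origin_labels = NULL,
                                 seed) {
  if (length(fold_changes) != n_genes)
    stop("fold_changes must have length n_genes")
  if (dispersion < 0) stop("dispersion must be >= 0")
  out <- withr::with_seed(seed, {
    base <- exp(stats::rnorm(n_genes, log(200), 1))
    lens <- sample(300:3000, n_genes, replace = TRUE)
    origins <- if (is.null(origin_labels)) {
      sample(c("host", "CGP3", "phage"), n_genes, replace = TRUE,
             prob = c(0.85, 0.05, 0.10))
    } else origin_labels
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    cols <- list()
    for (r in seq_len(n_reps)) cols[[paste0("uninfected_", r)]] <- draw(base)
    for (r in seq_len(n_reps)) cols[[paste0("infected_", r)]] <- draw(base * fold_changes)
    list(counts = do.call(cbind, cols), base = base, lens = lens,
         origins = origins)
  })
  counts <- out$counts
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  samples <- data.frame(
    id = colnames(counts),
    condition = rep(c("uninfected", "infected"), each = n_reps),
    replicate = rep(seq_len(n_reps), times = 2L),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(id = rownames(counts), length = out$lens,
                      origin = out$origins, stringsAsFactors = FALSE)
  list(counts = counts, genes = genes, samples = samples,
       truth = list(seed = seed, base_mean = out$base,
                    fold_changes = fold_changes))
}
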