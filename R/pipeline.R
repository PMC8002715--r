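## Single-entry demonstration pipeline: regenerates every synthetic input
## class and runs each analysis stage in dependency order, writing plain
## TSV/JSON outputs plus a manifest with checksums so a rerun can be
## audited for byte-identity.

PIPELINE_STAGES <- c("simulate", "stats", "jsd", "ani", "lifestyle",
                     "repeats", "variant", "rnaseq")

STAGE_DEPS <- list(
  simulate = character(),
  stats = "simulate", jsd = "simulate", ani = "simulate",
  lifestyle = "simulate", repeats = "simulate", variant = "simulate",
  rnaseq = "simulate"
)

#' Demonstration run configuration
#'
#' All stage parameters mirror the package defaults; genome sizes are kept
#' modest (kilobases) so the full demo runs in seconds while exercising
#' every stage.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param stages Stages to run (dependency order is enforced).
#' @return A `phagekit_config` list.
#' @export
demo_config <- function(out_dir, seed = 1L, stages = PIPELINE_STAGES) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    params = list(
      genome_len = 20000L, gc = 0.544,
      family_rates = c(0.01, 0.05, 0.20), family_n = 2L,
      k = 4L, strand = "both",
      ani_len = 8000L, ani_rates = c(0.02, 0.10), frag_len = 1020L,
      n_temp = 6L, n_vir = 6L,
      repeat_copies = 6L,
      n_genes = 200L, n_up = 10L, n_down = 10L
    )
  ), class = "phagekit_config")
}

validate_config <- function(config) {
  if (!is(config, "phagekit_config")) stop("not a phagekit_config")
  if (is.null(config$out_dir)) stop("config lacks out_dir")
  if (is.null(config$seed) || is.na(config$seed))
    stop("seed is mandatory for stochastic stages")
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (st in config$stages) {
    miss <- setdiff(STAGE_DEPS[[st]], config$stages)
    if (length(miss))
      stop("stage '", st, "' requires stage(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(config)
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_as), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order.  A stage failure
#' halts its dependents (status `skipped`) with a clear message; every
#' output file is listed in the returned manifest with its MD5 checksum,
#' and the whole run is deterministic given the config seed.
#'
#' @param config A `phagekit_config` (see [demo_config()]).
#' @return List with `report` (`data.frame(stage, status, message)`),
#'   `manifest` (`data.frame(stage, file, md5)`) and `config`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  seed <- config$seed
  out <- function(...) file.path(config$out_dir, ...)
  status <- stats::setNames(rep("pending", length(config$stages)),
                            config$stages)
  messages <- stats::setNames(rep("", length(config$stages)), config$stages)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[stage]] <<- data.frame(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  }
  env <- new.env()

  runners <- list(
    simulate = function() {
      focal <- random_genome(p$genome_len, p$gc, seed = seed, id = "focal")
      fam <- list(focal = unname(focal))
      labels <- character()
      for (r in p$family_rates) {
        for (i in seq_len(p$family_n)) {
          id <- sprintf("rate%.2f_%d", r, i)
          fam[[id]] <- unname(mutate_genome(focal, r, seed = seed + 1000L +
                                              round(1e4 * r) + i))
          labels[[id]] <- sprintf("rate%.2f", r)
        }
      }
      env$genomes <- unlist(fam)
      env$family_labels <- labels
      write_fasta(env$genomes, out("genomes.fasta"))

      base <- random_genome(p$ani_len, p$gc, seed = seed + 7L, id = "aniA")
      env$ani_genomes <- c(aniA = unname(base),
                           aniB = unname(mutate_genome(base, p$ani_rates[[1L]],
                                                       seed = seed + 8L)),
                           aniC = unname(random_genome(p$ani_len, p$gc,
                                                       seed = seed + 9L)))
      write_fasta(env$ani_genomes, out("ani_genomes.fasta"))

      bg <- random_genome(5000L, 0.5, seed = seed + 11L, id = "repeat_genome")
      pl <- plant_tandem_array(bg, pos = 2000L, copies = p$repeat_copies)
      env$repeat_genome <- pl$seq
      env$repeat_truth <- pl$truth
      write_fasta(pl$seq, out("repeat_genome.fasta"))

      env$corpus <- simulate_domain_corpus(p$n_temp, p$n_vir,
                                           seed = seed + 13L)
      write_tsv(env$corpus$hits, out("domain_hits.tsv"))

      fcs <- rep(1, p$n_genes)
      fcs[seq_len(p$n_up)] <- 4
      fcs[p$n_up + seq_len(p$n_down)] <- 0.25
      env$ct <- simulate_count_table(p$n_genes, fold_changes = fcs,
                                     seed = seed + 17L)
      write_tsv(data.frame(id = rownames(env$ct$counts), env$ct$counts,
                           check.names = FALSE), out("counts.tsv"))
      write_tsv(env$ct$genes, out("genes.tsv"))
      write_tsv(env$ct$samples, out("samples.tsv"))
      jsonlite::write_json(list(seed = seed, repeat_truth = env$repeat_truth[
        c("pos", "start", "end", "unit", "copies")]),
        out("truth.json"), auto_unbox = TRUE, digits = NA)
      note("simulate", out(c("genomes.fasta", "ani_genomes.fasta",
                             "repeat_genome.fasta", "domain_hits.tsv",
                             "counts.tsv", "genes.tsv", "samples.tsv",
                             "truth.json")))
    },
    stats = function() {
      write_tsv(genome_stats(env$genomes), out("stats.tsv"))
      note("stats", out("stats.tsv"))
    },
    jsd = function() {
      dm <- distance_matrix(kmer_profiles(env$genomes, k = p$k,
                                          strand = p$strand))
      write_matrix_tsv(dm, out("jsd_matrix.tsv"), out("jsd_long.tsv"))
      gs <- group_summary(dm, "focal", env$family_labels)
      write_tsv(gs, out("jsd_groups.tsv"))
      note("jsd", out(c("jsd_matrix.tsv", "jsd_long.tsv", "jsd_groups.tsv")))
    },
    ani = function() {
      am <- ani_matrix(env$ani_genomes, frag_len = p$frag_len)
      write_matrix_tsv(am, out("ani_matrix.tsv"))
      jsonlite::write_json(list(leaf_order = am$linkage_order,
                                merge = am$hclust$merge,
                                height = am$hclust$height),
                           out("ani_linkage.json"), digits = NA)
      note("ani", out(c("ani_matrix.tsv", "ani_linkage.json")))
    },
    lifestyle = function() {
      model <- build_model(env$corpus$hits, env$corpus$labels)
      write_lifestyle_model(model, out("lifestyle_model.json"))
      cv <- evaluate_loocv(env$corpus$hits, env$corpus$labels)
      write_tsv(cv$predictions, out("lifestyle_loocv.tsv"))
      note("lifestyle", out(c("lifestyle_model.json", "lifestyle_loocv.tsv")))
    },
    repeats = function() {
      arr <- detect_tandem_arrays(env$repeat_genome)
      write_tsv(arr[, setdiff(names(arr), "variants")], out("repeats.tsv"))
      g <- env$repeat_genome
      tr <- env$repeat_truth
      lf <- substr(g, tr$start - 30L, tr$start - 1L)
      rf <- substr(g, tr$end + 1L, tr$end + 30L)
      amp <- stats::setNames(
        vapply(c(4L, 6L, 8L), function(n)
          paste0(lf, paste(rep(tr$unit, n), collapse = ""), rf),
          character(1)),
        paste0("amplicon_", c(4L, 6L, 8L)))
      gt <- genotype_copy_number(amp, lf, rf, nchar(tr$unit))
      write_tsv(gt$calls, out("repeat_genotypes.tsv"))
      note("repeats", out(c("repeats.tsv", "repeat_genotypes.tsv")))
    },
    variant = function() {
      cds <- random_cds(400L, seed = seed + 23L)
      gene <- new_gene_model("demo_gene", 101L, 100L + nchar(cds), "+",
                             cds, seqid = "demo_ref")
      calls <- data.frame(ref_id = "demo_ref",
                          genome_pos = c(101L + 1048L, 101L + 1021L, 50L),
                          ref_base = substring(cds, c(1049L, 1022L, 1L),
                                               c(1049L, 1022L, 1L)),
                          alt_base = "", stringsAsFactors = FALSE)
      calls$ref_base[3L] <- "A"
      calls$alt_base <- vapply(calls$ref_base, function(b)
        setdiff(c("A", "C", "G", "T"), b)[[1L]], character(1))
      write_tsv(summarize_snps(calls, gene), out("snp_summary.tsv"))
      note("variant", out("snp_summary.tsv"))
    },
    rnaseq = function() {
      sm <- summarize_rnaseq(env$ct$counts, env$ct$genes, env$ct$samples,
                             baseline = "uninfected")
      write_tsv(as.data.frame(sm$tpm), out("tpm.tsv"), rownames_as = "id")
      write_tsv(as.data.frame(sm$origin_fractions), out("origin_fractions.tsv"),
                rownames_as = "origin")
      write_tsv(sm$fold_changes, out("fold_changes.tsv"), rownames_as = "id")
      write_tsv(as.data.frame(sm$correlation), out("correlation.tsv"),
                rownames_as = "sample")
      note("rnaseq", out(c("tpm.tsv", "origin_fractions.tsv",
                           "fold_changes.tsv", "correlation.tsv")))
    }
  )

  for (st in PIPELINE_STAGES) {
    if (!st %in% config$stages) next
    deps <- STAGE_DEPS[[st]]
    failed_dep <- deps[status[deps] %in% c("failed", "skipped")]
    if (length(failed_dep)) {
      status[[st]] <- "skipped"
      messages[[st]] <- paste("dependency failed:",
                              paste(failed_dep, collapse = ", "))
      next
    }
    res <- tryCatch({
      runners[[st]]()
      "ok"
    }, error = function(e) conditionMessage(e))
    if (identical(res, "ok")) {
      status[[st]] <- "ok"
    } else {
      status[[st]] <- "failed"
      messages[[st]] <- res
    }
  }
  report <- data.frame(stage = names(status), status = unname(status),
                       message = unname(messages), stringsAsFactors = FALSE)
  report <- report[report$status != "pending", , drop = FALSE]
  manifest <- if (length(manifest)) do.call(rbind, unname(manifest)) else
    data.frame(stage = character(), file = character(), md5 = character())
  rownames(manifest) <- NULL
  write_tsv(report, file.path(config$out_dir, "report.tsv"))
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  list(report = report, manifest = manifest, config = config)
}

#' Random in-frame CDS without internal stops
#'
#' Starts with ATG, ends with TAA, interior codons drawn uniformly from the
#' 61 sense codons.
#'
#' @param n_codons Total codons including start and stop.
#' @param seed Integer seed.
#' @return Character scalar of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed) {
  stopifnot(n_codons >= 3L)
  codons <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, {
    paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
          collapse = "")
  })
}
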