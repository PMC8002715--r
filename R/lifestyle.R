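## Domain-count lifestyle classification for actinobacteriophages.  A
## labelled corpus of conserved-domain hits (e.g. RPS-TBLASTN vs CDD,
## produced upstream) is split by known lifestyle; domains occurring
## exclusively in one class form that class's specific set; a new genome is
## labelled by whichever specific set collects more of its hits.

.check_hits <- function(hits) {
  need <- c("genome_id", "domain_id", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    stop("evalues must be finite and >= 0")
  if (any(!nzchar(hits$domain_id))) stop("empty domain_id")
  invisible(hits)
}

#' Learn lifestyle-specific domain sets from a labelled corpus
#'
#' After e-value filtering, a domain is temperate-specific when it occurs in
#' at least one temperate genome and in at most `max_other_class_genomes`
#' virulent genomes (default 0: absolute exclusivity), and symmetrically for
#' virulent-specific domains.  The two sets are disjoint by construction.
#'
#' @param hits `data.frame(genome_id, domain_id, evalue, bitscore, ...)`.
#' @param labels Named character vector mapping every corpus genome id to
#'   `"temperate"` or `"virulent"`.
#' @param evalue_cutoff Hits above this e-value are ignored (default 0.001).
#' @param max_other_class_genomes Relaxation knob: number of opposite-class
#'   genomes a domain may appear in and still count as specific.
#' @return Object of class `LifestyleModel`: list with `temperate_specific`,
#'   `virulent_specific` (sorted character vectors), `corpus_summary` and
#'   the parameters used.
#' @export
build_model <- function(hits, labels, evalue_cutoff = 0.001,
                        max_other_class_genomes = 0L) {
  .check_hits(hits)
  if (!all(unique(labels) %in% c("temperate", "virulent")))
    stop("labels must be 'temperate' or 'virulent'")
  if (length(unique(labels)) < 2L)
    stop("corpus must contain both lifestyles")
  unlabeled <- setdiff(unique(hits$genome_id), names(labels))
  if (length(unlabeled))
    stop("unlabelled genomes in corpus: ", paste(unlabeled, collapse = ", "))
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  h$label <- labels[h$genome_id]
  ## genomes (not occurrences) per class for each domain
  gd <- unique(h[, c("domain_id", "genome_id", "label")])
  n_temp <- table(factor(gd$domain_id[gd$label == "temperate"]))
  n_vir <- table(factor(gd$domain_id[gd$label == "virulent"]))
  doms <- unique(gd$domain_id)
  t_cnt <- stats::setNames(rep(0L, length(doms)), doms)
  v_cnt <- t_cnt
  t_cnt[names(n_temp)] <- as.integer(n_temp)
  v_cnt[names(n_vir)] <- as.integer(n_vir)
  temperate_specific <- sort(doms[t_cnt >= 1L & v_cnt <= max_other_class_genomes])
  virulent_specific <- sort(doms[v_cnt >= 1L & t_cnt <= max_other_class_genomes])
  overlap <- intersect(temperate_specific, virulent_specific)
  temperate_specific <- setdiff(temperate_specific, overlap)
  virulent_specific <- setdiff(virulent_specific, overlap)
  stopifnot(!length(intersect(temperate_specific, virulent_specific)))
  structure(list(
    temperate_specific = temperate_specific,
    virulent_specific = virulent_specific,
    corpus_summary = list(
      n_genomes = table(labels[unique(h$genome_id)]),
      n_domains = length(doms)),
    evalue_cutoff = evalue_cutoff,
    max_other_class_genomes = max_other_class_genomes
  ), class = "LifestyleModel")
}

#' @export
print.LifestyleModel <- function(x, ...) {
  cat(sprintf("LifestyleModel: %d temperate-specific, %d virulent-specific domains\n",
              length(x$temperate_specific), length(x$virulent_specific)))
  invisible(x)
}

#' Classify a genome's lifestyle from its domain hits
#'
#' Hits passing the e-value cutoff are counted against each specific set;
#' the label is whichever set collects more, `"ambiguous"` on a tie (counts
#' 0/0 included).  `count_mode = "occurrences"` counts every hit (the
#' default reading of total mapped domain counts); `"distinct"` counts each
#' domain once.
#'
#' @param hits Hit table for one genome (or several; counted per
#'   `genome_id`).
#' @param model A `LifestyleModel`.
#' @param evalue_cutoff E-value filter applied before counting.
#' @param count_mode `"occurrences"` or `"distinct"`.
#' @param genome_id Optional ids to predict for; genomes among them without
#'   any hit get counts 0/0 and label `"ambiguous"`.  Defaults to the ids
#'   present in `hits`.
#' @return `data.frame(genome_id, temperate_count, virulent_count, label)`.
#' @export
classify <- function(hits, model, evalue_cutoff = 0.001,
                     count_mode = c("occurrences", "distinct"),
                     genome_id = NULL) {
  count_mode <- match.arg(count_mode)
  stopifnot(is(model, "LifestyleModel"))
  if (is.null(genome_id)) genome_id <- unique(hits$genome_id)
  if (!length(genome_id)) {
    return(data.frame(genome_id = character(), temperate_count = integer(),
                      virulent_count = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  if (nrow(hits)) .check_hits(hits)
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  out <- lapply(genome_id, function(g) {
    hg <- h[h$genome_id == g, , drop = FALSE]
    dom <- hg$domain_id
    if (count_mode == "distinct") dom <- unique(dom)
    tc <- sum(dom %in% model$temperate_specific)
    vc <- sum(dom %in% model$virulent_specific)
    data.frame(genome_id = g, temperate_count = tc, virulent_count = vc,
               label = if (tc > vc) "temperate"
                       else if (vc > tc) "virulent" else "ambiguous",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leave-one-out cross-validation of the lifestyle classifier
#'
#' For each corpus genome, the model is rebuilt without it and the held-out
#' genome is classified.  Ambiguous predictions (tied counts) contribute
#' 1/2 to the accuracy -- the expected accuracy of resolving the tie at
#' random -- so the reported accuracy stays deterministic while an
#' uninformative corpus (e.g. permuted labels) scores ~0.5 rather than 0.
#' A class represented by a single genome cannot be held out (the remaining
#' corpus would be single-class); such genomes are skipped with a warning.
#'
#' @inheritParams build_model
#' @param count_mode Passed to [classify()].
#' @return List with `accuracy`, `confusion` (true x predicted table) and
#'   `predictions`.
#' @export
evaluate_loocv <- function(hits, labels, evalue_cutoff = 0.001,
                           max_other_class_genomes = 0L,
                           count_mode = "occurrences") {
  .check_hits(hits)
  ids <- names(labels)
  class_sizes <- table(labels)
  preds <- list()
  for (g in ids) {
    if (class_sizes[[labels[[g]]]] < 2L) {
      warning("skipping ", g, ": only genome of class ", labels[[g]])
      next
    }
    train <- hits[hits$genome_id != g, , drop = FALSE]
    m <- build_model(train, labels[names(labels) != g],
                     evalue_cutoff = evalue_cutoff,
                     max_other_class_genomes = max_other_class_genomes)
    test <- hits[hits$genome_id == g, , drop = FALSE]
    p <- classify(test, m, evalue_cutoff = evalue_cutoff,
                  count_mode = count_mode, genome_id = g)
    p$true <- labels[[g]]
    preds[[g]] <- p
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  confusion <- table(true = predictions$true,
                     predicted = factor(predictions$label,
                                        levels = c("temperate", "virulent",
                                                   "ambiguous")))
  list(accuracy = mean(ifelse(predictions$label == "ambiguous", 0.5,
                              predictions$label == predictions$true)),
       confusion = confusion, predictions = predictions)
}

#' Read a domain-hit table from TSV
#'
#' Expects columns `genome_id`, `domain_id`, `evalue` and optionally
#' `bitscore`, `qstart`, `qend`, `strand` (a superset of BLAST tabular
#' output after column mapping).
#'
#' @param path TSV path.
#' @return Hit `data.frame`.
#' @export
read_domain_hits <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .check_hits(h)
}

#' Serialize / restore a lifestyle model as JSON
#'
#' @param model A `LifestyleModel`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `LifestyleModel` (read).
#' @export
write_lifestyle_model <- function(model, path) {
  jsonlite::write_json(list(
    temperate_specific = model$temperate_specific,
    virulent_specific = model$virulent_specific,
    evalue_cutoff = model$evalue_cutoff,
    max_other_class_genomes = model$max_other_class_genomes
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lifestyle_model
#' @export
read_lifestyle_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    temperate_specific = as.character(x$temperate_specific),
    virulent_specific = as.character(x$virulent_specific),
    corpus_summary = NULL,
    evalue_cutoff = x$evalue_cutoff,
    max_other_class_genomes = x$max_other_class_genomes
  ), class = "LifestyleModel")
}
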