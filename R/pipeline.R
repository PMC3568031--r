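expand_gene_candidates <- function(recurrence, per_sample) {
  pooled <- pool_samples(per_sample)
  gl <- recurrence$gene_level
  if (nrow(gl) == 0) {
    out <- data.frame(key = character(), gene = character(),
                      n_carriers = integer())
    out$carriers <- list()
    return(out)
  }
  rows <- lapply(seq_len(nrow(gl)), function(i) {
    keys <- gl$keys[[i]]
    carrier_by_key <- lapply(keys, function(k)
      unique(pooled$sample_id[pooled$key == k]))
    out <- data.frame(key = keys, gene = gl$gene[[i]],
                      n_carriers = lengths(carrier_by_key),
                      stringsAsFactors = FALSE)
    out$carriers <- carrier_by_key
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

score_candidates <- function(candidates, variants, alignments = NULL,
                             model = grantham_model()) {
  n <- nrow(candidates)
  candidates$protein <- variants$protein[match(candidates$key, variants$key)]
  pc <- parse_protein_change(candidates$protein)
  candidates$grantham <- ifelse(
    !is.na(pc$aa_from) & pc$aa_from != pc$aa_to,
    mapply(function(a, b) if (is.na(a)) NA_real_ else
      grantham_distance(a, b, model), pc$aa_from, pc$aa_to),
    NA_real_)
  candidates$conservation <- rep(NA_real_, n)
  if (!is.null(alignments)) {
    for (i in seq_len(n)) {
      g <- candidates$gene[[i]]
      if (!is.na(g) && g %in% names(alignments) && !is.na(pc$residue[[i]])) {
        candidates$conservation[[i]] <-
          conservation_fraction(alignments[[g]], pc$residue[[i]])
      }
    }
  }
  candidates
}

#' Run the full prioritization pipeline
#'
#' Cascade -> recurrence -> trio/control/confirmation validation -> impact
#' scoring and ranking, with an optional gene-refocus pass that re-examines
#' named genes in the pre-novelty-filter data (rescuing variants a
#' position-only database collation removed).
#'
#' @param cohort A [variant_cohort()] holding probands and parents.
#' @param trios Trio table ([trio_table()] / [read_pedigree()]).
#' @param db Known-variant database.
#' @param genes Expression gene set.
#' @param controls Control-cohort genotype table.
#' @param oracle Confirmation oracle.
#' @param match_mode Novelty matching semantics.
#' @param min_carriers Recurrence threshold (default 4).
#' @param keep_classes Consequence classes retained.
#' @param level Candidate definition: `"gene"` (default; any variant of a
#'   gene shared by `min_carriers` probands) or `"variant"` (the identical
#'   variant shared).
#' @param refocus_genes Genes to re-examine ignoring the novelty filter.
#' @param alignments Optional named list (gene -> [homolog_alignment()])
#'   enabling conservation scoring.
#' @param model Grantham model for substitution scoring.
#' @param probands Probands to analyse (default: trio probands with data in
#'   the cohort).
#' @return A `denovo_report`: cascade `report`, ranked `candidates` (with
#'   trio statuses, control counts, confirmation, scores and prevalence),
#'   `removed` (every excluded candidate with its reason), `recurrence`,
#'   `survivors`, `refocus_recovered`, and the `inputs` needed to extend the
#'   cohort later.
#' @export
run_pipeline <- function(cohort, trios, db, genes, controls, oracle,
                         match_mode = c("allele_aware", "position_only"),
                         min_carriers = 4, keep_classes = nsss_classes(),
                         level = c("gene", "variant"), refocus_genes = NULL,
                         alignments = NULL, model = grantham_model(),
                         probands = NULL) {
  match_mode <- match.arg(match_mode)
  level <- match.arg(level)
  if (is.null(probands))
    probands <- intersect(trios$proband_id, cohort$samples)
  if (length(probands) == 0) stop("no probands with data in the cohort")

  casc <- run_cascade(cohort, db, genes, match_mode, keep_classes, probands)
  survivors <- casc$survivors

  refocus_recovered <- list()
  if (length(refocus_genes)) {
    prefilter <- per_sample_variants(cohort, probands)
    for (g in refocus_genes) {
      ref <- gene_refocus(prefilter, g, keep_classes)
      ref <- lapply(ref, function(v) filter_expressed(v, genes))
      gained <- mapply(function(r, s) r[!r$key %in% s$key, , drop = FALSE],
                       ref, survivors[probands], SIMPLIFY = FALSE)
      refocus_recovered[[g]] <- gained
      survivors <- mapply(function(s, r) rbind(s, r), survivors[probands],
                          gained, SIMPLIFY = FALSE)
    }
  }

  rec <- shared_variants(survivors, min_carriers)
  candidates <- if (level == "gene") expand_gene_candidates(rec, survivors)
    else rec$variant_level[c("key", "gene", "n_carriers", "carriers")]

  val <- exclude_non_causal(candidates, trios, cohort$genotypes, controls,
                            oracle)
  retained <- score_candidates(val$retained, cohort$variants, alignments,
                               model)
  retained <- rank_candidates(retained)
  if (nrow(retained)) {
    prev <- lapply(lengths(retained$carriers), prevalence,
                   cohort_size = length(probands))
    retained$prevalence_percent <- vapply(prev, `[[`, 1, "percent")
    retained$prevalence_fraction <- vapply(prev, `[[`, 1, "fraction")
  } else {
    retained$prevalence_percent <- numeric(0)
    retained$prevalence_fraction <- numeric(0)
  }

  # conservation of records: every variant carried by any proband ends up
  # exactly once in {retained candidates} + {removed with reason}: cascade
  # removals, sub-threshold recurrence, and validation exclusions
  g <- cohort$genotypes
  carried_keys <- unique(g$key[g$sample_id %in% probands &
                                 g$zygosity %in% c("het", "hom_alt")])
  all_keys <- unique(unlist(lapply(survivors, function(v) v$key)))
  casc_removed_keys <- setdiff(carried_keys, all_keys)
  cv <- cohort$variants[match(casc_removed_keys, cohort$variants$key), ,
                        drop = FALSE]
  casc_reason <- ifelse(is_known(cv, db, match_mode), "registered_known",
                        ifelse(!cv$consequence %in% keep_classes,
                               "consequence_filtered", "not_brain_expressed"))
  cand_keys <- unique(c(retained$key, val$removed$key))
  sub <- setdiff(all_keys, cand_keys)
  removed <- val$removed
  if (length(sub)) {
    pooled <- pool_samples(survivors)
    extra <- data.frame(key = sub,
                        gene = pooled$gene[match(sub, pooled$key)],
                        n_carriers = vapply(sub, function(k)
                          length(unique(pooled$sample_id[pooled$key == k])),
                          1L),
                        reason = "below_min_carriers",
                        stringsAsFactors = FALSE)
    extra$carriers <- lapply(sub, function(k)
      unique(pooled$sample_id[pooled$key == k]))
    removed <- rbind(removed[c("key", "gene", "n_carriers", "reason",
                               "carriers")],
                     extra[c("key", "gene", "n_carriers", "reason",
                             "carriers")])
  } else {
    removed <- removed[c("key", "gene", "n_carriers", "reason", "carriers")]
  }
  if (nrow(cv)) {
    casc_removed <- data.frame(key = cv$key, gene = cv$gene,
                               n_carriers = NA_integer_,
                               reason = casc_reason, stringsAsFactors = FALSE)
    casc_removed$carriers <- rep(list(character(0)), nrow(cv))
    removed <- rbind(removed, casc_removed)
  }
  rownames(removed) <- NULL

  structure(list(report = casc$report, candidates = retained,
                 removed = removed, recurrence = rec, survivors = survivors,
                 refocus_recovered = refocus_recovered,
                 probands = probands,
                 inputs = list(cohort = cohort, trios = trios, db = db,
                               genes = genes, controls = controls,
                               oracle = oracle, alignments = alignments,
                               model = model),
                 settings = list(match_mode = match_mode,
                                 min_carriers = min_carriers,
                                 keep_classes = keep_classes,
                                 level = level,
                                 refocus_genes = refocus_genes)),
            class = "denovo_report")
}

#' @export
print.denovo_report <- function(x, ...) {
  cat("<denovo_report> ", length(x$probands), " probands, match_mode=",
      x$settings$match_mode, ", min_carriers=", x$settings$min_carriers,
      "\n", sep = "")
  if (nrow(x$candidates) == 0) {
    cat("no surviving candidates\n")
  } else {
    for (i in seq_len(nrow(x$candidates))) {
      c_ <- x$candidates[i, ]
      cat(sprintf("  %s %s (%s): %d carrier(s) [%s], de novo in %d, %s, %d%%\n",
                  c_$gene, ifelse(is.na(c_$protein), c_$key, c_$protein),
                  c_$key, length(c_$carriers[[1]]),
                  paste(c_$carriers[[1]], collapse = ", "), c_$n_de_novo,
                  ifelse(c_$validated, "validated de novo", "unvalidated"),
                  c_$prevalence_percent))
    }
  }
  cat("  removed:", nrow(x$removed), "candidate record(s)\n")
  invisible(x)
}

#' Extend a report with additional genotyped individuals
#'
#' Recomputes carrier lists, trio validation, confirmation and prevalence
#' for the existing candidate loci over an enlarged proband cohort — the
#' move that takes targeted re-sequencing of new patients at the candidate
#' sites and folds it into the discovery cohort.
#'
#' @param report A `denovo_report` from [run_pipeline()].
#' @param genotypes Genotype table for the added samples (candidate loci
#'   only is enough); may be empty.
#' @param trios Trio rows for added probands (parent availability included).
#' @param probands Labels of the added probands (default: the probands of
#'   `trios`).
#' @return An updated `denovo_report` over the extended cohort.
#' @export
extend_cohort <- function(report, genotypes, trios = NULL, probands = NULL) {
  stopifnot(inherits(report, "denovo_report"))
  inp <- report$inputs
  if (is.null(probands))
    probands <- if (!is.null(trios)) trios$proband_id else
      unique(genotypes$sample_id)
  clash <- intersect(probands, report$probands)
  if (length(clash))
    stop("sample id collision with existing cohort: ",
         paste(clash, collapse = ", "))
  all_probands <- c(report$probands, probands)
  all_trios <- if (is.null(trios)) inp$trios else rbind(inp$trios, trios)
  all_gt <- rbind(inp$cohort$genotypes[c("sample_id", "key", "zygosity")],
                  genotypes[c("sample_id", "key", "zygosity")])

  validation_reasons <- c("confirmation_failed", "present_in_controls",
                          "inherited_in_all_carriers")
  cand_keys <- unique(c(report$candidates$key, report$removed$key[
    report$removed$reason %in% validation_reasons]))
  variants <- inp$cohort$variants
  carriers <- lapply(cand_keys, function(k)
    unique(all_gt$sample_id[all_gt$key == k & all_gt$sample_id %in%
                              all_probands &
                              all_gt$zygosity %in% c("het", "hom_alt")]))
  keep <- lengths(carriers) > 0
  candidates <- data.frame(key = cand_keys[keep],
                           gene = variants$gene[match(cand_keys[keep],
                                                      variants$key)],
                           n_carriers = lengths(carriers)[keep],
                           stringsAsFactors = FALSE)
  candidates$carriers <- carriers[keep]

  val <- exclude_non_causal(candidates, all_trios, all_gt, inp$controls,
                            inp$oracle)
  retained <- score_candidates(val$retained, variants, inp$alignments,
                               inp$model)
  retained <- rank_candidates(retained)
  if (nrow(retained)) {
    prev <- lapply(lengths(retained$carriers), prevalence,
                   cohort_size = length(all_probands))
    retained$prevalence_percent <- vapply(prev, `[[`, 1, "percent")
    retained$prevalence_fraction <- vapply(prev, `[[`, 1, "fraction")
  }

  report$candidates <- retained
  report$removed <- rbind(
    val$removed[c("key", "gene", "n_carriers", "reason", "carriers")],
    report$removed[!report$removed$reason %in% validation_reasons,
                   c("key", "gene", "n_carriers", "reason", "carriers")])
  report$probands <- all_probands
  report$inputs$trios <- all_trios
  report$inputs$cohort$genotypes <- all_gt
  report$inputs$cohort$samples <- unique(c(inp$cohort$samples, probands,
                                           genotypes$sample_id))
  report
}

#' Read a pipeline configuration file (YAML)
#'
#' Paths and settings for a file-based pipeline run:
#' `variants`/`dialect`, `pedigree`, `known_db`, `gene_set`, `controls`,
#' `oracle`, and optional `match_mode`, `min_carriers`, `level`,
#' `refocus_genes`.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  needed <- c("variants", "pedigree", "known_db", "gene_set", "controls",
              "oracle")
  missing_keys <- setdiff(needed, names(cfg))
  if (length(missing_keys))
    stop("pipeline config is missing: ", paste(missing_keys, collapse = ", "))
  cfg
}

#' Run the pipeline from a configuration
#'
#' @param config A list from [read_pipeline_config()].
#' @return A `denovo_report`.
#' @export
run_pipeline_from_config <- function(config) {
  cohort <- read_variant_table(config$variants,
                               config$dialect %||% "annotated_tsv")
  run_pipeline(cohort,
               trios = read_pedigree(config$pedigree),
               db = read_known_db(config$known_db),
               genes = read_gene_set(config$gene_set),
               controls = read_genotype_table(config$controls),
               oracle = read_confirmation_oracle(config$oracle),
               match_mode = config$match_mode %||% "allele_aware",
               min_carriers = config$min_carriers %||% 4,
               level = config$level %||% "gene",
               refocus_genes = config$refocus_genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
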