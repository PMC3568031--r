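#' Is a variant registered in the known-variant database?
#'
#' Two matching semantics are supported. `allele_aware` (the default
#' throughout the package) calls a variant known only when a database record
#' shares chromosome, position, ref and alt. `position_only` calls it known
#' when any record merely shares chromosome and position — the collation mode
#' that silently discards a novel substitution whenever a *different* allele
#' at the same site has been registered (the D801N/D801Y pitfall).
#'
#' @param variants A variant table.
#' @param db A known-variant table ([known_db()]).
#' @param match_mode `"allele_aware"` or `"position_only"`.
#' @return Logical vector, one element per variant row.
#' @export
is_known <- function(variants, db,
                     match_mode = c("allele_aware", "position_only")) {
  match_mode <- match.arg(match_mode)
  if (match_mode == "allele_aware") {
    variants$key %in% db$key
  } else {
    paste(variants$chrom, variants$pos) %in% paste(db$chrom, db$pos)
  }
}

#' Novelty filter: drop database-registered variants
#'
#' @inheritParams is_known
#' @return The subset of `variants` not matched in `db`, input order kept.
#' @export
filter_novel <- function(variants, db,
                         match_mode = c("allele_aware", "position_only")) {
  variants[!is_known(variants, db, match_mode), , drop = FALSE]
}

#' Consequence filter: keep protein-altering / splice-site classes
#'
#' @param variants A variant table.
#' @param keep_classes Consequence classes to retain; defaults to the NS/SS
#'   set ([nsss_classes()]).
#' @return Filtered variant table, input order kept.
#' @export
filter_consequence <- function(variants, keep_classes = nsss_classes()) {
  bad <- setdiff(keep_classes, consequence_classes())
  if (length(bad))
    stop("keep_classes outside the consequence vocabulary: ",
         paste(bad, collapse = ", "))
  variants[variants$consequence %in% keep_classes, , drop = FALSE]
}

#' Expression filter: keep variants in a gene set
#'
#' Gene symbols are compared case-insensitively. Variants without a gene
#' symbol never pass.
#'
#' @param variants A variant table.
#' @param genes A [gene_set()] (or character vector of symbols).
#' @return Filtered variant table, input order kept.
#' @export
filter_expressed <- function(variants, genes) {
  keep <- !is.na(variants$gene) & toupper(variants$gene) %in% toupper(genes)
  variants[keep, , drop = FALSE]
}

stage_counts <- function(v) {
  snv <- v[!is_indel(v), , drop = FALSE]
  c(variants = nrow(snv),
    genes = length(unique(snv$gene[!is.na(snv$gene)])),
    indels = sum(is_indel(v)))
}

#' Run the sequential filter cascade over a cohort
#'
#' Applies novelty, consequence and expression filters in order to each
#' sample's carried variants and counts survivors at every stage boundary.
#' SNVs and indels are tallied separately; gene counts are distinct symbols
#' among that stage's SNVs. The report carries per-sample rows plus two
#' cohort rows: `TOTAL_SUM` (column sums over samples) and `TOTAL_UNIQUE`
#' (each distinct variant key / gene counted once across the cohort).
#'
#' @param cohort A [variant_cohort()].
#' @param db Known-variant table.
#' @param genes Expression gene set.
#' @param match_mode Novelty matching semantics (see [is_known()]).
#' @param keep_classes Consequence classes retained.
#' @param samples Samples to run (default: all cohort samples).
#' @return A list with `survivors` (named list of per-sample variant tables
#'   after all three filters) and `report` (the stage-count `data.frame`).
#' @export
run_cascade <- function(cohort, db, genes,
                        match_mode = c("allele_aware", "position_only"),
                        keep_classes = nsss_classes(),
                        samples = cohort$samples) {
  match_mode <- match.arg(match_mode)
  if (length(samples) < 1) stop("cascade needs at least one sample")
  stages <- list()
  survivors <- list()
  rows <- lapply(samples, function(s) {
    total <- carried_variants(cohort, s)
    novel <- filter_novel(total, db, match_mode)
    nsss <- filter_consequence(novel, keep_classes)
    brain <- filter_expressed(nsss, genes)
    stages[[s]] <<- list(total = total, novel = novel, nsss = nsss,
                         brain = brain)
    survivors[[s]] <<- brain
    ct <- lapply(list(total, novel, nsss, brain), stage_counts)
    data.frame(sample_id = s,
               n_total_variants = ct[[1]][["variants"]],
               n_total_genes = ct[[1]][["genes"]],
               n_total_indels = ct[[1]][["indels"]],
               n_novel_variants = ct[[2]][["variants"]],
               n_novel_indels = ct[[2]][["indels"]],
               n_novel_nsss_variants = ct[[3]][["variants"]],
               n_novel_nsss_genes = ct[[3]][["genes"]],
               n_novel_nsss_indels = ct[[3]][["indels"]],
               n_brain_variants = ct[[4]][["variants"]],
               n_brain_genes = ct[[4]][["genes"]],
               n_brain_indels = ct[[4]][["indels"]],
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  num <- names(report)[-1]
  sums <- c(list(sample_id = "TOTAL_SUM"),
            as.list(colSums(report[, num, drop = FALSE])))
  uniq_counts <- function(stage, what) {
    pooled <- do.call(rbind, lapply(stages, `[[`, stage))
    pooled <- pooled[!duplicated(pooled$key), , drop = FALSE]
    stage_counts(pooled)[[what]]
  }
  uniq <- list(sample_id = "TOTAL_UNIQUE")
  for (st in c("total", "novel", "nsss", "brain")) {
    pref <- switch(st, total = "n_total", novel = "n_novel",
                   nsss = "n_novel_nsss", brain = "n_brain")
    uniq[[paste0(pref, "_variants")]] <- uniq_counts(st, "variants")
    uniq[[paste0(pref, "_indels")]] <- uniq_counts(st, "indels")
    if (pref != "n_novel")
      uniq[[paste0(pref, "_genes")]] <- uniq_counts(st, "genes")
  }
  report <- rbind(report, as.data.frame(sums, stringsAsFactors = FALSE),
                  as.data.frame(uniq, stringsAsFactors = FALSE)[names(report)])
  rownames(report) <- NULL
  check_cascade_monotonic(report)
  list(survivors = survivors, report = report, match_mode = match_mode)
}

check_cascade_monotonic <- function(report) {
  ok <- with(report, n_total_variants >= n_novel_variants &
               n_novel_variants >= n_novel_nsss_variants &
               n_novel_nsss_variants >= n_brain_variants &
               n_novel_nsss_genes >= n_brain_genes &
               n_novel_nsss_genes <= n_novel_nsss_variants &
               n_brain_genes <= n_brain_variants)
  if (!all(ok))
    stop("cascade report violates stage monotonicity for sample(s): ",
         paste(report$sample_id[!ok], collapse = ", "))
  invisible(report)
}

#' Write a cascade report as TSV
#'
#' @param report The `report` element of [run_cascade()]'s result.
#' @param path Output path.
#' @export
write_cascade_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
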