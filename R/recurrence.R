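pool_samples <- function(per_sample) {
  if (length(per_sample) == 0)
    return(data.frame(sample_id = character(), key = character(),
                      gene = character()))
  do.call(rbind, lapply(names(per_sample), function(s) {
    v <- per_sample[[s]]
    if (nrow(v) == 0) return(NULL)
    data.frame(sample_id = s, key = v$key, gene = v$gene,
               stringsAsFactors = FALSE)
  }))
}

#' Variants and genes shared across probands
#'
#' Variant-level sharing counts probands carrying the *identical* variant
#' (same chrom:pos:ref:alt). Gene-level sharing counts distinct probands
#' carrying *any* variant of the gene, not necessarily the same one — this
#' is what flags a gene hit by four different substitutions in four patients
#' alongside one substitution recurring in six.
#'
#' @param per_sample Named list of per-sample variant tables (e.g. the
#'   `survivors` of [run_cascade()]).
#' @param min_carriers Minimum number of carrier probands for a variant or
#'   gene to be reported. Default 4: half an 8-proband exome cohort, the
#'   smallest sharing worth pursuing.
#' @return A list of two `data.frame`s, `variant_level` (`key`, `gene`,
#'   `n_carriers`, `carriers` list-column) and `gene_level` (`gene`,
#'   `n_carriers`, `carriers`, `n_variants`, `keys` list-column), both sorted
#'   by decreasing carrier count.
#' @export
shared_variants <- function(per_sample, min_carriers = 4) {
  if (min_carriers < 1) stop("min_carriers must be >= 1")
  pooled <- pool_samples(per_sample)
  if (is.null(pooled) || nrow(pooled) == 0) {
    empty_v <- data.frame(key = character(), gene = character(),
                          n_carriers = integer())
    empty_v$carriers <- list()
    empty_g <- data.frame(gene = character(), n_carriers = integer(),
                          n_variants = integer())
    empty_g$carriers <- list()
    empty_g$keys <- list()
    return(list(variant_level = empty_v, gene_level = empty_g))
  }
  pooled <- pooled[!duplicated(pooled[c("sample_id", "key")]), , drop = FALSE]

  by_key <- split(pooled$sample_id, pooled$key)
  vl <- data.frame(key = names(by_key),
                   gene = pooled$gene[match(names(by_key), pooled$key)],
                   n_carriers = lengths(by_key), stringsAsFactors = FALSE)
  vl$carriers <- unname(by_key)
  vl <- vl[vl$n_carriers >= min_carriers, , drop = FALSE]
  vl <- vl[order(-vl$n_carriers, vl$key), , drop = FALSE]

  with_gene <- pooled[!is.na(pooled$gene), , drop = FALSE]
  by_gene <- split(with_gene, toupper(with_gene$gene))
  gl <- data.frame(gene = vapply(by_gene, function(d) d$gene[[1]], ""),
                   n_carriers = vapply(by_gene,
                                       function(d) length(unique(d$sample_id)),
                                       1L),
                   n_variants = vapply(by_gene,
                                       function(d) length(unique(d$key)), 1L),
                   stringsAsFactors = FALSE)
  gl$carriers <- lapply(by_gene, function(d) unique(d$sample_id))
  gl$keys <- lapply(by_gene, function(d) unique(d$key))
  gl <- gl[gl$n_carriers >= min_carriers, , drop = FALSE]
  gl <- gl[order(-gl$n_carriers, gl$gene), , drop = FALSE]
  rownames(vl) <- rownames(gl) <- NULL
  list(variant_level = vl, gene_level = gl)
}

#' Cohort prevalence of a candidate mutation
#'
#' @param n_carriers Number of carrier probands (> 0).
#' @param cohort_size Total probands (> 0).
#' @return A list: `fraction` (raw proportion) and `percent` (rounded
#'   half-up to the nearest integer percent, the convention under which
#'   19 of 82 prints as 23\%).
#' @export
prevalence <- function(n_carriers, cohort_size) {
  if (cohort_size == 0) stop("cohort_size must be positive")
  if (n_carriers <= 0 || n_carriers > cohort_size)
    stop("carrier count must satisfy 0 < n_carriers <= cohort_size")
  frac <- n_carriers / cohort_size
  list(fraction = frac, percent = floor(100 * frac + 0.5))
}

#' Re-examine one gene in the pre-filter data (gene refocus)
#'
#' The rescue move for candidates lost to the novelty filter: given the
#' *pre-novelty* per-sample variant tables, return every consequence-passing
#' variant of the gene for every sample, regardless of database registration.
#' This is how a position-only collation's false "known" call is recovered
#' once a gene is already implicated.
#'
#' @param per_sample Named list of per-sample variant tables *before* the
#'   novelty filter (e.g. from [per_sample_variants()]).
#' @param gene Gene symbol (case-insensitive).
#' @param keep_classes Consequence classes retained (default NS/SS).
#' @return Named list of per-sample variant tables restricted to the gene.
#' @export
gene_refocus <- function(per_sample, gene, keep_classes = nsss_classes()) {
  if (!nzchar(gene)) stop("gene symbol must be non-empty")
  lapply(per_sample, function(v) {
    v <- v[!is.na(v$gene) & toupper(v$gene) == toupper(gene), , drop = FALSE]
    filter_consequence(v, keep_classes)
  })
}
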