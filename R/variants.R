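#' @keywords internal
"_PACKAGE"

#' Closed consequence vocabulary
#'
#' The annotation classes recognized by the cascade, ordered from most to
#' least severe. Severity only matters when a source supplies several
#' annotations for one variant and a single canonical one must be kept.
#'
#' @return Character vector of consequence terms, most severe first.
#' @export
consequence_classes <- function() {
  c("splice_acceptor", "splice_donor", "frameshift_indel",
    "missense", "inframe_indel", "synonymous", "other")
}

#' Protein-altering consequence classes (NS/SS)
#'
#' Non-synonymous plus splice-site acceptor/donor classes: the default set
#' retained by [filter_consequence()].
#'
#' @return Character vector of consequence terms.
#' @export
nsss_classes <- function() {
  c("missense", "splice_acceptor", "splice_donor",
    "frameshift_indel", "inframe_indel")
}

zygosity_levels <- function() c("hom_ref", "het", "hom_alt", "missing")

#' Variant identity key
#'
#' Variant identity is the 4-tuple (chromosome, position, ref, alt);
#' annotations such as gene or protein change are attributes, not identity.
#' This is what lets D801N (chr19:42474557 G>A) and D801Y (G>T) at the same
#' position remain distinct variants.
#'
#' @param chrom,pos,ref,alt Vectors of the four identity components.
#' @return Character vector of keys `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct and validate a variant annotation table
#'
#' One row per distinct variant. `protein` must be given for missense and
#' synonymous variants (single-letter short form, e.g. `"D801N"`) and must be
#' `NA` for all other classes.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ref,alt Reference and alternate allele strings (`ref != alt`).
#' @param gene Gene symbols (`NA` allowed; such variants never pass the
#'   expression filter).
#' @param cdna HGVS-c strings, e.g. `"c.2401G>A"` (`NA` allowed).
#' @param protein Single-letter protein change, e.g. `"D801N"`, or `NA`.
#' @param consequence One of [consequence_classes()].
#' @return A `data.frame` with the input columns plus `key`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene = NA_character_,
                          cdna = NA_character_, protein = NA_character_,
                          consequence = "other") {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  v <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(toupper(as.character(ref)), n),
    alt = rep_len(toupper(as.character(alt)), n),
    gene = rep_len(as.character(gene), n),
    cdna = rep_len(as.character(cdna), n),
    protein = rep_len(as.character(protein), n),
    consequence = rep_len(as.character(consequence), n),
    stringsAsFactors = FALSE
  )
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  validate_variants(v)
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  required <- c("chrom", "pos", "ref", "alt", "gene", "cdna", "protein",
                "consequence", "key")
  missing_cols <- setdiff(required, names(v))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(v) == 0) return(v)
  if (any(is.na(v$pos)) || any(v$pos < 1))
    stop("variant positions must be integers >= 1 (1-based coordinates)")
  if (any(v$ref == v$alt))
    stop("ref and alt alleles must differ")
  bad <- setdiff(unique(v$consequence), consequence_classes())
  if (length(bad))
    stop("unknown consequence term(s): ", paste(bad, collapse = ", "),
         " (vocabulary: ", paste(consequence_classes(), collapse = ", "), ")")
  coding <- v$consequence %in% c("missense", "synonymous")
  if (any(coding & is.na(v$protein)))
    stop("missense/synonymous variants must carry a protein change")
  if (any(!coding & !is.na(v$protein)))
    stop("protein change is only defined for missense/synonymous variants")
  if (anyDuplicated(v$key))
    stop("duplicate variant keys: ",
         paste(unique(v$key[duplicated(v$key)]), collapse = ", "))
  rownames(v) <- NULL
  v
}

is_indel <- function(v) {
  nchar(v$ref) != nchar(v$alt) |
    v$consequence %in% c("frameshift_indel", "inframe_indel")
}

#' Construct a genotype table
#'
#' Long-format genotype calls: one row per (sample, variant). Samples absent
#' at a variant are implicitly reference; an explicit `"missing"` zygosity
#' records a failed call.
#'
#' @param sample_id Sample labels.
#' @param key Variant keys (see [variant_key()]).
#' @param zygosity One of `hom_ref`, `het`, `hom_alt`, `missing`.
#' @return A validated `data.frame`.
#' @export
genotype_table <- function(sample_id, key, zygosity) {
  g <- data.frame(sample_id = as.character(sample_id),
                  key = as.character(key),
                  zygosity = as.character(zygosity),
                  stringsAsFactors = FALSE)
  bad <- setdiff(unique(g$zygosity), zygosity_levels())
  if (length(bad))
    stop("unknown zygosity value(s): ", paste(bad, collapse = ", "))
  g
}

#' Bundle variants and genotypes into a cohort object
#'
#' @param variants A variant table ([variant_table()]).
#' @param genotypes A genotype table ([genotype_table()]); every key must
#'   refer to a row of `variants`.
#' @param samples Sample labels covered by the cohort (defaults to the
#'   samples present in `genotypes`).
#' @return An object of class `variant_cohort`.
#' @export
variant_cohort <- function(variants, genotypes, samples = NULL) {
  variants <- validate_variants(variants)
  genotypes <- genotype_table(genotypes$sample_id, genotypes$key,
                              genotypes$zygosity)
  orphan <- setdiff(genotypes$key, variants$key)
  if (length(orphan))
    stop("genotype calls reference unknown variants: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  if (is.null(samples)) samples <- unique(genotypes$sample_id)
  structure(list(variants = variants, genotypes = genotypes,
                 samples = as.character(samples)),
            class = "variant_cohort")
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("<variant_cohort> ", nrow(x$variants), " variants, ",
      length(x$samples), " samples, ", nrow(x$genotypes),
      " genotype calls\n", sep = "")
  invisible(x)
}

#' Variants carried by one sample
#'
#' @param cohort A `variant_cohort`.
#' @param sample_id Sample label.
#' @return The subset of the cohort's variant table carried (het or hom_alt)
#'   by the sample, in variant-table order.
#' @export
carried_variants <- function(cohort, sample_id) {
  g <- cohort$genotypes
  keys <- g$key[g$sample_id == sample_id & g$zygosity %in% c("het", "hom_alt")]
  cohort$variants[cohort$variants$key %in% keys, , drop = FALSE]
}

#' Per-sample carried variant tables
#'
#' @param cohort A `variant_cohort`.
#' @param samples Samples to extract (default: all cohort samples).
#' @return Named list of variant tables, one per sample.
#' @export
per_sample_variants <- function(cohort, samples = cohort$samples) {
  stats::setNames(lapply(samples, function(s) carried_variants(cohort, s)),
                  samples)
}

#' Look up one sample's zygosity at one variant
#'
#' Absent records default to `hom_ref`, the usual exome-table convention in
#' which only non-reference calls are materialized.
#'
#' @param genotypes A genotype table.
#' @param sample_id Sample label.
#' @param key Variant key.
#' @param default Zygosity assumed when no record exists.
#' @return A zygosity string.
#' @export
zygosity_of <- function(genotypes, sample_id, key, default = "hom_ref") {
  hit <- genotypes$zygosity[genotypes$sample_id == sample_id &
                              genotypes$key == key]
  if (length(hit) == 0) default else hit[[1]]
}
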