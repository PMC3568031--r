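#' Load a homolog alignment from aligned FASTA
#'
#' Reads an aligned protein FASTA (orthologues/isoforms of the candidate
#' gene product) and anchors residue numbering on a designated reference
#' row: alignment columns where the reference is non-gap are mapped to
#' consecutive reference residue numbers.
#'
#' @param path Aligned FASTA path.
#' @param reference Name (or unique prefix) of the reference row; default
#'   the first sequence.
#' @return An object of class `homolog_alignment`: `labels`, `residues`
#'   (character matrix, rows = sequences, columns = alignment columns),
#'   `reference`, and `column_map` (reference residue number -> column).
#' @export
read_homolog_alignment <- function(path, reference = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  homolog_alignment(stats::setNames(as.character(seqs), names(seqs)),
                    reference)
}

#' @rdname read_homolog_alignment
#' @param sequences Named character vector of aligned (equal-length,
#'   gapped with `-`) residue strings.
#' @export
homolog_alignment <- function(sequences, reference = NULL) {
  if (length(sequences) < 2)
    stop("a homolog alignment needs at least two rows")
  if (length(unique(nchar(sequences))) != 1)
    stop("all alignment rows must have equal length")
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("alignment rows must be named")
  if (is.null(reference)) reference <- labels[[1]]
  ref_idx <- which(labels == reference)
  if (length(ref_idx) != 1) {
    ref_idx <- grep(reference, labels, fixed = TRUE)
    if (length(ref_idx) != 1)
      stop("reference '", reference, "' does not match exactly one row")
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- labels
  ref_cols <- which(mat[ref_idx, ] != "-")
  structure(list(labels = labels, residues = mat,
                 reference = labels[[ref_idx]],
                 column_map = ref_cols),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, ...) {
  cat("<homolog_alignment> ", length(x$labels), " rows x ",
      ncol(x$residues), " columns; reference: ", x$reference,
      " (", length(x$column_map), " residues)\n", sep = "")
  invisible(x)
}

#' Cross-species conservation of a reference residue
#'
#' Fraction of alignment rows, at the column carrying the given reference
#' residue number, whose residue equals the reference residue. Rows gapped
#' at that column are excluded from the denominator; if every non-reference
#' row is gapped there the column carries no homologous information and an
#' error is raised.
#'
#' @param alignment A [homolog_alignment()].
#' @param residue_number Reference (human) residue number.
#' @return Fraction in \[0, 1\].
#' @export
conservation_fraction <- function(alignment, residue_number) {
  col <- alignment$column_map[residue_number]
  if (residue_number < 1 || residue_number > length(alignment$column_map) ||
      is.na(col))
    stop("residue number ", residue_number,
         " is outside the reference sequence")
  column <- alignment$residues[, col]
  ref_aa <- column[[match(alignment$reference, alignment$labels)]]
  informative <- column[names(column) != alignment$reference & column != "-"]
  if (length(informative) == 0)
    stop("no informative (non-gap) homolog rows at residue ", residue_number)
  non_gap <- column[column != "-"]
  sum(non_gap == ref_aa) / length(non_gap)
}

#' Rank candidate variants
#'
#' Ordinal prioritization; no pathogenic/benign cut-off is asserted. Sort
#' key, descending: confirmed de novo carriers, total carriers, conservation,
#' Grantham distance; ties broken by genomic coordinate (chromosome, then
#' position), which also makes the order deterministic.
#'
#' @param candidates `data.frame` with columns `key`, `n_de_novo`,
#'   `carriers` (list-column) and optionally `conservation`, `grantham`.
#' @return The same `data.frame`, reordered.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  parts <- strsplit(candidates$key, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1)
  pos <- as.integer(vapply(parts, `[[`, "", 2))
  grant <- if ("grantham" %in% names(candidates)) candidates$grantham else
    rep(NA_real_, nrow(candidates))
  cons <- if ("conservation" %in% names(candidates)) candidates$conservation
    else rep(NA_real_, nrow(candidates))
  grant[is.na(grant)] <- -Inf
  cons[is.na(cons)] <- -Inf
  n_carriers <- lengths(candidates$carriers)
  ord <- order(-candidates$n_de_novo, -n_carriers, -cons, -grant,
               chrom, pos)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a phenotype table
#'
#' One row per patient; feature columns take categorical values with
#' `"yes"`, `"no"` and `"unknown"` as the usual vocabulary. The set of legal
#' feature names is frozen at construction.
#'
#' @param patient_id Patient labels.
#' @param mutation Protein-change label carried by each patient.
#' @param ... Named feature vectors (each recycled to the patient count).
#' @return `data.frame` of class `phenotype_table` with a `schema` attribute.
#' @export
phenotype_table <- function(patient_id, mutation, ...) {
  feats <- list(...)
  if (length(feats) == 0) stop("at least one feature column is required")
  d <- data.frame(patient_id = as.character(patient_id),
                  mutation = as.character(mutation),
                  stringsAsFactors = FALSE)
  for (f in names(feats)) d[[f]] <- rep_len(as.character(feats[[f]]),
                                            nrow(d))
  structure(d, schema = names(feats),
            class = c("phenotype_table", "data.frame"))
}

#' Cross-tabulate a clinical feature against a mutation
#'
#' @param phenotypes A [phenotype_table()].
#' @param mutation Protein-change label (e.g. `"E815K"`).
#' @param feature Feature name from the table's schema.
#' @return List: `n_with_feature` (carriers with feature value `"yes"`) and
#'   `n_carriers` (all carriers of the mutation).
#' @export
aggregate_phenotypes <- function(phenotypes, mutation, feature) {
  schema <- attr(phenotypes, "schema")
  if (!feature %in% schema)
    stop("unknown feature '", feature, "'; schema: ",
         paste(schema, collapse = ", "))
  carriers <- phenotypes[phenotypes$mutation == mutation, , drop = FALSE]
  list(n_with_feature = sum(carriers[[feature]] == "yes"),
       n_carriers = nrow(carriers))
}
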