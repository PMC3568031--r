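#' Classify a proband's variant against the parental genotypes
#'
#' Mendelian trio classification of a single variant:
#' \itemize{
#'   \item proband het/hom_alt with both parents available, called and
#'     homozygous reference: `de_novo`;
#'   \item proband carrier with a carrier parent: `inherited_paternal`,
#'     `inherited_maternal`, or `inherited_either` when both parents carry
#'     it (an observed carrier parent dominates over a missing one);
#'   \item proband carrier but a needed parent is unavailable or has a
#'     missing call, and no carrier parent was observed: `unknown_parent`;
#'   \item proband homozygous reference: `absent_in_proband`.
#' }
#' An explicit failed (`missing`) proband call is an error, not a status;
#' a proband without a record reads as reference, the exome-table
#' convention in which only non-reference calls are materialized.
#'
#' @param key Variant key ([variant_key()]).
#' @param trio One row of a trio table ([trio_table()]).
#' @param genotypes Genotype table covering proband and available parents;
#'   absent records for available individuals are read as `hom_ref`.
#' @return One of the six status strings.
#' @export
classify_trio <- function(key, trio, genotypes) {
  pz <- zygosity_of(genotypes, trio$proband_id, key, default = "hom_ref")
  if (pz == "missing")
    stop("proband genotype missing for ", trio$proband_id, " at ", key)
  if (pz == "hom_ref") return("absent_in_proband")

  parent_state <- function(id, available) {
    if (!available) return("unknown")
    z <- zygosity_of(genotypes, id, key, default = "hom_ref")
    if (z == "missing") return("unknown")
    if (z %in% c("het", "hom_alt")) "carrier" else "non_carrier"
  }
  f <- parent_state(trio$father_id, trio$father_available)
  m <- parent_state(trio$mother_id, trio$mother_available)
  if (f == "carrier" && m == "carrier") return("inherited_either")
  if (f == "carrier") return("inherited_paternal")
  if (m == "carrier") return("inherited_maternal")
  if (f == "non_carrier" && m == "non_carrier") return("de_novo")
  "unknown_parent"
}

#' Count control individuals carrying a variant
#'
#' @param key Variant key.
#' @param control_genotypes Genotype table for the control cohort (see
#'   [read_genotype_table()]); controls without a record are non-carriers.
#' @return Number of distinct control individuals with at least one
#'   alternate allele.
#' @export
control_screen <- function(key, control_genotypes) {
  g <- control_genotypes
  length(unique(g$sample_id[g$key == key &
                              g$zygosity %in% c("het", "hom_alt")]))
}

#' Confirm a candidate against the validation oracle
#'
#' Looks up every carrier observation of the variant in the confirmation
#' oracle (the stand-in for Sanger re-sequencing). A candidate is `"failed"`
#' — a sequencing artifact — when no carrier observation is confirmed;
#' otherwise `"confirmed"`, with unconfirmed individual carriers reported so
#' they can be dropped. An observation absent from the oracle is an error:
#' validation never passes silently.
#'
#' @param key Variant key.
#' @param carrier_ids Proband labels carrying the variant.
#' @param oracle A [confirmation_oracle()] table.
#' @return List with `status` (`"confirmed"`/`"failed"`) and `per_carrier`
#'   (named logical vector).
#' @export
confirm_variant <- function(key, carrier_ids, oracle) {
  hit <- oracle[oracle$key == key, , drop = FALSE]
  idx <- match(carrier_ids, hit$sample_id)
  if (anyNA(idx))
    stop("confirmation oracle has no entry for ", key, " in sample(s): ",
         paste(carrier_ids[is.na(idx)], collapse = ", "))
  per <- stats::setNames(hit$confirmed[idx], carrier_ids)
  list(status = if (any(per)) "confirmed" else "failed", per_carrier = per)
}

#' Exclude non-causal candidates
#'
#' Applies the three exclusion rules used to whittle shared candidates down
#' to pathogenic de novo mutations:
#' \enumerate{
#'   \item confirmation failure (sequencing artifact) removes the candidate;
#'     individually unconfirmed carriers are dropped from surviving ones;
#'   \item presence in any control individual removes the candidate;
#'   \item a candidate inherited in every informative carrier trio is
#'     removed; one de novo observation retains it (and marks it validated);
#'     a candidate whose carriers are all uninformative (`unknown_parent`)
#'     is retained but flagged unvalidated.
#' }
#'
#' @param candidates `data.frame` with columns `key`, `gene` and a `carriers`
#'   list-column (e.g. `variant_level` from [shared_variants()], or rows
#'   expanded from its gene level).
#' @param trios Trio table.
#' @param genotypes Genotype table covering probands and parents.
#' @param control_genotypes Control-cohort genotype table.
#' @param oracle Confirmation oracle.
#' @return List of `retained` and `removed` data.frames; both gain
#'   `trio_status` (list-column, per carrier), `n_de_novo`, `sanger`,
#'   `control_carriers`, and `removed` additionally a `reason`.
#' @export
exclude_non_causal <- function(candidates, trios, genotypes,
                               control_genotypes, oracle) {
  n <- nrow(candidates)
  candidates$reason <- rep(NA_character_, n)
  candidates$validated <- rep(FALSE, n)
  candidates$sanger <- rep(NA_character_, n)
  candidates$control_carriers <- rep(NA_integer_, n)
  candidates$n_de_novo <- rep(0L, n)
  candidates$trio_status <- vector("list", n)
  if (n == 0)
    return(list(retained = candidates, removed = candidates))

  # slice the lookup tables to candidate keys once; the per-candidate
  # operations then touch a handful of rows each
  slice <- function(d) {
    d <- d[d$key %in% candidates$key, , drop = FALSE]
    split(d, d$key)
  }
  gt_by_key <- slice(genotypes)
  ctl_by_key <- slice(control_genotypes)
  orc_by_key <- slice(oracle)
  empty_gt <- genotypes[0, , drop = FALSE]

  for (i in seq_len(n)) {
    key <- candidates$key[[i]]
    carriers <- candidates$carriers[[i]]
    conf <- confirm_variant(key, carriers,
                            orc_by_key[[key]] %||% oracle[0, , drop = FALSE])
    candidates$sanger[[i]] <- conf$status
    if (conf$status == "failed") {
      candidates$reason[[i]] <- "confirmation_failed"
      next
    }
    carriers <- carriers[conf$per_carrier]
    candidates$carriers[[i]] <- carriers

    cc <- control_screen(key, ctl_by_key[[key]] %||% empty_gt)
    candidates$control_carriers[[i]] <- cc
    if (cc >= 1) {
      candidates$reason[[i]] <- "present_in_controls"
      next
    }

    gk <- gt_by_key[[key]] %||% empty_gt
    status <- vapply(carriers, function(s) {
      trio <- trios[trios$proband_id == s, , drop = FALSE]
      if (nrow(trio) == 0) return("unknown_parent")
      classify_trio(key, trio[1, ], gk)
    }, "")
    candidates$trio_status[[i]] <- status
    candidates$n_de_novo[[i]] <- sum(status == "de_novo")
    inherited <- startsWith(status, "inherited")
    if (any(status == "de_novo")) {
      candidates$validated[[i]] <- TRUE
    } else if (length(status) > 0 && all(inherited)) {
      candidates$reason[[i]] <- "inherited_in_all_carriers"
    }
    # else: only unknown_parent (or mixed unknown/inherited without any
    # de novo observation) -> retained, validated stays FALSE
  }
  removed <- candidates[!is.na(candidates$reason), , drop = FALSE]
  retained <- candidates[is.na(candidates$reason), , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}
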