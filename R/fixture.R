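# Chromosome-6 and -3 coordinates for the SYNE1/CNTN4 decoy variants are
# synthetic placeholders (the study's published table gives genomic
# positions only for the chromosome-19 ATP1A3 variants).

fixture_atp1a3 <- function() {
  variant_table(chrom = "19",
                pos = c(42479781L, 42474436L, 42474557L, 42472976L),
                ref = "G", alt = c("T", "A", "A", "A"),
                gene = "ATP1A3",
                cdna = c("c.2263G>T", "c.2443G>A", "c.2401G>A", "c.2780G>A"),
                protein = c("G755C", "E815K", "D801N", "C927Y"),
                consequence = "missense")
}

fixture_syne1_novel <- function() {
  variant_table(chrom = "6", pos = 152700100L + c(1:4) * 10L,
                ref = c("G", "T", "A", "G"), alt = c("A", "G", "G", "A"),
                gene = "SYNE1",
                cdna = c("c.3955G>A", "c.7196T>G", "c.10126A>G", "c.24665G>A"),
                protein = c("E1319K", "V2399A", "M3376V", "R8222Q"),
                consequence = "missense")
}

fixture_syne1_known <- function() {
  n <- 15L
  variant_table(chrom = "6", pos = 152500000L + seq_len(n) * 100L,
                ref = "C", alt = "T", gene = "SYNE1",
                cdna = sprintf("c.%dC>T", 1000L + seq_len(n) * 3L),
                protein = sprintf("P%dL", 400L + seq_len(n)),
                consequence = "missense")
}

fixture_cntn4 <- function() {
  variant_table(chrom = "3", pos = 2611000L, ref = "T", alt = "G",
                gene = "CNTN4", cdna = "c.2813T>G", protein = "V938G",
                consequence = "missense")
}

#' The in-paper trio cohort fixture
#'
#' A complete transcription of the study facts the pipeline operates on:
#' ten sporadic AHC probands (I-1 … X-1, the first eight exome-sequenced),
#' the four heterozygous ATP1A3 missense mutations (E815K in II-1, III-1,
#' IV-1 and — by targeted extension — IX-1 and X-1; D801N in VI-1, VII-1,
#' VIII-1; G755C in I-1; C927Y in V-1), the CNTN4 V938G exome call shared by
#' six probands that failed Sanger confirmation, the four novel inherited
#' SYNE1 variants plus fifteen database-registered SYNE1 substitutions (so a
#' gene refocus on SYNE1 finds 19 distinct non-synonymous SNVs, with
#' per-sample counts 10/10/8/10/9/8/10/9), a known-variant database holding
#' the D801Y record at the D801N site (chr19:42474557 G>T — the
#' position-only novelty pitfall), a 96-member control cohort carrying
#' E1319K/V2399A/M3376V in 2/2/2 individuals and no ATP1A3 mutation, the
#' confirmation oracle, trios (IX-1's parents unavailable), and the clinical
#' phenotype table.
#'
#' Each proband additionally carries background decoys: two
#' database-registered SNVs, one novel synonymous SNV in a brain gene and
#' one novel missense SNV in a non-brain gene, so every cascade stage
#' removes something.
#'
#' @return A list shaped like [simulate_cohort()]'s output: `cohort` (the 8
#'   exome probands and their parents), `trios` (all ten), `known_db`,
#'   `controls`, `oracle`, `gene_set`, `phenotypes`, `extension` (targeted
#'   E815K genotypes for IX-1/X-1), `exome_probands`, `all_probands`.
#' @export
fixture_paper_cohort <- function() {
  exome <- paste0(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"), "-1")
  all_pro <- c(exome, "IX-1", "X-1")

  atp <- fixture_atp1a3()
  atp_carriers <- list(G755C = "I-1",
                       E815K = c("II-1", "III-1", "IV-1"),
                       D801N = c("VI-1", "VII-1", "VIII-1"),
                       C927Y = "V-1")
  sy_new <- fixture_syne1_novel()
  sy_new_carriers <- list(E1319K = "VII-1", V2399A = "III-1",
                          M3376V = "V-1", R8222Q = "I-1")
  sy_known <- fixture_syne1_known()
  cntn4 <- fixture_cntn4()
  cntn4_carriers <- c("II-1", "III-1", "IV-1", "VI-1", "VII-1", "VIII-1")

  # registered SYNE1 variants per sample, cyclic so per-sample refocus
  # counts come out 10/10/8/10/9/8/10/9 over 19 distinct keys
  syne1_known_need <- c(`I-1` = 9, `II-1` = 10, `III-1` = 7, `IV-1` = 10,
                        `V-1` = 8, `VI-1` = 8, `VII-1` = 9, `VIII-1` = 9)
  offs <- 0L
  sy_known_gt <- do.call(rbind, lapply(exome, function(s) {
    k <- syne1_known_need[[s]]
    idx <- ((offs + seq_len(k) - 1L) %% 15L) + 1L
    offs <<- offs + k
    data.frame(sample_id = s, key = sy_known$key[idx], zygosity = "het",
               stringsAsFactors = FALSE)
  }))

  # per-proband background decoys
  i <- seq_along(exome)
  decoy_known <- variant_table("1", 1000000L + rep(i, each = 2) * 20L +
                                 rep(c(0L, 7L), 8),
                               ref = "A", alt = "G", gene = "TTN",
                               cdna = NA, protein = NA, consequence = "other")
  decoy_syn <- variant_table("9", 137100000L + i * 13L, ref = "C", alt = "T",
                             gene = "GRIN1", cdna = NA,
                             protein = sprintf("A%dA", 100L + i),
                             consequence = "synonymous")
  decoy_nonbrain <- variant_table("2", 179400000L + i * 17L, ref = "G",
                                  alt = "C", gene = "OBSCN", cdna = NA,
                                  protein = sprintf("R%dT", 200L + i),
                                  consequence = "missense")

  variants <- rbind(atp, sy_new, sy_known, cntn4, decoy_known, decoy_syn,
                    decoy_nonbrain)

  gt <- list(sy_known_gt)
  add <- function(samples, keys) {
    gt[[length(gt) + 1L]] <<- data.frame(sample_id = samples, key = keys,
                                         zygosity = "het",
                                         stringsAsFactors = FALSE)
  }
  for (p in names(atp_carriers))
    add(atp_carriers[[p]], atp$key[atp$protein == p])
  for (p in names(sy_new_carriers)) {
    carrier <- sy_new_carriers[[p]]
    key <- sy_new$key[sy_new$protein == p]
    add(carrier, key)
    add(paste0(carrier, "-F"), key)  # inherited from the healthy father
  }
  add(cntn4_carriers, cntn4$key[rep(1L, length(cntn4_carriers))])
  add(rep(exome, each = 2), decoy_known$key)
  add(exome, decoy_syn$key)
  add(exome, decoy_nonbrain$key)
  # registered decoys and the SYNE1 registered variants are transmitted
  add(rep(paste0(exome, "-M"), each = 2), decoy_known$key)
  add(paste0(sy_known_gt$sample_id, "-M"), sy_known_gt$key)
  # novel decoys are inherited too (benign polymorphisms not yet registered)
  add(paste0(exome, "-F"), decoy_syn$key)
  add(paste0(exome, "-M"), decoy_nonbrain$key)
  genotypes <- do.call(rbind, gt)

  parents <- c(paste0(exome, "-F"), paste0(exome, "-M"))
  cohort <- variant_cohort(variants, genotypes,
                           samples = c(exome, parents))

  trios <- trio_table(all_pro,
                      father_id = ifelse(all_pro == "IX-1", NA,
                                         paste0(all_pro, "-F")),
                      mother_id = ifelse(all_pro == "IX-1", NA,
                                         paste0(all_pro, "-M")))

  db <- rbind(
    known_db("19", 42474557L, "G", "T", "RDP_D801Y"),  # the collision record
    known_db(sy_known$chrom, sy_known$pos, sy_known$ref, sy_known$alt,
             sprintf("KV_SYNE1_%02d", seq_len(nrow(sy_known)))),
    known_db(decoy_known$chrom, decoy_known$pos, decoy_known$ref,
             decoy_known$alt, sprintf("KV_BG_%02d", seq_len(nrow(decoy_known)))))

  controls_ids <- sprintf("CTRL%03d", 1:96)
  ctl <- data.frame(
    sample_id = controls_ids[1:6],
    key = rep(sy_new$key[match(c("E1319K", "V2399A", "M3376V"),
                               sy_new$protein)], each = 2),
    zygosity = "het", stringsAsFactors = FALSE)
  controls <- genotype_table(ctl$sample_id, ctl$key, ctl$zygosity)
  attr(controls, "samples") <- controls_ids

  oracle <- rbind(
    do.call(rbind, lapply(names(atp_carriers), function(p)
      confirmation_oracle(atp$key[atp$protein == p], atp_carriers[[p]], TRUE))),
    confirmation_oracle(atp$key[atp$protein == "E815K"], c("IX-1", "X-1"),
                        TRUE),
    do.call(rbind, lapply(names(sy_new_carriers), function(p)
      confirmation_oracle(sy_new$key[sy_new$protein == p],
                          sy_new_carriers[[p]], TRUE))),
    confirmation_oracle(cntn4$key[rep(1L, length(cntn4_carriers))],
                        cntn4_carriers, FALSE),
    # registered SYNE1 variants are real (inherited) calls: a SYNE1 refocus
    # can bring them to validation, where they confirm
    confirmation_oracle(sy_known_gt$key, sy_known_gt$sample_id, TRUE))

  extension <- genotype_table(c("IX-1", "X-1"),
                              atp$key[c(2L, 2L)], c("het", "het"))

  out <- list(cohort = cohort, trios = trios, known_db = db,
              controls = controls, oracle = oracle,
              gene_set = gene_set(c("ATP1A3", "SYNE1", "CNTN4", "GRIN1",
                                    "SCN1A"), "brain_expressed"),
              phenotypes = fixture_phenotypes(),
              extension = extension, exome_probands = exome,
              all_probands = all_pro, atp1a3 = atp)
  check_fixture(out)
  out
}

# internal consistency: ATP1A3 carrier counts 5/3/1/1 over the 10 probands
check_fixture <- function(fx) {
  atp <- fx$atp1a3
  gt <- rbind(fx$cohort$genotypes[c("sample_id", "key", "zygosity")],
              fx$extension)
  counts <- vapply(c("E815K", "D801N", "G755C", "C927Y"), function(p) {
    key <- atp$key[atp$protein == p]
    length(unique(gt$sample_id[gt$key == key & gt$sample_id %in%
                                 fx$all_probands &
                                 gt$zygosity %in% c("het", "hom_alt")]))
  }, 1L)
  if (!identical(unname(counts), c(5L, 3L, 1L, 1L)))
    stop("fixture inconsistency: ATP1A3 carrier counts are ",
         paste(counts, collapse = "/"), ", expected 5/3/1/1")
  invisible(fx)
}

#' Clinical phenotype fixture
#'
#' Ten AHC patients with their mutation and binarized clinical features
#' (respiratory abnormality such as apnea or ventilator dependence, status
#' epilepticus, epilepsy, developmental regression, headache, and whether
#' flunarizine was the drug reported effective against the paralytic
#' attacks). `"unknown"` marks features not assessable.
#'
#' @return A [phenotype_table()].
#' @export
fixture_phenotypes <- function() {
  phenotype_table(
    patient_id = paste0(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                          "IX", "X"), "-1"),
    mutation = c("G755C", "E815K", "E815K", "E815K", "C927Y", "D801N",
                 "D801N", "D801N", "E815K", "E815K"),
    respiratory_abnormality = c("yes", "no", "yes", "yes", "no", "no", "no",
                                "yes", "yes", "yes"),
    status_epilepticus = c("no", "yes", "yes", "no", "no", "no", "no",
                           "yes", "yes", "yes"),
    epilepsy = c("yes", "yes", "yes", "no", "no", "no", "yes", "yes",
                 "yes", "yes"),
    regression = c("no", "yes", "yes", "no", "yes", "no", "no", "yes",
                   "yes", "no"),
    headache = c("yes", "yes", "no", "no", "no", "no", "no", "no",
                 "unknown", "unknown"),
    flunarizine_effective = c("yes", "no", "yes", "yes", "no", "yes",
                              "yes", "yes", "unknown", "no"))
}

#' A small synthetic homolog alignment around a reference protein
#'
#' Builds an aligned set of orthologue-like rows that are identical to the
#' reference except at chosen positions in chosen rows — a stand-in for a
#' curated cross-species alignment, used to exercise conservation scoring.
#'
#' @param ref_length Reference protein length.
#' @param n_rows Number of homolog rows (excluding the reference).
#' @param mismatches `data.frame` with columns `row` (1-based homolog
#'   index), `residue` (reference residue number) and `aa` (replacement).
#' @param seed Seed for the reference sequence.
#' @return A [homolog_alignment()] whose reference row is `"human"`.
#' @export
synthetic_homolog_alignment <- function(ref_length = 60, n_rows = 9,
                                        mismatches = NULL, seed = 7) {
  set.seed(seed)
  ref <- paste(sample(aa20, ref_length, replace = TRUE), collapse = "")
  rows <- rep(ref, n_rows)
  if (!is.null(mismatches)) {
    for (i in seq_len(nrow(mismatches))) {
      r <- mismatches$row[[i]]
      substr(rows[[r]], mismatches$residue[[i]], mismatches$residue[[i]]) <-
        mismatches$aa[[i]]
    }
  }
  homolog_alignment(stats::setNames(c(ref, rows),
                                    c("human", sprintf("species%02d",
                                                       seq_len(n_rows)))),
                    reference = "human")
}
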