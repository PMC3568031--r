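#' Simulation parameters for a synthetic trio-exome cohort
#'
#' Defaults describe a desk-scale cohort shaped like an 8-trio sporadic-
#' disease exome study: ~5,000 variants per proband with class fractions
#' chosen so the expected brain-expressed novel NS/SS count per proband is
#' ~105, inside the 77–129 per-patient range such cascades report.
#'
#' @param n_trios Number of proband/father/mother trios.
#' @param variants_per_proband Mean background variant count per proband
#'   (Poisson).
#' @param fraction_known Probability a background variant is registered in
#'   the known-variant database.
#' @param fraction_nsss_of_novel Probability a novel variant is
#'   protein-altering/splice-site (NS/SS).
#' @param fraction_brain_of_nsss Probability any variant falls in a
#'   brain-expressed gene.
#' @param n_planted Number of planted pathogenic de novo variants shared
#'   across probands.
#' @param planted_carrier_count Probands carrying each planted variant.
#' @param artifact_rate Probability a novel variant is a confirmation-
#'   failing sequencing artifact (de-novo-looking, fails the oracle).
#' @param control_cohort_size Number of control individuals.
#' @param n_genes Synthetic gene-universe size.
#' @param seed Integer seed; generation is reproducible from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_trios = 8, variants_per_proband = 5000,
                       fraction_known = 0.80, fraction_nsss_of_novel = 0.35,
                       fraction_brain_of_nsss = 0.30, n_planted = 1,
                       planted_carrier_count = min(5L, n_trios),
                       artifact_rate = 0.002,
                       control_cohort_size = 96, n_genes = 400, seed = 1) {
  p <- list(n_trios = as.integer(n_trios),
            variants_per_proband = variants_per_proband,
            fraction_known = fraction_known,
            fraction_nsss_of_novel = fraction_nsss_of_novel,
            fraction_brain_of_nsss = fraction_brain_of_nsss,
            n_planted = as.integer(n_planted),
            planted_carrier_count = as.integer(planted_carrier_count),
            artifact_rate = artifact_rate,
            control_cohort_size = as.integer(control_cohort_size),
            n_genes = as.integer(n_genes), seed = as.integer(seed))
  fr <- c(p$fraction_known, p$fraction_nsss_of_novel,
          p$fraction_brain_of_nsss, p$artifact_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (p$n_trios < 1) stop("n_trios must be >= 1")
  if (p$planted_carrier_count > p$n_trios)
    stop("planted_carrier_count cannot exceed n_trios")
  if (p$n_planted > 0 && p$planted_carrier_count < 1)
    stop("planted variants need at least one carrier")
  structure(p, class = "sim_params")
}

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "V", "W", "Y")

random_protein_change <- function(n, synonymous = FALSE) {
  from <- sample(aa20, n, replace = TRUE)
  to <- if (synonymous) from else
    vapply(from, function(a) sample(setdiff(aa20, a), 1), "")
  paste0(from, sample(100:999, n, replace = TRUE), to)
}

#' Simulate a trio-exome cohort with truth labels
#'
#' Emits a complete, internally consistent input bundle: per-sample variant
#' tables for probands and parents, pedigree, known-variant database,
#' control genotypes, confirmation oracle — plus a truth sidecar labelling
#' every variant `known_background`, `novel_benign_inherited`,
#' `planted_de_novo` or `sequencing_artifact`. Known-background and benign
#' variants are each inherited from one parent; planted variants and
#' artifacts look de novo (parents reference), but only planted variants
#' pass the confirmation oracle. Planted variants are absent from database
#' and controls and shared by `planted_carrier_count` probands.
#'
#' @param params A [sim_params()].
#' @return List: `cohort` ([variant_cohort()]), `trios`, `known_db`,
#'   `controls` (genotype table), `oracle`, `truth`, `gene_set` (the
#'   brain-expressed subset), `probands`, `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  probands <- sprintf("P%02d", seq_len(params$n_trios))
  fathers <- paste0(probands, "-F")
  mothers <- paste0(probands, "-M")
  genes <- sprintf("GENE%04d", seq_len(params$n_genes))
  n_brain <- max(1L, round(params$n_genes * 0.3))
  brain_genes <- genes[seq_len(n_brain)]

  n_bg <- stats::rpois(params$n_trios, params$variants_per_proband)
  n_total <- sum(n_bg) + params$n_planted
  # unique synthetic exome coordinates across the whole cohort
  pos_pool <- sample.int(2^27, n_total)
  chrom_pool <- sample(as.character(1:22), n_total, replace = TRUE)

  owner <- rep(probands, n_bg)
  n <- sum(n_bg)
  known <- stats::runif(n) < params$fraction_known
  artifact <- !known & stats::runif(n) < params$artifact_rate
  nsss <- stats::runif(n) < params$fraction_nsss_of_novel
  brain <- stats::runif(n) < params$fraction_brain_of_nsss
  consequence <- ifelse(nsss,
                        sample(c("missense", "splice_acceptor", "splice_donor"),
                               n, replace = TRUE, prob = c(0.92, 0.04, 0.04)),
                        sample(c("synonymous", "other"), n, replace = TRUE,
                               prob = c(0.85, 0.15)))
  gene <- ifelse(brain, sample(brain_genes, n, replace = TRUE),
                 sample(setdiff(genes, brain_genes), n, replace = TRUE))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  protein <- rep(NA_character_, n)
  protein[consequence == "missense"] <-
    random_protein_change(sum(consequence == "missense"))
  protein[consequence == "synonymous"] <-
    random_protein_change(sum(consequence == "synonymous"), synonymous = TRUE)

  v_bg <- variant_table(chrom_pool[seq_len(n)], pos_pool[seq_len(n)],
                        ref, alt, gene, NA_character_, protein, consequence)

  # planted shared pathogenic de novo variants: missense, brain-expressed
  planted_idx <- if (params$n_planted > 0) n + seq_len(params$n_planted)
    else integer(0)
  v_planted <- if (params$n_planted > 0) {
    pref <- sample(c("A", "C", "G", "T"), params$n_planted, replace = TRUE)
    variant_table(chrom_pool[planted_idx], pos_pool[planted_idx], pref,
                  vapply(pref, function(r)
                    sample(setdiff(c("A", "C", "G", "T"), r), 1), ""),
                  sample(brain_genes, params$n_planted, replace = TRUE),
                  NA_character_, random_protein_change(params$n_planted),
                  "missense")
  } else v_bg[0, ]
  planted_carriers <- lapply(seq_len(params$n_planted), function(i)
    sample(probands, params$planted_carrier_count))

  variants <- rbind(v_bg, v_planted)

  # genotypes: probands het; inherited classes get one het parent
  inherit_from <- sample(c("F", "M"), n, replace = TRUE)
  parent_id <- ifelse(inherit_from == "F", paste0(owner, "-F"),
                      paste0(owner, "-M"))
  inherited <- !artifact  # known and benign-novel are parent-transmitted
  gt <- rbind(
    data.frame(sample_id = owner, key = v_bg$key, zygosity = "het",
               stringsAsFactors = FALSE),
    data.frame(sample_id = parent_id[inherited], key = v_bg$key[inherited],
               zygosity = "het", stringsAsFactors = FALSE))
  if (params$n_planted > 0) {
    gt <- rbind(gt, do.call(rbind, lapply(seq_len(params$n_planted),
      function(i) data.frame(sample_id = planted_carriers[[i]],
                             key = v_planted$key[[i]], zygosity = "het",
                             stringsAsFactors = FALSE))))
  }
  cohort <- variant_cohort(variants, gt,
                           samples = c(probands, fathers, mothers))

  trios <- trio_table(probands, fathers, mothers)

  db <- known_db(v_bg$chrom[known], v_bg$pos[known], v_bg$ref[known],
                 v_bg$alt[known],
                 sprintf("KV%06d", seq_len(sum(known))))

  # controls carry a sample of registered variants only
  controls_ids <- sprintf("CTRL%03d", seq_len(params$control_cohort_size))
  known_keys <- db$key
  ctl <- do.call(rbind, lapply(controls_ids, function(s) {
    k <- sample(known_keys, min(50, length(known_keys)))
    data.frame(sample_id = s, key = k, zygosity = "het",
               stringsAsFactors = FALSE)
  }))
  controls <- genotype_table(ctl$sample_id, ctl$key, ctl$zygosity)
  attr(controls, "samples") <- controls_ids

  # oracle covers everything that can reach the confirmation stage: NS/SS
  # brain-expressed background variants (registered ones included — a gene
  # refocus can resurrect them) plus planted variants
  reach <- nsss & brain
  oracle <- confirmation_oracle(v_bg$key[reach], owner[reach],
                                !artifact[reach])
  if (params$n_planted > 0) {
    oracle <- rbind(oracle, do.call(rbind, lapply(seq_len(params$n_planted),
      function(i) confirmation_oracle(v_planted$key[[i]],
                                      planted_carriers[[i]], TRUE))))
  }

  class_bg <- ifelse(known, "known_background",
                     ifelse(artifact, "sequencing_artifact",
                            "novel_benign_inherited"))
  truth <- data.frame(key = c(v_bg$key, v_planted$key),
                      class = c(class_bg,
                                rep("planted_de_novo", params$n_planted)),
                      intended_status = c(ifelse(artifact, "de_novo",
                                                 "inherited")[seq_len(n)],
                                          rep("de_novo", params$n_planted)),
                      stringsAsFactors = FALSE)
  truth$carriers <- c(as.list(owner), planted_carriers)

  list(cohort = cohort, trios = trios, known_db = db, controls = controls,
       oracle = oracle, truth = truth,
       gene_set = gene_set(brain_genes, "brain_expressed_sim"),
       probands = probands, params = params)
}

#' Plant a position-collision record in the known database
#'
#' Registers a *different* alternate allele at a planted (or any) variant's
#' site, reproducing the configuration in which a position-only novelty
#' collation wrongly treats the variant as known while allele-aware matching
#' keeps it novel.
#'
#' @param sim Output of [simulate_cohort()] (or any list with `known_db` and
#'   a variant table in `cohort`).
#' @param key Variant key of the planted variant.
#' @param source_id Label for the decoy database record.
#' @return The modified known-variant database.
#' @export
plant_position_collision <- function(sim, key, source_id = "COLLISION") {
  v <- sim$cohort$variants
  hit <- v[v$key == key, , drop = FALSE]
  if (nrow(hit) != 1) stop("no such variant in the cohort: ", key)
  other_alt <- setdiff(c("A", "C", "G", "T"), c(hit$ref, hit$alt))[[1]]
  rbind(sim$known_db,
        known_db(hit$chrom, hit$pos, hit$ref, other_alt, source_id))
}

#' Write a simulated (or fixture) cohort bundle to disk
#'
#' Serializes every component in the package's text formats: VCF and
#' annotated TSV for variants+genotypes, PED for the pedigree, TSVs for the
#' known database, control genotypes, oracle and truth labels.
#'
#' @param sim Output of [simulate_cohort()] or [fixture_paper_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(sim$cohort, file.path(dir, "cohort.vcf"), "vcf")
  write_variant_table(sim$cohort, file.path(dir, "cohort.tsv"),
                      "annotated_tsv")
  write_pedigree(sim$trios, file.path(dir, "cohort.ped"))
  write_known_db(sim$known_db, file.path(dir, "known_db.tsv"))
  write_genotype_table(sim$controls, file.path(dir, "controls.tsv"))
  write_confirmation_oracle(sim$oracle, file.path(dir, "oracle.tsv"))
  writeLines(sort(unclass(sim$gene_set)), file.path(dir, "gene_set.txt"))
  if (!is.null(sim$truth)) {
    t <- sim$truth
    t$carriers <- vapply(t$carriers, paste, "", collapse = ",")
    utils::write.table(t, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
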