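test_that("simulation parameters are validated", {
  expect_error(sim_params(planted_carrier_count = 9, n_trios = 8),
               "cannot exceed")
  expect_error(sim_params(fraction_known = 1.2), "fractions")
  expect_error(sim_params(n_trios = 0), "n_trios")
})

test_that("simulation is byte-identical under the same seed and differs across seeds", {
  p <- sim_params(n_trios = 3, variants_per_proband = 300, seed = 77)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$known_db, s2$known_db)
  expect_identical(s1$controls, s2$controls)
  expect_identical(s1$oracle, s2$oracle)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_params(n_trios = 3, variants_per_proband = 300,
                                   seed = 78))
  expect_false(identical(s1$cohort$variants$key, s3$cohort$variants$key))
})

test_that("truth classes carry their structural guarantees", {
  sim <- simulate_cohort(sim_params(n_trios = 4, variants_per_proband = 500,
                                    artifact_rate = 0.05, seed = 12))
  truth <- sim$truth
  g <- sim$cohort$genotypes
  known <- truth$key[truth$class == "known_background"]
  expect_true(all(known %in% sim$known_db$key))
  novel <- truth$key[truth$class != "known_background"]
  expect_false(any(novel %in% sim$known_db$key))
  # inherited classes: exactly one carrier parent per carrier proband
  inh <- truth[truth$class == "novel_benign_inherited", ]
  some <- inh[sample.int(nrow(inh), 20), ]
  for (i in seq_len(nrow(some))) {
    k <- some$key[[i]]
    carriers_all <- g$sample_id[g$key == k & g$zygosity %in%
                                  c("het", "hom_alt")]
    parents <- grep("-[FM]$", carriers_all, value = TRUE)
    expect_length(parents, 1)
  }
  # planted: shared by the configured carrier count, no parent carries it,
  # absent from controls
  planted <- truth[truth$class == "planted_de_novo", ]
  expect_equal(nrow(planted), 1)
  k <- planted$key[[1]]
  carriers_all <- g$sample_id[g$key == k & g$zygosity %in%
                                c("het", "hom_alt")]
  expect_length(carriers_all, sim$params$planted_carrier_count)
  expect_false(any(grepl("-[FM]$", carriers_all)))
  expect_equal(control_screen(k, sim$controls), 0)
  # artifacts fail the oracle wherever it covers them
  art <- truth$key[truth$class == "sequencing_artifact"]
  expect_gt(length(art), 0)
  covered <- sim$oracle[sim$oracle$key %in% art, ]
  expect_true(all(!covered$confirmed))
})

test_that("per-stage counts on simulated data sit within 3 standard errors of expectation", {
  p <- sim_params(n_trios = 6, variants_per_proband = 2000, seed = 31)
  sim <- simulate_cohort(p)
  casc <- run_cascade(sim$cohort, sim$known_db, sim$gene_set,
                      samples = sim$probands)
  r <- casc$report[seq_len(p$n_trios), ]
  n <- r$n_total_variants + r$n_total_indels
  check_band <- function(observed, size, prob) {
    expected <- size * prob
    se <- sqrt(size * prob * (1 - prob))
    expect_true(all(abs(observed - expected) <= 3 * se + 1e-9),
                info = paste("obs", paste(observed, collapse = ","),
                             "exp", round(expected[1], 1)))
  }
  check_band(r$n_novel_variants + r$n_novel_indels, n,
             1 - p$fraction_known)
  p_nsss <- (1 - p$fraction_known) * p$fraction_nsss_of_novel
  check_band(r$n_novel_nsss_variants + r$n_novel_nsss_indels, n, p_nsss)
  check_band(r$n_brain_variants + r$n_brain_indels, n,
             p_nsss * p$fraction_brain_of_nsss)
})

test_that("the full pipeline recovers exactly the planted variant", {
  sim <- simulate_cohort(sim_params(seed = 101))
  planted <- sim$truth$key[sim$truth$class == "planted_de_novo"]
  r <- run_pipeline(sim$cohort, sim$trios, sim$known_db, sim$gene_set,
                    sim$controls, sim$oracle)
  expect_setequal(r$candidates$key, planted)
  expect_true(all(r$candidates$validated))
})

test_that("with artifact_rate = 0 the confirmation stage removes nothing", {
  sim <- simulate_cohort(sim_params(n_trios = 4, variants_per_proband = 600,
                                    artifact_rate = 0, seed = 8))
  r <- run_pipeline(sim$cohort, sim$trios, sim$known_db, sim$gene_set,
                    sim$controls, sim$oracle, min_carriers = 1)
  expect_false(any(r$removed$reason == "confirmation_failed"))
  expect_setequal(r$candidates$key,
                  sim$truth$key[sim$truth$class == "planted_de_novo"])
})

test_that("a planted position collision hides the variant from position-only matching only", {
  sim <- simulate_cohort(sim_params(n_trios = 4, variants_per_proband = 400,
                                    planted_carrier_count = 3, seed = 55))
  planted <- sim$truth$key[sim$truth$class == "planted_de_novo"]
  db2 <- plant_position_collision(sim, planted)
  expect_equal(nrow(db2), nrow(sim$known_db) + 1)
  v <- sim$cohort$variants[sim$cohort$variants$key == planted, ]
  expect_true(is_known(v, db2, "position_only"))
  expect_false(is_known(v, db2, "allele_aware"))
  # the collision record itself never appears in any sample
  collision_key <- setdiff(db2$key, sim$known_db$key)
  expect_false(collision_key %in% sim$cohort$genotypes$key)
  # cascade with position-only misses it; allele-aware and refocus find it
  r_pos <- run_pipeline(sim$cohort, sim$trios, db2, sim$gene_set,
                        sim$controls, sim$oracle,
                        match_mode = "position_only", min_carriers = 3)
  expect_false(planted %in% r_pos$candidates$key)
  r_aa <- run_pipeline(sim$cohort, sim$trios, db2, sim$gene_set,
                       sim$controls, sim$oracle, min_carriers = 3)
  expect_true(planted %in% r_aa$candidates$key)
  gene <- v$gene
  r_ref <- run_pipeline(sim$cohort, sim$trios, db2, sim$gene_set,
                        sim$controls, sim$oracle,
                        match_mode = "position_only", min_carriers = 3,
                        refocus_genes = gene)
  expect_true(planted %in% r_ref$candidates$key)
})

test_that("the paper fixture satisfies its internal carrier-count contract", {
  fx <- fixture_paper_cohort()
  gt <- rbind(fx$cohort$genotypes[c("sample_id", "key", "zygosity")],
              fx$extension)
  counts <- vapply(c("E815K", "D801N", "G755C", "C927Y"), function(p) {
    key <- fx$atp1a3$key[fx$atp1a3$protein == p]
    length(unique(gt$sample_id[gt$key == key &
                                 gt$sample_id %in% fx$all_probands]))
  }, 1L)
  expect_equal(unname(counts), c(5L, 3L, 1L, 1L))
  expect_equal(length(unique(fx$atp1a3$protein)), 4)
  expect_equal(length(attr(fx$controls, "samples")), 96)
})

test_that("a cohort bundle written to disk reloads into the same pipeline result", {
  sim <- simulate_cohort(sim_params(n_trios = 3, variants_per_proband = 150,
                                    planted_carrier_count = 3, seed = 19))
  dir <- tempfile("bundle")
  write_cohort_bundle(sim, dir)
  cohort <- read_variant_table(file.path(dir, "cohort.tsv"), "annotated_tsv")
  trios <- read_pedigree(file.path(dir, "cohort.ped"))
  db <- read_known_db(file.path(dir, "known_db.tsv"))
  gs <- read_gene_set(file.path(dir, "gene_set.txt"))
  controls <- read_genotype_table(file.path(dir, "controls.tsv"))
  oracle <- read_confirmation_oracle(file.path(dir, "oracle.tsv"))
  r_mem <- run_pipeline(sim$cohort, sim$trios, sim$known_db, sim$gene_set,
                        sim$controls, sim$oracle, min_carriers = 3)
  r_dsk <- run_pipeline(cohort, trios, db, gs, controls, oracle,
                        min_carriers = 3)
  expect_setequal(r_dsk$candidates$key, r_mem$candidates$key)
  expect_equal(r_dsk$report$n_brain_variants, r_mem$report$n_brain_variants)
})
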