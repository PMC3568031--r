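# Independent rule table for trio classification, written as a direct
# transcription of the Mendelian contract (separate code path from the
# implementation): proband carrier + both parents observed reference is de
# novo; an observed carrier parent gives the corresponding inherited status
# and dominates an uninformative other parent; otherwise the parent
# information is insufficient.
oracle_classify <- function(pz, f_obs, m_obs) {
  # f_obs/m_obs: "ref", "carrier", or "uninformative" (unavailable, missing
  # call)
  if (pz == "hom_ref") return("absent_in_proband")
  if (f_obs == "carrier" && m_obs == "carrier") return("inherited_either")
  if (f_obs == "carrier") return("inherited_paternal")
  if (m_obs == "carrier") return("inherited_maternal")
  if (f_obs == "ref" && m_obs == "ref") return("de_novo")
  "unknown_parent"
}

test_that("trio classification matches a brute-force enumeration of the genotype/availability space", {
  key <- "1:100:A:G"
  proband_zyg <- c("hom_ref", "het", "hom_alt")
  parent_cases <- list(
    list(avail = FALSE, zyg = NULL, obs = "uninformative"),
    list(avail = TRUE, zyg = NULL, obs = "ref"),        # no record: hom_ref
    list(avail = TRUE, zyg = "hom_ref", obs = "ref"),
    list(avail = TRUE, zyg = "het", obs = "carrier"),
    list(avail = TRUE, zyg = "hom_alt", obs = "carrier"),
    list(avail = TRUE, zyg = "missing", obs = "uninformative"))
  n_checked <- 0
  for (pz in proband_zyg) for (fc in parent_cases) for (mc in parent_cases) {
    trio <- trio_table("P", if (fc$avail) "F" else NA,
                       if (mc$avail) "M" else NA)
    ids <- c("P", if (!is.null(fc$zyg)) "F", if (!is.null(mc$zyg)) "M")
    zygs <- c(pz, if (!is.null(fc$zyg)) fc$zyg, if (!is.null(mc$zyg)) mc$zyg)
    g <- genotype_table(ids, key, zygs)
    got <- classify_trio(key, trio[1, ], g)
    expect_identical(got, oracle_classify(pz, fc$obs, mc$obs),
                     info = paste(pz, fc$obs, mc$obs))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 3 * 6 * 6)
})

test_that("a failed proband call is an error; an absent record reads as reference", {
  trio <- trio_table("P", "F", "M")
  g2 <- genotype_table("P", "1:100:A:G", "missing")
  expect_error(classify_trio("1:100:A:G", trio[1, ], g2), "proband genotype")
  g <- genotype_table(c("F", "M"), "1:100:A:G", c("hom_ref", "hom_ref"))
  expect_identical(classify_trio("1:100:A:G", trio[1, ], g),
                   "absent_in_proband")
})

test_that("fixture trio calls: de novo ATP1A3, inherited SYNE1, unknown for IX-1", {
  fx <- fixture_paper_cohort()
  gt <- rbind(fx$cohort$genotypes[c("sample_id", "key", "zygosity")],
              fx$extension)
  e815k <- fx$atp1a3$key[fx$atp1a3$protein == "E815K"]
  trio_of <- function(id) fx$trios[fx$trios$proband_id == id, ][1, ]
  expect_identical(classify_trio(e815k, trio_of("III-1"), gt), "de_novo")
  expect_identical(classify_trio(e815k, trio_of("IX-1"), gt),
                   "unknown_parent")
  expect_identical(classify_trio(e815k, trio_of("X-1"), gt), "de_novo")
  r8222q <- "6:152700140:G:A"
  expect_identical(classify_trio(r8222q, trio_of("I-1"), gt),
                   "inherited_paternal")
  expect_identical(classify_trio(e815k, trio_of("V-1"), gt),
                   "absent_in_proband")
})

test_that("control screening counts carriers and is additive over disjoint control sets", {
  fx <- fixture_paper_cohort()
  sy <- fixture_paper_cohort()$cohort$variants
  e1319k <- sy$key[!is.na(sy$protein) & sy$protein == "E1319K"]
  r8222q <- sy$key[!is.na(sy$protein) & sy$protein == "R8222Q"]
  expect_equal(control_screen(e1319k, fx$controls), 2)
  expect_equal(control_screen(r8222q, fx$controls), 0)
  for (k in fx$atp1a3$key) expect_equal(control_screen(k, fx$controls), 0)
  # additivity over a disjoint partition of the control cohort
  half1 <- fx$controls[fx$controls$sample_id %in% sprintf("CTRL%03d", 1:3), ]
  half2 <- fx$controls[!fx$controls$sample_id %in% sprintf("CTRL%03d", 1:3), ]
  for (k in c(e1319k, r8222q, fx$atp1a3$key))
    expect_equal(control_screen(k, half1) + control_screen(k, half2),
                 control_screen(k, fx$controls))
})

test_that("confirmation: CNTN4 fails, ATP1A3 confirms, absent entries error", {
  fx <- fixture_paper_cohort()
  v <- fx$cohort$variants
  cntn4 <- v$key[!is.na(v$protein) & v$protein == "V938G"]
  cntn4_carriers <- c("II-1", "III-1", "IV-1", "VI-1", "VII-1", "VIII-1")
  conf <- confirm_variant(cntn4, cntn4_carriers, fx$oracle)
  expect_identical(conf$status, "failed")
  e815k <- fx$atp1a3$key[fx$atp1a3$protein == "E815K"]
  conf2 <- confirm_variant(e815k, c("II-1", "III-1", "IV-1"), fx$oracle)
  expect_identical(conf2$status, "confirmed")
  expect_true(all(conf2$per_carrier))
  expect_error(confirm_variant(e815k, "NOT-A-SAMPLE", fx$oracle),
               "no entry")
})

test_that("simulated artifacts fail confirmation by construction", {
  sim <- simulate_cohort(sim_params(n_trios = 6, variants_per_proband = 800,
                                    artifact_rate = 0.05, seed = 3))
  art <- sim$truth[sim$truth$class == "sequencing_artifact", ]
  art <- art[art$key %in% sim$oracle$key, ]
  expect_gt(nrow(art), 0)
  for (i in seq_len(min(5, nrow(art)))) {
    conf <- confirm_variant(art$key[[i]], art$carriers[[i]], sim$oracle)
    expect_identical(conf$status, "failed")
  }
})

test_that("exclusion logic leaves exactly the four ATP1A3 mutations from the fixture candidates", {
  fx <- fixture_paper_cohort()
  casc <- run_cascade(fx$cohort, fx$known_db, fx$gene_set, "allele_aware",
                      samples = fx$exome_probands)
  rec <- shared_variants(casc$survivors, min_carriers = 4)
  candidates <- trionovo:::expand_gene_candidates(rec, casc$survivors)
  out <- exclude_non_causal(candidates, fx$trios, fx$cohort$genotypes,
                            fx$controls, fx$oracle)
  expect_setequal(out$retained$key, fx$atp1a3$key)
  expect_true(all(out$retained$validated))
  reasons <- setNames(out$removed$reason, out$removed$gene)
  expect_identical(unname(reasons[names(reasons) == "CNTN4"]),
                   "confirmation_failed")
  sy_reasons <- reasons[names(reasons) == "SYNE1"]
  expect_equal(sum(sy_reasons == "present_in_controls"), 3)
  expect_equal(sum(sy_reasons == "inherited_in_all_carriers"), 1)
})

test_that("an all-inherited candidate set is excluded entirely", {
  v <- variant_table("1", 10L, "A", "G", gene = "G1", protein = "D1N",
                     consequence = "missense")
  g <- genotype_table(c("P1", "P1-F"), v$key, "het")
  trios <- trio_table("P1", "P1-F", "P1-M")
  cands <- data.frame(key = v$key, gene = "G1", n_carriers = 1L)
  cands$carriers <- list("P1")
  oracle <- confirmation_oracle(v$key, "P1", TRUE)
  controls <- genotype_table(character(0), character(0), character(0))
  out <- exclude_non_causal(cands, trios, g, controls, oracle)
  expect_equal(nrow(out$retained), 0)
  expect_identical(out$removed$reason, "inherited_in_all_carriers")
})

test_that("a variant de novo in one carrier survives even if inherited in another", {
  v <- variant_table("1", 10L, "A", "G", gene = "G1", protein = "D1N",
                     consequence = "missense")
  g <- genotype_table(c("P1", "P1-F", "P2"), v$key, "het")
  trios <- trio_table(c("P1", "P2"), c("P1-F", "P2-F"), c("P1-M", "P2-M"))
  cands <- data.frame(key = v$key, gene = "G1", n_carriers = 2L)
  cands$carriers <- list(c("P1", "P2"))
  oracle <- confirmation_oracle(rep(v$key, 2), c("P1", "P2"), TRUE)
  controls <- genotype_table(character(0), character(0), character(0))
  out <- exclude_non_causal(cands, trios, g, controls, oracle)
  expect_equal(nrow(out$retained), 1)
  expect_equal(out$retained$n_de_novo, 1)
  expect_true(out$retained$validated)
})

test_that("exclusion never removes a confirmed, control-absent variant that is de novo somewhere", {
  sim <- simulate_cohort(sim_params(n_trios = 5, variants_per_proband = 500,
                                    seed = 21))
  casc <- run_cascade(sim$cohort, sim$known_db, sim$gene_set,
                      samples = sim$probands)
  rec <- shared_variants(casc$survivors, min_carriers = 1)
  cands <- rec$variant_level[c("key", "gene", "n_carriers", "carriers")]
  out <- exclude_non_causal(cands, sim$trios, sim$cohort$genotypes,
                            sim$controls, sim$oracle)
  for (i in seq_len(nrow(out$removed))) {
    row <- out$removed[i, ]
    if (row$reason %in% c("confirmation_failed", "present_in_controls")) next
    st <- row$trio_status[[1]]
    expect_false(any(st == "de_novo"))
  }
})
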