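test_that("position-only matching wrongly treats D801N as known, allele-aware does not", {
  atp <- atp1a3_variants()
  db <- d801y_db()
  d801n <- atp[atp$protein == "D801N", ]
  expect_true(is_known(d801n, db, "position_only"))
  expect_false(is_known(d801n, db, "allele_aware"))
  expect_false(any(is_known(atp, known_db(character(0), integer(0),
                                          character(0), character(0)),
                            "position_only")))
  expect_false(any(is_known(atp, known_db(character(0), integer(0),
                                          character(0), character(0)),
                            "allele_aware")))
})

test_that("novelty filtering preserves order and respects match mode", {
  atp <- atp1a3_variants()
  db <- d801y_db()
  pos_only <- filter_novel(atp, db, "position_only")
  expect_setequal(pos_only$protein, c("G755C", "E815K", "C927Y"))
  expect_identical(pos_only$key,
                   atp$key[atp$protein %in% pos_only$protein])
  expect_equal(nrow(filter_novel(atp, db, "allele_aware")), 4)
  expect_equal(nrow(filter_novel(atp[0, ], db)), 0)
})

test_that("consequence filter keeps NS/SS classes and drops the rest", {
  v <- variant_table("1", c(1, 2, 3) * 10L, "A", "G",
                     gene = "G1",
                     protein = c("E815K", "L10L", NA),
                     consequence = c("missense", "synonymous",
                                     "splice_acceptor"))
  kept <- filter_consequence(v)
  expect_setequal(kept$consequence, c("missense", "splice_acceptor"))
  expect_error(filter_consequence(v, keep_classes = "bogus"), "vocabulary")
})

test_that("expression filter is case-insensitive and drops missing symbols", {
  v <- variant_table("1", c(10L, 20L, 30L), "A", "G",
                     gene = c("atp1a3", "ZZZ9", NA),
                     protein = c("D10N", "D20N", "D30N"),
                     consequence = "missense")
  kept <- filter_expressed(v, gene_set(c("ATP1A3", "SYNE1")))
  expect_equal(kept$gene, "atp1a3")
  expect_equal(nrow(filter_expressed(v[0, ], gene_set("ATP1A3"))), 0)
})

test_that("the three filters are idempotent and order-invariant as set operations", {
  fx <- fixture_paper_cohort()
  v <- carried_variants(fx$cohort, "III-1")
  db <- fx$known_db
  gs <- fx$gene_set
  f1 <- function(x) filter_novel(x, db, "position_only")
  f2 <- function(x) filter_consequence(x)
  f3 <- function(x) filter_expressed(x, gs)
  ref <- f3(f2(f1(v)))
  expect_identical(f1(ref), ref)
  expect_identical(f2(ref), ref)
  expect_identical(f3(ref), ref)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  fs <- list(f1, f2, f3)
  for (p in perms) {
    out <- fs[[p[3]]](fs[[p[2]]](fs[[p[1]]](v)))
    expect_setequal(out$key, ref$key)
  }
})

test_that("allele-aware survivors are a superset of position-only survivors", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    grid <- expand.grid(chrom = c("1", "2"), pos = (1:25) * 7L,
                        ref = c("A", "C"), alt = c("G", "T"),
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid), n), ]
    v <- variant_table(grid$chrom, grid$pos, grid$ref, grid$alt)
    db_idx <- sample(seq_len(nrow(v)), 10)
    # register half the picked records with a shifted alt allele: a pure
    # position collision
    shift <- seq_along(db_idx) <= 5
    db_alt <- ifelse(shift,
                     ifelse(v$alt[db_idx] == "G", "T", "G"),
                     v$alt[db_idx])
    db <- known_db(v$chrom[db_idx], v$pos[db_idx], v$ref[db_idx], db_alt)
    aa <- filter_novel(v, db, "allele_aware")
    po <- filter_novel(v, db, "position_only")
    expect_true(all(po$key %in% aa$key))
    # the difference is exactly the position-sharing, allele-differing set
    diff_keys <- setdiff(aa$key, po$key)
    expected <- aa$key[paste(aa$chrom, aa$pos) %in% paste(db$chrom, db$pos) &
                         !aa$key %in% db$key]
    expect_setequal(diff_keys, expected)
  }
})

test_that("cascade counts on the fixture identify ATP1A3 carriers under position-only matching", {
  fx <- fixture_paper_cohort()
  casc <- run_cascade(fx$cohort, fx$known_db, fx$gene_set,
                      match_mode = "position_only",
                      samples = fx$exome_probands)
  atp_carriers <- names(Filter(function(v) any(v$gene == "ATP1A3"),
                               casc$survivors))
  expect_length(atp_carriers, 5)
  expect_setequal(atp_carriers, c("I-1", "II-1", "III-1", "IV-1", "V-1"))
  # allele-aware finds all 8
  casc2 <- run_cascade(fx$cohort, fx$known_db, fx$gene_set,
                       match_mode = "allele_aware",
                       samples = fx$exome_probands)
  atp_carriers2 <- names(Filter(function(v) any(v$gene == "ATP1A3"),
                                casc2$survivors))
  expect_length(atp_carriers2, 8)
})

test_that("a sample whose variants are all registered yields zero downstream counts", {
  v <- variant_table("1", c(10L, 20L), "A", "G", gene = "BRAIN1",
                     protein = c("D1N", "D2N"), consequence = "missense")
  g <- genotype_table(c("S1", "S1"), v$key, "het")
  co <- variant_cohort(v, g)
  db <- known_db(v$chrom, v$pos, v$ref, v$alt)
  casc <- run_cascade(co, db, gene_set("BRAIN1"))
  row <- casc$report[casc$report$sample_id == "S1", ]
  expect_equal(row$n_total_variants, 2)
  expect_equal(row$n_novel_variants, 0)
  expect_equal(row$n_novel_nsss_variants, 0)
  expect_equal(row$n_brain_variants, 0)
})

test_that("cascade reports are monotone across stages for simulated cohorts", {
  sim <- simulate_cohort(sim_params(n_trios = 3, variants_per_proband = 400,
                                    seed = 5))
  casc <- run_cascade(sim$cohort, sim$known_db, sim$gene_set,
                      samples = sim$probands)
  r <- casc$report
  expect_true(all(r$n_total_variants >= r$n_novel_variants))
  expect_true(all(r$n_novel_variants >= r$n_novel_nsss_variants))
  expect_true(all(r$n_novel_nsss_variants >= r$n_brain_variants))
  expect_true(all(r$n_novel_nsss_genes <= r$n_novel_nsss_variants))
  expect_true(all(r$n_brain_genes <= r$n_brain_variants))
  # cohort unique totals never exceed per-sample sums
  uniq <- r[r$sample_id == "TOTAL_UNIQUE", -1]
  sums <- r[r$sample_id == "TOTAL_SUM", -1]
  expect_true(all(uniq <= sums))
})

test_that("per-stage cascade counts equal the simulator truth labels", {
  sim <- simulate_cohort(sim_params(n_trios = 4, variants_per_proband = 600,
                                    seed = 9))
  casc <- run_cascade(sim$cohort, sim$known_db, sim$gene_set,
                      samples = sim$probands)
  truth <- sim$truth
  v <- sim$cohort$variants
  brain <- toupper(v$gene) %in% toupper(sim$gene_set)
  nsss <- v$consequence %in% nsss_classes()
  for (s in sim$probands) {
    carried <- carried_variants(sim$cohort, s)$key
    cls <- truth$class[match(carried, truth$key)]
    novel <- carried[cls != "known_background"]
    idx <- match(novel, v$key)
    row <- casc$report[casc$report$sample_id == s, ]
    expect_equal(row$n_novel_variants + row$n_novel_indels, length(novel))
    expect_equal(row$n_novel_nsss_variants, sum(nsss[idx]))
    expect_equal(row$n_brain_variants, sum(nsss[idx] & brain[idx]))
  }
})
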