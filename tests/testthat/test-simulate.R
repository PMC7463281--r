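test_that("all generators are deterministic given a seed", {
  scn <- demography_scenario(sr_fraction = 0.3, total_ne = 5e5, locus_length = 400)
  a <- sim_pooled_counts(scn, depth = 30, seed = 1)
  b <- sim_pooled_counts(scn, depth = 30, seed = 1)
  expect_equal(a$table, b$table)
  expect_equal(a$truth, b$truth)
  expect_equal(
    sim_haplotype_panel(seed = 2)$panel,
    sim_haplotype_panel(seed = 2)$panel
  )
  expect_equal(
    sim_testcross_progeny(1000, 0.01, seed = 3)$counts,
    sim_testcross_progeny(1000, 0.01, seed = 3)$counts
  )
  expect_equal(
    sim_segregation_counts(100, 0.9, seed = 4)$counts,
    sim_segregation_counts(100, 0.9, seed = 4)$counts
  )
  expect_equal(
    sim_survey_sample(500, c(0.8, 0.2, 0, 0), seed = 5)$counts,
    sim_survey_sample(500, c(0.8, 0.2, 0, 0), seed = 5)$counts
  )
})

test_that("generator input validation", {
  scn <- demography_scenario(locus_length = 100)
  expect_error(sim_pooled_counts(scn, depth = 0), ">= 1")
  expect_error(sim_testcross_progeny(0, 0.01), ">= 1")
  expect_error(sim_segregation_counts(0, 0.5), ">= 1")
  expect_error(sim_survey_sample(0, c(1, 0, 0, 0)), ">= 1")
  expect_error(
    sim_haplotype_panel(length_bp = 5, n_fixed = 10, seed = 1),
    "exceed"
  )
})

test_that("zero divergence gives near-zero estimated F_ST", {
  # two pools of 8 chromosomes drawn from the same latent frequencies
  # (taken from a coalescent replicate): true differentiation is 0, so
  # the pipeline estimate must be within noise of 0
  withr::with_seed(12, {
    L <- 5000
    scn <- demography_scenario(
      sr_fraction = 0.5, total_ne = 4e5, locus_length = L, x_factor = 1
    )
    sim <- sim_pooled_counts(scn, depth = 50)
    p <- numeric(L)
    p[sim$truth$pos] <- sim$truth$freq_st
    draw_pool <- function() {
      samp <- rbinom(L, 8, p) / 8
      d <- rpois(L, 50) + 1L
      der <- rbinom(L, d, samp)
      list(a = d - der, t = der)
    }
    p1 <- draw_pool()
    p2 <- draw_pool()
    tbl <- toy_sync(p1$a, p1$t, p2$a, p2$t)
  })
  est <- fst_region(tbl, c("p1", "p2"), n_boot = 500, seed = 1)
  expect_lt(abs(est$estimate), 0.05)
  expect_true(est$ci_low <= 0.02)
})

test_that("windowed F_ST increases with the SR origin time", {
  scn_old <- demography_scenario(locus_length = 1000, origin_time = 2e6)
  scn_young <- demography_scenario(locus_length = 1000, origin_time = 2e5)
  mean_fst <- function(scn, seed) {
    vals <- vapply(1:8, function(i) {
      sim <- sim_pooled_counts(scn, depth = 50, seed = seed + i)
      fst_region(sim$table, c("SR", "ST"), n_boot = 0)$estimate
    }, numeric(1))
    mean(vals)
  }
  expect_gt(mean_fst(scn_old, 100), mean_fst(scn_young, 200))
})

test_that("testcross generator: c = 0 means no recombinants", {
  out <- sim_testcross_progeny(5000, 0, seed = 6)
  rec <- out$counts$count[grepl("recombinant", out$counts$class)]
  expect_equal(sum(rec), 0)
  expect_equal(sum(out$counts$count), 5000)
})

test_that("testcross CI coverage for c = 0.0012 at n = 10000", {
  set.seed(13)
  n_rep <- 1000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    out <- sim_testcross_progeny(10000, 0.0012)
    rec <- sum(out$counts$count[grepl("recombinant", out$counts$class)])
    ci <- recomb_fraction(rec, 10000)
    covered[i] <- ci$ci_low <= 0.0012 && 0.0012 <= ci$ci_high
  }
  expect_gte(mean(covered), 0.93)
})

test_that("a fully inviable recombinant class reproduces a 12:0-style imbalance", {
  out <- sim_testcross_progeny(1e4, 0.0024, viability = c(1, 0), seed = 14)
  counts <- setNames(out$counts$count, out$counts$class)
  expect_equal(unname(counts["recombinant_2"]), 0L)
  r1 <- unname(counts["recombinant_1"])
  expect_gt(r1, 0)
  test <- chi2_reciprocal(r1, 0)
  expect_lt(test$p_exact, 0.05)
})

test_that("segregation generator: flag level and power", {
  set.seed(15)
  null_flags <- vapply(1:500, function(i) {
    out <- sim_segregation_counts(100, 0.5)
    segregation_k(out$counts$females, out$counts$males)$distorting
  }, logical(1))
  expect_gte(mean(!null_flags), 0.94)
  drive_flags <- vapply(1:500, function(i) {
    out <- sim_segregation_counts(96, 0.969)
    segregation_k(out$counts$females, out$counts$males)$distorting
  }, logical(1))
  expect_gt(mean(drive_flags), 0.99)
})

test_that("survey generator recovers the pooled disequilibrium at large n", {
  freqs <- c(ST = 0.86526, SR = 0.13455, BM = 0.00004, T = 0.00015)
  out <- sim_survey_sample(2e5, freqs, seed = 16)
  drawn <- setNames(out$counts$count / sum(out$counts$count), out$counts$type)
  s <- survey_ld(drawn)
  expect_lt(abs(s$D - 0.116), 0.005)
  # degenerate frequencies propagate to a degenerate r2
  mono <- sim_survey_sample(100, c(1, 0, 0, 0), seed = 17)
  drawn_mono <- setNames(mono$counts$count / 100, mono$counts$type)
  expect_true(is.na(survey_ld(drawn_mono)$r2))
})

test_that("pooled counts: table structure and truth sidecar agree", {
  scn <- demography_scenario(sr_fraction = 0.3, total_ne = 6e5, locus_length = 800)
  sim <- sim_pooled_counts(scn, depth = 40, seed = 18)
  expect_s3_class(sim$table, "sync_tbl")
  expect_equal(nrow(sim$table), 800)
  expect_true(all(sim$truth$pos %in% sim$table$pos))
  expect_true(all(sim$truth$freq_sr >= 0 & sim$truth$freq_sr <= 1))
  expect_true(all(!is.na(sim$table$outgroup)))
  # truth categories use the classify_sites vocabulary
  expect_true(all(sim$truth$category %in% c(
    "fixed_derived_pool1", "fixed_derived_pool2", "shared_polymorphism",
    "private_polymorphism_pool1", "private_polymorphism_pool2", "monomorphic"
  )))
})
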