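test_that("pool corrections approach the classical limits at deep coverage", {
  n <- 8
  a_n <- sum(1 / seq_len(n - 1))
  # with min_count 1 and many reads, C_pi -> (n-1)/n and C_S -> a_n
  expect_equal(xdrive:::.pi_correction(2000, 1, n), (n - 1) / n, tolerance = 2e-3)
  expect_equal(xdrive:::.s_correction(2000, 1, n), a_n, tolerance = 2e-3)
  # min_count 2 discards singleton-read configurations: corrections shrink
  expect_lt(xdrive:::.pi_correction(50, 2, n), xdrive:::.pi_correction(50, 1, n))
  expect_lt(xdrive:::.s_correction(50, 2, n), xdrive:::.s_correction(50, 1, n))
  # cache returns identical values
  expect_equal(
    xdrive:::.cached_correction(50, 2, n, "pi"),
    xdrive:::.pi_correction(50, 2, n)
  )
})

test_that("single-SNP window matches the hand-computed estimate", {
  # one biallelic site (20 A, 10 T) among 50 callable positions
  L <- 50
  a1 <- rep(30L, L)
  t1 <- rep(0L, L)
  a1[25] <- 20L
  t1[25] <- 10L
  tbl <- toy_sync(a1, t1, a2 = rep(30L, L), t2 = rep(0L, L))
  pw <- diversity_windows(tbl, "p1", "pi", window_bp = 50)
  h <- 2 * 20 * 10 / (30 * 29)
  expect_equal(pw$estimate, (h / xdrive:::.pi_correction(30, 2, 8)) / L)
  expect_equal(pw$n_snps, 1)
  expect_equal(pw$n_sites, L)
  tw <- diversity_windows(tbl, "p1", "theta_w", window_bp = 50)
  expect_equal(tw$estimate, (1 / xdrive:::.s_correction(30, 2, 8)) / L)
  # Tajima's D numerator sign: pi term vs theta term
  dw <- diversity_windows(tbl, "p1", "tajimas_d", window_bp = 50)
  expect_equal(
    sign(dw$estimate),
    sign(pw$estimate - tw$estimate)
  )
})

test_that("min_count excludes low-count minor alleles", {
  L <- 10
  a1 <- rep(30L, L)
  t1 <- rep(0L, L)
  t1[5] <- 1L # singleton read: not a SNP at min_count = 2
  tbl <- toy_sync(a1, t1, a2 = rep(30L, L), t2 = rep(0L, L))
  pw <- diversity_windows(tbl, "p1", "pi", window_bp = 10)
  expect_equal(pw$n_snps, 0)
  expect_equal(pw$estimate, 0)
  pw1 <- diversity_windows(tbl, "p1", "pi", window_bp = 10, min_count = 1)
  expect_equal(pw1$n_snps, 1)
  expect_gt(pw1$estimate, 0)
})

test_that("windows with too many uncallable positions are skipped", {
  # 100-bp window with only 50 callable rows present: 50% uncallable
  L <- 50
  tbl <- toy_sync(
    a1 = rep(30L, L), t1 = rep(0L, L),
    a2 = rep(30L, L), t2 = rep(0L, L),
    pos = seq_len(L)
  )
  out <- diversity_windows(tbl, "p1", "pi", window_bp = 100, max_uncallable = 0.4)
  expect_true(out$skipped)
  expect_true(is.na(out$estimate))
  expect_equal(out$frac_uncallable, 0.5)
  ok <- diversity_windows(tbl, "p1", "pi", window_bp = 100, max_uncallable = 0.6)
  expect_false(ok$skipped)
  expect_equal(ok$estimate, 0)
})

test_that("intergenic masking removes genic positions from both sums", {
  L <- 100
  a1 <- rep(30L, L)
  t1 <- rep(0L, L)
  a1[10] <- 20L
  t1[10] <- 10L # SNP inside the masked feature
  a1[60] <- 20L
  t1[60] <- 10L # SNP outside
  tbl <- toy_sync(a1, t1, a2 = rep(30L, L), t2 = rep(0L, L))
  genes <- tibble::tibble(chrom = "X", start = 1, end = 50)
  masked <- diversity_windows(tbl, "p1", "pi",
    window_bp = 100, intergenic = genes, max_uncallable = 0.6
  )
  expect_equal(masked$n_sites, 50)
  expect_equal(masked$n_snps, 1)
  unmasked <- diversity_windows(tbl, "p1", "pi", window_bp = 100)
  expect_equal(unmasked$n_snps, 2)
})

test_that("pooled pi recovers the generating heterozygosity within 10%", {
  # seeded replicate draws from the shared coalescent generator; the
  # corrected estimator's mean tracks the mean realized sample pi
  set.seed(11)
  n_rep <- 40
  pis <- numeric(n_rep)
  tru <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    scn <- demography_scenario(
      sr_fraction = 0.5, total_ne = 4e5, locus_length = 2000, x_factor = 1
    )
    sim <- sim_pooled_counts(scn, depth = 60)
    pw <- diversity_windows(sim$table, "ST", "pi", window_bp = 2000)
    pis[r] <- pw$estimate
    n <- 8
    tru[r] <- sum(2 * sim$truth$freq_st * (1 - sim$truth$freq_st) * n / (n - 1)) / 2000
  }
  expect_lt(abs(mean(pis) - mean(tru)) / mean(tru), 0.10)
})

test_that("windowed Tajima's D is calibrated near zero on neutral data", {
  set.seed(7)
  n_rep <- 60
  ds <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    scn <- demography_scenario(
      sr_fraction = 0.5, total_ne = 4e5, locus_length = 2000, x_factor = 1
    )
    sim <- sim_pooled_counts(scn, depth = 60)
    ds[r] <- diversity_windows(sim$table, "ST", "tajimas_d", window_bp = 2000)$estimate
  }
  se <- sd(ds, na.rm = TRUE) / sqrt(sum(!is.na(ds)))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 3 * se)
})

test_that("the SR pool's star genealogy pushes Tajima's D negative", {
  set.seed(3)
  n_rep <- 25
  d_sr <- numeric(n_rep)
  d_st <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    scn <- demography_scenario(sr_fraction = 0.135, locus_length = 2000)
    sim <- sim_pooled_counts(scn, depth = 60)
    d_sr[r] <- diversity_windows(sim$table, "SR", "tajimas_d", window_bp = 2000)$estimate
    d_st[r] <- diversity_windows(sim$table, "ST", "tajimas_d", window_bp = 2000)$estimate
  }
  expect_lt(mean(d_sr, na.rm = TRUE), mean(d_st, na.rm = TRUE))
  expect_lt(mean(d_sr, na.rm = TRUE), 0)
})

test_that("unknown pools are rejected", {
  tbl <- toy_sync(a1 = 30, t1 = 0, a2 = 30, t2 = 0)
  expect_error(diversity_windows(tbl, "nope"), "not in table")
})
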