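sim_panel_case <- function(seed = 1, ...) {
  sim_haplotype_panel(
    n_per_arrangement = 8, regions = c("XR1", "XR2"), length_bp = 120,
    seed = seed, ...
  )
}

test_that("FASTA round-trip preserves the panel", {
  sim <- sim_panel_case(seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_panel_fasta(sim$panel, dir)
  back <- read_haplotype_panel(paths)
  ordered <- sim$panel[order(sim$panel$region, sim$panel$strain), ]
  got <- back[order(back$region, back$strain), ]
  expect_equal(unname(got$seq), ordered$seq)
  expect_equal(got$arrangement, ordered$arrangement)
})

test_that("read_haplotype_panel validates names and alignment", {
  dir <- withr::local_tempdir()
  bad_names <- file.path(dir, "r1.fasta")
  writeLines(c(">s1", "ACGT", ">s2|ST", "ACGT"), bad_names)
  expect_error(read_haplotype_panel(c(r1 = bad_names)), "strain\\|arrangement")
  ragged <- file.path(dir, "r2.fasta")
  writeLines(c(">s1|SR", "ACGTA", ">s2|ST", "ACGT"), ragged)
  expect_error(read_haplotype_panel(c(r2 = ragged)), "aligned")
})

test_that("singleton and indel columns are removed, truth-checked", {
  sim <- sim_panel_case(seed = 3)
  sm <- build_segregating_matrix(sim$panel)
  kept <- sm$sites |>
    dplyr::left_join(sim$truth, by = c("region", "position"))
  # nothing kept may come from singleton, indel, or monomorphic columns
  expect_true(all(kept$class %in% c("fixed", "shared")))
  # every fixed column survives (8 vs 8 split can never be a singleton)
  truth_fixed <- sim$truth[sim$truth$class == "fixed", ]
  expect_true(all(
    paste(truth_fixed$region, truth_fixed$position) %in%
      paste(sm$sites$region, sm$sites$position)
  ))
  expect_equal(rownames(sm$matrix), unique(sim$panel$strain))
  expect_true(all(sm$matrix %in% 0:1))
})

test_that("min_minor controls singleton removal", {
  sim <- sim_panel_case(seed = 4)
  with_singletons <- build_segregating_matrix(sim$panel, min_minor = 1)
  without <- build_segregating_matrix(sim$panel, min_minor = 2)
  expect_gt(ncol(with_singletons$matrix), ncol(without$matrix))
})

test_that("outgroup polarity labels derived alleles", {
  # 4 strains, one region, two sites; outgroup carries the first allele
  panel <- tibble::tibble(
    strain = c("a", "b", "c", "d"),
    arrangement = c("SR", "SR", "ST", "ST"),
    region = "r",
    seq = c("AAG", "AAG", "GAG", "GAG")
  )
  sm <- build_segregating_matrix(panel, outgroup = c(r = "AAG"))
  expect_equal(sm$sites$polarity, "derived")
  expect_equal(sm$sites$allele1, "G") # non-ancestral at column 1
  expect_equal(unname(sm$matrix[, 1]), c(0L, 0L, 1L, 1L))
})

test_that("ld_matrix r2 equals the brute-force haplotype-table value", {
  sim <- sim_panel_case(seed = 5)
  sm <- build_segregating_matrix(sim$panel)
  ld <- ld_matrix(sm)
  for (row in sample.int(nrow(ld), min(25, nrow(ld)))) {
    a <- sm$matrix[, ld$site_i[row]]
    b <- sm$matrix[, ld$site_j[row]]
    expect_equal(ld$r2[row], oracle_r2(a, b), tolerance = 1e-12)
  }
  # provenance joined
  expect_true(all(c("region_i", "region_j") %in% names(ld)))
})

test_that("an all-fixed panel gives r2 = 1 everywhere", {
  sim <- sim_haplotype_panel(
    n_per_arrangement = 8, length_bp = 60, n_fixed = 6,
    n_shared = 0, n_singleton = 0, n_indel = 0, seed = 6
  )
  sm <- build_segregating_matrix(sim$panel)
  ld <- ld_matrix(sm)
  expect_equal(ld$r2, rep(1, nrow(ld)))
  expect_true(all(ld$q < 0.05))
})

test_that("BH q-values match the step-up definition", {
  sim <- sim_panel_case(seed = 7)
  sm <- build_segregating_matrix(sim$panel)
  ld <- ld_matrix(sm)
  expect_equal(ld$q, oracle_bh(ld$p), tolerance = 1e-12)
  fet <- arrangement_fet(sm)
  expect_equal(fet$q, oracle_bh(fet$p), tolerance = 1e-12)
  # toy vector against the definition directly
  p <- c(0.01, 0.04, 0.03, 0.005, 0.9)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
})

test_that("permutation significance is seeded and bounded", {
  sim <- sim_haplotype_panel(
    n_per_arrangement = 4, length_bp = 60, n_fixed = 3,
    n_shared = 2, n_singleton = 0, n_indel = 0, seed = 8
  )
  sm <- build_segregating_matrix(sim$panel)
  p1 <- ld_matrix(sm, significance = "permutation", n_perm = 200, seed = 1)
  p2 <- ld_matrix(sm, significance = "permutation", n_perm = 200, seed = 1)
  expect_equal(p1, p2)
  expect_true(all(p1$p > 0 & p1$p <= 1))
})

test_that("arrangement FET: the 8/8 fixed split has the exact hypergeometric p", {
  sim <- sim_haplotype_panel(
    n_per_arrangement = 8, length_bp = 60, n_fixed = 4,
    n_shared = 0, n_singleton = 0, n_indel = 0, seed = 9
  )
  sm <- build_segregating_matrix(sim$panel)
  fet <- arrangement_fet(sm)
  # the most extreme 8-vs-8 table: two-sided p = 2 / C(16, 8)
  expect_equal(fet$p, rep(2 / choose(16, 8), nrow(fet)), tolerance = 1e-12)
  expect_true(all(fet$powered))
  expect_true(all(fet$min_attainable_p <= fet$p + 1e-12))
})

test_that("zero fixed sites yield no significant arrangement association", {
  sim <- sim_haplotype_panel(
    n_per_arrangement = 8, length_bp = 200, n_fixed = 0,
    n_shared = 8, n_singleton = 0, n_indel = 0, seed = 10
  )
  sm <- build_segregating_matrix(sim$panel)
  fet <- arrangement_fet(sm)
  expect_true(all(fet$q >= 0.05))
})

test_that("matrix preconditions are enforced", {
  m <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 0L, 0L, 0L))
  expect_error(ld_matrix(m), "zero-variance")
  expect_error(ld_matrix(m[, 1, drop = FALSE]), "at least 2")
  expect_error(
    arrangement_fet(m, arrangement = c("SR", "SR", "ST", "ST")),
    "zero-variance"
  )
  expect_error(
    arrangement_fet(m[, 1, drop = FALSE], arrangement = rep("SR", 4)),
    "exactly two"
  )
  expect_error(arrangement_fet(m[, 1, drop = FALSE]), "required")
  small <- tibble::tibble(
    strain = c("a", "b"), arrangement = c("SR", "ST"),
    region = "r", seq = c("AA", "AT")
  )
  expect_error(build_segregating_matrix(small), "at least 4")
})
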