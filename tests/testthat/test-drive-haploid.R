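table1 <- c(ST = 0.86526, SR = 0.13455, BM = 0.00004, T = 0.00015)

test_that("gamete_distribution computes allele frequencies and D by definition", {
  d <- gamete_distribution(table1)
  p_A <- table1[["SR"]] + table1[["BM"]]
  q_B <- table1[["SR"]] + table1[["T"]]
  expect_equal(d$p_A, p_A)
  expect_equal(d$q_B, q_B)
  expect_equal(d$D, table1[["SR"]] - p_A * q_B)
  expect_equal(d$r2, d$D^2 / (p_A * (1 - p_A) * q_B * (1 - q_B)))
  # monomorphic locus: r2 undefined
  expect_true(is.na(gamete_distribution(c(ST = 1, SR = 0, BM = 0, T = 0))$r2))
  # unnamed vectors are taken in canonical order
  expect_equal(gamete_distribution(unname(table1))$D, d$D)
  expect_error(gamete_distribution(c(0.5, 0.5)), "length-4")
  expect_error(gamete_distribution(c(0.5, 0.6, 0, 0)), "sum to 1")
})

test_that("classical haploid recursion: recombination alone drives D to zero", {
  eq <- haploid_selection_equilibrium(
    c(ST = 0.4, SR = 0.4, BM = 0.1, T = 0.1),
    s = c(0, 0, 0, 0), c = 0.05
  )
  expect_true(eq$converged)
  expect_equal(eq$distribution$D, 0, tolerance = 1e-8)
  # allele frequencies are untouched by recombination
  expect_equal(eq$distribution$p_A, 0.5, tolerance = 1e-9)
  expect_equal(eq$distribution$q_B, 0.5, tolerance = 1e-9)
})

test_that("classical recursion: with c = 0 the fittest type fixes", {
  eq <- haploid_selection_equilibrium(
    c(ST = 0.25, SR = 0.25, BM = 0.25, T = 0.25),
    s = c(ST = 0, SR = 0.1, BM = 0.2, T = 0.3), c = 0,
    t_max = 1e6
  )
  expect_equal(eq$distribution$ST, 1, tolerance = 1e-6)
})

test_that("pairing model equilibrium matches its closed form", {
  k <- setNames(measured_k()$k, measured_k()$type)
  s <- c(ST = 0, SR = 0, BM = 0.65, T = 0.30)
  x0 <- c(ST = 0.865, SR = 0.135, BM = 0, T = 0)
  eq <- haploid_selection_equilibrium(x0, s, c = 0.0012, production = "pairing", k = k)
  P <- (0.0012 / 2) * x0[["SR"]] * x0[["ST"]]
  lam <- function(g) (2 + 2 * k[[g]]) / (2 + 2 * k[["ST"]])
  y_exp <- vapply(c("BM", "T"), function(g) {
    (1 - s[[g]]) * P / (1 - (1 - s[[g]]) * lam(g))
  }, numeric(1))
  tot <- x0[["ST"]] + x0[["SR"]] + sum(y_exp)
  expect_equal(eq$distribution$BM, y_exp[["BM"]] / tot, tolerance = 1e-12)
  expect_equal(eq$distribution$T, y_exp[["T"]] / tot, tolerance = 1e-12)
})

test_that("pairing model reports divergence when selection cannot hold a class", {
  # BM has lambda > 1 (transmission advantage): s = 0 diverges
  expect_error(
    haploid_selection_equilibrium(
      c(ST = 0.865, SR = 0.135, BM = 0, T = 0),
      s = c(0, 0, 0, 0), c = 0.0012, production = "pairing"
    ),
    "diverges"
  )
})

test_that("fit_haploid_s round-trips a known s through the pairing equilibrium", {
  k <- setNames(measured_k()$k, measured_k()$type)
  lam <- function(g) (2 + 2 * k[[g]]) / (2 + 2 * k[["ST"]])
  s_true <- c(T = 0.30, BM = 0.65)
  cc <- 0.0012
  # build a self-consistent observed vector: backbone plus the exact
  # pairing-model equilibrium recombinant frequencies, summing to 1
  SR <- 0.135
  ST <- 1 - SR
  for (iter in 1:50) {
    P <- (cc / 2) * SR * ST
    yT <- (1 - s_true[["T"]]) * P / (1 - (1 - s_true[["T"]]) * lam("T"))
    yBM <- (1 - s_true[["BM"]]) * P / (1 - (1 - s_true[["BM"]]) * lam("BM"))
    ST <- 1 - SR - yT - yBM
  }
  obs <- c(ST = ST, SR = SR, BM = yBM, T = yT)
  fit <- fit_haploid_s(obs, c = cc, k = k)
  expect_equal(fit$fits$s[fit$fits$type == "T"], s_true[["T"]], tolerance = 1e-5)
  expect_equal(fit$fits$s[fit$fits$type == "BM"], s_true[["BM"]], tolerance = 1e-5)
})

test_that("fit_haploid_s input validation", {
  expect_error(fit_haploid_s(table1, c = 0), "positive")
  bad <- c(ST = 0.865, SR = 0.135, BM = 0, T = 0)
  expect_error(fit_haploid_s(bad), "positive")
})

test_that("haploid fit accessors return tidy shapes", {
  fit <- fit_haploid_s(table1)
  td <- tidy(fit)
  expect_true(all(c("type", "s", "observed", "lambda") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$s_T > 0 && gl$s_T < 1)
  expect_true(gl$s_BM > 0 && gl$s_BM < 1)
})
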