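test_that("diploid_step matches exhaustive mating-table enumeration", {
  set.seed(42)
  for (rep in 1:15) {
    cs <- random_drive_case()
    params <- drive_params(
      k = cs$k, costs = cs$costs, c = cs$c,
      male_expressed = cs$male_expressed
    )
    nxt <- diploid_step(cs$state, params)
    orc <- oracle_diploid_step(
      cs$state$F, as.numeric(cs$state$m),
      as.numeric(cs$k), as.numeric(cs$costs), cs$c, cs$male_expressed
    )
    expect_equal(unname(nxt$F), unname(orc$F), tolerance = 1e-12)
    expect_equal(unname(nxt$m), orc$m, tolerance = 1e-12)
    expect_equal(nxt$sex_ratio, orc$sex_ratio, tolerance = 1e-12)
    # frequencies remain simplex-valued
    expect_equal(sum(nxt$F), 1, tolerance = 1e-12)
    expect_equal(sum(nxt$m), 1, tolerance = 1e-12)
    expect_true(all(nxt$F >= -1e-15) && all(nxt$m >= -1e-15))
  }
})

test_that("neutral recursion conserves allele frequencies while |D| decays", {
  params <- drive_params(
    k = c(0.5, 0.5, 0.5, 0.5), costs = c(0, 0, 0, 0), c = 0.02
  )
  st <- diploid_state(c(ST = 0.5, SR = 0.3, BM = 0.1, T = 0.1))
  s0 <- state_summary(st, params)
  prev_absD <- abs(s0$D_pooled)
  cur <- st
  for (t in 1:60) {
    cur <- diploid_step(cur, params)
    s <- state_summary(cur, params)
    expect_equal(s$p_A_pooled, s0$p_A_pooled, tolerance = 1e-12)
    expect_equal(s$q_B_pooled, s0$q_B_pooled, tolerance = 1e-12)
    expect_lte(abs(s$D_pooled), prev_absD + 1e-15)
    prev_absD <- abs(s$D_pooled)
  }
  expect_lt(prev_absD, abs(s0$D_pooled) / 2)
})

test_that("neutral Mendelian system has a 1:1 sex ratio; drive biases it", {
  neutral <- drive_params(k = rep(0.5, 4), costs = rep(0, 4), c = 0)
  st <- diploid_state(c(0.7, 0.3, 0, 0))
  expect_equal(diploid_step(st, neutral)$sex_ratio, 0.5)
  # a population fixed for SR males sires 96.9% daughters
  drv <- drive_params(costs = rep(0, 4), c = 0)
  st_sr <- diploid_state(x_female = c(0, 1, 0, 0), x_male = c(0, 1, 0, 0))
  expect_equal(diploid_step(st_sr, drv)$sex_ratio, 0.969)
})

test_that("find_balance_cost round-trips: equilibrium frequency hits the target", {
  fit <- find_balance_cost(k_full = 0.969, target = 0.135)
  expect_equal(fit$eq_freq, 0.135, tolerance = 1e-5)
  expect_true(fit$cost > 0 && fit$cost < 1)
  expect_equal(fit$percent, 100 * fit$cost)
  gl <- glance(fit)
  expect_equal(gl$cost, fit$cost)
})

test_that("the balance state is a fixed point of the full recursion", {
  fit <- find_balance_cost(k_full = 0.969, target = 0.135)
  st <- xdrive:::.balance_state(fit$cost)
  params <- drive_params(
    k = c(ST = 0.5, SR = 0.969, BM = 0.5, T = 0.5),
    costs = c(0, fit$cost, 0, 0), c = 0
  )
  nxt <- diploid_step(st, params)
  expect_equal(unname(nxt$F), unname(st$F), tolerance = 1e-9)
  expect_equal(unname(as.numeric(nxt$m)), unname(as.numeric(st$m)), tolerance = 1e-9)
})

test_that("two-type equilibrium frequency is monotone decreasing in the cost", {
  eqs <- vapply(
    c(0.2, 0.4, 0.6, 0.8),
    function(cost) xdrive:::.two_type_eq(cost),
    numeric(1)
  )
  expect_true(all(diff(eqs) < 0))
})

test_that("female-limited recessive costs cannot balance strong drive", {
  # documented model decision: with male_expressed = FALSE no cost in
  # [0, 1] holds k = 0.969 at frequency 0.135, so the solver must refuse
  expect_error(
    find_balance_cost(k_full = 0.969, target = 0.135, male_expressed = FALSE),
    "unreachable"
  )
})

test_that("find_balance_cost rejects driveless and unreachable inputs", {
  expect_error(find_balance_cost(k_full = 0.5, target = 0.1), "no drive")
  expect_error(find_balance_cost(k_full = 0.969, target = 2), regexp = ".")
})

test_that("ld_decay_experiment decays monotonically from the balance D0", {
  ex <- ld_decay_experiment(sr_cost = 0.48, t_max = 150)
  expect_s3_class(ex, "ld_decay_experiment")
  expect_gt(ex$D0, 0.1)
  traj <- tidy(ex)
  expect_equal(nrow(traj), 151)
  # D decays monotonically through the half-life region (it later relaxes
  # toward a small positive drive-recombination equilibrium value)
  expect_true(all(diff(traj$D_pooled[1:100]) < 0))
  expect_lt(traj$D_pooled[100], ex$D0 / 2)
  expect_true(is.finite(ex$half_life[["pooled"]]))
  # recombinant classes are being produced from the SR/ST heterozygotes
  expect_gt(traj$BM_pooled[151], 0)
  expect_gt(traj$T_pooled[151], 0)
  gl <- glance(ex)
  expect_equal(gl$D0, ex$D0)
})

test_that("diploid recursion LD decays faster than the gametic-phase law", {
  # ongoing drive + selection removes recombinants through the male pool,
  # so the D half-life falls far below the neutral 577 generations
  ex <- ld_decay_experiment(sr_cost = 0.48, t_max = 150)
  expect_lt(ex$half_life[["pooled"]], half_life(0.0012)$rounded / 2)
})

test_that("state and parameter validation", {
  expect_error(drive_params(k = c(0.5, 1.2, 0.5, 0.5)), "0, 1")
  expect_error(drive_params(costs = c(-0.1, 0, 0, 0)), "0, 1")
  expect_error(diploid_state(c(0.5, 0.6, 0, 0)), "sum to 1")
  badF <- matrix(1 / 8, 4, 4)
  expect_error(diploid_state(x_male = rep(0.25, 4), F = badF), "sum to 1")
  st <- diploid_state(rep(0.25, 4))
  all_dead <- drive_params(costs = c(1, 1, 1, 1), c = 0)
  expect_error(diploid_step(st, all_dead), "inviable")
})

test_that("iterate_to_equilibrium converges and reports half-lives", {
  params <- drive_params(k = rep(0.5, 4), costs = rep(0, 4), c = 0.05)
  st <- diploid_state(c(ST = 0.5, SR = 0.3, BM = 0.1, T = 0.1))
  eq <- iterate_to_equilibrium(st, params, tol = 1e-10, t_max = 5000)
  expect_true(eq$converged)
  expect_true(all(is.finite(eq$half_life)))
  final <- state_summary(eq$state, params)
  expect_equal(final$D_pooled, 0, tolerance = 1e-6)
  # D0 = 0 start (linkage equilibrium): half-life undefined
  st_le <- diploid_state(c(0.25, 0.25, 0.25, 0.25))
  eq0 <- iterate_to_equilibrium(st_le, params, tol = 1e-10, t_max = 100)
  expect_true(is.na(eq0$half_life[["pooled"]]))
})

test_that("state_summary pools female and male gametes 2:1", {
  params <- drive_params(costs = rep(0, 4), c = 0.0012)
  st <- diploid_state(
    x_female = c(0.6, 0.2, 0.1, 0.1),
    x_male = c(0.4, 0.4, 0.1, 0.1)
  )
  s <- state_summary(st, params)
  xf <- xdrive:::.female_gametes(st$F, params$c)
  expect_equal(
    s$SR_pooled,
    unname((2 / 3) * xf[["SR"]] + (1 / 3) * st$m[["SR"]])
  )
  expect_equal(s$SR_male, unname(st$m[["SR"]]))
})

test_that("tidy.diploid_state returns the 10 female genotypes plus 4 male types", {
  st <- diploid_state(c(0.5, 0.3, 0.1, 0.1))
  td <- tidy(st)
  expect_equal(sum(td$sex == "female"), 10)
  expect_equal(sum(td$sex == "male"), 4)
  expect_equal(sum(td$frequency[td$sex == "female"]), 1, tolerance = 1e-12)
  expect_equal(sum(td$frequency[td$sex == "male"]), 1, tolerance = 1e-12)
})
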