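# Deterministic diploid X-linked drive-selection-recombination recursion:
# sex-structured genotype frequencies over the four gamete types, male
# meiotic drive, female-only recombination, recessive viability costs, and
# the solvers built on top (balance cost, invasion thresholds, LD decay).

#' Model parameters for the diploid X-linked drive recursion
#'
#' @param k Per-type segregation proportions (proportion of a male's
#'   progeny that are daughters, i.e. receive his X). Defaults to the
#'   measured values; use `measured_k(mendelian_st = TRUE)` semantics via
#'   `mendelian_st = TRUE` to treat `ST` as Mendelian.
#' @param costs Per-type recessive homozygous viability costs in `[0, 1]`.
#' @param c Female recombination fraction between the basal+medial unit
#'   (locus A) and the terminal inversion (locus B); no recombination in
#'   males.
#' @param male_expressed If `TRUE` (default), the recessive cost of a type
#'   is also expressed in hemizygous males carrying it (standard X-linked
#'   recessive exposure). If `FALSE`, costs act on homozygous females only.
#'   The default matters: with female-limited costs no cost in `[0, 1]`
#'   can hold strong drive (`k = 0.969`) at intermediate frequency, so the
#'   drive-selection balance analyses require male expression.
#' @param mendelian_st Replace `ST`'s measured `k` (0.439) with 0.5.
#' @return Object of class `drive_params`.
#' @export
#' @examples
#' drive_params(costs = c(0, 0.43, 0, 0))
drive_params <- function(k = NULL, costs = c(0, 0, 0, 0), c = 0.0012,
                         male_expressed = TRUE, mendelian_st = FALSE) {
  if (is.null(k)) k <- .k_vector(mendelian_st = mendelian_st)
  k <- .canon4(k, "k")
  if (mendelian_st) k[["ST"]] <- 0.5
  costs <- .canon4(costs, "costs")
  .assert_prob(k, "k")
  .assert_prob(costs, "costs")
  .assert_prob(c, "c")
  structure(
    list(k = k, costs = costs, c = c, male_expressed = isTRUE(male_expressed)),
    class = "drive_params"
  )
}

#' @export
print.drive_params <- function(x, ...) {
  cat("X-linked drive model parameters\n")
  cat("  k:     ", paste(sprintf("%s=%.3f", names(x$k), x$k), collapse = " "), "\n")
  cat("  costs: ", paste(sprintf("%s=%.3f", names(x$costs), x$costs), collapse = " "), "\n")
  cat("  c =", x$c, " male_expressed =", x$male_expressed, "\n")
  invisible(x)
}

#' Sex-structured diploid state
#'
#' Constructs the model state: female genotype frequencies over ordered
#' pairs of the four gamete types (a 4x4 matrix whose unordered-pair sums
#' give the 10 genotypes) and male hemizygote frequencies over the four
#' types. When built from gamete-pool frequencies, females are formed by
#' random union (`outer(xf, xf)`).
#'
#' @param x_female Length-4 female gamete-pool frequencies (maternal and
#'   paternal contributions assumed equal), or `NULL` when `F` is given.
#' @param x_male Length-4 male frequencies; defaults to `x_female`.
#' @param F Optional explicit 4x4 ordered-pair female genotype matrix.
#' @return Object of class `diploid_state` with elements `F` (4x4), `m`
#'   (length 4), `generation`.
#' @export
#' @examples
#' diploid_state(c(ST = 0.865, SR = 0.135, BM = 0, T = 0))
diploid_state <- function(x_female = NULL, x_male = x_female, F = NULL) {
  if (is.null(F)) {
    x_female <- .canon4(x_female, "x_female")
    .assert_freq_vector(x_female, "x_female")
    F <- outer(as.numeric(x_female), as.numeric(x_female))
  } else {
    if (!is.matrix(F) || !all(dim(F) == c(4, 4))) abort("`F` must be a 4x4 matrix.")
    if (any(F < -1e-15) || abs(sum(F) - 1) > 1e-8) {
      abort("`F` must be non-negative and sum to 1.")
    }
  }
  x_male <- .canon4(x_male, "x_male")
  .assert_freq_vector(x_male, "x_male")
  dimnames(F) <- list(gamete_types(), gamete_types())
  structure(
    list(F = F, m = setNames(as.numeric(x_male), gamete_types()), generation = 0L),
    class = "diploid_state"
  )
}

#' @export
print.diploid_state <- function(x, ...) {
  cat("Diploid X-linked state (generation ", x$generation, ")\n", sep = "")
  print(state_summary(x))
  invisible(x)
}

#' @export
tidy.diploid_state <- function(x, ...) {
  types <- gamete_types()
  combos <- tidyr::expand_grid(a = types, b = types) |>
    filter(match(.data$a, types) <= match(.data$b, types))
  combos |>
    mutate(
      sex = "female",
      genotype = paste(.data$a, .data$b, sep = "/"),
      frequency = purrr::map2_dbl(.data$a, .data$b, function(a, b) {
        if (a == b) x$F[a, b] else x$F[a, b] + x$F[b, a]
      })
    ) |>
    select("sex", "genotype", "frequency") |>
    bind_rows(tibble(
      sex = "male", genotype = types, frequency = as.numeric(x$m)
    ))
}

# marginal maternal-gamete-origin frequencies of the female genotype matrix
.female_marginal <- function(F) (rowSums(F) + colSums(F)) / 2

# gamete output of the (post-selection) female genotype matrix with
# female-only recombination between locus A and locus B: double
# heterozygotes SR/ST (AB/ab) and BM/T (Ab/aB) exchange gamete classes at
# c/2 per recombinant class
.female_gametes <- function(F, c) {
  g <- .female_marginal(F)
  h_coupling <- F["SR", "ST"] + F["ST", "SR"] # AB/ab
  h_repulsion <- F["BM", "T"] + F["T", "BM"] # Ab/aB
  d <- (c / 2) * h_coupling - (c / 2) * h_repulsion
  g[["ST"]] <- g[["ST"]] - d
  g[["SR"]] <- g[["SR"]] - d
  g[["BM"]] <- g[["BM"]] + d
  g[["T"]] <- g[["T"]] + d
  g
}

#' One generation of the diploid X-linked drive recursion
#'
#' Advances the sex-structured state by one generation:
#' 1. viability selection — female genotype `g/g` is weighted by
#'    `1 - cost_g` (heterozygous females unaffected); when
#'    `male_expressed`, a hemizygous male of type `g` is weighted by
#'    `1 - cost_g`; each sex renormalized;
#' 2. female meiosis — Mendelian gamete output with recombination `c`
#'    acting only in double heterozygotes (`SR/ST` produces `BM` and `T`
#'    gametes at `c/2` each; `BM/T` produces `SR` and `ST` at `c/2` each);
#' 3. male meiosis/drive — a father of type `g` sires daughters (who
#'    receive his X) in proportion to `k_g`, so the paternal-X
#'    distribution among daughters is `m * k / sum(m * k)`;
#' 4. random mating with equal male mating success — next-generation
#'    females from maternal gamete x paternal X (symmetrized over origin),
#'    males from maternal gametes;
#' 5. population sex ratio from the mean `k` among (post-selection)
#'    fathers.
#'
#' @param state A [diploid_state()].
#' @param params A [drive_params()].
#' @return The next-generation `diploid_state`, with attribute `sex_ratio`
#'   (proportion of daughters) available via `state$sex_ratio`.
#' @export
#' @examples
#' st <- diploid_state(c(0.865, 0.135, 0, 0))
#' diploid_step(st, drive_params(costs = c(0, 0.43, 0, 0)))
diploid_step <- function(state, params) {
  stopifnot(inherits(state, "diploid_state"), inherits(params, "drive_params"))
  F <- state$F
  m <- state$m
  costs <- params$costs

  # 1. viability selection (recessive)
  w <- matrix(1, 4, 4)
  diag(w) <- 1 - as.numeric(costs)
  F <- F * w
  sF <- sum(F)
  if (sF <= 0) abort("all females inviable under the supplied costs.")
  F <- F / sF
  if (params$male_expressed) {
    m <- m * (1 - as.numeric(costs))
    sm <- sum(m)
    if (sm <= 0) abort("all males inviable under the supplied costs.")
    m <- m / sm
  }

  # 2. female meiosis with recombination
  gf <- .female_gametes(F, params$c)

  # 3. male drive: paternal-X distribution among daughters
  kbar <- sum(m * params$k)
  if (kbar <= 0) abort("no daughters produced (sum(m * k) = 0).")
  pat <- m * params$k / kbar

  # 4. random union
  Fn <- (outer(as.numeric(gf), as.numeric(pat)) +
    outer(as.numeric(pat), as.numeric(gf))) / 2
  mn <- gf

  if (any(Fn < -1e-15) || any(mn < -1e-15)) {
    abort("internal error: negative frequency after update.")
  }
  dimnames(Fn) <- list(gamete_types(), gamete_types())
  structure(
    list(
      F = Fn, m = setNames(as.numeric(mn), gamete_types()),
      generation = state$generation + 1L, sex_ratio = kbar
    ),
    class = "diploid_state"
  )
}

#' Summaries of a diploid state
#'
#' @param state A [diploid_state()].
#' @param params Optional [drive_params()]; when supplied, `D_female` is
#'   measured in the female-transmitted gamete pool (including
#'   recombination), otherwise in the female genotype marginal.
#' @return One-row tibble: per-type frequencies in the female pool, male
#'   pool, and pooled X pool (2/3 female + 1/3 male); `p_A`, `q_B`, `D`
#'   and `r2` in each pool; `sex_ratio` when known.
#' @export
state_summary <- function(state, params = NULL) {
  stopifnot(inherits(state, "diploid_state"))
  xf <- if (is.null(params)) {
    .female_marginal(state$F)
  } else {
    .female_gametes(state$F, params$c)
  }
  xm <- state$m
  xp <- (2 / 3) * xf + (1 / 3) * xm
  stat <- function(x, suffix) {
    d <- gamete_distribution(x / sum(x))
    names(d) <- paste0(names(d), "_", suffix)
    d
  }
  bind_cols(
    tibble(generation = state$generation),
    stat(xp, "pooled"), stat(xf, "female"), stat(xm, "male"),
    tibble(sex_ratio = state$sex_ratio %||% NA_real_)
  )
}

#' Iterate the diploid recursion to equilibrium
#'
#' Runs [diploid_step()] until the maximum change in any female-genotype or
#' male frequency falls below `tol`, or `t_max` generations. Records the
#' trajectory of pooled/female/male disequilibrium and reports the D
#' half-life (first generation at which `|D|` in the pooled X pool falls
#' to half its initial value; also per pool).
#'
#' @param state Initial [diploid_state()].
#' @param params [drive_params()].
#' @param tol Convergence tolerance (max absolute per-entry change).
#' @param t_max Generation cap.
#' @param record If `TRUE` (default), keep the per-generation trajectory.
#' @return Object of class `drive_equilibrium`: `state` (final),
#'   `converged`, `generations`, `trajectory` (tibble of
#'   [state_summary()] rows when recorded), `half_life` (named vector for
#'   pooled/female/male pools; `NA` if not reached or `D0 = 0`).
#' @export
#' @examples
#' st <- diploid_state(c(0.865, 0.135, 0, 0))
#' eq <- iterate_to_equilibrium(st, drive_params(costs = c(0, 0.482, 0, 0)),
#'   t_max = 2000
#' )
#' eq$converged
iterate_to_equilibrium <- function(state, params, tol = 1e-12, t_max = 1e6,
                                   record = TRUE) {
  stopifnot(inherits(state, "diploid_state"), inherits(params, "drive_params"))
  traj <- if (record) vector("list", 0L) else NULL
  if (record) traj[[1]] <- state_summary(state, params)
  D0 <- abs(state_summary(state, params)[, c("D_pooled", "D_female", "D_male")])
  hl <- setNames(rep(NA_real_, 3), c("pooled", "female", "male"))

  converged <- FALSE
  gen <- 0L
  cur <- state
  while (gen < t_max) {
    nxt <- diploid_step(cur, params)
    gen <- gen + 1L
    s <- state_summary(nxt, params)
    if (record) traj[[gen + 1L]] <- s
    Dn <- abs(s[, c("D_pooled", "D_female", "D_male")])
    for (i in 1:3) {
      if (is.na(hl[i]) && D0[[i]] > 0 && isTRUE(Dn[[i]] <= D0[[i]] / 2)) {
        hl[i] <- gen
      }
    }
    delta <- max(abs(nxt$F - cur$F), abs(nxt$m - cur$m))
    cur <- nxt
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      state = cur, params = params, converged = converged, generations = gen,
      trajectory = if (record) list_rbind(traj) else NULL,
      half_life = hl
    ),
    class = "drive_equilibrium"
  )
}

#' @export
print.drive_equilibrium <- function(x, ...) {
  cat(
    "Diploid drive recursion:", x$generations, "generations,",
    if (x$converged) "converged" else "NOT converged", "\n"
  )
  cat(
    "D half-life (generations): pooled", x$half_life[["pooled"]],
    "female", x$half_life[["female"]], "male", x$half_life[["male"]], "\n"
  )
  print(state_summary(x$state, x$params))
  invisible(x)
}

#' @export
tidy.drive_equilibrium <- function(x, ...) {
  if (is.null(x$trajectory)) abort("trajectory was not recorded; rerun with record = TRUE.")
  x$trajectory
}

#' @export
glance.drive_equilibrium <- function(x, ...) {
  s <- state_summary(x$state, x$params)
  tibble(
    converged = x$converged, generations = x$generations,
    half_life_pooled = x$half_life[["pooled"]],
    half_life_female = x$half_life[["female"]],
    half_life_male = x$half_life[["male"]],
    SR_pooled = s$SR_pooled, D_pooled = s$D_pooled
  )
}

# long-run pooled SR frequency of the two-type (ST, SR) system at a given
# SR cost; shared by find_balance_cost and the invasion/decay setups
.two_type_eq <- function(cost, k_full = 0.969, k_st = 0.5, q0 = 0.1,
                         male_expressed = TRUE, tol = 1e-13, t_max = 5e5,
                         return_state = FALSE) {
  params <- drive_params(
    k = c(ST = k_st, SR = k_full, BM = 0.5, T = 0.5),
    costs = c(0, cost, 0, 0), c = 0, male_expressed = male_expressed
  )
  st <- diploid_state(c(ST = 1 - q0, SR = q0, BM = 0, T = 0))
  x_old <- rep(NA_real_, 4)
  for (t in seq_len(t_max)) {
    st <- diploid_step(st, params)
    x <- (2 / 3) * .female_marginal(st$F) + (1 / 3) * st$m
    if (!anyNA(x_old) && max(abs(x - x_old)) < tol) break
    x_old <- x
  }
  if (return_state) st else x[["SR"]]
}

#' Recessive cost balancing the driving SR chromosome at a target frequency
#'
#' Bisection on the `SR`/`SR` recessive viability cost in the two-type
#' (`ST`, full `SR`) X-linked drive recursion such that the long-run
#' pooled SR X-chromosome frequency equals the target. With
#' `male_expressed = TRUE` (default) the recessive cost is also exposed in
#' hemizygous males; with female-only costs no interior balance exists for
#' strong drive and an error reports the attainable range.
#'
#' @param k_full Segregation proportion of the full SR chromosome
#'   (must exceed 0.5; no drive means no interior equilibrium).
#' @param target Target long-run pooled SR frequency.
#' @param c Unused in the two-type system (recombinants disabled); kept
#'   for interface uniformity.
#' @param k_st Segregation proportion assigned to `ST` (default Mendelian
#'   0.5; set 0.439 for the measured value).
#' @param male_expressed See [drive_params()].
#' @param tol Bisection tolerance on the cost.
#' @return Object of class `balance_cost_fit` with `cost`, `eq_freq`
#'   (equilibrium frequency at the fitted cost), `percent`, and call
#'   parameters. `glance()` returns a one-row tibble.
#' @export
#' @examples
#' \donttest{
#' find_balance_cost(k_full = 0.969, target = 0.135)
#' }
find_balance_cost <- function(k_full = 0.969, target = 0.135, c = 0,
                              k_st = 0.5, male_expressed = TRUE,
                              tol = 1e-6) {
  if (k_full <= 0.5) abort("no drive (k_full <= 0.5): no interior equilibrium exists.")
  .assert_prob(target, "target")
  eqf <- function(cost) .two_type_eq(cost, k_full = k_full, k_st = k_st,
                                     male_expressed = male_expressed)
  lo <- 0
  hi <- 1
  f_lo <- eqf(lo)
  f_hi <- eqf(hi)
  if (!(f_hi <= target && target <= f_lo)) {
    abort(sprintf(
      "target %.4f unreachable: attainable long-run SR frequency range is [%.4f, %.4f] over costs [0, 1].",
      target, f_hi, f_lo
    ))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eqf(mid) > target) lo <- mid else hi <- mid
  }
  cost <- (lo + hi) / 2
  structure(
    list(
      cost = cost, percent = 100 * cost, eq_freq = eqf(cost), target = target,
      k_full = k_full, k_st = k_st, male_expressed = male_expressed
    ),
    class = "balance_cost_fit"
  )
}

#' @export
print.balance_cost_fit <- function(x, ...) {
  cat(sprintf(
    "Drive-selection balance: cost = %.4f (%.1f%%) holds SR (k = %.3f) at %.4f\n",
    x$cost, x$percent, x$k_full, x$eq_freq
  ))
  invisible(x)
}

#' @export
glance.balance_cost_fit <- function(x, ...) {
  tibble(
    cost = x$cost, percent = x$percent, eq_freq = x$eq_freq,
    target = x$target, k_full = x$k_full, k_st = x$k_st,
    male_expressed = x$male_expressed
  )
}

#' @export
tidy.balance_cost_fit <- function(x, ...) glance.balance_cost_fit(x)

# build the four-type state at the two-type drive-selection balance
.balance_state <- function(cost, k_full = 0.969, k_st = 0.5,
                           male_expressed = TRUE) {
  .two_type_eq(cost,
    k_full = k_full, k_st = k_st, male_expressed = male_expressed,
    return_state = TRUE
  )
}

#' LD decay of the inversion haplotype under ongoing drive and selection
#'
#' Runs the full four-type diploid recursion from the two-type
#' drive-selection balance with recombination switched on, and reports the
#' disequilibrium trajectory and its half-life. At the two-type balance at
#' SR frequency `q`, the initial disequilibrium is `D0 = q(1 - q)` (0.117
#' at `q = 0.135`); recombination in `SR`/`ST` females then feeds the
#' recombinant classes and `D` decays.
#'
#' @param k Per-type segregation proportions; defaults to all-measured
#'   values (`mendelian_st = TRUE` switches `ST` to 0.5).
#' @param c Female recombination fraction (default 0.0012).
#' @param sr_cost Recessive cost on `SR`; `NULL` (default) solves it
#'   self-consistently with [find_balance_cost()] so the starting state is
#'   stationary at `target_sr`.
#' @param recombinant_costs Costs on `BM` and `T` during the decay run
#'   (length-2 named or unnamed vector, default 0).
#' @param target_sr SR frequency defining the balance (default 0.135).
#' @param male_expressed,mendelian_st See [drive_params()].
#' @param t_max Generations to run (default 5000).
#' @return Object of class `ld_decay_experiment`: `half_life` (named,
#'   pooled/female/male), `D0` (pooled), `sr_cost`, `trajectory` tibble,
#'   `params`. `glance()` summarises; `tidy()` returns the trajectory.
#' @export
#' @examples
#' \donttest{
#' ex <- ld_decay_experiment(t_max = 500)
#' ex$half_life
#' }
ld_decay_experiment <- function(k = NULL, c = 0.0012, sr_cost = NULL,
                                recombinant_costs = c(BM = 0, T = 0),
                                target_sr = 0.135, male_expressed = TRUE,
                                mendelian_st = FALSE, t_max = 5000) {
  if (is.null(k)) k <- .k_vector(mendelian_st = mendelian_st)
  k <- .canon4(k, "k")
  if (is.null(sr_cost)) {
    sr_cost <- find_balance_cost(
      k_full = k[["SR"]], target = target_sr, k_st = k[["ST"]],
      male_expressed = male_expressed
    )$cost
  }
  rc <- recombinant_costs
  if (is.null(names(rc))) names(rc) <- c("BM", "T")
  params <- drive_params(
    k = k, costs = c(ST = 0, SR = sr_cost, BM = rc[["BM"]], T = rc[["T"]]),
    c = c, male_expressed = male_expressed
  )
  st0 <- .balance_state(sr_cost,
    k_full = k[["SR"]], k_st = k[["ST"]],
    male_expressed = male_expressed
  )
  st0$generation <- 0L
  res <- iterate_to_equilibrium(st0, params, tol = 0, t_max = t_max, record = TRUE)
  structure(
    list(
      half_life = res$half_life, D0 = res$trajectory$D_pooled[1],
      sr_cost = sr_cost, trajectory = res$trajectory, params = params
    ),
    class = "ld_decay_experiment"
  )
}

#' @export
print.ld_decay_experiment <- function(x, ...) {
  cat(sprintf(
    "LD decay under drive-selection balance: D0 = %.4f, SR cost = %.4f\n",
    x$D0, x$sr_cost
  ))
  cat(
    "D half-life (generations): pooled", x$half_life[["pooled"]],
    "female", x$half_life[["female"]], "male", x$half_life[["male"]], "\n"
  )
  invisible(x)
}

#' @export
tidy.ld_decay_experiment <- function(x, ...) x$trajectory

#' @export
glance.ld_decay_experiment <- function(x, ...) {
  tibble(
    half_life_pooled = x$half_life[["pooled"]],
    half_life_female = x$half_life[["female"]],
    half_life_male = x$half_life[["male"]],
    D0 = x$D0, sr_cost = x$sr_cost, c = x$params$c
  )
}

#' Minimal recombinant cost that protects the full SR chromosome
#'
#' Invasion analysis for a single recombinant class. The system starts at
#' the two-type (`ST`, full `SR`) drive-selection balance; recombination
#' in `SR`/`ST` females continuously regenerates the focal recombinant
#' (the other recombinant class is removed each generation so the analysis
#' isolates one class). The function bisects on the focal recombinant's
#' recessive homozygous cost for the threshold below which the full `SR`
#' chromosome is asymptotically lost and above which it persists at a
#' positive long-run frequency.
#'
#' @param type Focal recombinant, `"BM"` or `"T"`.
#' @param k Per-type segregation proportions (default measured;
#'   `mendelian_st = TRUE` for Mendelian `ST`).
#' @param c Female recombination fraction (default 0.0012).
#' @param sr_cost Cost on `SR`; `NULL` solves the balance cost for
#'   `target_sr`.
#' @param target_sr SR frequency defining the initial balance.
#' @param male_expressed,mendelian_st See [drive_params()].
#' @param horizon Generations run per classification (doubled, up to
#'   `8 * horizon`, when the outcome is undecided).
#' @param tol Bisection tolerance on the cost.
#' @param loss_tol SR pooled frequency below which SR counts as lost.
#' @return Object of class `exclusion_cost_fit`: `cost` (threshold; 0 when
#'   SR persists even at recombinant cost 0, flagged
#'   `no_threshold = TRUE`), `percent`, per-bracket classifications, call
#'   info. `glance()` returns a one-row tibble.
#' @export
#' @examples
#' \donttest{
#' min_cost_to_exclude("BM", horizon = 20000)
#' }
min_cost_to_exclude <- function(type = c("BM", "T"), k = NULL, c = 0.0012,
                                sr_cost = NULL, target_sr = 0.135,
                                male_expressed = TRUE, mendelian_st = FALSE,
                                horizon = 5e4, tol = 1e-3, loss_tol = 1e-9) {
  type <- match.arg(type)
  other <- setdiff(c("BM", "T"), type)
  if (is.null(k)) k <- .k_vector(mendelian_st = mendelian_st)
  k <- .canon4(k, "k")
  if (is.null(sr_cost)) {
    sr_cost <- find_balance_cost(
      k_full = k[["SR"]], target = target_sr, k_st = k[["ST"]],
      male_expressed = male_expressed
    )$cost
  }
  st0 <- .balance_state(sr_cost,
    k_full = k[["SR"]], k_st = k[["ST"]],
    male_expressed = male_expressed
  )

  classify <- function(cost) {
    costs <- c(ST = 0, SR = sr_cost, BM = 0, T = 0)
    costs[[type]] <- cost
    params <- drive_params(k = k, costs = costs, c = c,
                           male_expressed = male_expressed)
    st <- st0
    sr_prev <- NA_real_
    for (chunk in 1:8) {
      for (t in seq_len(horizon)) {
        st <- diploid_step(st, params)
        # isolate the focal recombinant: remove the other class
        st$F[other, ] <- 0
        st$F[, other] <- 0
        st$F <- st$F / sum(st$F)
        st$m[[other]] <- 0
        st$m <- st$m / sum(st$m)
      }
      x <- (2 / 3) * .female_marginal(st$F) + (1 / 3) * st$m
      sr <- x[["SR"]]
      if (sr < loss_tol) return("lost")
      # stationary well away from loss: SR moved negligibly over a whole chunk
      if (!is.na(sr_prev) && sr > 1e-3 && abs(sr - sr_prev) < 1e-8) {
        return("persists")
      }
      sr_prev <- sr
    }
    "undecided"
  }

  cls0 <- classify(0)
  if (cls0 == "persists") {
    return(structure(
      list(
        cost = 0, percent = 0, type = type, no_threshold = TRUE,
        bracket = c(lower = 0, upper = 0),
        classification = c(lower = cls0, upper = "persists"),
        sr_cost = sr_cost, k = k, c = c, male_expressed = male_expressed
      ),
      class = "exclusion_cost_fit"
    ))
  }
  cls1 <- classify(1)
  if (cls0 == "undecided" && cls1 == "undecided") {
    abort("outcome undecided at both brackets within the horizon; increase `horizon`.")
  }
  if (cls1 != "persists") {
    abort(sprintf(
      "SR does not persist even at recombinant cost 1 (classification: %s); no threshold in [0, 1].",
      cls1
    ))
  }
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    cm <- classify(mid)
    if (cm == "lost") lo <- mid
    else if (cm == "persists") hi <- mid
    else abort(sprintf("outcome undecided at cost %.4f; increase `horizon`.", mid))
  }
  cost <- (lo + hi) / 2
  structure(
    list(
      cost = cost, percent = 100 * cost, type = type, no_threshold = FALSE,
      bracket = c(lower = lo, upper = hi),
      classification = c(lower = "lost", upper = "persists"),
      sr_cost = sr_cost, k = k, c = c, male_expressed = male_expressed
    ),
    class = "exclusion_cost_fit"
  )
}

#' @export
print.exclusion_cost_fit <- function(x, ...) {
  if (x$no_threshold) {
    cat(sprintf(
      "Invasion analysis (%s): SR persists even with a cost-free recombinant; threshold cost = 0.\n",
      x$type
    ))
  } else {
    cat(sprintf(
      "Invasion analysis (%s): minimal recessive cost to protect SR = %.4f (%.1f%%)\n",
      x$type, x$cost, x$percent
    ))
  }
  invisible(x)
}

#' @export
glance.exclusion_cost_fit <- function(x, ...) {
  tibble(
    type = x$type, cost = x$cost, percent = x$percent,
    no_threshold = x$no_threshold, sr_cost = x$sr_cost, c = x$c,
    male_expressed = x$male_expressed
  )
}

#' @export
tidy.exclusion_cost_fit <- function(x, ...) glance.exclusion_cost_fit(x)
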