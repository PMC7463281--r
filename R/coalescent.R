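# Self-contained Kingman coalescent with piecewise-constant demography for
# the three-lineage (outgroup, ST, SR) scenario: the SR inversion descends
# from a single founder chromosome at its origin time (forced star
# coalescence), then shares the ancestral population with ST until the
# species split with the outgroup.

#' Demography scenario for the inversion coalescent
#'
#' @param total_ne Total focal-species N_e before the X correction
#'   (default 1.8e6). The ST share is `total_ne * (1 - sr_fraction)` so
#'   the total is preserved.
#' @param sr_fraction Present-day SR frequency (one of 0.30 / 0.135 /
#'   0.01 in the study; any value in (0, 1)).
#' @param outgroup_ne Outgroup N_e (default 3.6e5, a fivefold reduction).
#' @param origin_time SR origin, generations ago (default 2e6).
#' @param split_time Species split, generations ago (default 4e6; the
#'   alternate scenario uses 8e6 with origin 4e6).
#' @param x_factor Hemizygosity correction applied multiplicatively to
#'   every N_e exactly once, at construction (default 3/4).
#' @param mu Per-bp per-generation mutation rate (default 3.5e-9).
#' @param locus_length Simulated non-recombining locus length in bp
#'   (default 10000, mirroring the 10-kb analysis windows).
#' @param samples Named sample sizes `c(outgroup = , st = , sr = )`
#'   (default 1, 8, 8).
#' @param n_reps Default replicate count (default 1e5; tests and the
#'   scaled acceptance runs use fewer).
#' @param ancestral_ne Optional N_e of the population ancestral to the
#'   species pair (pre-split); defaults to `total_ne`.
#' @return Object of class `demography_scenario` (list of validated,
#'   X-corrected parameters).
#' @export
#' @examples
#' demography_scenario(sr_fraction = 0.01)
demography_scenario <- function(total_ne = 1.8e6, sr_fraction = 0.135,
                                outgroup_ne = 3.6e5, origin_time = 2e6,
                                split_time = 4e6, x_factor = 3 / 4,
                                mu = 3.5e-9, locus_length = 1e4,
                                samples = c(outgroup = 1, st = 8, sr = 8),
                                n_reps = 1e5, ancestral_ne = total_ne) {
  if (sr_fraction <= 0 || sr_fraction >= 1) abort("`sr_fraction` must be in (0, 1).")
  if (origin_time >= split_time) abort("`origin_time` must precede `split_time`.")
  if (locus_length <= 0) abort("`locus_length` must be positive.")
  if (any(samples < 1) || !all(c("outgroup", "st", "sr") %in% names(samples))) {
    abort("`samples` must provide outgroup/st/sr sizes >= 1.")
  }
  structure(
    list(
      n_sr = sr_fraction * total_ne * x_factor,
      n_st = (1 - sr_fraction) * total_ne * x_factor,
      n_out = outgroup_ne * x_factor,
      n_anc = total_ne * x_factor, # ST lineage between origin and split
      n_root = ancestral_ne * x_factor,
      sr_fraction = sr_fraction, origin_time = origin_time,
      split_time = split_time, mu = mu, locus_length = locus_length,
      samples = samples, n_reps = n_reps
    ),
    class = "demography_scenario"
  )
}

#' @export
print.demography_scenario <- function(x, ...) {
  cat("Coalescent demography scenario (X-corrected haploid sizes)\n")
  cat(sprintf(
    "  N_sr = %.0f, N_st = %.0f, N_out = %.0f; origin %.0f, split %.0f generations\n",
    x$n_sr, x$n_st, x$n_out, x$origin_time, x$split_time
  ))
  cat(sprintf(
    "  mu = %.2e, locus = %d bp, samples: %d outgroup / %d ST / %d SR\n",
    x$mu, as.integer(x$locus_length), x$samples[["outgroup"]],
    x$samples[["st"]], x$samples[["sr"]]
  ))
  invisible(x)
}

# One coalescent genealogy. `pop` assigns each sample to a population id;
# `epochs` is a list of (end_time, sizes named by pop id, events at end).
# Returns parent/time vectors plus the number of samples.
.sim_tree <- function(scn) {
  ns <- scn$samples
  n_samp <- sum(ns)
  group <- rep(c("outgroup", "st", "sr"), times = c(ns[["outgroup"]], ns[["st"]], ns[["sr"]]))

  parent <- integer(n_samp)
  node_time <- numeric(n_samp)
  active_id <- seq_len(n_samp)
  active_pop <- group
  t <- 0
  nid <- n_samp

  new_node <- function(tm) {
    nid <<- nid + 1L
    parent[nid] <<- 0L
    node_time[nid] <<- tm
    nid
  }

  sizes <- c(outgroup = scn$n_out, st = scn$n_st, sr = scn$n_sr)
  boundaries <- c(scn$origin_time, scn$split_time, Inf)
  phase <- 1L

  while (length(active_id) > 1L) {
    ks <- table(active_pop)
    pops <- names(ks)[ks >= 2]
    rates <- vapply(pops, function(p) {
      k <- ks[[p]]
      k * (k - 1) / 2 / sizes[[p]]
    }, numeric(1))
    R <- sum(rates)
    t_next <- if (R > 0) t + rexp(1, R) else Inf

    if (t_next >= boundaries[phase]) {
      t <- boundaries[phase]
      if (phase == 1L) {
        # SR origin: all surviving SR lineages descend from one founder
        sr_idx <- which(active_pop == "sr")
        if (length(sr_idx) >= 2) {
          anc <- new_node(t)
          parent[active_id[sr_idx]] <- anc
          keep <- setdiff(seq_along(active_id), sr_idx)
          active_id <- c(active_id[keep], anc)
          active_pop <- c(active_pop[keep], "st")
        } else if (length(sr_idx) == 1) {
          active_pop[sr_idx] <- "st"
        }
        sizes[["st"]] <- scn$n_anc
      } else if (phase == 2L) {
        # species split: everything in the root population
        active_pop[] <- "root"
        sizes <- c(sizes, root = scn$n_root)
      }
      phase <- phase + 1L
      next
    }

    t <- t_next
    p <- if (length(pops) == 1) pops else sample(pops, 1, prob = rates)
    idx <- which(active_pop == p)
    pick <- sample(idx, 2)
    anc <- new_node(t)
    parent[active_id[pick]] <- anc
    active_id <- c(active_id[-pick], anc)
    active_pop <- c(active_pop[-pick], p)
  }

  list(
    parent = parent[seq_len(nid)], time = node_time[seq_len(nid)],
    n_samp = n_samp, group = group, tmrca = t
  )
}

# summary statistics from a genealogy with Poisson infinite-sites mutation
.tree_stats <- function(tree, mu, L) {
  nid <- length(tree$parent)
  n_samp <- tree$n_samp
  groups <- list(
    st = which(tree$group == "st"),
    sr = which(tree$group == "sr"),
    joint = which(tree$group %in% c("st", "sr"))
  )
  # descendant sample counts per group for each node (leaf-up accumulation)
  desc <- matrix(0, nid, length(groups))
  colnames(desc) <- names(groups)
  for (g in names(groups)) desc[groups[[g]], g] <- 1
  ord <- order(tree$time[seq_len(nid)])
  for (i in ord) {
    p <- tree$parent[i]
    if (p > 0) desc[p, ] <- desc[p, ] + desc[i, ]
  }
  ptime <- ifelse(tree$parent > 0, tree$time[pmax(tree$parent, 1L)], 0)
  blen <- ifelse(tree$parent > 0, ptime - tree$time[seq_len(nid)], 0)
  muts <- rpois(nid, mu * L * blen)

  out <- list()
  for (g in names(groups)) {
    n_g <- length(groups[[g]])
    d <- desc[, g]
    seg <- d > 0 & d < n_g
    S <- sum(muts[seg])
    pi_tot <- if (n_g >= 2) sum(muts * d * (n_g - d)) / (n_g * (n_g - 1) / 2) else NA_real_
    out[[paste0("S_", g)]] <- S
    out[[paste0("pi_", g)]] <- pi_tot / L
  }
  # SR TMRCA (highest node with all SR descendants reached first): compute
  # as the smallest node time at which some node has all SR samples below it
  sr_n <- length(groups$sr)
  full <- which(desc[, "sr"] == sr_n)
  out$tmrca_sr <- min(tree$time[full])
  out$tmrca <- tree$tmrca
  out
}

.tajima_d_from <- function(S, pi_total, n) {
  if (is.na(S) || S == 0 || n < 2) return(NA_real_)
  tc <- .tajima_constants(n)
  (pi_total - S / tc$a1) / sqrt(tc$e1 * S + tc$e2 * S * (S - 1))
}

#' Simulate neutral coalescent replicates
#'
#' Runs the scenario's three-lineage coalescent with forced single-founder
#' coalescence of the SR lineages at the origin time, Poisson
#' infinite-sites mutation along branches, and per-replicate summary
#' statistics.
#'
#' @param scenario A [demography_scenario()].
#' @param n_reps Number of replicates (defaults to the scenario's).
#' @param seed Optional RNG seed.
#' @return Tibble with one row per replicate: `rep`, per-group `pi`
#'   (per site) and segregating sites `S` (ST, SR, and the 16-sample
#'   joint set), Tajima's D per group, `ratio` (`pi_st / pi_sr`, `NA`
#'   when `pi_sr` is 0), `tmrca_sr`, `tmrca`.
#' @export
#' @examples
#' scn <- demography_scenario(sr_fraction = 0.135, locus_length = 1000)
#' simulate_neutral_replicates(scn, n_reps = 5, seed = 1)
simulate_neutral_replicates <- function(scenario, n_reps = scenario$n_reps,
                                        seed = NULL) {
  stopifnot(inherits(scenario, "demography_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n_st <- scenario$samples[["st"]]
  n_sr <- scenario$samples[["sr"]]
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tree <- .sim_tree(scenario)
    st <- .tree_stats(tree, scenario$mu, scenario$locus_length)
    rows[[r]] <- tibble(
      rep = r,
      pi_st = st$pi_st, pi_sr = st$pi_sr, pi_joint = st$pi_joint,
      S_st = st$S_st, S_sr = st$S_sr, S_joint = st$S_joint,
      tajimas_d_st = .tajima_d_from(st$S_st, st$pi_st * scenario$locus_length, n_st),
      tajimas_d_sr = .tajima_d_from(st$S_sr, st$pi_sr * scenario$locus_length, n_sr),
      ratio = ifelse(st$pi_sr > 0, st$pi_st / st$pi_sr, NA_real_),
      tmrca_sr = st$tmrca_sr, tmrca = st$tmrca
    )
  }
  list_rbind(rows)
}

#' Simulate a single panmictic population (calibration helper)
#'
#' Plain Kingman coalescent in one constant-size population, used for
#' closed-form checks (`E[T2] = N` for two samples; Watterson's formula
#' for segregating sites).
#'
#' @param n Sample size.
#' @param N Haploid population size.
#' @param mu Per-bp mutation rate.
#' @param locus_length Locus length in bp.
#' @param n_reps Replicates.
#' @param seed Optional RNG seed.
#' @return Tibble: `rep`, `S`, `pi` (per site), `tmrca`.
#' @export
simulate_panmictic <- function(n, N, mu = 3.5e-9, locus_length = 1e4,
                               n_reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tree <- .sim_tree_single(n, N)
    stats <- .tree_stats(
      list(
        parent = tree$parent, time = tree$time, n_samp = n,
        group = rep("st", n), tmrca = tree$tmrca
      ),
      mu, locus_length
    )
    rows[[r]] <- tibble(
      rep = r, S = stats$S_st, pi = stats$pi_st, tmrca = tree$tmrca
    )
  }
  list_rbind(rows)
}

# minimal single-population tree
.sim_tree_single <- function(n, N) {
  parent <- integer(n)
  node_time <- numeric(n)
  active <- seq_len(n)
  t <- 0
  nid <- n
  while (length(active) > 1) {
    k <- length(active)
    t <- t + rexp(1, k * (k - 1) / 2 / N)
    nid <- nid + 1L
    parent[nid] <- 0L
    node_time[nid] <- t
    pick <- sample(seq_along(active), 2)
    parent[active[pick]] <- nid
    active <- c(active[-pick], nid)
  }
  list(parent = parent, time = node_time, tmrca = t)
}

#' Neutrality test for an observed diversity reduction
#'
#' Compares an observed `pi_ST / pi_SR` ratio against the neutral
#' coalescent distribution of the ratio: the one-sided empirical p-value
#' is the proportion of replicates with ratio at most the observed value
#' (is the observed reduction in SR diversity too small — the ratio too
#' low — to be explained by the neutral single-founder model?).
#'
#' @param observed_ratio Observed `pi_ST / pi_SR`.
#' @param replicates Tibble from [simulate_neutral_replicates()] (or a
#'   scenario, which is then simulated).
#' @param n_reps Replicates when simulating from a scenario.
#' @param alpha Significance level (default 0.05).
#' @param alternative `"less"` (default, one-sided as above),
#'   `"greater"`, or `"two.sided"`.
#' @param seed Optional RNG seed when simulating.
#' @return Object of class `neutrality_test`: `p_value`, `p_display`
#'   (`"< 1/n"` at the boundary), `reject`, `n_used`, `n_na`,
#'   `observed_ratio`. `glance()` returns a one-row tibble.
#' @export
neutrality_test <- function(observed_ratio, replicates, n_reps = 2000,
                            alpha = 0.05, alternative = c("less", "greater", "two.sided"),
                            seed = NULL) {
  alternative <- match.arg(alternative)
  if (inherits(replicates, "demography_scenario")) {
    replicates <- simulate_neutral_replicates(replicates, n_reps = n_reps, seed = seed)
  }
  ratios <- replicates$ratio
  n_na <- sum(is.na(ratios))
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) abort("all replicate ratios are NA (pi_SR = 0 everywhere).")
  n <- length(ratios)
  p_less <- mean(ratios <= observed_ratio)
  p <- switch(alternative,
    less = p_less,
    greater = mean(ratios >= observed_ratio),
    two.sided = min(1, 2 * min(p_less, mean(ratios >= observed_ratio)))
  )
  boundary <- p == 0
  structure(
    list(
      p_value = if (boundary) 1 / n else p,
      p_display = if (boundary) sprintf("< 1/%d", n) else format(p, digits = 3),
      reject = (if (boundary) 1 / n else p) < alpha,
      alpha = alpha, alternative = alternative,
      n_used = n, n_na = n_na, observed_ratio = observed_ratio
    ),
    class = "neutrality_test"
  )
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf(
    "Neutral coalescent test: observed ratio %.3f, p %s (%s), %s at alpha = %.2f\n",
    x$observed_ratio, x$p_display, x$alternative,
    if (x$reject) "REJECT neutrality" else "retain neutrality", x$alpha
  ))
  invisible(x)
}

#' @export
glance.neutrality_test <- function(x, ...) {
  tibble(
    observed_ratio = x$observed_ratio, p_value = x$p_value,
    reject = x$reject, alpha = x$alpha, alternative = x$alternative,
    n_used = x$n_used, n_na = x$n_na
  )
}
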