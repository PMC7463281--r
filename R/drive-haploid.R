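# Haploid gametic models: equilibrium of recombinant classes under
# selection and recurrent recombinant production, and the inverse fit of
# haploid selection coefficients from observed natural frequencies.

#' Summaries of a four-type gamete distribution
#'
#' Computes allele frequencies and disequilibrium for a frequency vector
#' over the four gamete types (`ST`, `SR`, `BM`, `T`). Locus A is the
#' basal+medial inversion unit (carried by `SR` and `BM`); locus B is the
#' terminal inversion (carried by `SR` and `T`).
#'
#' @param x Length-4 frequency vector (named or in canonical
#'   `gamete_types()` order), summing to 1.
#' @return One-row tibble with per-type frequencies, `p_A`, `q_B`, `D`
#'   (`P(AB) - p_A * q_B`) and `r2` (`NA` when either locus is
#'   monomorphic).
#' @export
#' @examples
#' gamete_distribution(c(ST = 0.86526, SR = 0.13455, BM = 0.00004, T = 0.00015))
gamete_distribution <- function(x) {
  x <- .canon4(x, "x")
  .assert_freq_vector(x, "x")
  p_A <- sum(x * .carries_A)
  q_B <- sum(x * .carries_B)
  D <- x[["SR"]] - p_A * q_B
  denom <- p_A * (1 - p_A) * q_B * (1 - q_B)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  tibble(
    ST = x[["ST"]], SR = x[["SR"]], BM = x[["BM"]], T = x[["T"]],
    p_A = p_A, q_B = q_B, D = D, r2 = r2
  )
}

# relative per-generation transmission of an X type with segregation
# proportion k, normalized to the baseline type (2/3 of X chromosomes pass
# through females with Mendelian transmission; 1/3 through males where a
# type-k father's X reaches a fraction k of his progeny as daughters)
.drive_lambda <- function(k, k_baseline) (2 + 2 * k) / (2 + 2 * k_baseline)

#' Haploid selection/recombination equilibrium
#'
#' Iterates a haploid gametic model to equilibrium. Two production models
#' are available:
#'
#' * `"classical"`: the textbook two-locus haploid recursion. Each
#'   generation, per-type fitnesses `1 - s` act and the pool is
#'   renormalized; recombination under random union then moves
#'   disequilibrium toward zero (`x_AB' = x_AB - c * D`, etc., with
#'   `D = x_AB x_ab - x_Ab x_aB`).
#' * `"pairing"`: a linearized model for rare recombinant classes on a
#'   fixed (`SR`, `ST`) backbone. Each recombinant class `y` follows
#'   `y' = (1 - s) * (lambda(k) * y + (c / 2) * p_SR * p_ST)`, where
#'   `lambda(k) = (2 + 2k) / (2 + 2k_ST)` is the X-linked transmission of
#'   a type with segregation proportion `k` relative to the `ST` baseline,
#'   and the production term is the recombinant output of `SR`/`ST`
#'   heterozygous females at `c / 2` per recombinant class. The backbone
#'   frequencies are held fixed ("holding `SR` and `ST` at their observed
#'   frequencies"); the fixed point of this linear recursion is computed
#'   exactly, with divergence reported when `(1 - s) * lambda >= 1`.
#'
#' @param x Initial four-type frequency vector (named or canonical order).
#' @param s Per-type haploid selection coefficients (length 4, `ST`
#'   conventionally 0), proportional reductions in fitness.
#' @param c Recombination fraction per generation.
#' @param production `"classical"` or `"pairing"` (see above).
#' @param k Per-type segregation proportions, used only by the `"pairing"`
#'   model's transmission factor. Defaults to the measured values.
#' @param tol Convergence tolerance on the max per-type change.
#' @param t_max Generation cap.
#' @return Object of class `haploid_equilibrium`: a list with
#'   `distribution` (tibble from [gamete_distribution()]), `generations`,
#'   `converged`, and the call parameters.
#' @export
#' @examples
#' # neutral decay: no selection, recombination drives D to 0
#' eq <- haploid_selection_equilibrium(
#'   c(ST = 0.4, SR = 0.4, BM = 0.1, T = 0.1),
#'   s = c(0, 0, 0, 0), c = 0.01
#' )
#' eq$distribution$D
haploid_selection_equilibrium <- function(x, s, c,
                                          production = c("classical", "pairing"),
                                          k = .k_vector(),
                                          tol = 1e-12, t_max = 1e6) {
  production <- match.arg(production)
  x <- .canon4(x, "x")
  .assert_freq_vector(x, "x")
  s <- .canon4(s, "s")
  .assert_prob(s, "s")
  .assert_prob(c, "c")
  k <- .canon4(k, "k")

  if (production == "classical") {
    xv <- as.numeric(x)
    gen <- 0L
    converged <- FALSE
    while (gen < t_max) {
      xs <- xv * (1 - as.numeric(s))
      xs <- xs / sum(xs)
      # D on (A, B) with coupling gamete SR (AB) and repulsion BM (Ab), T (aB)
      D <- xs[2] * xs[1] - xs[3] * xs[4]
      # coupling gametes (SR = AB, ST = ab) lose c*D; repulsion gametes gain
      xn <- c(xs[1] - c * D, xs[2] - c * D, xs[3] + c * D, xs[4] + c * D)
      gen <- gen + 1L
      if (max(abs(xn - xv)) < tol) {
        xv <- xn
        converged <- TRUE
        break
      }
      xv <- xn
    }
    if (!converged) {
      abort(sprintf(
        "haploid_selection_equilibrium did not converge in %d generations (final max change above tol).",
        as.integer(t_max)
      ))
    }
    dist <- gamete_distribution(setNames(pmax(xv, 0) / sum(pmax(xv, 0)), gamete_types()))
  } else {
    lam <- .drive_lambda(k, k[["ST"]])
    P <- (c / 2) * x[["SR"]] * x[["ST"]]
    y <- vapply(c("BM", "T"), function(g) {
      a <- (1 - s[[g]]) * lam[[g]]
      if (a >= 1) {
        abort(sprintf(
          "pairing-model recombinant class %s diverges: (1 - s) * lambda = %.6f >= 1 (no equilibrium).",
          g, a
        ))
      }
      (1 - s[[g]]) * P / (1 - a)
    }, numeric(1))
    xb <- c(ST = x[["ST"]], SR = x[["SR"]], BM = y[["BM"]], T = y[["T"]])
    dist <- gamete_distribution(xb / sum(xb))
    gen <- NA_integer_
    converged <- TRUE
  }

  structure(
    list(
      distribution = dist, generations = gen, converged = converged,
      production = production, s = s, c = c, k = k
    ),
    class = "haploid_equilibrium"
  )
}

#' @export
print.haploid_equilibrium <- function(x, ...) {
  cat("Haploid gametic equilibrium (", x$production, " production)\n", sep = "")
  print(x$distribution)
  invisible(x)
}

#' @export
tidy.haploid_equilibrium <- function(x, ...) {
  x$distribution |>
    tidyr::pivot_longer(dplyr::all_of(gamete_types()),
      names_to = "type", values_to = "frequency"
    ) |>
    select("type", "frequency")
}

#' @export
glance.haploid_equilibrium <- function(x, ...) {
  dplyr::bind_cols(
    x$distribution[, c("p_A", "q_B", "D", "r2")],
    tibble(production = x$production, converged = x$converged)
  )
}

#' Fit haploid selection coefficients from observed natural frequencies
#'
#' Solves, one coefficient at a time by bisection, for the haploid
#' selection coefficient `s` at which the `"pairing"`-model equilibrium
#' frequency of a rare recombinant class equals its observed natural
#' frequency, holding the `SR` and `ST` backbone at the observed
#' frequencies. Strong selection is required to reconcile laboratory
#' recombination rates with the rarity of recombinants in nature.
#'
#' @param observed Named frequencies of the four types (e.g. the pooled
#'   natural-survey values). Must sum to 1.
#' @param c Recombination fraction per generation (default 0.0012).
#' @param k Per-type segregation proportions used for the transmission
#'   factor; defaults to the measured values.
#' @param types Which recombinant classes to fit (default both).
#' @param tol Bisection tolerance on `s`.
#' @return Object of class `haploid_s_fit`: tibble in `$fits` with one row
#'   per fitted class (`type`, `s`, `observed`, `lambda`, `production`),
#'   plus call info. `tidy()` returns the tibble.
#' @export
#' @examples
#' fit_haploid_s(
#'   c(ST = 0.86526, SR = 0.13455, BM = 0.00004, T = 0.00015),
#'   c = 0.0012
#' )
fit_haploid_s <- function(observed, c = 0.0012, k = .k_vector(),
                          types = c("T", "BM"), tol = 1e-8) {
  observed <- .canon4(observed, "observed")
  .assert_freq_vector(observed, "observed", tol = 5e-5)
  if (c <= 0) abort("`c` must be positive to produce recombinants.")
  k <- .canon4(k, "k")
  types <- match.arg(types, c("T", "BM"), several.ok = TRUE)
  if (any(observed[types] <= 0)) {
    abort("observed recombinant frequencies must be positive.")
  }

  P <- (c / 2) * observed[["SR"]] * observed[["ST"]]
  fits <- map(types, function(g) {
    lam <- .drive_lambda(k[[g]], k[["ST"]])
    eqf <- function(s) {
      a <- (1 - s) * lam
      if (a >= 1) Inf else (1 - s) * P / (1 - a)
    }
    target <- observed[[g]]
    lo <- 0
    hi <- 1
    f_lo <- eqf(lo) - target
    f_hi <- eqf(hi) - target
    if (f_lo < 0 || f_hi > 0) {
      abort(sprintf(
        "no root in [0, 1] for type %s: equilibrium range [%.3g, %s] does not bracket observed %.3g.",
        g, eqf(1), ifelse(is.finite(f_lo + target), format(eqf(0)), "Inf"), target
      ))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (eqf(mid) > target) lo <- mid else hi <- mid
    }
    s_hat <- (lo + hi) / 2
    tibble(type = g, s = s_hat, observed = target, lambda = lam)
  }) |> list_rbind()

  structure(
    list(fits = fits, c = c, k = k, observed = observed, production = "pairing"),
    class = "haploid_s_fit"
  )
}

#' @export
print.haploid_s_fit <- function(x, ...) {
  cat("Haploid selection coefficients (pairing-model equilibrium inversion)\n")
  print(x$fits)
  invisible(x)
}

#' @export
tidy.haploid_s_fit <- function(x, ...) x$fits

#' @export
glance.haploid_s_fit <- function(x, ...) {
  tibble(
    c = x$c,
    n_types = nrow(x$fits),
    s_T = if ("T" %in% x$fits$type) x$fits$s[x$fits$type == "T"] else NA_real_,
    s_BM = if ("BM" %in% x$fits$type) x$fits$s[x$fits$type == "BM"] else NA_real_
  )
}
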