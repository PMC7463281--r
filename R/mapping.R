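# Classical genetics statistics for the recombination and segregation
# experiments and the natural-survey haplotype tables.

# exact (Clopper-Pearson) two-sided binomial CI via beta tail inversion
.clopper_pearson <- function(x, n, confidence = 0.95) {
  alpha <- 1 - confidence
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Recombination fraction with exact binomial confidence interval
#'
#' @param recombinants Number of recombinant progeny.
#' @param total Total progeny scored.
#' @param confidence Confidence level (default 0.95).
#' @return One-row tibble: `recombinants`, `total`, `estimate`, `ci_low`,
#'   `ci_high`, `cm_raw` (100 * r centimorgans, uncorrected) and
#'   `cm_kosambi` (`NA` when `r >= 0.5`).
#' @export
#' @examples
#' recomb_fraction(12, 10000)
recomb_fraction <- function(recombinants, total, confidence = 0.95) {
  if (length(total) != 1L || total < 1) abort("`total` must be a positive count.")
  if (recombinants < 0 || recombinants > total) {
    abort("`recombinants` must lie in [0, total].")
  }
  r <- recombinants / total
  ci <- .clopper_pearson(recombinants, total, confidence)
  tibble(
    recombinants = recombinants, total = total, estimate = r,
    ci_low = ci[["low"]], ci_high = ci[["high"]],
    cm_raw = 100 * r,
    cm_kosambi = if (r < 0.5) kosambi_cm(r) else NA_real_
  )
}

#' Kosambi map distance
#'
#' Corrects a recombination fraction for multiple crossovers with
#' interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centimorgans.
#' @export
#' @examples
#' kosambi_cm(0.4224) # > 50 cM
kosambi_cm <- function(r) {
  if (any(r < 0) || any(r >= 0.5)) {
    abort("`r` must lie in [0, 0.5): 0.5 is beyond map resolution.")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Chi-square test for reciprocal recombinant classes
#'
#' Tests two reciprocal class counts against the 1:1 Mendelian
#' expectation: `chi2 = sum((obs - exp)^2 / exp)` with
#' `exp = (n1 + n2) / 2`, 1 degree of freedom, no continuity correction
#' by default. An exact two-sided binomial p-value is also reported.
#'
#' @param class1,class2 Counts of the two reciprocal classes.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `chi2`, `df`, `p_chi2`, `p_exact`.
#' @export
#' @examples
#' chi2_reciprocal(12, 0) # chi2 = 12
chi2_reciprocal <- function(class1, class2, correct = FALSE) {
  n <- class1 + class2
  if (n < 1) abort("at least one class must be nonzero.")
  e <- n / 2
  dev <- abs(class1 - e)
  if (correct) dev <- max(0, dev - 0.5)
  chi2 <- 2 * dev^2 / e
  p_exact <- min(1, 2 * pbinom(min(class1, class2), n, 0.5))
  tibble(
    chi2 = chi2, df = 1L, p_chi2 = pchisq(chi2, 1, lower.tail = FALSE),
    p_exact = p_exact
  )
}

#' Two-locus LD from survey haplotype frequencies
#'
#' Computes the disequilibrium of the full SR haplotype from a four-class
#' frequency vector: `p_A = P(SR) + P(BM)` (basal+medial unit),
#' `q_B = P(SR) + P(T)` (terminal inversion), `D = P(SR) - p_A * q_B`,
#' `r2 = D^2 / (p_A (1 - p_A) q_B (1 - q_B))`.
#'
#' @param freqs Length-4 frequencies (named `ST`, `SR`, `BM`, `T` or in
#'   that order), summing to 1 within Table-1-style rounding (5e-5).
#' @return One-row tibble: `p_A`, `q_B`, `D`, `r2` (`NA` with `D = 0`
#'   when either locus is monomorphic), plus Lewontin `d_prime`.
#' @export
#' @examples
#' survey_ld(c(ST = 0.86526, SR = 0.13455, BM = 0.00004, T = 0.00015))
survey_ld <- function(freqs) {
  freqs <- .canon4(freqs, "freqs")
  if (abs(sum(freqs) - 1) > 5e-5) abort("`freqs` must sum to 1 (tol 5e-5).")
  if (any(freqs < 0)) abort("`freqs` must be non-negative.")
  freqs <- freqs / sum(freqs)
  p_A <- freqs[["SR"]] + freqs[["BM"]]
  q_B <- freqs[["SR"]] + freqs[["T"]]
  denom <- p_A * (1 - p_A) * q_B * (1 - q_B)
  if (denom == 0) {
    return(tibble(p_A = p_A, q_B = q_B, D = 0, r2 = NA_real_, d_prime = NA_real_))
  }
  D <- freqs[["SR"]] - p_A * q_B
  d_max <- if (D >= 0) min(p_A * (1 - q_B), (1 - p_A) * q_B) else min(p_A * q_B, (1 - p_A) * (1 - q_B))
  tibble(p_A = p_A, q_B = q_B, D = D, r2 = D^2 / denom, d_prime = D / d_max)
}

#' Segregation proportion k with exact confidence interval
#'
#' The proportion of female progeny sired by an assayed male, with an
#' exact (Clopper-Pearson) binomial confidence interval and a
#' `distorting` flag set when the interval excludes the Mendelian 0.5.
#'
#' @param females,males Progeny counts.
#' @param confidence Confidence level (default 0.95).
#' @return One-row tibble: `females`, `males`, `k`, `ci_low`, `ci_high`,
#'   `distorting`.
#' @export
#' @examples
#' segregation_k(93, 3) # k = 0.969, distorting
segregation_k <- function(females, males, confidence = 0.95) {
  n <- females + males
  if (n < 1) abort("total progeny must be >= 1.")
  k <- females / n
  ci <- .clopper_pearson(females, n, confidence)
  tibble(
    females = females, males = males, k = k,
    ci_low = ci[["low"]], ci_high = ci[["high"]],
    distorting = ci[["low"]] > 0.5 || ci[["high"]] < 0.5
  )
}

#' Natural-survey haplotype frequency table
#'
#' Loads the packaged survey table of X-chromosome haplotype frequencies
#' (ten natural population surveys plus the pooled row): per-study
#' frequencies of the `ST`, full `SR`, basal+medial-only (`BM`) and
#' terminal-only (`T`) classes with sample sizes.
#'
#' @return Tibble with columns `study`, `n`, `ST`, `SR`, `BM`, `T`,
#'   `pooled` (logical; `TRUE` for the across-survey pooled row).
#' @export
#' @examples
#' sr_survey_table()
sr_survey_table <- function() {
  path <- system.file("extdata", "sr_survey_frequencies.tsv", package = "xdrive")
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(pooled = .data$study == "pooled")
}
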