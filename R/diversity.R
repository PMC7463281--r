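# Pooled nucleotide diversity and Tajima's D with pool-size and
# minimum-allele-count corrections (the PoPoolation family of estimators),
# in physical windows with an uncallable-fraction rule and optional
# intergenic masking.

# Correction factors. Model: a segregating site has (unknown) derived
# count k among the n pool chromosomes with probability proportional to
# 1/k (neutral equilibrium SFS); M reads are drawn binomially at
# chromosome frequency k/n; a SNP is accepted when the minor read count
# is >= b (equivalently the derived read count m is in [b, M - b]).
#
# C_pi(M, b, n) = sum_k (1/k) sum_{m = b}^{M - b} h(m, M) Binom(m; M, k/n)
#   with h(m, M) = 2 m (M - m) / (M (M - 1)) the measured heterozygosity,
#   so that sum(h) / C_pi estimates theta (and hence pi) per site.
# C_S(M, b, n)  = sum_k (1/k) sum_{m = b}^{M - b} Binom(m; M, k/n),
#   so that S / C_S estimates theta per site (Watterson).
# With b = 1 and deep coverage these reduce to (n - 1)/n and a_n.
.pi_correction <- function(M, b, n) {
  k <- seq_len(n - 1)
  m <- seq.int(b, M - b)
  h <- 2 * m * (M - m) / (M * (M - 1))
  sum(vapply(k, function(kk) sum(h * dbinom(m, M, kk / n)) / kk, numeric(1)))
}

.s_correction <- function(M, b, n) {
  k <- seq_len(n - 1)
  m <- seq.int(b, M - b)
  sum(vapply(k, function(kk) sum(dbinom(m, M, kk / n)) / kk, numeric(1)))
}

# cached versions keyed by (M, b, n) for speed across sites
.correction_cache <- new.env(parent = emptyenv())
.cached_correction <- function(M, b, n, which = c("pi", "s")) {
  which <- match.arg(which)
  key <- paste(which, M, b, n, sep = "_")
  got <- get0(key, envir = .correction_cache)
  if (!is.null(got)) return(got)
  val <- if (which == "pi") .pi_correction(M, b, n) else .s_correction(M, b, n)
  assign(key, val, envir = .correction_cache)
  val
}

# Tajima (1989) constants at sample size n
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site contributions for one pool: measured heterozygosity and SNP
# acceptance under the min-count rule, plus corrections
.pool_site_stats <- function(x, pool, n_pool, min_count) {
  counts <- .pool_counts(x, pool)
  ord <- t(apply(counts, 1, sort, decreasing = TRUE))
  M <- rowSums(counts)
  c1 <- ord[, 1]
  c2 <- ord[, 2]
  minor <- M - c1
  is_snp <- minor >= min_count & M >= 2 & ord[, 3] == 0 # biallelic in-pool
  # measured heterozygosity of a biallelic site from read counts
  h <- ifelse(M >= 2, 2 * c1 * c2 / (M * (M - 1)), 0)
  pi_term <- rep(0, nrow(x))
  s_term <- rep(0, nrow(x))
  idx <- which(is_snp)
  for (i in idx) {
    Cpi <- .cached_correction(M[i], min_count, n_pool, "pi")
    Cs <- .cached_correction(M[i], min_count, n_pool, "s")
    pi_term[i] <- h[i] / Cpi
    s_term[i] <- 1 / Cs
  }
  list(pi_term = pi_term, s_term = s_term, n_snps = is_snp)
}

#' Windowed pooled diversity statistics
#'
#' Nucleotide diversity (`pi`), Watterson's theta (`theta_w`) and
#' Tajima's D (`tajimas_d`) from pooled read counts, in nonoverlapping
#' physical windows. Estimators carry the pool-size and
#' minimum-minor-allele-count corrections (sums over the latent pool
#' frequency weighted by the neutral frequency spectrum and binomial read
#' sampling). Windows where the fraction of uncallable positions exceeds
#' `max_uncallable` are skipped; uncallable positions never enter the
#' denominator. Positions absent from the table count as uncallable.
#'
#' @param x A `sync_tbl`.
#' @param pool Pool name.
#' @param statistic One of `"pi"`, `"theta_w"`, `"tajimas_d"`.
#' @param window_bp Window span in bp (default 10000), tiled from
#'   position 1 per chromosome.
#' @param intergenic Optional tibble of gene features (`chrom`, `start`,
#'   `end`, 1-based closed); positions inside any feature are excluded
#'   from numerator and denominator.
#' @param min_count Minimum pooled minor-allele read count for a SNP
#'   (default 2).
#' @param max_uncallable Skip windows with more than this fraction of
#'   uncallable positions (default 0.4).
#' @return Tibble of window rows: `chrom`, `start`, `end`, `n_sites`
#'   (callable denominator), `n_snps`, `stat`, `estimate`,
#'   `frac_uncallable`, `skipped`.
#' @export
diversity_windows <- function(x, pool, statistic = c("pi", "tajimas_d", "theta_w"),
                              window_bp = 10000, intergenic = NULL,
                              min_count = 2, max_uncallable = 0.4) {
  statistic <- match.arg(statistic)
  pools <- sync_pools(x)
  if (!pool %in% pools$pool) abort(sprintf("pool '%s' not in table.", pool))
  n_pool <- pools$size[pools$pool == pool]

  masked <- rep(FALSE, nrow(x))
  if (!is.null(intergenic) && nrow(intergenic) > 0) {
    for (j in seq_len(nrow(intergenic))) {
      masked <- masked | (x$chrom == intergenic$chrom[j] &
        x$pos >= intergenic$start[j] & x$pos <= intergenic$end[j])
    }
  }

  stats <- .pool_site_stats(x, pool, n_pool, min_count)
  site <- tibble(
    chrom = x$chrom, pos = x$pos,
    callable = x$callable & !masked,
    pi_term = ifelse(x$callable & !masked, stats$pi_term, 0),
    s_term = ifelse(x$callable & !masked, stats$s_term, 0),
    snp = x$callable & !masked & stats$n_snps
  )

  tc <- .tajima_constants(n_pool)

  win <- site |>
    mutate(window = (.data$pos - 1) %/% window_bp) |>
    group_by(.data$chrom, .data$window) |>
    summarise(
      start = unique(.data$window) * window_bp + 1,
      end = (unique(.data$window) + 1) * window_bp,
      n_sites = sum(.data$callable),
      n_snps = sum(.data$snp),
      pi_sum = sum(.data$pi_term),
      s_sum = sum(.data$s_term),
      .groups = "drop"
    ) |>
    mutate(
      # positions absent from the table are uncallable by definition
      frac_uncallable = 1 - .data$n_sites / window_bp,
      skipped = .data$frac_uncallable > max_uncallable | .data$n_sites == 0
    )

  est <- switch(statistic,
    pi = win$pi_sum / win$n_sites,
    theta_w = win$s_sum / win$n_sites,
    tajimas_d = {
      d <- win$pi_sum - win$s_sum
      vd <- tc$e1 * win$n_snps + tc$e2 * win$n_snps * (win$n_snps - 1)
      ifelse(win$n_snps > 0, d / sqrt(vd), NA_real_)
    }
  )
  win |>
    mutate(stat = statistic, estimate = ifelse(.data$skipped, NA_real_, est)) |>
    select(
      "chrom", "start", "end", "n_sites", "n_snps", "stat", "estimate",
      "frac_uncallable", "skipped"
    )
}
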