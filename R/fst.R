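# Pool-seq F_ST: methods-of-moments estimator in its identity-probability
# form with pool-size and read-sampling corrections, windowed with a
# within-window SNP bootstrap.

# Per-site variance components for a pool pair.
# For pool i with read counts c_ia of each allele (r_i total reads) from a
# pool of n_i chromosomes:
#   D2_i = sum_a c_ia (c_ia - 1) / (r_i (r_i - 1))   (two distinct reads identical)
#   Q1_i = (D2_i - 1/n_i) / (1 - 1/n_i)              (identity within pool,
#                                                     corrected for reads drawn
#                                                     from the same chromosome)
#   Q2   = sum_a p_1a p_2a                           (identity between pools)
# and the multilocus estimator is F = sum(Q1 - Q2) / sum(1 - Q2) with
# Q1 = (Q1_1 + Q1_2) / 2, summed over SNPs (ratio of summed components).
.fst_site_components <- function(c1_1, c2_1, c1_2, c2_2, n1, n2) {
  r1 <- c1_1 + c2_1
  r2 <- c1_2 + c2_2
  D2_1 <- (c1_1 * (c1_1 - 1) + c2_1 * (c2_1 - 1)) / (r1 * (r1 - 1))
  D2_2 <- (c1_2 * (c1_2 - 1) + c2_2 * (c2_2 - 1)) / (r2 * (r2 - 1))
  Q1_1 <- (D2_1 - 1 / n1) / (1 - 1 / n1)
  Q1_2 <- (D2_2 - 1 / n2) / (1 - 1 / n2)
  Q2 <- (c1_1 / r1) * (c1_2 / r2) + (c2_1 / r1) * (c2_2 / r2)
  list(num = (Q1_1 + Q1_2) / 2 - Q2, den = 1 - Q2)
}

.fst_ratio <- function(num, den) {
  d <- sum(den)
  if (d <= 0) NA_real_ else sum(num) / d
}

.fst_boot <- function(num, den, n_boot) {
  if (n_boot <= 0) return(numeric(0))
  vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(num), replace = TRUE)
    .fst_ratio(num[i], den[i])
  }, numeric(1))
}

#' Windowed pool-seq F_ST
#'
#' Multilocus F_ST between two pools in nonoverlapping windows of a fixed
#' number of SNPs, using the pool-seq methods-of-moments estimator
#' (pool-size- and read-sampling-corrected identity probabilities; the
#' window statistic is the ratio of summed variance components, not the
#' mean of per-SNP ratios). Confidence intervals resample SNPs within
#' each window with replacement.
#'
#' @param x A `sync_tbl` (see [load_sync_table()]).
#' @param pool_pair Character vector of the two pool names.
#' @param window_snps Window size in SNPs (default 100). The trailing
#'   partial window is reported with `partial = TRUE`.
#' @param n_boot Bootstrap replicates per window (default 200; 0 skips
#'   the CI).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Tibble of window statistics: `chrom`, `start`, `end`,
#'   `n_snps`, `stat`, `estimate`, `ci_low`, `ci_high`, `n_boot`,
#'   `partial`, `negative` (flag; negative estimates are reported as
#'   computed, not clipped).
#' @export
fst_windows <- function(x, pool_pair, window_snps = 100, n_boot = 200,
                        seed = NULL) {
  pools <- sync_pools(x)
  if (!all(pool_pair %in% pools$pool) || length(pool_pair) != 2) {
    abort("`pool_pair` must name two pools present in the table.")
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- pools$size[pools$pool == pool_pair[1]]
  n2 <- pools$size[pools$pool == pool_pair[2]]

  y <- x[x$callable, , drop = FALSE]
  bi <- .site_biallelic(y, pool_pair)
  # SNP = polymorphic across the union of the two pools, with reads in both
  r1 <- bi$c1_1 + bi$c2_1
  r2 <- bi$c1_2 + bi$c2_2
  is_snp <- bi$n_obs == 2 & r1 >= 2 & r2 >= 2
  if (!any(is_snp)) abort("no biallelic callable SNPs for this pool pair.")
  snp <- tibble(
    chrom = y$chrom[is_snp], pos = y$pos[is_snp],
    c1_1 = bi$c1_1[is_snp], c2_1 = bi$c2_1[is_snp],
    c1_2 = bi$c1_2[is_snp], c2_2 = bi$c2_2[is_snp]
  )
  comp <- .fst_site_components(snp$c1_1, snp$c2_1, snp$c1_2, snp$c2_2, n1, n2)
  snp$num <- comp$num
  snp$den <- comp$den

  snp |>
    group_by(.data$chrom) |>
    mutate(window = (row_number() - 1) %/% window_snps) |>
    group_by(.data$chrom, .data$window) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos), n_snps = n(),
      estimate = .fst_ratio(.data$num, .data$den),
      boot = list(.fst_boot(.data$num, .data$den, n_boot)),
      .groups = "drop"
    ) |>
    mutate(
      stat = "fst",
      ci_low = map_dbl(.data$boot, function(b) {
        if (length(b) == 0) NA_real_ else unname(quantile(b, 0.025, na.rm = TRUE))
      }),
      ci_high = map_dbl(.data$boot, function(b) {
        if (length(b) == 0) NA_real_ else unname(quantile(b, 0.975, na.rm = TRUE))
      }),
      n_boot = n_boot,
      partial = .data$n_snps < window_snps,
      negative = !is.na(.data$estimate) & .data$estimate < 0
    ) |>
    select(
      "chrom", "start", "end", "n_snps", "stat", "estimate",
      "ci_low", "ci_high", "n_boot", "partial", "negative"
    )
}

#' Region-level pool-seq F_ST
#'
#' The multilocus ratio-of-sums estimator over all callable SNPs in the
#' table (or a region), with a SNP bootstrap CI.
#'
#' @inheritParams fst_windows
#' @param region Optional `c(chrom, start, end)` restriction.
#' @return One-row tibble like [fst_windows()].
#' @export
fst_region <- function(x, pool_pair, region = NULL, n_boot = 1000,
                       seed = NULL) {
  pools <- sync_pools(x)
  if (!is.null(region)) {
    x <- x[x$chrom == region[[1]] &
      x$pos >= as.numeric(region[[2]]) &
      x$pos <= as.numeric(region[[3]]), , drop = FALSE]
    attr(x, "pools") <- pools
    class(x) <- unique(c("sync_tbl", class(x)))
  }
  out <- fst_windows(x, pool_pair,
    window_snps = .Machine$integer.max,
    n_boot = n_boot, seed = seed
  )
  out$partial <- FALSE
  out
}
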