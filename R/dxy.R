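# Absolute divergence d_XY between pools (or pool vs outgroup) from
# pooled allele frequencies, via probabilistic consensus sequences and the
# exact expectation, with a site bootstrap.

# per-site base frequency matrix (sites x 4) for a pool or the outgroup
.freq_matrix <- function(x, who) {
  if (identical(who, "outgroup")) {
    if (all(is.na(x$outgroup))) abort("table has no outgroup alleles.")
    m <- matrix(0, nrow(x), 4, dimnames = list(NULL, .BASES))
    ok <- !is.na(x$outgroup)
    m[cbind(which(ok), match(x$outgroup[ok], .BASES))] <- 1
    m[!ok, ] <- NA_real_
    m
  } else {
    counts <- .pool_counts(x, who)
    counts / rowSums(counts)
  }
}

#' Absolute divergence between two pools
#'
#' `d_XY` between two pools (or a pool and the outgroup) over the
#' callable sites of a region. Two forms are reported: the exact
#' expectation over consensus draws,
#' `mean_s(1 - sum_a p_a(s) q_a(s))` (the per-site probability that
#' consensus bases drawn with probabilities equal to the pool allele
#' frequencies differ), and the seeded draw-based mean over `n_draws`
#' consensus pairs. The CI resamples sites with replacement.
#'
#' @param x A `sync_tbl`.
#' @param pair Length-2 character: two pool names, or a pool name and
#'   `"outgroup"`.
#' @param region Optional `c(chrom, start, end)` restriction.
#' @param n_boot Bootstrap replicates over sites (default 10000).
#' @param n_draws Consensus draws for the draw-based form (default 100).
#' @param seed Optional RNG seed.
#' @return One-row tibble: `n_sites`, `estimate` (exact expectation),
#'   `estimate_draw`, `draw_sd`, `ci_low`, `ci_high`, `n_boot`.
#' @export
dxy <- function(x, pair, region = NULL, n_boot = 10000, n_draws = 100,
                seed = NULL) {
  if (length(pair) != 2) abort("`pair` must name two pools (or one pool and 'outgroup').")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(region)) {
    pools <- sync_pools(x)
    x <- x[x$chrom == region[[1]] &
      x$pos >= as.numeric(region[[2]]) &
      x$pos <= as.numeric(region[[3]]), , drop = FALSE]
    attr(x, "pools") <- pools
  }
  y <- x[x$callable, , drop = FALSE]
  attr(y, "pools") <- attr(x, "pools")
  p <- .freq_matrix(y, pair[1])
  q <- .freq_matrix(y, pair[2])
  ok <- complete.cases(p) & complete.cases(q)
  p <- p[ok, , drop = FALSE]
  q <- q[ok, , drop = FALSE]
  L <- nrow(p)
  if (L == 0) abort("zero callable sites in the region.")

  per_site <- 1 - rowSums(p * q)
  exact <- mean(per_site)

  draw_consensus <- function(f) {
    apply(f, 1, function(pr) sample(.BASES, 1, prob = pr))
  }
  draws <- vapply(seq_len(n_draws), function(d) {
    mean(draw_consensus(p) != draw_consensus(q))
  }, numeric(1))

  boots <- if (n_boot > 0) {
    vapply(seq_len(n_boot), function(b) {
      mean(per_site[sample.int(L, replace = TRUE)])
    }, numeric(1))
  } else {
    numeric(0)
  }

  tibble(
    n_sites = L,
    estimate = exact,
    estimate_draw = mean(draws),
    draw_sd = sd(draws),
    ci_low = if (n_boot > 0) unname(quantile(boots, 0.025)) else NA_real_,
    ci_high = if (n_boot > 0) unname(quantile(boots, 0.975)) else NA_real_,
    n_boot = n_boot
  )
}
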