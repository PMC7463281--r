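# Per-site classification of pooled variation against an outgroup:
# fixed derived differences, shared and private polymorphisms, with
# windowed and regional summary ratios.

#' Classify sites by fixation and polymorphism state
#'
#' Each callable site is assigned one mutually exclusive category from
#' the allele counts of two pools and the outgroup allele:
#' `fixed_derived_pool1` / `fixed_derived_pool2` (the pools are fixed for
#' different alleles and the outgroup carries the other pool's allele, so
#' the focal pool's allele is derived), `shared_polymorphism` (both pools
#' polymorphic), `private_polymorphism_pool1` / `..._pool2` (exactly one
#' pool polymorphic), `monomorphic` (both pools fixed for the same
#' allele), `unpolarizable` (fixed difference but outgroup missing or not
#' matching either allele), and `uncallable`.
#'
#' @param x A `sync_tbl`.
#' @param pool_pair Character vector of the two pool names (pool1,
#'   pool2).
#' @param window_bp Window span for windowed summaries (default 10000).
#' @return Object of class `site_classification`: list with `sites`
#'   (tibble `chrom`, `pos`, `category`, `ancestral`), `summary`
#'   (category counts plus the fixed-derived : shared ratio per pool),
#'   and `windows` (per-window counts, ratio, and proportion of fixed
#'   derived sites). `tidy()` returns the per-site tibble.
#' @export
classify_sites <- function(x, pool_pair, window_bp = 10000) {
  pools <- sync_pools(x)
  if (!all(pool_pair %in% pools$pool) || length(pool_pair) != 2) {
    abort("`pool_pair` must name two pools present in the table.")
  }
  c1 <- .pool_counts(x, pool_pair[1])
  c2 <- .pool_counts(x, pool_pair[2])

  alleles1 <- c1 > 0
  alleles2 <- c2 > 0
  n1 <- rowSums(alleles1)
  n2 <- rowSums(alleles2)
  fixed_base1 <- ifelse(n1 == 1, .BASES[max.col(c1, ties.method = "first")], NA)
  fixed_base2 <- ifelse(n2 == 1, .BASES[max.col(c2, ties.method = "first")], NA)
  og <- x$outgroup

  category <- rep("monomorphic", nrow(x))
  poly1 <- n1 >= 2
  poly2 <- n2 >= 2
  category[poly1 & poly2] <- "shared_polymorphism"
  category[poly1 & !poly2] <- "private_polymorphism_pool1"
  category[!poly1 & poly2] <- "private_polymorphism_pool2"
  fixed_diff <- !poly1 & !poly2 & !is.na(fixed_base1) & !is.na(fixed_base2) &
    fixed_base1 != fixed_base2
  category[fixed_diff] <- "unpolarizable"
  category[fixed_diff & !is.na(og) & og == fixed_base2] <- "fixed_derived_pool1"
  category[fixed_diff & !is.na(og) & og == fixed_base1] <- "fixed_derived_pool2"
  # no reads in either pool
  category[n1 == 0 | n2 == 0] <- "uncallable"
  category[!x$callable] <- "uncallable"

  ancestral <- rep(NA_character_, nrow(x))
  ancestral[category == "fixed_derived_pool1"] <- fixed_base2[category == "fixed_derived_pool1"]
  ancestral[category == "fixed_derived_pool2"] <- fixed_base1[category == "fixed_derived_pool2"]

  sites <- tibble(chrom = x$chrom, pos = x$pos, category = category, ancestral = ancestral)

  lvls <- c(
    "fixed_derived_pool1", "fixed_derived_pool2", "shared_polymorphism",
    "private_polymorphism_pool1", "private_polymorphism_pool2",
    "monomorphic", "unpolarizable", "uncallable"
  )
  counts <- table(factor(category, levels = lvls))
  summary <- tibble(category = lvls, count = as.integer(counts))
  n_shared <- counts[["shared_polymorphism"]]
  ratios <- tibble(
    pool = pool_pair,
    fixed_derived = c(counts[["fixed_derived_pool1"]], counts[["fixed_derived_pool2"]]),
    shared = n_shared,
    fixed_to_shared = if (n_shared > 0) {
      c(counts[["fixed_derived_pool1"]], counts[["fixed_derived_pool2"]]) / n_shared
    } else {
      NA_real_
    }
  )

  windows <- sites |>
    mutate(window = (.data$pos - 1) %/% window_bp) |>
    group_by(.data$chrom, .data$window) |>
    summarise(
      start = unique(.data$window) * window_bp + 1,
      end = (unique(.data$window) + 1) * window_bp,
      n_sites = sum(.data$category != "uncallable"),
      fixed_derived_pool1 = sum(.data$category == "fixed_derived_pool1"),
      fixed_derived_pool2 = sum(.data$category == "fixed_derived_pool2"),
      shared = sum(.data$category == "shared_polymorphism"),
      .groups = "drop"
    ) |>
    mutate(
      ratio_pool1 = ifelse(.data$shared > 0, .data$fixed_derived_pool1 / .data$shared, NA_real_),
      prop_fixed_derived_pool1 = ifelse(.data$n_sites > 0,
        .data$fixed_derived_pool1 / .data$n_sites, NA_real_
      )
    ) |>
    select(-"window")

  structure(
    list(sites = sites, summary = summary, ratios = ratios, windows = windows),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Site classification\n")
  print(x$summary)
  print(x$ratios)
  invisible(x)
}

#' @export
tidy.site_classification <- function(x, ...) x$sites

#' @export
glance.site_classification <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "category", values_from = "count")
}
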