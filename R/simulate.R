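# Seeded synthetic-data generators: every analysis input format can be
# produced with known truth, so the whole pipeline is testable offline.
# Pooled counts reuse the internal coalescent so data generation and
# neutrality-test calibration share one stochastic model.

# genotype matrix (samples x segregating sites) from one genealogy
.tree_genotypes <- function(tree, mu, L) {
  nid <- length(tree$parent)
  n_samp <- tree$n_samp
  below <- matrix(FALSE, nid, n_samp)
  below[cbind(seq_len(n_samp), seq_len(n_samp))] <- TRUE
  ord <- order(tree$time[seq_len(nid)])
  for (i in ord) {
    p <- tree$parent[i]
    if (p > 0) below[p, ] <- below[p, ] | below[i, ]
  }
  ptime <- ifelse(tree$parent > 0, tree$time[pmax(tree$parent, 1L)], 0)
  blen <- ifelse(tree$parent > 0, ptime - tree$time[seq_len(nid)], 0)
  muts <- rpois(nid, mu * L * blen)
  carriers <- rep(seq_len(nid), muts)
  if (length(carriers) == 0) {
    return(matrix(0L, n_samp, 0))
  }
  g <- t(below[carriers, , drop = FALSE]) * 1L
  g
}

#' Simulate a pooled-count sync table from the coalescent
#'
#' Draws one non-recombining locus genealogy under a
#' [demography_scenario()], places infinite-sites mutations, and emits a
#' sync table of binomial read counts for the SR and ST pools plus the
#' outgroup allele, together with a truth record. Every position of the
#' locus appears (invariant positions carry monomorphic counts), so
#' window denominators behave like real data.
#'
#' @param scenario A [demography_scenario()].
#' @param depth Mean read depth per pool (Poisson; default 50).
#' @param chrom Chromosome label (default `"X"`).
#' @param seed Optional RNG seed.
#' @return List: `table` (a `sync_tbl` with pools `SR`, `ST` and
#'   outgroup alleles), `truth` (tibble of segregating sites: `pos`,
#'   true pool allele frequencies, `category` per [classify_sites()]
#'   semantics).
#' @export
sim_pooled_counts <- function(scenario, depth = 50, chrom = "X", seed = NULL) {
  stopifnot(inherits(scenario, "demography_scenario"))
  if (depth < 1) abort("`depth` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(scenario$locus_length)
  ns <- scenario$samples
  tree <- .sim_tree(scenario)
  g <- .tree_genotypes(tree, scenario$mu, L)
  n_sites <- ncol(g)
  if (n_sites > L) {
    keep <- sample.int(n_sites, L)
    g <- g[, keep, drop = FALSE]
    n_sites <- L
  }
  pos_var <- sort(sample.int(L, n_sites))

  idx_out <- seq_len(ns[["outgroup"]])
  idx_st <- ns[["outgroup"]] + seq_len(ns[["st"]])
  idx_sr <- ns[["outgroup"]] + ns[["st"]] + seq_len(ns[["sr"]])

  anc_base <- sample(.BASES, L, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(.BASES, b), 1), character(1))

  freq_sr <- freq_st <- rep(0, L)
  og_derived <- rep(FALSE, L)
  if (n_sites > 0) {
    freq_sr[pos_var] <- colMeans(g[idx_sr, , drop = FALSE])
    freq_st[pos_var] <- colMeans(g[idx_st, , drop = FALSE])
    og_derived[pos_var] <- g[idx_out[1], ] == 1
  }

  make_pool <- function(freq, pool) {
    M <- rpois(L, depth)
    der <- rbinom(L, M, freq)
    counts <- matrix(0L, L, 6, dimnames = list(NULL, .SYNC_FIELDS))
    for (b in .BASES) {
      counts[, b] <- (anc_base == b) * (M - der) + (der_base == b) * der
    }
    out <- as.data.frame(counts)
    names(out) <- paste(pool, .SYNC_FIELDS, sep = ".")
    out
  }

  sites <- bind_cols(
    tibble(
      chrom = chrom, pos = seq_len(L), ref = anc_base,
      outgroup = ifelse(og_derived, der_base, anc_base)
    ),
    make_pool(freq_sr, "SR"),
    make_pool(freq_st, "ST")
  )
  tbl <- as_sync_table(sites, pool_info(c("SR", "ST"), c(ns[["sr"]], ns[["st"]]), c("SR", "ST")))

  truth <- tibble(
    chrom = chrom, pos = pos_var,
    freq_sr = freq_sr[pos_var], freq_st = freq_st[pos_var],
    outgroup_derived = og_derived[pos_var]
  ) |>
    mutate(category = dplyr::case_when(
      .data$freq_sr %in% c(0, 1) & .data$freq_st %in% c(0, 1) &
        .data$freq_sr != .data$freq_st & !.data$outgroup_derived &
        .data$freq_sr == 1 ~ "fixed_derived_pool1",
      .data$freq_sr %in% c(0, 1) & .data$freq_st %in% c(0, 1) &
        .data$freq_sr != .data$freq_st & !.data$outgroup_derived &
        .data$freq_st == 1 ~ "fixed_derived_pool2",
      # outgroup carries the derived base: the other pool's (ancestral)
      # allele is the derived one after polarization against the outgroup
      .data$freq_sr %in% c(0, 1) & .data$freq_st %in% c(0, 1) &
        .data$freq_sr != .data$freq_st & .data$outgroup_derived &
        .data$freq_sr == 1 ~ "fixed_derived_pool2",
      .data$freq_sr %in% c(0, 1) & .data$freq_st %in% c(0, 1) &
        .data$freq_sr != .data$freq_st & .data$outgroup_derived &
        .data$freq_st == 1 ~ "fixed_derived_pool1",
      !.data$freq_sr %in% c(0, 1) & !.data$freq_st %in% c(0, 1) ~ "shared_polymorphism",
      !.data$freq_sr %in% c(0, 1) ~ "private_polymorphism_pool1",
      !.data$freq_st %in% c(0, 1) ~ "private_polymorphism_pool2",
      TRUE ~ "monomorphic"
    ))

  list(table = tbl, truth = truth)
}

#' Simulate an arrangement-labeled haplotype panel
#'
#' Builds aligned sequences per region with configurable numbers of
#' arrangement-fixed columns, shared polymorphic columns, singleton
#' columns, and indel columns; all other columns are monomorphic. A truth
#' sidecar lists each column's class.
#'
#' @param n_per_arrangement Strains per arrangement (default 8).
#' @param regions Region ids (default `"XR1"`).
#' @param length_bp Alignment length per region (default 200).
#' @param n_fixed,n_shared,n_singleton,n_indel Column counts per region.
#' @param seed Optional RNG seed.
#' @return List: `panel` (tibble compatible with
#'   [build_segregating_matrix()]), `truth` (tibble `region`, `position`,
#'   `class`).
#' @export
sim_haplotype_panel <- function(n_per_arrangement = 8, regions = "XR1",
                                length_bp = 200, n_fixed = 5, n_shared = 5,
                                n_singleton = 2, n_indel = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_special <- n_fixed + n_shared + n_singleton + n_indel
  if (n_special > length_bp) abort("special columns exceed `length_bp`.")
  strains <- c(
    paste0("SR_", seq_len(n_per_arrangement)),
    paste0("ST_", seq_len(n_per_arrangement))
  )
  arr <- rep(c("SR", "ST"), each = n_per_arrangement)
  n_str <- length(strains)

  panel <- list()
  truth <- list()
  for (rg in regions) {
    m <- matrix(sample(.BASES, length_bp, replace = TRUE),
      nrow = n_str, ncol = length_bp, byrow = TRUE
    )
    cls <- rep("monomorphic", length_bp)
    special <- sample.int(length_bp, n_special)
    take <- function(n) {
      out <- special[seq_len(n)]
      special <<- special[-seq_len(n)]
      out
    }
    for (j in if (n_fixed > 0) take(n_fixed) else integer(0)) {
      b <- m[1, j]
      alt <- sample(setdiff(.BASES, b), 1)
      m[arr == "SR", j] <- alt
      cls[j] <- "fixed"
    }
    for (j in if (n_shared > 0) take(n_shared) else integer(0)) {
      b <- m[1, j]
      alt <- sample(setdiff(.BASES, b), 1)
      carriers <- c(
        sample(which(arr == "SR"), max(1, n_per_arrangement %/% 2)),
        sample(which(arr == "ST"), max(1, n_per_arrangement %/% 2))
      )
      m[carriers, j] <- alt
      cls[j] <- "shared"
    }
    for (j in if (n_singleton > 0) take(n_singleton) else integer(0)) {
      b <- m[1, j]
      alt <- sample(setdiff(.BASES, b), 1)
      m[sample.int(n_str, 1), j] <- alt
      cls[j] <- "singleton"
    }
    for (j in if (n_indel > 0) take(n_indel) else integer(0)) {
      m[sample.int(n_str, sample(1:3, 1)), j] <- "-"
      cls[j] <- "indel"
    }
    panel[[rg]] <- tibble(
      strain = strains, arrangement = arr, region = rg,
      seq = apply(m, 1, paste, collapse = "")
    )
    truth[[rg]] <- tibble(region = rg, position = seq_len(length_bp), class = cls)
  }
  list(panel = list_rbind(panel), truth = list_rbind(truth))
}

#' Write a haplotype panel as per-region FASTA files
#'
#' @param panel Panel tibble (`strain`, `arrangement`, `region`, `seq`).
#' @param dir Output directory.
#' @return Named vector of file paths (by region), suitable for
#'   [read_haplotype_panel()].
#' @export
write_panel_fasta <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (rg in unique(panel$region)) {
    sub <- panel[panel$region == rg, ]
    path <- file.path(dir, paste0(rg, ".fasta"))
    lines <- as.vector(rbind(
      paste0(">", sub$strain, "|", sub$arrangement),
      sub$seq
    ))
    writeLines(lines, path)
    paths[rg] <- path
  }
  paths
}

#' Simulate testcross progeny counts
#'
#' Multinomial draw over the four marker classes: parental classes at
#' `(1 - c) / 2` each, recombinant classes at `c / 2` each, optionally
#' reweighted by per-recombinant-class relative viabilities.
#'
#' @param n Progeny count.
#' @param c Recombination fraction.
#' @param viability Relative viabilities of the two recombinant classes
#'   (default `c(1, 1)`; 0 suppresses a class entirely).
#' @param seed Optional RNG seed.
#' @return List: `counts` tibble (`class`, `count`), `truth` (the
#'   generating probabilities and parameters).
#' @export
sim_testcross_progeny <- function(n, c, viability = c(1, 1), seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  .assert_prob(c, "c")
  if (!is.null(seed)) set.seed(seed)
  w <- c((1 - c) / 2, (1 - c) / 2, (c / 2) * viability[1], (c / 2) * viability[2])
  p <- w / sum(w)
  cls <- c("parental_1", "parental_2", "recombinant_1", "recombinant_2")
  draw <- as.integer(rmultinom(1, n, p))
  list(
    counts = tibble(class = cls, count = draw),
    truth = tibble(class = cls, prob = p, c = c, n = n)
  )
}

#' Simulate a segregation assay
#'
#' @param n Progeny count.
#' @param k True proportion of daughters.
#' @param seed Optional RNG seed.
#' @return List: `counts` tibble (`females`, `males`), `truth`.
#' @export
sim_segregation_counts <- function(n, k, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  .assert_prob(k, "k")
  if (!is.null(seed)) set.seed(seed)
  f <- rbinom(1, n, k)
  list(
    counts = tibble(females = f, males = n - f),
    truth = tibble(n = n, k = k)
  )
}

#' Simulate a natural-survey haplotype sample
#'
#' @param n Chromosomes sampled.
#' @param freqs True haplotype frequencies (named `ST`, `SR`, `BM`, `T`
#'   or in canonical order).
#' @param seed Optional RNG seed.
#' @return List: `table` tibble (`study`, `n`, frequency columns in
#'   [sr_survey_table()] layout), `counts`, `truth`.
#' @export
sim_survey_sample <- function(n, freqs, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  freqs <- .canon4(freqs, "freqs")
  .assert_freq_vector(freqs, "freqs", tol = 5e-5)
  if (!is.null(seed)) set.seed(seed)
  draw <- as.integer(rmultinom(1, n, freqs))
  names(draw) <- gamete_types()
  list(
    table = tibble(
      study = "simulated", n = n,
      SR = draw[["SR"]] / n, BM = draw[["BM"]] / n,
      T = draw[["T"]] / n, ST = draw[["ST"]] / n
    ),
    counts = tibble(type = gamete_types(), count = draw),
    truth = tibble(type = gamete_types(), freq = as.numeric(freqs), n = n)
  )
}
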