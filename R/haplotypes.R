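# Haplotype-panel LD: aligned intergenic amplicons labeled by
# arrangement, reduced to a binary segregating-site matrix, pairwise r²
# with chi-square or permutation significance, and per-site Fisher exact
# tests of arrangement association.

#' Read an arrangement-labeled haplotype panel
#'
#' Reads one aligned multi-FASTA per region. Sequence names encode the
#' arrangement as `strain|SR` or `strain|ST`.
#'
#' @param paths Named character vector of FASTA paths; names are region
#'   ids. Unnamed paths get region ids from file names.
#' @param manifest Optional region manifest tibble (`region`, `chrom`,
#'   `start`, `end`) carried through to site provenance.
#' @return Tibble (`haplotype_panel`): `strain`, `arrangement`, `region`,
#'   `seq` (aligned sequence string).
#' @export
read_haplotype_panel <- function(paths, manifest = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required to read FASTA panels.")
  }
  if (is.null(names(paths))) {
    names(paths) <- stringr::str_remove(basename(paths), "\\.(fa|fasta)$")
  }
  panel <- imap(paths, function(path, region) {
    ss <- Biostrings::readDNAStringSet(path)
    nm <- names(ss)
    parts <- stringr::str_split_fixed(nm, stringr::fixed("|"), 2)
    if (any(parts[, 2] == "")) {
      abort(sprintf("sequence names in %s must be 'strain|arrangement'.", path))
    }
    tibble(
      strain = parts[, 1], arrangement = parts[, 2], region = region,
      seq = as.character(ss)
    )
  }) |> list_rbind()
  bad <- panel |>
    group_by(.data$region) |>
    summarise(ok = length(unique(nchar(.data$seq))) == 1, .groups = "drop")
  if (any(!bad$ok)) {
    abort(sprintf(
      "unequal sequence lengths within region(s): %s (sequences must be aligned).",
      paste(bad$region[!bad$ok], collapse = ", ")
    ))
  }
  if (!is.null(manifest)) attr(panel, "manifest") <- manifest
  class(panel) <- c("haplotype_panel", class(panel))
  panel
}

#' Build the binary segregating-site matrix from a panel
#'
#' Splits each region's alignment into columns; removes columns
#' containing indels (`-`) or ambiguous bases, monomorphic columns, and
#' singleton columns (minor count 1); codes the survivors 0/1 and
#' concatenates regions. Coding: 1 = derived allele when an outgroup
#' sequence is supplied for the region, otherwise 1 = minor allele (ties
#' broken toward the lexicographically larger base). Coding affects
#' display only, not r².
#'
#' @param panel A tibble with `strain`, `arrangement`, `region`, `seq`
#'   (see [read_haplotype_panel()]); strains must be identical across
#'   regions.
#' @param outgroup Optional named character vector of outgroup sequences
#'   per region (for derived/ancestral polarity).
#' @param min_minor Minimum minor-allele count to keep a column
#'   (default 2, i.e. singletons removed).
#' @return Object of class `segregating_matrix`: list with `matrix`
#'   (strains x sites, 0/1, column names `region:position`), `sites`
#'   (tibble `site`, `region`, `position`, `allele0`, `allele1`,
#'   `polarity`), `arrangement` (named by strain).
#' @export
build_segregating_matrix <- function(panel, outgroup = NULL, min_minor = 2) {
  regions <- unique(panel$region)
  strains <- unique(panel$strain)
  if (length(strains) < 4) abort("need at least 4 strains (2 per arrangement).")
  arr <- panel |>
    dplyr::distinct(.data$strain, .data$arrangement)
  if (nrow(arr) != length(strains)) abort("inconsistent arrangement labels per strain.")

  cols <- list()
  meta <- list()
  for (rg in regions) {
    sub <- panel[panel$region == rg, ]
    sub <- sub[match(strains, sub$strain), ]
    if (anyNA(sub$strain)) abort(sprintf("region %s is missing strains.", rg))
    m <- do.call(rbind, strsplit(toupper(sub$seq), ""))
    og <- if (!is.null(outgroup) && rg %in% names(outgroup)) {
      strsplit(toupper(outgroup[[rg]]), "")[[1]]
    } else {
      NULL
    }
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (any(!col %in% .BASES)) next # indel or ambiguous base
      tab <- sort(table(col), decreasing = TRUE)
      if (length(tab) != 2) next # monomorphic or multiallelic
      if (min(tab) < min_minor) next # singleton
      major <- names(tab)[1]
      minor <- names(tab)[2]
      if (tab[1] == tab[2]) { # tie: lexicographically larger base is "1"
        minor <- max(names(tab))
        major <- setdiff(names(tab), minor)
      }
      polarity <- "minor"
      one <- minor
      if (!is.null(og) && length(og) >= j && og[j] %in% c(major, minor)) {
        one <- setdiff(c(major, minor), og[j]) # derived = non-ancestral
        polarity <- "derived"
      }
      cols[[length(cols) + 1L]] <- as.integer(col == one)
      meta[[length(meta) + 1L]] <- tibble(
        region = rg, position = j, allele0 = setdiff(c(major, minor), one),
        allele1 = one, polarity = polarity
      )
    }
  }
  if (length(cols) == 0) abort("no segregating sites after filtering.")
  mat <- do.call(cbind, cols)
  sites <- list_rbind(meta) |>
    mutate(site = paste(.data$region, .data$position, sep = ":")) |>
    relocate("site")
  rownames(mat) <- strains
  colnames(mat) <- sites$site
  structure(
    list(
      matrix = mat, sites = sites,
      arrangement = setNames(arr$arrangement, arr$strain)[strains]
    ),
    class = "segregating_matrix"
  )
}

#' @export
print.segregating_matrix <- function(x, ...) {
  cat(sprintf(
    "Segregating-site matrix: %d strains x %d sites (%d regions)\n",
    nrow(x$matrix), ncol(x$matrix), length(unique(x$sites$region))
  ))
  invisible(x)
}

#' @export
tidy.segregating_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "strain") |>
    tidyr::pivot_longer(-"strain", names_to = "site", values_to = "allele") |>
    left_join(x$sites, by = "site")
}

#' Pairwise linkage disequilibrium matrix
#'
#' For haploid 0/1 data the composite correlation-based LD measure
#' reduces to the squared Pearson correlation of allele indicators:
#' `r² = D² / (p(1-p) q(1-q))`. Significance per pair from `n r²`
#' against chi-square(1) or by seeded permutation of one column;
#' Benjamini-Hochberg adjustment over all tested pairs.
#'
#' @param x A `segregating_matrix` (or plain 0/1 matrix, strains in
#'   rows).
#' @param significance `"chisq"` (default) or `"permutation"`.
#' @param n_perm Permutations when `significance = "permutation"`.
#' @param seed Optional RNG seed for permutations.
#' @return Long tibble: `site_i`, `site_j`, `r2`, `p`, `q` (BH), plus
#'   region/coordinate provenance when available.
#' @export
ld_matrix <- function(x, significance = c("chisq", "permutation"),
                      n_perm = 1000, seed = NULL) {
  significance <- match.arg(significance)
  if (!is.null(seed)) set.seed(seed)
  m <- if (inherits(x, "segregating_matrix")) x$matrix else x
  if (ncol(m) < 2) abort("need at least 2 polymorphic columns.")
  if (any(apply(m, 2, var) == 0)) abort("zero-variance column present (matrix not preprocessed?).")
  n <- nrow(m)
  cm <- suppressWarnings(cor(m))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  r2 <- cm[pairs]^2
  p <- if (significance == "chisq") {
    pchisq(n * r2, df = 1, lower.tail = FALSE)
  } else {
    vapply(seq_len(nrow(pairs)), function(idx) {
      a <- m[, pairs[idx, 1]]
      b <- m[, pairs[idx, 2]]
      obs <- cor(a, b)^2
      perms <- vapply(seq_len(n_perm), function(pp) cor(a, sample(b))^2, numeric(1))
      (sum(perms >= obs) + 1) / (n_perm + 1)
    }, numeric(1))
  }
  out <- tibble(
    site_i = colnames(m)[pairs[, 1]],
    site_j = colnames(m)[pairs[, 2]],
    r2 = r2, p = p, q = p.adjust(p, method = "BH")
  )
  if (inherits(x, "segregating_matrix")) {
    prov <- x$sites |> select("site", "region", "position")
    out <- out |>
      left_join(prov |> rename(region_i = "region", position_i = "position"),
        by = c(site_i = "site")
      ) |>
      left_join(prov |> rename(region_j = "region", position_j = "position"),
        by = c(site_j = "site")
      )
  }
  out
}

#' Per-site Fisher exact test of arrangement association
#'
#' Two-sided Fisher exact test of each site's 2x2 allele-by-arrangement
#' table, BH-adjusted over sites, with a power note: the smallest
#' p-value attainable given the site's margins (a site whose margins
#' cannot reach `alpha` can never be significant regardless of effect).
#'
#' @param x A `segregating_matrix`, or a 0/1 matrix plus `arrangement`.
#' @param arrangement Arrangement label per strain (taken from the
#'   `segregating_matrix` when available).
#' @param alpha Significance level for the power note (default 0.05).
#' @return Tibble: `site`, `p`, `q`, `min_attainable_p`, `powered`.
#' @export
arrangement_fet <- function(x, arrangement = NULL, alpha = 0.05) {
  m <- if (inherits(x, "segregating_matrix")) x$matrix else x
  if (is.null(arrangement) && inherits(x, "segregating_matrix")) {
    arrangement <- x$arrangement
  }
  if (is.null(arrangement)) abort("`arrangement` labels are required.")
  arrangement <- as.factor(arrangement)
  if (nlevels(arrangement) != 2) abort("exactly two arrangement labels are required.")
  res <- map(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (var(col) == 0) abort("zero-variance column present (matrix not preprocessed?).")
    tab <- table(factor(col, levels = 0:1), arrangement)
    ft <- fisher.test(tab)
    # smallest attainable p given margins: most extreme tables
    k <- sum(col) # allele-1 margin
    ngrp <- table(arrangement)
    lo <- max(0, k - ngrp[2])
    hi <- min(k, ngrp[1])
    p_ext <- vapply(c(lo, hi), function(a) {
      t2 <- matrix(c(a, k - a, ngrp[1] - a, ngrp[2] - (k - a)), 2, 2)
      fisher.test(t2)$p.value
    }, numeric(1))
    tibble(
      site = colnames(m)[j] %||% as.character(j),
      p = ft$p.value, min_attainable_p = min(p_ext)
    )
  }) |> list_rbind()
  res |>
    mutate(
      q = p.adjust(.data$p, method = "BH"),
      powered = .data$min_attainable_p < alpha
    ) |>
    relocate("site", "p", "q")
}
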