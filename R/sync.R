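# Sync-format pooled allele-count tables: parsing, serialization, site
# filtering, and internal count accessors shared by the window statistics.

.BASES <- c("A", "T", "C", "G")
.SYNC_FIELDS <- c("A", "T", "C", "G", "N", "del")

#' Pool metadata constructor
#'
#' @param pool Pool names (character).
#' @param size Haploid pool sizes (number of chromosomes per pool).
#' @param arrangement Optional arrangement labels.
#' @return Tibble with columns `pool`, `size`, `arrangement`.
#' @export
#' @examples
#' pool_info(c("SR", "ST"), c(8, 8), c("SR", "ST"))
pool_info <- function(pool, size, arrangement = NA_character_) {
  if (any(size < 1)) abort("pool sizes must be >= 1.")
  tibble(pool = pool, size = as.integer(size), arrangement = arrangement)
}

# accessor for the pools attribute with a clear failure mode
sync_pools <- function(x) {
  p <- attr(x, "pools")
  if (is.null(p)) {
    abort("this table has lost its `pools` attribute; rebuild it with `as_sync_table()`.")
  }
  p
}

#' Construct a sync site table from components
#'
#' Builds the `sync_tbl` object used by all pooled statistics: a tibble
#' with columns `chrom`, `pos`, `ref`, optional `outgroup` (allele
#' character), `callable`, and per-pool count columns named
#' `"<pool>.<base>"` for bases A, T, C, G, N, del; pool metadata is
#' attached as the `pools` attribute.
#'
#' @param sites Tibble with `chrom`, `pos`, `ref` and count columns.
#' @param pools A [pool_info()] tibble.
#' @return A `sync_tbl`.
#' @export
as_sync_table <- function(sites, pools) {
  needed <- unlist(lapply(pools$pool, function(p) paste(p, .SYNC_FIELDS, sep = ".")))
  missing_cols <- setdiff(c("chrom", "pos", "ref", needed), names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"outgroup" %in% names(sites)) sites$outgroup <- NA_character_
  if (!"callable" %in% names(sites)) sites$callable <- TRUE
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) {
    abort(sprintf(
      "duplicate (chrom, pos) entries, first at %s:%d.",
      sites$chrom[dup][1], sites$pos[dup][1]
    ))
  }
  sites <- arrange(sites, .data$chrom, .data$pos) |>
    relocate("chrom", "pos", "ref", "outgroup", "callable")
  out <- as_tibble(sites)
  attr(out, "pools") <- pools
  class(out) <- c("sync_tbl", class(out))
  out
}

#' Read a sync-format pooled count file
#'
#' Parses the tab-separated sync format: `chrom`, `pos` (1-based), `ref`,
#' then one `A:T:C:G:N:del` count column per pool. An optional trailing
#' column can carry an outgroup "pool" of effective size 1; it is reduced
#' to the outgroup allele (its majority base; `NA` when uncovered).
#'
#' @param path Path to the sync file (no header).
#' @param pools A [pool_info()] tibble describing the count columns in
#'   file order.
#' @param outgroup If `TRUE`, the file has one extra trailing count
#'   column holding the outgroup.
#' @return A `sync_tbl` (see [as_sync_table()]).
#' @export
load_sync_table <- function(path, pools, outgroup = FALSE) {
  n_counts <- nrow(pools) + as.integer(outgroup)
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(raw) != 3 + n_counts) {
    abort(sprintf(
      "expected %d columns (chrom, pos, ref, %d count columns), found %d.",
      3 + n_counts, n_counts, ncol(raw)
    ))
  }
  pos <- suppressWarnings(as.integer(raw[[2]]))
  if (anyNA(pos)) {
    abort(sprintf("malformed position field at line %d.", which(is.na(pos))[1]))
  }

  parse_counts <- function(col, label) {
    parts <- stringr::str_split_fixed(col, ":", 7)
    if (any(parts[, 7] != "") || any(parts[, 6] == "")) {
      bad <- which(parts[, 7] != "" | parts[, 6] == "")[1]
      abort(sprintf("malformed %s count field at line %d (need 6 ':'-separated integers).", label, bad))
    }
    m <- suppressWarnings(matrix(as.integer(parts[, 1:6]), ncol = 6))
    if (anyNA(m)) {
      abort(sprintf(
        "non-numeric %s count field at line %d.", label,
        which(rowSums(is.na(m)) > 0)[1]
      ))
    }
    if (any(m < 0)) abort(sprintf("negative %s count at line %d.", label, which(rowSums(m < 0) > 0)[1]))
    colnames(m) <- .SYNC_FIELDS
    m
  }

  sites <- tibble(chrom = raw[[1]], pos = pos, ref = raw[[3]])
  for (i in seq_len(nrow(pools))) {
    m <- parse_counts(raw[[3 + i]], pools$pool[i])
    for (f in .SYNC_FIELDS) sites[[paste(pools$pool[i], f, sep = ".")]] <- m[, f]
  }
  if (outgroup) {
    m <- parse_counts(raw[[3 + n_counts]], "outgroup")
    base_counts <- m[, .BASES, drop = FALSE]
    tot <- rowSums(base_counts)
    sites$outgroup <- ifelse(tot == 0, NA_character_,
      .BASES[max.col(base_counts, ties.method = "first")]
    )
  }
  as_sync_table(sites, pools)
}

#' Write a sync table to disk
#'
#' Serializes a `sync_tbl` back to the tab-separated sync format (one
#' `A:T:C:G:N:del` column per pool; outgroup allele, when present, as a
#' trailing single-read pseudo-pool).
#'
#' @param x A `sync_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  pools <- sync_pools(x)
  cols <- list(x$chrom, x$pos, x$ref)
  for (p in pools$pool) {
    m <- as.matrix(x[, paste(p, .SYNC_FIELDS, sep = ".")])
    cols <- c(cols, list(apply(m, 1, paste, collapse = ":")))
  }
  if (any(!is.na(x$outgroup))) {
    og <- vapply(x$outgroup, function(a) {
      counts <- setNames(rep(0L, 6), .SYNC_FIELDS)
      if (!is.na(a)) counts[a] <- 1L
      paste(counts, collapse = ":")
    }, character(1))
    cols <- c(cols, list(og))
  }
  df <- as.data.frame(cols, col.names = paste0("V", seq_along(cols)))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

# per-pool base-count matrix (sites x 4) for internal use
.pool_counts <- function(x, pool) {
  as.matrix(x[, paste(pool, .BASES, sep = ".")])
}

# per-pool total read coverage (all six fields)
.pool_coverage <- function(x, pool) {
  rowSums(as.matrix(x[, paste(pool, .SYNC_FIELDS, sep = ".")]))
}

# bases observed (count > 0) across the given pools; returns sites x 4 logical
.observed_alleles <- function(x, pools_use) {
  tot <- Reduce(`+`, lapply(pools_use, function(p) .pool_counts(x, p)))
  tot > 0
}

#' Filter and flag sites for callability
#'
#' Applies the variant-level filters: a site is uncallable when any
#' pool's total coverage is below that pool's haploid size or above the
#' pool's per-chromosome mean coverage plus `max_sd` standard deviations;
#' positions within `indel_pad` bp of an indel are masked (uncallable);
#' sites with more than two observed alleles across the pools are removed
#' entirely. Monomorphic callable sites are retained (they enter
#' denominators of window statistics).
#'
#' @param x A `sync_tbl`.
#' @param coverage_stats Optional tibble `pool`, `chrom`, `mean`, `sd`;
#'   computed from the table when `NULL`.
#' @param indel_positions Optional tibble with `chrom`, `pos` of indels
#'   (each masks `pos +/- indel_pad`).
#' @param max_sd Coverage outlier multiplier (default 3).
#' @param indel_pad Masking pad around indels in bp (default 5).
#' @return The filtered `sync_tbl` with `callable` updated.
#' @export
filter_sites <- function(x, coverage_stats = NULL, indel_positions = NULL,
                         max_sd = 3, indel_pad = 5) {
  pools <- sync_pools(x)
  if (nrow(x) == 0) return(x)
  if (anyNA(pools$size)) abort("pool sizes missing from pool metadata.")

  cov <- vapply(pools$pool, function(p) .pool_coverage(x, p),
    numeric(nrow(x))
  )
  cov <- matrix(cov, nrow = nrow(x))
  colnames(cov) <- pools$pool

  if (is.null(coverage_stats)) {
    coverage_stats <- purrr::map(pools$pool, function(p) {
      tibble(chrom = x$chrom, cv = cov[, p]) |>
        group_by(.data$chrom) |>
        summarise(mean = mean(.data$cv), sd = sd(.data$cv), .groups = "drop") |>
        mutate(pool = p, sd = ifelse(is.na(.data$sd), 0, .data$sd))
    }) |> list_rbind()
  }

  callable <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(pools))) {
    p <- pools$pool[i]
    st <- coverage_stats[coverage_stats$pool == p, ]
    mu <- st$mean[match(x$chrom, st$chrom)]
    sg <- st$sd[match(x$chrom, st$chrom)]
    callable <- callable & cov[, p] >= pools$size[i] & cov[, p] <= mu + max_sd * sg
  }

  if (!is.null(indel_positions) && nrow(indel_positions) > 0) {
    for (j in seq_len(nrow(indel_positions))) {
      hit <- x$chrom == indel_positions$chrom[j] &
        abs(x$pos - indel_positions$pos[j]) <= indel_pad
      callable <- callable & !hit
    }
  }

  n_alleles <- rowSums(.observed_alleles(x, pools$pool))
  keep <- n_alleles <= 2
  out <- x[keep, , drop = FALSE]
  out$callable <- callable[keep] & x$callable[keep]
  attr(out, "pools") <- pools
  class(out) <- unique(c("sync_tbl", class(out)))
  out
}

# biallelic site summary used by fst/dxy/classify: for each site the two
# site alleles (major first by pooled count), per-pool counts of each
.site_biallelic <- function(x, pools_use) {
  counts <- lapply(pools_use, function(p) .pool_counts(x, p))
  tot <- Reduce(`+`, counts)
  ord <- t(apply(tot, 1, order, decreasing = TRUE))
  a1 <- ord[, 1]
  a2 <- ord[, 2]
  n_obs <- rowSums(tot > 0)
  # for monomorphic sites the second "allele" is arbitrary with count 0
  res <- list(
    allele1 = .BASES[a1], allele2 = .BASES[a2], n_obs = n_obs
  )
  idx <- cbind(seq_len(nrow(x)), a1)
  idx2 <- cbind(seq_len(nrow(x)), a2)
  for (i in seq_along(pools_use)) {
    res[[paste0("c1_", i)]] <- counts[[i]][idx]
    res[[paste0("c2_", i)]] <- counts[[i]][idx2]
  }
  res
}
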