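# Divergence dating: transform window F_ST estimates to divergence-scaled
# times and calibrate per window against an outgroup split of known age.

#' Log transform of F_ST to a divergence scale
#'
#' `T = -ln(1 - F_ST)`, which grows approximately linearly with
#' divergence time. Negative inputs are clipped to 0 (with a flag);
#' `F_ST >= 1` is an error (infinite divergence).
#'
#' @param fst Numeric vector of F_ST values, each `< 1`.
#' @return Tibble with `fst` (as supplied), `T`, `clipped`.
#' @export
#' @examples
#' budowle_transform(c(0, 0.761))
budowle_transform <- function(fst) {
  if (any(!is.finite(fst)) || any(fst >= 1)) {
    abort("`fst` must be finite and < 1 (F_ST = 1 implies infinite divergence).")
  }
  clipped <- fst < 0
  fst_use <- pmax(fst, 0)
  tibble(fst = fst, T = -log(1 - fst_use), clipped = clipped)
}

#' Per-window calibrated divergence ages
#'
#' Scales the focal pair's transformed differentiation by the calibration
#' pair's in each window: `age = calibration_age * T_focal / T_cal`,
#' where `T = -ln(1 - F_ST)` and the calibration pair is assigned a known
#' split age (default 2,000,000 years). Windows with `T_cal = 0` are
#' excluded. The region estimate is the mean of window ages with a
#' bootstrap-over-windows CI.
#'
#' @param focal Tibble of focal-pair window F_ST (needs `chrom`, `start`,
#'   `end`, `estimate`; the output of [fst_windows()] works directly).
#' @param calibration Same-shape tibble for the calibration pair, on the
#'   same windows.
#' @param calibration_age Split age of the calibration pair in years
#'   (default 2e6).
#' @param n_boot Bootstrap replicates over windows (default 10000).
#' @param weight_by_snps If `TRUE`, the region mean weights windows by
#'   their `n_snps` column.
#' @param seed Optional RNG seed.
#' @return Object of class `calibrated_ages`: `windows` tibble (`chrom`,
#'   `start`, `end`, `T_focal`, `T_cal`, `age`), `region` one-row tibble
#'   (`age`, `ci_low`, `ci_high`, `n_windows`, `n_boot`). `tidy()` gives
#'   the windows, `glance()` the region row.
#' @export
window_scaled_ages <- function(focal, calibration, calibration_age = 2e6,
                               n_boot = 10000, weight_by_snps = FALSE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- c("chrom", "start", "end")
  if (!all(key %in% names(focal)) || !all(key %in% names(calibration))) {
    abort("both inputs need chrom/start/end window columns.")
  }
  j <- dplyr::inner_join(
    focal |> select(dplyr::all_of(key), fst_focal = "estimate",
                    dplyr::any_of("n_snps")),
    calibration |> select(dplyr::all_of(key), fst_cal = "estimate"),
    by = key
  )
  if (nrow(j) == 0) abort("focal and calibration windows share no coordinates.")
  j <- j |>
    filter(!is.na(.data$fst_focal), !is.na(.data$fst_cal)) |>
    mutate(
      T_focal = budowle_transform(.data$fst_focal)$T,
      T_cal = budowle_transform(.data$fst_cal)$T
    )
  dropped <- sum(j$T_cal == 0)
  if (dropped > 0) {
    inform(sprintf("%d window(s) excluded (calibration T = 0).", dropped))
  }
  j <- filter(j, .data$T_cal > 0)
  if (nrow(j) == 0) abort("no usable windows (all calibration T = 0).")
  j <- mutate(j, age = calibration_age * .data$T_focal / .data$T_cal)

  w <- if (weight_by_snps && "n_snps" %in% names(j)) j$n_snps else rep(1, nrow(j))
  region_age <- sum(w * j$age) / sum(w)
  boots <- if (n_boot > 0) {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nrow(j), replace = TRUE)
      sum(w[i] * j$age[i]) / sum(w[i])
    }, numeric(1))
  } else {
    numeric(0)
  }

  structure(
    list(
      windows = select(
        j, dplyr::all_of(key), "T_focal", "T_cal", "age"
      ),
      region = tibble(
        age = region_age,
        ci_low = if (n_boot > 0) unname(quantile(boots, 0.025)) else NA_real_,
        ci_high = if (n_boot > 0) unname(quantile(boots, 0.975)) else NA_real_,
        n_windows = nrow(j), n_boot = n_boot,
        calibration_age = calibration_age
      )
    ),
    class = "calibrated_ages"
  )
}

#' @export
print.calibrated_ages <- function(x, ...) {
  cat("Calibrated divergence ages\n")
  print(x$region)
  invisible(x)
}

#' @export
tidy.calibrated_ages <- function(x, ...) x$windows

#' @export
glance.calibrated_ages <- function(x, ...) x$region
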