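# ggplot2 helpers for the main result objects.

#' Plot windowed statistics along the chromosome
#'
#' @param windows A window tibble from [fst_windows()],
#'   [diversity_windows()] or [window_scaled_ages()] output (needs
#'   `start`, `estimate`; ribbons drawn when `ci_low`/`ci_high` exist).
#' @return A ggplot object.
#' @export
plot_windows <- function(windows) {
  p <- ggplot2::ggplot(windows, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$estimate
  ))
  if (all(c("ci_low", "ci_high") %in% names(windows))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(
      x = "position (bp)",
      y = if ("stat" %in% names(windows)) unique(windows$stat)[1] else "estimate"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise linkage disequilibrium
#'
#' @param ld Long pair tibble from [ld_matrix()].
#' @param value Column to display (default `"r2"`).
#' @return A ggplot object.
#' @export
plot_ld_heatmap <- function(ld, value = "r2") {
  sites <- unique(c(ld$site_i, ld$site_j))
  ld2 <- ld |>
    mutate(
      site_i = factor(.data$site_i, levels = sites),
      site_j = factor(.data$site_j, levels = sites)
    )
  ggplot2::ggplot(ld2, ggplot2::aes(
    x = .data$site_i, y = .data$site_j, fill = .data[[value]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.ld_decay_experiment <- function(object, ...) {
  traj <- object$trajectory |>
    select("generation", "D_pooled", "D_female", "D_male") |>
    tidyr::pivot_longer(-"generation", names_to = "pool", values_to = "D") |>
    mutate(pool = stringr::str_remove(.data$pool, "^D_"))
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$generation, y = .data$D, colour = .data$pool
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$D0 / 2, linetype = "dashed") +
    ggplot2::labs(
      x = "generation", y = "D(AB)",
      title = sprintf(
        "LD decay under drive-selection balance (pooled half-life %s generations)",
        object$half_life[["pooled"]]
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.drive_equilibrium <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("trajectory was not recorded; rerun with record = TRUE.")
  }
  traj <- object$trajectory |>
    select("generation",
      ST = "ST_pooled", SR = "SR_pooled", BM = "BM_pooled", T = "T_pooled"
    ) |>
    tidyr::pivot_longer(-"generation", names_to = "type", values_to = "frequency")
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$generation, y = .data$frequency, colour = .data$type
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "pooled X frequency") +
    ggplot2::theme_minimal()
}
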