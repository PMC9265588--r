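# ggplot2 figures for the result types.

#' Plot day/night distributions of a cell measurement
#'
#' Per-animal jittered points with group mean +/- SEM, the layout used to
#' present volume and dry-mass distributions across a cohort.
#'
#' @param records Cell table.
#' @param variable `"volume"` or `"dry_mass"`.
#' @param exclude_damaged Drop damaged cells (default TRUE).
#' @return A ggplot object.
#' @export
plot_group_distributions <- function(records, variable = "volume",
                                     exclude_damaged = TRUE) {
  col <- variable_column(records, variable)
  if (exclude_damaged && "damaged" %in% names(records)) {
    records <- records[!records$damaged, ]
  }
  lab <- switch(col, volume_um3 = "cell volume (µm³)",
                drymass_pg = "dry mass (pg)", col)
  summ <- dplyr::summarise(
    dplyr::group_by(records, .data$group),
    m = mean(.data[[col]]),
    sem = stats::sd(.data[[col]]) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(records, ggplot2::aes(x = .data$group, y = .data[[col]])) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$animal_id),
                         width = 0.15, alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_pointrange(data = summ,
                             ggplot2::aes(x = .data$group, y = .data$m,
                                          ymin = .data$m - .data$sem,
                                          ymax = .data$m + .data$sem),
                             inherit.aes = FALSE, linewidth = 0.8, size = 0.5) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_classic()
}

#' Plot the volume-vs-mass regression per group
#'
#' Scatter of cell volume against dry mass with the per-group least-squares
#' line whose reciprocal slope is the group's mass density.
#'
#' @param records Cell table.
#' @param exclude_damaged Drop damaged cells (default TRUE).
#' @return A ggplot object.
#' @export
plot_mass_volume <- function(records, exclude_damaged = TRUE) {
  if (exclude_damaged && "damaged" %in% names(records)) {
    records <- records[!records$damaged, ]
  }
  ggplot2::ggplot(records, ggplot2::aes(x = .data$drymass_pg,
                                        y = .data$volume_um3,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::labs(x = "dry mass (pg)", y = "volume (µm³)",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot a radial power spectrum table
#'
#' Log-power versus spatial frequency with the diffraction-limit reference
#' line. Pass several spectra bound together with an extra `image` column to
#' overlay them (the DIC-vs-phase contrast QC).
#' @param spectrum Tibble from [radial_power_spectrum()].
#' @export
plot_spectrum <- function(spectrum) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$freq, y = .data$log_power))
  if ("image" %in% names(spectrum)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$image))
  } else {
    p <- p + ggplot2::geom_line()
  }
  dl <- unique(spectrum$diffraction_limit)
  if (length(dl) == 1 && is.finite(dl)) {
    p <- p + ggplot2::geom_vline(xintercept = dl, linetype = "dashed")
  }
  p + ggplot2::labs(x = "spatial frequency (cycles/µm)",
                    y = "log10 power (normalized)") +
    ggplot2::theme_classic()
}
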