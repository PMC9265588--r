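# Synthetic day/night cohorts. The image-level simulator runs every cell
# through the full measurement chain (phantom -> interferograms -> retrieval
# -> integration -> fluorescence-derived traces -> voxelization -> phase
# refinement -> densitometry); the record-level simulator draws measurement
# outcomes directly and is used to calibrate the statistics.

#' Default acquisition configuration for cohort simulations
#'
#' 45 x 45 x 27 um fields at (0.375, 0.375, 1.0) um voxels, so the 0.375 um
#' shear is exactly one pixel.
#' @param seed Integer seed.
#' @export
cohort_config <- function(seed = 1L) {
  acquisition_config(voxel_um = c(0.375, 0.375, 1.0), shear_um = 0.375,
                     seed = seed)
}

#' Simulate a day/night cohort through the full imaging pipeline
#'
#' One tomogram per animal, `cells_per_animal` soma-like cells each. Night
#' cells are generated with their volumes scaled by `volume_scale_night`
#' at constant expected dry mass (contrast scales reciprocally). Biological
#' variability is log-normal, with independent animal-level and cell-level
#' factors for volume and for mass. Every tomogram is rendered to four-frame
#' interferograms, reconstructed, segmented from the fluorescence-like
#' channel, and quantified; the result is a cell table ready for
#' [compare_groups()].
#'
#' @param n_animals Animals per group (default 9).
#' @param cells_per_animal Cells per animal (default 7).
#' @param volume_scale_night Night/day volume ratio injected (default 0.75).
#' @param mean_radius Day-group mean cell radius in um (default 3.5).
#' @param delta_n Day-group peak refractive contrast (default 0.02).
#' @param sd_log_volume_cell,sd_log_volume_animal Log-scale sd of the
#'   cell-level (0.20) and animal-level (0.08) volume factors.
#' @param sd_log_mass_cell,sd_log_mass_animal Log-scale sd of the cell-level
#'   (0.20) and animal-level (0.08) mass factors.
#' @param shape Tomogram grid `(ny, nx, nz)` (default `c(120, 120, 27)`).
#' @param config Acquisition configuration (default [cohort_config()]).
#' @param noise_sd Interferogram read noise (default 0.05 on a base
#'   intensity of 10).
#' @param alpha Refractive-index increment, mL/g (default 0.2).
#' @param seed Integer seed.
#' @return Tibble of cell records (see [build_cell_table()]) with attribute
#'   `truth`: per-animal ground-truth tables and the injected scaling.
#' @export
simulate_cohort <- function(n_animals = 9, cells_per_animal = 7,
                            volume_scale_night = 0.75,
                            mean_radius = 3.5, delta_n = 0.02,
                            sd_log_volume_cell = 0.20, sd_log_volume_animal = 0.08,
                            sd_log_mass_cell = 0.20, sd_log_mass_animal = 0.08,
                            shape = c(120, 120, 27),
                            config = cohort_config(),
                            noise_sd = 0.05, alpha = 0.2, seed = 1L) {
  config <- as_glim_config(config)
  tabs <- list()
  truth <- list()
  k <- 0L
  for (grp in c("day", "night")) {
    vscale <- if (grp == "night") volume_scale_night else 1
    for (a in seq_len(n_animals)) {
      k <- k + 1L
      sd_a <- child_seed(seed, k)
      animal <- sprintf("%s_%02d", grp, a)
      fac <- with_seed(sd_a, list(
        av = exp(stats::rnorm(1, 0, sd_log_volume_animal)),
        am = exp(stats::rnorm(1, 0, sd_log_mass_animal)),
        cv = exp(stats::rnorm(cells_per_animal, 0, sd_log_volume_cell)),
        cm = exp(stats::rnorm(cells_per_animal, 0, sd_log_mass_cell))
      ))
      volfac <- vscale * fac$av * fac$cv
      radius <- mean_radius * volfac^(1 / 3)
      dn <- delta_n * fac$am * fac$cm / volfac

      # rejection-sampled placement can fail for unlucky draws; re-seed and
      # retry a few times rather than aborting a whole cohort
      ph <- NULL
      for (attempt in 1:4) {
        ph <- tryCatch(
          make_phantom(shape, n_cells = cells_per_animal, radius = radius,
                       delta_n = dn, config = config, alpha = alpha,
                       seed = child_seed(sd_a, attempt)),
          error = function(e) NULL)
        if (!is.null(ph)) break
      }
      if (is.null(ph)) {
        stop(sprintf("could not place %d cells for animal %s after 4 attempts",
                     cells_per_animal, animal), call. = FALSE)
      }
      phase0 <- project_phase(ph)
      stk <- simulate_interferograms(phase0, config = config,
                                     noise_sd = noise_sd,
                                     seed = child_seed(sd_a, 2))
      grad <- retrieve_phase_gradient(stk)
      phase <- integrate_gradient_hilbert(grad)
      fl <- fluorescence_channel(ph, seed = child_seed(sd_a, 3))
      traces <- suppressMessages(traces_from_fluorescence(fl))
      if (!length(traces)) next
      masks <- segment_cells(traces, phase)
      ids <- vapply(masks, function(m) as.character(m$cell_id), character(1))
      groups <- tibble::tibble(cell_id = ids, animal_id = animal, group = grp)
      tab <- suppressMessages(
        build_cell_table(masks, phase, groups, alpha = alpha, config = config)
      )
      tab$cell_id <- paste(animal, tab$cell_id, sep = "_")
      tabs[[k]] <- tab
      truth[[k]] <- dplyr::mutate(ph$cell_truth, animal_id = animal, group = grp)
    }
  }
  out <- dplyr::bind_rows(tabs)
  attr(out, "truth") <- list(cells = dplyr::bind_rows(truth),
                             volume_scale_night = volume_scale_night)
  out
}

#' Simulate a cohort at the record level
#'
#' Draws per-cell volume and dry mass directly from the cohort's log-normal
#' biological model, bypassing image formation. Used to calibrate the group
#' statistics (type-I error, power) where thousands of model fits are needed.
#'
#' @inheritParams simulate_cohort
#' @param mean_volume Day-group mean volume, um^3 (default 180, a soma of
#'   radius 3.5 um).
#' @param mean_mass Mean dry mass, pg (default 30).
#' @param mass_scale_night Night/day mass ratio (default 1: volume regulation
#'   at constant dry mass).
#' @return Tibble with `cell_id`, `animal_id`, `group`, `volume_um3`,
#'   `drymass_pg`, `damaged`.
#' @export
simulate_cohort_records <- function(n_animals = 9, cells_per_animal = 7,
                                    volume_scale_night = 0.75,
                                    mass_scale_night = 1,
                                    mean_volume = 180, mean_mass = 30,
                                    sd_log_volume_cell = 0.20,
                                    sd_log_volume_animal = 0.08,
                                    sd_log_mass_cell = 0.20,
                                    sd_log_mass_animal = 0.08,
                                    seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (grp in c("day", "night")) {
      vs <- if (grp == "night") volume_scale_night else 1
      ms <- if (grp == "night") mass_scale_night else 1
      for (a in seq_len(n_animals)) {
        av <- exp(stats::rnorm(1, 0, sd_log_volume_animal))
        am <- exp(stats::rnorm(1, 0, sd_log_mass_animal))
        n <- cells_per_animal
        vol <- mean_volume * vs * av * exp(stats::rnorm(n, 0, sd_log_volume_cell))
        mass <- mean_mass * ms * am * exp(stats::rnorm(n, 0, sd_log_mass_cell))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell_id = sprintf("%s_%02d_%d", grp, a, seq_len(n)),
          animal_id = sprintf("%s_%02d", grp, a),
          group = grp, volume_um3 = vol, drymass_pg = mass,
          density_g_per_L = mass / vol * PG_PER_UM3_TO_G_PER_L,
          damaged = FALSE
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
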