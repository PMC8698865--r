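#' Enumerate the factorial aquarium design
#'
#' Builds the sampling layout of a two-species x two-temperature heat-wave
#' mesocosm experiment. The default arguments reproduce the 28-aquarium
#' design used for native vs invasive clams: per species, 4 aquaria are
#' destructively sampled at day 6 (before the temperature rise), 4 aquaria
#' per species x treatment run to day 12, and 4 animal-free aquaria serve as
#' procedural control (kept at constant temperature to the end).
#'
#' Stocking density differs between species so that total biomass per
#' aquarium is comparable; the defaults (3 native, 4 invasive individuals
#' per aquarium) give day-6 totals of 12 and 16 and day-12 totals of 24 and
#' 32 individuals.
#'
#' @param species_levels Character vector of two species labels,
#'   `c(native, invasive)`.
#' @param treatment_levels Character vector of temperature treatments;
#'   default `c("CT", "HW")` (constant temperature, heat wave).
#' @param sampling_days Integer vector of destructive sampling days.
#' @param aquaria_per_cell_d6 Aquaria per species sampled on the first day.
#' @param aquaria_per_cell_d12 Aquaria per species x treatment cell run to
#'   the final day.
#' @param control_aquaria Number of animal-free procedural-control aquaria.
#' @param individuals_per_aquarium Named integer vector of stocking density
#'   per species (names must match `species_levels`).
#'
#' @return A tibble with one row per aquarium: `aquarium_id`, `role`
#'   (`"experimental"` or `"procedural_control"`), `species` (`NA` for
#'   controls), `treatment` (`NA` for aquaria sampled before the
#'   temperature rise; controls are `"CT"`), `sampling_day`, and
#'   `n_individuals`.
#' @examples
#' design <- build_design()
#' nrow(design)                     # 28 aquaria
#' sum(design$n_individuals)        # 28 + 56 individuals
#' @export
build_design <- function(species_levels = c("native", "invasive"),
                         treatment_levels = c("CT", "HW"),
                         sampling_days = c(6L, 12L),
                         aquaria_per_cell_d6 = 4L,
                         aquaria_per_cell_d12 = 4L,
                         control_aquaria = 4L,
                         individuals_per_aquarium = c(native = 3L, invasive = 4L)) {
  if (length(species_levels) < 1L || anyDuplicated(species_levels) > 0L) {
    stop("`species_levels` must be distinct labels", call. = FALSE)
  }
  if (length(treatment_levels) < 1L) {
    stop("`treatment_levels` must contain at least one treatment", call. = FALSE)
  }
  counts <- c(aquaria_per_cell_d6 = aquaria_per_cell_d6,
              aquaria_per_cell_d12 = aquaria_per_cell_d12)
  if (any(counts <= 0) || any(counts != as.integer(counts))) {
    stop("aquaria counts must be positive integers", call. = FALSE)
  }
  if (control_aquaria < 0) {
    stop("`control_aquaria` must be non-negative", call. = FALSE)
  }
  if (!all(species_levels %in% names(individuals_per_aquarium))) {
    stop("`individuals_per_aquarium` must be named for every species", call. = FALSE)
  }
  if (any(individuals_per_aquarium[species_levels] <= 0)) {
    stop("stocking densities must be positive", call. = FALSE)
  }
  if (length(sampling_days) != 2L) {
    stop("`sampling_days` must give a baseline day and a final day", call. = FALSE)
  }

  d6 <- tidyr::expand_grid(species = species_levels,
                           replicate = seq_len(aquaria_per_cell_d6)) |>
    dplyr::mutate(role = "experimental",
                  treatment = NA_character_,
                  sampling_day = sampling_days[1])
  d12 <- tidyr::expand_grid(species = species_levels,
                            treatment = treatment_levels,
                            replicate = seq_len(aquaria_per_cell_d12)) |>
    dplyr::mutate(role = "experimental", sampling_day = sampling_days[2])
  ctrl <- tibble::tibble(species = NA_character_,
                         treatment = "CT",
                         replicate = seq_len(control_aquaria),
                         role = "procedural_control",
                         sampling_day = sampling_days[2])

  design <- dplyr::bind_rows(d6, d12, ctrl) |>
    dplyr::mutate(
      aquarium_id = sprintf("A%02d", dplyr::row_number()),
      n_individuals = ifelse(.data$role == "experimental",
                             individuals_per_aquarium[.data$species], 0L)
    ) |>
    dplyr::select("aquarium_id", "role", "species", "treatment",
                  "sampling_day", "n_individuals")
  design
}

#' Expand a design to one row per stocked individual
#'
#' @param design A design tibble from [build_design()].
#' @return A tibble with `aquarium_id`, `species`, `treatment`,
#'   `sampling_day`, and a unique `individual_id` per animal; control
#'   aquaria (no animals) contribute no rows.
#' @examples
#' ind <- enumerate_individuals(build_design())
#' table(ind$species, ind$sampling_day)
#' @export
enumerate_individuals <- function(design) {
  stopifnot(is.data.frame(design), all(c("aquarium_id", "n_individuals") %in% names(design)))
  design |>
    dplyr::filter(.data$n_individuals > 0L) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      aquarium_id = .data$aquarium_id,
      species = .data$species,
      treatment = .data$treatment,
      sampling_day = .data$sampling_day,
      individual_id = sprintf("%s_i%d", .data$aquarium_id, seq_len(.data$n_individuals))
    )
}

#' Drop procedural-control aquaria from a table
#'
#' Ecological-response models contrast the two species, so animal-free
#' procedural controls are excluded before fitting.
#'
#' @param data A tibble with a `role` or `species` column.
#' @return The tibble without procedural-control rows.
#' @export
drop_procedural_controls <- function(data) {
  if ("role" %in% names(data)) {
    dplyr::filter(data, .data$role != "procedural_control")
  } else {
    dplyr::filter(data, !is.na(.data$species))
  }
}
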