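#' Day-6 baseline means per species and biomarker
#'
#' The reference level for all percent-change normalization: the arithmetic
#' mean of the raw day-6 values of each biomarker within each species.
#'
#' @param panel Long biomarker panel (columns `species`, `day`,
#'   `biomarker`, `value`).
#' @param baseline_day Day used as baseline (default 6).
#' @return A tibble with `species`, `biomarker`, `baseline_mean`, `n_d6`.
#' @export
baseline_means <- function(panel, baseline_day = 6) {
  d6 <- dplyr::filter(panel, .data$day == baseline_day)
  if (nrow(d6) == 0L) {
    stop("panel contains no baseline (day ", baseline_day, ") records", call. = FALSE)
  }
  d6 |>
    dplyr::group_by(.data$species, .data$biomarker) |>
    dplyr::summarise(baseline_mean = mean(.data$value), n_d6 = dplyr::n(),
                     .groups = "drop")
}

#' Baseline mean for one species x biomarker
#'
#' @inheritParams baseline_means
#' @param species,biomarker Labels selecting the cell.
#' @return A single numeric baseline mean.
#' @examples
#' panel <- tibble::tibble(species = "native", day = 6,
#'                         biomarker = "CAT", value = c(1, 2, 3))
#' baseline_mean(panel, "native", "CAT")
#' @export
baseline_mean <- function(panel, species, biomarker, baseline_day = 6) {
  rows <- panel$day == baseline_day & panel$species == species &
    panel$biomarker == biomarker
  if (!any(rows)) {
    stop("no day-", baseline_day, " records for ", species, "/", biomarker,
         call. = FALSE)
  }
  mean(panel$value[rows])
}

#' Energy available
#'
#' Sum of the three energy reserve fractions, all expressed in a common
#' energy unit.
#'
#' @param protein,carbohydrate,lipid Non-negative reserve contents.
#' @return `protein + carbohydrate + lipid` (vectorized).
#' @examples
#' energy_available(1, 1, 1)
#' @export
energy_available <- function(protein, carbohydrate, lipid) {
  if (any(c(protein, carbohydrate, lipid) < 0, na.rm = TRUE)) {
    stop("energy reserve fractions must be non-negative", call. = FALSE)
  }
  protein + carbohydrate + lipid
}

#' Cellular energy allocation
#'
#' The ratio of energy available (`Ea`, summed reserves) to energy
#' consumption (`Ec`, electron transport system activity), a proxy for the
#' organism's net cellular energy budget.
#'
#' @param ea Energy available, `>= 0`.
#' @param ec Energy consumption, `> 0`.
#' @return `ea / ec` (vectorized).
#' @examples
#' cea(3, 1)
#' @export
cea <- function(ea, ec) {
  if (any(ea < 0, na.rm = TRUE)) stop("`ea` must be non-negative", call. = FALSE)
  if (any(ec <= 0, na.rm = TRUE)) stop("`ec` must be strictly positive", call. = FALSE)
  ea / ec
}

#' Append derived energy-budget biomarkers to a panel
#'
#' Computes, for every individual at every day, the energy available
#' (`Ea = protein + carbohydrate + lipid`) and the cellular energy
#' allocation (`CEA = Ea / ETS`), and appends them to the panel as derived
#' biomarker rows. Deriving them per individual (before any averaging)
#' lets them flow through percent-change normalization and the IBR index
#' exactly like assayed biomarkers.
#'
#' @param panel Long biomarker panel containing `protein`, `carbohydrate`,
#'   `lipid` and `ETS` rows per individual.
#' @return The panel with additional `Ea` and `CEA` rows (unit
#'   `"derived"`).
#' @export
add_energy_budget <- function(panel) {
  have <- unique(panel$biomarker)
  need <- c("protein", "carbohydrate", "lipid", "ETS")
  if (!all(need %in% have)) {
    stop("panel lacks required biomarkers: ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  keys <- intersect(c("aquarium_id", "species", "treatment", "day", "individual_id"),
                    names(panel))
  wide <- panel |>
    dplyr::filter(.data$biomarker %in% need) |>
    dplyr::select(dplyr::all_of(keys), "biomarker", "value") |>
    tidyr::pivot_wider(names_from = "biomarker", values_from = "value")
  if (anyNA(wide[need])) {
    stop("some individuals are missing reserve or ETS measurements", call. = FALSE)
  }
  derived <- wide |>
    dplyr::mutate(Ea = energy_available(.data$protein, .data$carbohydrate, .data$lipid),
                  CEA = cea(.data$Ea, .data$ETS)) |>
    dplyr::select(dplyr::all_of(keys), "Ea", "CEA") |>
    tidyr::pivot_longer(c("Ea", "CEA"), names_to = "biomarker",
                        values_to = "value") |>
    dplyr::mutate(unit = "derived")
  dplyr::bind_rows(panel, derived)
}

#' Baseline percent-change normalization
#'
#' Expresses each final-day raw biomarker value as a percent change
#' relative to the mean day-6 value of the same biomarker within the same
#' species: `Bn = (B_D12 - mean(B_D6)) / mean(B_D6) * 100`. This puts both
#' species on a common, unit-free response scale.
#'
#' @param panel Long biomarker panel with day-6 and final-day rows.
#' @param baseline_day Baseline day (default 6).
#' @return A tibble of final-day rows with `value_pct` (the normalized
#'   percent change) replacing the raw value.
#' @examples
#' panel <- tibble::tibble(
#'   species = "native", treatment = c(NA, "HW"), day = c(6, 12),
#'   individual_id = c("a", "b"), biomarker = "CAT", value = c(2, 3))
#' normalize_biomarkers(panel)$value_pct  # +50
#' @export
normalize_biomarkers <- function(panel, baseline_day = 6) {
  bl <- baseline_means(panel, baseline_day)
  bad <- dplyr::filter(bl, .data$baseline_mean == 0)
  if (nrow(bad) > 0L) {
    stop("zero day-", baseline_day, " baseline for ",
         paste(bad$biomarker, bad$species, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  final_day <- max(panel$day)
  panel |>
    dplyr::filter(.data$day == final_day) |>
    dplyr::inner_join(dplyr::select(bl, "species", "biomarker", "baseline_mean"),
                      by = c("species", "biomarker")) |>
    dplyr::mutate(value_pct = (.data$value - .data$baseline_mean) /
                    .data$baseline_mean * 100) |>
    dplyr::select(-"value", -"baseline_mean")
}

#' Group summaries of normalized biomarker changes
#'
#' Mean percent change per species x treatment x biomarker, with two
#' standard errors: `se_naive`, the dispersion of the final-day individuals
#' alone (the conventional reported SE), and `se_change`, which also
#' propagates the sampling error of the estimated day-6 baseline mean by
#' the delta method. Because every normalized value shares the same
#' estimated baseline, `se_naive` understates the uncertainty of the mean
#' change; confidence intervals here use `se_change` with a t quantile on
#' `min(n_d6, n_d12) - 1` degrees of freedom.
#'
#' @param panel Long raw biomarker panel (both days).
#' @param baseline_day Baseline day (default 6).
#' @param conf_level Confidence level for the interval.
#' @return A tibble with `species`, `treatment`, `biomarker`, `n_d6`,
#'   `n_d12`, `mean_change`, `se_naive`, `se_change`, `ci_lower`,
#'   `ci_upper`.
#' @export
change_summary <- function(panel, baseline_day = 6, conf_level = 0.95) {
  bl <- baseline_means(panel, baseline_day)
  d6_stats <- panel |>
    dplyr::filter(.data$day == baseline_day) |>
    dplyr::group_by(.data$species, .data$biomarker) |>
    dplyr::summarise(m6 = mean(.data$value), s6 = stats::sd(.data$value),
                     n6 = dplyr::n(), .groups = "drop")
  final_day <- max(panel$day)
  alpha <- 1 - conf_level
  panel |>
    dplyr::filter(.data$day == final_day) |>
    dplyr::group_by(.data$species, .data$treatment, .data$biomarker) |>
    dplyr::summarise(m12 = mean(.data$value), s12 = stats::sd(.data$value),
                     n12 = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(d6_stats, by = c("species", "biomarker")) |>
    dplyr::mutate(
      mean_change = 100 * (.data$m12 / .data$m6 - 1),
      se_naive = 100 * .data$s12 / (.data$m6 * sqrt(.data$n12)),
      se_change = sqrt((100 / .data$m6)^2 * .data$s12^2 / .data$n12 +
                         (100 * .data$m12 / .data$m6^2)^2 * .data$s6^2 / .data$n6),
      df = pmin(.data$n6, .data$n12) - 1,
      ci_lower = .data$mean_change - stats::qt(1 - alpha / 2, .data$df) * .data$se_change,
      ci_upper = .data$mean_change + stats::qt(1 - alpha / 2, .data$df) * .data$se_change
    ) |>
    dplyr::select("species", "treatment", "biomarker", n_d6 = "n6", n_d12 = "n12",
                  "mean_change", "se_naive", "se_change", "ci_lower", "ci_upper")
}
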