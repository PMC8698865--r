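#' Physicochemical conditions of the reference experiment
#'
#' The published per-cell water-quality summaries (mean and standard error
#' of salinity, temperature, pH and dissolved oxygen) recorded before and
#' after the heaters were switched on at day 6. These printed values are
#' the only physicochemical record available for the reference experiment
#' and serve as inputs for checks on the realised thermal contrast.
#'
#' @return A tibble with columns `period` (`"before_d6"` / `"after_d6"`),
#'   `group` (species:treatment cell or `"control"`), `treatment`,
#'   `salinity`, `temperature_c`, `ph`, `dissolved_o2` and their standard
#'   errors (`*_se`).
#' @examples
#' experiment_conditions()
#' @export
experiment_conditions <- function() {
  tibble::tribble(
    ~period,     ~group,          ~treatment, ~salinity, ~salinity_se, ~temperature_c, ~temperature_c_se, ~ph,  ~ph_se, ~dissolved_o2, ~dissolved_o2_se,
    "before_d6", "control",       "CT",       28.14,     0.02,         17.31,          0.07,              8.08, 0.04,   9.43,          0.08,
    "before_d6", "native:CT",     "CT",       28.19,     0.02,         17.41,          0.04,              8.06, 0.03,   9.27,          0.06,
    "before_d6", "native:HW",     "HW",       28.18,     0.03,         17.42,          0.06,              8.07, 0.06,   9.42,          0.05,
    "before_d6", "invasive:CT",   "CT",       28.17,     0.01,         17.23,          0.04,              8.08, 0.02,   9.37,          0.05,
    "before_d6", "invasive:HW",   "HW",       28.19,     0.03,         17.29,          0.06,              8.10, 0.03,   9.46,          0.05,
    "after_d6",  "control",       "CT",       28.41,     0.06,         18.18,          0.10,              8.32, 0.01,   9.41,          0.03,
    "after_d6",  "native:CT",     "CT",       28.53,     0.03,         18.15,          0.09,              8.29, 0.02,   9.39,          0.07,
    "after_d6",  "native:HW",     "HW",       28.70,     0.09,         21.90,          0.19,              8.27, 0.04,   8.64,          0.14,
    "after_d6",  "invasive:CT",   "CT",       28.35,     0.04,         18.03,          0.08,              8.24, 0.01,   9.27,          0.09,
    "after_d6",  "invasive:HW",   "HW",       28.71,     0.13,         22.35,          0.20,              8.24, 0.02,   8.27,          0.13
  )
}

#' Pooled water temperature per treatment
#'
#' Averages the per-cell mean temperatures over all aquaria groups held at
#' each treatment within a period. Procedural-control aquaria were kept at
#' constant temperature, so they pool with the CT cells. After day 6 the
#' realised heat-wave contrast must exceed the nominal 4.5 degree step
#' minus room-heating spillover onto CT aquaria; the pooled post-day-6
#' difference here is just over 4 degrees C.
#'
#' @param conditions Conditions tibble, by default [experiment_conditions()].
#' @param period Which period to pool, `"after_d6"` (default) or
#'   `"before_d6"`.
#' @return A tibble with `treatment` and pooled `temperature_c`.
#' @examples
#' pooled_temperature()
#' @export
pooled_temperature <- function(conditions = experiment_conditions(),
                               period = "after_d6") {
  conditions |>
    dplyr::filter(.data$period == !!period) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(temperature_c = mean(.data$temperature_c), .groups = "drop")
}
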