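#' Log ratio of final-day biomarker values to their baseline mean
#'
#' First step of the integrated biological response (IBRv2) calculation:
#' each individual final-day value is log-transformed relative to the
#' species' day-6 baseline mean, `Y = log(B_D12 / mean(B_D6))`, damping the
#' influence of extreme raw values.
#'
#' @param panel Long raw biomarker panel (both days).
#' @param biomarkers Character vector of biomarkers to include.
#' @param log_base Base of the logarithm (default 10).
#' @param baseline_day Baseline day (default 6).
#' @return A tibble of final-day rows with columns `individual_id`,
#'   `species`, `treatment`, `biomarker`, `Y`.
#' @export
ibr_log_ratio <- function(panel, biomarkers = unique(panel$biomarker),
                          log_base = 10, baseline_day = 6) {
  sub <- dplyr::filter(panel, .data$biomarker %in% biomarkers)
  missing <- setdiff(biomarkers, unique(sub$biomarker))
  if (length(missing) > 0L) {
    stop("biomarkers absent from panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  final_day <- max(sub$day)
  d12 <- dplyr::filter(sub, .data$day == final_day)
  if (any(d12$value <= 0)) {
    bad <- d12[d12$value <= 0, ][1, ]
    stop("non-positive biomarker value for individual ", bad$individual_id,
         ", biomarker ", bad$biomarker, "; log ratio undefined", call. = FALSE)
  }
  bl <- baseline_means(sub, baseline_day)
  if (any(bl$baseline_mean <= 0)) {
    stop("non-positive baseline mean; log ratio undefined", call. = FALSE)
  }
  d12 |>
    dplyr::inner_join(dplyr::select(bl, "species", "biomarker", "baseline_mean"),
                      by = c("species", "biomarker")) |>
    dplyr::mutate(Y = log(.data$value / .data$baseline_mean, base = log_base)) |>
    dplyr::select("individual_id", "species", "treatment", "biomarker", "Y")
}

#' Standardize log ratios within condition cells
#'
#' Second IBRv2 step: within each biomarker x grouping cell, centre and
#' scale the log ratios, `Z = (Y - mu) / s`, with `mu` the cell mean and
#' `s` the sample (n-1) standard deviation. The default grouping is
#' species x treatment (each experimental condition standardized on its
#' own spread); `grouping = "species"` pools treatments instead.
#'
#' Cells with zero variance cannot be standardized; with
#' `zero_variance_guard = TRUE` (default) their deviation contribution is
#' later set to zero with a warning rather than failing the run.
#'
#' @param y_tbl Output of [ibr_log_ratio()].
#' @param grouping `"species_treatment"` (default) or `"species"`.
#' @param zero_variance_guard Logical; zero-spread cells contribute 0
#'   instead of erroring.
#' @return `y_tbl` with added `mu`, `s`, `Z`, and logical `zero_var`.
#' @export
ibr_standardize <- function(y_tbl, grouping = c("species_treatment", "species"),
                            zero_variance_guard = TRUE) {
  grouping <- match.arg(grouping)
  group_vars <- c("biomarker", "species",
                  if (grouping == "species_treatment") "treatment")
  out <- y_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::mutate(mu = mean(.data$Y), s = stats::sd(.data$Y),
                  n_cell = dplyr::n()) |>
    dplyr::ungroup()
  if (any(out$n_cell < 2L)) {
    stop("standardization requires at least 2 individuals per cell", call. = FALSE)
  }
  out <- dplyr::mutate(out, zero_var = .data$s == 0,
                       Z = ifelse(.data$zero_var, NA_real_,
                                  (.data$Y - .data$mu) / .data$s))
  if (any(out$zero_var)) {
    if (!zero_variance_guard) {
      stop("zero variance in a biomarker cell; enable `zero_variance_guard` ",
           "to let it contribute 0", call. = FALSE)
    }
    warning("zero-variance biomarker cell(s): deviation contribution set to 0")
  }
  dplyr::select(out, -"n_cell")
}

#' Day-6 reference term of the deviation index
#'
#' Third IBRv2 step: the baseline individuals are expressed on the same
#' log-ratio scale, `Y_D6 = log(B_D6 / mean(B_D6))`, and the reference term
#' is their per-species mean, `Z_D6 = mean(Y_D6)` (taken literally as the
#' mean log ratio, without further standardization). By Jensen's
#' inequality this term is non-positive and shrinks toward 0 as baseline
#' spread shrinks; unlike the standardized `Z`, it depends on the log base.
#'
#' @inheritParams ibr_log_ratio
#' @return A tibble with `species`, `biomarker`, `z_d6`, `n_d6`.
#' @export
ibr_baseline_term <- function(panel, biomarkers = unique(panel$biomarker),
                              log_base = 10, baseline_day = 6) {
  d6 <- dplyr::filter(panel, .data$biomarker %in% biomarkers,
                      .data$day == baseline_day)
  if (nrow(d6) == 0L) stop("no baseline records", call. = FALSE)
  if (any(d6$value <= 0)) {
    stop("non-positive baseline biomarker value; log ratio undefined", call. = FALSE)
  }
  d6 |>
    dplyr::group_by(.data$species, .data$biomarker) |>
    dplyr::summarise(
      z_d6 = mean(log(.data$value / mean(.data$value), base = log_base)),
      n_d6 = dplyr::n(), .groups = "drop"
    )
}

#' Per-biomarker deviation index
#'
#' Fourth IBRv2 step: the deviation of each exposed individual from the
#' baseline condition, `A = Z_D12 - Z_D6`. A positive mean deviation
#' indicates induction of the biomarker relative to baseline, a negative
#' one inhibition. Zero-variance cells flagged upstream contribute 0.
#'
#' @param z_tbl Output of [ibr_standardize()].
#' @param baseline_tbl Output of [ibr_baseline_term()].
#' @return `z_tbl` with added `z_d6` and `A`.
#' @export
ibr_deviation <- function(z_tbl, baseline_tbl) {
  if (!setequal(unique(z_tbl$biomarker), unique(baseline_tbl$biomarker))) {
    stop("biomarker sets of exposed and baseline tables do not match", call. = FALSE)
  }
  out <- dplyr::inner_join(z_tbl,
                           dplyr::select(baseline_tbl, "species", "biomarker", "z_d6"),
                           by = c("species", "biomarker"))
  if (nrow(out) != nrow(z_tbl)) {
    stop("baseline term missing for some species x biomarker cells", call. = FALSE)
  }
  dplyr::mutate(out, A = ifelse(.data$zero_var, 0, .data$Z - .data$z_d6))
}

#' Integrated biological response index, version 2
#'
#' Computes the IBRv2 index per individual as the sum over the selected
#' biomarkers of the absolute deviation indexes, `IBRv2 = sum_b |A_b|`,
#' after log-ratio transformation, within-condition standardization and
#' subtraction of the day-6 reference term. Group summaries (mean +/- SE
#' over individuals per species x treatment) are attached.
#'
#' If derived biomarkers (`CEA`, `Ea`) are requested but absent, they are
#' first appended with [add_energy_budget()].
#'
#' @param panel Long raw biomarker panel with baseline and final-day rows.
#' @param biomarkers Biomarkers to integrate; the default is the
#'   seven-axis oxidative stress / metabolism / energy panel.
#' @param log_base Logarithm base (default 10; affects only the day-6
#'   reference term, the standardized `Z` being base-invariant).
#' @param grouping Standardization grouping, see [ibr_standardize()].
#' @param zero_variance_guard See [ibr_standardize()].
#' @param baseline_day Baseline day (default 6).
#' @return An object of class `ibr_result`: list with `components`
#'   (per-individual Y, Z, A per biomarker), `baseline` (day-6 reference
#'   terms), `individual` (per-individual IBRv2), `summary` (group mean,
#'   SE, n), and the settings used.
#' @examples
#' panel <- sample_biomarkers(build_design(), seed = 1)
#' res <- ibr_v2(panel)
#' res$summary
#' @export
ibr_v2 <- function(panel,
                   biomarkers = c("SOD", "CAT", "DNAd", "LPO", "IDH", "LDH", "CEA"),
                   log_base = 10,
                   grouping = c("species_treatment", "species"),
                   zero_variance_guard = TRUE,
                   baseline_day = 6) {
  grouping <- match.arg(grouping)
  if (length(biomarkers) == 0L) {
    stop("at least one biomarker is required", call. = FALSE)
  }
  derived <- intersect(c("CEA", "Ea"), setdiff(biomarkers, unique(panel$biomarker)))
  if (length(derived) > 0L) panel <- add_energy_budget(panel)

  y_tbl <- ibr_log_ratio(panel, biomarkers, log_base, baseline_day)
  z_tbl <- ibr_standardize(y_tbl, grouping, zero_variance_guard)
  baseline <- ibr_baseline_term(panel, biomarkers, log_base, baseline_day)
  comp <- ibr_deviation(z_tbl, baseline)

  individual <- comp |>
    dplyr::group_by(.data$individual_id, .data$species, .data$treatment) |>
    dplyr::summarise(n_biomarkers = dplyr::n(), ibr = sum(abs(.data$A)),
                     .groups = "drop")
  if (any(individual$n_biomarkers != length(biomarkers))) {
    stop("some individuals lack values for part of the biomarker set", call. = FALSE)
  }
  summary_tbl <- individual |>
    dplyr::group_by(.data$species, .data$treatment) |>
    dplyr::summarise(n = dplyr::n(), mean_ibr = mean(.data$ibr),
                     se_ibr = stats::sd(.data$ibr) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(components = comp, baseline = baseline,
                 individual = individual, summary = summary_tbl,
                 biomarkers = biomarkers, log_base = log_base,
                 grouping = grouping),
            class = "ibr_result")
}

#' @export
print.ibr_result <- function(x, ...) {
  cat("IBRv2 over", length(x$biomarkers), "biomarkers (log base",
      x$log_base, ", grouping:", x$grouping, ")\n")
  print(x$summary)
  invisible(x)
}

#' Tidy an IBRv2 result into its per-individual components
#'
#' @param x An `ibr_result`.
#' @param ... Unused.
#' @return The components tibble (per individual x biomarker log ratio,
#'   standardized value and deviation index).
#' @importFrom generics tidy
#' @export
tidy.ibr_result <- function(x, ...) x$components

#' One-row summary of an IBRv2 result
#'
#' @param x An `ibr_result`.
#' @param ... Unused.
#' @return One-row tibble with counts, settings and overall mean index.
#' @importFrom generics glance
#' @export
glance.ibr_result <- function(x, ...) {
  tibble::tibble(n_individuals = nrow(x$individual),
                 n_biomarkers = length(x$biomarkers),
                 log_base = x$log_base, grouping = x$grouping,
                 mean_ibr = mean(x$individual$ibr))
}

#' Star-plot data: mean biomarker deviations per condition
#'
#' Aggregates the per-individual deviation indexes to the mean deviation
#' per biomarker within each species x treatment, on a fixed, documented
#' axis order, ready for radar ("star") plotting.
#'
#' @param x An `ibr_result`.
#' @param axis_order Biomarker axis order; defaults to the order the index
#'   was computed with.
#' @return A tibble with `species`, `treatment`, `biomarker` (factor with
#'   the axis order), `mean_A`.
#' @export
star_plot_data <- function(x, axis_order = x$biomarkers) {
  stopifnot(inherits(x, "ibr_result"))
  if (!setequal(axis_order, x$biomarkers)) {
    stop("`axis_order` must be a permutation of the computed biomarkers",
         call. = FALSE)
  }
  x$components |>
    dplyr::group_by(.data$species, .data$treatment, .data$biomarker) |>
    dplyr::summarise(mean_A = mean(.data$A), .groups = "drop") |>
    dplyr::mutate(biomarker = factor(.data$biomarker, levels = axis_order)) |>
    dplyr::arrange(.data$species, .data$treatment, .data$biomarker)
}

#' Star (radar) plot of biomarker deviation indexes
#'
#' Draws, per species, a closed polygon of the mean deviation index of
#' each biomarker under each temperature treatment: the biomarker-level
#' decomposition of the IBRv2 index, with induction pointing outward and
#' inhibition inward from the zero ring.
#'
#' @param object An `ibr_result`.
#' @param ... Passed to [star_plot_data()].
#' @return A ggplot object.
#' @export
autoplot.ibr_result <- function(object, ...) {
  dat <- star_plot_data(object, ...)
  closed <- dat |>
    dplyr::mutate(axis = as.integer(.data$biomarker)) |>
    dplyr::bind_rows(dat |>
                       dplyr::filter(as.integer(.data$biomarker) == 1L) |>
                       dplyr::mutate(axis = length(levels(dat$biomarker)) + 1L))
  ggplot2::ggplot(closed, ggplot2::aes(x = .data$axis, y = .data$mean_A,
                                       colour = .data$treatment,
                                       group = .data$treatment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(breaks = seq_along(levels(dat$biomarker)),
                                labels = levels(dat$biomarker)) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "mean deviation index A",
                  colour = "treatment") +
    ggplot2::theme_minimal()
}
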