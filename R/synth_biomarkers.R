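#' Default biomarker effect specification
#'
#' Baseline levels, between-individual variability and day-12 treatment
#' effects for the ten assayed biomarkers, parameterised to reproduce the
#' reference experiment's reported percent changes. A multiplier of `m`
#' for a species x treatment cell means the day-12 expected raw value is
#' `m` times the day-6 baseline, so the expected baseline-normalized change
#' is `100 * (m - 1)` percent (e.g. DNA damage in the native species:
#' multiplier 3.06326, a +206.3% change). Biomarkers for which no change
#' was reported (SOD, LDH) keep multiplier 1. Noise is lognormal with unit
#' mean and a per-biomarker coefficient of variation, identical on both
#' days.
#'
#' @param species_levels Species labels, `c(native, invasive)`.
#' @param treatment_levels Treatment labels, default `c("CT", "HW")`.
#' @return A list of class `effect_spec` with tibbles `baselines`
#'   (`biomarker`, `species`, `mean`, `cv`, `unit`) and `effects`
#'   (`biomarker`, `species`, `treatment`, `multiplier`).
#' @examples
#' spec <- default_effect_spec()
#' subset(spec$effects, biomarker == "DNAd")
#' @export
default_effect_spec <- function(species_levels = c("native", "invasive"),
                                treatment_levels = c("CT", "HW")) {
  base <- tibble::tribble(
    ~biomarker,     ~mean, ~cv,  ~unit,
    "SOD",           12,   0.30, "U mg prot-1",
    "CAT",           25,   0.30, "U mg prot-1",
    "DNAd",           0.8, 0.60, "ug DNA g-1",
    "LPO",           80,   0.50, "nmol MDA g-1",
    "IDH",            3,   0.40, "nmol min-1 mg prot-1",
    "LDH",            8,   0.30, "nmol min-1 mg prot-1",
    "ETS",          300,   0.20, "mJ g-1 h-1",
    "protein",     9000,   0.20, "mJ g-1",
    "carbohydrate", 2500,  0.35, "mJ g-1",
    "lipid",       3500,   0.50, "mJ g-1"
  )
  baselines <- tidyr::expand_grid(species = species_levels, base) |>
    dplyr::select("biomarker", "species", "mean", "cv", "unit")

  nat <- species_levels[1]
  inv <- species_levels[2]
  ct <- treatment_levels[1]
  hw <- treatment_levels[2]
  effects <- tibble::tribble(
    ~biomarker,     ~species, ~treatment, ~multiplier,
    "SOD",          nat,      ct,         1.0,
    "SOD",          nat,      hw,         1.0,
    "SOD",          inv,      ct,         1.0,
    "SOD",          inv,      hw,         1.0,
    "CAT",          nat,      ct,         0.97780,
    "CAT",          nat,      hw,         0.83839,
    "CAT",          inv,      ct,         1.105,
    "CAT",          inv,      hw,         1.105,
    "DNAd",         nat,      ct,         3.06326,
    "DNAd",         nat,      hw,         3.06326,
    "DNAd",         inv,      ct,         1.00724,
    "DNAd",         inv,      hw,         1.00724,
    "LPO",          nat,      ct,         1.10993,
    "LPO",          nat,      hw,         1.07914,
    "LPO",          inv,      ct,         1.17845,
    "LPO",          inv,      hw,         0.80009,
    "IDH",          nat,      ct,         0.87239,
    "IDH",          nat,      hw,         0.87239,
    "IDH",          inv,      ct,         1.28479,
    "IDH",          inv,      hw,         1.28479,
    "LDH",          nat,      ct,         1.0,
    "LDH",          nat,      hw,         1.0,
    "LDH",          inv,      ct,         1.0,
    "LDH",          inv,      hw,         1.0,
    "ETS",          nat,      ct,         1.11793,
    "ETS",          nat,      hw,         1.21707,
    "ETS",          inv,      ct,         0.76518,
    "ETS",          inv,      hw,         0.62082,
    "protein",      nat,      ct,         1.29925,
    "protein",      nat,      hw,         1.29925,
    "protein",      inv,      ct,         0.98282,
    "protein",      inv,      hw,         0.98282,
    "carbohydrate", nat,      ct,         1.19954,
    "carbohydrate", nat,      hw,         0.97538,
    "carbohydrate", inv,      ct,         1.07068,
    "carbohydrate", inv,      hw,         1.11705,
    "lipid",        nat,      ct,         0.88534,
    "lipid",        nat,      hw,         0.87558,
    "lipid",        inv,      ct,         0.84646,
    "lipid",        inv,      hw,         1.64926
  )
  structure(list(baselines = baselines, effects = effects), class = "effect_spec")
}

#' Build a custom effect specification
#'
#' @param baselines Tibble with `biomarker`, `species`, `mean`, `cv` (and
#'   optionally `unit`).
#' @param effects Tibble with `biomarker`, `species`, `treatment`,
#'   `multiplier`.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(baselines, effects) {
  stopifnot(all(c("biomarker", "species", "mean", "cv") %in% names(baselines)),
            all(c("biomarker", "species", "treatment", "multiplier") %in% names(effects)))
  if (!"unit" %in% names(baselines)) baselines$unit <- NA_character_
  validate_effect_spec(structure(list(baselines = tibble::as_tibble(baselines),
                                      effects = tibble::as_tibble(effects)),
                                 class = "effect_spec"))
}

validate_effect_spec <- function(spec) {
  if (any(spec$baselines$mean <= 0)) {
    stop("baseline means must be strictly positive", call. = FALSE)
  }
  if (any(spec$baselines$cv < 0)) {
    stop("baseline CVs must be non-negative", call. = FALSE)
  }
  if (any(spec$effects$multiplier <= 0)) {
    stop("effect multipliers must be strictly positive", call. = FALSE)
  }
  spec
}

# lognormal multiplicative noise with unit mean and the given CV
rlnorm_unit_mean <- function(n, cv) {
  if (length(cv) == 1L) cv <- rep(cv, n)
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a per-individual biomarker panel
#'
#' Draws one raw value per individual x biomarker from the generating model
#' `value = baseline * multiplier * noise`, where the multiplier applies
#' only on the final sampling day (day-6 animals are sampled before the
#' heat wave) and the noise is unit-mean lognormal with the biomarker's CV.
#'
#' @param design Design tibble from [build_design()].
#' @param spec An `effect_spec`; default [default_effect_spec()].
#' @param seed Optional integer seed.
#' @return A long tibble (one row per individual x biomarker):
#'   `aquarium_id`, `species`, `treatment`, `day`, `individual_id`,
#'   `biomarker`, `value`, `unit`.
#' @examples
#' panel <- sample_biomarkers(build_design(), seed = 1)
#' dplyr::count(panel, day, species)
#' @export
sample_biomarkers <- function(design, spec = default_effect_spec(), seed = NULL) {
  validate_effect_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  individuals <- enumerate_individuals(design)
  final_day <- max(individuals$sampling_day)

  rows <- individuals |>
    dplyr::rename(day = "sampling_day") |>
    dplyr::inner_join(spec$baselines, by = "species", relationship = "many-to-many") |>
    dplyr::left_join(spec$effects, by = c("biomarker", "species", "treatment")) |>
    dplyr::mutate(multiplier = dplyr::if_else(.data$day == final_day,
                                              .data$multiplier, 1.0))
  if (anyNA(rows$multiplier[rows$day == final_day])) {
    missing <- rows |>
      dplyr::filter(.data$day == final_day, is.na(.data$multiplier)) |>
      dplyr::distinct(.data$biomarker, .data$species, .data$treatment)
    stop("no effect multiplier for: ",
         paste(missing$biomarker, missing$species, missing$treatment,
               sep = "/", collapse = ", "), call. = FALSE)
  }
  rows |>
    dplyr::mutate(value = .data$mean * .data$multiplier *
                    rlnorm_unit_mean(dplyr::n(), .data$cv)) |>
    dplyr::select("aquarium_id", "species", "treatment", "day",
                  "individual_id", "biomarker", "value", "unit")
}

#' Sample per-aquarium nutrient concentrations
#'
#' Draws water-column ammonia and phosphate concentrations for every
#' aquarium at each of its measured days, from unit-mean lognormal noise
#' around the configured means. With `cv = 0` the draws equal the means
#' exactly.
#'
#' @param design Design tibble from [build_design()].
#' @param means Named vector of nutrient means (mg/L).
#' @param cv Coefficient of variation shared by all nutrients.
#' @param seed Optional integer seed.
#' @return Long tibble: `aquarium_id`, `role`, `species`, `treatment`,
#'   `day`, `nutrient`, `value`.
#' @export
sample_nutrients <- function(design, means = c(NH3_N = 0.05, PO4_P = 0.03),
                             cv = 0.25, seed = NULL) {
  if (any(means <= 0)) stop("nutrient means must be positive", call. = FALSE)
  if (cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  days <- sort(unique(design$sampling_day))
  design |>
    dplyr::rowwise() |>
    dplyr::reframe(
      aquarium_id = .data$aquarium_id, role = .data$role,
      species = .data$species, treatment = .data$treatment,
      day = days[days <= .data$sampling_day]
    ) |>
    tidyr::expand_grid(nutrient = names(means)) |>
    dplyr::mutate(value = unname(means[.data$nutrient]) *
                    rlnorm_unit_mean(dplyr::n(), cv))
}
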