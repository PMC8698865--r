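#' Specify a factorial GLS model
#'
#' Describes one candidate model of the minimal-adequate-model workflow: a
#' response regressed on the full or reduced factorial of species and
#' temperature treatment, optionally with a per-stratum variance structure
#' (a variance covariate) so that residual spread may differ between
#' strata without transforming the data.
#'
#' @param response Name of the numeric response column.
#' @param fixed Character vector of fixed factor names (subset of the
#'   design factors; may be empty for an intercept-only model).
#' @param interaction Logical; include the two-way interaction (requires
#'   both factors in `fixed`).
#' @param var_structure One of `"identity"` (homoscedastic),
#'   `"species"`, `"treatment"`, `"species_treatment"` (separate residual
#'   variance per stratum of that factor or factor crossing).
#' @param method `"REML"` (variance-structure comparison, final
#'   re-expression) or `"ML"` (fixed-term likelihood-ratio tests).
#' @return A `gls_model_spec` object.
#' @examples
#' gls_model_spec("L_mean", var_structure = "species")
#' @export
gls_model_spec <- function(response,
                           fixed = c("species", "treatment"),
                           interaction = length(fixed) == 2L,
                           var_structure = c("identity", "species", "treatment",
                                             "species_treatment"),
                           method = c("REML", "ML")) {
  var_structure <- match.arg(var_structure)
  method <- match.arg(method)
  if (interaction && length(fixed) < 2L) {
    stop("an interaction term requires both main effects", call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, interaction = interaction,
                 var_structure = var_structure, method = method),
            class = "gls_model_spec")
}

spec_formula <- function(spec) {
  if (length(spec$fixed) == 0L) {
    stats::reformulate("1", response = spec$response)
  } else if (spec$interaction) {
    stats::reformulate(paste(spec$fixed, collapse = " * "), response = spec$response)
  } else {
    stats::reformulate(spec$fixed, response = spec$response)
  }
}

spec_weights <- function(spec) {
  switch(spec$var_structure,
    identity = NULL,
    species = nlme::varIdent(form = ~ 1 | species),
    treatment = nlme::varIdent(form = ~ 1 | treatment),
    species_treatment = nlme::varIdent(form = ~ 1 | species * treatment)
  )
}

n_variance_params <- function(spec, data) {
  strata <- switch(spec$var_structure,
    identity = return(0L),
    species = data$species,
    treatment = data$treatment,
    species_treatment = interaction(data$species, data$treatment, drop = TRUE)
  )
  length(unique(strata)) - 1L
}

spec_terms <- function(spec) {
  c(spec$fixed, if (spec$interaction) paste(sort(spec$fixed), collapse = ":"))
}

#' Fit a GLS model from a model specification
#'
#' Fits the specified factorial model by generalized least squares
#' (delegating the variance-weight estimation to [nlme::gls()]), under ML
#' or REML as the specification demands. With the identity variance
#' structure the fit reduces to ordinary least squares.
#'
#' @param data A data frame with the response and factor columns.
#' @param spec A [gls_model_spec()].
#' @return A `gls_fit`: list with the underlying `fit`, the `spec`, the
#'   total parameter count `k` (fixed coefficients + variance parameters +
#'   residual SD), `logLik` and `AIC` (`AIC = -2 logLik + 2 k`).
#' @examples
#' d <- tidyr::expand_grid(species = c("native", "invasive"),
#'                         treatment = c("CT", "HW"), rep = 1:5)
#' d$y <- stats::rnorm(nrow(d))
#' fit_gls(d, gls_model_spec("y"))
#' @export
fit_gls <- function(data, spec) {
  stopifnot(inherits(spec, "gls_model_spec"))
  if (!spec$response %in% names(data) || !is.numeric(data[[spec$response]])) {
    stop("response `", spec$response, "` must be a numeric column", call. = FALSE)
  }
  needed <- unique(c(spec$fixed,
                     switch(spec$var_structure,
                            identity = character(),
                            species = "species", treatment = "treatment",
                            species_treatment = c("species", "treatment"))))
  if (!all(needed %in% names(data))) {
    stop("data lacks factor column(s): ",
         paste(setdiff(needed, names(data)), collapse = ", "), call. = FALSE)
  }
  data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(needed), function(x) {
    if (is.factor(x)) x else factor(x)
  }))
  for (v in needed) {
    if (any(table(data[[v]]) == 0L)) {
      stop("factor `", v, "` has an empty stratum", call. = FALSE)
    }
  }
  if (anyNA(data[[spec$response]])) {
    stop("response contains missing values", call. = FALSE)
  }

  form <- spec_formula(spec)
  w <- spec_weights(spec)
  fit <- tryCatch(
    nlme::gls(model = form, data = data, weights = w, method = spec$method,
              na.action = stats::na.fail),
    error = function(e) stop("GLS fit failed (singular design or degenerate ",
                             "strata): ", conditionMessage(e), call. = FALSE)
  )
  k <- length(stats::coef(fit)) + n_variance_params(spec, data) + 1L
  ll <- as.numeric(stats::logLik(fit))
  structure(list(fit = fit, spec = spec, k = k, logLik = ll,
                 AIC = -2 * ll + 2 * k, n = nrow(data)),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("GLS fit:", deparse(spec_formula(x$spec)),
      "| variance:", x$spec$var_structure, "| method:", x$spec$method, "\n")
  cat(sprintf("logLik %.3f  AIC %.3f  (k = %d, n = %d)\n", x$logLik, x$AIC, x$k, x$n))
  invisible(x)
}

#' Tidy coefficient table of a GLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.gls_fit <- function(x, ...) {
  tt <- summary(x$fit)$tTable
  tibble::tibble(term = rownames(tt), estimate = tt[, 1], std_error = tt[, 2],
                 statistic = tt[, 3], p_value = tt[, 4])
}

#' One-row fit summary of a GLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return Tibble with log-likelihood, AIC, parameter count, method and
#'   variance structure.
#' @export
glance.gls_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = x$AIC, k = x$k, n = x$n,
                 method = x$spec$method, var_structure = x$spec$var_structure)
}

#' Likelihood-ratio test between nested ML fits
#'
#' Compares two nested fixed-effect structures fitted by full maximum
#' likelihood: `L_ratio = 2 (logLik_full - logLik_reduced)`, referred to a
#' chi-square distribution with degrees of freedom equal to the
#' parameter-count difference between the models (the convention used when
#' factor tests are reported as e.g. "df = 2, L-ratio = 11.074,
#' p = 0.004"). REML fits are rejected: their likelihoods are not
#' comparable across fixed structures.
#'
#' @param full,reduced `gls_fit` objects fitted by ML with the same
#'   response and variance structure, `reduced` nested in `full`.
#' @return Tibble with `df`, `L_ratio`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "gls_fit"), inherits(reduced, "gls_fit"))
  if (full$spec$method != "ML" || reduced$spec$method != "ML") {
    stop("likelihood-ratio tests require ML fits", call. = FALSE)
  }
  if (full$spec$response != reduced$spec$response ||
      full$spec$var_structure != reduced$spec$var_structure) {
    stop("models must share response and variance structure", call. = FALSE)
  }
  if (!all(spec_terms(reduced$spec) %in% spec_terms(full$spec)) ||
      reduced$k > full$k) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  df <- full$k - reduced$k
  l_ratio <- 2 * (full$logLik - reduced$logLik)
  if (l_ratio < -1e-6) {
    warning("negative likelihood ratio for nominally nested fits")
  }
  l_ratio <- max(l_ratio, 0)
  p <- if (df == 0L) 1 else stats::pchisq(l_ratio, df, lower.tail = FALSE)
  tibble::tibble(df = df, L_ratio = l_ratio, p_value = p)
}

#' Choose a variance structure by REML AIC
#'
#' Fits the same fixed structure under each candidate variance structure
#' using REML and keeps the candidate with the lowest AIC, breaking ties
#' toward fewer variance parameters. This mirrors the first stage of the
#' minimal-adequate-model workflow: the heteroscedasticity extension must
#' pay for its extra parameters against the homoscedastic baseline.
#'
#' @param data Data frame.
#' @param spec A [gls_model_spec()] giving the (full) fixed structure.
#' @param candidates Character vector of variance structures to screen;
#'   must contain `"identity"` when more than one candidate is given.
#' @return A list with `spec` (the winning specification, REML), and
#'   `aic_table` (tibble of candidate structures, parameter counts and
#'   AICs, in fitting order).
#' @export
select_variance_structure <- function(data, spec,
                                      candidates = c("identity", "species",
                                                     "treatment",
                                                     "species_treatment")) {
  stopifnot(inherits(spec, "gls_model_spec"))
  if (length(candidates) == 0L) stop("no candidates supplied", call. = FALSE)
  if (length(candidates) == 1L) {
    out <- gls_model_spec(spec$response, spec$fixed, spec$interaction,
                          var_structure = candidates, method = "REML")
    return(list(spec = out, aic_table = NULL))
  }
  if (!"identity" %in% candidates) {
    stop("`candidates` must include the homoscedastic \"identity\" baseline",
         call. = FALSE)
  }
  # a candidate can be unfittable (e.g. a zero-variance stratum); it is
  # recorded with NA AIC and skipped rather than aborting the screen
  fits <- purrr::map(candidates, function(vs) {
    tryCatch(
      fit_gls(data, gls_model_spec(spec$response, spec$fixed, spec$interaction,
                                   var_structure = vs, method = "REML")),
      error = function(e) e
    )
  })
  failed <- vapply(fits, inherits, logical(1), what = "error")
  aic_table <- tibble::tibble(
    var_structure = candidates,
    k = vapply(seq_along(fits), function(i) {
      if (failed[i]) NA_integer_ else fits[[i]]$k
    }, integer(1)),
    AIC = vapply(seq_along(fits), function(i) {
      if (failed[i]) NA_real_ else fits[[i]]$AIC
    }, numeric(1))
  )
  if (all(failed)) {
    stop("no candidate variance structure could be fitted: ",
         conditionMessage(fits[[1]]), call. = FALSE)
  }
  best <- order(aic_table$AIC, aic_table$k, na.last = TRUE)[1]
  list(spec = fits[[best]]$spec, aic_table = aic_table)
}

droppable_terms <- function(spec) {
  if (spec$interaction) {
    paste(sort(spec$fixed), collapse = ":")
  } else {
    spec$fixed
  }
}

drop_term <- function(spec, term, method = "ML") {
  if (grepl(":", term)) {
    gls_model_spec(spec$response, spec$fixed, interaction = FALSE,
                   var_structure = spec$var_structure, method = method)
  } else {
    gls_model_spec(spec$response, setdiff(spec$fixed, term), interaction = FALSE,
                   var_structure = spec$var_structure, method = method)
  }
}

#' Backward selection of the minimal adequate fixed structure
#'
#' Starting from the full factorial model, repeatedly refits under ML and
#' drops the least-significant droppable term whose likelihood-ratio
#' p-value is at or above `alpha`, respecting marginality (the interaction
#' must go before either main effect). The surviving structure is refitted
#' with REML for reporting, and the full trail of tests is returned.
#'
#' @param data Data frame.
#' @param spec A [gls_model_spec()]; its variance structure is kept fixed
#'   throughout (select it first with [select_variance_structure()]).
#' @param alpha Retention threshold for the LR p-value (default 0.05).
#' @return A `gls_selection`: list with `final` (REML `gls_fit` of the
#'   minimal model), `spec` (its specification), and `trail` (tibble of
#'   every tested deletion: `step`, `term`, `df`, `L_ratio`, `p_value`,
#'   `dropped`).
#' @examples
#' d <- tidyr::expand_grid(species = c("native", "invasive"),
#'                         treatment = c("CT", "HW"), rep = 1:6)
#' d$y <- stats::rnorm(nrow(d)) + (d$species == "native")
#' backward_select(d, gls_model_spec("y"))$trail
#' @export
backward_select <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "gls_model_spec"))
  current <- gls_model_spec(spec$response, spec$fixed, spec$interaction,
                            var_structure = spec$var_structure, method = "ML")
  trail <- list()
  step <- 0L
  repeat {
    terms <- droppable_terms(current)
    if (length(terms) == 0L) break
    step <- step + 1L
    full_fit <- fit_gls(data, current)
    tests <- purrr::map_dfr(terms, function(tm) {
      reduced <- fit_gls(data, drop_term(current, tm))
      dplyr::mutate(lr_test(full_fit, reduced), term = tm)
    })
    tests <- dplyr::mutate(tests, step = step)
    worst <- which.max(tests$p_value)
    tests$dropped <- FALSE
    if (tests$p_value[worst] >= alpha) {
      tests$dropped[worst] <- TRUE
      trail[[step]] <- tests
      current <- drop_term(current, tests$term[worst])
    } else {
      trail[[step]] <- tests
      break
    }
  }
  final_spec <- gls_model_spec(current$response, current$fixed, current$interaction,
                               var_structure = current$var_structure,
                               method = "REML")
  final <- fit_gls(data, final_spec)
  trail_tbl <- if (length(trail) > 0L) {
    dplyr::bind_rows(trail) |>
      dplyr::select("step", "term", "df", "L_ratio", "p_value", "dropped")
  } else {
    tibble::tibble(step = integer(), term = character(), df = integer(),
                   L_ratio = numeric(), p_value = numeric(), dropped = logical())
  }
  structure(list(final = final, spec = final_spec, trail = trail_tbl),
            class = "gls_selection")
}

#' @export
print.gls_selection <- function(x, ...) {
  cat("Minimal adequate model:", deparse(spec_formula(x$spec)),
      "| variance:", x$spec$var_structure, "\n")
  if (nrow(x$trail) > 0L) print(x$trail)
  invisible(x)
}

#' Simulate a balanced two-factor response table
#'
#' Draws a species x treatment factorial response with configurable cell
#' means and per-species residual SDs; the null workhorse for calibrating
#' the likelihood-ratio test and the variance-structure selection.
#'
#' @param n_per_cell Replicates per species x treatment cell.
#' @param species_levels,treatment_levels Factor labels.
#' @param intercept Grand mean.
#' @param species_effect,treatment_effect Named additive effects (defaults
#'   0).
#' @param interaction_effect Single added value in the last x last cell
#'   (default 0).
#' @param sd_by_species Named per-species residual SD (default 1 for all).
#' @return A tibble with `species`, `treatment`, `y`.
#' @export
simulate_factorial_response <- function(n_per_cell = 10,
                                        species_levels = c("native", "invasive"),
                                        treatment_levels = c("CT", "HW"),
                                        intercept = 0,
                                        species_effect = NULL,
                                        treatment_effect = NULL,
                                        interaction_effect = 0,
                                        sd_by_species = NULL) {
  if (is.null(species_effect)) {
    species_effect <- stats::setNames(rep(0, length(species_levels)), species_levels)
  }
  if (is.null(treatment_effect)) {
    treatment_effect <- stats::setNames(rep(0, length(treatment_levels)), treatment_levels)
  }
  if (is.null(sd_by_species)) {
    sd_by_species <- stats::setNames(rep(1, length(species_levels)), species_levels)
  }
  d <- tidyr::expand_grid(species = species_levels, treatment = treatment_levels,
                          rep = seq_len(n_per_cell))
  mu <- intercept + species_effect[d$species] + treatment_effect[d$treatment] +
    ifelse(d$species == species_levels[length(species_levels)] &
             d$treatment == treatment_levels[length(treatment_levels)],
           interaction_effect, 0)
  d$y <- stats::rnorm(nrow(d), mean = mu, sd = sd_by_species[d$species])
  dplyr::select(d, "species", "treatment", "y")
}
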