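make_two_day_panel <- function(d6_native, d12_rows, biomarker = "X") {
  d6 <- tibble::tibble(
    species = "native", treatment = NA_character_, day = 6,
    individual_id = paste0("b", seq_along(d6_native)),
    biomarker = biomarker, value = d6_native
  )
  dplyr::bind_rows(d6, d12_rows)
}

test_that("log ratios follow their closed form and reject non-positive values", {
  d12 <- tibble::tibble(species = "native", treatment = "HW", day = 12,
                        individual_id = c("i1", "i2"), biomarker = "X",
                        value = c(4, 40))
  panel <- make_two_day_panel(c(4, 4), d12)
  y <- ibr_log_ratio(panel, "X")
  expect_equal(y$Y[y$individual_id == "i1"], 0)          # equals baseline mean
  expect_equal(y$Y[y$individual_id == "i2"], 1)          # tenfold -> log10 = 1
  bad <- panel
  bad$value[4] <- -1
  expect_error(ibr_log_ratio(bad, "X"), "non-positive")
  set.seed(1)
  rnd <- random_panel(n_biomarkers = 2)
  y2 <- ibr_log_ratio(rnd, c("B1", "B2"))
  one <- y2[5, ]
  m6 <- mean(rnd$value[rnd$day == 6 & rnd$species == one$species &
                         rnd$biomarker == one$biomarker])
  v <- rnd$value[rnd$day == 12 & rnd$individual_id == one$individual_id &
                   rnd$biomarker == one$biomarker]
  expect_equal(one$Y, log10(v / m6))
})

test_that("standardization centres each cell and uses the sample SD", {
  y <- tibble::tibble(individual_id = c("i1", "i2"), species = "native",
                      treatment = "HW", biomarker = "X", Y = c(-1, 1))
  z <- ibr_standardize(y)
  expect_equal(z$Z, c(-1, 1) / sqrt(2))   # sample SD of {-1, 1} is sqrt(2)
  expect_equal(mean(z$Z), 0)
  single <- y[1, ]
  expect_error(ibr_standardize(single), "at least 2")
})

test_that("zero-variance cells warn and contribute zero deviation under the guard", {
  y <- tibble::tibble(individual_id = c("i1", "i2"), species = "native",
                      treatment = "HW", biomarker = "X", Y = c(0.3, 0.3))
  expect_error(ibr_standardize(y, zero_variance_guard = FALSE), "zero variance")
  expect_warning(z <- ibr_standardize(y), "zero-variance")
  baseline <- tibble::tibble(species = "native", biomarker = "X", z_d6 = -0.2)
  a <- ibr_deviation(z, baseline)
  expect_equal(a$A, c(0, 0))
})

test_that("the day-6 reference term matches hand computation", {
  p_equal <- tibble::tibble(species = "native", treatment = NA, day = 6,
                            individual_id = c("a", "b"), biomarker = "X",
                            value = c(7, 7))
  expect_equal(ibr_baseline_term(p_equal, "X")$z_d6, 0)

  p2 <- tibble::tibble(species = "native", treatment = NA, day = 6,
                       individual_id = c("a", "b"), biomarker = "X",
                       value = c(1, 10))
  # mean 5.5: (log10(1/5.5) + log10(10/5.5)) / 2 = -0.048455...
  expect_equal(ibr_baseline_term(p2, "X")$z_d6,
               (log10(1 / 5.5) + log10(10 / 5.5)) / 2)
  expect_lt(ibr_baseline_term(p2, "X")$z_d6, 0)  # Jensen: mean log ratio <= 0

  p1 <- p2[1, ]
  expect_equal(ibr_baseline_term(p1, "X")$z_d6, 0)  # single value equals its mean
})

test_that("deviation indexes subtract the reference and flag mismatches", {
  z <- tibble::tibble(individual_id = "i1", species = "native", treatment = "HW",
                      biomarker = "X", Y = 0.5, mu = 0, s = 1, zero_var = FALSE,
                      Z = 0.5)
  same <- tibble::tibble(species = "native", biomarker = "X", z_d6 = 0.5)
  expect_equal(ibr_deviation(z, same)$A, 0)
  other <- tibble::tibble(species = "native", biomarker = "Y", z_d6 = 0)
  expect_error(ibr_deviation(z, other), "do not match")
})

test_that("IBRv2 sums absolute deviations and is zero only when all are zero", {
  expect_equal(sum(abs(c(1, -2))), 3)  # definitional anchor for the sum below
  set.seed(2)
  panel <- random_panel(n_biomarkers = 3, n_per_cell = 5, n_d6 = 4)
  res <- ibr_v2(panel, biomarkers = c("B1", "B2", "B3"))
  expect_true(all(res$individual$ibr >= 0))
  manual <- res$components |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(ibr = sum(abs(.data$A)))
  expect_equal(sort(res$individual$ibr), sort(manual$ibr))
  expect_error(ibr_v2(panel, biomarkers = character()), "at least one")
})

test_that("a biomarker with zero deviation leaves every IBRv2 value unchanged", {
  set.seed(3)
  panel <- random_panel(n_biomarkers = 2, n_per_cell = 5, n_d6 = 4)
  base <- ibr_v2(panel, biomarkers = c("B1", "B2"))
  # constant extra biomarker: zero-variance guard makes its A identically 0
  extra <- panel |>
    dplyr::distinct(.data$individual_id, .data$species, .data$treatment,
                    .data$day, .data$aquarium_id) |>
    dplyr::mutate(biomarker = "B0", value = 5)
  augmented <- dplyr::bind_rows(panel, extra)
  expect_warning(aug <- ibr_v2(augmented, biomarkers = c("B1", "B2", "B0")),
                 "zero-variance")
  j <- dplyr::inner_join(base$individual, aug$individual, by = "individual_id")
  expect_equal(j$ibr.x, j$ibr.y, tolerance = 1e-12)
})

test_that("standardized values ignore the log base but the reference term does not", {
  set.seed(4)
  panel <- random_panel(n_biomarkers = 2, n_per_cell = 5, n_d6 = 4)
  r10 <- ibr_v2(panel, biomarkers = c("B1", "B2"), log_base = 10)
  re <- ibr_v2(panel, biomarkers = c("B1", "B2"), log_base = exp(1))
  key <- c("individual_id", "biomarker")
  j <- dplyr::inner_join(r10$components, re$components, by = key)
  expect_equal(j$Z.x, j$Z.y, tolerance = 1e-10)
  jb <- dplyr::inner_join(r10$baseline, re$baseline, by = c("species", "biomarker"))
  expect_equal(jb$z_d6.y, jb$z_d6.x * log(10), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(jb$z_d6.x, jb$z_d6.y)))
})

test_that("pipeline IBRv2 equals the straight-line oracle on random panels", {
  set.seed(5)
  for (rep in 1:20) {
    panel <- random_panel()
    bm <- unique(panel$biomarker)
    res <- ibr_v2(panel, biomarkers = bm)
    oracle <- ibr_oracle(panel, bm)
    j <- dplyr::inner_join(res$individual, oracle, by = "individual_id")
    expect_equal(nrow(j), nrow(res$individual))
    expect_equal(j$ibr.x, j$ibr.y, tolerance = 1e-12)
  }
})

test_that("star-plot data has the documented axis order and matches deviations", {
  design <- build_design()
  panel <- sample_biomarkers(design, seed = 6)
  res <- ibr_v2(panel)
  star <- star_plot_data(res)
  expect_equal(levels(star$biomarker),
               c("SOD", "CAT", "DNAd", "LPO", "IDH", "LDH", "CEA"))
  expect_equal(length(levels(star$biomarker)), 7L)
  manual <- res$components |>
    dplyr::group_by(.data$species, .data$treatment, .data$biomarker) |>
    dplyr::summarise(mean_A = mean(.data$A), .groups = "drop")
  j <- star |>
    dplyr::mutate(biomarker = as.character(.data$biomarker)) |>
    dplyr::inner_join(manual, by = c("species", "treatment", "biomarker"))
  expect_equal(j$mean_A.x, j$mean_A.y)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("tidy and glance expose components and settings", {
  panel <- sample_biomarkers(build_design(), seed = 7)
  res <- ibr_v2(panel)
  td <- tidy(res)
  expect_true(all(c("individual_id", "biomarker", "Y", "Z", "A") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_biomarkers, 7L)
  expect_equal(gl$log_base, 10)
})
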