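# Straight-line reimplementation of the IBRv2 chain (log ratio ->
# within-condition standardization -> baseline reference -> summed absolute
# deviations) with explicit loops and no grouping machinery. Used as the
# independent oracle for the pipeline implementation.
ibr_oracle <- function(panel, biomarkers, log_base = 10) {
  panel <- as.data.frame(panel)
  d12 <- panel[panel$day == 12, ]
  out <- list()
  for (sp in unique(d12$species)) {
    for (tr in unique(d12$treatment[d12$species == sp])) {
      ids <- unique(d12$individual_id[d12$species == sp & d12$treatment == tr])
      A <- matrix(NA_real_, length(ids), length(biomarkers))
      for (b in seq_along(biomarkers)) {
        bm <- biomarkers[b]
        v6 <- panel$value[panel$day == 6 & panel$species == sp &
                            panel$biomarker == bm]
        m6 <- mean(v6)
        Y <- vapply(ids, function(id) {
          v <- d12$value[d12$individual_id == id & d12$biomarker == bm &
                           d12$species == sp & d12$treatment == tr]
          log(v / m6, base = log_base)
        }, numeric(1))
        Z <- (Y - mean(Y)) / stats::sd(Y)
        z_d6 <- mean(log(v6 / m6, base = log_base))
        A[, b] <- Z - z_d6
      }
      out[[paste(sp, tr)]] <- data.frame(
        individual_id = ids, species = sp, treatment = tr,
        ibr = rowSums(abs(A)), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random complete long panel: every day-12 individual carries every
# biomarker; at least 2 day-6 and 2 day-12 individuals per cell.
random_panel <- function(n_biomarkers = sample(2:5, 1),
                         n_per_cell = sample(2:6, 1),
                         n_d6 = sample(2:6, 1)) {
  biomarkers <- paste0("B", seq_len(n_biomarkers))
  cells <- expand.grid(species = c("native", "invasive"),
                       treatment = c("CT", "HW"), stringsAsFactors = FALSE)
  rows <- list()
  for (sp in c("native", "invasive")) {
    ids6 <- paste0(sp, "_d6_", seq_len(n_d6))
    rows[[paste0(sp, "6")]] <- expand.grid(
      individual_id = ids6, biomarker = biomarkers, stringsAsFactors = FALSE)
    rows[[paste0(sp, "6")]]$species <- sp
    rows[[paste0(sp, "6")]]$treatment <- NA_character_
    rows[[paste0(sp, "6")]]$day <- 6
  }
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tr <- cells$treatment[i]
    ids <- paste0(sp, "_", tr, "_", seq_len(n_per_cell))
    g <- expand.grid(individual_id = ids, biomarker = biomarkers,
                     stringsAsFactors = FALSE)
    g$species <- sp; g$treatment <- tr; g$day <- 12
    rows[[paste(sp, tr)]] <- g
  }
  panel <- do.call(rbind, rows)
  panel$value <- stats::rlnorm(nrow(panel), meanlog = 1, sdlog = 0.6)
  panel$aquarium_id <- "A00"
  tibble::as_tibble(panel)
}
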