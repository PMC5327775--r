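# Shared fixtures, all built in code.

baseline_patient <- function(age = 40, spleen = 5, platelets = 400, blasts = 2,
                             eosinophils = 1, basophils = 1,
                             patient_id = "P001") {
  tibble::tibble(patient_id = patient_id, age = age, spleen = spleen,
                 platelets = platelets, blasts = blasts,
                 eosinophils = eosinophils, basophils = basophils)
}

# The reconstruction search takes a few seconds; reuse one cohort per seed
# across test files.
.fixtures <- new.env(parent = emptyenv())

reconstructed_cohort <- function(seed = 1) {
  key <- paste0("rc_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- reconstruct_cohort(target_tables(), seed = seed)
  }
  .fixtures[[key]]
}

reconstructed_report <- function(seed = 1) {
  key <- paste0("rep_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <-
      consistency_report(score_cohort(reconstructed_cohort(seed)))
  }
  .fixtures[[key]]
}

# Small random scored-and-labelled cohorts for property tests: labels and
# outcomes drawn directly, bypassing the score engine, so label-level
# invariants are exercised on arbitrary configurations.
random_label_cohort <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("X%03d", seq_len(n)),
    sokal_cat = sample(c("low", "intermediate", "high"), n, replace = TRUE),
    hasford_cat = sample(c("low", "intermediate", "high"), n, replace = TRUE),
    eutos_cat = sample(c("low", "high"), n, replace = TRUE),
    elts_cat = sample(c("low", "intermediate", "high"), n, replace = TRUE),
    mmr_achieved = sample(0:1, n, replace = TRUE)
  )
}

# Write a minimal targets JSON for reconstruct_cohort tests: counts is a
# named list pattern-key -> c(n_mmr, n_no_mmr), keys like "lowish.high.low...";
# strategy-2 marginals default to the strategy-1 ones (no intermediates).
write_targets_json <- function(counts, path = tempfile(fileext = ".json"),
                               intermediates = NULL) {
  patterns <- enumerate_combinations(4, 2)
  key <- paste(patterns$sokal, patterns$hasford, patterns$eutos, patterns$elts,
               sep = ".")
  patterns$n_mmr <- 0L
  patterns$n_no_mmr <- 0L
  for (k in names(counts)) {
    i <- match(k, key)
    stopifnot(!is.na(i))
    patterns$n_mmr[i] <- counts[[k]][1]
    patterns$n_no_mmr[i] <- counts[[k]][2]
  }
  s2 <- lapply(cml_systems, function(sys) {
    hi <- patterns[[sys]] == "high"
    extra <- if (!is.null(intermediates) && sys %in% names(intermediates)) {
      intermediates[[sys]]
    } else {
      c(0L, 0L)
    }
    list(n_mmr = sum(patterns$n_mmr[hi]) + extra[1],
         n_no_mmr = sum(patterns$n_no_mmr[hi]) + extra[2])
  })
  names(s2) <- cml_systems
  jsonlite::write_json(
    list(version = 1L,
         combination_rows = patterns,
         strategy2_high_marginals = s2),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  path
}
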