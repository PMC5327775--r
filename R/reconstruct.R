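#' Load the target aggregate tables for cohort reconstruction
#'
#' The targets consist of (a) the 16 strategy-1 joint risk-label combination
#' rows, each with MMR / no-MMR patient counts, and (b) per-system strategy-2
#' high-group marginals, from which the number of intermediate-category
#' patients per system is derived (strategy-2 high minus strategy-1 high).
#' The packaged default is the published 95-patient reference cohort.
#'
#' @param path Path to a targets JSON file; `NULL` (default) loads the
#'   packaged reference counts.
#' @return A list of class `cml_targets`: `rows` (16-row tibble with the
#'   four pattern columns, `n_mmr`, `n_no_mmr`), `strategy2_high` (per-system
#'   counts), `total`.
#' @export
target_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_counts.json", package = "cmlrisk",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rows <- tibble::as_tibble(raw$combination_rows)
  needed <- c(cml_systems, "n_mmr", "n_no_mmr")
  if (!all(needed %in% names(rows))) {
    stop("targets file must provide combination rows with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  # normalize to canonical enumeration order and check exhaustiveness
  patterns <- enumerate_combinations(4, 2)
  key <- function(df) paste(df$sokal, df$hasford, df$eutos, df$elts)
  idx <- match(key(patterns), key(rows))
  if (anyNA(idx) || nrow(rows) != nrow(patterns)) {
    stop("combination rows must cover all 16 label patterns exactly once",
         call. = FALSE)
  }
  rows <- rows[idx, needed]
  if (any(rows$n_mmr < 0) || any(rows$n_no_mmr < 0)) {
    stop("combination counts must be nonnegative", call. = FALSE)
  }
  s2 <- raw$strategy2_high_marginals
  if (!all(cml_systems %in% names(s2))) {
    stop("targets file must provide strategy-2 high marginals for all systems",
         call. = FALSE)
  }
  targets <- structure(
    list(rows = rows, strategy2_high = s2,
         total = sum(rows$n_mmr) + sum(rows$n_no_mmr)),
    class = "cml_targets"
  )
  validate_targets(targets)
  targets
}

# Per-system intermediate counts implied by the two strategies, split by MMR
# status: (# strategy-2 high) - (# strategy-1 high). Errors if the implied
# counts are negative or exceed the available lowish patients.
intermediate_counts <- function(targets) {
  rows <- targets$rows
  out <- lapply(cml_systems, function(sys) {
    hi <- rows[[sys]] == "high"
    s1 <- c(n_mmr = sum(rows$n_mmr[hi]), n_no_mmr = sum(rows$n_no_mmr[hi]))
    s2 <- c(n_mmr = targets$strategy2_high[[sys]]$n_mmr,
            n_no_mmr = targets$strategy2_high[[sys]]$n_no_mmr)
    lowish <- c(n_mmr = sum(rows$n_mmr[!hi]), n_no_mmr = sum(rows$n_no_mmr[!hi]))
    int <- s2 - s1
    if (any(int < 0) || any(int > lowish)) {
      stop(sprintf(
        "inconsistent targets for %s: strategy-2 high counts imply %d/%d intermediates but only %d/%d lowish patients exist",
        sys, int[["n_mmr"]], int[["n_no_mmr"]],
        lowish[["n_mmr"]], lowish[["n_no_mmr"]]), call. = FALSE)
    }
    int
  })
  names(out) <- cml_systems
  out
}

validate_targets <- function(targets) {
  if (targets$total < 1) stop("targets describe an empty cohort", call. = FALSE)
  ic <- intermediate_counts(targets)
  if (any(ic$eutos != 0)) {
    stop("EUTOS has no intermediate category; its strategy-2 marginals must equal strategy-1",
         call. = FALSE)
  }
  invisible(targets)
}

# Sampling ranges for the rejection search: broad uniforms over clinically
# admissible values, wide enough that every label pattern with overlapping
# score regions is reachable.
reconstruct_ranges <- function() {
  list(age = c(18, 80), spleen = c(0, 30), platelets = c(10, 3000),
       blasts = c(0, 15), eosinophils = c(0, 10), basophils = c(0, 12))
}

# Platelets are drawn log-uniformly: the clinically meaningful low-platelet
# regime (which drives the ELTS score up) would be vanishingly rare under a
# linear-scale uniform on a range reaching 3000.
draw_chunk <- function(n, rng) {
  ch <- lapply(rng, function(r) runif(n, r[1], r[2]))
  ch$platelets <- exp(runif(n, log(rng$platelets[1]), log(rng$platelets[2])))
  ch
}

# Three-level categories for a chunk of candidate baselines (no validation;
# the ranges above are admissible by construction).
chunk_categories <- function(ch) {
  list(
    sokal = categorize("sokal", sokal_score(ch$age, ch$spleen, ch$platelets,
                                            ch$blasts, validate = FALSE)),
    hasford = categorize("hasford", hasford_score(ch$age, ch$spleen, ch$blasts,
                                                  ch$eosinophils, ch$basophils,
                                                  ch$platelets, validate = FALSE)),
    eutos = categorize("eutos", eutos_score(ch$basophils, ch$spleen,
                                            validate = FALSE)),
    elts = categorize("elts", elts_score(ch$age, ch$spleen, ch$blasts,
                                         ch$platelets, validate = FALSE))
  )
}

#' Reconstruct a patient-level cohort matching published aggregate tables
#'
#' Builds exactly `targets$total` synthetic patients whose scored,
#' dichotomized (strategy 1) labels reproduce every combination-row count,
#' whose MMR flags match each row's MMR split exactly (assigned
#' deterministically, not sampled), and whose three-level categories also
#' reproduce the strategy-2 marginals. Patient baselines are found by
#' rejection sampling from broad uniform clinical ranges; every accepted
#' patient is verified by scoring with the score engine, never by trusting
#' the search's bookkeeping. Each combination row uses its own deterministic
#' PRNG stream derived from `seed` and the row index, so rows are
#' reproducible independently of one another.
#'
#' Intermediate-category assignments (which lowish patients are
#' intermediate rather than low, per system) are placed greedily in slot
#' order; since all implied intermediates fit inside the all-lowish
#' consensus row, this choice cannot affect any reported table.
#'
#' @param targets A `cml_targets` object from [target_tables()].
#' @param seed Integer seed for the rejection search.
#' @param max_draws Search budget per label pattern (candidate draws) before
#'   the pattern is declared unsatisfiable.
#' @return A tibble in the cohort schema of [generate_cohort()].
#' @examples
#' \donttest{
#' cohort <- reconstruct_cohort(target_tables(), seed = 1)
#' consistency_partition(score_cohort(cohort))$n_consensus  # 65
#' }
#' @export
reconstruct_cohort <- function(targets = target_tables(), seed = 1L,
                               max_draws = 2e7) {
  stopifnot(inherits(targets, "cml_targets"))
  seed <- as.integer(seed)
  rows <- targets$rows

  # one slot per patient: pattern row index, mmr flag (MMR slots first)
  slots <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    n_y <- rows$n_mmr[i]; n_n <- rows$n_no_mmr[i]
    if (n_y + n_n == 0) return(NULL)
    data.frame(row = i, mmr = rep(c(1L, 0L), c(n_y, n_n)))
  }))
  # target three-level category per system: start from the dichotomous label
  for (sys in cml_systems) {
    lab <- rows[[sys]][slots$row]
    slots[[paste0(sys, "_target")]] <- ifelse(lab == "high", "high", "low")
  }
  # upgrade the required number of lowish slots to "intermediate", greedily
  # in slot order, separately per MMR status
  ic <- intermediate_counts(targets)
  for (sys in setdiff(cml_systems, "eutos")) {
    tgt <- paste0(sys, "_target")
    for (m in c(1L, 0L)) {
      need <- if (m == 1L) ic[[sys]][["n_mmr"]] else ic[[sys]][["n_no_mmr"]]
      if (need == 0) next
      cand <- which(slots$mmr == m & slots[[tgt]] == "low")
      if (length(cand) < need) {
        stop(sprintf("cannot place %d intermediate %s patients", need, sys),
             call. = FALSE)
      }
      slots[[tgt]][cand[seq_len(need)]] <- "intermediate"
    }
  }

  rng <- reconstruct_ranges()
  chunk_size <- 20000L
  vars <- names(rng)
  result <- vector("list", nrow(slots))

  for (i in sort(unique(slots$row))) {
    set.seed(seed + 1000L * i)
    row_slots <- which(slots$row == i)
    tuples <- do.call(paste, c(slots[row_slots, paste0(cml_systems, "_target")],
                               list(sep = "|")))
    for (tup in unique(tuples)) {
      members <- row_slots[tuples == tup]
      want <- strsplit(tup, "|", fixed = TRUE)[[1]]
      names(want) <- cml_systems
      found <- list()
      drawn <- 0
      while (length(found) < length(members)) {
        if (drawn >= max_draws) {
          stop(sprintf(
            "unsatisfiable label pattern (%s) after %d draws; widen ranges or raise max_draws",
            paste(names(want), want, sep = "=", collapse = ", "), drawn),
            call. = FALSE)
        }
        ch <- draw_chunk(chunk_size, rng)
        drawn <- drawn + chunk_size
        cats <- chunk_categories(ch)
        hit <- cats$sokal == want[["sokal"]] &
          cats$hasford == want[["hasford"]] &
          cats$eutos == want[["eutos"]] &
          cats$elts == want[["elts"]]
        for (j in which(hit)) {
          if (length(found) >= length(members)) break
          found[[length(found) + 1L]] <- vapply(vars, function(v) ch[[v]][j],
                                                numeric(1))
        }
      }
      for (k in seq_along(members)) result[[members[k]]] <- found[[k]]
    }
  }

  mat <- do.call(rbind, result)
  col <- function(v) unname(mat[, v])
  cohort <- tibble::tibble(
    patient_id = sprintf("R%03d", seq_len(nrow(slots))),
    age = col("age"), spleen = col("spleen"),
    platelets = col("platelets"), blasts = col("blasts"),
    eosinophils = col("eosinophils"), basophils = col("basophils"),
    mmr_achieved = slots$mmr
  )

  # verify by scoring: every slot's three-level categories must match
  scored <- score_cohort(cohort)
  for (sys in cml_systems) {
    got <- scored[[paste0(sys, "_cat")]]
    want <- slots[[paste0(sys, "_target")]]
    if (!identical(got, want)) {
      stop("internal error: reconstructed cohort fails score verification for ",
           sys, call. = FALSE)
    }
  }
  cohort
}
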