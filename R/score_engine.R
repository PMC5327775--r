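#' Validate baseline clinical variables for CML risk scoring
#'
#' Checks the six diagnosis-time variables that feed the Sokal, Hasford,
#' EUTOS and ELTS scores: all must be finite, percentages must lie in
#' \[0, 100\], age and spleen size must be nonnegative, and platelets must be
#' strictly positive (the ELTS score raises platelets to the -0.5 power, so a
#' zero count is a singularity, not merely implausible).
#'
#' @param data A data frame with numeric columns `age` (completed years),
#'   `spleen` (cm below costal margin; 0 means non-palpable), `platelets`
#'   (count x 10^9/L), `blasts`, `eosinophils` and `basophils` (peripheral
#'   differential percentages).
#' @param strict If `TRUE` (default) violations are errors naming the field;
#'   if `FALSE` they are downgraded to warnings. Out-of-range percentages
#'   silently corrupt scores, hence strict-by-default.
#' @return `data`, invisibly.
#' @export
validate_baseline <- function(data, strict = TRUE) {
  needed <- c("age", "spleen", "platelets", "blasts", "eosinophils", "basophils")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing baseline column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_numeric_field(data$age, "age", lower = 0, upper = Inf, strict = strict)
  check_numeric_field(data$spleen, "spleen", lower = 0, upper = Inf, strict = strict)
  check_numeric_field(data$platelets, "platelets", lower = 0, strict_lower = TRUE,
                      strict = strict)
  for (pct in c("blasts", "eosinophils", "basophils")) {
    check_numeric_field(data[[pct]], pct, lower = 0, upper = 100, strict = strict)
  }
  invisible(data)
}

#' Sokal prognostic score
#'
#' `exp(0.0116 (age - 43.4) + 0.0345 (spleen - 7.51) +
#' 0.188 ((platelets/700)^2 - 0.563) + 0.0887 (blasts - 2.10))`, the original
#' survival-model form in which the exponential wraps the entire linear
#' predictor; only under that reading are the published 0.8 / 1.2 category
#' cut-offs meaningful. The score is strictly positive and equals exactly 1
#' when every centered term vanishes.
#'
#' @param age Age in years.
#' @param spleen Spleen size, cm below costal margin.
#' @param platelets Platelet count, x 10^9/L (strictly positive).
#' @param blasts Peripheral blasts, percent.
#' @param validate Check inputs before computing (default `TRUE`).
#' @return Numeric vector of score values.
#' @seealso [categorize()] for the low / intermediate / high cut-offs.
#' @examples
#' sokal_score(age = 60, spleen = 10, platelets = 300, blasts = 4)
#' @export
sokal_score <- function(age, spleen, platelets, blasts, validate = TRUE) {
  if (validate) {
    check_numeric_field(age, "age", lower = 0)
    check_numeric_field(spleen, "spleen", lower = 0)
    check_numeric_field(platelets, "platelets", lower = 0, strict_lower = TRUE)
    check_numeric_field(blasts, "blasts", lower = 0, upper = 100)
  }
  exp(0.0116 * (age - 43.4) +
      0.0345 * (spleen - 7.51) +
      0.188 * ((platelets / 700)^2 - 0.563) +
      0.0887 * (blasts - 2.10))
}

#' Hasford (Euro) prognostic score
#'
#' `1000 x (0.6666 I(age >= 50) + 0.0420 spleen + 0.0584 blasts +
#' 0.0413 eosinophils + 0.2039 I(basophils >= 3) + 1.0956 I(platelets >=
#' 1500))`. The x1000 applies to the whole sum (the original form; the
#' published 780 / 1480 cut-offs are unreachable otherwise). Age, basophils
#' and platelets enter only through threshold indicators, so the score is
#' piecewise constant in them.
#'
#' @inheritParams sokal_score
#' @param eosinophils,basophils Peripheral differential percentages.
#' @return Numeric vector of score values (0 to about 4000).
#' @examples
#' hasford_score(age = 55, spleen = 10, blasts = 3, eosinophils = 2,
#'               basophils = 4, platelets = 1600)  # 2643.9
#' @export
hasford_score <- function(age, spleen, blasts, eosinophils, basophils,
                          platelets, validate = TRUE) {
  if (validate) {
    check_numeric_field(age, "age", lower = 0)
    check_numeric_field(spleen, "spleen", lower = 0)
    check_numeric_field(blasts, "blasts", lower = 0, upper = 100)
    check_numeric_field(eosinophils, "eosinophils", lower = 0, upper = 100)
    check_numeric_field(basophils, "basophils", lower = 0, upper = 100)
    check_numeric_field(platelets, "platelets", lower = 0, strict_lower = TRUE)
  }
  1000 * (0.6666 * (age >= 50) +
          0.0420 * spleen +
          0.0584 * blasts +
          0.0413 * eosinophils +
          0.2039 * (basophils >= 3) +
          1.0956 * (platelets >= 1500))
}

#' EUTOS prognostic score
#'
#' `7 x basophils + 4 x spleen`; the only one of the four systems with just
#' two risk categories (low < 87, high >= 87).
#'
#' @inheritParams hasford_score
#' @return Numeric vector of nonnegative score values.
#' @examples
#' eutos_score(basophils = 3, spleen = 16.5)  # 87, on the high-risk boundary
#' @export
eutos_score <- function(basophils, spleen, validate = TRUE) {
  if (validate) {
    check_numeric_field(basophils, "basophils", lower = 0, upper = 100)
    check_numeric_field(spleen, "spleen", lower = 0)
  }
  7 * basophils + 4 * spleen
}

#' ELTS (EUTOS long-term survival) prognostic score
#'
#' `0.0025 (age/10)^3 + 0.0615 spleen + 0.1052 blasts +
#' 0.4104 (platelets/1000)^-0.5`, with age in completed years (non-integer
#' ages are floored). Strictly decreasing in platelets; platelets must be
#' strictly positive.
#'
#' @inheritParams sokal_score
#' @return Numeric vector of score values.
#' @examples
#' elts_score(age = 40, spleen = 8, blasts = 1.5, platelets = 511)
#' @export
elts_score <- function(age, spleen, blasts, platelets, validate = TRUE) {
  if (validate) {
    check_numeric_field(age, "age", lower = 0)
    check_numeric_field(spleen, "spleen", lower = 0)
    check_numeric_field(blasts, "blasts", lower = 0, upper = 100)
    check_numeric_field(platelets, "platelets", lower = 0, strict_lower = TRUE)
  }
  0.0025 * (floor(age) / 10)^3 +
    0.0615 * spleen +
    0.1052 * blasts +
    0.4104 * (platelets / 1000)^(-0.5)
}

#' Map a continuous score value to its published risk category
#'
#' Boundary conventions: Sokal low < 0.8, intermediate in \[0.8, 1.2\], high
#' > 1.2. Hasford low <= 780, intermediate in (780, 1480\], high > 1480 (the
#' published integer cut-offs "<= 780 / 781–1480 / >= 1481" leave the open
#' intervals (780, 781) and (1480, 1481) unaddressed for non-integer scores;
#' the half-open convention is continuous, gap-free and agrees with the
#' integers). EUTOS low < 87, high >= 87 (never intermediate). ELTS low <=
#' 1.5680, intermediate in (1.5680, 2.2185\], high > 2.2185 (the shared
#' endpoint 1.5680 belongs to low).
#'
#' @param system One of `"sokal"`, `"hasford"`, `"eutos"`, `"elts"`.
#' @param value Numeric vector of finite score values.
#' @return Character vector with values in `"low"`, `"intermediate"`,
#'   `"high"`.
#' @examples
#' categorize("sokal", 0.8)   # "intermediate"
#' categorize("eutos", 87)    # "high"
#' categorize("elts", 1.5680) # "low"
#' @export
categorize <- function(system, value) {
  system <- match.arg(system, cml_systems)
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("score value must be finite numeric", call. = FALSE)
  }
  switch(system,
    sokal = ifelse(value < 0.8, "low",
                   ifelse(value <= 1.2, "intermediate", "high")),
    hasford = ifelse(value <= 780, "low",
                     ifelse(value <= 1480, "intermediate", "high")),
    eutos = ifelse(value < 87, "low", "high"),
    elts = ifelse(value <= 1.5680, "low",
                  ifelse(value <= 2.2185, "intermediate", "high"))
  )
}

#' Score a whole cohort with all four systems
#'
#' Appends, for each system, the continuous score value and its risk
#' category: columns `sokal_value`, `sokal_cat`, `hasford_value`,
#' `hasford_cat`, `eutos_value`, `eutos_cat`, `elts_value`, `elts_cat`.
#'
#' @param data Data frame with the baseline columns of
#'   [validate_baseline()]; other columns (e.g. `patient_id`,
#'   `mmr_achieved`) pass through untouched.
#' @param validate Validation strictness passed to [validate_baseline()];
#'   use `validate = FALSE` to skip checks entirely.
#' @return `data` as a tibble with the eight score columns appended.
#' @export
score_cohort <- function(data, validate = TRUE) {
  if (isTRUE(validate)) validate_baseline(data, strict = TRUE)
  out <- tibble::as_tibble(data)
  out$sokal_value <- sokal_score(out$age, out$spleen, out$platelets,
                                 out$blasts, validate = FALSE)
  out$sokal_cat <- categorize("sokal", out$sokal_value)
  out$hasford_value <- hasford_score(out$age, out$spleen, out$blasts,
                                     out$eosinophils, out$basophils,
                                     out$platelets, validate = FALSE)
  out$hasford_cat <- categorize("hasford", out$hasford_value)
  out$eutos_value <- eutos_score(out$basophils, out$spleen, validate = FALSE)
  out$eutos_cat <- categorize("eutos", out$eutos_value)
  out$elts_value <- elts_score(out$age, out$spleen, out$blasts,
                               out$platelets, validate = FALSE)
  out$elts_cat <- categorize("elts", out$elts_value)
  out
}

#' Four-system risk profile for a single patient
#'
#' @param patient A one-row data frame or named list with the baseline
#'   variables of [validate_baseline()].
#' @param validate Check inputs (default `TRUE`).
#' @return A tibble with one row per system: `system`, `value`, `category`.
#' @examples
#' risk_profile(list(age = 60, spleen = 10, platelets = 300, blasts = 4,
#'                   eosinophils = 1, basophils = 1))
#' @export
risk_profile <- function(patient, validate = TRUE) {
  patient <- as.data.frame(patient)
  if (nrow(patient) != 1) {
    stop("risk_profile() expects a single patient", call. = FALSE)
  }
  scored <- score_cohort(patient, validate = validate)
  tibble::tibble(
    system = cml_systems,
    value = c(scored$sokal_value, scored$hasford_value,
              scored$eutos_value, scored$elts_value),
    category = c(scored$sokal_cat, scored$hasford_cat,
                 scored$eutos_cat, scored$elts_cat)
  )
}
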