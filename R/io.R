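# CSV schema <-> internal column names. Spleen is cm below costal margin;
# decimal separator is '.'; mmr_achieved is 0, 1 or empty (empty = outcome
# unknown, record excluded from analysis).
cohort_schema <- c(
  patient_id = "patient_id",
  age_years = "age",
  spleen_cm_bcm = "spleen",
  platelets_10e9_L = "platelets",
  blasts_pct = "blasts",
  eosinophils_pct = "eosinophils",
  basophils_pct = "basophils",
  mmr_achieved = "mmr_achieved"
)

scored_schema_cols <- c("sokal_value", "sokal_cat", "hasford_value", "hasford_cat",
                        "eutos_value", "eutos_cat", "elts_value", "elts_cat")

#' Read a cohort CSV, validating records and logging exclusions
#'
#' Expected header (any column order): `patient_id`, `age_years`,
#' `spleen_cm_bcm`, `platelets_10e9_L`, `blasts_pct`, `eosinophils_pct`,
#' `basophils_pct`, `mmr_achieved`. An empty `mmr_achieved` field marks a
#' record whose molecular outcome is unknown; such records are set aside and
#' reported in the exclusion log rather than analyzed.
#'
#' @param path Path to the CSV file.
#' @param strict Validation strictness passed to [validate_baseline()]:
#'   `TRUE` rejects out-of-range values, `FALSE` downgrades them to warnings.
#' @return A list of class `cml_cohort_file`: `cohort` (analyzable records,
#'   internal column names), `excluded` (records lacking an MMR flag),
#'   `n_total`, `n_excluded`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("malformed cohort file: ", conditionMessage(e),
                             call. = FALSE)
  )
  expected <- names(cohort_schema)
  if (!setequal(names(raw), expected)) {
    stop("cohort header mismatch; expected columns: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  names(raw) <- cohort_schema[names(raw)]

  dup <- raw$patient_id[duplicated(raw$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("age", "spleen", "platelets", "blasts", "eosinophils", "basophils")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == "")
    if (any(bad) || anyNA(v)) {
      stop(sprintf("unparseable or missing numeric value in column '%s' (rows %s)",
                   col, paste(utils::head(which(is.na(v)), 5), collapse = ", ")),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  mmr_raw <- trimws(raw$mmr_achieved)
  known <- !(is.na(mmr_raw) | mmr_raw == "")
  if (!all(mmr_raw[known] %in% c("0", "1"))) {
    stop("mmr_achieved must be 0, 1 or empty", call. = FALSE)
  }
  raw$mmr_achieved <- ifelse(known, as.integer(mmr_raw), NA_integer_)

  validate_baseline(raw, strict = strict)
  cohort <- tibble::as_tibble(raw[known, , drop = FALSE])
  excluded <- tibble::as_tibble(raw[!known, , drop = FALSE])
  message(sprintf("read %d records from %s: %d analyzable, %d excluded (missing MMR%s)",
                  nrow(raw), path, nrow(cohort), nrow(excluded),
                  if (nrow(excluded) > 0) {
                    paste0(": ", paste(utils::head(excluded$patient_id, 10),
                                       collapse = ", "))
                  } else ""))
  structure(
    list(cohort = cohort, excluded = excluded,
         n_total = nrow(raw), n_excluded = nrow(excluded)),
    class = "cml_cohort_file"
  )
}

#' Write a cohort (optionally scored) to CSV
#'
#' Inverse of [read_cohort()]: internal columns are mapped back to the CSV
#' schema, unknown MMR flags become empty fields, and any score columns
#' appended by [score_cohort()] are written after the schema columns at full
#' precision.
#'
#' @param data Cohort tibble with internal column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  inv <- stats::setNames(names(cohort_schema), cohort_schema)
  out <- data
  keep <- intersect(names(out), c(cohort_schema, scored_schema_cols))
  out <- out[, keep, drop = FALSE]
  names(out)[names(out) %in% cohort_schema] <-
    inv[names(out)[names(out) %in% cohort_schema]]
  # 17 significant digits so doubles survive a write -> read round trip
  # bit-exactly (default CSV printing keeps only 15)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           formatC(out[[col]], digits = 17, format = "g"))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# --- report serialization ----------------------------------------------------

fmt2 <- function(x) ifelse(is.na(x), "n/a", sprintf("%.2f", x))

pattern_display <- function(label, system) {
  if (label == "high") return("High")
  if (system == "eutos") "Low" else "Low and intermediate"
}

# Plain-list form of a report, used for JSON serialization; accuracies at
# full machine precision are not stored (the accuracy operation itself is
# defined with half-up rounding to 2 dp), but cell counts allow lossless
# recomputation.
report_to_list <- function(report) {
  st <- lapply(report$strategy_tables, function(block) {
    lapply(block, function(e) {
      t <- e$table
      list(n_high_nommr = t$n_high_nommr, n_high_mmr = t$n_high_mmr,
           n_lowish_nommr = t$n_lowish_nommr, n_lowish_mmr = t$n_lowish_mmr,
           total = t$total, accuracy = e$accuracy)
    })
  })
  comb <- report$partition$combination
  list(
    schema_version = 1L,
    n = report$n, n_mmr = report$n_mmr, n_no_mmr = report$n_no_mmr,
    partition_strategy = report$strategy,
    strategy_tables = st,
    combination_table = as.data.frame(comb),
    n_consensus = report$partition$n_consensus,
    n_conflict = report$partition$n_conflict,
    subgroup_accuracies = as.data.frame(report$subgroup_accuracies),
    consensus_misclassification = report$consensus_misclassification
  )
}

#' Render a consistency report as markdown or JSON
#'
#' The markdown rendering mirrors the two published table layouts: a
#' per-system block of dichotomized contingency rows with accuracies for
#' both merging strategies, and the 16-row combination table with conflict
#' rows first, then consensus rows, followed by subgroup accuracies. Empty
#' subgroups render as `n/a`. The JSON rendering is machine-readable, round
#' trips losslessly through [jsonlite::fromJSON()], and carries all cell
#' counts.
#'
#' @param report A `cml_report` from [consistency_report()].
#' @param format `"md"` or `"json"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("md", "json")) {
  stopifnot(inherits(report, "cml_report"))
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  }
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add(sprintf("# CML risk-score consistency report (%d patients: %d MMR, %d no MMR)",
              report$n, report$n_mmr, report$n_no_mmr))
  add("")
  add("## Risk groups and accuracy by combined-grouping strategy")
  for (s in 1:2) {
    add("")
    add(sprintf("### Combined groups (%d): intermediate merged with %s", s,
                if (s == 1) "low" else "high"))
    add("")
    add("| Score | Risk group | n | Not achieving MMR | Achieving MMR | Accuracy |")
    add("|---|---|---|---|---|---|")
    block <- report$strategy_tables[[paste0("strategy_", s)]]
    for (sys in cml_systems) {
      t <- block[[sys]]$table
      hi_name <- if (sys == "eutos") "High"
                 else if (s == 1) "High" else "Intermediate and high"
      lo_name <- if (sys == "eutos") "Low"
                 else if (s == 1) "Low and intermediate" else "Low"
      add(sprintf("| %s | %s | %d | %d | %d | %s |", sys, hi_name,
                  t$n_high_nommr + t$n_high_mmr, t$n_high_nommr, t$n_high_mmr,
                  fmt2(block[[sys]]$accuracy)))
      add(sprintf("| %s | %s | %d | %d | %d | |", sys, lo_name,
                  t$n_lowish_nommr + t$n_lowish_mmr, t$n_lowish_nommr,
                  t$n_lowish_mmr))
    }
  }
  add("")
  add("## Consistency of risk labels across the four systems")
  add("")
  add(sprintf("Consensus group: %d patients (%s%%); conflict group: %d patients (%s%%).",
              report$partition$n_consensus,
              fmt2(round_half_up(100 * report$partition$n_consensus / report$n, 2)),
              report$partition$n_conflict,
              fmt2(round_half_up(100 * report$partition$n_conflict / report$n, 2))))
  add("")
  add("| Group | Sokal | Hasford | EUTOS | ELTS | Achieving MMR | Not achieving MMR |")
  add("|---|---|---|---|---|---|---|")
  comb <- report$partition$combination
  ord <- c(which(!comb$consensus), which(comb$consensus))
  for (i in ord) {
    add(sprintf("| %s | %s | %s | %s | %s | %d | %d |",
                if (comb$consensus[i]) "Consensus" else "Conflict",
                pattern_display(comb$sokal[i], "sokal"),
                pattern_display(comb$hasford[i], "hasford"),
                pattern_display(comb$eutos[i], "eutos"),
                pattern_display(comb$elts[i], "elts"),
                comb$n_mmr[i], comb$n_no_mmr[i]))
  }
  mis <- report$consensus_misclassification
  add("")
  add(sprintf(paste0("Consensus-group misclassifications: %d (%s%% of the whole ",
                     "cohort; %s%% of the consensus group)."),
              mis$n_misclassified, fmt2(mis$pct_of_cohort),
              fmt2(mis$pct_of_consensus)))
  add("")
  add("## Per-system accuracy by subgroup")
  add("")
  add("| System | All patients | Consensus | Conflict |")
  add("|---|---|---|---|")
  sa <- report$subgroup_accuracies
  for (i in seq_len(nrow(sa))) {
    add(sprintf("| %s | %s | %s | %s |", sa$system[i], fmt2(sa$all[i]),
                fmt2(sa$consensus[i]), fmt2(sa$conflict[i])))
  }
  add("")
  paste(L, collapse = "\n")
}
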