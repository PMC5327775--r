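#' Collapse a three-level risk category to two levels
#'
#' Two merging strategies for the intermediate category of Sokal, Hasford and
#' ELTS: strategy 1 merges intermediate with low (`"lowish"`), strategy 2
#' merges intermediate with high. EUTOS, which is already dichotomous, maps
#' identically under both.
#'
#' @param category Character vector with values `"low"`, `"intermediate"`,
#'   `"high"`.
#' @param strategy `1` (low+intermediate vs high) or `2` (low vs
#'   intermediate+high).
#' @return Character vector with values `"lowish"` or `"high"`.
#' @examples
#' dichotomize("intermediate", strategy = 1)  # "lowish"
#' dichotomize("intermediate", strategy = 2)  # "high"
#' @export
dichotomize <- function(category, strategy = 1) {
  strategy <- as.integer(strategy)
  if (!strategy %in% c(1L, 2L)) stop("strategy must be 1 or 2", call. = FALSE)
  bad <- !category %in% c("low", "intermediate", "high")
  if (any(bad)) {
    stop("unknown risk category: ", paste(unique(category[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (strategy == 1L) {
    ifelse(category == "high", "high", "lowish")
  } else {
    ifelse(category == "low", "lowish", "high")
  }
}

#' Predicted MMR status implied by a dichotomized risk label
#'
#' The accuracy convention: a high-risk label predicts failure to achieve
#' major molecular response, a lowish label predicts achievement. This is the
#' unique two-element mapping under which dichotomized labels act as a binary
#' classifier of MMR.
#'
#' @param label Character vector with values `"lowish"` or `"high"`.
#' @return Logical vector: `TRUE` means MMR achievement is predicted.
#' @export
predicted_mmr <- function(label) {
  bad <- !label %in% c("lowish", "high")
  if (any(bad)) {
    stop("unknown label: ", paste(unique(label[bad]), collapse = ", "),
         call. = FALSE)
  }
  label == "lowish"
}

#' Build the 2x2 risk-label by MMR contingency table
#'
#' @param label Character vector of dichotomized labels (`"lowish"` /
#'   `"high"`), one per patient.
#' @param mmr Logical (or 0/1) vector of observed MMR achievement; missing
#'   values are an error — records with unknown MMR must be excluded upstream
#'   (see [read_cohort()]).
#' @return An object of class `cml_contingency`: counts `n_high_nommr`,
#'   `n_high_mmr`, `n_lowish_nommr`, `n_lowish_mmr` and `total`.
#' @export
build_contingency <- function(label, mmr) {
  if (length(label) != length(mmr)) {
    stop("label and mmr must have equal length", call. = FALSE)
  }
  if (anyNA(mmr)) {
    stop("missing MMR flags; exclude incomplete records upstream before analysis",
         call. = FALSE)
  }
  bad <- !label %in% c("lowish", "high")
  if (any(bad)) stop("unknown label in contingency input", call. = FALSE)
  mmr <- as.logical(mmr)
  structure(
    list(
      n_high_nommr = sum(label == "high" & !mmr),
      n_high_mmr = sum(label == "high" & mmr),
      n_lowish_nommr = sum(label == "lowish" & !mmr),
      n_lowish_mmr = sum(label == "lowish" & mmr),
      total = length(label)
    ),
    class = "cml_contingency"
  )
}

#' Construct a contingency table directly from its four cells
#'
#' Convenience for working from published aggregate counts rather than
#' patient-level data.
#'
#' @param n_high_nommr,n_high_mmr,n_lowish_nommr,n_lowish_mmr Nonnegative
#'   integer cell counts.
#' @return A `cml_contingency` object.
#' @examples
#' accuracy(contingency_from_cells(11, 14, 22, 48))  # 62.11
#' @export
contingency_from_cells <- function(n_high_nommr, n_high_mmr,
                                   n_lowish_nommr, n_lowish_mmr) {
  cells <- c(n_high_nommr, n_high_mmr, n_lowish_nommr, n_lowish_mmr)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  structure(
    list(n_high_nommr = n_high_nommr, n_high_mmr = n_high_mmr,
         n_lowish_nommr = n_lowish_nommr, n_lowish_mmr = n_lowish_mmr,
         total = sum(cells)),
    class = "cml_contingency"
  )
}

#' @export
print.cml_contingency <- function(x, ...) {
  m <- matrix(c(x$n_high_nommr, x$n_high_mmr, x$n_lowish_nommr, x$n_lowish_mmr),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("high", "lowish"), c("no MMR", "MMR")))
  print(m)
  cat("total:", x$total, " accuracy:", format(accuracy(x), nsmall = 2), "%\n")
  invisible(x)
}

#' Classification accuracy of a risk-label contingency table
#'
#' Agreements are high-risk patients who did not achieve MMR plus lowish
#' patients who did; accuracy is `100 x agreements / total`, rounded half-up
#' to two decimals.
#'
#' @param table A `cml_contingency` object with `total > 0`.
#' @return Accuracy in percent (0–100), rounded to 2 decimal places.
#' @examples
#' accuracy(contingency_from_cells(4, 2, 29, 60))  # 67.37
#' @export
accuracy <- function(table) {
  stopifnot(inherits(table, "cml_contingency"))
  if (table$total <= 0) {
    stop("accuracy undefined for an empty table", call. = FALSE)
  }
  round_half_up(100 * (table$n_high_nommr + table$n_lowish_mmr) / table$total, 2)
}

#' Enumerate all joint risk-label combinations across scoring systems
#'
#' With `S` systems of `N` labels each there are `N^S` joint patterns (16 for
#' four dichotomized systems). Order is deterministic: the first system is
#' the most significant digit and, for two labels, `"lowish"` sorts before
#' `"high"`; the all-lowish pattern is row 1 and the all-high pattern is the
#' last row.
#'
#' @param n_systems Number of scoring systems (>= 1).
#' @param labels_per_system Number of labels per system (>= 1).
#' @param systems Optional character vector of column names, length
#'   `n_systems`; defaults to [cml_systems] when `n_systems == 4`, otherwise
#'   `system_1 ... system_S`.
#' @param labels Optional label set, length `labels_per_system`; defaults to
#'   `c("lowish", "high")` for two labels, otherwise `"L1" ... "LN"`.
#' @return A tibble with `labels_per_system^n_systems` rows, one column per
#'   system.
#' @examples
#' nrow(enumerate_combinations(4, 2))  # 16
#' nrow(enumerate_combinations(2, 3))  # 9
#' @export
enumerate_combinations <- function(n_systems, labels_per_system,
                                   systems = NULL, labels = NULL) {
  n_systems <- as.integer(n_systems)
  labels_per_system <- as.integer(labels_per_system)
  if (is.na(n_systems) || n_systems < 1 ||
      is.na(labels_per_system) || labels_per_system < 1) {
    stop("n_systems and labels_per_system must be positive integers",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (labels_per_system == 2) c("lowish", "high")
              else paste0("L", seq_len(labels_per_system))
  }
  stopifnot(length(labels) == labels_per_system)
  if (is.null(systems)) {
    systems <- if (n_systems == 4) cml_systems
               else paste0("system_", seq_len(n_systems))
  }
  stopifnot(length(systems) == n_systems)
  # expand.grid varies the first factor fastest; feed systems in reverse so
  # the first system ends up most significant, then restore column order.
  grid <- do.call(expand.grid,
                  c(rep(list(labels), n_systems),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(n_systems)), drop = FALSE]
  ord <- do.call(order, lapply(grid, function(col) match(col, labels)))
  grid <- grid[ord, , drop = FALSE]
  names(grid) <- systems
  rownames(grid) <- NULL
  tibble::as_tibble(grid)
}

# Internal: per-patient dichotomized label columns for a scored cohort.
cohort_labels <- function(scored, strategy) {
  cat_cols <- paste0(cml_systems, "_cat")
  missing_cols <- setdiff(cat_cols, names(scored))
  if (length(missing_cols) > 0) {
    stop("cohort is not scored; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  incomplete <- Reduce(`|`, lapply(cat_cols, function(cc) is.na(scored[[cc]])))
  if (any(incomplete)) {
    ids <- if ("patient_id" %in% names(scored)) {
      scored$patient_id[incomplete]
    } else {
      which(incomplete)
    }
    stop("incomplete risk profile for patient(s): ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  labs <- lapply(cat_cols, function(cc) dichotomize(scored[[cc]], strategy))
  names(labs) <- cml_systems
  tibble::as_tibble(labs)
}

#' Partition a scored cohort into consensus and conflict groups
#'
#' After dichotomizing each system's category under the given strategy, a
#' patient belongs to the consensus group when all four labels agree and to
#' the conflict group otherwise. The full combination table counts patients
#' (split by MMR outcome) in each of the 16 joint label patterns.
#'
#' @param scored A scored cohort ([score_cohort()]) with a complete
#'   `mmr_achieved` column (0/1).
#' @param strategy Intermediate-merging strategy passed to [dichotomize()];
#'   defaults to 1, the higher-accuracy grouping under which the consensus
#'   analysis is defined.
#' @return An object of class `cml_partition`: `membership` (per-patient
#'   labels, MMR and consensus flag), `combination` (16-row tibble with
#'   pattern columns, `n_mmr`, `n_no_mmr`, `consensus`), `n_consensus`,
#'   `n_conflict`, `strategy`.
#' @export
consistency_partition <- function(scored, strategy = 1) {
  if (!"mmr_achieved" %in% names(scored)) {
    stop("cohort lacks an mmr_achieved column", call. = FALSE)
  }
  if (anyNA(scored$mmr_achieved)) {
    stop("missing MMR flags; exclude incomplete records upstream before analysis",
         call. = FALSE)
  }
  labs <- cohort_labels(scored, strategy)
  mmr <- as.logical(scored$mmr_achieved)
  consensus <- labs$sokal == labs$hasford &
    labs$hasford == labs$eutos & labs$eutos == labs$elts
  membership <- tibble::tibble(
    patient_id = if ("patient_id" %in% names(scored)) scored$patient_id
                 else as.character(seq_len(nrow(scored))),
    labs,
    consensus = consensus,
    mmr = mmr
  )
  patterns <- enumerate_combinations(4, 2)
  key <- function(df) paste(df$sokal, df$hasford, df$eutos, df$elts)
  idx <- match(key(membership), key(patterns))
  combination <- patterns
  combination$n_mmr <- as.integer(tabulate(idx[mmr], nbins = nrow(patterns)))
  combination$n_no_mmr <- as.integer(tabulate(idx[!mmr], nbins = nrow(patterns)))
  combination$consensus <- patterns$sokal == patterns$hasford &
    patterns$hasford == patterns$eutos & patterns$eutos == patterns$elts
  structure(
    list(membership = membership, combination = combination,
         n_consensus = sum(consensus), n_conflict = sum(!consensus),
         strategy = as.integer(strategy)),
    class = "cml_partition"
  )
}

#' @export
print.cml_partition <- function(x, ...) {
  n <- x$n_consensus + x$n_conflict
  cat(sprintf("Consensus/conflict partition (strategy %d): %d patients\n",
              x$strategy, n))
  cat(sprintf("  consensus: %d (%.2f%%)   conflict: %d (%.2f%%)\n",
              x$n_consensus, 100 * x$n_consensus / n,
              x$n_conflict, 100 * x$n_conflict / n))
  invisible(x)
}

#' Accuracy of one scoring system within a subgroup of the partition
#'
#' @param partition A `cml_partition` from [consistency_partition()].
#' @param subgroup `"all"`, `"consensus"` or `"conflict"`.
#' @param system One of [cml_systems].
#' @return Accuracy in percent, with the underlying `cml_contingency` table
#'   attached as attribute `"table"`.
#' @export
subgroup_accuracy <- function(partition, subgroup = c("all", "consensus", "conflict"),
                              system = cml_systems) {
  stopifnot(inherits(partition, "cml_partition"))
  subgroup <- match.arg(subgroup)
  system <- match.arg(system)
  m <- partition$membership
  keep <- switch(subgroup, all = rep(TRUE, nrow(m)),
                 consensus = m$consensus, conflict = !m$consensus)
  if (!any(keep)) {
    stop(sprintf("accuracy undefined: %s subgroup is empty", subgroup),
         call. = FALSE)
  }
  tab <- build_contingency(m[[system]][keep], m$mmr[keep])
  structure(accuracy(tab), table = tab)
}

#' Full consistency report for a scored cohort
#'
#' Assembles, from patient-level data: per-system 2x2 contingency tables and
#' accuracies under both intermediate-merging strategies; the 16-row joint
#' label combination table; the consensus/conflict split; per-system
#' accuracies in the whole cohort and in each subgroup; and the consensus
#' misclassification count under both denominators (share of the whole
#' cohort and share of the consensus group).
#'
#' @inheritParams consistency_partition
#' @param strategy Strategy used for the partition and subgroup accuracies
#'   (the per-system contingency block always covers both strategies).
#' @return An object of class `cml_report`; see [render_report()] for
#'   markdown and JSON serialization.
#' @export
consistency_report <- function(scored, strategy = 1) {
  if (!"mmr_achieved" %in% names(scored)) {
    stop("cohort lacks an mmr_achieved column", call. = FALSE)
  }
  if (anyNA(scored$mmr_achieved)) {
    stop("missing MMR flags; exclude incomplete records upstream before analysis",
         call. = FALSE)
  }
  mmr <- as.logical(scored$mmr_achieved)
  strategy_tables <- lapply(c(1L, 2L), function(s) {
    labs <- cohort_labels(scored, s)
    per_system <- lapply(cml_systems, function(sys) {
      tab <- build_contingency(labs[[sys]], mmr)
      list(table = tab, accuracy = accuracy(tab))
    })
    names(per_system) <- cml_systems
    per_system
  })
  names(strategy_tables) <- c("strategy_1", "strategy_2")

  part <- consistency_partition(scored, strategy = strategy)
  subgroups <- c("all", "consensus", "conflict")
  acc <- sapply(subgroups, function(g) {
    sapply(cml_systems, function(sys) {
      m <- part$membership
      keep <- switch(g, all = rep(TRUE, nrow(m)),
                     consensus = m$consensus, conflict = !m$consensus)
      if (!any(keep)) return(NA_real_)
      unclass(subgroup_accuracy(part, g, sys))[1]
    })
  })
  subgroup_accuracies <- tibble::tibble(
    system = cml_systems,
    all = acc[, "all"], consensus = acc[, "consensus"],
    conflict = acc[, "conflict"]
  )

  m <- part$membership
  cons <- m[m$consensus, , drop = FALSE]
  mis <- sum(predicted_mmr(cons$sokal) != cons$mmr)
  n <- nrow(m)
  structure(
    list(
      n = n, n_mmr = sum(mmr), n_no_mmr = sum(!mmr),
      strategy = as.integer(strategy),
      strategy_tables = strategy_tables,
      partition = part,
      subgroup_accuracies = subgroup_accuracies,
      consensus_misclassification = list(
        n_misclassified = mis,
        pct_of_cohort = round_half_up(100 * mis / n, 2),
        pct_of_consensus = if (part$n_consensus > 0) {
          round_half_up(100 * mis / part$n_consensus, 2)
        } else {
          NA_real_
        }
      )
    ),
    class = "cml_report"
  )
}

#' @export
print.cml_report <- function(x, ...) {
  cat(render_report(x, format = "md"))
  invisible(x)
}
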