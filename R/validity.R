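# Result qualification: the decision rules that classify each bidirectional
# result as valid, qualified (below the detection limit) or invalid (NV),
# plus the pre-assay analytical-sensitivity triage.

#' Analytical sensitivity triage
#'
#' Before the assay, a 40 nM test solution is injected; the observed peak
#' area decides whether the analytical method is sensitive enough to resolve
#' a given permeability. A peak area of at least 300,000 is required to
#' support a target Papp of 1e-6 cm/s, and at least 3,000,000 for a target
#' of 1e-7 cm/s.
#'
#' @param peak_area_40nM observed peak area of the 40 nM test solution
#'   (vectorized).
#' @param target_papp `1e-6` or `1e-7` (cm/s).
#' @return logical: feasible at the requested target.
#' @export
#' @examples
#' check_analytical_sensitivity(3e5, 1e-6)  # TRUE
#' check_analytical_sensitivity(3e5, 1e-7)  # FALSE
check_analytical_sensitivity <- function(peak_area_40nM, target_papp = 1e-6) {
  if (any(peak_area_40nM < 0)) stop_pf("peak area must be >= 0")
  threshold <- if (isTRUE(all.equal(target_papp, 1e-6))) {
    3e5
  } else if (isTRUE(all.equal(target_papp, 1e-7))) {
    3e6
  } else {
    stop_pf("target_papp must be 1e-6 or 1e-7 cm/s")
  }
  peak_area_40nM >= threshold
}

# Evaluate the decision rules for one result row; returns list(status, reasons)
.assess_one <- function(row, rules) {
  reasons <- character(0)

  # (1) replicate variability, evaluated on Papp replicate values
  rel <- c(row$rel_diff_ab, row$rel_diff_ba)
  if (any(!is.na(rel) & rel > rules$replicate_rel_diff_max)) {
    return(list(status = "invalid", reasons = "high_variability"))
  }

  # (2) mass-balance recovery, two complementary regimes
  rec_ab <- row$recovery_ab
  rec_ba <- row$recovery_ba
  both <- !is.na(rec_ab) && !is.na(rec_ba)
  if (both && abs(rec_ab - rec_ba) < rules$recovery_similarity_max_diff) {
    if (min(rec_ab, rec_ba) < rules$bidirectional_recovery_min) {
      return(list(status = "invalid", reasons = "poor_recovery_bidirectional"))
    }
  } else {
    recs <- c(rec_ab, rec_ba)
    if (any(!is.na(recs) & recs < rules$single_direction_recovery_min)) {
      return(list(status = "invalid", reasons = "poor_recovery_single"))
    }
  }

  # (3) detection limit: surviving censored results are qualified
  if (isTRUE(row$below_lod_ab) || isTRUE(row$below_lod_ba)) {
    return(list(status = "qualified", reasons = "below_lod"))
  }
  list(status = "valid", reasons = character(0))
}

#' Qualify bidirectional results as valid, qualified or invalid
#'
#' Applies the result-qualification decision rules in fixed precedence:
#' \enumerate{
#'   \item high data variability — any direction whose replicate relative
#'     difference exceeds 50% of the mean invalidates the result
#'     (`high_variability`);
#'   \item poor recovery — when both directions are present and their
#'     recoveries are similar (difference below 25 percentage points), a
#'     minimum recovery below 40% invalidates
#'     (`poor_recovery_bidirectional`); when the recoveries are dissimilar
#'     or only one direction is present, any direction below 65%
#'     invalidates (`poor_recovery_single`);
#'   \item poor detection sensitivity — surviving results whose receiver
#'     signal was below the detection limit are `qualified` with the
#'     permeability reported as an upper bound (`below_lod`);
#'   \item everything else is `valid`.
#' }
#' Invalidity takes precedence over qualification: a result failing recovery
#' is invalid even if it is also below the detection limit.
#'
#' @param results data.frame from [bidirectional_results()].
#' @param rules thresholds from [validity_rules()].
#' @return `results` with `validity` and `reasons` filled (reasons joined
#'   with `";"`; empty for valid results).
#' @export
assess_validity <- function(results, rules = validity_rules()) {
  stopifnot(inherits(rules, "validity_rules"))
  for (i in seq_len(nrow(results))) {
    verdict <- .assess_one(results[i, ], rules)
    results$validity[i] <- verdict$status
    results$reasons[i] <- paste(verdict$reasons, collapse = ";")
    if (verdict$status != "valid") {
      pf_log("info", sprintf("assess_validity: %s/%s -> %s (%s)",
                             results$compound_id[i], results$method[i],
                             verdict$status, results$reasons[i]))
    }
  }
  results
}

# Molecular-weight bin from interval bounds; NA when undecidable
.bin_mw <- function(lower, upper) {
  mapply(function(lo, hi) {
    if (!is.na(hi) && hi <= 500) return("<500")
    if (!is.na(lo) && !is.na(hi) && lo > 500 && hi <= 700) return("500-700")
    if (!is.na(lo) && lo >= 700) return(">700")
    NA_character_
  }, lower, upper)
}

#' Validity distribution by compound group
#'
#' Percentage of valid / qualified / invalid results, overall or grouped by
#' molecular-weight bin (`<500`, `500-700`, `>700`) or by the number of
#' Lipinski rule violations.
#'
#' @param results assessed results from [assess_validity()].
#' @param compounds compound descriptor table (see [read_compound_table()]);
#'   required for any grouping other than `"none"`.
#' @param grouping `"none"`, `"mw_bins"` or `"lipinski_count"`.
#' @return data.frame `group, percent_valid, percent_qualified,
#'   percent_invalid, n` (percentages per group sum to 100 up to rounding).
#' @export
summarize_validity <- function(results, compounds = NULL,
                               grouping = c("none", "mw_bins",
                                            "lipinski_count")) {
  grouping <- match.arg(grouping)
  stopifnot(all(results$validity %in% c("valid", "qualified", "invalid")))
  if (grouping == "none") {
    grp <- rep("all", nrow(results))
  } else {
    if (is.null(compounds)) stop_pf("grouping requires a compound table")
    idx <- match(results$compound_id, compounds$compound_id)
    unknown <- is.na(idx)
    if (any(unknown)) {
      warning(sprintf("%d result(s) with unknown compound id excluded",
                      sum(unknown)))
      pf_log("warn", sprintf("summarize_validity: dropped ids %s",
                             paste(unique(results$compound_id[unknown]),
                                   collapse = ", ")))
      results <- results[!unknown, , drop = FALSE]
      idx <- idx[!unknown]
    }
    grp <- if (grouping == "mw_bins") {
      mw <- compounds$mw[idx]
      .bin_mw(mw, mw)
    } else {
      lip <- count_lipinski_violations(compounds[idx, , drop = FALSE])
      as.character(lip$violations)
    }
  }
  tab <- lapply(split(seq_along(grp), grp), function(ix) {
    v <- results$validity[ix]
    data.frame(
      group = grp[ix[1]],
      percent_valid = 100 * mean(v == "valid"),
      percent_qualified = 100 * mean(v == "qualified"),
      percent_invalid = 100 * mean(v == "invalid"),
      n = length(ix), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, tab)
  rownames(out) <- NULL
  out
}
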