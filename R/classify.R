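# Compound classification: Lipinski/bRo5 annotation, permeability and
# solubility binning, and cut-off-based confusion-matrix evaluation of
# absorption prediction.

# Decide one rule against a (possibly unbounded) descriptor interval.
# Returns "violated", "compliant" or "unknown". Boundary values comply
# (a descriptor exactly at the threshold is not a violation).
.rule_interval <- function(lower, upper, threshold) {
  if (!is.na(lower) && lower > threshold) return("violated")
  if (!is.na(upper) && upper <= threshold) return("compliant")
  "unknown"
}

#' Count Lipinski rule violations
#'
#' Evaluates the four rules — MW > 500, cLogP > 5, HBD > 5, HBA > 10 — with
#' boundary values counting as compliant. Descriptors may be point values
#' (columns `mw`, `clogp`, `hbd`, `hba`) or intervals (`mw_lower`/`mw_upper`
#' etc., `NA` for an open side); a rule undecidable from an interval is
#' counted as unknown, not as a violation. `bro5` is `TRUE` when at least
#' two rules are decidably violated; if a `lipinski_class` column is present
#' its label overrides the computed flag (used for compounds whose
#' descriptors are only partially disclosed).
#'
#' @param compounds data.frame of descriptors (point and/or interval
#'   columns).
#' @return data.frame `violations` (0-4, decided violations only),
#'   `unknown` (count of undecidable rules), `bro5` (logical).
#' @export
#' @examples
#' count_lipinski_violations(
#'   data.frame(mw = 455, clogp = 5, hbd = 1, hba = 5))  # 0 violations
count_lipinski_violations <- function(compounds) {
  n <- nrow(compounds)
  get_bounds <- function(point, lower, upper) {
    lo <- hi <- rep(NA_real_, n)
    if (point %in% names(compounds)) {
      lo <- hi <- as.numeric(compounds[[point]])
    }
    if (lower %in% names(compounds)) {
      has <- !is.na(compounds[[lower]])
      lo[has] <- as.numeric(compounds[[lower]][has])
    }
    if (upper %in% names(compounds)) {
      has <- !is.na(compounds[[upper]])
      hi[has] <- as.numeric(compounds[[upper]][has])
    }
    list(lo = lo, hi = hi)
  }
  mw <- get_bounds("mw", "mw_lower", "mw_upper")
  lp <- get_bounds("clogp", "clogp_lower", "clogp_upper")
  hbd <- get_bounds("hbd", "hbd_lower", "hbd_upper")
  hba <- get_bounds("hba", "hba_lower", "hba_upper")
  thresholds <- c(500, 5, 5, 10)
  bounds <- list(mw, lp, hbd, hba)

  violations <- integer(n)
  unknown <- integer(n)
  for (i in seq_len(n)) {
    verdicts <- vapply(seq_along(bounds), function(j) {
      .rule_interval(bounds[[j]]$lo[i], bounds[[j]]$hi[i], thresholds[j])
    }, character(1))
    violations[i] <- sum(verdicts == "violated")
    unknown[i] <- sum(verdicts == "unknown")
  }
  bro5 <- violations >= 2
  if ("lipinski_class" %in% names(compounds)) {
    lab <- compounds$lipinski_class
    bro5[!is.na(lab)] <- lab[!is.na(lab)] == "bRo5"
  }
  data.frame(violations = violations, unknown = unknown, bro5 = bro5)
}

#' Bin apparent permeability into low / medium / high
#'
#' Permeability classes: low below 3e-6 cm/s, medium between 3 and
#' 10 x 1e-6 cm/s, high above 1e-5 cm/s. Values exactly at an edge fall in
#' the medium (closed) bin. A below-detection upper bound is binnable only
#' when the bound itself lies in the low bin (the true value then does
#' too); otherwise the result is `NA` (unbinnable).
#'
#' @param papp numeric Papp values (cm/s).
#' @param qualifier `"exact"` or `"less_than"`, recycled.
#' @param cfg a [classification_config()].
#' @return ordered factor with levels `low < medium < high` (`NA` =
#'   unbinnable).
#' @export
#' @examples
#' bin_papp(c(2e-6, 5e-6, 1.5e-5))
bin_papp <- function(papp, qualifier = "exact", cfg = classification_config()) {
  edges <- cfg$papp_bin_edges
  qualifier <- rep_len(qualifier, length(papp))
  lab <- ifelse(papp < edges[1], "low",
                ifelse(papp <= edges[2], "medium", "high"))
  unbinnable <- qualifier == "less_than" & lab != "low"
  lab[unbinnable | !qualifier %in% c("exact", "less_than")] <- NA
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Bin solubility
#'
#' @param solubility_uM numeric solubilities (uM).
#' @param cfg a [classification_config()]; the default single edge at
#'   200 uM yields classes `<200` and `>=200`.
#' @return factor of bin labels.
#' @export
bin_solubility <- function(solubility_uM, cfg = classification_config()) {
  edges <- cfg$solubility_bin_edges
  labs <- c(paste0("<", edges[1]),
            if (length(edges) > 1) {
              paste0(head(edges, -1), "-", edges[-1])
            },
            paste0(">=", edges[length(edges)]))
  cut(solubility_uM, breaks = c(0, edges, Inf), labels = labs, right = FALSE)
}

#' Confusion matrix for cut-off-based absorption prediction
#'
#' Classifies paired (predictor, fafg) observations into quadrants. In
#' `papp` mode a positive prediction is a permeability at or above the
#' cut-off; in `er` mode a positive prediction is an efflux ratio strictly
#' below the cut-off (ties are negative). The actual outcome is positive
#' when fafg is at or above its cut-off. Percentages are over all n pairs;
#' `total_true = tp + tn`.
#'
#' @param predictor numeric predictor values (Papp in cm/s, or ER).
#' @param fafg numeric absorption values, pre-clipped at the floor.
#' @param mode `"papp"` or `"er"`.
#' @param predictor_cutoff cut-off on the predictor.
#' @param fafg_cutoff cut-off on fafg.
#' @return list of class `"confusion_result"`: `n`, counts
#'   (`tp_n`, `tn_n`, `fp_n`, `fn_n`), percentages (`tp`, `tn`, `fp`, `fn`),
#'   `total_true`.
#' @export
#' @examples
#' confusion_matrix(c(2e-5, 1e-6), c(0.9, 0.1), "papp", 1e-5, 0.5)
confusion_matrix <- function(predictor, fafg, mode = c("papp", "er"),
                             predictor_cutoff, fafg_cutoff) {
  mode <- match.arg(mode)
  keep <- is.finite(predictor) & is.finite(fafg)
  predictor <- predictor[keep]; fafg <- fafg[keep]
  n <- length(predictor)
  if (n == 0) stop_pf("no finite pairs for confusion matrix")
  pred_pos <- if (mode == "papp") {
    predictor >= predictor_cutoff
  } else {
    predictor < predictor_cutoff
  }
  actual_pos <- fafg >= fafg_cutoff
  tp <- sum(pred_pos & actual_pos)
  tn <- sum(!pred_pos & !actual_pos)
  fp <- sum(pred_pos & !actual_pos)
  fn <- sum(!pred_pos & actual_pos)
  pct <- function(k) 100 * k / n
  structure(
    list(n = n, mode = mode,
         predictor_cutoff = predictor_cutoff, fafg_cutoff = fafg_cutoff,
         tp_n = tp, tn_n = tn, fp_n = fp, fn_n = fn,
         tp = pct(tp), tn = pct(tn), fp = pct(fp), fn = pct(fn),
         total_true = pct(tp) + pct(tn)),
    class = "confusion_result"
  )
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf("<confusion: %s cut-off %g / fafg %g, n = %d>\n",
              x$mode, x$predictor_cutoff, x$fafg_cutoff, x$n))
  cat(sprintf("  TP %.1f%%  TN %.1f%%  FP %.1f%%  FN %.1f%%  (total true %.1f%%)\n",
              x$tp, x$tn, x$fp, x$fn, x$total_true))
  invisible(x)
}

#' Classification report over a grid of cut-off pairs
#'
#' Runs [confusion_matrix()] for every requested (predictor, fafg) cut-off
#' pair and returns a tidy report mirroring a cut-off comparison table.
#'
#' @inheritParams confusion_matrix
#' @param cutoff_pairs data.frame with columns `predictor_cutoff` and
#'   `fafg_cutoff`, one row per scenario.
#' @return data.frame `mode, predictor_cutoff, fafg_cutoff, n, tp, tn, fp,
#'   fn, total_true`.
#' @export
classification_report <- function(predictor, fafg, mode, cutoff_pairs) {
  rows <- lapply(seq_len(nrow(cutoff_pairs)), function(i) {
    cm <- confusion_matrix(predictor, fafg, mode,
                           cutoff_pairs$predictor_cutoff[i],
                           cutoff_pairs$fafg_cutoff[i])
    data.frame(mode = mode,
               predictor_cutoff = cm$predictor_cutoff,
               fafg_cutoff = cm$fafg_cutoff, n = cm$n,
               tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
               total_true = cm$total_true)
  })
  do.call(rbind, rows)
}
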