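# Permeability core: apparent permeability, recovery, replicate
# aggregation, efflux ratio and between-method concordance.
#
# Unit model: LC-MS peak-area responses are converted to concentration
# equivalents (response / response_factor, in uM) before any formula. The
# permeated amount dQ is the receiver concentration times the receiver
# volume (mol); the driving concentration is the mean of the end-of-run
# donor concentration and the nominal start concentration, which corrects
# for donor depletion over the incubation. Papp = dQ / (dt * A * meanC),
# in cm/s.

#' Apparent permeability from a well-level transport record
#'
#' Computes Papp (cm/s) for each row of a transport table. When the receiver
#' response lies below the detection limit (`lod_response`), the value is
#' computed with the detection limit substituted for the receiver response
#' and flagged with qualifier `"less_than"`: the reported number is then an
#' upper bound on the true permeability.
#'
#' @param records validated transport records (see
#'   [validate_transport_records()]); a one-row data.frame works for a single
#'   record.
#' @param denominator `"averaged"` (default) uses the mean of the end donor
#'   concentration and the nominal start concentration; `"c0"` uses the
#'   nominal start concentration only (the classic sink-condition estimator,
#'   exposed for bias comparisons).
#' @return `records` with columns `papp_cm_s` and `papp_qualifier`
#'   (`"exact"` or `"less_than"`) appended.
#' @export
#' @examples
#' rec <- data.frame(
#'   compound_id = "cpd", method = "standard", direction = "AB",
#'   replicate = 1, t_inc_s = 3600, area_cm2 = 0.11, c0_uM = 3,
#'   donor_response_end = 2.7e6, receiver_response_end = 3e4,
#'   response_factor = 1e6, lod_response = 0, v_donor_uL = 100,
#'   v_receiver_uL = 200)
#' compute_papp(rec)$papp_cm_s  # ~5.32e-6 cm/s
compute_papp <- function(records, denominator = c("averaged", "c0")) {
  denominator <- match.arg(denominator)
  records <- validate_transport_records(records)
  below <- records$receiver_response_end < records$lod_response
  resp_recv <- ifelse(below, records$lod_response,
                      records$receiver_response_end)

  conc_recv <- resp_recv / records$response_factor              # uM
  conc_donor <- records$donor_response_end / records$response_factor
  dq <- conc_recv * .UM_TO_MOL_PER_CM3 *
    records$v_receiver_uL * .UL_TO_CM3                          # mol
  mean_c <- if (denominator == "averaged") {
    (conc_donor + records$c0_uM) / 2
  } else {
    records$c0_uM
  }
  mean_c <- mean_c * .UM_TO_MOL_PER_CM3                         # mol/cm^3
  if (any(mean_c == 0)) {
    stop_pf("row %d: zero driving concentration; Papp undefined",
            which(mean_c == 0)[1])
  }
  records$papp_cm_s <- dq / (records$t_inc_s * records$area_cm2 * mean_c)
  records$papp_qualifier <- ifelse(below, "less_than", "exact")
  records
}

#' Mass-balance recovery from a well-level transport record
#'
#' Fraction of the dosed amount found in donor plus receiver at the end of
#' the incubation, in percent. By default recovery is computed on amounts
#' (concentration times compartment volume) so that mass balance is
#' conservative when the two compartment volumes differ;
#' `mode = "response"` reproduces the plain response-ratio reading
#' `(C_Acceptor + C_Donor) / C0 * 100` with all three terms as
#' concentration equivalents, volume-unaware.
#'
#' @inheritParams compute_papp
#' @param mode `"amount"` (default) or `"response"`.
#' @param censor_at_lod if `TRUE`, a below-detection receiver response enters
#'   the balance at the detection limit (an upper bound), so that censoring
#'   alone cannot depress recovery. Used by the validity engine.
#' @return `records` with a `recovery_pct` column appended.
#' @export
compute_recovery <- function(records, mode = c("amount", "response"),
                             censor_at_lod = FALSE) {
  mode <- match.arg(mode)
  records <- validate_transport_records(records)
  resp_recv <- records$receiver_response_end
  if (censor_at_lod) {
    resp_recv <- pmax(resp_recv, records$lod_response)
  }
  conc_recv <- resp_recv / records$response_factor
  conc_donor <- records$donor_response_end / records$response_factor
  records$recovery_pct <- if (mode == "amount") {
    100 * (conc_recv * records$v_receiver_uL +
             conc_donor * records$v_donor_uL) /
      (records$c0_uM * records$v_donor_uL)
  } else {
    100 * (conc_recv + conc_donor) / records$c0_uM
  }
  records
}

#' Aggregate replicate permeability values for one direction
#'
#' Studies are run at least in technical duplicate and mean values are used
#' for the final analysis. The aggregate qualifier is conservative: if any
#' replicate is a below-detection upper bound, so is the mean. The replicate
#' relative difference is `|max - min| / mean * 100`.
#'
#' @param papp numeric vector of replicate Papp values (cm/s).
#' @param qualifier character vector (`"exact"`/`"less_than"`), one per
#'   replicate.
#' @param recovery_pct numeric vector of replicate recoveries (percent).
#' @return list with `papp_mean`, `qualifier`, `recovery_pct` (mean),
#'   `replicate_rel_diff_pct` (`NA` for a single replicate), `below_lod`,
#'   `n_replicates`.
#' @export
#' @examples
#' aggregate_replicates(c(4e-6, 8e-6), c("exact", "exact"), c(90, 94))
aggregate_replicates <- function(papp, qualifier = rep("exact", length(papp)),
                                 recovery_pct = rep(NA_real_, length(papp))) {
  if (length(papp) == 0) stop_pf("no replicate values to aggregate")
  stopifnot(length(qualifier) == length(papp),
            length(recovery_pct) == length(papp))
  m <- mean(papp)
  rel_diff <- if (length(papp) >= 2) {
    if (m == 0) 0 else abs(max(papp) - min(papp)) / m * 100
  } else {
    NA_real_
  }
  below <- any(qualifier == "less_than")
  list(
    papp_mean = m,
    qualifier = if (below) "less_than" else "exact",
    recovery_pct = mean(recovery_pct),
    replicate_rel_diff_pct = rel_diff,
    below_lod = below,
    n_replicates = length(papp)
  )
}

#' Efflux ratio with qualifier propagation
#'
#' ER = Papp(B-to-A) / Papp(A-to-B) on direction-mean permeabilities.
#' Below-detection bounds propagate conservatively: a censored B-to-A mean
#' makes the ratio an upper bound (`"less_than"`), a censored A-to-B mean a
#' lower bound (`"greater_than"`); both censored, or a zero A-to-B mean,
#' make the ratio `"undefined"`.
#'
#' @param ab,ba aggregates from [aggregate_replicates()] for the A-to-B and
#'   B-to-A directions.
#' @return list with `er` (numeric, `NA` when undefined) and `er_qualifier`
#'   (`"exact"`, `"less_than"`, `"greater_than"` or `"undefined"`).
#' @export
compute_efflux_ratio <- function(ab, ba) {
  ab_cens <- identical(ab$qualifier, "less_than")
  ba_cens <- identical(ba$qualifier, "less_than")
  if ((ab_cens && ba_cens) || ab$papp_mean == 0) {
    return(list(er = NA_real_, er_qualifier = "undefined"))
  }
  er <- ba$papp_mean / ab$papp_mean
  qual <- if (ba_cens) "less_than" else if (ab_cens) "greater_than" else "exact"
  list(er = er, er_qualifier = qual)
}

#' Per-compound bidirectional results from a transport table
#'
#' Runs the permeability core over a full transport table: per-row Papp and
#' recovery, replicate aggregation per compound x method x direction, and
#' the efflux ratio per compound x method. Validity status is left as
#' `"unassessed"`; apply [assess_validity()] to fill it.
#'
#' @inheritParams compute_papp
#' @param recovery_mode passed to [compute_recovery()].
#' @return data.frame with one row per compound x method: `compound_id`,
#'   `method`, `papp_ab`, `papp_ab_qualifier`, `papp_ba`,
#'   `papp_ba_qualifier`, `er`, `er_qualifier`, `recovery_ab`, `recovery_ba`,
#'   `rel_diff_ab`, `rel_diff_ba`, `below_lod_ab`, `below_lod_ba`,
#'   `validity`, `reasons`.
#' @export
bidirectional_results <- function(records,
                                  recovery_mode = c("amount", "response")) {
  recovery_mode <- match.arg(recovery_mode)
  records <- compute_papp(records)
  records <- compute_recovery(records, mode = recovery_mode,
                              censor_at_lod = TRUE)
  key <- interaction(records$compound_id, records$method, drop = TRUE)
  out <- lapply(split(records, key), function(grp) {
    aggs <- lapply(c(AB = "AB", BA = "BA"), function(d) {
      sub <- grp[grp$direction == d, , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      aggregate_replicates(sub$papp_cm_s, sub$papp_qualifier,
                           sub$recovery_pct)
    })
    er <- if (!is.null(aggs$AB) && !is.null(aggs$BA)) {
      compute_efflux_ratio(aggs$AB, aggs$BA)
    } else {
      list(er = NA_real_, er_qualifier = "undefined")
    }
    fld <- function(a, f) if (is.null(a)) NA else a[[f]]
    data.frame(
      compound_id = grp$compound_id[1], method = grp$method[1],
      papp_ab = fld(aggs$AB, "papp_mean"),
      papp_ab_qualifier = fld(aggs$AB, "qualifier"),
      papp_ba = fld(aggs$BA, "papp_mean"),
      papp_ba_qualifier = fld(aggs$BA, "qualifier"),
      er = er$er, er_qualifier = er$er_qualifier,
      recovery_ab = fld(aggs$AB, "recovery_pct"),
      recovery_ba = fld(aggs$BA, "recovery_pct"),
      rel_diff_ab = fld(aggs$AB, "replicate_rel_diff_pct"),
      rel_diff_ba = fld(aggs$BA, "replicate_rel_diff_pct"),
      below_lod_ab = isTRUE(fld(aggs$AB, "below_lod")),
      below_lod_ba = isTRUE(fld(aggs$BA, "below_lod")),
      validity = "unassessed", reasons = "",
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  pf_log("info", sprintf("bidirectional_results: %d records -> %d results",
                         nrow(records), nrow(res)))
  res
}

#' Between-method concordance of permeability or efflux ratio
#'
#' Pairs two result sets by `compound_id` (only pairs exact in both sets
#' enter), and summarizes the fold differences (`max(x, y)/min(x, y)`), the
#' fraction within 3-fold and the squared Pearson correlation. Because
#' permeabilities span orders of magnitude, R^2 is computed on log10 values
#' by default.
#'
#' @param a,b results from [bidirectional_results()].
#' @param quantity `"papp_ab"` or `"er"`.
#' @param r2_scale `"log10"` (default) or `"linear"`.
#' @return list of class `"concordance_summary"`: `n_pairs`,
#'   `frac_within_3fold`, `r2`, `fold_diffs`.
#' @export
compare_methods <- function(a, b, quantity = c("papp_ab", "er"),
                            r2_scale = c("log10", "linear")) {
  quantity <- match.arg(quantity)
  r2_scale <- match.arg(r2_scale)
  qual_col <- if (quantity == "papp_ab") "papp_ab_qualifier" else "er_qualifier"
  a <- a[a[[qual_col]] %in% "exact" & is.finite(a[[quantity]]), ]
  b <- b[b[[qual_col]] %in% "exact" & is.finite(b[[quantity]]), ]
  shared <- intersect(a$compound_id, b$compound_id)
  if (length(shared) == 0) stop_pf("no shared exact pairs to compare")
  x <- a[[quantity]][match(shared, a$compound_id)]
  y <- b[[quantity]][match(shared, b$compound_id)]
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  fold <- pmax(x, y) / pmin(x, y)
  r2 <- if (length(x) >= 2) {
    if (r2_scale == "log10") cor(log10(x), log10(y))^2 else cor(x, y)^2
  } else {
    NA_real_
  }
  structure(
    list(n_pairs = length(x),
         frac_within_3fold = mean(fold <= 3),
         r2 = r2, fold_diffs = fold),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance: %d pairs, %.1f%% within 3-fold, R^2 = %.3f>\n",
              x$n_pairs, 100 * x$frac_within_3fold, x$r2))
  invisible(x)
}
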