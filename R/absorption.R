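# Back-calculation of approximated intestinal absorption (fafg) from
# rodent IV/PO pharmacokinetic summaries, under the well-stirred liver
# model with a blood:plasma ratio of 1 and the fraction escaping gut
# metabolism assumed close to 1.

#' Hepatic availability from systemic clearance
#'
#' Well-stirred model: `fh = 1 - Cl / Qh`, with the species hepatic blood
#' flow Qh of 5.2 L/h/kg (mouse) or 3.8 L/h/kg (rat). Blood and plasma
#' clearance are used interchangeably (blood:plasma ratio assumed 1).
#'
#' @param cl clearance in L/h/kg (vectorized).
#' @param species `"mouse"` or `"rat"` (recycled).
#' @param epsilon_floor if `NULL` (default), a clearance at or above the
#'   hepatic blood flow is an error (the compound cannot enter the
#'   absorption back-calculation); a small positive number instead floors
#'   fh at that value.
#' @return hepatic availability fh in (0, 1].
#' @export
#' @examples
#' hepatic_availability(1.9, "rat")  # 0.5
hepatic_availability <- function(cl, species, epsilon_floor = NULL) {
  if (any(cl < 0)) stop_pf("clearance must be >= 0")
  qh <- qh_constant(species)
  fh <- 1 - cl / qh
  if (any(fh <= 0)) {
    if (is.null(epsilon_floor)) {
      stop_pf("clearance exceeds hepatic blood flow (fh <= 0) for %d record(s)",
              sum(fh <= 0))
    }
    stopifnot(epsilon_floor > 0)
    fh <- pmax(fh, epsilon_floor)
  }
  fh
}

#' Oral bioavailability from dose-normalized AUCs
#'
#' `F_PO = (AUC_PO * D_IV) / (AUC_IV * D_PO)`.
#'
#' @param pk one or more PK records (data.frame with `auc_iv`, `d_iv`,
#'   `auc_po`, `d_po`; see [read_pk_table()]).
#' @return F_PO (fraction; can exceed 1 for noisy inputs).
#' @export
oral_bioavailability <- function(pk) {
  if (any(pk$auc_iv <= 0) || any(pk$d_po <= 0)) {
    stop_pf("auc_iv and d_po must be > 0: F_PO undefined")
  }
  (pk$auc_po * pk$d_iv) / (pk$auc_iv * pk$d_po)
}

#' Approximated intestinal absorption (fafg) from a PK record
#'
#' `fafg = F_PO / fh`. Raw values below the clip floor (0.01) are set to the
#' floor and flagged `clipped_low`; values above 1 — possible from noise or
#' hepatic-availability misestimation, while fafg is a fraction by
#' definition — are capped at 1 and flagged `capped_high`. Multi-species
#' data are computed per record; no cross-species averaging is performed.
#'
#' @param pk validated PK records (see [read_pk_table()]).
#' @param clip_floor lower clip for reported fafg, default 0.01.
#' @param epsilon_floor passed to [hepatic_availability()].
#' @return data.frame `compound_id, species, fh, f_po, fafg, clipped_low,
#'   capped_high`.
#' @export
#' @examples
#' pk <- data.frame(compound_id = "cpd", species = "rat", matrix = "blood",
#'                  cl_L_per_h_kg = 1.9, auc_iv = 50, d_iv = 1,
#'                  auc_po = 100, d_po = 5)
#' estimate_fafg(pk)  # F_PO 0.4 / fh 0.5 -> fafg 0.8
estimate_fafg <- function(pk, clip_floor = 0.01, epsilon_floor = NULL) {
  fh <- hepatic_availability(pk$cl_L_per_h_kg, pk$species, epsilon_floor)
  f_po <- oral_bioavailability(pk)
  raw <- f_po / fh
  clipped <- raw < clip_floor
  capped <- raw > 1
  fafg <- pmin(pmax(raw, clip_floor), 1)
  data.frame(
    compound_id = pk$compound_id, species = pk$species,
    fh = fh, f_po = f_po, fafg = fafg,
    clipped_low = clipped, capped_high = capped,
    stringsAsFactors = FALSE
  )
}
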