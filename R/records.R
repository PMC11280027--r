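# Domain record schemas, validation and assay configuration objects.

.TRANSPORT_COLS <- c(
  "compound_id", "method", "direction", "replicate", "t_inc_s", "area_cm2",
  "c0_uM", "donor_response_end", "receiver_response_end", "response_factor",
  "lod_response", "v_donor_uL", "v_receiver_uL"
)
.TRANSPORT_OPTIONAL <- "area_cm2"
.METHODS <- c("standard", "bsa_modified", "equilibrated")
.DIRECTIONS <- c("AB", "BA")

#' Default filter surface area of a 96-well transwell insert (cm^2)
#' @export
DEFAULT_AREA_CM2 <- 0.11

#' Default compartment volumes (uL): apical 100, basolateral 200
#'
#' The assay protocol does not fix the assay-phase volumes, so they are
#' mandatory record fields; these defaults mirror the culture volumes of the
#' 96-well transwell format and are used by the simulator and by
#' [method_config()]. The transport direction decides which side is the
#' donor: apical for A-to-B, basolateral for B-to-A.
#' @export
DEFAULT_VOLUMES_UL <- c(apical = 100, basolateral = 200)

#' Validate a table of well-level transport records
#'
#' Checks the documented transport-table schema: one row per replicate of one
#' direction of one transwell run. Fails with an informative error naming the
#' offending column or row.
#'
#' @param records data.frame with the transport-table columns
#'   (`compound_id, method, direction, replicate, t_inc_s, area_cm2, c0_uM,
#'   donor_response_end, receiver_response_end, response_factor, lod_response,
#'   v_donor_uL, v_receiver_uL`). `area_cm2` may be absent, in which case the
#'   default 0.11 cm^2 is filled in.
#' @return the validated data.frame (invisibly modified: defaults filled,
#'   `method`/`direction` as character).
#' @export
validate_transport_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(setdiff(.TRANSPORT_COLS, .TRANSPORT_OPTIONAL),
                          names(records))
  if (length(missing_cols)) {
    stop_pf("transport table is missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  if (!"area_cm2" %in% names(records)) {
    records$area_cm2 <- if (nrow(records)) DEFAULT_AREA_CM2 else numeric(0)
  }
  records$area_cm2[is.na(records$area_cm2)] <- DEFAULT_AREA_CM2
  if (nrow(records) == 0) return(records)
  records$method <- as.character(records$method)
  records$direction <- as.character(records$direction)
  records$compound_id <- as.character(records$compound_id)

  bad_method <- !records$method %in% .METHODS
  if (any(bad_method)) {
    stop_pf("row %d: unknown method '%s' (expected %s)",
            which(bad_method)[1], records$method[which(bad_method)[1]],
            paste(.METHODS, collapse = "/"))
  }
  bad_dir <- !records$direction %in% .DIRECTIONS
  if (any(bad_dir)) {
    stop_pf("row %d: unknown direction '%s' (expected AB/BA)",
            which(bad_dir)[1], records$direction[which(bad_dir)[1]])
  }

  num_cols <- setdiff(.TRANSPORT_COLS, c("compound_id", "method", "direction"))
  for (col in num_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      stop_pf("column '%s' must be numeric", col)
    }
    if (anyNA(v)) {
      stop_pf("row %d: missing value in column '%s'", which(is.na(v))[1], col)
    }
  }
  check_pos <- function(col, strict = TRUE) {
    v <- records[[col]]
    bad <- if (strict) v <= 0 else v < 0
    if (any(bad)) {
      stop_pf("row %d: column '%s' must be %s (got %g)",
              which(bad)[1], col, if (strict) "> 0" else ">= 0",
              v[which(bad)[1]])
    }
  }
  for (col in c("replicate", "t_inc_s", "area_cm2", "c0_uM",
                "response_factor", "v_donor_uL", "v_receiver_uL")) {
    check_pos(col, strict = TRUE)
  }
  for (col in c("donor_response_end", "receiver_response_end",
                "lod_response")) {
    check_pos(col, strict = FALSE)
  }
  records
}

#' Assay method configuration
#'
#' Returns the protocol parameters of one of the three bidirectional
#' transport study designs: the cassetted 1 uM `standard` method (no BSA, no
#' pre-incubation), the 3 uM `bsa_modified` method (1% BSA throughout, no
#' pre-incubation) and the 3 uM `equilibrated` method (60 min pre-incubation
#' without BSA, then a 60 min main incubation with BSA and a mandatory
#' compound-specific analytical tune).
#'
#' @param label one of `"standard"`, `"bsa_modified"`, `"equilibrated"`.
#' @param ... named overrides for individual fields.
#' @return list of class `"method_config"` with fields `label`,
#'   `concentration_uM`, `cassette_size`, `bsa_pre`, `bsa_main`,
#'   `pre_incubation_s`, `main_incubation_s`, `compound_tune_required`.
#' @export
#' @examples
#' method_config("equilibrated")
method_config <- function(label = c("standard", "bsa_modified", "equilibrated"),
                          ...) {
  label <- match.arg(label)
  cfg <- switch(label,
    standard = list(
      label = "standard", concentration_uM = 1, cassette_size = 3,
      bsa_pre = FALSE, bsa_main = FALSE, pre_incubation_s = 0,
      main_incubation_s = 3600, compound_tune_required = FALSE
    ),
    bsa_modified = list(
      label = "bsa_modified", concentration_uM = 3, cassette_size = 1,
      bsa_pre = FALSE, bsa_main = TRUE, pre_incubation_s = 0,
      main_incubation_s = 3600, compound_tune_required = FALSE
    ),
    equilibrated = list(
      label = "equilibrated", concentration_uM = 3, cassette_size = 1,
      bsa_pre = FALSE, bsa_main = TRUE, pre_incubation_s = 3600,
      main_incubation_s = 3600, compound_tune_required = TRUE
    )
  )
  cfg <- modifyList(cfg, list(...))
  if (cfg$main_incubation_s <= 0) stop_pf("main_incubation_s must be > 0")
  if (cfg$cassette_size < 1) stop_pf("cassette_size must be >= 1")
  if (cfg$label == "equilibrated") {
    if (cfg$pre_incubation_s <= 0 || cfg$bsa_pre || !cfg$bsa_main) {
      stop_pf(paste0("equilibrated method requires pre_incubation_s > 0, ",
                     "bsa_pre = FALSE and bsa_main = TRUE"))
    }
  }
  class(cfg) <- "method_config"
  cfg
}

#' @export
print.method_config <- function(x, ...) {
  cat(sprintf("<method_config: %s>\n", x$label))
  cat(sprintf("  concentration: %g uM, cassette size: %d\n",
              x$concentration_uM, x$cassette_size))
  cat(sprintf("  BSA pre/main: %s/%s, pre-incubation: %g s, main: %g s\n",
              x$bsa_pre, x$bsa_main, x$pre_incubation_s, x$main_incubation_s))
  invisible(x)
}

#' Hepatic blood flow constant (L/h/kg)
#'
#' Species-specific hepatic blood flow used in the well-stirred hepatic
#' availability calculation: 5.2 L/h/kg for mouse and 3.8 L/h/kg for rat.
#'
#' @param species `"mouse"` or `"rat"`.
#' @return hepatic blood flow in L/h/kg.
#' @export
#' @examples
#' qh_constant("rat")
qh_constant <- function(species) {
  qh <- c(mouse = 5.2, rat = 3.8)
  species <- as.character(species)
  bad <- !species %in% names(qh)
  if (any(bad)) {
    stop_pf("unsupported species '%s'; supported: %s",
            species[bad][1], paste(names(qh), collapse = ", "))
  }
  unname(qh[species])
}

#' Validity rule thresholds
#'
#' Thresholds of the result-qualification decision rules: mass-balance
#' recovery below 65% in a single direction, or below 40% in bidirectional
#' studies where the two recoveries are similar (difference below 25
#' percentage points), invalidates a result; a replicate difference exceeding
#' 50% of the mean flags high variability.
#'
#' @param single_direction_recovery_min percent, default 65.
#' @param bidirectional_recovery_min percent, default 40.
#' @param recovery_similarity_max_diff percentage points, default 25.
#' @param replicate_rel_diff_max percent of the replicate mean, default 50.
#' @return list of class `"validity_rules"`.
#' @export
validity_rules <- function(single_direction_recovery_min = 65,
                           bidirectional_recovery_min = 40,
                           recovery_similarity_max_diff = 25,
                           replicate_rel_diff_max = 50) {
  vals <- c(single_direction_recovery_min, bidirectional_recovery_min,
            recovery_similarity_max_diff, replicate_rel_diff_max)
  if (any(vals <= 0) || any(vals > 100)) {
    stop_pf("all validity thresholds must lie in (0, 100]")
  }
  structure(
    list(single_direction_recovery_min = single_direction_recovery_min,
         bidirectional_recovery_min = bidirectional_recovery_min,
         recovery_similarity_max_diff = recovery_similarity_max_diff,
         replicate_rel_diff_max = replicate_rel_diff_max),
    class = "validity_rules"
  )
}

#' Classification cut-offs and bin edges
#'
#' Container for the permeability, efflux, absorption and solubility
#' cut-offs used in binning and confusion-matrix analyses: permeability bins
#' low/medium/high at 3 and 10 x 1e-6 cm/s, efflux-ratio cut-offs 2 and 5,
#' fafg cut-offs 0.3 and 0.5 with a clip floor of 0.01, and a solubility bin
#' edge at 200 uM.
#'
#' @param papp_bin_edges cm/s, default `c(3e-6, 1e-5)`.
#' @param papp_cutoffs cm/s, default `c(3e-6, 1e-5)`.
#' @param er_cutoffs dimensionless, default `c(2, 5)`.
#' @param fafg_cutoffs fractions, default `c(0.3, 0.5)`.
#' @param fafg_clip_floor fraction, default 0.01.
#' @param solubility_bin_edges uM, default `c(200)` (yields a "<200 uM" class).
#' @return list of class `"classification_config"`.
#' @export
classification_config <- function(papp_bin_edges = c(3e-6, 1e-5),
                                  papp_cutoffs = c(3e-6, 1e-5),
                                  er_cutoffs = c(2, 5),
                                  fafg_cutoffs = c(0.3, 0.5),
                                  fafg_clip_floor = 0.01,
                                  solubility_bin_edges = 200) {
  chk <- function(x, nm) {
    if (any(x <= 0) || is.unsorted(x, strictly = TRUE)) {
      stop_pf("%s must be positive and strictly increasing", nm)
    }
  }
  chk(papp_bin_edges, "papp_bin_edges"); chk(papp_cutoffs, "papp_cutoffs")
  chk(er_cutoffs, "er_cutoffs"); chk(fafg_cutoffs, "fafg_cutoffs")
  chk(solubility_bin_edges, "solubility_bin_edges")
  structure(
    list(papp_bin_edges = papp_bin_edges, papp_cutoffs = papp_cutoffs,
         er_cutoffs = er_cutoffs, fafg_cutoffs = fafg_cutoffs,
         fafg_clip_floor = fafg_clip_floor,
         solubility_bin_edges = solubility_bin_edges),
    class = "classification_config"
  )
}
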