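# End-to-end orchestration: simulate or read inputs, run every analysis
# stage in order, write all report tables plus a run manifest.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to transport/compound/PK tables) or
#' `simulate` (a [cohort_config()]) must be given.
#'
#' @param inputs named list with `transport` (path or named list of paths,
#'   one per method), `compounds`, `pk` (paths; `pk` optional).
#' @param simulate a [cohort_config()].
#' @param rules a [validity_rules()].
#' @param classification a [classification_config()].
#' @param recovery_mode `"amount"` or `"response"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the simulate branch (overrides the cohort
#'   config seed when given).
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            rules = validity_rules(),
                            classification = classification_config(),
                            recovery_mode = "amount",
                            out_dir = tempfile("permaflow_run_"),
                            seed = NULL, log_level = "warn") {
  if (is.null(inputs) == is.null(simulate)) {
    stop_pf("exactly one of 'inputs' or 'simulate' must be provided")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_config"))
  structure(
    list(inputs = inputs, simulate = simulate, rules = rules,
         classification = classification, recovery_mode = recovery_mode,
         out_dir = out_dir, seed = seed, log_level = log_level),
    class = "pipeline_config"
  )
}

.write_stage <- function(df, out_dir, name, counts) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  counts[[name]] <- nrow(df)
  pf_log("info", sprintf("stage %s: wrote %d rows", name, nrow(df)))
  counts
}

#' Run the full analysis pipeline
#'
#' Stage order: per-compound bidirectional results, validity assessment and
#' report, absorption back-calculation, between-method concordance (when at
#' least two methods are present), binned absorption summaries, and
#' confusion reports for all configured cut-off pairs. Every table is
#' written to `cfg$out_dir` together with `manifest.json` (configuration
#' echo, seed, package version, per-stage row counts).
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) list with all result tables and the manifest.
#' @export
#' @examples
#' \donttest{
#' cc <- cohort_config(n_compounds = 8, methods = "equilibrated", seed = 1)
#' res <- run_end_to_end(pipeline_config(simulate = cc))
#' }
run_end_to_end <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  old_opt <- options(permaflow.log_level = cfg$log_level)
  on.exit(options(old_opt))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    if (!is.null(cfg$seed)) sim_cfg$seed <- as.integer(cfg$seed)
    cohort <- generate_cohort(sim_cfg)
    transport <- cohort$transport
    compounds <- cohort$compounds
    pk <- cohort$pk
    counts <- .write_stage(cohort$ground_truth, cfg$out_dir,
                           "ground_truth", counts)
    for (m in names(transport)) {
      counts <- .write_stage(transport[[m]], cfg$out_dir,
                             paste0("transport_", m), counts)
    }
  } else {
    tr <- cfg$inputs$transport
    if (is.character(tr) && length(tr) == 1) {
      tab <- read_transport_table(tr)
      transport <- split(tab, tab$method)
    } else {
      transport <- lapply(tr, read_transport_table)
    }
    compounds <- if (!is.null(cfg$inputs$compounds)) {
      read_compound_table(cfg$inputs$compounds)
    } else {
      NULL
    }
    pk <- if (!is.null(cfg$inputs$pk)) read_pk_table(cfg$inputs$pk) else NULL
  }
  if (sum(vapply(transport, nrow, 0L)) == 0) {
    stop_pf("stage bidirectional_results: no transport records")
  }

  # --- permeability + validity -------------------------------------------
  results <- lapply(transport, function(tab) {
    assess_validity(bidirectional_results(tab, cfg$recovery_mode), cfg$rules)
  })
  all_results <- do.call(rbind, results)
  rownames(all_results) <- NULL
  counts <- .write_stage(all_results, cfg$out_dir, "results", counts)

  validity_report <- do.call(rbind, lapply(names(results), function(m) {
    rep_m <- summarize_validity(results[[m]], compounds,
                                if (is.null(compounds)) "none" else "mw_bins")
    cbind(method = m, rep_m)
  }))
  counts <- .write_stage(validity_report, cfg$out_dir,
                         "validity_report", counts)

  # --- absorption ---------------------------------------------------------
  absorption <- NULL
  if (!is.null(pk) && nrow(pk)) {
    absorption <- estimate_fafg(pk, cfg$classification$fafg_clip_floor)
    counts <- .write_stage(absorption, cfg$out_dir, "absorption", counts)
  }

  # --- concordance --------------------------------------------------------
  concordance <- NULL
  if (length(results) >= 2) {
    pairs <- utils::combn(names(results), 2, simplify = FALSE)
    concordance <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(c("papp_ab", "er"), function(q) {
        cs <- tryCatch(compare_methods(results[[pr[1]]], results[[pr[2]]], q),
                       error = function(e) NULL)
        if (is.null(cs)) return(NULL)
        data.frame(method_a = pr[1], method_b = pr[2], quantity = q,
                   n_pairs = cs$n_pairs,
                   frac_within_3fold = cs$frac_within_3fold, r2 = cs$r2)
      }))
    }))
    if (!is.null(concordance)) {
      counts <- .write_stage(concordance, cfg$out_dir, "concordance", counts)
    }
  }

  # --- binned summaries + confusion reports -------------------------------
  binned <- NULL
  confusion <- NULL
  if (!is.null(absorption)) {
    primary <- results[[length(results)]]  # last configured method
    ok <- primary$validity %in% c("valid") &
      primary$papp_ab_qualifier == "exact"
    idx <- match(primary$compound_id[ok], absorption$compound_id)
    papp_ok <- primary$papp_ab[ok][!is.na(idx)]
    er_ok <- primary$er[ok][!is.na(idx)]
    er_exact <- primary$er_qualifier[ok][!is.na(idx)] == "exact"
    fafg <- absorption$fafg[idx[!is.na(idx)]]

    if (length(papp_ok)) {
      bins <- bin_papp(papp_ok, cfg = cfg$classification)
      bs <- binned_summary(bins, fafg, pairwise_tests = TRUE)
      binned <- bs$summary
      counts <- .write_stage(binned, cfg$out_dir, "binned_fafg", counts)

      papp_pairs <- expand.grid(
        predictor_cutoff = cfg$classification$papp_cutoffs,
        fafg_cutoff = cfg$classification$fafg_cutoffs
      )
      confusion <- classification_report(papp_ok, fafg, "papp", papp_pairs)
      if (any(er_exact)) {
        er_pairs <- expand.grid(
          predictor_cutoff = cfg$classification$er_cutoffs,
          fafg_cutoff = cfg$classification$fafg_cutoffs
        )
        confusion <- rbind(
          confusion,
          classification_report(er_ok[er_exact], fafg[er_exact], "er",
                                er_pairs)
        )
      }
      counts <- .write_stage(confusion, cfg$out_dir, "confusion", counts)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("permaflow")),
    r_version = as.character(getRversion()),
    seed = cfg$seed %||% (if (!is.null(cfg$simulate)) cfg$simulate$seed),
    recovery_mode = cfg$recovery_mode,
    methods = names(results),
    stage_counts = counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(results = all_results, validity_report = validity_report,
                 absorption = absorption, concordance = concordance,
                 binned = binned, confusion = confusion,
                 manifest = manifest, out_dir = cfg$out_dir))
}
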