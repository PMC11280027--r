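# Mechanistic transwell simulator: a linear four-compartment mass-transfer
# model (donor | cell | receiver | plastic) integrated with a fixed-step
# explicit scheme. Provides ground-truth-labelled synthetic read-outs for
# every pipeline stage.
#
# Model. The monolayer is two identical membrane barriers in series, each
# with clearance CL_m = 2 * P * A, so the series permeability equals the
# ground-truth P of the run direction. The cell compartment has an
# effective exchange capacity cap = 3e-5 * (1 + kp_cell) cm^3: kp_cell
# scales the amount the monolayer must load before transport reaches steady
# state and is the mechanistic source of the lag that short, non
# pre-incubated runs under-measure. Plastic adsorption is first-order and
# irreversible from donor and receiver, scaled by the unbound fraction
# fu_bsa when BSA is present in that incubation phase (BSA is modelled only
# through reduced adsorption; transmembrane flux is unchanged). The
# pre-incubation phase, when configured, runs with the same dynamics, after
# which donor and receiver are replaced by fresh solutions while the cell
# and plastic loads persist.

.CELL_CAPACITY_BASE_CM3 <- 3e-5

#' Ground-truth simulated compound
#'
#' @param compound_id identifier.
#' @param papp_true_ab,papp_true_ba true apparent permeabilities (cm/s) for
#'   the absorptive and secretory directions.
#' @param kp_cell dimensionless cell-partition factor (>= 0); scales the
#'   cell-loading lag.
#' @param k_ads first-order plastic adsorption rate (1/s) per compartment.
#' @param fu_bsa unbound fraction in 1% BSA, in (0, 1].
#' @param response_factor LC-MS response (peak area) per uM.
#' @param lod_response detection limit in peak-area units.
#' @param noise_cv multiplicative lognormal noise CV on terminal responses.
#' @return list of class `"sim_compound"`.
#' @export
sim_compound <- function(compound_id, papp_true_ab, papp_true_ba = papp_true_ab,
                         kp_cell = 0, k_ads = 0, fu_bsa = 1,
                         response_factor = 1e7, lod_response = 5000,
                         noise_cv = 0) {
  stopifnot(papp_true_ab >= 0, papp_true_ba >= 0, kp_cell >= 0, k_ads >= 0,
            fu_bsa > 0, fu_bsa <= 1, response_factor > 0, lod_response >= 0,
            noise_cv >= 0)
  structure(
    list(compound_id = as.character(compound_id),
         papp_true_ab = papp_true_ab, papp_true_ba = papp_true_ba,
         kp_cell = kp_cell, k_ads = k_ads, fu_bsa = fu_bsa,
         response_factor = response_factor, lod_response = lod_response,
         noise_cv = noise_cv),
    class = "sim_compound"
  )
}

# One incubation phase. state = amounts (mol) in donor, cell, receiver,
# plastic. Columns of the step matrix sum to 1 exactly, so total mass is
# conserved to floating precision.
.run_phase <- function(state, papp, area, v_donor, v_receiver, cap,
                       k_ads, t_total, dt) {
  if (t_total <= 0) return(state)
  cl_m <- 2 * papp * area
  rates <- matrix(0, 4, 4)
  add_flow <- function(from, to, rate) {
    rates[to, from] <<- rates[to, from] + rate
    rates[from, from] <<- rates[from, from] - rate
  }
  add_flow(1, 2, cl_m / v_donor)
  add_flow(2, 1, cl_m / cap)
  add_flow(2, 3, cl_m / cap)
  add_flow(3, 2, cl_m / v_receiver)
  add_flow(1, 4, k_ads)
  add_flow(3, 4, k_ads)

  max_rate <- max(-diag(rates))
  if (max_rate * dt > 0.5) {
    stop_pf(paste0("integrator instability: dt * rate = %.3g > 0.5; ",
                   "reduce dt below %.3g s"),
            max_rate * dt, 0.5 / max_rate)
  }
  n_steps <- ceiling(t_total / dt)
  step <- diag(4) + dt * rates
  nm <- names(state)
  for (i in seq_len(n_steps)) {
    state <- step %*% state
  }
  setNames(drop(state), nm)
}

#' Simulate a bidirectional transwell run
#'
#' Generates well-level transport records (both directions, replicated) for
#' one compound under one method configuration. The dynamics are
#' deterministic; only the terminal LC-MS responses carry multiplicative
#' lognormal noise, drawn per replicate. Records whose true receiver
#' response falls below `lod_response` are emitted with that below-limit
#' response, so downstream analysis treats them as censored.
#'
#' @param compound a [sim_compound()].
#' @param method a [method_config()].
#' @param seed integer seed; `NULL` uses the current RNG state (so a caller
#'   can drive many simulations from one outer seed).
#' @param n_replicates technical replicates per direction, default 2.
#' @param dt integration step (s), default 1.
#' @param volumes_uL named vector `c(apical=, basolateral=)`; the direction
#'   decides which side is donor.
#' @param area_cm2 filter area, default 0.11.
#' @return transport-record data.frame (see [read_transport_table()]) with
#'   attribute `"phase_states"`: per direction, the dosed amount and the
#'   compartment amounts (mol) after each phase, for mass-balance checks.
#' @export
#' @examples
#' cpd <- sim_compound("cpd1", papp_true_ab = 5e-6)
#' rec <- simulate_transwell(cpd, method_config("standard"), seed = 1)
#' compute_papp(rec)$papp_cm_s
simulate_transwell <- function(compound, method = method_config("standard"),
                               seed = NULL, n_replicates = 2, dt = 1,
                               volumes_uL = DEFAULT_VOLUMES_UL,
                               area_cm2 = DEFAULT_AREA_CM2) {
  stopifnot(inherits(compound, "sim_compound"),
            inherits(method, "method_config"), n_replicates >= 1, dt > 0)
  with_seed(seed, {
    cap <- .CELL_CAPACITY_BASE_CM3 * (1 + compound$kp_cell)
    c0 <- method$concentration_uM
    fu_pre <- if (method$bsa_pre) compound$fu_bsa else 1
    fu_main <- if (method$bsa_main) compound$fu_bsa else 1

    rows <- list()
    states <- list()
    for (dir in c("AB", "BA")) {
      if (dir == "AB") {
        v_d <- volumes_uL[["apical"]] * .UL_TO_CM3
        v_r <- volumes_uL[["basolateral"]] * .UL_TO_CM3
        v_d_uL <- volumes_uL[["apical"]]; v_r_uL <- volumes_uL[["basolateral"]]
        papp <- compound$papp_true_ab
      } else {
        v_d <- volumes_uL[["basolateral"]] * .UL_TO_CM3
        v_r <- volumes_uL[["apical"]] * .UL_TO_CM3
        v_d_uL <- volumes_uL[["basolateral"]]; v_r_uL <- volumes_uL[["apical"]]
        papp <- compound$papp_true_ba
      }
      dose <- c0 * .UM_TO_MOL_PER_CM3 * v_d
      state <- c(donor = dose, cell = 0, receiver = 0, plastic = 0)

      pre_final <- NULL
      if (method$pre_incubation_s > 0) {
        state <- .run_phase(state, papp, area_cm2, v_d, v_r, cap,
                            compound$k_ads * fu_pre,
                            method$pre_incubation_s, dt)
        pre_final <- state
        # fresh donor solution and receiver buffer; cell/plastic persist
        state[1] <- dose
        state[3] <- 0
      }
      state <- .run_phase(state, papp, area_cm2, v_d, v_r, cap,
                          compound$k_ads * fu_main,
                          method$main_incubation_s, dt)
      states[[dir]] <- list(dose = dose, pre_final = pre_final,
                            main_final = state)

      conc_donor_uM <- (state[1] / v_d) / .UM_TO_MOL_PER_CM3
      conc_recv_uM <- (state[3] / v_r) / .UM_TO_MOL_PER_CM3
      for (rep_i in seq_len(n_replicates)) {
        noise <- rlnorm_cv(2, compound$noise_cv)
        rows[[length(rows) + 1]] <- data.frame(
          compound_id = compound$compound_id, method = method$label,
          direction = dir, replicate = rep_i,
          t_inc_s = method$main_incubation_s, area_cm2 = area_cm2,
          c0_uM = c0,
          donor_response_end =
            conc_donor_uM * compound$response_factor * noise[1],
          receiver_response_end =
            conc_recv_uM * compound$response_factor * noise[2],
          response_factor = compound$response_factor,
          lod_response = compound$lod_response,
          v_donor_uL = v_d_uL, v_receiver_uL = v_r_uL,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "phase_states") <- states
    out
  })
}

#' Generate rodent PK summary records with a known fafg ground truth
#'
#' Inverts the absorption back-calculation: the clearance is
#' `(1 - fh_true) * Qh(species)`, the IV AUC is `d_iv / cl`, and the PO AUC
#' is `fafg_true * fh_true * d_po / cl`, so that at zero noise
#' [estimate_fafg()] recovers `fafg_true` exactly.
#'
#' @param compound_id character vector.
#' @param fafg_true true absorption fractions in (0, 1].
#' @param fh_true true hepatic availabilities in (0, 1) (1 is excluded:
#'   zero clearance makes the IV AUC undefined).
#' @param species `"mouse"` or `"rat"` (recycled).
#' @param d_iv,d_po doses (recycled).
#' @param noise_cv multiplicative lognormal noise CV on both AUCs.
#' @param seed integer seed, or `NULL` for the ambient RNG state.
#' @return PK record data.frame (see [read_pk_table()]).
#' @export
#' @examples
#' pk <- generate_pk_records("cpd", 0.8, 0.5, "rat")
#' estimate_fafg(pk)$fafg  # 0.8
generate_pk_records <- function(compound_id, fafg_true, fh_true,
                                species = "rat", d_iv = 1, d_po = 5,
                                noise_cv = 0, seed = NULL) {
  n <- length(compound_id)
  fafg_true <- rep_len(fafg_true, n); fh_true <- rep_len(fh_true, n)
  species <- rep_len(species, n)
  d_iv <- rep_len(d_iv, n); d_po <- rep_len(d_po, n)
  if (any(fh_true <= 0 | fh_true >= 1)) {
    stop_pf("fh_true must lie strictly in (0, 1)")
  }
  if (any(fafg_true <= 0 | fafg_true > 1)) {
    stop_pf("fafg_true must lie in (0, 1]")
  }
  with_seed(seed, {
    qh <- qh_constant(species)
    cl <- (1 - fh_true) * qh
    auc_iv <- d_iv / cl * rlnorm_cv(n, noise_cv)
    auc_po <- fafg_true * fh_true * d_po / cl * rlnorm_cv(n, noise_cv)
    data.frame(
      compound_id = as.character(compound_id), species = species,
      matrix = "blood", cl_L_per_h_kg = cl,
      auc_iv = auc_iv, d_iv = d_iv, auc_po = auc_po, d_po = d_po,
      stringsAsFactors = FALSE
    )
  })
}

#' Cohort generator configuration
#'
#' Study-condition defaults for the synthetic cohort: about half the
#' compounds beyond rule-of-five, secretory permeability log-uniform over
#' 1e-6 to 3e-5 cm/s, efflux ratios log-uniform over 1 to 25 (so that most
#' compounds show an efflux liability), absorption linked to permeability
#' and efflux through a declared monotone map with lognormal scatter, and
#' stickier, slower-equilibrating descriptors for the bRo5 stratum.
#'
#' @param n_compounds cohort size (> 0).
#' @param bro5_fraction fraction of bRo5 compounds, default 0.51.
#' @param papp_ba_range log-uniform range (cm/s) of the secretory truth.
#' @param er_range log-uniform range of the true efflux ratio (the
#'   absorptive truth is `papp_ba / er`).
#' @param kp_cell_max upper bound of the cell-partition factor (bRo5
#'   compounds sample the upper 80% of the range, Ro5 the lower 20%).
#' @param k_ads_range log-uniform range (1/s) of the adsorption rate (bRo5
#'   upper half in log-space, Ro5 lower half).
#' @param fu_bsa_range unbound-fraction range in 1% BSA.
#' @param response_factor_range,lod_response_range log-uniform analytical
#'   ranges.
#' @param noise_cv terminal response noise CV.
#' @param fafg_noise_cv lognormal scatter on the absorption map.
#' @param pk_noise_cv noise CV on the generated PK AUCs.
#' @param fh_range uniform range of the true hepatic availability.
#' @param methods method labels to simulate transport tables for.
#' @param seed mandatory integer seed.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_compounds, bro5_fraction = 0.51,
                          papp_ba_range = c(1e-6, 3e-5),
                          er_range = c(1, 25),
                          kp_cell_max = 300,
                          k_ads_range = c(1e-6, 5e-4),
                          fu_bsa_range = c(0.05, 0.5),
                          response_factor_range = c(1e6, 3e7),
                          lod_response_range = c(1e3, 2e4),
                          noise_cv = 0.05, fafg_noise_cv = 0.35,
                          pk_noise_cv = 0, fh_range = c(0.2, 0.9),
                          methods = c("standard", "bsa_modified",
                                      "equilibrated"),
                          seed) {
  if (missing(seed) || is.null(seed)) stop_pf("cohort seed is mandatory")
  if (n_compounds <= 0) stop_pf("n_compounds must be > 0")
  if (bro5_fraction < 0 || bro5_fraction > 1) {
    stop_pf("bro5_fraction must lie in [0, 1]")
  }
  if (any(papp_ba_range <= 0) || papp_ba_range[1] > papp_ba_range[2]) {
    stop_pf("papp_ba_range must be positive and non-decreasing")
  }
  stopifnot(all(methods %in% .METHODS))
  structure(
    list(n_compounds = as.integer(n_compounds),
         bro5_fraction = bro5_fraction, papp_ba_range = papp_ba_range,
         er_range = er_range, kp_cell_max = kp_cell_max,
         k_ads_range = k_ads_range, fu_bsa_range = fu_bsa_range,
         response_factor_range = response_factor_range,
         lod_response_range = lod_response_range,
         noise_cv = noise_cv, fafg_noise_cv = fafg_noise_cv,
         pk_noise_cv = pk_noise_cv, fh_range = fh_range,
         methods = methods, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

runif_log <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Generate a ground-truth-labelled synthetic cohort
#'
#' Samples compound descriptors (bRo5 stratum allocated deterministically as
#' `round(bro5_fraction * n)`), ground-truth permeabilities, efflux ratios
#' and absorption, simulates bidirectional transport tables for the
#' configured methods, and emits matching PK records. Fully deterministic
#' under the configuration seed.
#'
#' The absorption truth follows the declared monotone map
#' `fafg = 0.62 / (1 + 10^(log10(7e-6) - log10(papp_ab))) / (1 + er/25)`
#' with lognormal scatter, clamped to \[0.01, 1\]: absorption rises with
#' absorptive permeability and falls with efflux.
#'
#' @param cfg a [cohort_config()].
#' @param dt integration step passed to [simulate_transwell()].
#' @return list with `compounds` (descriptor table), `transport` (named list
#'   of transport tables, one per method), `pk` (PK table), `ground_truth`
#'   (`compound_id, papp_true_ab, papp_true_ba, er_true, fafg_true`).
#' @export
generate_cohort <- function(cfg, dt = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_compounds
  with_seed(cfg$seed, {
    n_bro5 <- round(cfg$bro5_fraction * n)
    bro5 <- sample(rep(c(TRUE, FALSE), c(n_bro5, n - n_bro5)))

    mw <- ifelse(bro5, runif(n, 550, 1100), runif(n, 250, 500))
    clogp <- ifelse(bro5, runif(n, 5.5, 9), runif(n, -1, 5))
    hbd <- ifelse(bro5, sample(0:8, n, TRUE), sample(0:5, n, TRUE))
    hba <- ifelse(bro5, sample(0:14, n, TRUE), sample(0:10, n, TRUE))
    solubility <- ifelse(bro5, 10^runif(n, -0.3, 2.5), 10^runif(n, 0.5, 3))

    papp_ba <- runif_log(n, cfg$papp_ba_range)
    er_true <- runif_log(n, cfg$er_range)
    papp_ab <- papp_ba / er_true

    u <- runif(n)
    kp_cell <- ifelse(bro5, (0.2 + 0.8 * u), 0.2 * u) * cfg$kp_cell_max
    if (cfg$k_ads_range[2] <= 0) {
      k_ads <- rep(0, n)
    } else {
      lk <- log(cfg$k_ads_range)
      mid <- mean(lk)
      k_ads <- exp(ifelse(bro5, runif(n, mid, lk[2]), runif(n, lk[1], mid)))
    }
    fu_bsa <- runif(n, cfg$fu_bsa_range[1], cfg$fu_bsa_range[2])
    rf <- runif_log(n, cfg$response_factor_range)
    lod <- runif_log(n, cfg$lod_response_range)

    base <- 0.62 / (1 + 10^(log10(7e-6) - log10(papp_ab))) / (1 + er_true / 25)
    fafg_true <- pmin(pmax(base * rlnorm_cv(n, cfg$fafg_noise_cv), 0.01), 1)
    fh_true <- runif(n, cfg$fh_range[1], cfg$fh_range[2])
    species <- sample(c("mouse", "rat"), n, TRUE)

    ids <- sprintf("SIM%04d", seq_len(n))
    compounds <- data.frame(
      compound_id = ids, name = ids, mw = mw, clogp = clogp,
      hbd = hbd, hba = hba, solubility_uM = solubility,
      stringsAsFactors = FALSE
    )
    ground_truth <- data.frame(
      compound_id = ids, papp_true_ab = papp_ab, papp_true_ba = papp_ba,
      er_true = er_true, fafg_true = fafg_true, stringsAsFactors = FALSE
    )
    pk <- generate_pk_records(ids, fafg_true, fh_true, species,
                              noise_cv = cfg$pk_noise_cv)

    transport <- lapply(setNames(cfg$methods, cfg$methods), function(m) {
      mcfg <- method_config(m)
      tabs <- lapply(seq_len(n), function(i) {
        cpd <- sim_compound(ids[i], papp_ab[i], papp_ba[i],
                            kp_cell = kp_cell[i], k_ads = k_ads[i],
                            fu_bsa = fu_bsa[i], response_factor = rf[i],
                            lod_response = lod[i], noise_cv = cfg$noise_cv)
        simulate_transwell(cpd, mcfg, seed = NULL, dt = dt)
      })
      tab <- do.call(rbind, tabs)
      rownames(tab) <- NULL
      tab
    })
    pf_log("info", sprintf("generate_cohort: %d compounds (%d bRo5), %d method(s)",
                           n, n_bro5, length(cfg$methods)))
    list(compounds = compounds, transport = transport, pk = pk,
         ground_truth = ground_truth)
  })
}
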