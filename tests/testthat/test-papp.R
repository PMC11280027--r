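# Permeability core: Papp, recovery, replicate aggregation, efflux ratio,
# method concordance.

test_that("Papp matches the hand unit-analysis oracle", {
  # C0 3 uM, donor end 2.7 uM, receiver end 0.03 uM, v_recv 200 uL,
  # t 3600 s, A 0.11 cm^2 -> dQ = 6e-12 mol, meanC = 2.85e-9 mol/cm^3
  rec <- make_transport_row()
  got <- compute_papp(rec)
  expect_equal(got$papp_cm_s,
               papp_oracle(3, 2.7, 0.03, 200, 3600, 0.11))
  expect_equal(got$papp_cm_s, 5.32e-6, tolerance = 1e-3)
  expect_equal(got$papp_qualifier, "exact")
})

test_that("Papp degenerate and limiting cases behave", {
  # zero receiver response -> zero flux, exact
  rec <- make_transport_row(receiver_response_end = 0)
  got <- compute_papp(rec)
  expect_equal(got$papp_cm_s, 0)
  expect_equal(got$papp_qualifier, "exact")

  # no depletion: donor end = C0 -> averaged denominator reduces to C0
  rec <- make_transport_row(donor_response_end = 3e6)
  expect_equal(compute_papp(rec)$papp_cm_s,
               compute_papp(rec, denominator = "c0")$papp_cm_s)

  # receiver below LOD -> value computed at the LOD, flagged less_than
  rec <- make_transport_row(receiver_response_end = 1e3, lod_response = 5e3)
  got <- compute_papp(rec)
  expect_equal(got$papp_qualifier, "less_than")
  expect_equal(got$papp_cm_s, papp_oracle(3, 2.7, 5e-3, 200, 3600, 0.11))
})

test_that("recovery is conservative on amounts and supports response mode", {
  rec <- make_transport_row()  # donor 2.7 uM x 100 uL, recv 0.03 uM x 200 uL
  expect_equal(compute_recovery(rec)$recovery_pct, 92.0)

  # full conservation and total loss
  expect_equal(compute_recovery(
    make_transport_row(donor_response_end = 3e6,
                       receiver_response_end = 0))$recovery_pct, 100)
  expect_equal(compute_recovery(
    make_transport_row(donor_response_end = 0,
                       receiver_response_end = 0))$recovery_pct, 0)

  # literal response-ratio reading is volume-unaware
  expect_equal(compute_recovery(rec, mode = "response")$recovery_pct,
               (0.03 + 2.7) / 3 * 100)

  # censored receiver enters the balance at the LOD upper bound
  rec2 <- make_transport_row(receiver_response_end = 0, lod_response = 3e4)
  expect_equal(compute_recovery(rec2, censor_at_lod = TRUE)$recovery_pct, 92.0)
})

test_that("replicate aggregation uses means and range-over-mean spread", {
  agg <- aggregate_replicates(c(4e-6, 8e-6))
  expect_equal(agg$papp_mean, 6e-6)
  expect_equal(agg$replicate_rel_diff_pct, abs(4e-6 - 8e-6) / 6e-6 * 100)

  expect_equal(aggregate_replicates(c(5e-6, 5e-6))$replicate_rel_diff_pct, 0)

  single <- aggregate_replicates(3e-6, "exact", 88)
  expect_equal(single$papp_mean, 3e-6)
  expect_true(is.na(single$replicate_rel_diff_pct))

  # conservative qualifier propagation
  agg <- aggregate_replicates(c(1e-6, 2e-6), c("exact", "less_than"))
  expect_equal(agg$qualifier, "less_than")
  expect_true(agg$below_lod)

  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("efflux ratio propagates censoring bounds", {
  agg <- function(p, q = "exact") aggregate_replicates(p, rep(q, length(p)))
  expect_equal(compute_efflux_ratio(agg(2e-6), agg(1e-5)),
               list(er = 5, er_qualifier = "exact"))
  expect_equal(compute_efflux_ratio(agg(4e-6), agg(4e-6))$er, 1)

  # censored AB is an upper bound, so the ratio is a lower bound
  got <- compute_efflux_ratio(agg(0.5e-6, "less_than"), agg(5e-6))
  expect_equal(got$er_qualifier, "greater_than")
  expect_equal(got$er, 10)

  got <- compute_efflux_ratio(agg(1e-6), agg(5e-6, "less_than"))
  expect_equal(got$er_qualifier, "less_than")

  expect_equal(compute_efflux_ratio(agg(1e-6, "less_than"),
                                    agg(1e-6, "less_than"))$er_qualifier,
               "undefined")
  expect_equal(compute_efflux_ratio(agg(0), agg(1e-6))$er_qualifier,
               "undefined")
})

test_that("bidirectional assembly produces one row per compound x method", {
  rows <- rbind(
    make_transport_row("a", direction = "AB", replicate = 1),
    make_transport_row("a", direction = "AB", replicate = 2,
                       receiver_response_end = 4e4),
    make_transport_row("a", direction = "BA", replicate = 1,
                       v_donor_uL = 200, v_receiver_uL = 100,
                       receiver_response_end = 1e5),
    make_transport_row("a", direction = "BA", replicate = 2,
                       v_donor_uL = 200, v_receiver_uL = 100,
                       receiver_response_end = 1.2e5),
    make_transport_row("b", direction = "AB"),
    make_transport_row("b", direction = "BA",
                       v_donor_uL = 200, v_receiver_uL = 100)
  )
  res <- bidirectional_results(rows)
  expect_equal(nrow(res), 2)
  expect_setequal(res$compound_id, c("a", "b"))
  a <- res[res$compound_id == "a", ]
  per_row <- compute_papp(rows[rows$compound_id == "a", ])
  expect_equal(a$papp_ab,
               mean(per_row$papp_cm_s[per_row$direction == "AB"]))
  expect_equal(a$er, a$papp_ba / a$papp_ab)
  expect_equal(a$validity, "unassessed")
})

test_that("method concordance counts fold differences and self-compares", {
  mk <- function(papp) {
    res <- make_result_row(compound_id = sprintf("c%02d", seq_along(papp)))
    res <- res[rep(1, length(papp)), ]
    res$compound_id <- sprintf("c%02d", seq_along(papp))
    res$papp_ab <- papp
    res
  }
  a <- mk(10^seq(-6.5, -4.5, length.out = 10))
  expect_warning(self <- compare_methods(a, a, "papp_ab"), NA)
  expect_equal(self$frac_within_3fold, 1)
  expect_equal(self$r2, 1)

  b <- a
  b$papp_ab[1] <- a$papp_ab[1] * 10
  expect_equal(compare_methods(a, b, "papp_ab")$frac_within_3fold, 0.9)

  disjoint <- a
  disjoint$compound_id <- paste0("other", seq_len(nrow(a)))
  expect_error(compare_methods(a, disjoint, "papp_ab"), "no shared")

  # censored results never enter the comparison
  cens <- a
  cens$papp_ab_qualifier <- "less_than"
  expect_error(compare_methods(a, cens, "papp_ab"), "no shared")
})
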