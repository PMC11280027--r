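# Result qualification rules and analytical sensitivity triage.

test_that("analytical sensitivity thresholds gate the target permeability", {
  expect_true(check_analytical_sensitivity(3e5, 1e-6))
  expect_false(check_analytical_sensitivity(3e5, 1e-7))
  expect_true(check_analytical_sensitivity(3e6, 1e-7))
  expect_false(check_analytical_sensitivity(0, 1e-6))
  expect_false(check_analytical_sensitivity(0, 1e-7))
  expect_error(check_analytical_sensitivity(1e5, 1e-5), "target_papp")
})

test_that("each qualification branch triggers on its construction only", {
  rules <- validity_rules()

  # below-LOD receiver with good recoveries -> qualified upper bound
  qual <- assess_validity(make_result_row(
    below_lod_ab = TRUE, papp_ab_qualifier = "less_than",
    recovery_ab = 85, recovery_ba = 82), rules)
  expect_equal(qual$validity, "qualified")
  expect_equal(qual$reasons, "below_lod")

  # similar low recoveries (diff 3 points, min < 40) -> invalid
  inv <- assess_validity(make_result_row(recovery_ab = 35, recovery_ba = 38),
                         rules)
  expect_equal(inv$validity, "invalid")
  expect_equal(inv$reasons, "poor_recovery_bidirectional")

  # dissimilar recoveries use the 65% single-direction threshold
  inv <- assess_validity(make_result_row(recovery_ab = 90, recovery_ba = 30),
                         rules)
  expect_equal(inv$validity, "invalid")
  expect_equal(inv$reasons, "poor_recovery_single")
  ok <- assess_validity(make_result_row(recovery_ab = 95, recovery_ba = 68),
                        rules)
  expect_equal(ok$validity, "valid")

  # duplicates 4 and 8 x 1e-6 (rel diff 66.7%) -> invalid
  agg <- aggregate_replicates(c(4e-6, 8e-6))
  inv <- assess_validity(make_result_row(
    rel_diff_ab = agg$replicate_rel_diff_pct), rules)
  expect_equal(inv$validity, "invalid")
  expect_equal(inv$reasons, "high_variability")

  # clean duplicates, good recoveries, above LOD -> valid, no reasons
  ok <- assess_validity(make_result_row(), rules)
  expect_equal(ok$validity, "valid")
  expect_equal(ok$reasons, "")
})

test_that("invalidity takes precedence over below-LOD qualification", {
  res <- assess_validity(make_result_row(
    recovery_ab = 30, recovery_ba = 32,
    below_lod_ab = TRUE, papp_ab_qualifier = "less_than"))
  expect_equal(res$validity, "invalid")

  res <- assess_validity(make_result_row(
    rel_diff_ab = 80, below_lod_ba = TRUE))
  expect_equal(res$validity, "invalid")
  expect_equal(res$reasons, "high_variability")
})

test_that("every result gets exactly one status; reasons iff not valid", {
  set.seed(42)
  n <- 400
  res <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_result_row(
      compound_id = paste0("r", i),
      recovery_ab = runif(1, 10, 110), recovery_ba = runif(1, 10, 110),
      rel_diff_ab = runif(1, 0, 90), rel_diff_ba = runif(1, 0, 90),
      below_lod_ab = runif(1) < 0.3, below_lod_ba = runif(1) < 0.3)
  }))
  out <- assess_validity(res)
  expect_true(all(out$validity %in% c("valid", "qualified", "invalid")))
  expect_true(all((out$reasons == "") == (out$validity == "valid")))
})

test_that("improving sensitivity or recovery never worsens the status", {
  set.seed(7)
  for (i in seq_len(1000)) {
    row <- make_result_row(
      recovery_ab = runif(1, 10, 100), recovery_ba = runif(1, 10, 100),
      rel_diff_ab = runif(1, 0, 80), rel_diff_ba = runif(1, 0, 80),
      below_lod_ab = runif(1) < 0.4, below_lod_ba = runif(1) < 0.4)
    before <- assess_validity(row)$validity

    # better detection: censoring flags switch off
    better_lod <- row
    better_lod$below_lod_ab <- FALSE
    better_lod$below_lod_ba <- FALSE
    after <- assess_validity(better_lod)$validity
    expect_gte(status_rank(after), status_rank(before))

    # better recovery: both directions raised equally (similarity preserved)
    better_rec <- row
    delta <- runif(1, 0, 30)
    better_rec$recovery_ab <- row$recovery_ab + delta
    better_rec$recovery_ba <- row$recovery_ba + delta
    after <- assess_validity(better_rec)$validity
    expect_gte(status_rank(after), status_rank(before))
  }
})

test_that("qualified bounds dominate the uncensored permeability", {
  cc <- cohort_config(n_compounds = 40, noise_cv = 0,
                      methods = "standard", seed = 31)
  coh <- generate_cohort(cc)
  tab <- coh$transport$standard
  cens <- tab[tab$receiver_response_end < tab$lod_response, ]
  expect_gt(nrow(cens), 0)
  bound <- compute_papp(cens)
  uncensored <- cens
  uncensored$lod_response <- 0
  truth <- compute_papp(uncensored)
  expect_true(all(bound$papp_qualifier == "less_than"))
  expect_true(all(bound$papp_cm_s >= truth$papp_cm_s))
})

test_that("validity summaries partition percentages by group", {
  res <- do.call(rbind, c(
    lapply(1:10, function(i) make_result_row(paste0("v", i))),
    lapply(1:10, function(i) make_result_row(
      paste0("q", i), below_lod_ab = TRUE, papp_ab_qualifier = "less_than")),
    lapply(1:6, function(i) make_result_row(
      paste0("i", i), recovery_ab = 20, recovery_ba = 22))
  ))
  out <- assess_validity(res)
  summ <- summarize_validity(out)
  expect_equal(summ$n, 26)
  expect_equal(summ$percent_valid, 100 * 10 / 26, tolerance = 1e-10)
  expect_equal(summ$percent_qualified, 100 * 10 / 26, tolerance = 1e-10)
  expect_equal(summ$percent_invalid, 100 * 6 / 26, tolerance = 1e-10)
  expect_equal(summ$percent_valid + summ$percent_qualified +
                 summ$percent_invalid, 100, tolerance = 0.1)

  # grouping by Lipinski violation count against a hand tally
  compounds <- data.frame(
    compound_id = out$compound_id,
    mw = rep(c(400, 600, 800), length.out = 26),
    clogp = rep(c(2, 6), length.out = 26),
    hbd = 1, hba = 4
  )
  by_lip <- summarize_validity(out, compounds, "lipinski_count")
  lip <- count_lipinski_violations(compounds)
  tally <- table(lip$violations)
  expect_equal(by_lip$n[match(names(tally), by_lip$group)],
               as.integer(tally))

  # unknown compound ids are dropped with a warning
  expect_warning(
    summarize_validity(out, compounds[-1, , drop = FALSE], "mw_bins"),
    "unknown compound id")
})
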