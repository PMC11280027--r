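# Programmatic fixtures and independent oracles shared across test files.

make_transport_row <- function(compound_id = "cpd1", method = "standard",
                               direction = "AB", replicate = 1,
                               t_inc_s = 3600, area_cm2 = 0.11, c0_uM = 3,
                               donor_response_end = 2.7e6,
                               receiver_response_end = 3e4,
                               response_factor = 1e6, lod_response = 0,
                               v_donor_uL = 100, v_receiver_uL = 200) {
  data.frame(compound_id = compound_id, method = method,
             direction = direction, replicate = replicate,
             t_inc_s = t_inc_s, area_cm2 = area_cm2, c0_uM = c0_uM,
             donor_response_end = donor_response_end,
             receiver_response_end = receiver_response_end,
             response_factor = response_factor,
             lod_response = lod_response,
             v_donor_uL = v_donor_uL, v_receiver_uL = v_receiver_uL,
             stringsAsFactors = FALSE)
}

# A minimal assessed-result row in the shape produced by
# bidirectional_results(), for driving assess_validity directly.
make_result_row <- function(compound_id = "cpd1", method = "standard",
                            papp_ab = 5e-6, papp_ab_qualifier = "exact",
                            papp_ba = 5e-6, papp_ba_qualifier = "exact",
                            er = 1, er_qualifier = "exact",
                            recovery_ab = 90, recovery_ba = 90,
                            rel_diff_ab = 5, rel_diff_ba = 5,
                            below_lod_ab = FALSE, below_lod_ba = FALSE) {
  data.frame(compound_id = compound_id, method = method,
             papp_ab = papp_ab, papp_ab_qualifier = papp_ab_qualifier,
             papp_ba = papp_ba, papp_ba_qualifier = papp_ba_qualifier,
             er = er, er_qualifier = er_qualifier,
             recovery_ab = recovery_ab, recovery_ba = recovery_ba,
             rel_diff_ab = rel_diff_ab, rel_diff_ba = rel_diff_ba,
             below_lod_ab = below_lod_ab, below_lod_ba = below_lod_ba,
             validity = "unassessed", reasons = "",
             stringsAsFactors = FALSE)
}

# Independent Welch's t-test: direct evaluation of the statistic and the
# Welch-Satterthwaite degrees of freedom, separate from stats::t.test.
welch_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  sx <- vx / length(x)
  sy <- vy / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# Hand unit-analysis Papp oracle (amounts in mol, volumes in cm^3):
# dQ = C_recv * v_recv; Papp = dQ / (t * A * mean(C1, C0)).
papp_oracle <- function(c0_uM, donor_uM, recv_uM, v_recv_uL, t_s, area) {
  dq <- recv_uM * 1e-9 * v_recv_uL * 1e-3
  mean_c <- (donor_uM + c0_uM) / 2 * 1e-9
  dq / (t_s * area * mean_c)
}

status_rank <- function(s) c(invalid = 1, qualified = 2, valid = 3)[s]
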