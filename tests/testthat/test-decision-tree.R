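test_that("evaluate_pathway agrees with the joint-atom enumeration oracle", {
  set.seed(42)
  pop <- default_population()
  for (rep in 1:25) {
    prev <- runif(1, 0.001, 0.05)
    sh <- runif(1, 0.3, 0.95); qh <- runif(1, 0.85, 0.999)
    sm <- runif(1, sh, 0.99); qm <- runif(1, 0.6, qh)
    su <- runif(1, 0.5, 0.95); qu <- runif(1, 0.5, 0.95)
    stratum <- population_stratum("GE50", 1000, prev, 0.7,
                                  c(OTHER = 0.01), c("60" = 1))
    acc_single <- list(high = list(sensitivity = sh, specificity = qh),
                       uss = list(sensitivity = su, specificity = qu))
    acc_banded <- c(acc_single,
                    list(moderate = list(sensitivity = sm, specificity = qm)))
    cases <- list(
      list(pw = pathway_definition(1L, "SEQUENTIAL", "CA125_35", NA, "x"),
           acc = acc_single,
           oracle = enum_pathway_oracle("SEQUENTIAL", prev, sh, qh, su, qu)),
      list(pw = pathway_definition(2L, "SEQUENTIAL", "OVATOOLS", 0.01, 0.03),
           acc = acc_banded,
           oracle = enum_pathway_oracle("SEQUENTIAL", prev, sh, qh, su, qu, sm, qm)),
      list(pw = pathway_definition(6L, "CONCURRENT", "CA125_35", NA, "x"),
           acc = acc_single,
           oracle = enum_pathway_oracle("CONCURRENT", prev, sh, qh, su, qu))
    )
    for (cs in cases) {
      out <- evaluate_pathway(cs$pw, stratum, cs$acc)
      expect_equal(out$p_tp, cs$oracle$p_tp, tolerance = 1e-12)
      expect_equal(out$p_fn, cs$oracle$p_fn, tolerance = 1e-12)
      expect_equal(out$p_tn, cs$oracle$p_tn, tolerance = 1e-12)
      expect_equal(out$p_fp, cs$oracle$p_fp, tolerance = 1e-12)
      # four-way partition and prevalence identities
      expect_equal(out$p_tp + out$p_fn + out$p_tn + out$p_fp, 1,
                   tolerance = 1e-12)
      expect_equal(out$p_tp + out$p_fn, prev, tolerance = 1e-12)
    }
    # concurrent testing never detects less than the sequential combination
    expect_gte(1 - (1 - sh) * (1 - su), sh * su)
  }
})

test_that("perfect tests detect everything and refer only true cases", {
  acc <- list(high = list(sensitivity = 1, specificity = 1),
              moderate = list(sensitivity = 1, specificity = 1),
              uss = list(sensitivity = 1, specificity = 1))
  stratum <- default_population()$GE50
  for (pw in default_pathways()) {
    out <- evaluate_pathway(pw, stratum, acc)
    expect_equal(out$detection_rate, 1)
    expect_equal(out$referral_rate, stratum$oc_prevalence)
    expect_equal(out$p_fp, 0)
  }
  # zero prevalence: detection rate undefined, reported as absent
  s0 <- population_stratum("GE50", 10, 0, 0.7, c(OTHER = 0.01), c("60" = 1))
  out0 <- evaluate_pathway(default_pathways()$P1, s0, acc)
  expect_true(is.na(out0$detection_rate))
})

test_that("stage shift moves the incremental detected mass by rr_late only", {
  pop <- default_population()
  stratum <- pop$GE50
  p1 <- evaluate_pathway(default_pathways()$P1, stratum)
  p2 <- evaluate_pathway(default_pathways()$P2, stratum)
  shifted <- apply_stage_shift(p2, p1, 0.836, stratum)
  # two-state mass-balance oracle: late mass before vs after
  delta <- p2$p_tp - p1$p_tp
  late_before <- p2$p_tp * 0.72
  late_after <- shifted$late_stage_prop_detected * p2$p_tp
  expect_equal(late_before - late_after, delta * 0.72 * (1 - 0.836),
               tolerance = 1e-12)
  # the incremental mass itself carries late share 0.72 * 0.836
  frac <- delta / p2$p_tp
  expect_equal(shifted$late_stage_prop_detected,
               (1 - frac) * 0.72 + frac * 0.72 * 0.836, tolerance = 1e-12)
  expect_equal(0.72 * 0.836, 0.60192)
  expect_equal(shifted$late_stage_prop_missed, 0.72)

  # rr = 1 leaves staging untouched; self-comparison changes nothing
  same <- apply_stage_shift(p2, p1, 1, stratum)
  expect_equal(same$late_stage_prop_detected, 0.72)
  null <- apply_stage_shift(p1, p1, 0.836, stratum)
  expect_equal(null$late_stage_prop_detected, 0.72)

  # lower detection than reference: no reverse shift
  rev <- apply_stage_shift(p1, p2, 0.836, stratum)
  expect_equal(rev$late_stage_prop_detected, 0.72)

  # mismatched strata rejected; rr > 1 capped with a warning
  expect_error(apply_stage_shift(p2, p1, 0.836, pop$UNDER50), "same stratum")
  expect_warning(out <- apply_stage_shift(p2, p1, 1.2, stratum), "capping")
  expect_equal(out$late_stage_prop_detected, 0.72)
})

test_that("branch costs sum the stated primary-care sequences", {
  pws <- default_pathways()
  expect_equal(primary_care_cost(pws$P1, "blood_neg"), 59)
  expect_equal(primary_care_cost(pws$P1, "blood_pos_uss_neg"), 283)
  expect_equal(primary_care_cost(pws$P1, "blood_pos_uss_pos"), 323)
  expect_equal(primary_care_cost(pws$P2, "blood_high"), 99)
  expect_equal(primary_care_cost(pws$P6, "neg"), 263)
  expect_equal(primary_care_cost(pws$P6, "pos"), 303)
  expect_error(primary_care_cost(pws$P6, "blood_neg"), "not a branch")
  expect_error(primary_care_cost(pws$P1, "neg"), "not a branch")
})

test_that("expected primary-care cost matches atom enumeration with FN repeat", {
  pw <- default_pathways()$P2
  acc <- resolve_pathway_accuracy_for_test(pw, "GE50")
  got <- ovatriage:::expected_primary_care_cost(pw, acc)
  sm <- acc$moderate$sensitivity; qm <- acc$moderate$specificity
  sh <- acc$high$sensitivity; qh <- acc$high$specificity
  su <- acc$uss$sensitivity; qu <- acc$uss$specificity
  # oracle: enumerate branches; false negatives incur the branch cost twice
  oc <- sh * 99 + (sm - sh) * (su * 323 + (1 - su) * 2 * 283) +
    (1 - sm) * 2 * 59
  no_oc <- (1 - qh) * 99 + (qh - qm) * ((1 - qu) * 323 + qu * 283) + qm * 59
  expect_equal(got$oc, oc, tolerance = 1e-12)
  expect_equal(got$no_oc, no_oc, tolerance = 1e-12)
})

test_that("false-positive secondary-care cost mixes surgery and workup", {
  expect_equal(fp_secondary_cost(), 3094.25)
  uc <- default_unit_costs()
  uc$benign_surgery_rate <- 0
  expect_equal(fp_secondary_cost(uc), 395)
  uc$benign_surgery_rate <- 1
  expect_equal(fp_secondary_cost(uc), 3994)
  uc$surgery_complication_rate <- 0.15
  uc$surgery_complication_cost <- 1000
  expect_equal(fp_secondary_cost(uc), 3994 + 150)
})
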