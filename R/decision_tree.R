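# The six primary-care triage pathways and the diagnostic decision tree.
# Pathway 1 is current practice (CA125 >= 35 U/mL then USS). Pathways 2/3 are
# sequential risk-banded triage (Ovatools risk, or age-adjusted CA125
# thresholds accuracy-matched to it): risk < moderate threshold -> reassure;
# moderate band -> USS; >= high threshold -> direct urgent referral.
# Pathways 4/5/6 test CA125 and USS concurrently and refer if either is
# abnormal. The blood test and USS are conditionally independent given
# disease status; "no invasive OC" (the specificity denominator) includes
# other cancers and benign disease.

#' Define a triage pathway
#'
#' @param id Integer pathway id (1-6 for the published set).
#' @param mode `"SEQUENTIAL"` or `"CONCURRENT"`.
#' @param first_test Blood-test rule: `"CA125_35"`, `"OVATOOLS"` or
#'   `"AGE_ADJ_CA125"`.
#' @param moderate_threshold Ovatools risk fraction triggering USS in
#'   sequential banded pathways (`NA` for the single-cut pathway 1).
#' @param high_threshold Risk fraction (or CA125 cut label) triggering direct
#'   referral (sequential) or counting the blood test abnormal (concurrent).
#' @export
pathway_definition <- function(id, mode, first_test,
                               moderate_threshold = NA_real_,
                               high_threshold = NA) {
  mode <- match.arg(mode, c("SEQUENTIAL", "CONCURRENT"))
  first_test <- match.arg(first_test, c("CA125_35", "OVATOOLS", "AGE_ADJ_CA125"))
  if (mode == "SEQUENTIAL" && first_test != "CA125_35") {
    if (!is.numeric(moderate_threshold) || is.na(moderate_threshold) ||
        !is.numeric(high_threshold)) {
      stop("sequential risk-banded pathways need numeric moderate and high thresholds")
    }
    if (moderate_threshold >= high_threshold) {
      stop("moderate_threshold must be below high_threshold")
    }
  }
  structure(
    list(id = id, mode = mode, first_test = first_test,
         moderate_threshold = moderate_threshold,
         high_threshold = high_threshold),
    class = "pathway_definition"
  )
}

#' The six published triage pathways
#' @export
default_pathways <- function() {
  list(
    P1 = pathway_definition(1L, "SEQUENTIAL", "CA125_35", NA, "35 U/mL"),
    P2 = pathway_definition(2L, "SEQUENTIAL", "OVATOOLS", 0.01, 0.03),
    P3 = pathway_definition(3L, "SEQUENTIAL", "AGE_ADJ_CA125", 0.01, 0.03),
    P4 = pathway_definition(4L, "CONCURRENT", "OVATOOLS", NA, 0.03),
    P5 = pathway_definition(5L, "CONCURRENT", "AGE_ADJ_CA125", NA, 0.03),
    P6 = pathway_definition(6L, "CONCURRENT", "CA125_35", NA, "35 U/mL")
  )
}

risk_label <- function(x) {
  if (is.character(x)) return(x)
  paste0(format(100 * x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE), "%")
}

# Resolve the sensitivities/specificities a pathway needs for an age group.
# For non-tabulated Ovatools thresholds accuracy comes from the binormal ROC.
resolve_pathway_accuracy <- function(pathway, age_group,
                                     table = read_accuracy_table(),
                                     roc = NULL) {
  lookup <- function(threshold) {
    lab <- risk_label(threshold)
    hit <- try(get_accuracy(pathway$first_test, age_group, lab, table),
               silent = TRUE)
    if (!inherits(hit, "try-error")) {
      return(list(sensitivity = hit$sensitivity, specificity = hit$specificity))
    }
    if (is.numeric(threshold) &&
        pathway$first_test %in% c("OVATOOLS", "AGE_ADJ_CA125")) {
      if (is.null(roc)) roc <- ovatools_roc(age_group, table)
      pt <- roc_interpolate(roc, threshold)
      return(list(sensitivity = pt$sensitivity, specificity = pt$specificity))
    }
    stop(sprintf("no accuracy entry for (%s, %s, %s)",
                 pathway$first_test, age_group, lab))
  }
  uss <- get_accuracy("USS", age_group, table = table)
  out <- list(
    high = lookup(pathway$high_threshold),
    uss = list(sensitivity = uss$sensitivity, specificity = uss$specificity)
  )
  if (pathway$mode == "SEQUENTIAL" && !is.na(pathway$moderate_threshold)) {
    out$moderate <- lookup(pathway$moderate_threshold)
  }
  out
}

#' Evaluate a pathway's diagnostic decision tree on a stratum
#'
#' Computes the four outcome-class probabilities (true/false positive and
#' negative), the invasive-OC detection rate and the overall referral rate,
#' under conditional independence of the blood test and USS given disease
#' status. Closed forms by pathway mode:
#' sequential single-cut, P(detect|OC) = sens_blood * sens_USS and
#' P(refer|no OC) = (1-spec_blood) * (1-spec_USS); sequential banded,
#' P(detect|OC) = sens_high + (sens_mod - sens_high) * sens_USS and
#' P(refer|no OC) = (1-spec_high) + (spec_high - spec_mod) * (1-spec_USS);
#' concurrent, P(detect|OC) = 1 - (1-sens_blood)(1-sens_USS) and
#' P(refer|no OC) = 1 - spec_blood * spec_USS.
#'
#' @param pathway A [pathway_definition()].
#' @param stratum A [population_stratum()].
#' @param accuracy Accuracy table (or pre-resolved accuracy set from
#'   `resolve_pathway_accuracy`, detected by its structure).
#' @param roc Optional pre-built ROC curve for non-tabulated thresholds.
#' @return Object of class `diagnostic_outcome` with fields `p_tp`, `p_fn`,
#'   `p_tn`, `p_fp`, `detection_rate`, `referral_rate`,
#'   `late_stage_prop_detected`, `late_stage_prop_missed`.
#' @export
evaluate_pathway <- function(pathway, stratum,
                             accuracy = read_accuracy_table(), roc = NULL) {
  acc <- if (is.list(accuracy) && !is.null(accuracy$high)) {
    accuracy
  } else {
    resolve_pathway_accuracy(pathway, stratum$age_group, accuracy, roc)
  }
  prev <- stratum$oc_prevalence
  su <- acc$uss$sensitivity; qu <- acc$uss$specificity
  sh <- acc$high$sensitivity; qh <- acc$high$specificity
  if (pathway$mode == "SEQUENTIAL") {
    if (!is.null(acc$moderate)) {
      sm <- acc$moderate$sensitivity; qm <- acc$moderate$specificity
      p_det <- sh + (sm - sh) * su
      p_ref_neg <- (1 - qh) + (qh - qm) * (1 - qu)
    } else {
      p_det <- sh * su
      p_ref_neg <- (1 - qh) * (1 - qu)
    }
  } else {
    p_det <- 1 - (1 - sh) * (1 - su)
    p_ref_neg <- 1 - qh * qu
  }
  p_tp <- prev * p_det
  p_fn <- prev * (1 - p_det)
  p_fp <- (1 - prev) * p_ref_neg
  p_tn <- (1 - prev) * (1 - p_ref_neg)
  structure(
    list(pathway_id = pathway$id, age_group = stratum$age_group,
         p_tp = p_tp, p_fn = p_fn, p_tn = p_tn, p_fp = p_fp,
         detection_rate = if (prev > 0) p_det else NA_real_,
         referral_rate = p_tp + p_fp,
         late_stage_prop_detected = stratum$late_stage_prop,
         late_stage_prop_missed = stratum$late_stage_prop,
         accuracy = acc),
    class = "diagnostic_outcome"
  )
}

#' Apply the early-detection stage shift
#'
#' Cancers detected by the new pathway but missed by the reference pathway
#' (current practice) are assumed diagnosed earlier; among that incremental
#' detected mass, the probability of late-stage diagnosis is multiplied by
#' the relative risk `rr_late` (the removed fraction moves to early stage).
#' All other cases keep the stratum's usual-care staging. When the new
#' pathway detects fewer cancers than the reference, no reverse shift is
#' applied: missed cases simply revert to usual-care staging.
#'
#' @param outcome_new,outcome_ref `diagnostic_outcome` objects on the same
#'   stratum; `outcome_ref` is current practice (pathway 1).
#' @param rr_late Relative risk of late-stage diagnosis (default from the
#'   profile; point estimate 0.836).
#' @param stratum The shared `population_stratum`.
#' @return `outcome_new` with `late_stage_prop_detected` updated.
#' @export
apply_stage_shift <- function(outcome_new, outcome_ref, rr_late, stratum) {
  if (!identical(outcome_new$age_group, outcome_ref$age_group) ||
      !identical(outcome_new$age_group, stratum$age_group)) {
    stop("stage shift requires outcomes and stratum on the same stratum")
  }
  if (rr_late > 1) {
    warning("rr_late > 1; capping at 1")
    rr_late <- 1
  }
  late0 <- stratum$late_stage_prop
  delta <- max(0, outcome_new$p_tp - outcome_ref$p_tp)
  out <- outcome_new
  if (delta > 0 && outcome_new$p_tp > 0) {
    out$late_stage_prop_detected <-
      ((outcome_new$p_tp - delta) * late0 + delta * late0 * rr_late) /
      outcome_new$p_tp
  } else {
    out$late_stage_prop_detected <- late0
  }
  out$late_stage_prop_missed <- late0
  out
}

# Branch cost ingredients, from the stated primary-care sequences:
# every pathway starts with a face-to-face GP consultation, nurse-taken
# blood and the CA125 test (plus the USS up front in concurrent pathways);
# a USS arranged after the blood result adds a GP telephone follow-up and
# the scan; any referral is preceded by one further GP consultation.
branch_cost_table <- function(pathway, costs = default_unit_costs()) {
  base <- costs$gp_face_to_face + costs$nurse_blood + costs$ca125_test
  if (pathway$mode == "CONCURRENT") {
    cbase <- base + costs$uss
    tab <- data.frame(
      branch = c("neg", "pos"),
      cost = c(cbase, cbase + costs$gp_face_to_face)
    )
  } else if (!is.na(pathway$moderate_threshold)) {
    tab <- data.frame(
      branch = c("blood_low", "blood_mod_uss_neg", "blood_mod_uss_pos", "blood_high"),
      cost = c(base,
               base + costs$gp_telephone + costs$uss,
               base + costs$gp_telephone + costs$uss + costs$gp_face_to_face,
               base + costs$gp_face_to_face)
    )
  } else {
    tab <- data.frame(
      branch = c("blood_neg", "blood_pos_uss_neg", "blood_pos_uss_pos"),
      cost = c(base,
               base + costs$gp_telephone + costs$uss,
               base + costs$gp_telephone + costs$uss + costs$gp_face_to_face)
    )
  }
  tab
}

#' Primary-care cost of one branch of a pathway
#'
#' Sums the unit costs along the identified test-result branch. Branch names:
#' sequential single-cut pathways use `blood_neg`, `blood_pos_uss_neg`,
#' `blood_pos_uss_pos`; sequential banded pathways use `blood_low`,
#' `blood_mod_uss_neg`, `blood_mod_uss_pos`, `blood_high`; concurrent
#' pathways use `neg`, `pos`.
#'
#' @param pathway A `pathway_definition`.
#' @param branch Branch name.
#' @param costs A `unit_costs` object.
#' @return Cost in GBP.
#' @export
primary_care_cost <- function(pathway, branch, costs = default_unit_costs()) {
  tab <- branch_cost_table(pathway, costs)
  hit <- tab$cost[tab$branch == branch]
  if (length(hit) != 1) {
    stop(sprintf("branch '%s' is not a branch of a %s pathway",
                 branch, tolower(pathway$mode)))
  }
  hit
}

# Expected primary-care cost per woman by disease status, including the
# repeat of the full branch for false negatives (the diagnostic process is
# repeated once, costed as the same branch twice).
expected_primary_care_cost <- function(pathway, acc, costs = default_unit_costs()) {
  tab <- branch_cost_table(pathway, costs)
  cost_of <- function(b) tab$cost[tab$branch == b]
  su <- acc$uss$sensitivity; qu <- acc$uss$specificity
  sh <- acc$high$sensitivity; qh <- acc$high$specificity
  if (pathway$mode == "CONCURRENT") {
    p_det <- 1 - (1 - sh) * (1 - su)
    oc <- p_det * cost_of("pos") + (1 - p_det) * 2 * cost_of("neg")
    p_ref <- 1 - qh * qu
    no_oc <- p_ref * cost_of("pos") + (1 - p_ref) * cost_of("neg")
  } else if (!is.null(acc$moderate)) {
    sm <- acc$moderate$sensitivity; qm <- acc$moderate$specificity
    oc <- sh * cost_of("blood_high") +
      (sm - sh) * (su * cost_of("blood_mod_uss_pos") +
                   (1 - su) * 2 * cost_of("blood_mod_uss_neg")) +
      (1 - sm) * 2 * cost_of("blood_low")
    no_oc <- (1 - qh) * cost_of("blood_high") +
      (qh - qm) * ((1 - qu) * cost_of("blood_mod_uss_pos") +
                   qu * cost_of("blood_mod_uss_neg")) +
      qm * cost_of("blood_low")
  } else {
    oc <- sh * (su * cost_of("blood_pos_uss_pos") +
                (1 - su) * 2 * cost_of("blood_pos_uss_neg")) +
      (1 - sh) * 2 * cost_of("blood_neg")
    no_oc <- (1 - qh) * ((1 - qu) * cost_of("blood_pos_uss_pos") +
                         qu * cost_of("blood_pos_uss_neg")) +
      qh * cost_of("blood_neg")
  }
  list(oc = oc, no_oc = no_oc)
}

#' Expected secondary-care cost of a false-positive referral
#'
#' Referred women without an eventual cancer diagnosis either undergo surgery
#' for benign disease (rate 0.75, cost 3,994 GBP, optionally plus an expected
#' complication cost) or receive an outpatient consultation, a CA125 test and
#' a USS.
#'
#' @param costs A `unit_costs` object.
#' @return Expected cost in GBP per false-positive referral.
#' @export
fp_secondary_cost <- function(costs = default_unit_costs()) {
  r <- costs$benign_surgery_rate
  stopifnot(r >= 0, r <= 1)
  surgery <- costs$benign_surgery +
    costs$surgery_complication_rate * costs$surgery_complication_cost
  r * surgery + (1 - r) * (costs$outpatient + costs$ca125_test + costs$uss)
}
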