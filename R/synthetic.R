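# Synthetic stand-ins for the registry-fitted model inputs: population
# strata, stage-specific cancer survival, a cause-partitioned female life
# table, inpatient cost curves and an age-declining EQ-5D utility model.
# All defaults are deterministic and calibrated to published anchors; they
# are synthetic and affect absolute levels, not the structure of pathway
# comparisons.

CANCER_TYPES <- c("OVARIAN", "LOWER_GI", "UTERINE", "LUNG", "PANCREATIC", "OTHER")

#' Construct a population stratum
#'
#' @param age_group `"UNDER50"` or `"GE50"`.
#' @param n_women Number of women in the stratum.
#' @param oc_prevalence Probability of invasive ovarian cancer diagnosed
#'   within one year of the index test.
#' @param late_stage_prop Proportion of staged ovarian cancers that are
#'   late stage (III/IV) under usual care.
#' @param other_cancer_prev Named vector of one-year prevalences of the other
#'   modelled cancer types.
#' @param age_weights Named numeric vector of weights over integer ages
#'   (names are ages); normalised to sum to one.
#' @export
population_stratum <- function(age_group, n_women, oc_prevalence,
                               late_stage_prop, other_cancer_prev,
                               age_weights) {
  stopifnot(oc_prevalence >= 0, oc_prevalence <= 1,
            late_stage_prop >= 0, late_stage_prop <= 1,
            all(other_cancer_prev >= 0))
  if (oc_prevalence + sum(other_cancer_prev) > 1) {
    stop("cancer prevalences exceed 1 in stratum ", age_group)
  }
  age_weights <- age_weights / sum(age_weights)
  structure(
    list(age_group = age_group, n_women = n_women,
         oc_prevalence = oc_prevalence, late_stage_prop = late_stage_prop,
         other_cancer_prev = other_cancer_prev, age_weights = age_weights),
    class = "population_stratum"
  )
}

#' Default study population strata
#'
#' Two strata of CA125-tested women split at age 50, reproducing the published
#' cohort headers: under 50, n = 112,081 with 0.2% one-year invasive ovarian
#' cancer prevalence and 46% late stage; 50 and over, n = 164,746 with 1.05%
#' prevalence and 72% late stage. Other-cancer prevalences (lower GI 0.48%,
#' uterine 0.25%, lung 0.21%, pancreatic 0.16%, other 1%) are cohort-wide
#' figures, split across strata by an age gradient (default: the under-50
#' stratum carries half the cohort-wide rate and the 50+ stratum the
#' complementary multiplier so that the weighted mean is preserved). Ages are
#' weighted by a truncated normal (mean 54.6, SD 15.8, the cohort's age
#' distribution) restricted to each stratum's range.
#'
#' @param under50_gradient Multiplier applied to cohort-wide other-cancer
#'   prevalences in the under-50 stratum.
#' @return List of two `population_stratum` objects named `UNDER50`, `GE50`.
#' @export
default_population <- function(under50_gradient = 0.5) {
  n_u <- 112081; n_g <- 164746; n_tot <- n_u + n_g
  other <- c(LOWER_GI = 0.0048, UTERINE = 0.0025, LUNG = 0.0021,
             PANCREATIC = 0.0016, OTHER = 0.010)
  g_u <- under50_gradient
  g_g <- (n_tot - g_u * n_u) / n_g
  ages_u <- 18:49; ages_g <- 50:99
  w_u <- stats::dnorm(ages_u, 54.6, 15.8); names(w_u) <- ages_u
  w_g <- stats::dnorm(ages_g, 54.6, 15.8); names(w_g) <- ages_g
  list(
    UNDER50 = population_stratum("UNDER50", n_u, 0.002, 0.46, other * g_u, w_u),
    GE50    = population_stratum("GE50",    n_g, 0.0105, 0.72, other * g_g, w_g)
  )
}

#' Synthetic stage-specific cancer survival models
#'
#' Exponential (constant-hazard) survival per cancer type and stage, each
#' pinned exactly to a single anchor: S(t) = anchor solves the hazard in
#' closed form, h = -log(S)/t. Ovarian cancer is anchored to the published
#' 5-year survival of 95% (stage I, early) and 16% (stage IV, late); other
#' cancer types carry documented synthetic default anchors with late-stage
#' survival always at or below early-stage survival.
#'
#' @param anchors Data frame with columns `type`, `stage` (`EARLY`/`LATE`),
#'   `t` (years), `survival` in (0, 1). Defaults described above.
#' @return Object of class `survival_models`: a data frame with a `hazard`
#'   column (per year).
#' @export
synth_survival <- function(anchors = NULL) {
  if (is.null(anchors)) {
    anchors <- data.frame(
      type = rep(CANCER_TYPES, each = 2),
      stage = rep(c("EARLY", "LATE"), times = length(CANCER_TYPES)),
      t = 5,
      survival = c(0.95, 0.16,   # OVARIAN: published stage I / IV anchors
                   0.90, 0.25,   # LOWER_GI (synthetic)
                   0.92, 0.30,   # UTERINE (synthetic)
                   0.60, 0.05,   # LUNG (synthetic)
                   0.40, 0.03,   # PANCREATIC (synthetic)
                   0.85, 0.20)   # OTHER (synthetic)
    )
  }
  if (any(anchors$survival <= 0 | anchors$survival >= 1)) {
    stop("survival anchors must lie strictly in (0, 1)")
  }
  anchors$hazard <- -log(anchors$survival) / anchors$t
  for (ty in unique(anchors$type)) {
    he <- anchors$hazard[anchors$type == ty & anchors$stage == "EARLY"]
    hl <- anchors$hazard[anchors$type == ty & anchors$stage == "LATE"]
    if (length(he) && length(hl) && any(hl < he)) {
      stop("late-stage hazard below early-stage hazard for ", ty)
    }
  }
  structure(anchors, class = c("survival_models", class(anchors)))
}

cancer_hazard <- function(survival, type, stage) {
  h <- survival$hazard[survival$type == type & survival$stage == stage]
  if (length(h) != 1) stop("no survival model for ", type, " ", stage)
  h
}

#' Synthetic female life table partitioned by cause
#'
#' Gompertz-Makeham all-cause female mortality, mu(a) = A + B * exp(C * a)
#' (defaults A = 2e-4, B = 1.8e-5, C = 0.1, chosen to approximate UK female
#' rates), converted to annual probabilities and partitioned into cancer and
#' non-cancer mortality by a smooth age-dependent cancer share peaking in the
#' mid-60s. Deterministic.
#'
#' @param max_age Last tabulated age (default 110).
#' @param makeham,gompertz_b,gompertz_c Gompertz-Makeham parameters.
#' @return Data frame of class `life_table` with columns `age`,
#'   `cancer_mortality`, `noncancer_mortality` (annual probabilities).
#' @export
synth_life_table <- function(max_age = 110, makeham = 2e-4,
                             gompertz_b = 1.8e-5, gompertz_c = 0.1) {
  age <- 0:max_age
  mu <- makeham + gompertz_b * exp(gompertz_c * age)
  q <- 1 - exp(-mu)
  q <- pmin(q, 1)
  cancer_share <- 0.10 + 0.25 * exp(-((age - 66) / 18)^2)
  lt <- data.frame(
    age = age,
    cancer_mortality = cancer_share * q,
    noncancer_mortality = (1 - cancer_share) * q
  )
  structure(lt, class = c("life_table", class(lt)))
}

#' Synthetic EQ-5D utility model
#'
#' Age-declining baseline utility using the published female EQ-5D age
#' function (0.9508566 - 0.0002587 * age - 0.0000332 * age^2), cancer
#' decrements by type with two recency levels (diagnosed within one year vs
#' more than one year previously), an additional late-stage decrement
#' (default 0.046; scenario values 0.06 or 0), and benign-surgery effects
#' (-0.04 in the year of surgery, +0.008 per year thereafter). Utilities are
#' capped at 1.
#'
#' @param late_stage_extra Additional decrement while in the late-stage
#'   cancer state.
#' @param surgery_disutility QoL loss in the year of benign surgery.
#' @param surgery_gain Annual QoL gain in subsequent years.
#' @return Object of class `utility_model`.
#' @export
synth_qol_params <- function(late_stage_extra = 0.046,
                             surgery_disutility = 0.04,
                             surgery_gain = 0.008) {
  decrements <- data.frame(
    type = CANCER_TYPES,
    within1 = c(0.10, 0.10, 0.08, 0.15, 0.18, 0.08),
    after1  = c(0.05, 0.05, 0.04, 0.08, 0.10, 0.04)
  )
  structure(
    list(
      base = function(age) 0.9508566 - 0.0002587 * age - 0.0000332 * age^2,
      decrements = decrements,
      late_stage_extra = late_stage_extra,
      surgery_disutility = surgery_disutility,
      surgery_gain = surgery_gain,
      surgery_disutility_ci = c(0.01, 0.06),
      surgery_gain_ci = c(-0.005, 0.021)
    ),
    class = "utility_model"
  )
}

utility_at <- function(qol, age, type = "NONE", stage = NULL, t_since_dx = 0) {
  u <- qol$base(age)
  if (!identical(type, "NONE")) {
    d <- qol$decrements[qol$decrements$type == type, , drop = FALSE]
    if (nrow(d) != 1) stop("no utility decrement for cancer type ", type)
    u <- u - ifelse(t_since_dx < 1, d$within1, d$after1)
    if (identical(stage, "LATE")) u <- u - qol$late_stage_extra
  }
  pmin(u, 1)
}

#' Synthetic inpatient cost curves
#'
#' Annual hospital inpatient cost per cancer type and stage as a step
#' function of years since diagnosis (annual levels 0, 1, 2, 3, 4+), with
#' late-stage year-0 cost at or above early-stage, plus a constant background
#' annual inpatient cost for women without cancer. All values are synthetic
#' documented defaults in 2022 GBP.
#'
#' @param background Annual inpatient cost without a cancer diagnosis.
#' @return Object of class `cost_models`.
#' @export
synth_cost_models <- function(background = 450) {
  steps <- rbind(
    OVARIAN_EARLY    = c(12000, 4000, 2500, 1800, 1200),
    OVARIAN_LATE     = c(22000, 9000, 5000, 3500, 2500),
    LOWER_GI_EARLY   = c(10000, 3500, 2200, 1600, 1100),
    LOWER_GI_LATE    = c(18000, 8000, 4500, 3000, 2200),
    UTERINE_EARLY    = c(8000, 2500, 1500, 1200, 900),
    UTERINE_LATE     = c(15000, 6500, 3800, 2800, 2000),
    LUNG_EARLY       = c(11000, 5000, 3000, 2200, 1500),
    LUNG_LATE        = c(16000, 9000, 6000, 4000, 3000),
    PANCREATIC_EARLY = c(13000, 6000, 3500, 2500, 1800),
    PANCREATIC_LATE  = c(19000, 10000, 6500, 4500, 3200),
    OTHER_EARLY      = c(9000, 3000, 2000, 1500, 1000),
    OTHER_LATE       = c(15000, 7000, 4000, 3000, 2200)
  )
  colnames(steps) <- c("y0", "y1", "y2", "y3", "y4p")
  if (any(steps < 0) || background < 0) stop("costs must be non-negative")
  structure(list(steps = steps, background = background),
            class = "cost_models")
}

cost_at <- function(costs, type, stage = NULL, t_since_dx = 0) {
  if (identical(type, "NONE")) return(costs$background)
  key <- paste(type, stage, sep = "_")
  row <- costs$steps[key, ]
  idx <- min(floor(t_since_dx), 4) + 1
  unname(row[idx])
}

#' Default unit costs of the primary-care pathway (2022 GBP)
#'
#' @export
default_unit_costs <- function() {
  structure(
    list(ca125_test = 10, nurse_blood = 9, uss = 204,
         gp_face_to_face = 40, gp_telephone = 20,
         outpatient = 181, benign_surgery = 3994, benign_surgery_rate = 0.75,
         surgery_complication_rate = 0, surgery_complication_cost = 0),
    class = "unit_costs"
  )
}

#' Assemble the full synthetic model parametrization
#'
#' Bundles everything the pipeline needs: population strata, survival models,
#' life table, cost curves, utility model, test-accuracy table, unit costs
#' and the stage-shift relative risk (0.836, 95% CI 0.737-0.950: the relative
#' risk of late-stage diagnosis for earlier-detected vs usual-care cases).
#' The base case is fully deterministic; randomness enters only through the
#' probabilistic sensitivity analysis.
#'
#' @param strata,survival,life_table,qol,costs,unit_costs,accuracy Component
#'   overrides; defaults are the synthetic calibrated stand-ins.
#' @param rr_late Stage-shift relative risk.
#' @param rr_late_ci 95% CI of `rr_late` (used by the PSA).
#' @param other_late_stage_prop Late-stage proportion assumed for the other
#'   (non-ovarian) cancer types (synthetic default 0.5, pathway-invariant in
#'   the base case).
#' @return Object of class `triage_profile`.
#' @export
synthetic_profile <- function(strata = default_population(),
                              survival = synth_survival(),
                              life_table = synth_life_table(),
                              qol = synth_qol_params(),
                              costs = synth_cost_models(),
                              unit_costs = default_unit_costs(),
                              accuracy = read_accuracy_table(),
                              rr_late = 0.836,
                              rr_late_ci = c(0.737, 0.950),
                              other_late_stage_prop = 0.5) {
  if (rr_late <= 0) stop("rr_late must be positive")
  if (rr_late > 1) {
    warning("rr_late > 1; capping at 1")
    rr_late <- 1
  }
  structure(
    list(strata = strata, survival = survival, life_table = life_table,
         qol = qol, costs = costs, unit_costs = unit_costs,
         accuracy = accuracy, rr_late = rr_late, rr_late_ci = rr_late_ci,
         other_late_stage_prop = other_late_stage_prop,
         synthetic = TRUE),
    class = "triage_profile"
  )
}
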