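# Five-state lifetime Markov cohort model, annual cycles:
# NO_CANCER, EARLY_CANCER, LATE_CANCER (entry states) and the absorbing
# CANCER_DEATH / NONCANCER_DEATH. Cancer-death risk in the first
# `survival_model_horizon` years after diagnosis comes from the
# stage-specific survival models; beyond the horizon (and for women without
# a cancer diagnosis) from the cause-partitioned life table at current age.
# No early<->late transitions: progression is subsumed in the stage-specific
# death risk. Competing risks within a cycle are combined on the hazard
# scale with the joint-death overlap allocated proportionally to hazards.

MARKOV_STATES <- c("NO_CANCER", "EARLY_CANCER", "LATE_CANCER",
                   "CANCER_DEATH", "NONCANCER_DEATH")

#' Markov model settings
#'
#' @param max_age Age at which the simulation stops (default 110).
#' @param survival_model_horizon Years after diagnosis during which the
#'   stage-specific survival models drive cancer death (default 8; scenario
#'   15). Beyond it, life-table cancer mortality at current age applies.
#' @param discount_qaly,discount_cost Annual discount rates (default 0.035;
#'   scenario 0.015).
#' @param half_cycle Apply a half-cycle correction (default `FALSE`).
#' @export
markov_spec <- function(max_age = 110, survival_model_horizon = 8,
                        discount_qaly = 0.035, discount_cost = 0.035,
                        half_cycle = FALSE) {
  stopifnot(discount_qaly >= 0, discount_cost >= 0,
            survival_model_horizon >= 1, max_age > 18)
  structure(
    list(max_age = max_age, survival_model_horizon = survival_model_horizon,
         discount_qaly = discount_qaly, discount_cost = discount_cost,
         half_cycle = half_cycle),
    class = "markov_spec"
  )
}

life_table_at <- function(life_table, age) {
  i <- pmin(pmax(round(age), 0), max(life_table$age))
  idx <- match(i, life_table$age)
  list(cancer = life_table$cancer_mortality[idx],
       noncancer = life_table$noncancer_mortality[idx])
}

#' Annual probability of cancer death
#'
#' For `t_since_dx` below the survival-model horizon the probability comes
#' from the stage-specific (constant-hazard) survival model,
#' p = 1 - exp(-h); at or beyond the horizon it is the life-table cancer
#' mortality at current age.
#'
#' @param profile A `triage_profile`.
#' @param type Cancer type.
#' @param stage `"EARLY"` or `"LATE"`.
#' @param t_since_dx Whole years since diagnosis (cycle index).
#' @param age Current age.
#' @param spec A [markov_spec()].
#' @export
annual_cancer_death_prob <- function(profile, type, stage, t_since_dx, age,
                                     spec = markov_spec()) {
  if (any(t_since_dx < 0)) stop("t_since_dx must be non-negative")
  ifelse(t_since_dx < spec$survival_model_horizon,
         1 - exp(-cancer_hazard(profile$survival, type, stage)),
         life_table_at(profile$life_table, age)$cancer)
}

# competing-risk split: annual probs from two hazards, overlap allocated
# proportionally to hazards; reduces to the single-risk form when one is 0
combine_risks <- function(h_cancer, h_noncancer) {
  h_tot <- h_cancer + h_noncancer
  p_dead <- 1 - exp(-h_tot)
  share <- ifelse(h_tot > 0, h_cancer / h_tot, 0)
  list(cancer = p_dead * share, noncancer = p_dead * (1 - share))
}

#' One row of the Markov transition matrix
#'
#' @param state One of the five model states.
#' @param age Current age.
#' @param t_since_dx Years since diagnosis (cancer states).
#' @param profile A `triage_profile`.
#' @param spec A [markov_spec()].
#' @param type Cancer type (cancer states only).
#' @return Named probability vector over the five states, summing to 1.
#' @export
build_transition_row <- function(state, age, t_since_dx = 0,
                                 profile, spec = markov_spec(),
                                 type = "OVARIAN") {
  row <- stats::setNames(numeric(5), MARKOV_STATES)
  if (state %in% c("CANCER_DEATH", "NONCANCER_DEATH")) {
    row[state] <- 1
    return(row)
  }
  lt <- life_table_at(profile$life_table, age)
  h_nc <- -log(1 - pmin(lt$noncancer, 1 - 1e-12))
  if (state == "NO_CANCER") {
    h_c <- -log(1 - pmin(lt$cancer, 1 - 1e-12))
  } else {
    stage <- if (state == "EARLY_CANCER") "EARLY" else "LATE"
    p_c <- annual_cancer_death_prob(profile, type, stage, t_since_dx, age, spec)
    h_c <- -log(1 - pmin(p_c, 1 - 1e-12))
  }
  p <- combine_risks(h_c, h_nc)
  row["CANCER_DEATH"] <- p$cancer
  row["NONCANCER_DEATH"] <- p$noncancer
  row[state] <- 1 - p$cancer - p$noncancer
  row
}

#' Run the Markov cohort
#'
#' Projects a cohort entering at one age with a mix over entry states through
#' annual cycles until `max_age`. Deterministic.
#'
#' @param entry_mix Named probability vector over the five states (live
#'   entries usually over the three entry states); must sum to 1.
#' @param entry_age Integer entry age.
#' @param profile A `triage_profile`.
#' @param spec A [markov_spec()].
#' @param type Cancer type governing the cancer states' survival, QoL and
#'   costs.
#' @return Object of class `markov_trajectory`: matrix of state occupancy,
#'   one row per cycle start (cycle 0 = entry), plus attributes.
#' @export
run_cohort <- function(entry_mix, entry_age, profile, spec = markov_spec(),
                       type = "OVARIAN") {
  mix <- stats::setNames(numeric(5), MARKOV_STATES)
  mix[names(entry_mix)] <- entry_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("entry_mix must sum to 1")
  n_cycles <- max(spec$max_age - entry_age, 0)
  traj <- matrix(0, nrow = n_cycles + 1, ncol = 5,
                 dimnames = list(NULL, MARKOV_STATES))
  traj[1, ] <- mix
  occ <- mix
  for (t in seq_len(n_cycles) - 1L) {
    age <- entry_age + t
    nxt <- occ
    for (st in c("NO_CANCER", "EARLY_CANCER", "LATE_CANCER")) {
      if (occ[st] > 0) {
        row <- build_transition_row(st, age, t, profile, spec, type)
        nxt[st] <- occ[st] * row[st]
        nxt["CANCER_DEATH"] <- nxt["CANCER_DEATH"] + occ[st] * row["CANCER_DEATH"]
        nxt["NONCANCER_DEATH"] <- nxt["NONCANCER_DEATH"] + occ[st] * row["NONCANCER_DEATH"]
      }
    }
    occ <- nxt
    traj[t + 2L, ] <- occ
  }
  structure(traj, class = c("markov_trajectory", class(traj)),
            entry_age = entry_age, type = type)
}

#' Discounted lifetime outcomes of a trajectory
#'
#' Accumulates discounted QALYs, life years and inpatient costs over the
#' trajectory. Per-cycle utility is the age-declining baseline minus cancer
#' decrements (by type, recency and stage; the extra late-stage decrement
#' applies every cycle spent in the late-stage state); per-cycle costs come
#' from the stage- and time-since-diagnosis-specific cost curves, with the
#' background inpatient cost for women without cancer. Discount factor
#' (1+r)^(-t) with t = 0 for the first cycle.
#'
#' @param trajectory A `markov_trajectory` from [run_cohort()].
#' @param profile A `triage_profile` (utility and cost models).
#' @param spec A [markov_spec()].
#' @return List with `qaly`, `ly`, `cost` (all discounted).
#' @export
lifetime_outcomes <- function(trajectory, profile, spec = markov_spec()) {
  entry_age <- attr(trajectory, "entry_age")
  type <- attr(trajectory, "type")
  n_cycles <- nrow(trajectory) - 1L
  if (n_cycles == 0) return(list(qaly = 0, ly = 0, cost = 0))
  t <- seq_len(n_cycles) - 1L
  age <- entry_age + t
  occ <- trajectory[seq_len(n_cycles), , drop = FALSE]
  if (spec$half_cycle) {
    occ <- (occ + trajectory[seq_len(n_cycles) + 1L, , drop = FALSE]) / 2
  }
  vq <- (1 + spec$discount_qaly)^(-t)
  vc <- (1 + spec$discount_cost)^(-t)
  u_nc <- utility_at(profile$qol, age)
  u_ec <- utility_at(profile$qol, age, type, "EARLY", t_since_dx = t)
  u_lc <- utility_at(profile$qol, age, type, "LATE", t_since_dx = t)
  c_nc <- rep(cost_at(profile$costs, "NONE"), n_cycles)
  c_ec <- vapply(t, function(tt) cost_at(profile$costs, type, "EARLY", tt), 0)
  c_lc <- vapply(t, function(tt) cost_at(profile$costs, type, "LATE", tt), 0)
  alive <- occ[, "NO_CANCER"] + occ[, "EARLY_CANCER"] + occ[, "LATE_CANCER"]
  qaly <- sum(vq * (occ[, "NO_CANCER"] * u_nc +
                    occ[, "EARLY_CANCER"] * u_ec +
                    occ[, "LATE_CANCER"] * u_lc))
  cost <- sum(vc * (occ[, "NO_CANCER"] * c_nc +
                    occ[, "EARLY_CANCER"] * c_ec +
                    occ[, "LATE_CANCER"] * c_lc))
  list(qaly = qaly, ly = sum(vq * alive), cost = cost)
}

# Per-age lifetime outcomes for every cohort component a stratum needs:
# "NONE" plus each cancer type x stage. Also returns, for the no-cancer
# component, the discounted survival annuity from year 1 on (used for the
# benign-surgery QoL adjustment) and the discounted per-age life expectancy.
# This table depends only on (profile survival/life-table/qol/costs, spec),
# so it is computed once and reused across pathways, sweep cells and PSA
# draws (none of which perturb those inputs).
markov_component_table <- function(stratum, profile, spec = markov_spec()) {
  ages <- as.integer(names(stratum$age_weights))
  comps <- c("NONE", as.vector(outer(CANCER_TYPES, c("EARLY", "LATE"),
                                     paste, sep = "_")))
  out <- list()
  for (cmp in comps) {
    if (cmp == "NONE") {
      entry <- c(NO_CANCER = 1); type <- "OVARIAN"
    } else {
      parts <- strsplit(cmp, "_(?=EARLY$|LATE$)", perl = TRUE)[[1]]
      type <- parts[1]
      entry <- if (parts[2] == "EARLY") c(EARLY_CANCER = 1) else c(LATE_CANCER = 1)
    }
    res <- matrix(0, nrow = length(ages), ncol = 4,
                  dimnames = list(NULL, c("qaly", "ly", "cost", "annuity")))
    for (i in seq_along(ages)) {
      traj <- run_cohort(entry, ages[i], profile, spec, type)
      o <- lifetime_outcomes(traj, profile, spec)
      ann <- 0
      if (cmp == "NONE" && nrow(traj) > 2) {
        tt <- seq_len(nrow(traj) - 2L)
        ann <- sum((1 + spec$discount_qaly)^(-tt) * traj[tt + 1L, "NO_CANCER"])
      }
      res[i, ] <- c(o$qaly, o$ly, o$cost, ann)
    }
    out[[cmp]] <- data.frame(age = ages, res)
  }
  structure(out, ages = ages, class = "markov_component_table")
}

# age-weighted average of a component column
weight_component <- function(tab, stratum, column) {
  sum(stratum$age_weights * tab[[column]])
}
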