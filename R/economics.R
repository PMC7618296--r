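# Cost-effectiveness layer: combines the diagnostic tree and the Markov
# cohort into per-pathway discounted QALYs/costs per 1000 women, incremental
# analysis against current practice, ICER frontiers with (extended)
# dominance, probabilistic sensitivity analysis, CEACs and the Ovatools
# risk-threshold sweep.

#' Cost-effectiveness of one pathway on one stratum
#'
#' Evaluates the decision tree, applies the stage shift against the reference
#' pathway (current practice), routes the outcome classes through the Markov
#' model (age-distribution weighted), and adds primary-care and
#' false-positive secondary-care costs. Women with other cancers traverse the
#' model with their own synthetic survival/cost/utility curves and are
#' pathway-invariant in the base case; benign-surgery costs and QoL effects
#' apply only to referred women without any cancer diagnosis.
#'
#' @param pathway A [pathway_definition()].
#' @param stratum A [population_stratum()].
#' @param profile A [synthetic_profile()].
#' @param spec A [markov_spec()].
#' @param cache Optional precomputed `markov_component_table` for the stratum.
#' @param accuracy Accuracy table override (e.g. a PSA draw).
#' @param rr_late Stage-shift relative risk override.
#' @param surgery_disutility,surgery_gain Benign-surgery QoL overrides.
#' @param ref_pathway Reference pathway for the stage shift (default
#'   pathway 1, current practice).
#' @param roc Optional pre-built ROC curve for non-tabulated risk thresholds.
#' @param other_cancer_effects Optional list `list(rr = ...)` enabling the
#'   scenario in which incremental detection also shifts other-cancer staging
#'   (a stage-shift analog scaled by the pathway's incremental ovarian
#'   detection; parameters are user-supplied).
#' @return Object of class `ce_result`: a one-row data frame with per-1000
#'   discounted QALYs, LYs and costs, detection/referral rates and a cost
#'   breakdown.
#' @export
pathway_ce <- function(pathway, stratum, profile = synthetic_profile(),
                       spec = markov_spec(), cache = NULL,
                       accuracy = profile$accuracy,
                       rr_late = profile$rr_late,
                       surgery_disutility = profile$qol$surgery_disutility,
                       surgery_gain = profile$qol$surgery_gain,
                       ref_pathway = default_pathways()$P1,
                       roc = NULL, other_cancer_effects = NULL) {
  if (is.null(cache)) cache <- markov_component_table(stratum, profile, spec)
  out <- evaluate_pathway(pathway, stratum, accuracy, roc)
  ref <- evaluate_pathway(ref_pathway, stratum, accuracy, roc)
  out <- apply_stage_shift(out, ref, rr_late, stratum)

  prev <- stratum$oc_prevalence
  q_other <- stratum$other_cancer_prev
  late_det <- out$late_stage_prop_detected
  late_mis <- out$late_stage_prop_missed
  late_other <- rep(profile$other_late_stage_prop, length(q_other))
  names(late_other) <- names(q_other)
  if (!is.null(other_cancer_effects)) {
    d_det <- max(0, out$detection_rate - ref$detection_rate)
    late_other <- late_other * (1 - d_det * (1 - other_cancer_effects$rr))
  }

  w <- c(NONE = 1 - prev - sum(q_other),
         OVARIAN_EARLY = out$p_tp * (1 - late_det) + out$p_fn * (1 - late_mis),
         OVARIAN_LATE = out$p_tp * late_det + out$p_fn * late_mis)
  for (ty in names(q_other)) {
    w[paste0(ty, "_EARLY")] <- q_other[[ty]] * (1 - late_other[[ty]])
    w[paste0(ty, "_LATE")] <- q_other[[ty]] * late_other[[ty]]
  }

  agg <- function(col) {
    sum(vapply(names(w), function(cmp) {
      w[[cmp]] * weight_component(cache[[cmp]], stratum, col)
    }, 0))
  }
  qaly <- agg("qaly"); ly <- agg("ly"); inpatient <- agg("cost")

  # benign-surgery QoL layered on the no-cancer trajectory of FP referrals
  fp_nocancer <- out$p_fp * (1 - prev - sum(q_other)) / (1 - prev)
  surg_mass <- profile$unit_costs$benign_surgery_rate * fp_nocancer
  annuity <- weight_component(cache$NONE, stratum, "annuity")
  qaly <- qaly + surg_mass * (-surgery_disutility + surgery_gain * annuity)

  epc <- expected_primary_care_cost(pathway, out$accuracy, profile$unit_costs)
  primary <- prev * epc$oc + (1 - prev) * epc$no_oc
  fp_secondary <- fp_nocancer * fp_secondary_cost(profile$unit_costs)

  res <- data.frame(
    pathway_id = pathway$id, age_group = stratum$age_group,
    detection_rate = out$detection_rate, referral_rate = out$referral_rate,
    qaly = 1000 * qaly, ly = 1000 * ly,
    cost = 1000 * (inpatient + primary + fp_secondary),
    cost_primary = 1000 * primary,
    cost_fp_secondary = 1000 * fp_secondary,
    cost_inpatient = 1000 * inpatient
  )
  class(res) <- c("ce_result", class(res))
  res
}

#' Incremental QALYs and costs against a comparator pathway
#'
#' @param results Data frame of per-pathway results (rows of `ce_result`).
#' @param comparator_id Comparator pathway id (default 1, current practice).
#' @return `results` with `dqaly` and `dcost` columns (comparator row zero).
#' @export
incremental <- function(results, comparator_id = 1) {
  i <- which(results$pathway_id == comparator_id)
  if (length(i) != 1) stop("comparator pathway ", comparator_id, " not present")
  results$dqaly <- results$qaly - results$qaly[i]
  results$dcost <- results$cost - results$cost[i]
  results
}

# standard frontier algorithm on a plain (id, qaly, cost) table:
# sort by cost, drop strictly dominated options, then iteratively drop
# options whose pairwise ICER sequence is non-increasing until the frontier
# ICERs are strictly increasing
frontier_core <- function(df) {
  n <- nrow(df)
  dominated <- logical(n); tie <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$qaly[j] >= df$qaly[i] && df$cost[j] <= df$cost[i]) {
        if (df$qaly[j] > df$qaly[i] || df$cost[j] < df$cost[i]) {
          dominated[i] <- TRUE
        } else if (df$pathway_id[j] < df$pathway_id[i]) {
          dominated[i] <- TRUE; tie[i] <- TRUE
        }
      }
    }
  }
  ext <- logical(n)
  active <- which(!dominated)
  repeat {
    ord <- active[order(df$cost[active], df$qaly[active])]
    if (length(ord) < 3) break
    icers <- diff(df$cost[ord]) / diff(df$qaly[ord])
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    drop_i <- ord[bad[1] + 1L]   # middle point of the first non-increasing step
    ext[drop_i] <- TRUE
    active <- setdiff(active, drop_i)
  }
  ord <- active[order(df$cost[active], df$qaly[active])]
  icer <- rep(NA_real_, n); comparator <- rep(NA_integer_, n)
  if (length(ord) > 1) {
    for (k in 2:length(ord)) {
      i <- ord[k]; j <- ord[k - 1]
      icer[i] <- (df$cost[i] - df$cost[j]) / (df$qaly[i] - df$qaly[j])
      comparator[i] <- df$pathway_id[j]
    }
  }
  data.frame(pathway_id = df$pathway_id, qaly = df$qaly, cost = df$cost,
             dominated = dominated, extendedly_dominated = ext,
             on_frontier = !dominated & !ext, tie = tie,
             icer = icer, comparator = comparator)
}

#' ICER frontier with (extended) dominance
#'
#' Sorts pathways by cost, removes strictly dominated options, iteratively
#' removes extendedly dominated options until the frontier ICER ladder is
#' strictly increasing, and reports each frontier member's ICER against its
#' lower frontier neighbour. Pathways listed together in `no_compare_groups`
#' (by default the Ovatools pathway and its age-adjusted CA125 twin, 2/3 and
#' 4/5) are never compared with each other: each is evaluated in a frontier
#' that contains, from every other variant group, only that group's lowest-id
#' member, and is reported against the shared lower neighbour.
#'
#' @param results Data frame with columns `pathway_id`, `qaly`, `cost`
#'   (absolute or incremental; differences are what matter).
#' @param no_compare_groups List of integer vectors of mutually
#'   non-comparable pathway ids; `NULL` disables the rule.
#' @return Object of class `frontier_result`: per-pathway flags
#'   (`dominated`, `extendedly_dominated`, `on_frontier`, `tie`), `icer` and
#'   `comparator`.
#' @export
icer_frontier <- function(results,
                          no_compare_groups = list(c(2L, 3L), c(4L, 5L))) {
  df <- as.data.frame(results)[, c("pathway_id", "qaly", "cost")]
  if (nrow(df) < 1) stop("no pathways to compare")
  grp_of <- function(id) {
    for (k in seq_along(no_compare_groups)) {
      if (id %in% no_compare_groups[[k]]) return(k)
    }
    NA_integer_
  }
  if (is.null(no_compare_groups) || nrow(df) == 1) {
    out <- frontier_core(df)
  } else {
    out <- NULL
    for (r in seq_len(nrow(df))) {
      id <- df$pathway_id[r]
      # an option's evaluation subset: itself, all ungrouped options, and the
      # lowest-id member of every *other* variant group
      keep <- vapply(df$pathway_id, function(j) {
        gj <- grp_of(j); gi <- grp_of(id)
        if (j == id) return(TRUE)
        if (is.na(gj)) return(TRUE)
        if (!is.na(gi) && gj == gi) return(FALSE)
        j == min(intersect(no_compare_groups[[gj]], df$pathway_id))
      }, TRUE)
      sub <- frontier_core(df[keep, , drop = FALSE])
      out <- rbind(out, sub[sub$pathway_id == id, , drop = FALSE])
    }
    out <- out[match(df$pathway_id, out$pathway_id), ]
    rownames(out) <- NULL
  }
  class(out) <- c("frontier_result", class(out))
  out
}

#' Net monetary benefit
#'
#' @param dqaly,dcost Incremental QALYs and cost.
#' @param lambda Willingness-to-pay threshold (GBP per QALY), non-negative.
#' @return `lambda * dqaly - dcost`.
#' @export
net_benefit <- function(dqaly, dcost, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  lambda * dqaly - dcost
}

beta_moments <- function(mean, lo, hi) {
  s <- (hi - lo) / (2 * stats::qnorm(0.975))
  v <- s^2
  if (v <= 0) return(NULL)
  if (v >= mean * (1 - mean)) {
    stop("parameter distribution error: CI inconsistent with [0,1] support")
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

draw_accuracy_table <- function(table, n) {
  draws <- vector("list", nrow(table))
  for (r in seq_len(nrow(table))) {
    ps <- beta_moments(table$sensitivity[r], table$sens_low[r], table$sens_high[r])
    pq <- beta_moments(table$specificity[r], table$spec_low[r], table$spec_high[r])
    draws[[r]] <- list(
      sens = if (is.null(ps)) rep(table$sensitivity[r], n)
             else stats::rbeta(n, ps[1], ps[2]),
      spec = if (is.null(pq)) rep(table$specificity[r], n)
             else stats::rbeta(n, pq[1], pq[2])
    )
  }
  draws
}

# keep drawn Ovatools operating points ROC-consistent within an age group:
# the higher risk threshold may not have higher sensitivity or lower
# specificity than the lower threshold
enforce_roc_order <- function(tab) {
  for (ag in unique(tab$age_group)) {
    i1 <- which(tab$test_id == "OVATOOLS" & tab$age_group == ag &
                  tab$threshold_label == "1%")
    i3 <- which(tab$test_id == "OVATOOLS" & tab$age_group == ag &
                  tab$threshold_label == "3%")
    if (length(i1) == 1 && length(i3) == 1) {
      tab$sensitivity[i3] <- min(tab$sensitivity[i3], tab$sensitivity[i1])
      tab$specificity[i3] <- max(tab$specificity[i3], tab$specificity[i1])
    }
  }
  tab
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets (beta distributions, method-of-moments from the
#' printed 95% CIs, for sensitivities and specificities; lognormal matched to
#' its CI for the stage-shift relative risk, capped at 1; normal for the two
#' benign-surgery QoL deltas; parameters printed without uncertainty held
#' fixed) and evaluates the full model per draw. Reproducible given the seed.
#'
#' @param stratum A [population_stratum()].
#' @param profile A [synthetic_profile()].
#' @param spec A [markov_spec()].
#' @param n Number of draws (default 1000).
#' @param seed Integer seed.
#' @param pathways List of pathways to evaluate.
#' @param cache Optional precomputed `markov_component_table`.
#' @return Object of class `triage_psa` with the draw table and per-draw,
#'   per-pathway QALYs and costs per 1000 women.
#' @export
run_psa <- function(stratum, profile = synthetic_profile(),
                    spec = markov_spec(), n = 1000, seed = 1,
                    pathways = default_pathways(), cache = NULL) {
  stopifnot(n >= 1)
  if (is.null(cache)) cache <- markov_component_table(stratum, profile, spec)
  set.seed(seed)
  acc_draws <- draw_accuracy_table(profile$accuracy, n)
  mu <- log(profile$rr_late)
  sdlog <- (log(profile$rr_late_ci[2]) - log(profile$rr_late_ci[1])) /
    (2 * stats::qnorm(0.975))
  rr_draws <- stats::rlnorm(n, mu, sdlog)
  if (any(rr_draws > 1)) {
    warning(sum(rr_draws > 1), " rr_late draw(s) > 1 capped at 1")
    rr_draws <- pmin(rr_draws, 1)
  }
  sd_dis <- diff(profile$qol$surgery_disutility_ci) / (2 * stats::qnorm(0.975))
  sd_gain <- diff(profile$qol$surgery_gain_ci) / (2 * stats::qnorm(0.975))
  dis_draws <- stats::rnorm(n, profile$qol$surgery_disutility, sd_dis)
  gain_draws <- stats::rnorm(n, profile$qol$surgery_gain, sd_gain)

  npw <- length(pathways)
  ids <- vapply(pathways, function(p) p$id, 0L)
  qaly <- matrix(NA_real_, n, npw, dimnames = list(NULL, paste0("P", ids)))
  cost <- qaly
  tab0 <- profile$accuracy
  for (d in seq_len(n)) {
    tab <- tab0
    for (r in seq_len(nrow(tab))) {
      tab$sensitivity[r] <- acc_draws[[r]]$sens[d]
      tab$specificity[r] <- acc_draws[[r]]$spec[d]
    }
    tab <- enforce_roc_order(tab)
    for (k in seq_len(npw)) {
      ce <- pathway_ce(pathways[[k]], stratum, profile, spec, cache,
                       accuracy = tab, rr_late = rr_draws[d],
                       surgery_disutility = dis_draws[d],
                       surgery_gain = gain_draws[d])
      qaly[d, k] <- ce$qaly
      cost[d, k] <- ce$cost
    }
  }
  draws <- data.frame(rr_late = rr_draws, surgery_disutility = dis_draws,
                      surgery_gain = gain_draws)
  for (r in seq_len(nrow(tab0))) {
    nm <- paste(tab0$test_id[r], tab0$age_group[r], tab0$threshold_label[r], sep = ".")
    draws[[paste0("sens.", nm)]] <- acc_draws[[r]]$sens
    draws[[paste0("spec.", nm)]] <- acc_draws[[r]]$spec
  }
  structure(
    list(n = n, seed = seed, pathway_ids = ids, draws = draws,
         qaly = qaly, cost = cost, age_group = stratum$age_group),
    class = "triage_psa"
  )
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, the probability that each pathway
#' has the maximal net benefit across the PSA draws (ties split equally).
#'
#' @param psa A `triage_psa` from [run_psa()].
#' @param lambda_grid Thresholds in GBP/QALY (default 0 to 50,000 by 1,000).
#' @return Object of class `ceac_curve`: long data frame with `lambda`,
#'   `pathway_id`, `probability`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 50000, by = 1000)) {
  if (!inherits(psa, "triage_psa") || psa$n < 1) stop("empty PSA result")
  if (!length(lambda_grid) || any(lambda_grid < 0)) {
    stop("lambda_grid must be non-empty and non-negative")
  }
  npw <- length(psa$pathway_ids)
  out <- NULL
  for (lam in lambda_grid) {
    nb <- lam * psa$qaly - psa$cost
    wins <- numeric(npw)
    mx <- apply(nb, 1, max)
    for (d in seq_len(psa$n)) {
      top <- which(nb[d, ] >= mx[d] - 1e-9)
      wins[top] <- wins[top] + 1 / length(top)
    }
    out <- rbind(out, data.frame(lambda = lam, pathway_id = psa$pathway_ids,
                                 probability = wins / psa$n))
  }
  rownames(out) <- NULL
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Ovatools risk-threshold sweep
#'
#' Re-evaluates the sequential risk-banded pathway (pathway 2) against
#' current practice over a grid of (moderate, high) Ovatools risk thresholds,
#' with accuracy at non-tabulated thresholds interpolated on the binormal ROC
#' curve. Cells where pathway 2 is dominated (fewer QALYs at higher cost) or
#' dominating (more QALYs at lower cost) are flagged; in the south-west
#' quadrant (fewer QALYs, lower cost) the ratio reported is savings per QALY
#' forgone.
#'
#' @param stratum A [population_stratum()].
#' @param profile,spec Model parametrization.
#' @param moderate_grid,high_grid Risk-threshold grids (fractions); only
#'   cells with moderate < high are evaluated.
#' @param cache Optional precomputed component table.
#' @return Data frame with `moderate`, `high`, `dqaly`, `dcost`, `icer`,
#'   `flag` per 1000 women.
#' @export
threshold_sweep <- function(stratum, profile = synthetic_profile(),
                            spec = markov_spec(),
                            moderate_grid = seq(0.006, 0.04, by = 0.002),
                            high_grid = seq(0.01, 0.04, by = 0.005),
                            cache = NULL) {
  if (is.null(cache)) cache <- markov_component_table(stratum, profile, spec)
  roc <- ovatools_roc(stratum$age_group, profile$accuracy)
  p1 <- default_pathways()$P1
  ce1 <- pathway_ce(p1, stratum, profile, spec, cache, roc = roc)
  out <- NULL
  for (h in high_grid) {
    for (m in moderate_grid) {
      if (m >= h) next
      pw <- pathway_definition(2L, "SEQUENTIAL", "OVATOOLS", m, h)
      ce <- pathway_ce(pw, stratum, profile, spec, cache, roc = roc)
      dq <- ce$qaly - ce1$qaly
      dc <- ce$cost - ce1$cost
      flag <- if (dq > 0 && dc <= 0) "dominant"
              else if (dq <= 0 && dc >= 0) "dominated"
              else if (dq < 0 && dc < 0) "sw"
              else ""
      out <- rbind(out, data.frame(
        moderate = m, high = h, dqaly = dq, dcost = dc,
        icer = if (dq != 0) dc / dq else NA_real_, flag = flag
      ))
    }
  }
  rownames(out) <- NULL
  out
}
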