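#' Evaluate the ovarian-cancer triage pathways
#'
#' The package front end: runs the full decision-analytic model — diagnostic
#' decision tree, stage shift, lifetime Markov cohort projection and
#' cost-effectiveness analysis — for the six triage pathways on one or both
#' age strata, and returns a classed result with `print`, `summary`, `plot`
#' and `simulate` (probabilistic sensitivity analysis) methods.
#'
#' @param age_group `"GE50"`, `"UNDER50"` or `"BOTH"`.
#' @param profile Model parametrization from [synthetic_profile()] (or built
#'   from user-supplied delimited files via its component readers).
#' @param spec Markov settings from [markov_spec()].
#' @param pathways List of [pathway_definition()]s (default: the six
#'   published pathways).
#' @param config Optional `triage_config` (from [load_config()]); scenario
#'   switches in the config override `profile`/`spec` defaults.
#' @return Object of class `triage_ce`: per-stratum per-pathway results,
#'   incremental analysis vs current practice, and the dominance-pruned ICER
#'   frontier.
#' @examples
#' fit <- triage_ce("GE50")
#' fit
#' summary(fit)
#' @export
triage_ce <- function(age_group = c("BOTH", "GE50", "UNDER50"),
                      profile = NULL, spec = NULL,
                      pathways = default_pathways(), config = NULL) {
  age_group <- match.arg(age_group)
  if (!is.null(config)) {
    built <- apply_config(config)
    if (is.null(profile)) profile <- built$profile
    if (is.null(spec)) spec <- built$spec
    oce <- built$other_cancer_effects
  } else {
    oce <- NULL
  }
  if (is.null(profile)) profile <- synthetic_profile()
  if (is.null(spec)) spec <- markov_spec()
  groups <- if (age_group == "BOTH") c("UNDER50", "GE50") else age_group
  strata <- profile$strata[groups]
  out <- list(profile = profile, spec = spec, pathways = pathways,
              strata = strata, results = list(), frontier = list(),
              cache = list())
  for (g in groups) {
    stratum <- strata[[g]]
    cache <- markov_component_table(stratum, profile, spec)
    res <- do.call(rbind, lapply(pathways, function(pw) {
      pathway_ce(pw, stratum, profile, spec, cache,
                 other_cancer_effects = oce)
    }))
    rownames(res) <- NULL
    res <- incremental(res, comparator_id = 1)
    fr <- icer_frontier(res[, c("pathway_id", "qaly", "cost")])
    out$results[[g]] <- res
    out$frontier[[g]] <- fr
    out$cache[[g]] <- cache
  }
  class(out) <- "triage_ce"
  out
}

#' Tabulate a fitted triage evaluation in the published layout
#'
#' One row per pathway and stratum: detection and referral percentages
#' (rendered at the printed precision: one decimal below 10%, integers
#' above), incremental discounted QALYs and costs per 1000 women vs current
#' practice, and the frontier ICER with `D`/`ED` flags for (extendedly)
#' dominated pathways.
#'
#' @param fit A `triage_ce` object.
#' @return Data frame.
#' @export
ce_table <- function(fit) {
  stopifnot(inherits(fit, "triage_ce"))
  fmt_pct <- function(x) {
    p <- 100 * x
    ifelse(p >= 10, sprintf("%.0f", p), sprintf("%.1f", p))
  }
  out <- NULL
  for (g in names(fit$results)) {
    res <- fit$results[[g]]
    fr <- fit$frontier[[g]]
    icer <- ifelse(fr$dominated, "D",
                   ifelse(fr$extendedly_dominated, "ED",
                          ifelse(is.na(fr$icer), "",
                                 sprintf("%.0f", fr$icer))))
    out <- rbind(out, data.frame(
      age_group = g, pathway = res$pathway_id,
      detection_pct = fmt_pct(res$detection_rate),
      referral_pct = fmt_pct(res$referral_rate),
      dqaly_per_1000 = round(res$dqaly, 2),
      dcost_per_1000 = round(res$dcost),
      icer = icer
    ))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.triage_ce <- function(x, ...) {
  cat("Ovarian cancer triage pathway evaluation\n")
  cat(sprintf("  discount %.1f%%/yr (QALY) %.1f%%/yr (cost); survival-model horizon %d yr\n",
              100 * x$spec$discount_qaly, 100 * x$spec$discount_cost,
              x$spec$survival_model_horizon))
  for (g in names(x$strata)) {
    s <- x$strata[[g]]
    cat(sprintf("  %s: n=%s, OC prevalence %.2f%%, late stage %.0f%%\n",
                g, format(s$n_women, big.mark = ","),
                100 * s$oc_prevalence, 100 * s$late_stage_prop))
  }
  cat("\n")
  print(ce_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.triage_ce <- function(object, ...) {
  out <- list(table = ce_table(object), results = object$results,
              frontier = object$frontier)
  class(out) <- "summary.triage_ce"
  out
}

#' @export
print.summary.triage_ce <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("\nCost breakdown per 1000 women (GBP):\n")
  for (g in names(x$results)) {
    res <- x$results[[g]]
    cat(" ", g, "\n")
    print(data.frame(pathway = res$pathway_id,
                     primary_care = round(res$cost_primary),
                     fp_secondary = round(res$cost_fp_secondary),
                     inpatient = round(res$cost_inpatient),
                     total = round(res$cost)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted evaluation
#'
#' `simulate` draws `nsim` parameter sets and re-evaluates the model per
#' draw; see [run_psa()].
#'
#' @param object A `triage_ce` object.
#' @param nsim Number of PSA draws.
#' @param seed Integer seed.
#' @param age_group Which stratum to simulate (default: the first fitted).
#' @param ... Unused.
#' @return A `triage_psa` object.
#' @export
simulate.triage_ce <- function(object, nsim = 1000, seed = 1,
                               age_group = names(object$strata)[1], ...) {
  run_psa(object$strata[[age_group]], object$profile, object$spec,
          n = nsim, seed = seed, pathways = object$pathways,
          cache = object$cache[[age_group]])
}

#' Plot a fitted triage evaluation
#'
#' `type = "ce_plane"` draws the incremental cost-effectiveness plane (one
#' point per pathway vs current practice); `type = "ceac"` draws
#' cost-effectiveness acceptability curves and requires a `psa` object.
#'
#' @param x A `triage_ce` object.
#' @param type `"ce_plane"` or `"ceac"`.
#' @param age_group Stratum to plot.
#' @param psa A `triage_psa` (for `type = "ceac"`).
#' @param lambda_grid Thresholds for the CEAC.
#' @param ... Passed to the underlying plot call.
#' @export
plot.triage_ce <- function(x, type = c("ce_plane", "ceac"),
                           age_group = names(x$strata)[1], psa = NULL,
                           lambda_grid = seq(0, 50000, by = 1000), ...) {
  type <- match.arg(type)
  if (type == "ce_plane") {
    res <- x$results[[age_group]]
    graphics::plot(res$dqaly, res$dcost,
                   xlab = "Incremental QALYs per 1000 women",
                   ylab = "Incremental cost per 1000 women (GBP)",
                   main = paste("Cost-effectiveness plane,", age_group), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
    graphics::text(res$dqaly, res$dcost, labels = paste0("P", res$pathway_id),
                   pos = 3)
  } else {
    if (is.null(psa)) stop("type = 'ceac' needs a psa object from simulate()")
    cc <- ceac(psa, lambda_grid)
    ids <- unique(cc$pathway_id)
    graphics::plot(NULL, xlim = range(cc$lambda), ylim = c(0, 1),
                   xlab = "Willingness to pay (GBP/QALY)",
                   ylab = "Probability cost-effective",
                   main = paste("CEAC,", psa$age_group), ...)
    for (k in seq_along(ids)) {
      sub <- cc[cc$pathway_id == ids[k], ]
      graphics::lines(sub$lambda, sub$probability, col = k, lty = k)
    }
    graphics::legend("topright", legend = paste0("P", ids),
                     col = seq_along(ids), lty = seq_along(ids), cex = 0.8)
  }
  invisible(x)
}
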