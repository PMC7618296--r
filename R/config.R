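# Run configuration and result serialization. Configs are flat YAML
# key/value files; every switch defaults to the base case, unknown keys are
# rejected by name, and a load -> save -> load round trip is lossless.

#' Default run configuration
#'
#' All scenario switches at their base-case values: 3.5% discounting, 8-year
#' survival-model horizon, late-stage QoL decrement 0.046, published USS
#' accuracy and cost, benign-surgery rate 0.75 with no complication cost,
#' other-cancer effects off, PSA with 1000 draws.
#'
#' @param ... Named overrides of default fields.
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(...) {
  cfg <- list(
    age_group = "BOTH",
    accuracy_file = NA,
    discount_qaly = 0.035,
    discount_cost = 0.035,
    survival_horizon = 8,
    late_stage_decrement = 0.046,
    uss_sensitivity_mult = 1,
    uss_specificity_mult = 1,
    uss_cost = 204,
    surgery_rate_mult = 1,
    surgery_complication_rate = 0,
    surgery_complication_cost = 0,
    other_cancer_effects = FALSE,
    other_cancer_rr = 0.836,
    half_cycle = FALSE,
    psa_n = 1000,
    psa_seed = 1,
    out_dir = "results"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  class(cfg) <- "triage_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Missing keys are filled with base-case defaults; unknown keys raise an
#' error naming the offending key. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML config file.
#' @return A `triage_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(triage_config, raw)
}

#' Save a run configuration to YAML
#'
#' @param config A `triage_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "triage_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# translate a config into the profile/spec pair the model consumes
apply_config <- function(config) {
  stopifnot(inherits(config, "triage_config"))
  acc <- if (!is.na(config$accuracy_file)) {
    read_accuracy_table(config$accuracy_file)
  } else {
    read_accuracy_table()
  }
  if (config$uss_sensitivity_mult != 1 || config$uss_specificity_mult != 1) {
    i <- acc$test_id == "USS"
    acc$sensitivity[i] <- pmin(1, acc$sensitivity[i] * config$uss_sensitivity_mult)
    acc$specificity[i] <- pmin(1, acc$specificity[i] * config$uss_specificity_mult)
  }
  uc <- default_unit_costs()
  uc$uss <- config$uss_cost
  uc$benign_surgery_rate <- min(1, uc$benign_surgery_rate * config$surgery_rate_mult)
  uc$surgery_complication_rate <- config$surgery_complication_rate
  uc$surgery_complication_cost <- config$surgery_complication_cost
  profile <- synthetic_profile(
    qol = synth_qol_params(late_stage_extra = config$late_stage_decrement),
    unit_costs = uc, accuracy = acc
  )
  spec <- markov_spec(
    survival_model_horizon = config$survival_horizon,
    discount_qaly = config$discount_qaly,
    discount_cost = config$discount_cost,
    half_cycle = config$half_cycle
  )
  oce <- if (isTRUE(config$other_cancer_effects)) {
    list(rr = config$other_cancer_rr)
  } else NULL
  list(profile = profile, spec = spec, other_cancer_effects = oce)
}

#' Write evaluation results as delimited tables
#'
#' Emits, under `out_dir`: `summary.csv` (pathway, detection/referral
#' percentages at printed precision, incremental QALYs/costs per 1000, ICER
#' with D/ED flags), `cost_breakdown.csv`, optionally `ceac.csv` and
#' `sweep.csv`, and `run_metadata.yaml` recording the resolved config, its
#' hash, the PSA seed and the package version. Output is deterministic for a
#' given configuration.
#'
#' @param fit A `triage_ce` object.
#' @param out_dir Output directory (created if absent).
#' @param psa Optional `triage_psa`; writes the CEAC table.
#' @param sweep Optional threshold-sweep table.
#' @param config Optional `triage_config` recorded in the metadata.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(fit, out_dir, psa = NULL, sweep = NULL,
                          config = triage_config()) {
  stopifnot(inherits(fit, "triage_ce"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(ce_table(fit), "summary.csv")
  breakdown <- do.call(rbind, lapply(names(fit$results), function(g) {
    res <- fit$results[[g]]
    data.frame(age_group = g, pathway = res$pathway_id,
               primary_care = res$cost_primary,
               fp_secondary = res$cost_fp_secondary,
               inpatient = res$cost_inpatient, total = res$cost)
  }))
  w(breakdown, "cost_breakdown.csv")
  if (!is.null(psa)) w(as.data.frame(ceac(psa)), "ceac.csv")
  if (!is.null(sweep)) w(sweep, "sweep.csv")
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  files <- c(files, cfg_path)
  meta <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    psa_seed = if (!is.null(psa)) psa$seed else config$psa_seed,
    package_version = as.character(utils::packageVersion("ovatriage"))
  )
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  files <- c(files, meta_path)
  invisible(files)
}
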