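# Independent oracles and small fixtures shared across test files.

# Brute-force decision-tree oracle: enumerate every joint atom
# (disease status x blood-test band x USS result) and classify it,
# independently of the closed forms used by evaluate_pathway().
enum_pathway_oracle <- function(mode, prev, sh, qh, su, qu,
                                sm = NULL, qm = NULL) {
  atoms <- list()
  add <- function(p, referred, diseased) {
    atoms[[length(atoms) + 1]] <<- list(p = p, ref = referred, dis = diseased)
  }
  for (dis in c(TRUE, FALSE)) {
    pd <- if (dis) prev else 1 - prev
    if (mode == "CONCURRENT") {
      pb <- if (dis) sh else 1 - qh       # blood abnormal
      pu <- if (dis) su else 1 - qu       # USS abnormal
      for (b in c(TRUE, FALSE)) for (u in c(TRUE, FALSE)) {
        p <- pd * (if (b) pb else 1 - pb) * (if (u) pu else 1 - pu)
        add(p, b || u, dis)
      }
    } else if (!is.null(sm)) {            # sequential banded
      p_band <- if (dis) c(low = 1 - sm, mod = sm - sh, high = sh)
                else c(low = qm, mod = qh - qm, high = 1 - qh)
      pu <- if (dis) su else 1 - qu
      add(pd * p_band["low"], FALSE, dis)
      add(pd * p_band["mod"] * pu, TRUE, dis)
      add(pd * p_band["mod"] * (1 - pu), FALSE, dis)
      add(pd * p_band["high"], TRUE, dis)
    } else {                              # sequential single cut
      pb <- if (dis) sh else 1 - qh
      pu <- if (dis) su else 1 - qu
      add(pd * (1 - pb), FALSE, dis)
      add(pd * pb * pu, TRUE, dis)
      add(pd * pb * (1 - pu), FALSE, dis)
    }
  }
  p_tp <- sum(vapply(atoms, function(a) if (a$dis && a$ref) a$p else 0, 0))
  p_fn <- sum(vapply(atoms, function(a) if (a$dis && !a$ref) a$p else 0, 0))
  p_fp <- sum(vapply(atoms, function(a) if (!a$dis && a$ref) a$p else 0, 0))
  p_tn <- sum(vapply(atoms, function(a) if (!a$dis && !a$ref) a$p else 0, 0))
  list(p_tp = p_tp, p_fn = p_fn, p_tn = p_tn, p_fp = p_fp)
}

# Exhaustive frontier oracle: an option is on the frontier iff it attains
# the strictly maximal net benefit at some willingness-to-pay. Candidate
# thresholds are all pairwise slopes plus midpoints between them, which is
# exact for inputs in general position.
frontier_lambda_oracle <- function(df) {
  n <- nrow(df)
  slopes <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dq <- df$qaly[i] - df$qaly[j]
    if (i != j && dq != 0) {
      s <- (df$cost[i] - df$cost[j]) / dq
      if (s > 0) slopes <- c(slopes, s)
    }
  }
  slopes <- sort(unique(slopes))
  lams <- if (length(slopes)) {
    unique(c(slopes / 2, slopes,
             (head(slopes, -1) + tail(slopes, -1)) / 2,
             max(slopes) * 2, 1e-9))
  } else {
    c(1e-9, 1, 1e6)
  }
  on_front <- rep(FALSE, n)
  for (lam in lams) {
    nb <- lam * df$qaly - df$cost
    top <- which(nb == max(nb))
    if (length(top) == 1) on_front[top] <- TRUE
  }
  on_front
}

# Printed cost-effectiveness increments (QALYs gained and cost difference
# per 1000 women vs pathway 1), re-entered as data for frontier checks.
printed_increments <- function(age_group) {
  if (age_group == "UNDER50") {
    data.frame(pathway_id = 1:6,
               qaly = c(0, -0.97, -0.95, 0.3, 0.33, 2.44),
               cost = c(0, -33354, -33455, 258083, 259095, 334595))
  } else {
    data.frame(pathway_id = 1:6,
               qaly = c(0, 1.48, 1.53, 1.86, 1.86, 2.23),
               cost = c(0, 34894, 39327, 283225, 283223, 304856))
  }
}

resolve_pathway_accuracy_for_test <- function(pathway, age_group) {
  ovatriage:::resolve_pathway_accuracy(pathway, age_group)
}

# Small single-age strata for fast Markov-backed tests.
toy_strata <- function() {
  list(
    UNDER50 = population_stratum(
      "UNDER50", 1000, 0.002, 0.46,
      c(LOWER_GI = 0.002, UTERINE = 0.001, LUNG = 0.001,
        PANCREATIC = 0.001, OTHER = 0.005),
      stats::setNames(1, "40")),
    GE50 = population_stratum(
      "GE50", 1000, 0.0105, 0.72,
      c(LOWER_GI = 0.006, UTERINE = 0.003, LUNG = 0.003,
        PANCREATIC = 0.002, OTHER = 0.013),
      stats::setNames(1, "60"))
  )
}

toy_profile <- function(...) synthetic_profile(strata = toy_strata(), ...)

# Life table with constant cause-specific hazards, for closed-form checks.
flat_life_table <- function(h_cancer = 0, h_noncancer = 0) {
  lt <- data.frame(age = 0:110,
                   cancer_mortality = 1 - exp(-h_cancer),
                   noncancer_mortality = 1 - exp(-h_noncancer))
  class(lt) <- c("life_table", class(lt))
  lt
}

# Utility model with flat utility 1 and no decrements.
unit_utility <- function() {
  q <- synth_qol_params(late_stage_extra = 0)
  q$base <- function(age) rep(1, length(age))
  q$decrements$within1 <- 0
  q$decrements$after1 <- 0
  q
}
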