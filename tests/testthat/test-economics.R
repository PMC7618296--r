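test_that("incremental analysis is a simple antisymmetric difference", {
  res <- data.frame(pathway_id = 1:3, qaly = c(10, 12, 9),
                    cost = c(100, 150, 90))
  inc <- incremental(res)
  expect_equal(inc$dqaly, c(0, 2, -1))
  expect_equal(inc$dcost, c(0, 50, -10))
  inc3 <- incremental(res, comparator_id = 3)
  expect_equal(inc$dqaly[3], -inc3$dqaly[1])
  expect_equal(inc$dcost[3], -inc3$dcost[1])
  same <- incremental(data.frame(pathway_id = 1:2, qaly = c(5, 5),
                                 cost = c(7, 7)))
  expect_equal(same$dqaly, c(0, 0))
  expect_error(incremental(res, comparator_id = 9), "not present")
})

test_that("net benefit is lambda-linear with the right anchors", {
  expect_equal(net_benefit(1.48, 34894, 30000), 9506)
  expect_equal(net_benefit(2.5, 1234, 0), -1234)
  l <- c(0, 10000, 20000)
  nb <- net_benefit(2, 5000, l)
  expect_equal(diff(nb), rep(2 * 10000, 2))
  expect_error(net_benefit(1, 1, -5), "non-negative")
})

test_that("extended dominance removal matches the textbook example", {
  df <- data.frame(pathway_id = 1:3, qaly = c(0, 1, 2),
                   cost = c(0, 30000, 40000))
  fr <- icer_frontier(df, no_compare_groups = NULL)
  expect_true(fr$extendedly_dominated[2])
  expect_equal(fr$on_frontier, c(TRUE, FALSE, TRUE))
  expect_equal(fr$icer[3], 20000)
  expect_equal(fr$comparator[3], 1)
  # single option: trivially on the frontier, no ICER
  one <- icer_frontier(data.frame(pathway_id = 1, qaly = 1, cost = 1),
                       no_compare_groups = NULL)
  expect_true(one$on_frontier)
  expect_true(is.na(one$icer))
  # exact tie in both dimensions: lower id kept, tie flagged
  tie <- icer_frontier(data.frame(pathway_id = c(1, 2), qaly = c(1, 1),
                                  cost = c(10, 10)), no_compare_groups = NULL)
  expect_true(tie$on_frontier[1])
  expect_true(tie$dominated[2] && tie$tie[2])
})

test_that("frontier equals the exhaustive net-benefit search on random inputs", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    df <- data.frame(pathway_id = seq_len(n),
                     qaly = round(runif(n, 0, 10), 3),
                     cost = round(runif(n, 0, 1e5), 1))
    fr <- icer_frontier(df, no_compare_groups = NULL)
    expect_equal(fr$on_frontier, frontier_lambda_oracle(df),
                 info = paste("rep", rep))
    # dominance flags are sound
    for (i in which(fr$dominated & !fr$tie)) {
      expect_true(any(df$qaly >= df$qaly[i] & df$cost <= df$cost[i] &
                        (df$qaly > df$qaly[i] | df$cost < df$cost[i])))
    }
    # frontier ICERs strictly increase along the cost-ordered ladder
    front <- fr[fr$on_frontier, ]
    icers <- front$icer[order(front$cost)]
    icers <- icers[!is.na(icers)]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
  }
})

test_that("published increments flag pathways 4 and 5 as extendedly dominated", {
  for (ag in c("UNDER50", "GE50")) {
    fr <- icer_frontier(printed_increments(ag))
    expect_true(fr$extendedly_dominated[fr$pathway_id == 4], info = ag)
    expect_true(fr$extendedly_dominated[fr$pathway_id == 5], info = ag)
    expect_false(fr$dominated[fr$pathway_id == 2])
    expect_false(fr$dominated[fr$pathway_id == 3])
  }
})

test_that("PSA is seed-reproducible and respects parameter supports", {
  prof <- toy_profile()
  st <- prof$strata$GE50
  cache <- ovatriage:::markov_component_table(st, prof)
  a <- run_psa(st, prof, n = 40, seed = 11, cache = cache)
  b <- run_psa(st, prof, n = 40, seed = 11, cache = cache)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$cost, b$cost)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(st, prof, n = 40, seed = 12, cache = cache)
  expect_false(identical(a$qaly, c2$qaly))
  sens_cols <- grep("^sens\\.|^spec\\.", names(a$draws))
  expect_true(all(as.matrix(a$draws[, sens_cols]) >= 0 &
                    as.matrix(a$draws[, sens_cols]) <= 1))
  expect_true(all(a$draws$rr_late > 0 & a$draws$rr_late <= 1))
})

test_that("PSA draw means match their fitted distributions", {
  prof <- toy_profile()
  st <- prof$strata$GE50
  cache <- ovatriage:::markov_component_table(st, prof)
  # rr_late draws above 1 are capped with a warning by design
  psa <- suppressWarnings(run_psa(st, prof, n = 1000, seed = 3, cache = cache,
                                  pathways = default_pathways()[c("P1", "P2")]))
  # lognormal oracle for rr_late: mean and CLT bound computed independently
  sdlog <- (log(0.950) - log(0.737)) / (2 * qnorm(0.975))
  m_fit <- exp(log(0.836) + sdlog^2 / 2)
  s_fit <- m_fit * sqrt(exp(sdlog^2) - 1)
  expect_lt(abs(m_fit - 0.836), 0.005)
  expect_lt(abs(mean(psa$draws$rr_late) - m_fit), 3 * s_fit / sqrt(1000))
  # near-linearity: PSA mean increments close to the base case
  base <- lapply(default_pathways()[c("P1", "P2")], function(pw) {
    pathway_ce(pw, st, prof, cache = cache)
  })
  d_base <- base$P2$qaly - base$P1$qaly
  d_draw <- psa$qaly[, "P2"] - psa$qaly[, "P1"]
  expect_lt(abs(mean(d_draw) - d_base), 3 * sd(d_draw) / sqrt(1000))
  dc_base <- base$P2$cost - base$P1$cost
  dc_draw <- psa$cost[, "P2"] - psa$cost[, "P1"]
  expect_lt(abs(mean(dc_draw) - dc_base), 3 * sd(dc_draw) / sqrt(1000))
})

test_that("CEAC probabilities partition, split ties and saturate for dominance", {
  fake <- structure(list(
    n = 10, seed = 1, pathway_ids = c(1L, 2L),
    qaly = matrix(rep(c(5, 5), each = 10), ncol = 2),
    cost = matrix(rep(c(100, 100), each = 10), ncol = 2),
    age_group = "GE50"), class = "triage_psa")
  cc <- ceac(fake, c(0, 20000))
  expect_true(all(cc$probability == 0.5))
  dom <- fake
  dom$qaly[, 2] <- 6; dom$cost[, 2] <- 50
  cd <- ceac(dom, c(0, 20000))
  expect_equal(cd$probability[cd$pathway_id == 2], c(1, 1))
  # partition on a real (small) PSA
  prof <- toy_profile()
  psa <- run_psa(prof$strata$GE50, prof, n = 25, seed = 5,
                 cache = ovatriage:::markov_component_table(prof$strata$GE50, prof))
  cr <- ceac(psa, seq(0, 50000, by = 10000))
  sums <- tapply(cr$probability, cr$lambda, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("the threshold sweep is anchored at the base case and cost-monotone", {
  prof <- toy_profile()
  st <- prof$strata$GE50
  cache <- ovatriage:::markov_component_table(st, prof)
  sw <- threshold_sweep(st, prof, cache = cache,
                        moderate_grid = seq(0.006, 0.028, by = 0.002),
                        high_grid = c(0.02, 0.03))
  expect_true(all(sw$moderate < sw$high))
  base2 <- pathway_ce(default_pathways()$P2, st, prof, cache = cache)
  base1 <- pathway_ce(default_pathways()$P1, st, prof, cache = cache)
  cell <- sw[sw$moderate == 0.01 & sw$high == 0.03, ]
  expect_equal(cell$dqaly, base2$qaly - base1$qaly, tolerance = 1e-12)
  expect_equal(cell$dcost, base2$cost - base1$cost, tolerance = 1e-12)
  for (h in unique(sw$high)) {
    sub <- sw[sw$high == h, ]
    expect_true(all(diff(sub$dcost[order(sub$moderate)]) <= 0))
  }
})

test_that("with perfect tests health outcomes are pathway-invariant", {
  prof <- toy_profile()
  acc <- prof$accuracy
  acc$sensitivity <- 1; acc$specificity <- 1
  acc$sens_low <- 1; acc$sens_high <- 1; acc$spec_low <- 1; acc$spec_high <- 1
  st <- prof$strata$GE50
  cache <- ovatriage:::markov_component_table(st, prof)
  res <- lapply(default_pathways(), function(pw) {
    pathway_ce(pw, st, prof, cache = cache, accuracy = acc)
  })
  qalys <- vapply(res, function(r) r$qaly, 0)
  expect_true(all(abs(qalys - qalys[1]) < 1e-9))
  inpat <- vapply(res, function(r) r$cost_inpatient, 0)
  expect_true(all(abs(inpat - inpat[1]) < 1e-9))
  expect_true(all(vapply(res, function(r) r$cost_fp_secondary, 0) == 0))
  expect_true(all(vapply(res, function(r) r$detection_rate, 0) == 1))
})
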