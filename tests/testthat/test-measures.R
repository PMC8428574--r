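test_that("Harrell's C matches exhaustive pair enumeration on anchors", {
  expect_equal(harrell_c(c(3, 1, 2), c(1, 3, 2), c(1, 1, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 3, 2), c(1, 1, 1)), 1 / 3)
  expect_equal(harrell_c(c(2, 2, 2), c(1, 3, 2), c(1, 1, 1)), 0.5)
  expect_error(harrell_c(c(1, 2), c(1, 2), c(0, 0)), "no comparable")
})

test_that("Harrell's C is antisymmetric in crank when there are no ties", {
  for (seed in 1:10) {
    inst <- random_instance(12, seed)
    c1 <- harrell_c(inst$crank, inst$time, inst$status)
    c2 <- harrell_c(-inst$crank, inst$time, inst$status)
    expect_equal(c1 + c2, 1, tolerance = 1e-12)
  }
})

test_that("censoring-distribution KM matches survival::survfit on flipped status", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 80
  tt <- round(rexp(n), 2) + 0.01
  st <- rbinom(n, 1, 0.5)
  cw <- censoring_weights(tt, st)
  sf <- survival::survfit(survival::Surv(tt, 1 - st) ~ 1)
  at <- sf$time %in% cw$grid
  expect_equal(cw$G, sf$surv[at], tolerance = 1e-12)
  # left limits: G just before the first censoring time is 1
  expect_equal(eval_G(cw, cw$grid[1], left_limit = TRUE), 1)
})

test_that("IPCW scoring rules match the brute-force double-loop oracle", {
  for (seed in 1:40) {
    inst <- random_instance(sample(4:20, 1), seed)
    et <- sort(unique(inst$time[inst$status == 1]))
    expect_equal(graf_score(inst$dist, inst$time, inst$status, inst$G),
                 oracle_graf(inst$dist, inst$time, inst$status, inst$G, et),
                 tolerance = 1e-12)
    expect_equal(
      integrated_logloss(inst$dist, inst$time, inst$status, inst$G),
      oracle_logloss(inst$dist, inst$time, inst$status, inst$G, et),
      tolerance = 1e-12)
    expect_equal(schmid_score(inst$dist, inst$time, inst$status, inst$G),
                 oracle_schmid(inst$dist, inst$time, inst$status, inst$G, et),
                 tolerance = 1e-12)
  }
})

test_that("scoring-rule anchors: sharp, constant and censored cases", {
  # single subject dying at t = 5, predicted perfectly sharply
  sharp <- surv_distribution(c(4.999999, 5), c(1, 0))
  G1 <- censoring_weights(5, 1)
  expect_equal(graf_score(sharp, 5, 1, G1, eval_times = c(1, 4, 5, 6)), 0)
  expect_lt(integrated_logloss(sharp, 5, 1, G1, eval_times = c(1, 4, 5, 6)),
            1e-12)
  expect_equal(schmid_score(sharp, 5, 1, G1, eval_times = c(1, 4, 5, 6)), 0)

  # constant S = 0.5: Brier 0.25, log-loss log 2, Schmid 0.5 at all times
  half <- surv_distribution(c(0.5), matrix(0.5, 1, 1))
  bs <- graf_score(half, 5, 1, G1, eval_times = c(4, 6), integrated = FALSE)
  expect_equal(unname(bs), c(0.25, 0.25))
  expect_equal(graf_score(half, 5, 1, G1, eval_times = c(4, 6)), 0.25)
  expect_equal(integrated_logloss(half, 5, 1, G1, eval_times = c(4, 6)),
               log(2), tolerance = 1e-12)
  expect_equal(schmid_score(half, 5, 1, G1, eval_times = c(4, 6)), 0.5)

  # censored subjects contribute zero after their censoring time
  cens <- surv_distribution(1, matrix(0.5, 1, 1))
  Gc <- censoring_weights(c(2, 3), c(0, 1))
  expect_equal(
    unname(graf_score(cens, 2, 0, Gc, eval_times = 3, integrated = FALSE)),
    0)
  expect_error(graf_score(cens, 2, 0, Gc, eval_times = numeric(0)), "empty")
})

test_that("Graf and Schmid stay in [0,1]; log-loss is non-negative", {
  for (seed in 1:10) {
    inst <- random_instance(15, seed + 500)
    g <- graf_score(inst$dist, inst$time, inst$status, inst$G)
    s <- schmid_score(inst$dist, inst$time, inst$status, inst$G)
    l <- integrated_logloss(inst$dist, inst$time, inst$status, inst$G)
    expect_gte(g, 0); expect_lte(g, max(1 / inst$G$floor, 1))
    expect_gte(s, 0)
    expect_gte(l, 0)
  }
})

test_that("scores are invariant under permutation of subject order", {
  inst <- random_instance(15, 77)
  perm <- sample(15)
  d2 <- surv_distribution(inst$dist$grid, inst$dist$S[perm, ])
  expect_equal(
    graf_score(inst$dist, inst$time, inst$status, inst$G),
    graf_score(d2, inst$time[perm], inst$status[perm], inst$G),
    tolerance = 1e-14)
  expect_equal(
    harrell_c(inst$crank, inst$time, inst$status),
    harrell_c(inst$crank[perm], inst$time[perm], inst$status[perm]),
    tolerance = 1e-14)
  expect_equal(
    uno_c(inst$crank, inst$time, inst$status, inst$G),
    uno_c(inst$crank[perm], inst$time[perm], inst$status[perm], inst$G),
    tolerance = 1e-14)
})

test_that("Uno's C equals Harrell's C without censoring and the oracle with", {
  set.seed(31)
  tt <- c(1, 2, 3, 4, 5, 6)
  cr <- rnorm(6)
  G0 <- censoring_weights(tt, rep(1L, 6))
  expect_identical(uno_c(cr, tt, rep(1L, 6), G0),
                   harrell_c(cr, tt, rep(1L, 6)))
  # perfect anti-concordant ranking
  expect_equal(uno_c(seq_len(6), tt, rep(1L, 6), G0), 0)
  # brute-force equality on mixed censoring
  for (seed in 1:20) {
    inst <- random_instance(8, seed + 900)
    tau <- max(inst$time[inst$status == 1])
    if (sum(inst$status == 1 & inst$time < tau) == 0) next
    expect_equal(uno_c(inst$crank, inst$time, inst$status, inst$G),
                 oracle_uno_c(inst$crank, inst$time, inst$status, inst$G,
                              tau),
                 tolerance = 1e-12)
  }
})

test_that("time-dependent AUC matches enumeration and behaves at anchors", {
  # perfectly separating marker, uncensored
  tt <- c(1, 2, 3, 10, 11, 12)
  marker <- c(6, 5, 4, 3, 2, 1)
  G0 <- censoring_weights(tt, rep(1L, 6))
  expect_equal(uno_auc(marker, tt, rep(1L, 6), G0, t = 5), 1)
  expect_error(uno_auc(marker, tt, rep(1L, 6), G0, t = 0.5), "no cases")
  expect_error(uno_auc(marker, tt, rep(1L, 6), G0, t = 20), "no controls")

  # n = 6 hand-set instance vs brute force
  m2 <- c(2, 5, 1, 4, 3, 6)
  expect_equal(uno_auc(m2, tt, rep(1L, 6), G0, t = 5),
               oracle_uno_auc(m2, tt, rep(1L, 6), G0, 5),
               tolerance = 1e-12)
  # censored instances vs brute force
  for (seed in 1:20) {
    inst <- random_instance(10, seed + 1300)
    t0 <- stats::median(inst$time)
    if (!any(inst$time <= t0 & inst$status == 1) || !any(inst$time > t0)) next
    expect_equal(uno_auc(inst$crank, inst$time, inst$status, inst$G, t0),
                 oracle_uno_auc(inst$crank, inst$time, inst$status, inst$G,
                                t0),
                 tolerance = 1e-12)
  }

  # uninformative marker on a large uncensored sample is near 0.5
  set.seed(41)
  n <- 2000
  tt <- rexp(n)
  G <- censoring_weights(tt, rep(1L, n))
  auc <- uno_auc(rnorm(n), tt, rep(1L, n), G, t = stats::median(tt))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("calibration slope recovers 1 for the true lp and 1/2 when doubled", {
  task <- sim_task(5000, beta = c(0.5, -0.5), seed = 1234)
  lp <- attr(task, "truth")$lp
  b1 <- houwelingen_beta(lp, task$time, task$status)
  expect_gt(b1, 0.9); expect_lt(b1, 1.1)
  b2 <- houwelingen_beta(2 * lp, task$time, task$status)
  expect_lt(abs(b2 - 0.5), 0.1)
  expect_error(houwelingen_beta(rep(1, task$n), task$time, task$status),
               "constant")
})

test_that("KM calibration is zero for self-comparison and positive otherwise", {
  task <- sim_task(100, seed = 55)
  km <- fit_kaplan_meier(task)
  pred <- predict(km, task$X)
  expect_equal(as.numeric(km_calibration(pred$distr, task$time,
                                         task$status)), 0,
               tolerance = 1e-12)
  # S == 1 for everyone: discrepancy is max_t (1 - KM(t))
  ones <- surv_distribution(km$grid,
                            matrix(1, task$n, length(km$grid)))
  disc <- km_calibration(ones, task$time, task$status)
  expect_equal(as.numeric(disc), max(1 - km$surv), tolerance = 1e-12)
  expect_gt(as.numeric(disc), 0)
})

test_that("well-specified Cox predictions are KM-calibrated on large samples", {
  task <- sim_task(2000, seed = 66)
  holdout <- make_holdout(task, split = 0.5, seed = 1)
  test_idx <- holdout$folds[[1]]
  train <- task_subset(task, setdiff(seq_len(task$n), test_idx))
  fit <- fit_coxph(train)
  pred <- predict(fit, task$X[test_idx, , drop = FALSE])
  disc <- km_calibration(pred$distr, task$time[test_idx],
                         task$status[test_idx])
  expect_lte(as.numeric(disc), 0.05)
})

test_that("integrated Graf score is proper: the truth beats perturbations", {
  # data from a known exponential distribution; the true survival curve
  # should score better (lower) than biased versions of itself, on average
  set.seed(314)
  grid <- seq(0.1, 6, by = 0.1)
  s_true <- exp(-grid)
  diffs <- replicate(20, {
    n <- 150
    tt <- rexp(n)
    st <- rep(1L, n)
    G <- censoring_weights(tt, st)
    true_d <- surv_distribution(grid,
                                matrix(rep(s_true, each = n), nrow = n))
    pert <- pmin(pmax(s_true^2, 0), 1)   # a miscalibrated alternative
    pert_d <- surv_distribution(grid,
                                matrix(rep(pert, each = n), nrow = n))
    graf_score(pert_d, tt, st, G) - graf_score(true_d, tt, st, G)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("measure registry enforces required channels", {
  task <- sim_task(60, seed = 91)
  pred <- surv_prediction(crank = rnorm(task$n), learner_id = "ranker")
  G <- censoring_weights(task$time, task$status)
  expect_error(msr("surv.graf")$fun(pred, task$time, task$status, G),
               "lacks the 'distr' channel")
  expect_error(msr("surv.calib.beta")$fun(pred, task$time, task$status, G),
               "lacks the 'lp' channel")
  expect_equal(msr("surv.cindex")$fun(pred, task$time, task$status, G),
               harrell_c(pred$crank, task$time, task$status))
  expect_error(msr("nope"), "unknown measure")
})
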