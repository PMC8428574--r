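toy_task <- function() {
  surv_task(matrix(0, 3, 1), time = c(1, 2, 3), status = c(1, 1, 0))
}

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- fit_kaplan_meier(toy_task())
  expect_equal(km$grid, c(1, 2))
  expect_equal(km$surv, c(2 / 3, 1 / 3))
  d <- predict(km, matrix(0, 2, 1))$distr
  expect_equal(as.vector(eval_survival(d, c(1, 2, 3))[1, ]),
               c(2 / 3, 1 / 3, 1 / 3))

  # both die at t = 1
  km2 <- fit_kaplan_meier(surv_task(matrix(0, 2, 1), c(1, 1), c(1, 1)))
  expect_equal(km2$surv, 0)

  # no events: S == 1 with a warning
  expect_warning(
    km3 <- fit_kaplan_meier(surv_task(matrix(0, 2, 1), c(1, 2), c(0, 0))),
    "no events")
  expect_true(all(km3$surv == 1))
})

test_that("Nelson-Aalen matches the hand summation and dominates KM", {
  na <- fit_nelson_aalen(toy_task())
  expect_equal(na$cumhaz, c(1 / 3, 1 / 3 + 1 / 2))
  one <- fit_nelson_aalen(surv_task(matrix(0, 1, 1), 1, 1))
  expect_equal(one$cumhaz, 1)
  expect_equal(one$surv, exp(-1))

  # exp(-H) >= KM survival pointwise on arbitrary censored data
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    task <- surv_task(matrix(0, n, 1), round(rexp(n), 1) + 0.1,
                      rbinom(n, 1, 0.6))
    if (sum(task$status) == 0) next
    km <- fit_kaplan_meier(task)
    na <- fit_nelson_aalen(task)
    expect_true(all(na$surv >= km$surv - 1e-12))
  }
})

test_that("KM with no censoring equals one minus the ECDF", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    tt <- sample(1:15, n, replace = TRUE)
    km <- fit_kaplan_meier(surv_task(matrix(0, n, 1), tt, rep(1L, n)))
    ecdf_surv <- 1 - stats::ecdf(tt)(km$grid)
    expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("KM and Nelson-Aalen agree with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(99)
  n <- 120
  tt <- round(rexp(n), 1) + 0.1
  st <- rbinom(n, 1, 0.6)
  task <- surv_task(matrix(0, n, 1), tt, st)
  km <- fit_kaplan_meier(task)
  na <- fit_nelson_aalen(task)
  sf <- survival::survfit(survival::Surv(tt, st) ~ 1,
                          stype = 1, ctype = 1)
  at_events <- sf$time %in% km$grid
  expect_equal(km$surv, sf$surv[at_events], tolerance = 1e-12)
  expect_equal(na$cumhaz, sf$cumhaz[at_events], tolerance = 1e-12)
})

test_that("Cox fit matches a grid search of the hand-coded partial likelihood", {
  task <- surv_task(matrix(c(1, 0, 0, 1), ncol = 1), 1:4, rep(1L, 4))
  fit <- fit_coxph(task)
  grid <- seq(-10, 10, by = 1e-3)
  pl <- vapply(grid, oracle_breslow_pl, numeric(1),
               x = c(1, 0, 0, 1), time = 1:4, status = rep(1L, 4))
  expect_lt(abs(unname(fit$beta) - grid[which.max(pl)]), 1e-2)
  expect_lte(fit$convergence$grad_norm, 1e-9)
})

test_that("Cox detects monotone-likelihood divergence and bad inputs", {
  expect_error(
    fit_coxph(surv_task(matrix(c(1, 0), ncol = 1), 1:2, rep(1L, 2))),
    "divergence")
  expect_error(
    fit_coxph(surv_task(matrix(c(1, 1, 0, 0), ncol = 1), 1:4, rep(1L, 4))),
    "divergence.*x1")
  expect_error(
    fit_coxph(surv_task(matrix(1, 4, 1), 1:4, rep(1L, 4))),
    "constant covariate")
  expect_error(
    fit_coxph(surv_task(matrix(rnorm(4), 4, 1), 1:4, rep(0L, 4))),
    "at least one event")
})

test_that("Cox agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  tt <- round(rexp(n, exp(0.4 * X[, 1] - 0.6 * X[, 2])), 1) + 0.1
  st <- rbinom(n, 1, 0.7)
  fit <- fit_coxph(surv_task(X, tt, st))
  ref <- survival::coxph(survival::Surv(tt, st) ~ X, ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
  # Breslow baseline: uncenter ours and compare with basehaz at x = 0
  H0u <- fit$baseline_cumhazard * exp(-sum(colMeans(X) * fit$beta))
  bh <- survival::basehaz(ref, centered = FALSE)
  at <- bh$time %in% fit$baseline_times
  expect_equal(H0u, bh$hazard[at], tolerance = 1e-7)
})

test_that("Cox estimate is equivariant under covariate rescaling", {
  task <- sim_task(300, seed = 5)
  f1 <- fit_coxph(task)
  X2 <- task$X
  X2[, 1] <- X2[, 1] * 10 + 3
  f2 <- fit_coxph(surv_task(X2, task$time, task$status))
  expect_equal(unname(f1$beta[1]), unname(f2$beta[1] * 10),
               tolerance = 1e-6)
  expect_equal(unname(f1$beta[2]), unname(f2$beta[2]), tolerance = 1e-6)
})

test_that("Cox distr at beta = 0 equals the Breslow/Nelson-Aalen baseline", {
  task <- sim_task(60, seed = 8)
  na <- fit_nelson_aalen(task)
  # Breslow baseline evaluated at beta = 0 is exactly Nelson-Aalen
  Xc <- sweep(task$X, 2, colMeans(task$X))
  pre <- survkit:::cox_precompute(Xc, task$time, task$status)
  parts <- survkit:::cox_pl_parts(pre, c(0, 0))
  H0 <- cumsum(pre$d / parts$S0)
  expect_equal(parts$event_times, na$grid)
  expect_equal(H0, na$cumhaz, tolerance = 1e-12)
  # and the prediction pipeline replicates that baseline for lp = 0
  model <- fit_coxph(task)
  model$beta[] <- 0
  model$baseline_times <- na$grid
  model$baseline_cumhazard <- na$cumhaz
  pred <- predict(model, task$X)
  expect_equal(pred$distr$S,
               matrix(rep(na$surv, each = task$n), nrow = task$n),
               tolerance = 1e-12)
})

test_that("Cox recovers the generating coefficients on simulated PH data", {
  task <- sim_task(2000, beta = c(0.5, -0.5), seed = 2024)
  fit <- fit_coxph(task)
  expect_lt(max(abs(fit$beta - c(0.5, -0.5))), 0.1)
  pred <- predict(fit, task$X)
  expect_setequal(pred_channels(pred), c("crank", "lp", "distr"))
  expect_equal(pred$crank, pred$lp)
})

test_that("Weibull AFT recovers scale and agrees with survival::survreg", {
  w <- simulate_surv(sim_config(n = 5000, beta = 0, model = "ph",
                                baseline = "weibull", shape = 2, scale = 1,
                                censoring = "none", seed = 3))
  fit <- fit_weibull_aft(w)
  expect_lt(abs(fit$scale - 0.5), 0.05)

  skip_if_not_installed("survival")
  task <- sim_task(300, seed = 9, model = "aft", baseline = "weibull",
                   shape = 1.5)
  f1 <- fit_weibull_aft(task)
  f2 <- survival::survreg(
    survival::Surv(task$time, task$status) ~ task$X, dist = "weibull")
  expect_equal(unname(c(f1$intercept, f1$coefficients)),
               unname(coef(f2)), tolerance = 1e-5)
  expect_equal(f1$scale, f2$scale, tolerance = 1e-5)
})

test_that("Weibull AFT prediction channels follow the AFT conventions", {
  task <- sim_task(200, seed = 10, model = "aft", baseline = "weibull",
                   shape = 1.5)
  fit <- fit_weibull_aft(task)
  pred <- predict(fit, task$X)
  expect_setequal(pred_channels(pred),
                  c("response", "crank", "lp", "distr"))
  # higher lp = longer survival = lower risk
  expect_equal(pred$crank, -pred$lp)
  # response is the parametric median
  expect_equal(pred$response,
               exp(pred$lp + fit$scale * log(log(2))), tolerance = 1e-12)

  # no signal: coefficients near zero
  null_task <- sim_task(2000, beta = c(0, 0), seed = 11, model = "aft",
                        baseline = "weibull", shape = 1.5)
  f0 <- fit_weibull_aft(null_task)
  expect_lt(max(abs(f0$coefficients)), 0.1)

  expect_error(
    fit_weibull_aft(surv_task(matrix(rnorm(3), 3, 1), c(0, 1, 2),
                              c(1, 1, 1))),
    "positive")
})

test_that("every learner's prediction satisfies the container invariants", {
  task <- sim_task(80, seed = 12)
  for (id in c("surv.kaplan", "surv.nelson", "surv.coxph",
               "surv.weibull")) {
    learner <- lrn(id)
    model <- learner$fit(task)
    pred <- predict(model, task$X)
    expect_s3_class(pred, "surv_prediction")
    expect_setequal(pred_channels(pred), learner$predict_types)
    expect_equal(pred$n, task$n)
    S <- pred$distr$S
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(S[, -1, drop = FALSE] <=
                      S[, -ncol(S), drop = FALSE] + 1e-12))
  }
})
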