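# Independent brute-force reference implementations used as oracles.
# Everything here is written as plain double loops straight from the
# defining formulas, sharing no code path with the package internals.

# Step-function survival evaluation, one subject at a time.
oracle_eval_S <- function(dist, i, t) {
  s <- 1
  for (k in seq_along(dist$grid)) {
    if (dist$grid[k] <= t) s <- dist$S[i, k]
  }
  s
}

# Censoring survival function from a censoring_weights object, by
# scanning its grid; left = TRUE gives the left limit G(t-).
oracle_G <- function(G, t, left = FALSE) {
  g <- 1
  for (k in seq_along(G$grid)) {
    ok <- if (left) G$grid[k] < t else G$grid[k] <= t
    if (ok) g <- G$G[k]
  }
  max(g, G$floor)
}

oracle_trapz <- function(times, values) {
  m <- length(times)
  if (m == 1L) return(values[1L])
  tot <- 0
  for (k in seq_len(m - 1L)) {
    tot <- tot + (values[k] + values[k + 1L]) / 2 * (times[k + 1L] - times[k])
  }
  tot / (times[m] - times[1L])
}

# Generic IPCW scoring rule: loss_dead / loss_alive are scalar functions
# of the predicted survival probability.
oracle_ipcw <- function(dist, time, status, G, eval_times, integrated,
                        loss_dead, loss_alive) {
  n <- nrow(dist$S)
  vals <- numeric(length(eval_times))
  for (q in seq_along(eval_times)) {
    t <- eval_times[q]
    tot <- 0
    for (i in seq_len(n)) {
      Si <- oracle_eval_S(dist, i, t)
      if (time[i] <= t && status[i] == 1) {
        tot <- tot + loss_dead(Si) / oracle_G(G, time[i], left = TRUE)
      } else if (time[i] > t) {
        tot <- tot + loss_alive(Si) / oracle_G(G, t)
      }
    }
    vals[q] <- tot / n
  }
  if (integrated) oracle_trapz(eval_times, vals) else vals
}

oracle_graf <- function(dist, time, status, G, eval_times,
                        integrated = TRUE) {
  oracle_ipcw(dist, time, status, G, eval_times, integrated,
              function(S) S^2, function(S) (1 - S)^2)
}

oracle_logloss <- function(dist, time, status, G, eval_times,
                           integrated = TRUE, eps = 1e-15) {
  oracle_ipcw(dist, time, status, G, eval_times, integrated,
              function(S) -log(max(1 - S, eps)),
              function(S) -log(max(S, eps)))
}

oracle_schmid <- function(dist, time, status, G, eval_times,
                          integrated = TRUE) {
  oracle_ipcw(dist, time, status, G, eval_times, integrated,
              function(S) S, function(S) 1 - S)
}

oracle_harrell <- function(crank, time, status) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (status[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (crank[i] > crank[j]) num <- num + 1
        if (crank[i] == crank[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

oracle_uno_c <- function(crank, time, status, G, tau) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (status[i] == 1 && time[i] < time[j] && time[i] < tau) {
        w <- 1 / oracle_G(G, time[i], left = TRUE)^2
        den <- den + w
        if (crank[i] > crank[j]) num <- num + w
        if (crank[i] == crank[j]) num <- num + 0.5 * w
      }
    }
  }
  num / den
}

oracle_uno_auc <- function(marker, time, status, G, t) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (!(time[i] <= t && status[i] == 1)) next
    w <- 1 / oracle_G(G, time[i], left = TRUE)
    for (j in seq_len(n)) {
      if (time[j] <= t) next
      den <- den + w
      if (marker[i] > marker[j]) num <- num + w
      if (marker[i] == marker[j]) num <- num + 0.5 * w
    }
  }
  num / den
}

# Hand-coded Breslow partial log-likelihood for a single covariate
# (the Cox grid-search oracle).
oracle_breslow_pl <- function(beta, x, time, status) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    ev <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(x[ev]) * beta -
      length(ev) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Random censored test instance with a valid random step distribution.
random_instance <- function(n, seed, censor_prob = 0.4) {
  set.seed(seed)
  time <- round(rexp(n, 0.5), 2) + 0.01
  status <- rbinom(n, 1L, 1 - censor_prob)
  if (all(status == 0L)) status[sample.int(n, 1L)] <- 1L
  m <- sample(3:8, 1L)
  grid <- sort(sample(seq(0.05, max(time) * 1.2, by = 0.05), m))
  S <- t(apply(matrix(runif(n * m), n, m), 1L,
               function(u) rev(sort(u))))
  list(time = time, status = status, crank = rnorm(n),
       dist = surv_distribution(grid, S),
       G = censoring_weights(time, status))
}

# Simulated task shorthand used across test files.
sim_task <- function(n, beta = c(0.5, -0.5), seed = 42,
                     censor_rate = 0.3, model = "ph",
                     baseline = "exponential", ...) {
  cens <- if (is.null(censor_rate)) "none" else "exponential"
  simulate_surv(sim_config(n = n, beta = beta, model = model,
                           baseline = baseline, censoring = cens,
                           censor_rate = censor_rate, seed = seed, ...))
}
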