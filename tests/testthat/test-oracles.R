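test_that("with all rates zero and no radiation the state never changes", {
  m <- tiny_model(r_S = 0, r_P = 0, d = c(0, 0, 0),
                  n_S0 = 3, n_P0 = c(2, 1), n_M0 = 4)
  tr <- simulate_hierarchy(m, NULL, default_sens(), horizon = 10, seed = 1)
  expect_true(all(tr$path == rep(c(3, 2, 1, 4), each = nrow(tr$path))))
})

test_that("trajectories only move by the defined reaction stoichiometries", {
  m <- tiny_model(r_S = 0.8, r_P = 1.2, p = c(0.4, 0.3, 0.3), N = 2, k = 1,
                  d = c(0.1, 0.1, 0.1), n_S0 = 4, n_P0 = c(3, 2), n_M0 = 2)
  sch <- radiation_schedule(c(1, 2), 3)
  tr <- simulate_hierarchy(m, sch, default_sens(), horizon = 3, seed = 99)
  expect_true(all(tr$path >= 0))
  allowed <- rbind(c(1, 0, 0, 0),    # S -> S + S
                   c(0, 1, 0, 0),    # S -> S + P1
                   c(-1, 2, 0, 0),   # S -> P1 + P1
                   c(0, -1, 2, 0),   # P1 -> 2 P2
                   c(0, 0, -1, 2),   # P2 -> 2 M
                   -diag(4))         # natural deaths
  steps <- diff(tr$path)
  at_frac <- tr$times[-1] %in% sch$time_days
  for (i in which(!at_frac)) {
    hit <- apply(allowed, 1, function(a) all(steps[i, ] == a))
    expect_true(any(hit))
  }
  # thinning at a fraction can only reduce every compartment
  for (i in which(at_frac)) expect_true(all(steps[i, ] <= 0))
})

test_that("simulated means follow exponential decay and Yule growth", {
  sens <- default_sens()
  # pure natural death of 40 progenitors: mean n0 * exp(-d t)
  m_dec <- tiny_model(r_S = 0, r_P = 0, d = c(0, 0.5, 0), N = 1, k = 1,
                      n_S0 = 0, n_P0 = 40, n_M0 = 0)
  set.seed(7)
  sc <- cstcp:::ssa_inputs(m_dec, NULL, sens)
  res <- cstcp:::ssa_hierarchy_cpp(sc$init, 0, 0, 0.5, 0.3, 0.2, sc$d_nat,
                                   sc$frac_times, sc$frac_sf, 2, 2000L,
                                   1L, early_exit = FALSE, record = FALSE)
  mean_P1 <- mean(res$finals[, 2])
  exp_mean <- 40 * exp(-0.5 * 2)
  se <- sd(res$finals[, 2]) / sqrt(2000)
  expect_lt(abs(mean_P1 - exp_mean), 4 * se)
  # Yule process: pure symmetric stem renewal, mean n0 * exp(r t)
  m_yule <- tiny_model(r_S = 0.7, p = c(1, 0, 0), d = c(0, 0, 0),
                       N = 1, k = 1, n_S0 = 5, n_P0 = 0, n_M0 = 0)
  set.seed(8)
  sc <- cstcp:::ssa_inputs(m_yule, NULL, sens)
  res <- cstcp:::ssa_hierarchy_cpp(sc$init, 0.7, 0, 1, 0, 0, sc$d_nat,
                                   sc$frac_times, sc$frac_sf, 2, 2000L,
                                   1L, early_exit = FALSE, record = FALSE)
  mean_S <- mean(res$finals[, 1])
  se <- sd(res$finals[, 1]) / sqrt(2000)
  expect_lt(abs(mean_S - 5 * exp(1.4)), 4 * se)
})

test_that("Monte-Carlo TCP estimation has the expected limits and determinism", {
  sens <- default_sens()
  # a sterilising single fraction with no proliferation controls the tumour
  m <- tiny_model(r_S = 0, r_P = 0, d = c(0, 0, 0), n_S0 = 3, n_P0 = c(2, 1))
  sch_hot <- radiation_schedule(0.1, 300)
  est <- estimate_tcp(m, sch_hot, sens, 1, "cd", replicates = 1000, seed = 3)
  expect_gte(est$estimate, 0.999)
  # supercritical growth without radiation: constant-rate extinction law
  m_sup <- tiny_model(r_S = 1, p = c(0.6, 0.2, 0.2), d = c(0, 0, 0),
                      N = 1, k = 0, n_S0 = 3, n_P0 = 0, n_M0 = 0)
  b <- 0.6; d0 <- 0.2; g <- b - d0; t <- 5
  q_t <- d0 * (exp(g * t) - 1) / (b * exp(g * t) - d0)
  est2 <- estimate_tcp(m_sup, NULL, sens, t, "stem",
                       replicates = 20000, seed = 11)
  expect_gt(q_t^3, est2$ci_lo)
  expect_lt(q_t^3, est2$ci_hi)
  # bit-reproducibility under a fixed root seed
  a <- estimate_tcp(m, sch_hot, sens, 1, "stem", replicates = 500, seed = 21)
  b2 <- estimate_tcp(m, sch_hot, sens, 1, "stem", replicates = 500, seed = 21)
  expect_identical(a$estimate, b2$estimate)
  expect_error(estimate_tcp(m, sch_hot, sens, 1, "stem", replicates = 50),
               ">= 100")
})

test_that("Wilson interval brackets the estimate and shrinks with replicates", {
  ci_small <- cstcp:::wilson_interval(40, 100)
  ci_big <- cstcp:::wilson_interval(4000, 10000)
  expect_true(ci_small[1] <= 0.4 && 0.4 <= ci_small[2])
  expect_lt(diff(ci_big), diff(ci_small))
})

test_that("master equation reproduces pure-death extinction exactly", {
  m <- tiny_model(r_S = 0, r_P = 0, d = c(0.4, 0, 0), N = 1, k = 0,
                  n_S0 = 1, n_P0 = 0, n_M0 = 0)
  for (t in c(0.5, 2)) {
    me <- master_equation_tcp(m, NULL, default_sens(), t, "stem", cap = 2)
    expect_equal(as.numeric(me), 1 - exp(-0.4 * t), tolerance = 1e-8)
  }
})

test_that("truncation is honest: escaped mass is reported, bounds cap sensitivity, and errors when large", {
  m <- tiny_model(r_S = 0.6, r_P = 0.9, p = c(0.5, 0.3, 0.2), N = 2, k = 1,
                  d = c(0, 0, 0), n_S0 = 2, n_P0 = c(1, 0), n_M0 = 0)
  sch <- radiation_schedule(1, 4)
  lo <- master_equation_tcp(m, sch, default_sens(), 2, "cd", cap = 14,
                            escape_tol = 1e-4)
  hi <- master_equation_tcp(m, sch, default_sens(), 2, "cd", cap = 24,
                            escape_tol = 1e-8)
  esc <- attr(lo, "escaped_mass")
  expect_gt(esc, 0)
  expect_lt(abs(as.numeric(hi) - as.numeric(lo)), esc + 1e-9)
  expect_error(master_equation_tcp(m, sch, default_sens(), 2, "cd", cap = 5,
                                   escape_tol = 1e-10),
               "cap too small")
})

test_that("marginalising mature cells out of the master equation is exact", {
  m <- tiny_model(r_S = 0.5, r_P = 1.0, p = c(0.4, 0.3, 0.3), N = 1, k = 1,
                  d = c(0.05, 0.1, 0.3), n_S0 = 1, n_P0 = 1, n_M0 = 2)
  sch <- radiation_schedule(0.5, 3)
  a <- master_equation_tcp(m, sch, default_sens(), 1.5, "cd", cap = 12,
                           track_mature = FALSE)
  b <- master_equation_tcp(m, sch, default_sens(), 1.5, "cd",
                           cap = c(12, 12, 14), track_mature = TRUE,
                           escape_tol = 1e-6)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-6)
})

test_that("the two oracles agree with each other on a tiny instance", {
  fx <- oracle_fixtures()$mixed_death
  me <- master_equation_tcp(fx$model, fx$schedule, default_sens(),
                            fx$horizon, "cd", cap = fx$cap)
  est <- estimate_tcp(fx$model, fx$schedule, default_sens(), fx$horizon,
                      "cd", replicates = 20000, seed = 5, conf_level = 0.99)
  expect_gt(as.numeric(me), est$ci_lo)
  expect_lt(as.numeric(me), est$ci_hi)
})
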