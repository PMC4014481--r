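test_that("pure-death lineage reproduces 1 - exp(-delta t)", {
  m <- tiny_model(r_S = 0, d = c(0.3, 0, 0), n_S0 = 1)
  t <- c(0, 0.5, 1, 2, 5, 10)
  expect_equal(stem_extinction_single(m, NULL, default_sens(), t),
               1 - exp(-0.3 * t))
})

test_that("a single instantaneous fraction is one Bernoulli kill", {
  m <- tiny_model(r_S = 0, d = c(0, 0, 0), n_S0 = 1)
  sens <- default_sens()
  sch <- radiation_schedule(0, 5)
  q <- stem_extinction_single(m, sch, sens, c(0, 1, 10))
  expect_equal(q, rep(1 - exp(-(0.1 * 5 + 0.01 * 25)), 3))
})

test_that("constant-rate extinction matches the textbook birth-death formula", {
  # b = r_S * p1 = 0.1, delta = r_S * p3 = 0.05, no radiation
  m <- tiny_model(r_S = 0.5, p = c(0.2, 0.7, 0.1), d = c(0, 0, 0), n_S0 = 1)
  b <- 0.1; d <- 0.05; g <- b - d
  t <- c(1, 5, 20, 50)
  expect_equal(stem_extinction_single(m, NULL, default_sens(), t),
               d * (exp(g * t) - 1) / (b * exp(g * t) - d))
})

test_that("closed form agrees with an independent Riccati integration under scheme 1", {
  # independent oracle: integrate the backward Kolmogorov equation for the
  # lineage survival probability p numerically, segment by segment, with
  # the multiplicative jump p <- SF * p at each fraction crossed
  m <- tiny_model(r_S = 0.5, p = c(0.2, 0.7, 0.1), d = c(0, 0, 0), n_S0 = 1)
  sens <- default_sens()
  sch <- build_schedule(1)
  b <- 0.1; d0 <- 0.05
  sf <- survival_fraction(sens$alpha_pos, sens$beta_pos, sch$dose_Gy)
  riccati_q <- function(T) {
    rhs <- function(s, p, parms) list(-((d0 - b) * p + b * p^2))
    p <- 1; scur <- T
    keep <- which(sch$time_days <= T)
    for (f in rev(keep)) {
      tf <- sch$time_days[f]
      if (tf < scur) {
        sol <- deSolve::ode(p, c(0, scur - tf), rhs, NULL,
                            rtol = 1e-11, atol = 1e-13)
        p <- sol[nrow(sol), 2]
        scur <- tf
      }
      p <- sf[f] * p
    }
    if (scur > 0) {
      sol <- deSolve::ode(p, c(0, scur), rhs, NULL, rtol = 1e-11, atol = 1e-13)
      p <- sol[nrow(sol), 2]
    }
    1 - unname(p)
  }
  for (T in c(3.2, 10, 25, 42))
    expect_equal(stem_extinction_single(m, sch, sens, T), riccati_q(T),
                 tolerance = 1e-8)
})

test_that("with proliferation off the TCP is the exact binomial limit", {
  m <- tiny_model(r_S = 0, d = c(0, 0, 0), n_S0 = 7)
  sens <- default_sens()
  sch <- build_schedule(1)
  sf_total <- prod(survival_fraction(sens$alpha_pos, sens$beta_pos,
                                     sch$dose_Gy))
  curve <- tcp_s(m, sch, sens, times = c(39, 45))
  expect_equal(curve$tcp, rep((1 - sf_total)^7, 2))
})

test_that("TCP_S exponentiates the single-lineage probability over n_S0", {
  sens <- default_sens()
  sch <- build_schedule(1)
  t <- schedule_time_grid(sch)
  m1 <- tiny_model(n_S0 = 1, d = c(0.02, 0, 0))
  m100 <- tiny_model(n_S0 = 100, d = c(0.02, 0, 0))
  q <- stem_extinction_single(m1, sch, sens, t)
  expect_equal(tcp_s(m1, sch, sens, t)$tcp, q)
  expect_equal(tcp_s(m100, sch, sens, t)$tcp, q^100)
  m0 <- tiny_model(n_S0 = 0)
  expect_equal(tcp_s(m0, sch, sens, t)$tcp, rep(1, length(t)))
  expect_error(tcp_s(m1, sch, sens, times = numeric()), "empty")
})

test_that("TCP_S is monotone in time, initial burden, radiosensitivity and dose", {
  sens <- default_sens()
  sch <- build_schedule(1)
  t <- schedule_time_grid(sch)
  base <- tiny_model(r_S = 0.3, p = c(0.4, 0.4, 0.2), n_S0 = 10,
                     d = c(0, 0, 0))
  tcp0 <- tcp_s(base, sch, sens, t)$tcp
  expect_true(all(diff(tcp0) >= 0))
  # more stems, or faster stem birth: lower TCP
  bigger <- tiny_model(r_S = 0.3, p = c(0.4, 0.4, 0.2), n_S0 = 20,
                       d = c(0, 0, 0))
  expect_true(all(tcp_s(bigger, sch, sens, t)$tcp <= tcp0))
  # higher effective birth rate at fixed effective death rate
  faster <- tiny_model(r_S = 0.3, p = c(0.6, 0.2, 0.2), n_S0 = 10,
                       d = c(0, 0, 0))
  expect_true(all(tcp_s(faster, sch, sens, t)$tcp <= tcp0 + 1e-12))
  # more radiosensitive stems: higher TCP
  hot <- radiosensitivity_set(0.15, 0.015)
  expect_true(all(tcp_s(base, sch, hot, t)$tcp >= tcp0 - 1e-12))
  # an extra fraction appended: higher TCP at later times
  sch_plus <- radiation_schedule(c(sch$time_days, 42), c(sch$dose_Gy, 2))
  expect_true(all(tcp_s(base, sch_plus, sens, c(42, 43))$tcp >=
                    tcp_s(base, sch, sens, c(42, 43))$tcp))
  # curve dose column is the schedule's cumulative dose
  expect_equal(tcp_s(base, sch, sens, t)$dose_Gy, cumulative_dose(sch, t))
})

test_that("finite-duration fractions converge to instantaneous ones", {
  m <- tiny_model(r_S = 0.4, p = c(0.3, 0.5, 0.2), d = c(0.01, 0, 0),
                  n_S0 = 5)
  sens <- default_sens()
  sch <- radiation_schedule(c(0, 1, 2, 3, 4), 2)
  t <- c(0.5, 2.2, 4.5, 6)
  q_inst <- stem_extinction_single(m, sch, sens, t)
  q_short <- stem_extinction_single(m, sch, sens, t, fraction_duration = 1e-5)
  expect_equal(q_short, q_inst, tolerance = 1e-4)
  # a clearly finite duration still yields a valid monotone curve
  q_long <- stem_extinction_single(m, sch, sens, seq(0, 6, by = 0.1),
                                   fraction_duration = 0.25)
  expect_true(all(q_long >= 0 & q_long <= 1))
  expect_true(all(diff(q_long) >= -1e-12))
})
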