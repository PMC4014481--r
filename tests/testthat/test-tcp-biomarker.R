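test_that("the all-ones state is a fixed point of the backward system", {
  m <- tiny_model(N = 3, k = 2, n_P0 = c(1, 1, 1))
  expect_equal(backward_rhs(m, rep(1, 3)), rep(0, 3))       # reduced
  expect_equal(backward_rhs(m, rep(1, 5)), rep(0, 5))       # full
  expect_error(backward_rhs(m, c(0.5, 1.4, 1)), "outside")
})

test_that("backward derivative matches the hand-assembled PGF algebra", {
  m <- tiny_model(r_S = 0.5, r_P = 0.8, p = c(0.2, 0.5, 0.3),
                  N = 3, k = 1, d = c(0.05, 0.1, 0), n_P0 = c(1, 1, 1))
  # k = 1 reduced system: S couples to P1, P1's daughters (P2) are CD-
  u <- c(0.4, 0.7)
  dS <- -(0.5 * (0.2 * 0.16 + 0.5 * 0.4 * 0.7 + 0.3 * 0.49 - 0.4) +
            0.05 * (1 - 0.4))
  dP1 <- -(0.8 * (1 - 0.7) + 0.1 * (1 - 0.7))
  expect_equal(backward_rhs(m, u), c(dS, dP1))
  # k = 0: scalar stem equation with P1 treated as CD- (value 1)
  m0 <- tiny_model(r_S = 0.5, p = c(0.2, 0.5, 0.3), k = 0, d = c(0.05, 0, 0))
  u0 <- 0.4
  expect_equal(backward_rhs(m0, u0),
               -(0.5 * (0.2 * u0^2 + 0.5 * u0 + 0.3 - u0) + 0.05 * (1 - u0)))
})

test_that("fraction jump is the survival convex combination", {
  m <- tiny_model(N = 2, k = 1)
  sens <- default_sens()
  u <- c(0.4, 0.9)
  expect_equal(apply_fraction_jump(u, sens, 0, m), u)
  d <- 2
  sf <- survival_fraction(0.1, 0.01, d)
  expect_equal(apply_fraction_jump(u, sens, d, m), (1 - sf) + sf * u)
  # sterilising dose drives every entry to certain extinction
  expect_equal(apply_fraction_jump(u, sens, 500, m), c(1, 1), tolerance = 1e-9)
  # explicit arithmetic: u = 0.4, SF = 0.5 -> 0.7
  expect_equal((1 - 0.5) + 0.5 * 0.4, 0.7)
})

test_that("k = 0 biomarker TCP coincides with the stem TCP", {
  m <- tiny_model(r_S = 0.4, p = c(0.35, 0.45, 0.2), N = 3, k = 0,
                  d = c(0.02, 0.05, 0), n_S0 = 8, n_P0 = c(5, 5, 5), n_M0 = 3)
  sens <- default_sens()
  sch <- radiation_schedule(c(0, 1, 2, 3, 4), 2)
  t <- schedule_time_grid(sch)
  expect_equal(tcp_cd(m, sch, sens, t)$tcp, tcp_s(m, sch, sens, t)$tcp,
               tolerance = 1e-7)
})

test_that("reduced and full characteristic systems agree; CD- components stay at 1", {
  m <- tiny_model(r_S = 0.5, r_P = 0.8, p = c(0.3, 0.4, 0.3), N = 4, k = 2,
                  d = c(0.02, 0.05, 0.01), n_S0 = 3, n_P0 = c(2, 2, 1, 1),
                  n_M0 = 2)
  sens <- default_sens()
  sch <- radiation_schedule(c(0.5, 1.5), 3)
  for (T in c(1, 2.5)) {
    u_red <- cstcp:::cd_extinction_profile(m, sch, sens, T, reduced = TRUE)
    u_full <- cstcp:::cd_extinction_profile(m, sch, sens, T, reduced = FALSE)
    expect_equal(u_full[1:3], u_red, tolerance = 1e-7)
    expect_equal(u_full[4:6], rep(1, 3))
  }
  t <- c(1, 2, 3)
  expect_equal(tcp_cd(m, sch, sens, t, reduced = FALSE)$tcp,
               tcp_cd(m, sch, sens, t, reduced = TRUE)$tcp, tolerance = 1e-7)
})

test_that("without proliferation the biomarker TCP is a product of Bernoulli kills", {
  m <- tiny_model(r_S = 0, r_P = 0, d = c(0, 0, 0), N = 3, k = 2,
                  n_S0 = 4, n_P0 = c(3, 2, 5), n_M0 = 1)
  sens <- default_sens()
  d <- 6
  sch <- radiation_schedule(1, d)
  sf_pos <- survival_fraction(0.1, 0.01, d)
  expected <- (1 - sf_pos)^4 * (1 - sf_pos)^3 * (1 - sf_pos)^2
  expect_equal(tcp_cd(m, sch, sens, times = 2)$tcp, expected,
               tolerance = 1e-7)
})

test_that("biomarker TCP is bounded by the stem TCP and ordered in k", {
  sens <- default_sens()
  sch <- build_schedule(1)
  t <- schedule_time_grid(sch)[seq(1, 61, by = 4)]
  base <- default_glioma_model()
  stem <- tcp_s(base, sch, sens, t)$tcp
  prev <- stem
  for (k in 0:3) {
    mk <- cstcp:::set_model_k(base, k)
    ck <- tcp_cd(mk, sch, sens, t)$tcp
    expect_true(all(ck <= stem + 1e-9))
    expect_true(all(ck <= prev + 1e-9))   # non-increasing in k
    expect_true(all(diff(ck) >= -1e-9))   # non-decreasing in t
    prev <- ck
  }
})

test_that("radioresistant stems dominate the biomarker TCP", {
  # when stems are far less radiosensitive than the CD+ progenitors, the
  # progenitor contribution is negligible and TCP_CD+ ~ TCP_S
  m <- cstcp:::set_model_k(default_glioma_model(), 3)
  sch <- build_schedule(1)
  t <- seq(15, 40, by = 5)
  gaps <- vapply(c(0.1, 0.3, 0.6, 1.2), function(alpha_p) {
    sens <- radiosensitivity_set(alpha_p, alpha_p / 10,
                                 alpha_stem = 0.1, beta_stem = 0.01)
    max(tcp_s(m, sch, sens, t)$tcp - tcp_cd(m, sch, sens, t)$tcp)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))      # gap shrinks as progenitors soften
  expect_lt(gaps[4], gaps[1] / 20)      # and becomes negligible in the limit
  expect_lt(gaps[4], 5e-3)
})

test_that("event-based and explicitly segmented backward sweeps agree", {
  m <- tiny_model(r_S = 0.5, r_P = 0.8, p = c(0.3, 0.4, 0.3), N = 3, k = 2,
                  d = c(0.02, 0.05, 0), n_S0 = 3, n_P0 = c(2, 1, 1))
  sens <- default_sens()
  sch <- radiation_schedule(c(0, 0.75, 1.5, 2.25), 2.5)
  t <- c(0.5, 1.6, 3, 4)
  ev <- tcp_cd(m, sch, sens, t, segmented = FALSE)$tcp
  seg <- tcp_cd(m, sch, sens, t, segmented = TRUE)$tcp
  expect_equal(ev, seg, tolerance = 1e-7)
})

test_that("finite-duration fractions converge to instantaneous jumps", {
  m <- tiny_model(r_S = 0.4, r_P = 0.6, p = c(0.3, 0.5, 0.2), N = 2, k = 1,
                  d = c(0, 0, 0), n_S0 = 3, n_P0 = c(2, 0))
  sens <- default_sens()
  sch <- radiation_schedule(c(0.5, 1.5, 2.5), 3)
  t <- c(1, 2, 4)
  inst <- tcp_cd(m, sch, sens, t)$tcp
  short <- tcp_cd(m, sch, sens, t, fraction_duration = 1e-4)$tcp
  expect_equal(short, inst, tolerance = 1e-3)
  long <- tcp_cd(m, sch, sens, t, fraction_duration = 0.3)$tcp
  expect_true(all(long >= 0 & long <= 1))
})
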