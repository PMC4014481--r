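# Small model builders shared across the suite. All fixtures are built in
# code; nothing is read from disk.

tiny_model <- function(r_S = 0.5, r_P = 0.8,
                       p = c(0.5, 0.3, 0.2),
                       N = 2, k = 1,
                       d = c(0.05, 0.1, 0.02),
                       n_S0 = 2, n_P0 = c(1, 1), n_M0 = 1) {
  hierarchy_model(r_S = r_S, r_P = r_P,
                  p_sym_renew = p[1], p_asym = p[2], p_sym_diff = p[3],
                  n_generations = N, k_positive = k,
                  d_S = d[1], d_P = d[2], d_M = d[3],
                  n_S0 = n_S0, n_P0 = n_P0, n_M0 = n_M0)
}

default_sens <- function() default_radiosensitivity()

# Desk-scale fixtures for the dual-oracle equivalence checks: small initial
# populations, few fractions, short horizons, and a truncation cap sized so
# the escaped probability mass stays below the master-equation tolerance.
oracle_fixtures <- function() {
  list(
    mixed_death = list(
      model = tiny_model(),
      schedule = radiation_schedule(c(0.5, 1.5, 2.5), 4, label = "3x4Gy"),
      horizon = 4, cap = 25),
    subcritical = list(
      model = tiny_model(r_S = 0.3, r_P = 0.5, p = c(0.2, 0.5, 0.3),
                         N = 3, k = 3, d = c(0.05, 0.1, 0),
                         n_S0 = 3, n_P0 = c(2, 1, 0), n_M0 = 0),
      schedule = radiation_schedule(0:4, 2, label = "5x2Gy"),
      horizon = 5, cap = c(12, 17, 24, 34)),
    supercritical = list(
      model = tiny_model(r_S = 0.7, r_P = 1.0, p = c(0.6, 0.2, 0.2),
                         N = 1, k = 1, d = c(0, 0.05, 0),
                         n_S0 = 1, n_P0 = 2, n_M0 = 0),
      schedule = radiation_schedule(1, 8, label = "1x8Gy"),
      horizon = 3, cap = 35),
    chain4 = list(
      model = tiny_model(r_S = 0.2, r_P = 0.4, p = c(0.4, 0.4, 0.2),
                         N = 4, k = 3, d = c(0.05, 0.3, 0),
                         n_S0 = 2, n_P0 = c(1, 0, 0, 0), n_M0 = 0),
      schedule = radiation_schedule(c(0.5, 1.5), 3, label = "2x3Gy"),
      horizon = 2, cap = c(12, 8, 10, 14, 20), escape_tol = 1e-7),
    pure_kill = list(
      model = tiny_model(r_S = 0, r_P = 0, p = c(0.5, 0.3, 0.2),
                         N = 2, k = 2, d = c(0, 0, 0),
                         n_S0 = 5, n_P0 = c(3, 2), n_M0 = 2),
      schedule = radiation_schedule(0:3, 2.5, label = "4x2.5Gy"),
      horizon = 3, cap = 5)
  )
}
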