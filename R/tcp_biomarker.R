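#' Backward characteristic derivative of the CD+ extinction system
#'
#' The generating-function PDE of the multitype branching process is solved
#' along its characteristics: for each compartment `i`, `u_i(s)` is the
#' probability that a single cell of type `i` alive at time `s` leaves no
#' biomarker-positive descendants at the horizon. Moving backward in time
#' `s`, each `u_i` obeys
#' `du_i/ds = -[a_i (f_i(u) - u_i) + d_i (1 - u_i)]`
#' where `a_i` is the division rate, `f_i` the offspring PGF
#' ([offspring_pgf()]) and `d_i` the natural death rate; radiation enters
#' as jump conditions at fraction times ([apply_fraction_jump()]), not
#' through this right-hand side. Compartments outside the CD+ set have
#' `u_i = 1` identically (they can never spawn CD+ cells), so the system
#' closes on `S, P1..Pk` alone; the reduced form is used when `u` has
#' length `k_positive + 1`, the full form (over `S, P1..PN, M`) when it has
#' length `n_generations + 2`.
#'
#' @param model a validated [hierarchy_model()].
#' @param u numeric state vector, entries in `[0, 1]`; length
#'   `k_positive + 1` (reduced) or `n_generations + 2` (full).
#' @return `du/ds`, the backward-time derivative vector.
#' @export
backward_rhs <- function(model, u) {
  if (any(u < -1e-9 | u > 1 + 1e-9))
    stop("characteristic state outside [0, 1]: integrator failure")
  -cd_rhs_sigma(u, cd_parms(model, reduced = length(u) == model$k_positive + 1L))
}

# Parameters for the sigma-coordinate RHS (sigma = horizon - s, so the
# derivative flips sign relative to backward_rhs).
cd_parms <- function(model, reduced, extra_death = 0) {
  N <- model$n_generations; k <- model$k_positive
  if (reduced) {
    n <- k + 1L
    div_rate <- c(model$r_S, rep(model$r_P, k))
    death <- c(model$d_S, rep(model$d_P, k))
    daughter <- c(2L, seq_len(k) + 2L)      # index of P_{j+1}; > n means CD-
  } else {
    n <- N + 2L
    div_rate <- c(model$r_S, rep(model$r_P, N), 0)
    death <- c(model$d_S, rep(model$d_P, N), model$d_M)
    daughter <- c(2L, seq_len(N) + 2L, NA_integer_)
  }
  list(n = n, div_rate = div_rate, death = death + extra_death,
       daughter = daughter, full = !reduced, N = N,
       p1 = model$p_sym_renew, p2 = model$p_asym, p3 = model$p_sym_diff)
}

cd_rhs_sigma <- function(u, pr) {
  n <- pr$n
  du <- numeric(n)
  # daughter value: u at the daughter index, or 1 once the chain leaves the
  # tracked set (reduced mode) or reaches M (full mode handles M explicitly)
  dval <- function(i) {
    j <- pr$daughter[i]
    if (is.na(j)) return(NA_real_)
    if (j > n) 1 else u[j]
  }
  uP1 <- if (n >= 2L) u[2L] else 1
  fS <- pr$p1 * u[1L]^2 + pr$p2 * u[1L] * uP1 + pr$p3 * uP1^2
  du[1L] <- pr$div_rate[1L] * (fS - u[1L]) + pr$death[1L] * (1 - u[1L])
  if (n >= 2L) {
    for (i in 2L:n) {
      dv <- dval(i)
      div <- if (is.na(dv)) 0 else pr$div_rate[i] * (dv^2 - u[i])
      du[i] <- div + pr$death[i] * (1 - u[i])
    }
  }
  du
}

#' Radiation jump condition on the characteristic state
#'
#' At a fraction of dose `d`, a cell of compartment `i` is killed with
#' probability `1 - SF_i(d)`; a killed cell contributes certain CD+
#' extinction, a survivor continues, so
#' `u_i <- (1 - SF_i(d)) + SF_i(d) * u_i`.
#'
#' @param u characteristic state vector (reduced or full, see
#'   [backward_rhs()]).
#' @param sens a [radiosensitivity_set()].
#' @param dose fraction dose, Gy.
#' @param model the [hierarchy_model()] (fixes the compartment -> pos/neg
#'   assignment).
#' @return the updated state vector.
#' @export
apply_fraction_jump <- function(u, sens, dose, model) {
  sf <- jump_sf(model, sens, dose, reduced = length(u) == model$k_positive + 1L)
  (1 - sf) + sf * u
}

jump_sf <- function(model, sens, dose, reduced) {
  sf <- unname(fraction_survival(model, sens, dose))
  if (reduced) sf[seq_len(model$k_positive + 1L)] else sf
}

#' Measurable biomarker-positive TCP curve
#'
#' `TCP_CD+(T)`: the probability that every biomarker-positive cell (stem
#' plus progenitor generations `1..k`) is gone by the horizon `T`. For each
#' horizon the backward characteristic system ([backward_rhs()]) is
#' integrated from the terminal condition `u_i(T) = 0` on the CD+ set (1
#' elsewhere) down to `s = 0`, applying the radiation jump at every
#' fraction time crossed (fractions at `t = 0` and `t = T` inclusive,
#' matching the stem solver's convention); then
#' `TCP_CD+(T) = prod_i u_i(0)^(n_i0)` over the initial counts, CD-
#' compartments contributing factor 1. Integration stops exactly at each
#' fraction time (deSolve event handling, or explicit segmentation with
#' `segmented = TRUE`); the integrator never steps across a discontinuity.
#'
#' @inheritParams tcp_s
#' @param reduced use the provably equivalent reduced system over
#'   `S, P1..Pk` (default) instead of the full `S, P1..PN, M` system.
#' @param segmented integrate segment-by-segment between fractions instead
#'   of using integrator event handling; required for
#'   `fraction_duration > 0`.
#' @param rtol,atol integrator tolerances (lsoda).
#' @return a [tcp_curve()] with variant `"cd"` and `k = model$k_positive`.
#' @export
tcp_cd <- function(model, schedule, sens,
                   times = schedule_time_grid(schedule),
                   reduced = TRUE, segmented = FALSE,
                   fraction_duration = 0, rtol = 1e-8, atol = 1e-10) {
  model <- validate_model(model)
  if (length(times) == 0L) stop("empty time grid")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly increasing")
  if (fraction_duration > 0 && !segmented)
    segmented <- TRUE
  tcp <- vapply(times, function(T) {
    u0 <- cd_extinction_profile(model, schedule, sens, T, reduced = reduced,
                                segmented = segmented,
                                fraction_duration = fraction_duration,
                                rtol = rtol, atol = atol)
    cd_tcp_from_profile(model, u0, reduced)
  }, numeric(1))
  # absorb sub-tolerance integrator wiggle so the curve validates
  tcp <- cummax(pmin(pmax(tcp, 0), 1))
  dose <- if (is.null(schedule)) rep(0, length(times))
          else cumulative_dose(schedule, times)
  tcp_curve(times, dose, tcp, variant = "cd", k = model$k_positive)
}

cd_tcp_from_profile <- function(model, u0, reduced) {
  counts <- initial_counts(model)
  if (reduced) counts <- counts[seq_len(model$k_positive + 1L)]
  prod(u0 ^ unname(counts))
}

# u(0) for one horizon T. sigma = T - s runs 0 -> T; terminal condition at
# sigma = 0; fractions at calendar time tf become events at sigma = T - tf.
cd_extinction_profile <- function(model, schedule, sens, T,
                                  reduced = TRUE, segmented = FALSE,
                                  fraction_duration = 0,
                                  rtol = 1e-8, atol = 1e-10) {
  k <- model$k_positive; N <- model$n_generations
  n <- if (reduced) k + 1L else N + 2L
  u <- rep(1, n)
  u[seq_len(k + 1L)] <- 0  # CD+ set: S, P1..Pk
  if (is.null(schedule)) {
    ft <- numeric(); fd <- numeric()
  } else {
    keep <- schedule$time_days <= T + 1e-12
    ft <- schedule$time_days[keep]; fd <- schedule$dose_Gy[keep]
  }
  if (T == 0) {
    if (length(ft)) u <- apply_fraction_jump(u, sens, fd[1L], model)
    return(u)
  }
  if (segmented) {
    cd_profile_segmented(model, sens, T, u, ft, fd, reduced,
                         fraction_duration, rtol, atol)
  } else {
    cd_profile_events(model, sens, T, u, ft, fd, reduced, rtol, atol)
  }
}

cd_profile_events <- function(model, sens, T, u, ft, fd, reduced, rtol, atol) {
  pr <- cd_parms(model, reduced)
  # fraction at t = T acts on the terminal condition itself
  at_T <- length(ft) && abs(ft[length(ft)] - T) <= 1e-12
  if (at_T) {
    u <- apply_fraction_jump(u, sens, fd[length(fd)], model)
    ft <- ft[-length(ft)]; fd <- fd[-length(fd)]
  }
  at_0 <- length(ft) && ft[1L] <= 1e-12
  sig <- if (length(ft)) T - rev(ft) else numeric()
  sig_dose <- rev(fd)
  interior <- sig > 1e-12 & sig < T - 1e-12
  ev_sig <- sig[interior]; ev_dose <- sig_dose[interior]
  rhs <- function(t, y, parms) list(cd_rhs_sigma(y, parms))
  eventfun <- function(t, y, parms) {
    i <- which.min(abs(ev_sig - t))
    apply_fraction_jump(y, sens, ev_dose[i], model)
  }
  times <- sort(unique(c(0, ev_sig, T)))
  events <- if (length(ev_sig))
    list(func = eventfun, time = ev_sig) else NULL
  sol <- deSolve::ode(y = u, times = times, func = rhs, parms = pr,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  u <- as.numeric(sol[nrow(sol), -1L])
  check_unit_interval(u)
  if (at_0) u <- apply_fraction_jump(u, sens, fd[1L], model)
  u
}

cd_profile_segmented <- function(model, sens, T, u, ft, fd, reduced,
                                 dur, rtol, atol) {
  # walk backward from s = T to 0; with dur > 0 a fraction at tf becomes a
  # constant extra per-compartment kill hazard over [tf, tf + dur] instead
  # of a jump (windows may overlap; hazards add)
  n <- length(u)
  if (dur == 0) {
    brk_s <- ft; brk_dose <- fd
    brk_type <- rep("jump", length(ft))
    h <- rep(0, n)
  } else {
    if (!reduced)
      stop("fraction_duration > 0 is supported for the reduced system only")
    brk_s <- c(ft, ft + dur)
    brk_dose <- c(fd, fd)
    brk_type <- rep(c("on", "off"), each = length(ft))
    keep <- brk_s <= T + 1e-12
    brk_s <- brk_s[keep]; brk_dose <- brk_dose[keep]
    brk_type <- brk_type[keep]
    # hazard active at the horizon: windows opened but not yet closed
    h <- rep(0, n)
    for (i in which(brk_type == "on")) h <- h + frac_hazard(model, sens, brk_dose[i], n, dur)
    for (i in which(brk_type == "off")) h <- h - frac_hazard(model, sens, brk_dose[i], n, dur)
  }
  integrate_to <- function(u, from, to, hcur) {
    if (from - to <= 1e-13) return(u)
    pr <- cd_parms(model, reduced, extra_death = hcur)
    rhs <- function(t, y, parms) list(cd_rhs_sigma(y, parms))
    sol <- deSolve::ode(y = u, times = c(0, from - to), func = rhs,
                        parms = pr, method = "lsoda",
                        rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), -1L])
    check_unit_interval(y)
    y
  }
  s <- T
  for (i in order(brk_s, decreasing = TRUE)) {
    si <- brk_s[i]
    if (si > T + 1e-12) next
    u <- integrate_to(u, s, si, h)
    s <- si
    if (brk_type[i] == "jump") {
      u <- apply_fraction_jump(u, sens, brk_dose[i], model)
    } else if (brk_type[i] == "off") {
      # walking backward across the window end turns its hazard on
      h <- h + frac_hazard(model, sens, brk_dose[i], n, dur)
    } else {
      h <- h - frac_hazard(model, sens, brk_dose[i], n, dur)
    }
  }
  integrate_to(u, s, 0, h)
}

# per-compartment kill hazard of one fraction spread over a window
frac_hazard <- function(model, sens, dose, n, dur) {
  -log(jump_sf(model, sens, dose, reduced = TRUE))[seq_len(n)] / dur
}

check_unit_interval <- function(u, tol = 1e-6) {
  if (any(u < -tol | u > 1 + tol))
    stop("characteristic state left [0, 1] beyond tolerance; ",
         "tighten integrator tolerances")
  invisible(pmin(pmax(u, 0), 1))
}
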