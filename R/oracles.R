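#' Exact stochastic simulation of the hierarchy
#'
#' One exact Gillespie realisation of the multitype birth-death process:
#' constant-propensity Gillespie between consecutive fraction times (exact,
#' since all rates are constant there), with every cell of compartment `i`
#' surviving each fraction independently with probability `SF_i(dose)`
#' (binomial thinning). Reactions are the three stem division types, the
#' progenitor divisions `P_j -> 2 P_(j+1)` (with `P_N -> 2 M`) and natural
#' deaths.
#'
#' @param model a validated [hierarchy_model()].
#' @param schedule a [radiation_schedule()] or `NULL`.
#' @param sens a [radiosensitivity_set()].
#' @param horizon simulation end time, days (>= 0).
#' @param seed integer seed (`set.seed`); `NULL` to use the current RNG
#'   state.
#' @return an object of class `trajectory`: list with `times` (event and
#'   fraction times, days) and `path` (matrix of compartment counts, one
#'   row per time, columns `S`, `P1`..`PN`, `M`).
#' @export
simulate_hierarchy <- function(model, schedule, sens, horizon, seed = NULL) {
  model <- validate_model(model)
  if (horizon < 0) stop("horizon must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sc <- ssa_inputs(model, schedule, sens)
  res <- ssa_hierarchy_cpp(sc$init, model$r_S, model$r_P,
                           model$p_sym_renew, model$p_asym, model$p_sym_diff,
                           sc$d_nat, sc$frac_times, sc$frac_sf,
                           horizon, 1L, target_index(model, "stem"),
                           early_exit = FALSE, record = TRUE)
  path <- res$path
  colnames(path) <- compartment_labels(model)
  structure(list(times = res$times, path = path, horizon = horizon),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d recorded states over %g days; final counts: %s\n",
              length(x$times), x$horizon,
              paste(sprintf("%s=%d", colnames(x$path),
                            x$path[nrow(x$path), ]), collapse = ", ")))
  invisible(x)
}

ssa_inputs <- function(model, schedule, sens) {
  nc <- model$n_generations + 2L
  init <- as.integer(round(model$init_counts))
  d_nat <- c(model$d_S, rep(model$d_P, model$n_generations), model$d_M)
  if (is.null(schedule)) {
    frac_times <- numeric()
    frac_sf <- matrix(numeric(), 0L, nc)
  } else {
    frac_times <- schedule$time_days
    frac_sf <- t(vapply(schedule$dose_Gy,
                        function(d) unname(fraction_survival(model, sens, d)),
                        numeric(nc)))
  }
  list(init = init, d_nat = d_nat, frac_times = frac_times, frac_sf = frac_sf)
}

target_index <- function(model, target = c("stem", "cd")) {
  target <- match.arg(target)
  if (target == "stem") 1L else seq_len(model$k_positive + 1L)
}

#' Monte-Carlo TCP estimate
#'
#' Simulates many independent realisations and reports the fraction in
#' which the target set (the stem compartment, or the biomarker-positive
#' set `S, P1..Pk`) holds zero cells at the horizon, with a Wilson score
#' confidence interval. Because the target set sits at the top of the
#' unidirectional hierarchy it can never be repopulated once empty, so each
#' replicate stops as soon as the target set empties.
#'
#' @inheritParams simulate_hierarchy
#' @param target `"stem"` (TCP_S) or `"cd"` (TCP_CD+).
#' @param replicates number of replicates (>= 100).
#' @param seed integer root seed; the whole replicate batch is driven by
#'   `set.seed(seed)` and is bit-reproducible.
#' @param conf_level confidence level of the Wilson interval.
#' @return object of class `tcp_estimate`: list with `estimate`,
#'   `ci_lo`, `ci_hi`, `conf_level`, `replicates`, `seed`, `target`.
#' @export
estimate_tcp <- function(model, schedule, sens, horizon,
                         target = c("stem", "cd"),
                         replicates = 10000L, seed = 1L,
                         conf_level = 0.95) {
  target <- match.arg(target)
  model <- validate_model(model)
  if (replicates < 100L) stop("replicates must be >= 100")
  if (horizon < 0) stop("horizon must be >= 0")
  set.seed(seed)
  sc <- ssa_inputs(model, schedule, sens)
  res <- ssa_hierarchy_cpp(sc$init, model$r_S, model$r_P,
                           model$p_sym_renew, model$p_asym, model$p_sym_diff,
                           sc$d_nat, sc$frac_times, sc$frac_sf,
                           horizon, as.integer(replicates),
                           target_index(model, target),
                           early_exit = TRUE, record = FALSE)
  ci <- wilson_interval(res$extinct, replicates, conf_level)
  structure(list(estimate = res$extinct / replicates,
                 ci_lo = ci[1L], ci_hi = ci[2L], conf_level = conf_level,
                 replicates = as.integer(replicates), seed = seed,
                 target = target),
            class = "tcp_estimate")
}

#' @export
print.tcp_estimate <- function(x, ...) {
  cat(sprintf("TCP (%s) = %.4f  [%.4f, %.4f] %g%% Wilson CI, %d replicates, seed %d\n",
              x$target, x$estimate, x$ci_lo, x$ci_hi, 100 * x$conf_level,
              x$replicates, x$seed))
  invisible(x)
}

wilson_interval <- function(successes, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# --- truncated master equation --------------------------------------------

#' Truncated master-equation TCP
#'
#' Integrates the full joint forward master equation of the compartment
#' counts on a truncated state space (counts capped per compartment),
#' pushing the probability vector through the product-binomial thinning
#' kernel at every fraction, and returns the total probability of all
#' states with zero cells in the target set at the horizon. Transitions
#' that would exceed a cap send their probability flux to an absorbing
#' "escaped" account; the escaped mass bounds the truncation bias and the
#' function errors if it exceeds `escape_tol`. Mature cells produce
#' nothing, so by default they are marginalised out exactly
#' (`track_mature = FALSE`); setting `track_mature = TRUE` keeps the `M`
#' axis (with its own cap) for cross-checks.
#'
#' Intended for tiny instances only (truncated state space up to ~1e5
#' states); it is the high-precision oracle for [tcp_s()] and [tcp_cd()].
#'
#' @inheritParams estimate_tcp
#' @param cap integer cap per tracked compartment (scalar, or vector over
#'   `S, P1..PN[, M]`).
#' @param track_mature keep the mature-cell axis (default FALSE).
#' @param escape_tol maximum tolerated escaped probability mass.
#' @param rtol,atol integrator tolerances.
#' @return numeric TCP with attribute `escaped_mass`.
#' @export
master_equation_tcp <- function(model, schedule, sens, horizon,
                                target = c("stem", "cd"), cap = 10L,
                                track_mature = FALSE,
                                escape_tol = 1e-8,
                                rtol = 1e-10, atol = 1e-12) {
  target <- match.arg(target)
  model <- validate_model(model)
  N <- model$n_generations
  n_track <- N + 1L + as.integer(track_mature)   # S, P1..PN [, M]
  caps <- as.integer(rep(cap, length.out = n_track))
  dims <- caps + 1L
  nstate <- prod(dims)
  if (nstate > 2e6) stop("truncated state space too large (", nstate, " states)")
  init <- as.integer(round(model$init_counts))[seq_len(n_track)]
  if (any(init > caps)) stop("initial counts exceed the truncation cap")

  states <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1))))
  lin <- function(m) 1L + as.integer(m %*% cumprod(c(1L, dims[-length(dims)])))

  d_nat <- c(model$d_S, rep(model$d_P, N), model$d_M)[seq_len(n_track)]
  A <- build_generator(states, dims, caps, lin, model, d_nat, n_track)

  p <- numeric(nstate)
  p[lin(matrix(init, 1L))] <- 1

  seg_times <- if (is.null(schedule)) numeric()
               else schedule$time_days[schedule$time_days <= horizon + 1e-12]
  seg_doses <- if (is.null(schedule)) numeric()
               else schedule$dose_Gy[schedule$time_days <= horizon + 1e-12]
  sf_all <- if (length(seg_doses))
    t(vapply(seg_doses, function(d) unname(fraction_survival(model, sens, d)),
             numeric(N + 2L)))[, seq_len(n_track), drop = FALSE]
  else matrix(numeric(), 0L, n_track)

  tcur <- 0
  # lsoda's internal full Jacobian is quadratic in the state count; fall
  # back to the Jacobian-free Adams integrator for larger truncations
  ode_method <- if (nstate > 3000) "adams" else "lsoda"
  integrate_seg <- function(p, len) {
    if (len <= 1e-13) return(p)
    rhs <- function(t, y, parms) list(as.vector(parms %*% y))
    sol <- deSolve::ode(y = p, times = c(0, len), func = rhs, parms = A,
                        method = ode_method, rtol = rtol, atol = atol)
    as.numeric(sol[nrow(sol), -1L])
  }
  for (f in seq_along(seg_times)) {
    p <- integrate_seg(p, seg_times[f] - tcur)
    tcur <- seg_times[f]
    p <- apply_thinning_kernel(p, dims, sf_all[f, ])
  }
  p <- integrate_seg(p, horizon - tcur)

  escaped <- 1 - sum(p)
  if (escaped > escape_tol)
    stop(sprintf(paste0("truncation cap too small: escaped probability mass ",
                        "%.3g exceeds escape_tol = %.3g"), escaped, escape_tol))
  if (min(p) < -1e-9)
    stop("master-equation probability vector went negative")
  tgt <- target_index(model, target)
  zero_mask <- rowSums(states[, tgt, drop = FALSE]) == 0
  structure(sum(p[zero_mask]), escaped_mass = escaped)
}

# Sparse generator A with A[to, from] = rate; diagonal carries the full
# outflow including cap-escaping transitions, so column sums <= 0 and lost
# mass is exactly the truncation escape.
build_generator <- function(states, dims, caps, lin, model, d_nat, n_track) {
  N <- model$n_generations
  nstate <- nrow(states)
  from_i <- integer(); to_i <- integer(); val <- numeric()
  diag_out <- numeric(nstate)
  add_reaction <- function(rate_vec, delta) {
    act <- which(rate_vec > 0)
    if (!length(act)) return()
    diag_out[act] <<- diag_out[act] + rate_vec[act]
    to <- states[act, , drop = FALSE] +
      matrix(delta, length(act), n_track, byrow = TRUE)
    ok <- rowSums(to < 0 | to > matrix(caps, length(act), n_track,
                                       byrow = TRUE)) == 0
    if (any(ok)) {
      from_i <<- c(from_i, act[ok])
      to_i <<- c(to_i, lin(to[ok, , drop = FALSE]))
      val <<- c(val, rate_vec[act][ok])
    }
  }
  unit <- function(i, v) { x <- integer(n_track); x[i] <- v; x }
  nS <- states[, 1L]
  add_reaction(model$r_S * model$p_sym_renew * nS, unit(1L, 1L))         # S+S
  if (N >= 1L)
    add_reaction(model$r_S * model$p_asym * nS, unit(2L, 1L))            # S+P1
  d3 <- unit(1L, -1L); d3[2L] <- 2L
  add_reaction(model$r_S * model$p_sym_diff * nS, d3)                    # 2 P1
  for (j in seq_len(N)) {
    dj <- integer(n_track); dj[j + 1L] <- -1L
    if (j < N) dj[j + 2L] <- 2L
    else if (n_track == N + 2L) dj[j + 2L] <- 2L  # P_N -> 2 M if tracked
    add_reaction(model$r_P * states[, j + 1L], dj)
  }
  for (i in seq_len(n_track))
    if (d_nat[i] > 0) add_reaction(d_nat[i] * states[, i], unit(i, -1L))
  Matrix::sparseMatrix(i = c(to_i, seq_len(nstate)),
                       j = c(from_i, seq_len(nstate)),
                       x = c(val, -diag_out),
                       dims = c(nstate, nstate))
}

# Product-binomial thinning: apply the per-compartment binomial survival
# matrix along each axis of the probability array in turn.
apply_thinning_kernel <- function(p, dims, sf) {
  arr <- array(p, dims)
  nd <- length(dims)
  for (i in seq_len(nd)) {
    if (sf[i] >= 1) next
    counts <- 0:(dims[i] - 1L)
    B <- outer(counts, counts,
               function(m, n) stats::dbinom(m, n, sf[i]))
    perm <- c(i, setdiff(seq_len(nd), i))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = dims[i])
    a <- array(B %*% m, dim(a))
    arr <- aperm(a, order(perm))
  }
  as.vector(arr)
}
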