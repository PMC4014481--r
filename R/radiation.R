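#' Linear-quadratic survival fraction
#'
#' Per-cell probability of surviving one radiation fraction of the given
#' dose under the linear-quadratic model, `exp(-(alpha * d + beta * d^2))`.
#' All radiation-induced death is taken to occur at the fraction itself
#' (instantaneous-kill convention), so this survival fraction is the only
#' way dose enters the model.
#'
#' @param alpha linear radiosensitivity, 1/Gy.
#' @param beta quadratic radiosensitivity, 1/Gy^2.
#' @param dose fraction dose in Gy (vectorised, must be >= 0).
#' @return survival probability in (0, 1].
#' @examples
#' survival_fraction(0.3, 0.03, 2)   # exp(-0.72)
#' @export
survival_fraction <- function(alpha, beta, dose) {
  if (any(dose < 0)) stop("dose must be non-negative")
  exp(-(alpha * dose + beta * dose^2))
}

#' Radiosensitivity set for biomarker-positive and -negative cells
#'
#' Holds one LQ (alpha, beta) pair for biomarker-positive cells (stems and
#' the first `k_positive` progenitor generations) and one for
#' biomarker-negative cells (later generations and mature cells). By
#' default the negative-cell parameters are three times the positive-cell
#' ones, reflecting the greater radioresistance of CD133+ glioma cells;
#' explicit overrides are permitted.
#'
#' By default the stem compartment shares the biomarker-positive pair (the
#' characteristic assumption that gives the biomarker TCP its value as a
#' surrogate); `alpha_stem`/`beta_stem` allow stems to be given their own,
#' e.g. much lower, radiosensitivity, in which case the stem population
#' dominates the biomarker TCP.
#'
#' @param alpha_pos,beta_pos LQ parameters of biomarker-positive cells
#'   (1/Gy and 1/Gy^2, > 0).
#' @param alpha_neg,beta_neg LQ parameters of biomarker-negative cells;
#'   default three-fold the positive values.
#' @param alpha_stem,beta_stem LQ parameters of the stem compartment;
#'   default equal to the biomarker-positive pair.
#' @return an object of class `radiosensitivity_set`.
#' @export
radiosensitivity_set <- function(alpha_pos, beta_pos,
                                 alpha_neg = 3 * alpha_pos,
                                 beta_neg = 3 * beta_pos,
                                 alpha_stem = alpha_pos,
                                 beta_stem = beta_pos) {
  v <- c(alpha_pos = alpha_pos, beta_pos = beta_pos,
         alpha_neg = alpha_neg, beta_neg = beta_neg,
         alpha_stem = alpha_stem, beta_stem = beta_stem)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all radiosensitivity parameters must be positive")
  structure(as.list(v), class = "radiosensitivity_set")
}

#' Default radiosensitivities
#'
#' The package's declared default LQ parameters:
#' `alpha_pos = 0.1` /Gy, `beta_pos = 0.01` /Gy^2 (alpha/beta = 10 Gy),
#' tripled for biomarker-negative cells.
#' @return a [radiosensitivity_set()].
#' @export
default_radiosensitivity <- function() radiosensitivity_set(0.1, 0.01)

#' @export
print.radiosensitivity_set <- function(x, ...) {
  cat(sprintf("LQ radiosensitivities: CD+ alpha = %g /Gy, beta = %g /Gy^2; CD- alpha = %g, beta = %g\n",
              x$alpha_pos, x$beta_pos, x$alpha_neg, x$beta_neg))
  invisible(x)
}

#' Per-compartment LQ parameters
#'
#' Maps each compartment of the hierarchy to its (alpha, beta) pair using
#' the biomarker assignment: `S` gets the stem parameters (by default the
#' positive-cell pair), `P1..Pk` the positive-cell parameters, all other
#' compartments the negative-cell parameters.
#'
#' @param sens a [radiosensitivity_set()].
#' @param model a [hierarchy_model()].
#' @return data.frame with columns `compartment`, `positive`, `alpha`,
#'   `beta`, one row per compartment in order `S`, `P1`..`PN`, `M`.
#' @export
compartment_sensitivities <- function(sens, model) {
  pos <- biomarker_positive(model)
  alpha <- ifelse(pos, sens$alpha_pos, sens$alpha_neg)
  beta <- ifelse(pos, sens$beta_pos, sens$beta_neg)
  alpha[1L] <- sens$alpha_stem
  beta[1L] <- sens$beta_stem
  data.frame(compartment = names(pos), positive = unname(pos),
             alpha = alpha, beta = beta, row.names = NULL)
}

#' Per-compartment survival fractions for one fraction dose
#'
#' @param model a [hierarchy_model()].
#' @param sens a [radiosensitivity_set()].
#' @param dose fraction dose, Gy.
#' @return named numeric vector of survival probabilities over compartments.
#' @export
fraction_survival <- function(model, sens, dose) {
  cs <- compartment_sensitivities(sens, model)
  stats::setNames(survival_fraction(cs$alpha, cs$beta, dose), cs$compartment)
}

# --- schedules -------------------------------------------------------------

#' Radiation fractionation schedule
#'
#' An ordered list of radiation fractions, each with a delivery time (days
#' since the start of treatment, fraction 1 at t = 0) and a dose in Gy.
#'
#' @param times fraction times in days, strictly increasing, >= 0.
#' @param doses fraction doses in Gy, > 0 (recycled from a scalar).
#' @param label free-text schedule label.
#' @return an object of class `radiation_schedule`: a data.frame with
#'   columns `time_days` and `dose_Gy`.
#' @export
radiation_schedule <- function(times, doses, label = "custom") {
  if (length(doses) == 1L) doses <- rep(doses, length(times))
  if (length(times) != length(doses))
    stop("times and doses must have equal length")
  if (length(times) == 0L) stop("a schedule needs at least one fraction")
  if (any(times < 0)) stop("fraction times must be >= 0")
  if (any(diff(times) <= 0)) stop("fraction times must be strictly increasing")
  if (any(doses <= 0)) stop("fraction doses must be > 0")
  structure(data.frame(time_days = as.numeric(times),
                       dose_Gy = as.numeric(doses)),
            label = label, class = c("radiation_schedule", "data.frame"))
}

#' Build one of the three named fractionation schemes
#'
#' Scheme 1 (conventional): 2 Gy per fraction, one fraction per weekday, 30
#' fractions over 6 treatment weeks. Scheme 2 (hyperfractionated): 1.2 Gy
#' per fraction, two fractions per weekday, 50 fractions over 5 weeks.
#' Scheme 3 (accelerated hyperfractionated): 1.5 Gy per fraction, two
#' fractions per weekday, 40 fractions over 4 weeks. All three deliver a
#' total of exactly 60 Gy, with no fractions on weekends. Treatment starts
#' on a Monday at t = 0 days; twice-daily fractions are separated by
#' `bid_gap_hours`.
#'
#' @param scheme integer 1, 2 or 3.
#' @param bid_gap_hours gap between the two daily fractions of schemes 2
#'   and 3, hours (default 6).
#' @return a [radiation_schedule()].
#' @export
build_schedule <- function(scheme, bid_gap_hours = 6) {
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:3) stop("unknown scheme id: ", scheme)
  gap <- bid_gap_hours / 24
  plan <- switch(scheme,
                 list(dose = 2.0, per_day = 1L, n = 30L, label = "scheme 1 (conventional)"),
                 list(dose = 1.2, per_day = 2L, n = 50L, label = "scheme 2 (hyperfractionated)"),
                 list(dose = 1.5, per_day = 2L, n = 40L, label = "scheme 3 (accelerated hyperfractionated)"))
  n_days <- plan$n %/% plan$per_day
  weekdays <- unlist(lapply(seq_len(ceiling(n_days / 5)) - 1L,
                            function(w) w * 7 + 0:4))[seq_len(n_days)]
  times <- if (plan$per_day == 1L) weekdays
           else as.vector(rbind(weekdays, weekdays + gap))
  radiation_schedule(times, plan$dose, label = plan$label)
}

#' Cumulative dose delivered by a schedule
#'
#' Right-continuous step function of time: the sum of the doses of all
#' fractions delivered at or before `t`.
#'
#' @param schedule a [radiation_schedule()].
#' @param t time(s) in days, >= 0 (vectorised).
#' @return cumulative dose in Gy.
#' @export
cumulative_dose <- function(schedule, t) {
  if (any(t < 0)) stop("t must be non-negative")
  cd <- cumsum(schedule$dose_Gy)
  idx <- findInterval(t, schedule$time_days)
  ifelse(idx == 0L, 0, cd[pmax(idx, 1L)])
}

#' Default evaluation time grid for a schedule
#'
#' Fraction times plus the midpoints of the inter-fraction intervals, plus
#' t = 0 and a short post-treatment tail, so every jump of the TCP curve is
#' sampled on both sides.
#'
#' @param schedule a [radiation_schedule()].
#' @param tail_days days appended after the last fraction (default 1).
#' @return increasing numeric vector of times in days.
#' @export
schedule_time_grid <- function(schedule, tail_days = 1) {
  tf <- schedule$time_days
  mids <- if (length(tf) > 1L) (tf[-1L] + tf[-length(tf)]) / 2 else numeric()
  sort(unique(c(0, tf, mids, max(tf) + c(tail_days / 2, tail_days))))
}

#' @export
print.radiation_schedule <- function(x, ...) {
  cat(sprintf("Radiation schedule '%s': %d fractions, %g Gy total, days %g-%g\n",
              attr(x, "label"), nrow(x), sum(x$dose_Gy),
              min(x$time_days), max(x$time_days)))
  invisible(x)
}

#' Write / read a schedule as a two-column CSV
#'
#' The CSV has columns `time_days` and `dose_Gy`, one row per fraction.
#' @param schedule a [radiation_schedule()].
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns a [radiation_schedule()].
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[c("time_days", "dose_Gy")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param label label for the schedule read from `path`.
#' @export
read_schedule_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("time_days", "dose_Gy") %in% names(df)))
    stop("schedule CSV must have columns time_days, dose_Gy")
  radiation_schedule(df$time_days, df$dose_Gy, label = label)
}
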