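#' Experiment configuration
#'
#' Bundles everything one computational experiment needs: the hierarchy
#' model, the radiosensitivities, a schedule (a named scheme id or an
#' explicit fraction table), the sweep of biomarker depths `k`, the
#' evaluation time grid, an output directory, the RNG seed and the oracle
#' settings. Round-trips losslessly through YAML
#' ([write_experiment_config()] / [read_experiment_config()]).
#'
#' @param model a [hierarchy_model()].
#' @param sens a [radiosensitivity_set()].
#' @param scheme scheme id 1, 2 or 3, or `NA` when `schedule` is given.
#' @param schedule explicit [radiation_schedule()] (overrides `scheme`).
#' @param k_sweep integer vector of biomarker depths for the k sweep.
#' @param times evaluation grid; `NULL` means [schedule_time_grid()].
#' @param out_dir output directory or `NULL` (no files written).
#' @param seed integer RNG seed for oracle runs.
#' @param oracle_replicates Monte-Carlo replicates for oracle runs.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(model = default_glioma_model(),
                              sens = default_radiosensitivity(),
                              scheme = 1L, schedule = NULL,
                              k_sweep = 0:3, times = NULL,
                              out_dir = NULL, seed = 1L,
                              oracle_replicates = 10000L) {
  model <- validate_model(model)
  if (is.null(schedule)) schedule <- build_schedule(scheme)
  else scheme <- NA_integer_
  if (any(k_sweep < 0L) || any(k_sweep > model$n_generations))
    stop("k_sweep entries must lie in 0..n_generations")
  structure(list(model = model, sens = sens,
                 scheme = if (is.na(scheme)) NA_integer_ else as.integer(scheme),
                 schedule = schedule,
                 k_sweep = as.integer(k_sweep), times = times,
                 out_dir = out_dir, seed = as.integer(seed),
                 oracle_replicates = as.integer(oracle_replicates)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment config:\n  ")
  print(x$model)
  cat("  ")
  print(x$sens)
  cat("  ")
  print(x$schedule)
  cat(sprintf("  k sweep: %s; seed %d; oracle replicates %d\n",
              paste(x$k_sweep, collapse = ","), x$seed, x$oracle_replicates))
  invisible(x)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  x <- list(model = model_to_config(config$model),
            sens = list(alpha_pos = config$sens$alpha_pos,
                        beta_pos = config$sens$beta_pos,
                        alpha_neg = config$sens$alpha_neg,
                        beta_neg = config$sens$beta_neg),
            scheme = config$scheme,
            schedule = list(time_days = config$schedule$time_days,
                            dose_Gy = config$schedule$dose_Gy,
                            label = attr(config$schedule, "label")),
            k_sweep = config$k_sweep, times = config$times,
            out_dir = config$out_dir, seed = config$seed,
            oracle_replicates = config$oracle_replicates)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("model", "sens", "scheme", "schedule", "k_sweep", "times",
             "out_dir", "seed", "oracle_replicates")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown experiment config key(s): ", paste(unknown, collapse = ", "))
  experiment_config(
    model = model_from_config(x$model),
    sens = do.call(radiosensitivity_set, x$sens),
    schedule = radiation_schedule(x$schedule$time_days, x$schedule$dose_Gy,
                                  label = x$schedule$label),
    k_sweep = x$k_sweep, times = x$times, out_dir = x$out_dir,
    seed = if (is.null(x$seed)) 1L else x$seed,
    oracle_replicates = if (is.null(x$oracle_replicates)) 10000L
                        else x$oracle_replicates)
}

set_model_k <- function(model, k) {
  model$k_positive <- as.integer(k)
  validate_model(model)
}

#' TCP_S versus TCP_CD+ for a sweep of biomarker depths
#'
#' Computes the theoretical stem TCP and the measurable biomarker TCP for
#' each `k` in the configured sweep under the configured schedule
#' (conventional scheme 1 by default), versus time and versus cumulative
#' dose. The `k = 0` biomarker curve coincides with the stem curve. When
#' `config$out_dir` is set, one CSV (+ JSON sidecar) is written per curve:
#' `tcp_stem.csv` and `tcp_cd_k<k>.csv`.
#'
#' @param config an [experiment_config()].
#' @return list with `stem` (a [tcp_curve()]), `cd` (named list of
#'   [tcp_curve()] per k), and `long` (one data.frame with columns
#'   `variant`, `k`, `t_days`, `dose_Gy`, `tcp`).
#' @export
run_fig3 <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sched <- config$schedule
  times <- if (is.null(config$times)) schedule_time_grid(sched) else config$times
  stem <- tcp_s(config$model, sched, config$sens, times)
  cd <- lapply(config$k_sweep, function(k)
    tcp_cd(set_model_k(config$model, k), sched, config$sens, times))
  names(cd) <- paste0("k", config$k_sweep)
  long <- rbind(
    data.frame(variant = "stem", k = NA_integer_, as.data.frame(stem)),
    do.call(rbind, lapply(seq_along(cd), function(i)
      data.frame(variant = "cd", k = config$k_sweep[i],
                 as.data.frame(cd[[i]])))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prm <- list(schedule = attr(sched, "label"))
    write_tcp_curve(stem, file.path(config$out_dir, "tcp_stem.csv"), prm)
    for (i in seq_along(cd))
      write_tcp_curve(cd[[i]],
                      file.path(config$out_dir,
                                sprintf("tcp_cd_k%d.csv", config$k_sweep[i])),
                      prm)
  }
  list(stem = stem, cd = cd, long = long)
}

#' Compare the three fractionation schemes
#'
#' Computes the stem TCP and the `k = 3` biomarker TCP for schemes 1-3
#' (conventional, hyperfractionated, accelerated hyperfractionated), all
#' delivering 60 Gy, versus time and versus cumulative dose. When
#' `config$out_dir` is set, writes `tcp_<variant>_scheme<i>.csv` files.
#'
#' @param config an [experiment_config()]; its schedule field is ignored
#'   (the three named schemes are built internally), `k = 3` is clamped to
#'   `n_generations`.
#' @return list with `stem` and `cd` (each a named list of [tcp_curve()]
#'   per scheme) and `long` (combined data.frame with a `scheme` column).
#' @export
run_scheme_comparison <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  k <- min(3L, config$model$n_generations)
  model_k <- set_model_k(config$model, k)
  out <- list(stem = list(), cd = list())
  rows <- list()
  for (s in 1:3) {
    sched <- build_schedule(s)
    times <- schedule_time_grid(sched)
    st <- tcp_s(config$model, sched, config$sens, times)
    cd <- tcp_cd(model_k, sched, config$sens, times)
    out$stem[[paste0("scheme", s)]] <- st
    out$cd[[paste0("scheme", s)]] <- cd
    rows[[length(rows) + 1L]] <-
      data.frame(variant = "stem", scheme = s, k = NA_integer_,
                 as.data.frame(st))
    rows[[length(rows) + 1L]] <-
      data.frame(variant = "cd", scheme = s, k = k, as.data.frame(cd))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      prm <- list(schedule = attr(sched, "label"))
      write_tcp_curve(st, file.path(config$out_dir,
                                    sprintf("tcp_stem_scheme%d.csv", s)), prm)
      write_tcp_curve(cd, file.path(config$out_dir,
                                    sprintf("tcp_cd_scheme%d.csv", s)), prm)
    }
  }
  out$long <- do.call(rbind, rows)
  out
}

#' Scheme ranking consistency between two curve families
#'
#' The schedule comparison is "qualitatively consistent" between the
#' theoretical and the measurable TCP when, at every common cumulative dose
#' level, the ordering of the schemes by TCP is the same in both families.
#' The common dose levels are the multiples of 6 Gy (the smallest dose all
#' three schemes deliver exactly) up to 60 Gy. Levels where any curve sits
#' below `min_tcp` are skipped: deep in the tail all schemes give
#' essentially zero control and the ordering of values like 1e-40 carries
#' no information about the visible rise of the curves, which is what the
#' consistency claim is about.
#'
#' @param family_a,family_b named lists of [tcp_curve()] per scheme (as
#'   returned in `run_scheme_comparison()$stem` / `$cd`).
#' @param dose_levels common dose levels, Gy.
#' @param min_tcp floor below which a level is not compared (default 0.01).
#' @return `TRUE` if the per-level scheme rankings agree at every compared
#'   level (and at least one level was compared).
#' @export
scheme_ranking_consistent <- function(family_a, family_b,
                                      dose_levels = seq(6, 60, by = 6),
                                      min_tcp = 0.01) {
  stopifnot(identical(names(family_a), names(family_b)))
  compared <- 0L
  for (D in dose_levels) {
    va <- vapply(family_a, tcp_at_dose, numeric(1), dose = D)
    vb <- vapply(family_b, tcp_at_dose, numeric(1), dose = D)
    if (min(va, vb) < min_tcp) next
    compared <- compared + 1L
    if (!identical(rank(va, ties.method = "first"),
                   rank(vb, ties.method = "first"))) return(FALSE)
  }
  compared > 0L
}

#' Extra dose and extra time implied by the measurable TCP
#'
#' Quantifies the cost of using the conservative biomarker TCP in place of
#' the theoretical stem TCP: at each TCP level, the additional cumulative
#' dose (Gy) and additional treatment time (days) needed for the TCP_CD+
#' curve to reach the level the TCP_S curve reaches.
#'
#' @param stem_curve a [tcp_curve()] of variant `"stem"`.
#' @param cd_curve a [tcp_curve()] of variant `"cd"`.
#' @param levels TCP levels to match.
#' @return data.frame with columns `level`, `extra_days`, `extra_dose_Gy`
#'   (`NA` where a curve never reaches the level).
#' @export
surrogate_cost <- function(stem_curve, cd_curve, levels = c(0.5, 0.9)) {
  data.frame(
    level = levels,
    extra_days = vapply(levels, function(L)
      tcp_crossing(cd_curve, L, "time") - tcp_crossing(stem_curve, L, "time"),
      numeric(1)),
    extra_dose_Gy = vapply(levels, function(L)
      tcp_crossing(cd_curve, L, "dose") - tcp_crossing(stem_curve, L, "dose"),
      numeric(1)))
}
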