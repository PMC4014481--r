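#' TCP curve container
#'
#' A sampled tumour control probability curve: ordered (time, cumulative
#' dose, probability) triples for one TCP variant — either the theoretical
#' stem-cell TCP (`variant = "stem"`) or the measurable biomarker-positive
#' TCP (`variant = "cd"`, with its `k`). Extinction is absorbing, so the
#' probability column must be non-decreasing in time (a small numerical
#' slack of 1e-7 is allowed for ODE output).
#'
#' @param t_days increasing sample times, days.
#' @param dose_Gy cumulative dose at each sample time, Gy.
#' @param tcp probabilities in `[0, 1]`.
#' @param variant `"stem"` or `"cd"`.
#' @param k number of biomarker-positive progenitor generations (required
#'   for `variant = "cd"`).
#' @return object of class `tcp_curve`: a data.frame with columns
#'   `t_days`, `dose_Gy`, `tcp` and attributes `variant`, `k`.
#' @export
tcp_curve <- function(t_days, dose_Gy, tcp, variant = c("stem", "cd"),
                      k = NA_integer_) {
  variant <- match.arg(variant)
  if (length(t_days) == 0L) stop("empty time grid")
  if (any(diff(t_days) <= 0)) stop("t_days must be strictly increasing")
  if (length(dose_Gy) != length(t_days) || length(tcp) != length(t_days))
    stop("t_days, dose_Gy and tcp must have equal length")
  if (any(tcp < -1e-9 | tcp > 1 + 1e-9))
    stop("tcp values must lie in [0, 1]")
  tcp <- pmin(pmax(tcp, 0), 1)
  if (any(diff(tcp) < -1e-7))
    stop("tcp must be non-decreasing in time (extinction is absorbing)")
  if (variant == "cd" && is.na(k)) stop("variant 'cd' requires k")
  structure(data.frame(t_days = t_days, dose_Gy = dose_Gy, tcp = tcp),
            variant = variant, k = if (is.na(k)) NA_integer_ else as.integer(k),
            class = c("tcp_curve", "data.frame"))
}

#' @export
print.tcp_curve <- function(x, ...) {
  v <- attr(x, "variant")
  tag <- if (v == "cd") sprintf("TCP_CD+ (k = %d)", attr(x, "k")) else "TCP_S"
  cat(sprintf("%s curve: %d samples, t in [%g, %g] d, dose up to %g Gy, TCP %0.4g -> %0.4g\n",
              tag, nrow(x), min(x$t_days), max(x$t_days), max(x$dose_Gy),
              x$tcp[1L], x$tcp[nrow(x)]))
  invisible(x)
}

#' Interpolated crossing of a TCP level
#'
#' First time (or cumulative dose) at which the curve reaches a given TCP
#' level, by linear interpolation between adjacent samples on the chosen
#' axis. Used to quantify the extra time / extra dose implied by requiring
#' biomarker-positive control instead of stem-cell control.
#'
#' @param curve a [tcp_curve()].
#' @param level TCP level in (0, 1).
#' @param axis `"time"` (days) or `"dose"` (Gy).
#' @return crossing coordinate, or `NA` if the curve never reaches `level`.
#' @export
tcp_crossing <- function(curve, level, axis = c("time", "dose")) {
  axis <- match.arg(axis)
  x <- if (axis == "time") curve$t_days else curve$dose_Gy
  y <- curve$tcp
  if (max(y) < level) return(NA_real_)
  i <- which(y >= level)[1L]
  if (i == 1L || y[i] == y[i - 1L] || x[i] == x[i - 1L]) return(x[i])
  x[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
}

#' TCP value at a given cumulative dose
#'
#' Evaluates the curve at the moment the schedule first reaches (at least)
#' the given cumulative dose, i.e. just after the fraction that attains it.
#'
#' @param curve a [tcp_curve()].
#' @param dose cumulative dose, Gy.
#' @return TCP value, or `NA` if the curve never reaches `dose`.
#' @export
tcp_at_dose <- function(curve, dose) {
  i <- which(curve$dose_Gy >= dose - 1e-9)
  if (!length(i)) return(NA_real_)
  curve$tcp[i[1L]]
}

#' Write a TCP curve as CSV with a JSON provenance sidecar
#'
#' The CSV has columns `t_days`, `dose_Gy`, `tcp`; the sidecar
#' (`<path>.json`) records the variant, `k` and any parameter list passed.
#'
#' @param curve a [tcp_curve()].
#' @param path CSV output path.
#' @param params optional named list echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_tcp_curve <- function(curve, path, params = list()) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  meta <- c(list(variant = attr(curve, "variant"), k = attr(curve, "k"),
                 n_samples = nrow(curve)), params)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
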