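#' Hierarchical cancer stem cell population model
#'
#' Defines the kinetic parameters and initial state of a unidirectional
#' tumour hierarchy: stem cells `S` divide at rate `r_S` and each division is
#' symmetric self-renewal (`S -> S + S`, probability `p_sym_renew`),
#' asymmetric (`S -> S + P1`, probability `p_asym`) or symmetric
#' differentiation (`S -> P1 + P1`, probability `p_sym_diff`). A progenitor
#' of generation `j` divides at rate `r_P` into two generation `j + 1`
#' daughters; after `n_generations` divisions the daughters are mature cells
#' `M`, which never divide. The stem compartment plus the first `k_positive`
#' progenitor generations carry the surface biomarker (e.g. CD133 in glioma)
#' and form the biomarker-positive (CD+) set.
#'
#' @param r_S stem division rate, per day (>= 0).
#' @param r_P progenitor division rate, per day (>= 0).
#' @param p_sym_renew probability a stem division is `S -> S + S`.
#' @param p_asym probability a stem division is `S -> S + P1`.
#' @param p_sym_diff probability a stem division is `S -> P1 + P1`. The three
#'   probabilities must sum to 1.
#' @param n_generations integer `N >= 1`, number of progenitor generations.
#' @param k_positive integer in `0..n_generations`, number of progenitor
#'   generations sharing the biomarker (0 means the biomarker marks stems
#'   only).
#' @param d_S,d_P,d_M natural (radiation-independent) apoptosis rates per
#'   day for stem, progenitor and mature cells.
#' @param n_S0 initial stem cell count.
#' @param n_P0 integer vector of length `n_generations`: initial count per
#'   progenitor generation (recycled from a scalar).
#' @param n_M0 initial mature cell count.
#'
#' @return An object of class `hierarchy_model`.
#' @examples
#' m <- hierarchy_model(r_S = 0.4, r_P = 0.5,
#'                      p_sym_renew = 0.3, p_asym = 0.5, p_sym_diff = 0.2,
#'                      n_generations = 3, k_positive = 2,
#'                      n_S0 = 10, n_P0 = c(5, 5, 5))
#' effective_stem_rates(m)
#' @export
hierarchy_model <- function(r_S, r_P,
                            p_sym_renew, p_asym, p_sym_diff,
                            n_generations, k_positive = min(n_generations, 3L),
                            d_S = 0, d_P = 0, d_M = 0,
                            n_S0 = 1L, n_P0 = 0L, n_M0 = 0L) {
  n_generations <- as.integer(n_generations)
  k_positive <- as.integer(k_positive)
  if (length(n_P0) == 1L) n_P0 <- rep(n_P0, n_generations)
  if (length(n_P0) != n_generations)
    stop("n_P0 must have one count per progenitor generation (",
         n_generations, ")")
  m <- structure(
    list(r_S = as.numeric(r_S), r_P = as.numeric(r_P),
         p_sym_renew = as.numeric(p_sym_renew),
         p_asym = as.numeric(p_asym),
         p_sym_diff = as.numeric(p_sym_diff),
         n_generations = n_generations, k_positive = k_positive,
         d_S = as.numeric(d_S), d_P = as.numeric(d_P), d_M = as.numeric(d_M),
         init_counts = c(n_S0 = as.numeric(n_S0),
                         stats::setNames(as.numeric(n_P0),
                                         paste0("n_P0_", seq_len(n_generations))),
                         n_M0 = as.numeric(n_M0))),
    class = "hierarchy_model")
  validate_model(m)
}

#' Validate a hierarchy model
#'
#' Checks the model invariants: the stem division probabilities lie on the
#' probability simplex (sum to 1 within 1e-12), all rates and counts are
#' non-negative, counts are integral and `k_positive <= n_generations`.
#'
#' @param model a [hierarchy_model()] object.
#' @return `model`, unchanged, if every invariant holds; otherwise an error
#'   naming the violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "hierarchy_model"))
  p <- c(model$p_sym_renew, model$p_asym, model$p_sym_diff)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("stem division probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop(sprintf(paste0("stem division probabilities must sum to 1 ",
                        "(simplex violation: sum = %.15g)"), sum(p)))
  rates <- c(r_S = model$r_S, r_P = model$r_P,
             d_S = model$d_S, d_P = model$d_P, d_M = model$d_M)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  if (length(bad))
    stop("negative or non-finite rate(s): ", paste(bad, collapse = ", "))
  if (model$n_generations < 1L)
    stop("n_generations must be >= 1")
  if (model$k_positive < 0L || model$k_positive > model$n_generations)
    stop(sprintf("k_positive must lie in 0..n_generations (got k = %d, N = %d)",
                 model$k_positive, model$n_generations))
  cnt <- model$init_counts
  if (length(cnt) != model$n_generations + 2L)
    stop("init_counts must have one entry per compartment (S, P1..PN, M)")
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("initial counts must be non-negative integers")
  model
}

#' Compartment labels of a hierarchy model
#'
#' @param model a [hierarchy_model()] object.
#' @return character vector `c("S", "P1", ..., "PN", "M")`.
#' @export
compartment_labels <- function(model) {
  c("S", paste0("P", seq_len(model$n_generations)), "M")
}

#' Biomarker-positive compartments
#'
#' The biomarker-positive (CD+) set is exactly the stem compartment plus the
#' first `k_positive` progenitor generations; all later generations and
#' mature cells are biomarker-negative.
#'
#' @param model a [hierarchy_model()] object.
#' @return logical vector over compartments (`S`, `P1`..`PN`, `M`), `TRUE`
#'   for biomarker-positive compartments.
#' @export
biomarker_positive <- function(model) {
  labs <- compartment_labels(model)
  stats::setNames(seq_along(labs) <= model$k_positive + 1L, labs)
}

#' Initial counts as a named compartment vector
#' @param model a [hierarchy_model()] object.
#' @return numeric vector named `S`, `P1`..`PN`, `M`.
#' @export
initial_counts <- function(model) {
  stats::setNames(as.numeric(model$init_counts), compartment_labels(model))
}

#' Effective stem birth and death rates
#'
#' Projects the three stem division pathways onto the stem count alone:
#' `S -> S + S` is a birth (rate `r_S * p_sym_renew`), `S -> P1 + P1`
#' removes a stem cell and so acts as a death (rate `r_S * p_sym_diff`), and
#' the asymmetric division `S -> S + P1` leaves the stem count unchanged.
#' Natural apoptosis `d_S` adds to the death rate. Because progenitors never
#' regenerate stem cells, the stem count is itself a linear birth-death
#' process with these two rates, which is what makes the closed-form stem
#' TCP possible.
#'
#' @param model a validated [hierarchy_model()].
#' @return named numeric vector `c(birth = b_eff, death = delta0)`, per day.
#' @export
effective_stem_rates <- function(model) {
  model <- validate_model(model)
  c(birth = model$r_S * model$p_sym_renew,
    death = model$r_S * model$p_sym_diff + model$d_S)
}

#' Single-division offspring probability generating function
#'
#' Evaluates the offspring PGF of one division of a cell in the given
#' compartment at the point `z` (a vector over compartments): for `S` it is
#' `p1 z_S^2 + p2 z_S z_P1 + p3 z_P1^2`; for a progenitor generation `j < N`
#' it is `z_{P(j+1)}^2`; for `P_N` it is `z_M^2`. Natural death and
#' radiation kills are not divisions and are handled by the solvers, not
#' here. Mature cells do not divide and asking for their PGF is an error.
#'
#' @param model a validated [hierarchy_model()].
#' @param compartment compartment label (`"S"`, `"P1"`, ...) or index.
#' @param z numeric vector of length `n_generations + 2` with entries in
#'   `[0, 1]`, ordered `S`, `P1`..`PN`, `M` (names, if present, are checked).
#' @return the PGF value, a probability.
#' @export
offspring_pgf <- function(model, compartment, z) {
  model <- validate_model(model)
  labs <- compartment_labels(model)
  if (is.character(compartment)) {
    idx <- match(compartment, labs)
    if (is.na(idx)) stop("unknown compartment: ", compartment)
  } else {
    idx <- as.integer(compartment)
    if (idx < 1L || idx > length(labs)) stop("compartment index out of range")
  }
  if (length(z) != length(labs))
    stop("z must have one entry per compartment (", length(labs), ")")
  if (!is.null(names(z)) && !identical(names(z), labs))
    stop("names(z) must be the compartment labels in order")
  if (any(z < 0 | z > 1)) stop("z entries must lie in [0, 1]")
  N <- model$n_generations
  if (idx == length(labs))
    stop("mature cells do not divide; no offspring PGF is defined for M")
  if (idx == 1L) {
    zS <- z[[1L]]; zP1 <- z[[2L]]
    model$p_sym_renew * zS^2 + model$p_asym * zS * zP1 +
      model$p_sym_diff * zP1^2
  } else {
    # P_j -> two daughters of the next compartment down the chain
    z[[idx + 1L]]^2
  }
}

#' @export
print.hierarchy_model <- function(x, ...) {
  cat(sprintf("Hierarchical CSC model: S -> P1..P%d -> M\n", x$n_generations))
  cat(sprintf("  stem divisions: r_S = %g /day, p(S+S, S+P1, P1+P1) = (%g, %g, %g)\n",
              x$r_S, x$p_sym_renew, x$p_asym, x$p_sym_diff))
  cat(sprintf("  progenitor divisions: r_P = %g /day; natural death (d_S, d_P, d_M) = (%g, %g, %g) /day\n",
              x$r_P, x$d_S, x$d_P, x$d_M))
  cat(sprintf("  biomarker-positive: S plus first %d progenitor generation(s)\n",
              x$k_positive))
  cnt <- initial_counts(x)
  cat("  initial counts:", paste(sprintf("%s=%g", names(cnt), cnt), collapse = ", "),
      "\n")
  invisible(x)
}

# --- flat config I/O -------------------------------------------------------

.model_config_fields <- c("r_S", "r_P", "p_sym_renew", "p_asym", "p_sym_diff",
                          "n_generations", "k_positive",
                          "d_S", "d_P", "d_M", "n_S0", "n_P0", "n_M0")

#' Read a hierarchy model from a flat YAML or JSON config
#'
#' The file must contain exactly the constructor fields of
#' [hierarchy_model()] (`r_S`, `r_P`, `p_sym_renew`, `p_asym`, `p_sym_diff`,
#' `n_generations`, `k_positive`, `d_S`, `d_P`, `d_M`, `n_S0`, `n_P0`,
#' `n_M0`); optional fields may be omitted, but any unknown key is an error,
#' so a misspelled rate name cannot silently fall back to a default.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [hierarchy_model()].
#' @export
read_model_config <- function(path) {
  cfg <- read_flat_config(path)
  model_from_config(cfg)
}

model_from_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .model_config_fields)
  if (length(unknown))
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "))
  required <- c("r_S", "r_P", "p_sym_renew", "p_asym", "p_sym_diff",
                "n_generations")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("missing model config key(s): ", paste(missing, collapse = ", "))
  do.call(hierarchy_model, cfg)
}

model_to_config <- function(model) {
  list(r_S = model$r_S, r_P = model$r_P,
       p_sym_renew = model$p_sym_renew, p_asym = model$p_asym,
       p_sym_diff = model$p_sym_diff,
       n_generations = model$n_generations, k_positive = model$k_positive,
       d_S = model$d_S, d_P = model$d_P, d_M = model$d_M,
       n_S0 = unname(model$init_counts[1L]),
       n_P0 = unname(model$init_counts[2L:(model$n_generations + 1L)]),
       n_M0 = unname(model$init_counts[model$n_generations + 2L]))
}

read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json, got: ", path)
  }
}

#' Default glioma-like parameter set
#'
#' A documented, synthetic parameter set used throughout the examples and
#' the schedule-comparison experiments. It is assembled once from typical
#' values in the glioma radiobiology modelling literature (slowly cycling,
#' slowly expanding stem pool; faster-cycling progenitors; five progenitor
#' generations of which the first three share the CD133-like biomarker) and
#' is not a fit to any specific data set.
#'
#' @return a validated [hierarchy_model()].
#' @export
default_glioma_model <- function() {
  hierarchy_model(
    r_S = 0.1, r_P = 0.5,
    p_sym_renew = 0.3, p_asym = 0.6, p_sym_diff = 0.1,
    n_generations = 5L, k_positive = 3L,
    d_S = 0, d_P = 0, d_M = 0,
    n_S0 = 100L, n_P0 = c(200L, 400L, 800L, 1600L, 3200L), n_M0 = 10000L)
}
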