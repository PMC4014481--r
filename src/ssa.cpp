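#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie simulation of the S -> P1..PN -> M hierarchy with
// instantaneous radiation fractions applied as independent binomial
// thinning. Rates are constant between consecutive fraction times, so
// plain constant-propensity Gillespie is exact on each segment.
//
// Compartments: 0 = S, 1..N = progenitor generations, N+1 = M.
// Reactions:
//   stem division      rate r_S * nS, type ~ (p1: S+S, p2: S+P1, p3: 2 P1)
//   P_j division       rate r_P * nPj -> two cells of the next compartment
//   natural death i    rate d[i] * n[i]
//
// Uses the R RNG, so set.seed() in R governs reproducibility.

// [[Rcpp::export]]
List ssa_hierarchy_cpp(IntegerVector init, double r_S, double r_P,
                       double p1, double p2, double p3,
                       NumericVector d_nat,
                       NumericVector frac_times, NumericMatrix frac_sf,
                       double horizon, int reps,
                       IntegerVector target_idx,  // 1-based compartment idx
                       bool early_exit, bool record) {
  const int nc = init.size();
  const int nf = frac_times.size();
  if (frac_sf.nrow() != nf || frac_sf.ncol() != nc)
    stop("frac_sf must be (n fractions) x (n compartments)");
  if (record && reps != 1) stop("record mode requires reps = 1");

  IntegerMatrix finals(early_exit ? 0 : reps, early_exit ? 0 : nc);
  int extinct = 0;

  std::vector<double> rec_t;
  std::vector<int> rec_state;

  std::vector<double> state(nc);
  for (int rep = 0; rep < reps; ++rep) {
    for (int i = 0; i < nc; ++i) state[i] = init[i];
    double t = 0.0;
    int fi = 0;
    if (record) {
      rec_t.push_back(t);
      for (int i = 0; i < nc; ++i) rec_state.push_back((int) state[i]);
    }
    bool target_zero_exit = false;
    while (true) {
      // total propensity
      double aS = r_S * state[0];
      double aP = 0.0;
      for (int j = 1; j <= nc - 2; ++j) aP += state[j];
      aP *= r_P;
      double aD = 0.0;
      for (int i = 0; i < nc; ++i) aD += d_nat[i] * state[i];
      double a0 = aS + aP + aD;

      double next_frac = (fi < nf) ? frac_times[fi] : R_PosInf;
      double t_event = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;

      if (next_frac <= horizon && next_frac <= t_event) {
        t = next_frac;
        for (int i = 0; i < nc; ++i)
          if (state[i] > 0)
            state[i] = R::rbinom(state[i], frac_sf(fi, i));
        ++fi;
        if (record) {
          rec_t.push_back(t);
          for (int i = 0; i < nc; ++i) rec_state.push_back((int) state[i]);
        }
      } else if (t_event > horizon) {
        t = horizon;
        break;
      } else {
        t = t_event;
        double u = R::unif_rand() * a0;
        if (u < aS) {
          double v = R::unif_rand();
          if (v < p1) {                 // S -> S + S
            state[0] += 1;
          } else if (v < p1 + p2) {     // S -> S + P1
            state[1] += 1;
          } else {                      // S -> P1 + P1
            state[0] -= 1;
            state[1] += 2;
          }
        } else if (u < aS + aP) {
          double w = (u - aS) / r_P;    // pick progenitor generation
          int j = 1;
          double acc = state[1];
          while (j < nc - 2 && w >= acc) { ++j; acc += state[j]; }
          state[j] -= 1;
          state[j + 1] += 2;            // j = N spills into M
        } else {
          double w = u - aS - aP;
          int i = 0;
          double acc = d_nat[0] * state[0];
          while (i < nc - 1 && w >= acc) { ++i; acc += d_nat[i] * state[i]; }
          state[i] -= 1;
        }
        if (record) {
          rec_t.push_back(t);
          for (int i = 0; i < nc; ++i) rec_state.push_back((int) state[i]);
        }
      }
      if (early_exit) {
        // the target set (stem-rooted prefix of the hierarchy) can never be
        // repopulated once empty, so the extinction indicator is decided
        bool all_zero = true;
        for (int k = 0; k < target_idx.size(); ++k)
          if (state[target_idx[k] - 1] > 0) { all_zero = false; break; }
        if (all_zero) { target_zero_exit = true; break; }
      }
    }
    bool ext;
    if (target_zero_exit) {
      ext = true;
    } else {
      ext = true;
      for (int k = 0; k < target_idx.size(); ++k)
        if (state[target_idx[k] - 1] > 0) { ext = false; break; }
    }
    if (ext) ++extinct;
    if (!early_exit)
      for (int i = 0; i < nc; ++i) finals(rep, i) = (int) state[i];
  }

  List out = List::create(_["extinct"] = extinct, _["reps"] = reps);
  if (!early_exit) out["finals"] = finals;
  if (record) {
    int ne = rec_t.size();
    IntegerMatrix path(ne, nc);
    for (int e = 0; e < ne; ++e)
      for (int i = 0; i < nc; ++i) path(e, i) = rec_state[e * nc + i];
    out["times"] = NumericVector(rec_t.begin(), rec_t.end());
    out["path"] = path;
  }
  return out;
}
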