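#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One engaged polymerase on the lattice. `twist_up` is the accumulated
// relative twist (in turns) with the *upstream* neighbour; it is reset to
// zero whenever the pairing changes (Top1 swivel abstraction).
struct Pol {
  int pos;        // 1-based active-site position
  int maxpos;     // furthest position reached (backtrack depth = maxpos - pos)
  double birth;   // absolute time of initiation [s]
  double twist_up;
};

static const double BP_PER_TURN = 10.3; // one DNA rotation per 10.3 nt
static const double P0 = 0.25;          // baseline translocation attempt prob.

static inline double entrain(int len, int ler) {
  if (len < 0) return 0.0;
  if (ler <= 0) return 1.0;
  double f = (double)len / (double)ler;
  return f > 1.0 ? 1.0 : f;
}

// Mean of folding bias over [pos - w, pos - 1] (1-based), clamped to the
// template; empty window -> 0.
static inline double window_mean(const NumericVector &fold, int pos, int w) {
  if (fold.size() == 0 || w <= 0) return 0.0;
  int lo = pos - w;      // 1-based
  int hi = pos - 1;
  if (lo < 1) lo = 1;
  if (hi > (int)fold.size()) hi = fold.size();
  if (hi < lo) return 0.0;
  double s = 0.0;
  for (int i = lo; i <= hi; ++i) s += fold[i - 1];
  return s / (double)(hi - lo + 1);
}

// Forward/backward/stay probabilities for polymerase j given the full unit
// state. Exponential-bias Brownian ratchet: baseline bias E0 satisfies
// p_f - p_b = v_bar * dt on a neutral template with no neighbours.
static void step_probs(const std::vector<Pol> &pols, int j,
                       const NumericVector &fold,
                       int gene_length, int footprint, int hybrid_length,
                       double dt, double v_bar, double dg_structure,
                       double dg_hybrid_ratio, int structure_window,
                       double torsion_c, int ler_length,
                       double &pf, double &pb, int &warn) {
  int n = pols.size();
  double e0 = 2.0 * std::asinh(v_bar * dt / (2.0 * P0));
  double ej = entrain(pols[j].pos, ler_length);

  // torsion: pair k couples pol k (downstream) with pol k+1 (upstream);
  // twist of pair k is stored on pol k. Positive twist resists further
  // advance of the downstream member and pulls the upstream member forward.
  double et = 0.0;
  if (j + 1 < n)
    et -= torsion_c * pols[j].twist_up * ej * entrain(pols[j + 1].pos, ler_length);
  if (j > 0)
    et += torsion_c * pols[j - 1].twist_up * entrain(pols[j - 1].pos, ler_length) * ej;

  // paired nascent RNA behind the polymerase blocks reverse translocation
  double s = window_mean(fold, pols[j].pos, structure_window);
  double h = window_mean(fold, pols[j].pos, hybrid_length);
  double eb_block = dg_structure * (s + dg_hybrid_ratio * h);

  pf = P0 * std::exp((e0 + et) / 2.0);
  pb = P0 * std::exp(-(e0 + et) / 2.0 - eb_block);

  bool clamped = false;
  if (pf > 1.0) { pf = 1.0; clamped = true; }
  if (pb > 1.0) { pb = 1.0; clamped = true; }
  if (pf < 0.0) pf = 0.0;
  if (pb < 0.0) pb = 0.0;
  if (pf + pb > 1.0) { double z = pf + pb; pf /= z; pb /= z; clamped = true; }
  if (clamped) ++warn;

  // steric exclusion (index 0 = most downstream; positions strictly decrease)
  if (j > 0 && pols[j - 1].pos - pols[j].pos <= footprint) pf = 0.0;
  if (pols[j].pos == 1) pb = 0.0;
  else if (j + 1 < n && pols[j].pos - pols[j + 1].pos <= footprint) pb = 0.0;
}

// [[Rcpp::export(name = ".cpp_step_probabilities")]]
NumericVector cpp_step_probabilities(IntegerVector positions, NumericVector twists,
                                     int j, NumericVector folding,
                                     int gene_length, int footprint,
                                     int hybrid_length, double dt, double v_bar,
                                     double dg_structure, double dg_hybrid_ratio,
                                     int structure_window, double torsion_c,
                                     int ler_length) {
  std::vector<Pol> pols(positions.size());
  for (int i = 0; i < positions.size(); ++i) {
    pols[i].pos = positions[i];
    pols[i].maxpos = positions[i];
    pols[i].birth = 0.0;
    pols[i].twist_up = twists[i];
  }
  double pf = 0.0, pb = 0.0;
  int warn = 0;
  step_probs(pols, j - 1, folding, gene_length, footprint, hybrid_length, dt,
             v_bar, dg_structure, dg_hybrid_ratio, structure_window, torsion_c,
             ler_length, pf, pb, warn);
  return NumericVector::create(_["p_forward"] = pf, _["p_backward"] = pb,
                               _["p_stay"] = 1.0 - pf - pb,
                               _["clamped"] = (double)warn);
}

// Advance a transcription unit by `nsteps` time steps of dt seconds.
// Per step, in order: (1) initiation attempt if due and promoter free,
// (2) one translocation draw per polymerase, downstream -> upstream,
// (3) premature-termination draws (position <= pt_distance),
// (4) run-off completion at gene_length. Occupancy accumulates dt at each
// polymerase position after the moves.
// [[Rcpp::export(name = ".cpp_advance")]]
List cpp_advance(IntegerVector positions, IntegerVector maxpositions,
                 NumericVector births, NumericVector twists,
                 double time0, int nsteps,
                 int gene_length, int footprint, int hybrid_length,
                 double dt, double initiation_prob, double initiation_interval,
                 double v_bar, double dg_structure, double dg_hybrid_ratio,
                 int structure_window, double torsion_c,
                 double p_pt, int pt_distance, int ler_length,
                 NumericVector folding, double burn_in,
                 bool stochastic, bool debug_steric) {
  std::vector<Pol> pols(positions.size());
  for (int i = 0; i < positions.size(); ++i) {
    pols[i].pos = positions[i];
    pols[i].maxpos = maxpositions[i];
    pols[i].birth = births[i];
    pols[i].twist_up = twists[i];
  }

  NumericVector occupancy(gene_length);
  double hazard = (pt_distance > 0) ? p_pt * v_bar / (double)pt_distance : 0.0;
  double p_term = hazard * dt;
  int init_every = (int)std::lround(initiation_interval / dt);
  if (init_every < 1) init_every = 1;
  int fwd_every = (int)std::lround(1.0 / (v_bar * dt));
  if (fwd_every < 1) fwd_every = 1;
  int step0 = (int)std::lround(time0 / dt);

  long initiations = 0, productive = 0, nonproductive = 0;
  long initiations_ss = 0, productive_ss = 0, nonproductive_ss = 0;
  double sum_engaged = 0.0, sum_engaged_ss = 0.0;
  long steps_ss = 0;
  double sum_transit = 0.0;
  long n_transit = 0;
  int warn = 0;

  for (int step = 0; step < nsteps; ++step) {
    double t = time0 + step * dt;
    bool post_burn = (t >= burn_in);
    int abs_step = step0 + step;

    // (1) initiation
    if (abs_step % init_every == 0) {
      bool promoter_free =
          pols.empty() || pols.back().pos > footprint;
      if (promoter_free && unif_rand() < initiation_prob) {
        if (!pols.empty()) pols.back().twist_up = 0.0; // new upstream pairing
        Pol p;
        p.pos = 1; p.maxpos = 1; p.birth = t; p.twist_up = 0.0;
        pols.push_back(p);
        ++initiations;
        if (post_burn) ++initiations_ss;
      }
    }

    // (2) translocation, downstream -> upstream
    int n = pols.size();
    for (int j = 0; j < n; ++j) {
      int move = 0;
      if (stochastic) {
        double pf, pb;
        step_probs(pols, j, folding, gene_length, footprint, hybrid_length, dt,
                   v_bar, dg_structure, dg_hybrid_ratio, structure_window,
                   torsion_c, ler_length, pf, pb, warn);
        double u = unif_rand();
        if (u < pf) move = 1;
        else if (u < pf + pb) move = -1;
      } else {
        // constant-velocity control: one forward step every 1/(v_bar*dt)
        // steps, steric exclusion still enforced, no backtracking
        if (abs_step % fwd_every == 0 &&
            !(j > 0 && pols[j - 1].pos - pols[j].pos <= footprint))
          move = 1;
      }
      if (move != 0) {
        pols[j].pos += move;
        if (pols[j].pos > pols[j].maxpos) pols[j].maxpos = pols[j].pos;
        double dtw = (double)move / BP_PER_TURN;
        if (j + 1 < n) pols[j].twist_up += dtw;
        if (j > 0) pols[j - 1].twist_up -= dtw;
      }
    }

    if (debug_steric) {
      for (int j = 1; j < n; ++j) {
        if (pols[j - 1].pos - pols[j].pos < footprint)
          stop("steric invariant violated at step %d (gap %d < footprint)",
               step, pols[j - 1].pos - pols[j].pos);
      }
    }

    // occupancy census (before removals; a polymerase's final position counts)
    for (int j = 0; j < n; ++j) {
      int idx = pols[j].pos;
      if (idx >= 1 && idx <= gene_length) occupancy[idx - 1] += dt;
    }

    // (3) premature termination
    if (p_term > 0.0) {
      for (int j = (int)pols.size() - 1; j >= 0; --j) {
        if (pols[j].pos <= pt_distance && unif_rand() < p_term) {
          if (j > 0) pols[j - 1].twist_up = 0.0; // pairing change relaxes twist
          pols.erase(pols.begin() + j);
          ++nonproductive;
          if (post_burn) ++nonproductive_ss;
        }
      }
    }

    // (4) run-off completion
    while (!pols.empty() && pols.front().pos >= gene_length) {
      sum_transit += (t + dt) - pols.front().birth;
      ++n_transit;
      pols.erase(pols.begin());
      ++productive;
      if (post_burn) ++productive_ss;
    }

    sum_engaged += (double)pols.size();
    if (post_burn) { sum_engaged_ss += (double)pols.size(); ++steps_ss; }
  }

  int n_end = pols.size();
  IntegerVector out_pos(n_end), out_max(n_end);
  NumericVector out_birth(n_end), out_twist(n_end);
  for (int i = 0; i < n_end; ++i) {
    out_pos[i] = pols[i].pos;
    out_max[i] = pols[i].maxpos;
    out_birth[i] = pols[i].birth;
    out_twist[i] = pols[i].twist_up;
  }

  return List::create(
      _["positions"] = out_pos, _["max_positions"] = out_max,
      _["births"] = out_birth, _["twists"] = out_twist,
      _["time"] = time0 + nsteps * dt, _["occupancy"] = occupancy,
      _["initiations"] = (double)initiations,
      _["productive"] = (double)productive,
      _["nonproductive"] = (double)nonproductive,
      _["initiations_ss"] = (double)initiations_ss,
      _["productive_ss"] = (double)productive_ss,
      _["nonproductive_ss"] = (double)nonproductive_ss,
      _["mean_engaged"] = nsteps > 0 ? sum_engaged / nsteps : NA_REAL,
      _["mean_engaged_ss"] = steps_ss > 0 ? sum_engaged_ss / steps_ss : NA_REAL,
      _["steps_ss"] = (double)steps_ss,
      _["sum_transit"] = sum_transit, _["n_transit"] = (double)n_transit,
      _["warnings"] = (double)warn);
}
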