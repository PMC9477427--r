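// Exact continuous-time (Gillespie) simulation of the H3K27 lattice model.
//
// States: 0 = u, 1 = ac, 2 = me1, 3 = me2, 4 = me3.
//
// One call simulates a single epoch [tStart, tEnd] with fixed kinetic rates
// and enzyme profiles; scheduled replication events and passive recording
// times fall inside the epoch. The R wrapper chains epochs to implement
// protocols that change parameters or profiles mid-run.
//
// A per-site spreading sum S[i] = sum_j K(i,j) psiS[j] [state j == me3] is
// maintained incrementally: O(n) work when a site enters or leaves me3,
// O(1) otherwise. The Gillespie clock is truncated at scheduled events
// (replication, epoch end) and the waiting time redrawn afterwards, which is
// statistically exact for a time-homogeneous process between events.
//
// Histone turnover fires on every site at rate gTurn. On a modified site it
// resets the state to u; on an unmodified site it leaves the state unchanged
// but still replaces the physical histone, so the pool label flips. This
// keeps the old-histone fraction independent of the epigenetic state, as it
// must be for a state-blind exchange process.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Engine {
  int n;
  const double *psiS, *psiP, *psiU, *K; // K column-major n x n
  // rates
  double kme1, kme2, kme3, eme1, eme2, eme3, gme, kac, gac, gturn;
  std::vector<double> S;   // spreading sums
  std::vector<double> a;   // per-site total propensity
  double A;                // total propensity

  double siteRate(int i, const int *state) const {
    switch (state[i]) {
    case 0: return kme1 * psiS[i] + eme1 * S[i] + kac * psiP[i] + gturn;
    case 1: return gac + gturn;
    case 2: return kme2 * psiS[i] + eme2 * S[i] + gme * psiU[i] + gturn;
    case 3: return kme3 * psiS[i] + eme3 * S[i] + gme * psiU[i] + gturn;
    default: return gme * psiU[i] + gturn;
    }
  }

  void rebuild(const int *state) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j)
        if (state[j] == 4) s += K[(size_t)j * n + i] * psiS[j];
      S[i] = s;
    }
    A = 0.0;
    for (int i = 0; i < n; ++i) { a[i] = siteRate(i, state); A += a[i]; }
  }

  // site j entered (+1) or left (-1) the me3 state; state[] already updated
  void me3Flip(int j, int sign, const int *state) {
    const double w = psiS[j];
    for (int i = 0; i < n; ++i) S[i] += sign * K[(size_t)j * n + i] * w;
    A = 0.0;
    for (int i = 0; i < n; ++i) { a[i] = siteRate(i, state); A += a[i]; }
  }

  void localUpdate(int i, const int *state) {
    double old = a[i];
    a[i] = siteRate(i, state);
    A += a[i] - old;
  }
};

} // namespace

// [[Rcpp::export(name = ".gillespie_epoch")]]
List gillespie_epoch(IntegerVector state0, IntegerVector pool0,
                     NumericVector incorp0,
                     NumericVector psiS, NumericVector psiP, NumericVector psiU,
                     NumericMatrix kernel, NumericVector rates,
                     double tStart, double tEnd,
                     NumericVector repTimes, NumericVector recTimes,
                     double labelEpoch) {
  const int n = state0.size();
  if (psiS.size() != n || psiP.size() != n || psiU.size() != n ||
      kernel.nrow() != n || kernel.ncol() != n)
    stop("profile/kernel dimensions do not match the configuration");
  if (rates.size() != 10) stop("expected 10 rate constants");

  std::vector<int> state(state0.begin(), state0.end());
  std::vector<int> pool(pool0.begin(), pool0.end());
  std::vector<double> incorp(incorp0.begin(), incorp0.end());

  Engine eng;
  eng.n = n;
  eng.psiS = psiS.begin(); eng.psiP = psiP.begin(); eng.psiU = psiU.begin();
  eng.K = kernel.begin();
  eng.kme1 = rates[0]; eng.kme2 = rates[1]; eng.kme3 = rates[2];
  eng.eme1 = rates[3]; eng.eme2 = rates[4]; eng.eme3 = rates[5];
  eng.gme = rates[6]; eng.kac = rates[7]; eng.gac = rates[8];
  eng.gturn = rates[9];
  eng.S.assign(n, 0.0); eng.a.assign(n, 0.0);
  eng.rebuild(state.data());

  const int nRec = recTimes.size();
  IntegerMatrix recStates(nRec, n), recPools(nRec, n);
  int ir = 0, irep = 0;
  const int nRep = repTimes.size();
  long nRepEvents = 0, sitesErased = 0, sitesFlipped = 0;
  long eventCount = 0;

  RNGScope scope;
  double t = tStart;

  while (true) {
    // next stochastic reaction time
    double tReact = (eng.A > 0.0) ? t + R::exp_rand() / eng.A : R_PosInf;
    double tRep = (irep < nRep) ? repTimes[irep] : R_PosInf;
    double tEvent = std::min(tReact, std::min(tRep, tEnd));

    // record every sample time passed before the next state change
    while (ir < nRec && recTimes[ir] <= tEvent) {
      for (int i = 0; i < n; ++i) {
        recStates(ir, i) = state[i];
        recPools(ir, i) = pool[i];
      }
      ++ir;
    }

    if (tRep <= tReact && tRep <= tEnd) {
      // scheduled replication: each site independently lost with prob 1/2
      t = tRep; ++irep; ++nRepEvents;
      bool anyMe3 = false;
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < 0.5) {
          ++sitesErased;
          if (state[i] == 4) anyMe3 = true;
          state[i] = 0;
          if (t >= labelEpoch) {
            if (pool[i] == 0) ++sitesFlipped;
            pool[i] = 1;
            incorp[i] = t;
          }
        }
      }
      (void)anyMe3;
      eng.rebuild(state.data());
      continue;
    }

    if (tReact >= tEnd) { t = tEnd; break; }

    // stochastic reaction
    t = tReact;
    ++eventCount;
    double u = unif_rand() * eng.A;
    int i = 0;
    double acc = eng.a[0];
    while (u > acc && i < n - 1) { ++i; acc += eng.a[i]; }
    double r = u - (acc - eng.a[i]); // position within site i's rate budget

    int s = state[i];
    switch (s) {
    case 0: { // u: -> me1 | -> ac | turnover (pool flip only)
      double r1 = eng.kme1 * psiS[i] + eng.eme1 * eng.S[i];
      double r2 = eng.kac * psiP[i];
      if (r < r1) {
        state[i] = 2; eng.localUpdate(i, state.data());
      } else if (r < r1 + r2) {
        state[i] = 1; eng.localUpdate(i, state.data());
      } else {
        if (t >= labelEpoch) { pool[i] = 1; incorp[i] = t; }
      }
      break;
    }
    case 1: { // ac: deacetylation or turnover -> u
      state[i] = 0;
      if (r >= eng.gac && t >= labelEpoch) { pool[i] = 1; incorp[i] = t; }
      eng.localUpdate(i, state.data());
      break;
    }
    case 2: { // me1: -> me2 | demethylation -> u | turnover -> u
      double r1 = eng.kme2 * psiS[i] + eng.eme2 * eng.S[i];
      double r2 = eng.gme * psiU[i];
      if (r < r1) state[i] = 3;
      else {
        state[i] = 0;
        if (r >= r1 + r2 && t >= labelEpoch) { pool[i] = 1; incorp[i] = t; }
      }
      eng.localUpdate(i, state.data());
      break;
    }
    case 3: { // me2: -> me3 | -> me1 | turnover -> u
      double r1 = eng.kme3 * psiS[i] + eng.eme3 * eng.S[i];
      double r2 = eng.gme * psiU[i];
      if (r < r1) {
        state[i] = 4; eng.me3Flip(i, +1, state.data());
      } else if (r < r1 + r2) {
        state[i] = 2; eng.localUpdate(i, state.data());
      } else {
        state[i] = 0;
        if (t >= labelEpoch) { pool[i] = 1; incorp[i] = t; }
        eng.localUpdate(i, state.data());
      }
      break;
    }
    default: { // me3: demethylation -> me2 | turnover -> u
      if (r < eng.gme * psiU[i]) state[i] = 3;
      else {
        state[i] = 0;
        if (t >= labelEpoch) { pool[i] = 1; incorp[i] = t; }
      }
      eng.me3Flip(i, -1, state.data());
      break;
    }
    }

    if (eventCount % 16384 == 0) {
      eng.rebuild(state.data()); // guard against floating-point drift
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
    _["states"] = recStates, _["pools"] = recPools,
    _["finalState"] = IntegerVector(state.begin(), state.end()),
    _["finalPool"] = IntegerVector(pool.begin(), pool.end()),
    _["incorporation"] = NumericVector(incorp.begin(), incorp.end()),
    _["nReplications"] = (double)nRepEvents,
    _["sitesErased"] = (double)sitesErased,
    _["nReactions"] = (double)eventCount);
}
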