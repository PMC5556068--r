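// Simulation kernel for the two-type exclusion Markov chain.
//
// State is the L x L occupancy matrix (0 empty, 1 tumor, 2 normal),
// column-major as passed from R; (r, c) are 0-based here and converted
// back to R's 1-based convention at the interface. The kernel uses R's
// RNG stream (unif_rand), so runs are reproducible via set.seed().
//
// Admissibility is maintained incrementally: every placement goes through
// canPlace(), which scans the diamond neighborhood of radius
// max_j D(i, j) - 1 around the target. Since exclusion distances are
// small (<= 3 by default), a "full" admissibility check reduces to
// running the same local scan at every occupied vertex: any violating
// pair is within distance max D - 1 of each other.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int L;
  int D[3][3];          // D[i][j], i, j in {1, 2}
  double alpha[3], delta[3], rho[3];
  int rad[3];           // max_j D[i][j] - 1: scan radius for placing type i
  std::vector<int> state;  // col-major, state[r + c * L]

  inline int at(int r, int c) const { return state[r + c * L]; }
  inline void set(int r, int c, int v) { state[r + c * L] = v; }
  inline bool border(int r, int c) const {
    return r == 0 || c == 0 || r == L - 1 || c == L - 1;
  }

  // Can a cell of type t be placed at (r, c), disregarding the cell at
  // (ignR, ignC) if given? Border sites never accept a cell.
  bool canPlace(int r, int c, int t, int ignR = -1, int ignC = -1) const {
    if (border(r, c)) return false;
    const int rad_t = rad[t];
    for (int dr = -rad_t; dr <= rad_t; ++dr) {
      int rr = r + dr;
      if (rr < 0 || rr >= L) continue;
      int rem = rad_t - std::abs(dr);
      for (int dc = -rem; dc <= rem; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= L) continue;
        if (rr == ignR && cc == ignC) continue;
        int u = at(rr, cc);
        if (u != 0 && std::abs(dr) + std::abs(dc) < D[t][u]) return false;
      }
    }
    return true;
  }

  // Sites on the ring at graph distance d from (r, c); f is called with
  // each in-grid ring site.
  template <typename F>
  void forRing(int r, int c, int d, F f) const {
    for (int dr = -d; dr <= d; ++dr) {
      int rr = r + dr;
      if (rr < 0 || rr >= L) continue;
      int rem = d - std::abs(dr);
      int cc = c + rem;
      if (cc >= 0 && cc < L) f(rr, cc);
      if (rem > 0) {
        cc = c - rem;
        if (cc >= 0 && cc < L) f(rr, cc);
      }
    }
  }

  // Local admissibility of the cell at (r, c) against its neighborhood.
  bool cellLocallyAdmissible(int r, int c) const {
    int t = at(r, c);
    if (t == 0) return true;
    if (border(r, c)) return false;
    const int rad_t = rad[t];
    for (int dr = -rad_t; dr <= rad_t; ++dr) {
      int rr = r + dr;
      if (rr < 0 || rr >= L) continue;
      int rem = rad_t - std::abs(dr);
      for (int dc = -rem; dc <= rem; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= L) continue;
        int u = at(rr, cc);
        if (u != 0 && std::abs(dr) + std::abs(dc) < D[t][u]) return false;
      }
    }
    return true;
  }

  bool fullyAdmissible() const {
    for (int c = 0; c < L; ++c)
      for (int r = 0; r < L; ++r)
        if (at(r, c) != 0 && !cellLocallyAdmissible(r, c)) return false;
    return true;
  }
};

Model buildModel(const IntegerMatrix& state, const IntegerMatrix& D,
                 const NumericVector& alpha, const NumericVector& delta,
                 const NumericVector& rho) {
  Model m;
  m.L = state.nrow();
  if (state.ncol() != m.L) stop("state must be square");
  for (int i = 1; i <= 2; ++i)
    for (int j = 1; j <= 2; ++j)
      m.D[i][j] = D(i - 1, j - 1);
  for (int i = 1; i <= 2; ++i) {
    m.alpha[i] = alpha[i - 1];
    m.delta[i] = delta[i - 1];
    m.rho[i] = rho[i - 1];
    m.rad[i] = std::max(m.D[i][1], m.D[i][2]) - 1;
    if (m.D[i][i] > 8) stop("self-exclusion distances above 8 are not supported");
  }
  m.state.assign(state.begin(), state.end());
  return m;
}

struct StepOutcome {
  // event codes: 0 none (quiescence / stay empty), 1 death, 2 migrate out,
  // 3 birth, 4 migrate in
  int event = 0;
  int type = 0;
  int tr = -1, tc = -1;  // target (migration destination or source)
};

// One chain update at vertex (r, c). Mutates m.state and the counts when
// commit is true; always fills `out`.
void updateVertex(Model& m, int r, int c, long long cnt[3], StepOutcome& out,
                  bool commit) {
  out = StepOutcome();
  int t = m.at(r, c);
  if (t != 0) {
    // occupied: quiescence / death / migrate out
    int recvR[33], recvC[33], ne = 0;  // ring at distance d has 4d <= 32 sites
    if (m.delta[t] > 0) {
      int d = m.D[t][t];
      m.forRing(r, c, d, [&](int rr, int cc) {
        if (m.at(rr, cc) == 0 && m.canPlace(rr, cc, t, r, c)) {
          recvR[ne] = rr; recvC[ne] = cc; ++ne;
        }
      });
    }
    double Q = m.alpha[t] + ne * m.delta[t] + m.rho[t];
    if (Q <= 0) stop("degenerate occupied-vertex distribution: Q = 0");
    double u = unif_rand() * Q;
    if (u < m.alpha[t]) {
      return;  // quiescence
    }
    u -= m.alpha[t];
    if (u < m.rho[t]) {
      out.event = 1; out.type = t;
      if (commit) { m.set(r, c, 0); --cnt[t]; }
      return;
    }
    u -= m.rho[t];
    int k = (int)(u / m.delta[t]);
    if (k >= ne) k = ne - 1;  // guard FP edge
    out.event = 2; out.type = t; out.tr = recvR[k]; out.tc = recvC[k];
    if (commit) {
      m.set(r, c, 0);
      m.set(recvR[k], recvC[k], t);
    }
    return;
  }
  // empty vertex
  if (m.border(r, c)) return;
  int donR[2][33], donC[2][33], n[3] = {0, 0, 0};
  for (int i = 1; i <= 2; ++i) {
    int d = m.D[i][i];
    m.forRing(r, c, d, [&](int rr, int cc) {
      if (m.at(rr, cc) == i) {
        donR[i - 1][n[i]] = rr; donC[i - 1][n[i]] = cc; ++n[i];
      }
    });
  }
  if (n[1] == 0 && n[2] == 0) return;
  double w[3] = {0, 0, 0};
  bool I[3] = {false, false, false};
  for (int i = 1; i <= 2; ++i) {
    if (n[i] > 0) {
      I[i] = m.canPlace(r, c, i);
      if (I[i]) w[i] = n[i] * (m.alpha[i] + m.delta[i]);
    }
  }
  double R = m.rho[1] + m.rho[2] + w[1] + w[2];
  if (w[1] + w[2] <= 0) return;  // R = rho1 + rho2: stays empty
  double u = unif_rand() * R;
  if (u < m.rho[1] + m.rho[2]) return;  // stay empty
  u -= m.rho[1] + m.rho[2];
  for (int i = 1; i <= 2; ++i) {
    if (w[i] <= 0) continue;
    double births = n[i] * m.alpha[i];
    if (u < births) {
      out.event = 3; out.type = i;
      if (commit) { m.set(r, c, i); ++cnt[i]; }
      return;
    }
    u -= births;
    double migs = n[i] * m.delta[i];
    if (u < migs) {
      int k = (int)(u / m.delta[i]);
      if (k >= n[i]) k = n[i] - 1;
      out.event = 4; out.type = i;
      out.tr = donR[i - 1][k]; out.tc = donC[i - 1][k];
      if (commit) {
        m.set(donR[i - 1][k], donC[i - 1][k], 0);
        m.set(r, c, i);
      }
      return;
    }
    u -= migs;
  }
  // FP slack: treat as stay empty
}

}  // namespace

// [[Rcpp::export]]
List kernel_run(IntegerMatrix state, IntegerMatrix D, NumericVector alpha,
                NumericVector delta, NumericVector rho, double n_steps,
                double record_every, NumericVector snapshot_steps,
                bool validate_local, double validate_full_every) {
  Model m = buildModel(state, D, alpha, delta, rho);
  const int L = m.L;
  long long cnt[3] = {0, 0, 0};
  for (int v = 0; v < L * L; ++v)
    if (m.state[v]) ++cnt[m.state[v]];

  const long long N = (long long)n_steps;
  const long long rec = record_every >= 1 ? (long long)record_every : 1;
  const long long fullEvery = (long long)validate_full_every;

  std::vector<double> recSteps, recC1, recC2;
  recSteps.reserve((size_t)(N / rec) + 2);
  List snaps;
  std::vector<double> snapAt(snapshot_steps.begin(), snapshot_steps.end());
  std::vector<double> snapTaken;
  size_t snapIdx = 0;

  auto record = [&](long long s) {
    recSteps.push_back((double)s);
    recC1.push_back((double)cnt[1]);
    recC2.push_back((double)cnt[2]);
  };
  auto takeSnap = [&](long long s) {
    IntegerMatrix out(L, L);
    std::copy(m.state.begin(), m.state.end(), out.begin());
    snaps.push_back(out);
    snapTaken.push_back((double)s);
  };

  record(0);
  while (snapIdx < snapAt.size() && snapAt[snapIdx] <= 0) {
    takeSnap(0);
    ++snapIdx;
  }

  StepOutcome out;
  for (long long s = 1; s <= N; ++s) {
    int v = (int)(unif_rand() * (L * L));
    if (v >= L * L) v = L * L - 1;
    int r = v % L, c = v / L;
    updateVertex(m, r, c, cnt, out, true);
    if (validate_local && out.event != 0) {
      bool ok = true;
      if (out.event == 3 || out.event == 4)
        ok = m.cellLocallyAdmissible(r, c);
      else if (out.event == 2)
        ok = m.cellLocallyAdmissible(out.tr, out.tc);
      if (!ok) stop("admissibility violated at step %lld", s);
    }
    if (fullEvery > 0 && s % fullEvery == 0 && !m.fullyAdmissible())
      stop("full admissibility check failed at step %lld", s);
    if (s % rec == 0) record(s);
    while (snapIdx < snapAt.size() && (long long)snapAt[snapIdx] == s) {
      takeSnap(s);
      ++snapIdx;
    }
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (N % rec != 0) record(N);

  IntegerMatrix finalState(L, L);
  std::copy(m.state.begin(), m.state.end(), finalState.begin());
  return List::create(
      _["steps"] = NumericVector(recSteps.begin(), recSteps.end()),
      _["count1"] = NumericVector(recC1.begin(), recC1.end()),
      _["count2"] = NumericVector(recC2.begin(), recC2.end()),
      _["state"] = finalState,
      _["snapshots"] = snaps,
      _["snapshot_steps"] = NumericVector(snapTaken.begin(), snapTaken.end()));
}

// Repeatedly sample the kernel's single-vertex update at a fixed vertex
// without committing any change, tallying outcomes. Used to cross-check
// the kernel's sampling against the analytic update distributions.
// (r, c) are 1-based as in R; outcome names use 1-based target sites.
// [[Rcpp::export]]
List kernel_sample_vertex(IntegerMatrix state, IntegerMatrix D,
                          NumericVector alpha, NumericVector delta,
                          NumericVector rho, int r, int c, int n) {
  Model m = buildModel(state, D, alpha, delta, rho);
  long long cnt[3] = {0, 0, 0};
  std::map<std::string, long> tally;
  int t0 = m.at(r - 1, c - 1);
  StepOutcome out;
  for (int k = 0; k < n; ++k) {
    updateVertex(m, r - 1, c - 1, cnt, out, false);
    std::string key;
    char buf[64];
    switch (out.event) {
      case 0: key = t0 == 0 ? "stay_empty" : "quiescence"; break;
      case 1: key = "death"; break;
      case 2:
        snprintf(buf, sizeof(buf), "migrate_out_%d_%d", out.tr + 1, out.tc + 1);
        key = buf; break;
      case 3:
        snprintf(buf, sizeof(buf), "birth_%d", out.type);
        key = buf; break;
      case 4:
        snprintf(buf, sizeof(buf), "migrate_in_%d_%d_%d", out.type,
                 out.tr + 1, out.tc + 1);
        key = buf; break;
    }
    ++tally[key];
  }
  CharacterVector nm(tally.size());
  NumericVector cv(tally.size());
  int i = 0;
  for (auto& kv : tally) {
    nm[i] = kv.first;
    cv[i] = (double)kv.second;
    ++i;
  }
  cv.names() = nm;
  return List::create(_["counts"] = cv, _["n"] = n);
}

// Full admissibility check used as a fast path by R-level validation.
// [[Rcpp::export]]
bool kernel_is_admissible(IntegerMatrix state, IntegerMatrix D) {
  NumericVector a = NumericVector::create(1, 1);
  Model m = buildModel(state, D, a, a, a);
  return m.fullyAdmissible();
}
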