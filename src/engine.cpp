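// Reduced-coordinate simulation of online SGD for the K-unit two-layer ReLU
// network on the XOR Gaussian-mixture task.
//
// The network state enters the learning dynamics only through
//   M  (K x 2)  projections of the first-layer rows onto the class means,
//   Q  (K x K)  Gram matrix of the row components orthogonal to the means,
//   w2 (K)      readout weights,
// so one SGD step costs O(K^2) independently of the input dimension d.
// Stimulus draws are reproduced exactly in distribution: with u = L z
// (L = chol(Q), z standard normal) the orthogonal noise projections are
// N(0, Q) and |g_orth|^2 = |z|^2 + chisq(d - 2 - K).
//
// Two integration modes:
//   B = 1             the literal online process, one stimulus per step;
//   B > 1             drift estimated from B fresh stimuli per step; with
//                     mf = true the second-order (eta^2) drift of Q keeps its
//                     full one-sample magnitude, giving the deterministic
//                     mean-field equations with stochasticity confined to the
//                     initialization (and O(1/sqrt(B)) estimator noise).
//
// All randomness comes from an internal xoshiro256++ stream seeded per
// network as f(master_seed, seed_id); results are independent of execution
// order. R's RNG is not touched.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr int KMAX = 8;

struct Xo {
  uint64_t s[4];
  double spare; bool has_spare;
  static uint64_t sm64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL; uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t a, uint64_t b) {
    uint64_t x = a * 0x9E3779B97f4A7C15ULL ^ (b + 0x632BE59BD9B4E019ULL);
    for (int i = 0; i < 4; i++) s[i] = sm64(x);
    has_spare = false;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54; }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do { u = 2 * unif() - 1; v = 2 * unif() - 1; q = u * u + v * v; }
    while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
  // Marsaglia-Tsang; valid for shape >= 1 (always true here: df/2 >= 1)
  double gam(double a) {
    double dd = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9 * dd);
    for (;;) {
      double x = norm(), v = 1 + c * x;
      if (v <= 0) continue;
      v = v * v * v;
      double u = unif();
      if (std::log(u) < 0.5 * x * x + dd - dd * v + dd * std::log(v)) return dd * v;
    }
  }
  double chisq(double df) { return 2.0 * gam(df / 2.0); }
};

struct Net {
  int K;
  double M[KMAX][2];
  double Q[KMAX][KMAX];
  double w2[KMAX];
  int first;  // which cluster/sign block comes first in the bad curriculum
};

bool cholK(int K, const double Q[KMAX][KMAX], double L[KMAX][KMAX]) {
  double A[KMAX][KMAX];
  double tr = 0;
  for (int i = 0; i < K; i++) tr += Q[i][i];
  double jit = 1e-13 * (tr + 1e-30);
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) A[i][j] = Q[i][j] + ((i == j) ? jit : 0.0);
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) L[i][j] = 0;
  for (int j = 0; j < K; j++) {
    double s = A[j][j];
    for (int k = 0; k < j; k++) s -= L[j][k] * L[j][k];
    if (s <= 0) return false;
    L[j][j] = std::sqrt(s);
    for (int i = j + 1; i < K; i++) {
      double t = A[i][j];
      for (int k = 0; k < j; k++) t -= L[i][k] * L[j][k];
      L[i][j] = t / L[j][j];
    }
  }
  return true;
}

// gram: 0 = entrywise init (rows N(0, wstd^2 I_d); Q ~ wstd^2 Wishart_K(d-2)),
//       1 = isotropic dimension-free init (Q = wstd^2 I_K)
void init_net(Net &N, Xo &r, int K, double wstd, double w2std, int d, int gram) {
  N.K = K;
  for (int k = 0; k < K; k++) {
    N.M[k][0] = wstd * r.norm();
    N.M[k][1] = wstd * r.norm();
    N.w2[k] = w2std * r.norm();
  }
  double s2 = wstd * wstd;
  if (gram == 0) {
    double A[KMAX][KMAX];
    for (int i = 0; i < K; i++) for (int j = 0; j < K; j++) A[i][j] = 0;
    for (int i = 0; i < K; i++) {
      A[i][i] = std::sqrt(r.chisq((double)(d - 2 - i)));
      for (int j = 0; j < i; j++) A[i][j] = r.norm();
    }
    for (int i = 0; i < K; i++)
      for (int j = 0; j <= i; j++) {
        double t = 0;
        for (int m = 0; m < K; m++) t += A[i][m] * A[j][m];
        N.Q[i][j] = N.Q[j][i] = s2 * t;
      }
  } else {
    for (int i = 0; i < K; i++)
      for (int j = 0; j < K; j++) N.Q[i][j] = (i == j) ? s2 : 0.0;
  }
  N.first = (r.unif() < 0.5) ? 0 : 1;
}

// bmode: 0 both clusters, fair labels and signs;
//        1 cluster blocks: label forced to `first` w.p. p1 (bad curriculum);
//        2 sign blocks: center sign forced w.p. p1, labels fair.
inline void draw_trial_cond(Xo &r, int bmode, double p1, int first,
                            int &y, double &s) {
  if (bmode == 1) {
    y = (r.unif() < p1) ? first : 1 - first;
    s = (r.unif() < 0.5) ? 1.0 : -1.0;
  } else if (bmode == 2) {
    y = (r.unif() < 0.5) ? 1 : 0;
    double sf = first ? -1.0 : 1.0;
    s = (r.unif() < p1) ? sf : -sf;
  } else {
    y = (r.unif() < 0.5) ? 1 : 0;
    s = (r.unif() < 0.5) ? 1.0 : -1.0;
  }
}

// One online step (B = 1), exact.
void step_online(Net &N, Xo &r, double sigma, int bmode, double p1,
                 double eta_step, int d) {
  const int K = N.K;
  int y; double s;
  draw_trial_cond(r, bmode, p1, N.first, y, s);
  double g0 = r.norm(), g1 = r.norm();
  double L[KMAX][KMAX];
  cholK(K, N.Q, L);
  double z[KMAX], u[KMAX];
  for (int k = 0; k < K; k++) z[k] = r.norm();
  for (int k = 0; k < K; k++) {
    double t = 0;
    for (int j = 0; j <= k; j++) t += L[k][j] * z[j];
    u[k] = t;
  }
  double pre[KMAX], h[KMAX], f = 0;
  for (int k = 0; k < K; k++) {
    pre[k] = s * N.M[k][y] + sigma * (g0 * N.M[k][0] + g1 * N.M[k][1] + u[k]);
    h[k] = pre[k] > 0 ? pre[k] : 0;
    f += N.w2[k] * h[k];
  }
  double p = 1.0 / (1.0 + std::exp(-f)), delta = p - (double)y;
  double c[KMAX];
  for (int k = 0; k < K; k++) c[k] = (pre[k] > 0) ? eta_step * delta * N.w2[k] : 0.0;
  double z2 = 0;
  for (int k = 0; k < K; k++) z2 += z[k] * z[k];
  double G2 = z2 + r.chisq((double)(d - 2 - K));
  for (int k = 0; k < K; k++) {
    N.w2[k] -= eta_step * delta * h[k];
    N.M[k][y] -= c[k] * s;
    N.M[k][0] -= c[k] * sigma * g0;
    N.M[k][1] -= c[k] * sigma * g1;
  }
  double Qn[KMAX][KMAX];
  for (int i = 0; i < K; i++)
    for (int j = 0; j <= i; j++) {
      double t = N.Q[i][j] - sigma * (c[i] * u[j] + c[j] * u[i])
                 + c[i] * c[j] * sigma * sigma * G2;
      Qn[i][j] = Qn[j][i] = t;
    }
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) N.Q[i][j] = Qn[i][j];
}

// One drift step estimated from B stimuli. With mf = true the quadratic Q
// term keeps its one-sample magnitude (mean-field equations); otherwise it is
// the plain minibatch-SGD step.
void step_batch(Net &N, Xo &r, double sigma, int bmode, double p1,
                double eta_step, int d, int B, bool mf, int stride = 1) {
  const int K = N.K;
  double L[KMAX][KMAX];
  cholK(K, N.Q, L);
  double aw2[KMAX] = {0}, aM[KMAX][2] = {{0}};
  double aQu[KMAX][KMAX], aQc[KMAX][KMAX];
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) { aQu[i][j] = 0; aQc[i][j] = 0; }
  double nu = (double)(d - 2 - K);
  for (int b = 0; b < B; b++) {
    int y; double s;
    draw_trial_cond(r, bmode, p1, N.first, y, s);
    double g0 = r.norm(), g1 = r.norm();
    double z[KMAX], u[KMAX];
    for (int k = 0; k < K; k++) z[k] = r.norm();
    for (int k = 0; k < K; k++) {
      double t = 0;
      for (int j = 0; j <= k; j++) t += L[k][j] * z[j];
      u[k] = t;
    }
    double pre[KMAX], h[KMAX], f = 0;
    for (int k = 0; k < K; k++) {
      pre[k] = s * N.M[k][y] + sigma * (g0 * N.M[k][0] + g1 * N.M[k][1] + u[k]);
      h[k] = pre[k] > 0 ? pre[k] : 0;
      f += N.w2[k] * h[k];
    }
    double p = 1.0 / (1.0 + std::exp(-f)), delta = p - (double)y;
    double c[KMAX];
    for (int k = 0; k < K; k++) c[k] = (pre[k] > 0) ? delta * N.w2[k] : 0.0;
    double z2 = 0;
    for (int k = 0; k < K; k++) z2 += z[k] * z[k];
    // normal approximation to chisq(d-2-K); relative error O(1/d), and this
    // term only feeds the second-order Q drift
    double G2 = z2 + nu + std::sqrt(2.0 * nu) * r.norm();
    for (int k = 0; k < K; k++) {
      aw2[k] += delta * h[k];
      aM[k][y] += c[k] * s;
      aM[k][0] += c[k] * sigma * g0;
      aM[k][1] += c[k] * sigma * g1;
    }
    for (int i = 0; i < K; i++)
      for (int j = 0; j <= i; j++) {
        aQu[i][j] += c[i] * u[j] + c[j] * u[i];
        aQc[i][j] += c[i] * c[j] * G2;
      }
  }
  double ib = 1.0 / (double)B;
  // with a stride-scaled step (eta_step = stride * eta / d) the second-order
  // drift must stay proportional to the time increment, not its square
  double qcs = mf ? ib / (double)stride : ib * ib;
  for (int k = 0; k < K; k++) {
    N.w2[k] -= eta_step * aw2[k] * ib;
    N.M[k][0] -= eta_step * aM[k][0] * ib;
    N.M[k][1] -= eta_step * aM[k][1] * ib;
  }
  double Qn[KMAX][KMAX];
  for (int i = 0; i < K; i++)
    for (int j = 0; j <= i; j++) {
      double t = N.Q[i][j] - eta_step * sigma * aQu[i][j] * ib
                 + eta_step * eta_step * sigma * sigma * aQc[i][j] * qcs;
      Qn[i][j] = Qn[j][i] = t;
    }
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++) N.Q[i][j] = Qn[i][j];
}

// Accuracy on m fresh trials whose (sigma, p1) pairs are drawn uniformly from
// the supplied pools; abstentions (logit exactly 0) count as incorrect.
double eval_net(Net &N, Xo &r, const std::vector<double> &sigpool,
                const std::vector<double> &ppool, int bmode, int m, int d) {
  const int K = N.K;
  double L[KMAX][KMAX];
  cholK(K, N.Q, L);
  int P = (int)sigpool.size();
  double correct = 0;
  for (int i = 0; i < m; i++) {
    int idx = (P > 1) ? (int)(r.unif() * P) : 0;
    if (idx >= P) idx = P - 1;
    int y; double s;
    draw_trial_cond(r, bmode, ppool.empty() ? 0.5 : ppool[idx], N.first, y, s);
    double sigma = sigpool[idx];
    double g0 = r.norm(), g1 = r.norm();
    double z[KMAX], u[KMAX];
    for (int k = 0; k < K; k++) z[k] = r.norm();
    for (int k = 0; k < K; k++) {
      double t = 0;
      for (int j = 0; j <= k; j++) t += L[k][j] * z[j];
      u[k] = t;
    }
    double f = 0;
    for (int k = 0; k < K; k++) {
      double pre = s * N.M[k][y] + sigma * (g0 * N.M[k][0] + g1 * N.M[k][1] + u[k]);
      if (pre > 0) f += N.w2[k] * pre;
    }
    int dec = (f > 0) ? 1 : ((f < 0) ? 0 : -1);
    if (dec == y) correct += 1.0;
  }
  return correct / m;
}

void state_to_row(const Net &N, int i, NumericMatrix &Mo, NumericMatrix &w2o,
                  NumericMatrix &Qo, IntegerVector &fo) {
  const int K = N.K;
  for (int k = 0; k < K; k++) {
    Mo(i, k) = N.M[k][0];
    Mo(i, K + k) = N.M[k][1];
    w2o(i, k) = N.w2[k];
    for (int j = 0; j < K; j++) Qo(i, k * K + j) = N.Q[k][j];
  }
  fo[i] = N.first;
}

void row_to_state(Net &N, int K, int i, const NumericMatrix &Mo,
                  const NumericMatrix &w2o, const NumericMatrix &Qo,
                  const IntegerVector &fo) {
  N.K = K;
  for (int k = 0; k < K; k++) {
    N.M[k][0] = Mo(i, k);
    N.M[k][1] = Mo(i, K + k);
    N.w2[k] = w2o(i, k);
    for (int j = 0; j < K; j++) N.Q[k][j] = Qo(i, k * K + j);
  }
  N.first = fo[i];
}

} // namespace

// [[Rcpp::export]]
List cpp_population(int n_networks, int d, int K, double w_std, double w2_std,
                    double eta, NumericVector sigma_t, NumericVector p1_t,
                    int bmode, int n_eval, int n_test, double sigma_test,
                    double master_seed, IntegerVector seed_ids,
                    int gram = 0, int B = 1, bool mf = false,
                    int shuffle_blocks = 0) {
  if (K < 1 || K > KMAX) stop("K must be between 1 and %d", KMAX);
  if (d < K + 3) stop("input dimension too small for the reduced engine");
  int T = sigma_t.size();
  if (p1_t.size() != T) stop("sigma_t and p1_t lengths differ");
  if (shuffle_blocks > 0 && T % shuffle_blocks != 0)
    stop("schedule length not divisible by the number of blocks");
  int units = T / d;
  double eta_step = eta / (double)d;
  NumericMatrix train_acc(n_networks, units);
  NumericVector test_acc(n_networks);
  NumericMatrix Mo(n_networks, 2 * K), w2o(n_networks, K), Qo(n_networks, K * K);
  IntegerVector fo(n_networks);
  std::vector<double> sp(d), pp(d), sig(T);
  for (int i = 0; i < n_networks; i++) {
    Xo r;
    r.seed((uint64_t)master_seed, (uint64_t)seed_ids[i]);
    Net N;
    init_net(N, r, K, w_std, w2_std, d, gram);
    // per-network difficulty order: permute contiguous blocks of the base
    // schedule with this network's own stream
    if (shuffle_blocks > 0) {
      int L = shuffle_blocks, blk = T / shuffle_blocks;
      std::vector<int> ord(L);
      for (int l = 0; l < L; l++) ord[l] = l;
      for (int l = L - 1; l > 0; l--) {
        int j = (int)(r.unif() * (l + 1));
        if (j > l) j = l;
        std::swap(ord[l], ord[j]);
      }
      for (int l = 0; l < L; l++)
        for (int j = 0; j < blk; j++) sig[l * blk + j] = sigma_t[ord[l] * blk + j];
    } else {
      for (int t = 0; t < T; t++) sig[t] = sigma_t[t];
    }
    int u = 0;
    for (int t = 0; t < T; t++) {
      if (B == 1) step_online(N, r, sig[t], bmode, p1_t[t], eta_step, d);
      else step_batch(N, r, sig[t], bmode, p1_t[t], eta_step, d, B, mf);
      if ((t + 1) % d == 0 && u < units) {
        int lo = t + 1 - d;
        for (int j = 0; j < d; j++) { sp[j] = sig[lo + j]; pp[j] = p1_t[lo + j]; }
        train_acc(i, u) = eval_net(N, r, sp, pp, bmode, n_eval, d);
        u++;
      }
    }
    std::vector<double> st(1, sigma_test), pt(1, 0.5);
    test_acc[i] = eval_net(N, r, st, pt, 0, n_test, d);
    state_to_row(N, i, Mo, w2o, Qo, fo);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["train_acc"] = train_acc, _["test_acc"] = test_acc,
                      _["M"] = Mo, _["w2"] = w2o, _["Q"] = Qo,
                      _["first"] = fo);
}

// [[Rcpp::export]]
NumericMatrix cpp_extend(NumericMatrix M, NumericMatrix w2, NumericMatrix Q,
                         IntegerVector first, int d, int K, double eta,
                         double sigma_hard, NumericVector extra_units,
                         int n_test, double master_seed, IntegerVector seed_ids,
                         int B = 1, bool mf = false, int stride = 1) {
  if (K < 1 || K > KMAX) stop("K out of range");
  int n = M.nrow();
  double eta_step = eta / (double)d * stride;
  int nc = extra_units.size();
  NumericMatrix out(n, nc);
  std::vector<double> st(1, sigma_hard), pt(1, 0.5);
  for (int i = 0; i < n; i++) {
    Xo r;
    r.seed((uint64_t)master_seed + 0x51abULL, (uint64_t)seed_ids[i]);
    Net N;
    row_to_state(N, K, i, M, w2, Q, first);
    double done = 0;
    for (int c2 = 0; c2 < nc; c2++) {
      long steps = (long)std::llround((extra_units[c2] - done) * d / stride);
      for (long t = 0; t < steps; t++) {
        if (B == 1) step_online(N, r, sigma_hard, 0, 0.5, eta_step, d);
        else step_batch(N, r, sigma_hard, 0, 0.5, eta_step, d, B, mf, stride);
      }
      done = extra_units[c2];
      out(i, c2) = eval_net(N, r, st, pt, 0, n_test, d);
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Deterministic replay of the two-layer update rule on given stimuli; used to
// verify that the R reference implementation and the compiled update agree to
// machine precision.
// [[Rcpp::export]]
List cpp_sgd_path(NumericMatrix W1, NumericVector w2, NumericMatrix X,
                  IntegerVector y, double eta_step) {
  int K = W1.nrow(), d = W1.ncol(), n = X.nrow();
  if (X.ncol() != d) stop("stimulus dimension mismatch");
  NumericMatrix W(clone(W1));
  NumericVector v(clone(w2));
  for (int t = 0; t < n; t++) {
    std::vector<double> pre(K), h(K);
    double f = 0;
    for (int k = 0; k < K; k++) {
      double s = 0;
      for (int j = 0; j < d; j++) s += W(k, j) * X(t, j);
      pre[k] = s;
      h[k] = s > 0 ? s : 0;
      f += v[k] * h[k];
    }
    double p = 1.0 / (1.0 + std::exp(-f)), delta = p - (double)y[t];
    for (int k = 0; k < K; k++) {
      double c = (pre[k] > 0) ? eta_step * delta * v[k] : 0.0;
      if (c != 0.0)
        for (int j = 0; j < d; j++) W(k, j) -= c * X(t, j);
    }
    for (int k = 0; k < K; k++) v[k] -= eta_step * delta * h[k];
  }
  return List::create(_["W1"] = W, _["w2"] = v);
}
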