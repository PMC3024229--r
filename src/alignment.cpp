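#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed similarity matrix.
// sim(i, j) scores pairing residue i of sequence a with residue j of b.
// A gap run of length k costs gap_open + k * gap_ext.
//
// Three-state DP: M ends in a paired column, X ends consuming a (gap in b),
// Y ends consuming b (gap in a). Traceback ties are broken deterministically
// in the fixed order M > X > Y so identical inputs always give identical
// alignments.
//
// Returns score plus the aligned index paths (1-based; 0 marks a gap).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align(NumericMatrix sim, double gap_open, double gap_ext) {
  const int n = sim.nrow(), m = sim.ncol();
  if (n < 1 || m < 1) stop("both sequences must be non-empty");
  const double go = gap_open + gap_ext;  // cost of the first gapped position

  // DP matrices, (n+1) x (m+1), row-major index i*(m+1)+j
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which predecessor state (0=M,1=X,2=Y) fed each cell/state
  std::vector<signed char> tM((n + 1) * (m + 1), -1);
  std::vector<signed char> tX((n + 1) * (m + 1), -1);
  std::vector<signed char> tY((n + 1) * (m + 1), -1);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + i * gap_ext);
    tX[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + j * gap_ext);
    tY[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  // pick best of (m, x, y) with preference M > X > Y on ties
  auto best3 = [](double m_, double x_, double y_, signed char &which) {
    double b = m_; which = 0;
    if (x_ > b) { b = x_; which = 1; }
    if (y_ > b) { b = y_; which = 2; }
    return b;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      signed char w;
      double d = best3(M[idx(i - 1, j - 1)], X[idx(i - 1, j - 1)],
                       Y[idx(i - 1, j - 1)], w);
      if (d > NEG_INF) {
        M[idx(i, j)] = d + sim(i - 1, j - 1);
        tM[idx(i, j)] = w;
      }
      double x = best3(M[idx(i - 1, j)] - go, X[idx(i - 1, j)] - gap_ext,
                       Y[idx(i - 1, j)] - go, w);
      if (x > NEG_INF) { X[idx(i, j)] = x; tX[idx(i, j)] = w; }
      double y = best3(M[idx(i, j - 1)] - go, Y[idx(i, j - 1)] - gap_ext,
                       X[idx(i, j - 1)] - go, w);
      // preference order among predecessors of Y is M > X > Y; recompute
      // explicitly to keep the stated order
      y = NEG_INF;
      signed char wy = -1;
      double cand[3] = {M[idx(i, j - 1)] - go, X[idx(i, j - 1)] - go,
                        Y[idx(i, j - 1)] - gap_ext};
      for (int k = 0; k < 3; ++k)
        if (cand[k] > y) { y = cand[k]; wy = (signed char) k; }
      if (y > NEG_INF) { Y[idx(i, j)] = y; tY[idx(i, j)] = wy; }
    }
  }

  signed char state;
  double score = best3(M[idx(n, m)], X[idx(n, m)], Y[idx(n, m)], state);

  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  signed char s = state;
  while (i > 0 || j > 0) {
    signed char prev;
    if (s == 0) {            // paired column
      prev = tM[idx(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
    } else if (s == 1) {     // consume a, gap in b
      prev = tX[idx(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i;
    } else {                 // consume b, gap in a
      prev = tY[idx(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j;
    }
    s = prev;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Variant taking integer-coded residues plus the substitution matrix, so
// callers avoid materializing an n x m similarity matrix per pair.
// [[Rcpp::export]]
List gotoh_align_idx(IntegerVector a, IntegerVector b, NumericMatrix submat,
                     double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  NumericMatrix sim(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      sim(i, j) = submat(a[i] - 1, b[j] - 1);
  return gotoh_align(sim, gap_open, gap_ext);
}

// Score-only variant used by the all-vs-all search where the full traceback
// is not needed until a hit passes thresholds. Kept separate so the hot loop
// allocates no traceback storage.
// [[Rcpp::export]]
double gotoh_score_idx(IntegerVector av, IntegerVector bv,
                       NumericMatrix submat, double gap_open,
                       double gap_ext) {
  const int n = av.size(), m = bv.size();
  if (n < 1 || m < 1) stop("both sequences must be non-empty");
  const double go = gap_open + gap_ext;
  std::vector<double> Mp(m + 1, NEG_INF), Xp(m + 1, NEG_INF), Yp(m + 1, NEG_INF);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) Yp[j] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Xc[0] = -(gap_open + i * gap_ext);
    Yc[0] = NEG_INF;
    const int ai = av[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double d = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      Mc[j] = (d > NEG_INF) ? d + submat(ai, bv[j - 1] - 1) : NEG_INF;
      Xc[j] = std::max(Mp[j] - go, std::max(Xp[j] - gap_ext, Yp[j] - go));
      Yc[j] = std::max(Mc[j - 1] - go, std::max(Xc[j - 1] - go, Yc[j - 1] - gap_ext));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// Exact event-by-event (Gillespie) simulation of independent codon sites
// under an embedded jump chain. Uses R's RNG so results are reproducible
// under set.seed(). states are 1-based codon indices; jump_cum holds the
// cumulative jump distribution per row.
// [[Rcpp::export]]
IntegerVector evolve_states(IntegerVector states, NumericVector rates,
                            NumericMatrix jump_cum, double t) {
  const int ncod = states.size(), k = rates.size();
  IntegerVector out(ncod);
  GetRNGstate();
  for (int s = 0; s < ncod; ++s) {
    int cur = states[s] - 1;
    double remaining = t;
    for (;;) {
      double rate = rates[cur];
      if (rate <= 0) break;
      double dt = R::exp_rand() / rate;
      if (dt > remaining) break;
      remaining -= dt;
      double u = R::unif_rand();
      int nxt = 0;
      while (nxt < k - 1 && jump_cum(cur, nxt) < u) ++nxt;
      cur = nxt;
    }
    out[s] = cur + 1;
  }
  PutRNGstate();
  return out;
}
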