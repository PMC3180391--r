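#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Residue codes: 0 = gap, 1..K index into the substitution matrix M (K x K).
// Gap model: a run of n gap columns costs g + n * x in one go, i.e. the first
// gap position of a run costs g + x and every further position costs x.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// A profile: nrow sequences by ncol columns, row-major codes.
struct Profile {
  int nrow = 0, ncol = 0;
  std::vector<int> codes;    // row-major, nrow * ncol
  std::vector<int> members;  // original sequence indices (1-based)
  int at(int r, int c) const { return codes[(size_t)r * ncol + c]; }
};

// Gotoh DP workspace, reused across calls.
struct Workspace {
  std::vector<double> S, P, Hprev, Hcur, Eprev, Ecur;
  std::vector<unsigned char> tb, steps;
};
static Workspace ws;

// Profile-profile global affine-gap alignment. Column-column score is the
// mean of M(a, b) over all cross residue pairs (gap pairs contribute 0).
// Traceback ties: diagonal, then gap-in-B (consume A), then gap-in-A.
// Within a gap state, opening from the main state is preferred on ties.
static void profile_align_core(const Profile& A, const Profile& B,
                               const double* M, int K, double g, double x,
                               Profile& out, double& score) {
  const int na = A.nrow, La = A.ncol, nb = B.nrow, Lb = B.ncol;
  if (La < 1 || Lb < 1) stop("empty profile");

  // S[i*Lb + j] = mean cross-pair score of columns i (A) and j (B).
  // Precompute, for the profile with more rows, the per-residue column
  // score sums P[r][col] = sum over its residues c of column col of
  // M(c-1, r); then gather over the smaller profile's residues. P is laid
  // out residue-major so the gather runs over contiguous memory.
  ws.S.assign((size_t)La * Lb, 0.0);
  const double inv = 1.0 / ((double)na * (double)nb);
  if (na <= nb) {
    ws.P.assign((size_t)K * Lb, 0.0);
    for (int j = 0; j < Lb; ++j)
      for (int b = 0; b < nb; ++b) {
        int c = B.at(b, j);
        if (c > 0) {
          const double* mcol = M + (size_t)(c - 1) * K;
          for (int r = 0; r < K; ++r) ws.P[(size_t)r * Lb + j] += mcol[r];
        }
      }
    for (int i = 0; i < La; ++i) {
      double* srow = &ws.S[(size_t)i * Lb];
      for (int a = 0; a < na; ++a) {
        int c = A.at(a, i);
        if (c > 0) {
          const double* prow = &ws.P[(size_t)(c - 1) * Lb];
          for (int j = 0; j < Lb; ++j) srow[j] += prow[j];
        }
      }
      for (int j = 0; j < Lb; ++j) srow[j] *= inv;
    }
  } else {
    ws.P.assign((size_t)K * La, 0.0);
    for (int i = 0; i < La; ++i)
      for (int a = 0; a < na; ++a) {
        int c = A.at(a, i);
        if (c > 0) {
          const double* mcol = M + (size_t)(c - 1) * K;
          for (int r = 0; r < K; ++r) ws.P[(size_t)r * La + i] += mcol[r];
        }
      }
    std::vector<int> bcol((size_t)Lb * nb);
    for (int j = 0; j < Lb; ++j)
      for (int b = 0; b < nb; ++b) bcol[(size_t)j * nb + b] = B.at(b, j);
    for (int i = 0; i < La; ++i) {
      double* srow = &ws.S[(size_t)i * Lb];
      for (int j = 0; j < Lb; ++j) {
        double s = 0.0;
        const int* bc = &bcol[(size_t)j * nb];
        for (int b = 0; b < nb; ++b)
          if (bc[b] > 0) s += ws.P[(size_t)(bc[b] - 1) * La + i];
        srow[j] = s * inv;
      }
    }
  }

  // Rolling two-row DP; full matrices are never materialised. The packed
  // traceback byte holds: bits 0-1 = H choice (0 diag, 1 gap-in-B,
  // 2 gap-in-A), bit 2 = E extends, bit 3 = F extends.
  const double open = g + x;
  const int R = La + 1, C = Lb + 1;
  if ((int)ws.Hprev.size() < C) {
    ws.Hprev.resize(C); ws.Hcur.resize(C);
    ws.Eprev.resize(C); ws.Ecur.resize(C);
  }
  if (ws.tb.size() < (size_t)R * C) ws.tb.resize((size_t)R * C);
  double* Hprev = ws.Hprev.data(); double* Hcur = ws.Hcur.data();
  double* Eprev = ws.Eprev.data(); double* Ecur = ws.Ecur.data();
  unsigned char* tb = ws.tb.data();

  Hprev[0] = 0.0;
  tb[0] = 0;
  for (int j = 1; j <= Lb; ++j) {
    Hprev[j] = g + j * x;
    Eprev[j] = NEG_INF;
    tb[j] = 2 | ((j > 1) ? 8 : 0);
  }
  for (int i = 1; i <= La; ++i) {
    const double* srow = &ws.S[(size_t)(i - 1) * Lb];
    unsigned char* trow = tb + (size_t)i * C;
    Hcur[0] = Ecur[0] = g + i * x;
    trow[0] = 1 | ((i > 1) ? 4 : 0);
    double f = NEG_INF;        // F of current row, previous column
    double hleft = Hcur[0];    // H of current row, previous column
    double hdiag = Hprev[0];   // H of previous row, previous column
    for (int j = 1; j <= Lb; ++j) {
      const double hup = Hprev[j];
      double eOpen = hup + open, eExt = Eprev[j] + x;
      double e; unsigned char t;
      if (eOpen >= eExt) { e = eOpen; t = 0; } else { e = eExt; t = 4; }
      double fOpen = hleft + open, fExt = f + x;
      if (fOpen >= fExt) { f = fOpen; } else { f = fExt; t |= 8; }
      double best = hdiag + srow[j - 1];
      unsigned char tbh = 0;
      if (e > best) { best = e; tbh = 1; }
      if (f > best) { best = f; tbh = 2; }
      Hcur[j] = best; Ecur[j] = e;
      trow[j] = t | tbh;
      hdiag = hup;
      hleft = best;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  score = Hprev[Lb];

  ws.steps.clear();
  int i = La, j = Lb, state = 0;
  while (i > 0 || j > 0) {
    const unsigned char t = tb[(size_t)i * C + j];
    if (state == 0) {
      state = t & 3;
      if (state == 0) { ws.steps.push_back(0); --i; --j; }
    } else if (state == 1) {
      ws.steps.push_back(1);
      state = (t & 4) ? 1 : 0;
      --i;
    } else {
      ws.steps.push_back(2);
      state = (t & 8) ? 2 : 0;
      --j;
    }
  }
  const int Ln = (int)ws.steps.size();
  out.nrow = na + nb;
  out.ncol = Ln;
  out.codes.assign((size_t)(na + nb) * Ln, 0);
  out.members.clear();
  out.members.insert(out.members.end(), A.members.begin(), A.members.end());
  out.members.insert(out.members.end(), B.members.begin(), B.members.end());
  int ci = 0, cj = 0;
  for (int s = Ln - 1, col = 0; s >= 0; --s, ++col) {
    unsigned char st = ws.steps[s];
    if (st != 2) {  // diag or gap-in-B: consume a column of A
      for (int a = 0; a < na; ++a)
        out.codes[(size_t)a * Ln + col] = A.at(a, ci);
      ++ci;
    }
    if (st != 1) {  // diag or gap-in-A: consume a column of B
      for (int b = 0; b < nb; ++b)
        out.codes[(size_t)(na + b) * Ln + col] = B.at(b, cj);
      ++cj;
    }
  }
}

static Profile profile_from_matrix(const IntegerMatrix& m) {
  Profile p;
  p.nrow = m.nrow();
  p.ncol = m.ncol();
  p.codes.resize((size_t)p.nrow * p.ncol);
  for (int r = 0; r < p.nrow; ++r)
    for (int c = 0; c < p.ncol; ++c)
      p.codes[(size_t)r * p.ncol + c] = m(r, c);
  p.members.resize(p.nrow);
  for (int r = 0; r < p.nrow; ++r) p.members[r] = r + 1;
  return p;
}

static IntegerMatrix profile_to_matrix(const Profile& p,
                                       const std::vector<int>& row_order) {
  IntegerMatrix out((int)row_order.size(), p.ncol);
  for (size_t r = 0; r < row_order.size(); ++r)
    for (int c = 0; c < p.ncol; ++c)
      out((int)r, c) = p.at(row_order[r], c);
  return out;
}

// [[Rcpp::export]]
List cpp_profile_align(IntegerMatrix A, IntegerMatrix B, NumericMatrix M,
                       double g, double x) {
  Profile pa = profile_from_matrix(A), pb = profile_from_matrix(B), out;
  double score;
  profile_align_core(pa, pb, REAL(M), M.nrow(), g, x, out, score);
  std::vector<int> order(out.nrow);
  for (int r = 0; r < out.nrow; ++r) order[r] = r;
  return List::create(_["codes"] = profile_to_matrix(out, order),
                      _["score"] = score);
}

// Whole-tree progressive alignment. `leaves` is a list of integer code
// vectors (one per sequence, in index order); `plan` is an (n-1) x 2 matrix
// of post-order merges where entry k refers to leaf k (1..n) or to the
// result of merge k - n (k > n). Rows of the result are returned in
// original sequence order.
// [[Rcpp::export]]
IntegerMatrix cpp_progressive_align(List leaves, IntegerMatrix plan,
                                    NumericMatrix M, double g, double x) {
  const int n = leaves.size();
  std::vector<Profile> nodes((size_t)(2 * n - 1));
  for (int i = 0; i < n; ++i) {
    IntegerVector v = leaves[i];
    Profile& p = nodes[i];
    p.nrow = 1;
    p.ncol = v.size();
    p.codes.assign(v.begin(), v.end());
    p.members.assign(1, i + 1);
  }
  const double* Mp = REAL(M);
  const int K = M.nrow();
  double score;
  for (int k = 0; k < plan.nrow(); ++k) {
    const int a = plan(k, 0) - 1, b = plan(k, 1) - 1;
    profile_align_core(nodes[a], nodes[b], Mp, K, g, x, nodes[n + k], score);
    nodes[a] = Profile();  // release
    nodes[b] = Profile();
  }
  Profile& root = nodes[2 * n - 2];
  std::vector<int> order(root.nrow);
  for (int r = 0; r < root.nrow; ++r) order[root.members[r] - 1] = r;
  return profile_to_matrix(root, order);
}

// Hill-climbing leaf-shuffle search used by the mutation operator. Starting
// from the guide tree encoded by `plan`, repeatedly swaps two random leaf
// labels (drawn from R's RNG stream), re-aligns, and accepts the swap when
// the weighted sum-of-pairs fitness of the realignment beats the best seen
// in the loop; stops after `patience` consecutive failures. Only profiles
// of internal nodes on the root paths of the two swapped leaves are
// recomputed per trial. Returns the best alignment (rows in sequence
// order) and its fitness, or fitness = -Inf equivalent behaviour is left to
// the caller via the returned value.
// [[Rcpp::export]]
List cpp_mutation_search(List leaves, IntegerMatrix plan, NumericMatrix M,
                         double g, double x, NumericVector w, int patience) {
  const int n = leaves.size();
  const int nint = plan.nrow();
  const int nn = 2 * n - 1;
  const double* Mp = REAL(M);
  const int K = M.nrow();

  std::vector<std::vector<int>> seq(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = leaves[i];
    seq[i].assign(v.begin(), v.end());
  }
  // perm[leafpos] = sequence index currently at that leaf position
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<int> parent(nn, -1);
  for (int k = 0; k < nint; ++k) {
    parent[plan(k, 0) - 1] = n + k;
    parent[plan(k, 1) - 1] = n + k;
  }

  auto leaf_profile = [&](int pos, const std::vector<int>& pm, Profile& p) {
    p.nrow = 1;
    p.ncol = (int)seq[pm[pos]].size();
    p.codes = seq[pm[pos]];
    p.members.assign(1, pm[pos] + 1);
  };
  auto wspm_of = [&](const Profile& root) {
    double total = 0.0;
    const int N = root.nrow, L = root.ncol;
    for (int i = 0; i < N - 1; ++i) {
      const int* ri = &root.codes[(size_t)i * L];
      const double wi = w[root.members[i] - 1];
      for (int j = i + 1; j < N; ++j) {
        const int* rj = &root.codes[(size_t)j * L];
        const double W = wi * w[root.members[j] - 1];
        int run_i = 0, run_j = 0;
        for (int l = 0; l < L; ++l) {
          const int ci = ri[l], cj = rj[l];
          if (ci == 0 && cj == 0) continue;
          if (ci > 0 && cj > 0) {
            total += W * Mp[(size_t)(ci - 1) * K + (cj - 1)];
            if (run_i) { total += W * (g + run_i * x); run_i = 0; }
            if (run_j) { total += W * (g + run_j * x); run_j = 0; }
          } else if (ci == 0) {
            if (run_j) { total += W * (g + run_j * x); run_j = 0; }
            ++run_i;
          } else {
            if (run_i) { total += W * (g + run_i * x); run_i = 0; }
            ++run_j;
          }
        }
        if (run_i) total += W * (g + run_i * x);
        if (run_j) total += W * (g + run_j * x);
      }
    }
    return total;
  };

  std::vector<Profile> cache(nn), trial(nn);
  std::vector<char> dirty(nn, 0);
  double score;
  for (int i = 0; i < n; ++i) leaf_profile(i, perm, cache[i]);
  for (int k = 0; k < nint; ++k)
    profile_align_core(cache[plan(k, 0) - 1], cache[plan(k, 1) - 1], Mp, K,
                       g, x, cache[n + k], score);
  Profile best = cache.back();
  double best_fit = wspm_of(best);

  // Fitness of an already-tried (and failed) swap is unchanged until a
  // swap is accepted, so failed trials are memoised per unordered pair;
  // a repeat still counts as an unsuccessful attempt.
  std::vector<double> tried((size_t)n * n, NEG_INF);
  std::vector<int> pm(n);
  int failures = 0;
  while (failures < patience) {
    int a = (int)(unif_rand() * n);
    int b = (int)(unif_rand() * n);
    if (a >= n) a = n - 1;
    if (b >= n) b = n - 1;
    if (a == b) continue;  // redraw without counting a failure
    if (a > b) std::swap(a, b);
    if (tried[(size_t)a * n + b] != NEG_INF) {
      ++failures;
      continue;
    }
    pm = perm;
    std::swap(pm[a], pm[b]);
    std::fill(dirty.begin(), dirty.end(), 0);
    for (int v : {a, b}) {
      dirty[v] = 1;
      for (int u = parent[v]; u != -1; u = parent[u]) dirty[u] = 1;
    }
    leaf_profile(a, pm, trial[a]);
    leaf_profile(b, pm, trial[b]);
    for (int k = 0; k < nint; ++k) {
      if (!dirty[n + k]) continue;
      const int ca = plan(k, 0) - 1, cb = plan(k, 1) - 1;
      profile_align_core(dirty[ca] ? trial[ca] : cache[ca],
                         dirty[cb] ? trial[cb] : cache[cb],
                         Mp, K, g, x, trial[n + k], score);
    }
    double fit = wspm_of(trial.back());
    if (fit > best_fit) {
      best_fit = fit;
      best = trial.back();
      perm = pm;
      for (int v = 0; v < nn; ++v)
        if (dirty[v]) cache[v] = trial[v];
      failures = 0;
      std::fill(tried.begin(), tried.end(), NEG_INF);
    } else {
      tried[(size_t)a * n + b] = fit;
      ++failures;
    }
  }

  std::vector<int> order(best.nrow);
  for (int r = 0; r < best.nrow; ++r) order[best.members[r] - 1] = r;
  return List::create(_["codes"] = profile_to_matrix(best, order),
                      _["fitness"] = best_fit);
}

// Observed distance of a sequence pair from its global affine-gap
// alignment: mismatch columns (residue != residue, or residue vs gap)
// divided by alignment length.
// [[Rcpp::export]]
double cpp_dp_distance(IntegerVector a, IntegerVector b, NumericMatrix M,
                       double g, double x) {
  Profile pa, pb, out;
  pa.nrow = 1; pa.ncol = a.size(); pa.codes.assign(a.begin(), a.end());
  pa.members.assign(1, 1);
  pb.nrow = 1; pb.ncol = b.size(); pb.codes.assign(b.begin(), b.end());
  pb.members.assign(1, 2);
  double score;
  profile_align_core(pa, pb, REAL(M), M.nrow(), g, x, out, score);
  int mism = 0;
  for (int c = 0; c < out.ncol; ++c) {
    int ca = out.at(0, c), cb = out.at(1, c);
    if (ca == 0 || cb == 0 || ca != cb) ++mism;
  }
  return (double)mism / out.ncol;
}

// Weighted sum-of-pairs score with affine gaps, computed per unordered row
// pair on its gap-gap-deleted projection. Residue-residue columns contribute
// W_ij * m(a, b) to the per-column vector at their original column index;
// each maximal gap run in either projected row contributes W_ij * (g + n*x)
// to gap_total.
// [[Rcpp::export]]
List cpp_wspm(IntegerMatrix codes, NumericVector w, NumericMatrix M,
              double g, double x) {
  const int N = codes.nrow(), L = codes.ncol();
  NumericVector per_column(L);
  double gap_total = 0.0;
  // column-major copy for stride-1 row access
  std::vector<int> rm((size_t)N * L);
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < L; ++l) rm[(size_t)i * L + l] = codes(i, l);
  for (int i = 0; i < N - 1; ++i) {
    const int* ri = &rm[(size_t)i * L];
    for (int j = i + 1; j < N; ++j) {
      const int* rj = &rm[(size_t)j * L];
      const double W = w[i] * w[j];
      int run_i = 0, run_j = 0;
      for (int l = 0; l < L; ++l) {
        const int ci = ri[l], cj = rj[l];
        if (ci == 0 && cj == 0) continue;  // projected out
        if (ci > 0 && cj > 0) {
          per_column[l] += W * M(ci - 1, cj - 1);
          if (run_i) { gap_total += W * (g + run_i * x); run_i = 0; }
          if (run_j) { gap_total += W * (g + run_j * x); run_j = 0; }
        } else if (ci == 0) {
          if (run_j) { gap_total += W * (g + run_j * x); run_j = 0; }
          ++run_i;
        } else {
          if (run_i) { gap_total += W * (g + run_i * x); run_i = 0; }
          ++run_j;
        }
      }
      if (run_i) gap_total += W * (g + run_i * x);
      if (run_j) gap_total += W * (g + run_j * x);
    }
  }
  double total = gap_total;
  for (int l = 0; l < L; ++l) total += per_column[l];
  return List::create(_["total"] = total, _["per_column"] = per_column,
                      _["gap_total"] = gap_total);
}
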