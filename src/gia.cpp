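#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Informativeness for assignment from per-chromosome allele codes.
// codes: 0-based dense allele codes, one per training chromosome.
// pop:   0-based population index per chromosome.
// popn:  number of training chromosomes per population (length K).
// Uses natural log and the 0*log(0) = 0 convention.
static double ia_from_counts(const std::vector<double>& cnt, int K, int N,
                             const IntegerVector& popn) {
  double iaval = 0.0;
  for (int j = 0; j < N; ++j) {
    double pbar = 0.0, term2 = 0.0;
    for (int i = 0; i < K; ++i) {
      double f = cnt[(size_t)j * K + i] / popn[i];
      pbar += f;
      if (f > 0.0) term2 += f * std::log(f);
    }
    pbar /= K;
    if (pbar > 0.0) iaval -= pbar * std::log(pbar);
    iaval += term2 / K;
  }
  return iaval;
}

static void count_alleles(const IntegerVector& codes, const IntegerVector& pop,
                          int K, int N, std::vector<double>& cnt) {
  cnt.assign((size_t)N * K, 0.0);
  const int n = codes.size();
  for (int r = 0; r < n; ++r) cnt[(size_t)codes[r] * K + pop[r]] += 1.0;
}

// [[Rcpp::export]]
double cpp_ia_codes(IntegerVector codes, IntegerVector pop, int K,
                    IntegerVector popn) {
  int N = 0;
  for (int r = 0; r < codes.size(); ++r) if (codes[r] + 1 > N) N = codes[r] + 1;
  std::vector<double> cnt;
  count_alleles(codes, pop, K, N, cnt);
  return ia_from_counts(cnt, K, N, popn);
}

// Dense recoding of the chromosome-wise pair (x, y): haplotype-alleles are
// numbered 0, 1, ... in order of first appearance scanning chromosomes in
// storage order (the order of the individual list).
// [[Rcpp::export]]
IntegerVector cpp_combine_codes(IntegerVector x, IntegerVector y) {
  const int n = x.size();
  int ny = 0;
  for (int r = 0; r < n; ++r) if (y[r] + 1 > ny) ny = y[r] + 1;
  std::unordered_map<long long, int> seen;
  seen.reserve(n * 2);
  IntegerVector out(n);
  int next = 0;
  for (int r = 0; r < n; ++r) {
    long long key = (long long)x[r] * ny + y[r];
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen.emplace(key, next);
      out[r] = next++;
    } else {
      out[r] = it->second;
    }
  }
  return out;
}

// GIA for the pair (x, y): IA(combined) - IA(x) - IA(y).
// [[Rcpp::export]]
double cpp_gia_codes(IntegerVector x, IntegerVector y, IntegerVector pop,
                     int K, IntegerVector popn) {
  IntegerVector h = cpp_combine_codes(x, y);
  return cpp_ia_codes(h, pop, K, popn) - cpp_ia_codes(x, pop, K, popn) -
         cpp_ia_codes(y, pop, K, popn);
}

// Full greedy merge loop for one window.
// A:     training chromosomes x window markers, dense 0-based codes.
// cols:  global (1-based) column index of each window marker, used for
//        reporting and the deterministic tie-break.
// Returns the final partition as a list of global column-index vectors,
// plus the merge count and the spans of loci that reached one allele per
// chromosome.
// [[Rcpp::export]]
List cpp_greedy_window(IntegerMatrix A, IntegerVector cols,
                       IntegerVector pop, int K, IntegerVector popn,
                       double threshold, int max_alleles) {
  const int w = A.ncol();
  const int nt = A.nrow();
  std::vector<std::vector<int> > codes;
  std::vector<std::vector<int> > members;
  std::vector<int> nall;            // alleles per locus
  std::vector<double> iav;          // cached IA per locus
  std::vector<int> mins;            // smallest original column index
  std::vector<bool> active;
  std::vector<double> cnt;

  codes.reserve(2 * w); members.reserve(2 * w);
  for (int j = 0; j < w; ++j) {
    std::vector<int> cj(nt);
    int nj = 0;
    for (int r = 0; r < nt; ++r) {
      cj[r] = A(r, j);
      if (cj[r] + 1 > nj) nj = cj[r] + 1;
    }
    count_alleles(wrap(cj), pop, K, nj, cnt);
    iav.push_back(ia_from_counts(cnt, K, nj, popn));
    codes.push_back(cj);
    nall.push_back(nj);
    members.push_back(std::vector<int>(1, cols[j]));
    mins.push_back(cols[j]);
    active.push_back(true);
  }

  // combine two dense code vectors; out gets first-appearance codes
  std::vector<int> lookup;
  std::vector<int> comb(nt);
  int n_comb = 0;
  auto combine = [&](int i, int j) {
    lookup.assign((size_t)nall[i] * nall[j], -1);
    n_comb = 0;
    const std::vector<int>& x = codes[i];
    const std::vector<int>& y = codes[j];
    for (int r = 0; r < nt; ++r) {
      int key = x[r] * nall[j] + y[r];
      if (lookup[key] < 0) lookup[key] = n_comb++;
      comb[r] = lookup[key];
    }
  };
  auto ia_comb = [&]() {
    cnt.assign((size_t)n_comb * K, 0.0);
    for (int r = 0; r < nt; ++r) cnt[(size_t)comb[r] * K + pop[r]] += 1.0;
    return ia_from_counts(cnt, K, n_comb, popn);
  };

  // upper-triangular GIA table, grown as loci are added
  std::vector<std::vector<double> > G(w);
  for (int i = 0; i < w; ++i) {
    G[i].assign(w, R_NegInf);
    for (int j = i + 1; j < w; ++j) {
      combine(i, j);
      G[i][j] = ia_comb() - iav[i] - iav[j];
    }
  }

  int n_merges = 0;
  std::vector<int> warn_lo, warn_hi;
  for (;;) {
    double best = R_NegInf;
    int bi = -1, bj = -1, bk1 = 0, bk2 = 0;
    const int S = (int)codes.size();
    for (int i = 0; i < S; ++i) {
      if (!active[i]) continue;
      for (int j = i + 1; j < S; ++j) {
        if (!active[j] || G[i][j] == R_NegInf) continue;
        double g = G[i][j];
        int k1 = std::min(mins[i], mins[j]);
        int k2 = std::max(mins[i], mins[j]);
        if (g > best ||
            (g == best && (k1 < bk1 || (k1 == bk1 && k2 < bk2)))) {
          best = g; bi = i; bj = j; bk1 = k1; bk2 = k2;
        }
      }
    }
    if (bi < 0 || best <= threshold) break;
    combine(bi, bj);
    if (max_alleles > 0 && n_comb > max_alleles) {
      G[bi][bj] = R_NegInf;            // veto, keep looking
      continue;
    }
    if (n_comb == nt) {
      warn_lo.push_back(bk1);
      int hi = 0;
      for (int m : members[bi]) hi = std::max(hi, m);
      for (int m : members[bj]) hi = std::max(hi, m);
      warn_hi.push_back(hi);
    }
    double ia_new = ia_comb();
    std::vector<int> mem(members[bi]);
    mem.insert(mem.end(), members[bj].begin(), members[bj].end());
    active[bi] = active[bj] = false;
    codes.push_back(comb);
    members.push_back(mem);
    nall.push_back(n_comb);
    iav.push_back(ia_new);
    mins.push_back(bk1);
    active.push_back(true);
    int nw = (int)codes.size();
    for (int i = 0; i < nw - 1; ++i) G[i].push_back(R_NegInf);
    G.push_back(std::vector<double>(nw, R_NegInf));
    for (int k = 0; k < nw - 1; ++k) {
      if (!active[k]) continue;
      combine(k, nw - 1);
      G[k][nw - 1] = ia_comb() - iav[k] - ia_new;
    }
    ++n_merges;
  }

  List out_members;
  for (size_t i = 0; i < codes.size(); ++i) {
    if (active[i]) out_members.push_back(wrap(members[i]));
  }
  return List::create(_["members"] = out_members,
                      _["n_merges"] = n_merges,
                      _["warn_lo"] = wrap(warn_lo),
                      _["warn_hi"] = wrap(warn_hi));
}
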