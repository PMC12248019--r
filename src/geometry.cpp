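// Rigid-body superposition and superposition-search kernels.
// Coordinates are n x 3 matrices in Angstrom throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares rigid superposition of X onto Y (Kabsch, proper rotation).
// Fills Rrot (3x3) and tv (3) so that  y_i ~ Rrot * x_i + tv; returns rmsd.
static double kabsch_core(const arma::mat& X, const arma::mat& Y,
                          arma::mat& Rrot, arma::vec& tv) {
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx, Yc = Y.each_row() - cy;
  arma::mat H = Xc.t() * Yc;                    // 3x3 covariance
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0.0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3); D(2, 2) = d;
  Rrot = V * D * U.t();
  tv = cy.t() - Rrot * cx.t();
  arma::mat Xt = Xc * Rrot.t();                 // rotated, still centred
  double ss = arma::accu(arma::square(Xt - Yc));
  return std::sqrt(ss / X.n_rows);
}

// Apply stored transform to all rows of X.
static arma::mat apply_rt(const arma::mat& X, const arma::mat& Rrot,
                          const arma::vec& tv) {
  arma::mat Xt = X * Rrot.t();
  Xt.each_row() += tv.t();
  return Xt;
}

static arma::vec row_dists(const arma::mat& A, const arma::mat& B) {
  return arma::sqrt(arma::sum(arma::square(A - B), 1));
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& X, const arma::mat& Y) {
  arma::mat Rrot; arma::vec tv;
  double rmsd = kabsch_core(X, Y, Rrot, tv);
  return List::create(_["rotation"] = Rrot, _["translation"] = tv,
                      _["rmsd"] = rmsd);
}

// Seed windows used by the TM/GDT searches: lengths {4, n/2, n} at stride
// max(1, n/10), plus the full-length window.
static std::vector<std::pair<int,int>> seed_windows(int n, int dense_limit = 40) {
  std::vector<std::pair<int,int>> seeds;
  if (n <= dense_limit) {              // dense grid: every fragment length and start
    for (int len = 3; len <= n; ++len)
      for (int s = 0; s + len <= n; ++s) seeds.push_back({s, len});
    return seeds;
  }
  int lens[5] = {4, 8, n / 4, n / 2, n};
  int stride = std::max(1, n / 15);
  for (int li = 0; li < 5; ++li) {
    int len = std::max(3, lens[li]);
    if (len > n) len = n;
    bool dup = false;
    for (auto& sd : seeds) if (sd.second == len && sd.first == 0) { dup = len == n; }
    if (dup) continue;
    for (int s = 0; s + len <= n; s += stride) seeds.push_back({s, len});
    if (len == n) break;
  }
  seeds.push_back({0, n});
  return seeds;
}

// Iterative refinement from one seed selection; returns best TM seen.
static double tm_refine(const arma::mat& M, const arma::mat& Rf, double d0,
                        double Lnorm, arma::uvec sel, int niter) {
  double best = 0.0;
  double cutoff = std::max(2.0 * d0, 3.5);
  arma::mat Rrot; arma::vec tv;
  for (int it = 0; it < niter; ++it) {
    if (sel.n_elem < 3) break;
    kabsch_core(M.rows(sel), Rf.rows(sel), Rrot, tv);
    arma::vec d = row_dists(apply_rt(M, Rrot, tv), Rf);
    double tm = arma::accu(1.0 / (1.0 + arma::square(d / d0))) / Lnorm;
    if (tm > best) best = tm;
    arma::uvec nsel = arma::find(d < cutoff);
    if (nsel.n_elem < 4) nsel = arma::uvec(arma::sort_index(d)).head(std::min<arma::uword>(4, d.n_elem));
    bool same = (nsel.n_elem == sel.n_elem) && arma::all(nsel == sel);
    sel = nsel;
    if (same) break;
  }
  return best;
}

// TM-score over a fixed residue correspondence: M and Rf are matched
// representative-atom coordinates; Lnorm is the normalisation length.
// [[Rcpp::export]]
double cpp_tm_search(const arma::mat& M, const arma::mat& Rf, double d0,
                     double Lnorm, int niter = 20) {
  int n = M.n_rows;
  double best = 0.0;
  for (auto& sd : seed_windows(n)) {
    arma::uvec sel = arma::regspace<arma::uvec>(sd.first, sd.first + sd.second - 1);
    double tm = tm_refine(M, Rf, d0, Lnorm, sel, niter);
    if (tm > best) best = tm;
  }
  return best;
}

// Maximum number of matched residues fitting under `thr` Angstrom after
// some superposition (iterative peeling from seed windows).
// [[Rcpp::export]]
int cpp_gdt_count(const arma::mat& M, const arma::mat& Rf, double thr,
                  int niter = 20) {
  int n = M.n_rows, best = 0;
  arma::mat Rrot; arma::vec tv;
  std::vector<arma::uvec> starts;
  for (auto& sd : seed_windows(n, 12))
    starts.push_back(arma::regspace<arma::uvec>(sd.first, sd.first + sd.second - 1));
  if (n <= 12) {     // toy sizes: exhaustive single-shot subset scan
    for (unsigned mask = 0; mask < (1u << n); ++mask) {
      int bits = __builtin_popcount(mask);
      if (bits < 3) continue;
      arma::uvec sel(bits); int p = 0;
      for (int b = 0; b < n; ++b) if (mask & (1u << b)) sel(p++) = b;
      kabsch_core(M.rows(sel), Rf.rows(sel), Rrot, tv);
      arma::vec d = row_dists(apply_rt(M, Rrot, tv), Rf);
      int c = arma::accu(d <= thr);
      if (c > best) best = c;
    }
    return best;
  }
  arma::vec best_d;
  for (auto& seed_sel : starts) {
    arma::uvec sel = seed_sel;
    arma::vec d;
    for (int it = 0; it < niter; ++it) {
      if (sel.n_elem < 3) break;
      kabsch_core(M.rows(sel), Rf.rows(sel), Rrot, tv);
      d = row_dists(apply_rt(M, Rrot, tv), Rf);
      arma::uvec fit = arma::find(d <= thr);
      if ((int)fit.n_elem >= best) { best = fit.n_elem; best_d = d; }
      arma::uvec nsel = fit;
      if (nsel.n_elem < 3) nsel = arma::uvec(arma::sort_index(d)).head(std::min<arma::uword>(3, d.n_elem));
      bool same = (nsel.n_elem == sel.n_elem) && arma::all(nsel == sel);
      sel = nsel;
      if (same) break;
    }
  }
  // extension phase from the best superposition found: superpose on the k
  // nearest residues for growing k, reaching non-contiguous fit sets
  if (best_d.n_elem == (arma::uword)n) {
    arma::vec d = best_d;
    for (int k = 3; k <= n; ++k) {
      arma::uvec ksel = arma::uvec(arma::sort_index(d)).head(k);
      for (int rep = 0; rep < 5; ++rep) {
        kabsch_core(M.rows(ksel), Rf.rows(ksel), Rrot, tv);
        d = row_dists(apply_rt(M, Rrot, tv), Rf);
        int c = arma::accu(d <= thr);
        if (c > best) best = c;
        arma::uvec nk = arma::uvec(arma::sort_index(d)).head(k);
        if (arma::all(nk == ksel)) break;
        ksel = nk;
      }
    }
  }
  return best;
}

// Needleman-Wunsch over a similarity matrix with linear gap penalty.
// Returns 1-based index pairs of the aligned positions.
static void nw_align(const arma::mat& S, double gap,
                     std::vector<int>& ai, std::vector<int>& bi) {
  int n = S.n_rows, m = S.n_cols;
  arma::mat F(n + 1, m + 1, arma::fill::zeros);
  arma::Mat<int> ptr(n + 1, m + 1, arma::fill::zeros); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) { F(i, 0) = F(i - 1, 0) + gap; ptr(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = F(0, j - 1) + gap; ptr(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) + gap, left = F(i, j - 1) + gap;
      if (diag >= up && diag >= left) { F(i, j) = diag; ptr(i, j) = 1; }
      else if (up >= left) { F(i, j) = up; ptr(i, j) = 2; }
      else { F(i, j) = left; ptr(i, j) = 3; }
    }
  }
  ai.clear(); bi.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = ptr(i, j);
    if (p == 1) { ai.push_back(i); bi.push_back(j); --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
}

// Sequence-independent structural alignment (TM-align style): fragment /
// gapless-threading seeds, then iterative DP on TM-weighted distances.
// Score is normalised by the number of rows of B.
// [[Rcpp::export]]
List cpp_tmalign(const arma::mat& A, const arma::mat& B, double d0,
                 double gap = -0.6, int nouter = 8) {
  int nA = A.n_rows, nB = B.n_rows;
  double Lnorm = nB;
  double best_tm = -1.0;
  std::vector<int> best_ai, best_bi;

  // initial aligned index sets (0-based into A and B)
  std::vector<std::pair<std::vector<int>, std::vector<int>>> inits;
  // gapless threading over a strided set of offsets (DP repairs the rest)
  int ostride = std::max(1, std::min(nA, nB) / 10);
  for (int off = -(nA - 3); off <= nB - 3; off += ostride) {
    std::vector<int> ai, bi;
    for (int i = 0; i < nA; ++i) {
      int j = i + off;
      if (j >= 0 && j < nB) { ai.push_back(i); bi.push_back(j); }
    }
    if ((int)ai.size() >= 3) inits.push_back({ai, bi});
  }
  arma::mat Rrot; arma::vec tv;
  for (auto& init : inits) {
    arma::uvec ua = arma::conv_to<arma::uvec>::from(init.first);
    arma::uvec ub = arma::conv_to<arma::uvec>::from(init.second);
    // score the init alignment itself so that any legal gapless
    // correspondence is a lower bound on the final score
    {
      arma::uvec all = arma::regspace<arma::uvec>(0, ua.n_elem - 1);
      double tm0 = tm_refine(A.rows(ua), B.rows(ub), d0, Lnorm, all, 20);
      if (tm0 > best_tm) { best_tm = tm0; best_ai = init.first; best_bi = init.second; }
    }
    kabsch_core(A.rows(ua), B.rows(ub), Rrot, tv);
    std::vector<int> ai(init.first), bi(init.second);
    double prev_tm = -1.0;
    for (int outer = 0; outer < nouter; ++outer) {
      // superpose on current aligned pairs with TM-style reweighting:
      // iterate twice keeping pairs within 2*d0
      arma::uvec va = arma::conv_to<arma::uvec>::from(ai);
      arma::uvec vb = arma::conv_to<arma::uvec>::from(bi);
      kabsch_core(A.rows(va), B.rows(vb), Rrot, tv);
      for (int rep = 0; rep < 2; ++rep) {
        arma::vec d = row_dists(apply_rt(A.rows(va), Rrot, tv), B.rows(vb));
        arma::uvec keep = arma::find(d < std::max(2.0 * d0, 4.5));
        if (keep.n_elem >= 3) {
          kabsch_core(A.rows(va.elem(keep)), B.rows(vb.elem(keep)), Rrot, tv);
        }
      }
      arma::mat At = apply_rt(A, Rrot, tv);
      // similarity matrix
      arma::mat S(nA, nB);
      for (int i = 0; i < nA; ++i) {
        arma::rowvec a = At.row(i);
        for (int j = 0; j < nB; ++j) {
          double dx = a(0) - B(j, 0), dy = a(1) - B(j, 1), dz = a(2) - B(j, 2);
          double dd = dx * dx + dy * dy + dz * dz;
          S(i, j) = 1.0 / (1.0 + dd / (d0 * d0));
        }
      }
      std::vector<int> nai, nbi;
      nw_align(S, gap, nai, nbi);
      if ((int)nai.size() < 3) break;
      // TM of the new alignment (superpose on aligned pairs, refined)
      arma::uvec wa(nai.size()), wb(nbi.size());
      for (size_t k = 0; k < nai.size(); ++k) { wa(k) = nai[k] - 1; wb(k) = nbi[k] - 1; }
      arma::uvec all = arma::regspace<arma::uvec>(0, wa.n_elem - 1);
      double tm = tm_refine(A.rows(wa), B.rows(wb), d0, Lnorm, all, 20);
      ai.assign(nai.begin(), nai.end());
      for (auto& v : ai) --v;
      bi.assign(nbi.begin(), nbi.end());
      for (auto& v : bi) --v;
      if (tm > best_tm) { best_tm = tm; best_ai = ai; best_bi = bi; }
      if (std::abs(tm - prev_tm) < 1e-7) break;
      prev_tm = tm;
    }
  }
  // final polish: full multi-seed superposition search on the best
  // alignment (matches the fixed-correspondence score machinery)
  if (best_ai.size() >= 3) {
    arma::uvec wa(best_ai.size()), wb(best_bi.size());
    for (size_t k = 0; k < best_ai.size(); ++k) { wa(k) = best_ai[k]; wb(k) = best_bi[k]; }
    double tm = cpp_tm_search(A.rows(wa), B.rows(wb), d0, Lnorm, 20);
    if (tm > best_tm) best_tm = tm;
  }
  IntegerVector out_a(best_ai.size()), out_b(best_bi.size());
  for (size_t k = 0; k < best_ai.size(); ++k) {
    out_a[k] = best_ai[k] + 1; out_b[k] = best_bi[k] + 1;
  }
  return List::create(_["score"] = best_tm, _["a"] = out_a, _["b"] = out_b);
}
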