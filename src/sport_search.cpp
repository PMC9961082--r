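// Cross-validated grid search for the sequential orthogonalized
// multi-block PLS model: enumerates every ordering of the candidate
// blocks and every latent-variable vector in {0..lvMax}^K, accumulating
// the prediction error sum of squares for held-out samples of one fold.
//
// The cached path walks the prefix tree of block sequences once per fold:
// a NIPALS fit at a tree node serves all 0..lvMax truncations and all
// downstream suffixes. The uncached path recomputes every configuration
// from scratch through the same arithmetic, so both paths agree
// bit-for-bit; it exists to validate the caching and is only practical on
// small grids.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// NIPALS PLS1 with X-deflation on (X, y), centered internally; test rows
// follow the same projection-deflation chain. Extraction stops early when
// the residual predictor rank is exhausted; returns the number of
// components actually extracted.
int nipals(const mat& X, const vec& y, const mat& Xtest, int lvMax,
           mat& T, mat& Ttest, vec& q, double& ySub) {
  const uword n = X.n_rows;
  rowvec xm = mean(X, 0);
  mat Xc = X.each_row() - xm;
  ySub = mean(y);
  vec yc = y - ySub;
  mat Xtc = Xtest.each_row() - xm;
  const double tol = 1e-12 * std::max(abs(Xc).max(), 1.0);
  T.set_size(n, lvMax);
  Ttest.set_size(Xtest.n_rows, lvMax);
  q.set_size(lvMax);
  int a = 0;
  for (; a < lvMax; ++a) {
    vec w = Xc.t() * yc;
    double nw = norm(w);
    if (nw < tol) break;
    w /= nw;
    if (w(index_max(abs(w))) < 0) w = -w;
    vec t = Xc * w;
    double t2 = dot(t, t);
    if (t2 < tol * tol) break;
    vec p = Xc.t() * t / t2;
    q(a) = dot(yc, t) / t2;
    Xc -= t * p.t();
    vec tt = Xtc * w;
    Xtc -= tt * p.t();
    T.col(a) = t;
    Ttest.col(a) = tt;
  }
  return a;
}

// Lexicographic rank of a permutation of 0..k-1.
int permRank(const std::vector<int>& p) {
  int k = (int)p.size(), rank = 0;
  int fact = 1;
  for (int i = 2; i < k; ++i) fact *= i; // (k-1)!
  std::vector<bool> used(k, false);
  for (int i = 0; i < k; ++i) {
    int smaller = 0;
    for (int v = 0; v < p[i]; ++v) if (!used[v]) ++smaller;
    rank += smaller * fact;
    used[p[i]] = true;
    if (k - 1 - i > 0) fact /= (k - 1 - i);
  }
  return rank;
}

struct SearchCtx {
  std::vector<mat> Xtr, Xte;
  vec y, yTest;
  int K, lvMax, S;
  vec* press;
};

// One step of the chain: orthogonalize block b against the accumulated
// (normalized) scores, fit NIPALS on the current residuals, and hand the
// truncated states to a consumer.
void extend(const SearchCtx& c, int b, const mat& Qacc, const mat& QaccTest,
            const vec& resid, const vec& predTest,
            mat& T, mat& Ttest, vec& q, double& ySub, int& aEff) {
  mat Xo = c.Xtr[b], XoTest = c.Xte[b];
  if (Qacc.n_cols > 0) {
    mat proj = Qacc.t() * c.Xtr[b];
    Xo -= Qacc * proj;
    XoTest -= QaccTest * proj;
  }
  aEff = nipals(Xo, resid, XoTest, c.lvMax, T, Ttest, q, ySub);
  (void)predTest;
}

void dfs(const SearchCtx& c, std::vector<int>& path, std::vector<int>& lvs,
         std::vector<bool>& used, const mat& Qacc, const mat& QaccTest,
         const vec& resid, const vec& predTest) {
  int depth = (int)path.size();
  if (depth == c.K) {
    int id = permRank(path);
    for (int j = 0; j < c.K; ++j) id = id * c.S + lvs[j];
    (*c.press)(id) += accu(square(c.yTest - predTest));
    return;
  }
  for (int b = 0; b < c.K; ++b) {
    if (used[b]) continue;
    mat T, Ttest;
    vec q;
    double ySub;
    int aEff;
    extend(c, b, Qacc, QaccTest, resid, predTest, T, Ttest, q, ySub, aEff);
    used[b] = true;
    path.push_back(b);
    for (int l = 0; l <= c.lvMax; ++l) {
      lvs.push_back(l);
      if (l == 0) {
        dfs(c, path, lvs, used, Qacc, QaccTest, resid, predTest);
      } else {
        int le = std::min(l, aEff);
        vec fit(resid.n_rows, fill::value(ySub));
        vec fitTest(predTest.n_rows, fill::value(ySub));
        mat Qn = Qacc, QnTest = QaccTest;
        if (le > 0) {
          fit += T.cols(0, le - 1) * q.subvec(0, le - 1);
          fitTest += Ttest.cols(0, le - 1) * q.subvec(0, le - 1);
          Qn.resize(Qacc.n_rows, Qacc.n_cols + le);
          QnTest.resize(QaccTest.n_rows, QaccTest.n_cols + le);
          for (int a = 0; a < le; ++a) {
            double nt = norm(T.col(a));
            Qn.col(Qacc.n_cols + a) = T.col(a) / nt;
            QnTest.col(QaccTest.n_cols + a) = Ttest.col(a) / nt;
          }
        }
        dfs(c, path, lvs, used, Qn, QnTest, resid - fit, predTest + fitTest);
      }
      lvs.pop_back();
    }
    path.pop_back();
    used[b] = false;
  }
}

// Uncached reference: every configuration recomputed from scratch.
void naive(const SearchCtx& c) {
  std::vector<int> perm(c.K);
  for (int i = 0; i < c.K; ++i) perm[i] = i;
  std::vector<int> lvs(c.K, 0);
  do {
    long nCfg = 1;
    for (int j = 0; j < c.K; ++j) nCfg *= c.S;
    for (long cfg = 0; cfg < nCfg; ++cfg) {
      long rest = cfg;
      for (int j = c.K - 1; j >= 0; --j) { lvs[j] = rest % c.S; rest /= c.S; }
      mat Qacc(c.y.n_rows, 0), QaccTest(c.yTest.n_rows, 0);
      vec resid = c.y;
      vec predTest(c.yTest.n_rows, fill::zeros);
      for (int j = 0; j < c.K; ++j) {
        if (lvs[j] == 0) continue;
        mat T, Ttest;
        vec q;
        double ySub;
        int aEff;
        extend(c, perm[j], Qacc, QaccTest, resid, predTest,
               T, Ttest, q, ySub, aEff);
        int le = std::min(lvs[j], aEff);
        vec fit(resid.n_rows, fill::value(ySub));
        vec fitTest(predTest.n_rows, fill::value(ySub));
        mat Qn = Qacc, QnTest = QaccTest;
        if (le > 0) {
          fit += T.cols(0, le - 1) * q.subvec(0, le - 1);
          fitTest += Ttest.cols(0, le - 1) * q.subvec(0, le - 1);
          Qn.resize(Qacc.n_rows, Qacc.n_cols + le);
          QnTest.resize(QaccTest.n_rows, QaccTest.n_cols + le);
          for (int a = 0; a < le; ++a) {
            double nt = norm(T.col(a));
            Qn.col(Qacc.n_cols + a) = T.col(a) / nt;
            QnTest.col(QaccTest.n_cols + a) = Ttest.col(a) / nt;
          }
        }
        Qacc = Qn;
        QaccTest = QnTest;
        resid -= fit;
        predTest += fitTest;
      }
      int id = permRank(perm);
      for (int j = 0; j < c.K; ++j) id = id * c.S + lvs[j];
      (*c.press)(id) += accu(square(c.yTest - predTest));
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
}

} // namespace

// [[Rcpp::export(name = ".sportCvPress")]]
arma::vec sportCvPress(Rcpp::List trainBlocks, Rcpp::List testBlocks,
                       arma::vec yTrain, arma::vec yTest, int lvMax,
                       bool cached = true) {
  SearchCtx c;
  c.K = trainBlocks.size();
  c.lvMax = lvMax;
  c.S = lvMax + 1;
  for (int b = 0; b < c.K; ++b) {
    c.Xtr.push_back(Rcpp::as<mat>(trainBlocks[b]));
    c.Xte.push_back(Rcpp::as<mat>(testBlocks[b]));
  }
  c.y = yTrain;
  c.yTest = yTest;
  long nPerm = 1;
  for (int i = 2; i <= c.K; ++i) nPerm *= i;
  long nCfg = nPerm;
  for (int j = 0; j < c.K; ++j) nCfg *= c.S;
  vec press(nCfg, fill::zeros);
  c.press = &press;
  if (cached) {
    std::vector<int> path, lvs;
    std::vector<bool> used(c.K, false);
    mat Qacc(c.y.n_rows, 0), QaccTest(c.yTest.n_rows, 0);
    vec resid = c.y;
    vec predTest(c.yTest.n_rows, fill::zeros);
    dfs(c, path, lvs, used, Qacc, QaccTest, resid, predTest);
  } else {
    naive(c);
  }
  return press;
}
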