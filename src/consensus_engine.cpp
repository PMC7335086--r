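#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Partial Fisher-Yates draw of m indices from pool (without replacement),
// driven by R's RNG so that set.seed() upstream controls everything.
static void draw_without_replacement(arma::uvec &pool, int m, arma::uvec &out) {
  int n = pool.n_elem;
  for (int i = 0; i < m; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1; // guard against unif_rand() == 1.0 edge
    unsigned int tmp = pool[i]; pool[i] = pool[j]; pool[j] = tmp;
    out[i] = pool[i];
  }
}

// Number of distinct rows of X (exact; only called for small m).
static int n_distinct_rows(const arma::mat &X) {
  int m = X.n_rows;
  arma::vec proj = arma::sum(X, 1);
  arma::uvec ord = arma::sort_index(proj);
  int distinct = 1;
  for (int i = 1; i < m; ++i) {
    bool same = (proj[ord[i]] == proj[ord[i - 1]]);
    if (same) same = arma::approx_equal(X.row(ord[i]), X.row(ord[i - 1]), "absdiff", 0.0);
    if (!same) ++distinct;
  }
  return distinct;
}

// Lloyd k-means with k-means++ initialization, squared-Euclidean distances
// computed through BLAS. Rows of X are the clustered objects.
static arma::uvec kmeanspp_lloyd(const arma::mat &X, int k, int iter_max,
                                 int restarts) {
  int m = X.n_rows;
  arma::vec xsq = arma::sum(arma::square(X), 1);
  arma::uvec best_lab(m, arma::fill::zeros);
  double best_wss = arma::datum::inf;
  for (int r = 0; r < restarts; ++r) {
    arma::mat C(k, X.n_cols);
    arma::vec d2(m);
    d2.fill(arma::datum::inf);
    int first = (int)std::floor(unif_rand() * m);
    if (first >= m) first = m - 1;
    C.row(0) = X.row(first);
    for (int c = 1; c < k; ++c) {
      arma::vec dc = xsq + arma::dot(C.row(c - 1), C.row(c - 1)) -
                     2.0 * (X * C.row(c - 1).t());
      dc.clamp(0.0, arma::datum::inf);
      d2 = arma::min(d2, dc);
      double tot = arma::accu(d2);
      int pick;
      if (tot <= 0.0) {
        pick = (int)std::floor(unif_rand() * m);
        if (pick >= m) pick = m - 1;
      } else {
        double u = unif_rand() * tot, acc = 0.0;
        pick = m - 1;
        for (int i = 0; i < m; ++i) {
          acc += d2[i];
          if (acc >= u) { pick = i; break; }
        }
      }
      C.row(c) = X.row(pick);
    }
    arma::uvec lab(m, arma::fill::zeros);
    arma::uvec prev(m);
    prev.fill(m + 1); // never equal to a label on the first pass
    for (int it = 0; it < iter_max; ++it) {
      arma::mat D = -2.0 * (X * C.t());
      D.each_col() += xsq;
      D.each_row() += arma::sum(arma::square(C), 1).t();
      lab = arma::index_min(D, 1);
      if (arma::all(lab == prev)) break;
      prev = lab;
      for (int c = 0; c < k; ++c) {
        arma::uvec mem = arma::find(lab == (unsigned)c);
        if (mem.n_elem > 0) {
          C.row(c) = arma::mean(X.rows(mem), 0);
        } else { // empty cluster: reseed at a random point
          int p = (int)std::floor(unif_rand() * m);
          if (p >= m) p = m - 1;
          C.row(c) = X.row(p);
        }
      }
    }
    arma::mat D = -2.0 * (X * C.t());
    D.each_col() += xsq;
    D.each_row() += arma::sum(arma::square(C), 1).t();
    double wss = arma::accu(arma::min(D, 1));
    if (wss < best_wss) { best_wss = wss; best_lab = lab; }
  }
  return best_lab;
}

//' @useDynLib rcclust, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export(name = ".consensus_engine")]]
List consensus_engine(const arma::mat &Z, IntegerVector ks, double p_item,
                      double p_feature, int repeats, int iter_max,
                      int restarts, bool return_draws) {
  RNGScope scope;
  const int N = Z.n_rows, G = Z.n_cols, nk = ks.size();
  const int m = (int)std::ceil(p_item * N);
  const int f = (int)std::ceil(p_feature * G);
  int kmax = 0;
  for (int i = 0; i < nk; ++i) kmax = std::max(kmax, (int)ks[i]);
  if (m < kmax) stop("subsample size (%d) smaller than largest k (%d)", m, kmax);
  if (f < 1) stop("feature subsample is empty");

  arma::imat co_sample(N, N, arma::fill::zeros);
  std::vector<arma::imat> co(nk, arma::imat(N, N, arma::fill::zeros));
  arma::uvec spool = arma::regspace<arma::uvec>(0, N - 1);
  arma::uvec fpool = arma::regspace<arma::uvec>(0, G - 1);
  arma::uvec items(m), feats(f);
  List draws(return_draws ? repeats : 0);

  for (int rep = 0; rep < repeats; ++rep) {
    arma::mat X;
    int tries = 0;
    for (;;) { // redraw degenerate subsamples (fewer distinct points than kmax)
      draw_without_replacement(spool, m, items);
      draw_without_replacement(fpool, f, feats);
      X = Z.submat(items, feats);
      if (m >= 3 * kmax || n_distinct_rows(X) >= kmax) break;
      if (++tries >= 10)
        stop("subsample has fewer than k distinct points after 10 redraws");
    }
    if (return_draws) {
      IntegerVector d(m);
      for (int a = 0; a < m; ++a) d[a] = items[a] + 1;
      draws[rep] = d;
    }
    arma::uvec sit = arma::sort(items);
    for (int a = 0; a < m; ++a) {
      co_sample(sit[a], sit[a])++;
      for (int b = a + 1; b < m; ++b) co_sample(sit[a], sit[b])++;
    }
    for (int kk = 0; kk < nk; ++kk) {
      arma::uvec lab = kmeanspp_lloyd(X, ks[kk], iter_max, restarts);
      arma::imat &cc = co[kk];
      for (int a = 0; a < m; ++a) {
        cc(items[a], items[a])++;
        for (int b = a + 1; b < m; ++b) {
          if (lab[a] == lab[b]) {
            int i = items[a], j = items[b];
            if (i < j) cc(i, j)++; else cc(j, i)++;
          }
        }
      }
    }
  }
  co_sample = arma::symmatu(co_sample);
  List out(nk);
  for (int kk = 0; kk < nk; ++kk) out[kk] = wrap(arma::symmatu(co[kk]));
  List res = List::create(_["co_sample"] = wrap(co_sample),
                          _["co_cluster"] = out);
  if (return_draws) res["draws"] = draws;
  return res;
}
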