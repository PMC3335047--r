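#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Draw an n x m genotype matrix under Hardy-Weinberg equilibrium.
// Entry = count of minor (B) alleles: P(2) = p^2, P(1) = 2p(1-p), P(0) = (1-p)^2,
// with p = maf[j] for column j. Uses R's RNG so set.seed() governs.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_genotypes(int n, NumericVector maf) {
  int m = maf.size();
  IntegerMatrix g(n, m);
  for (int j = 0; j < m; ++j) {
    double p = maf[j];
    double t2 = p * p;            // BB
    double t1 = t2 + 2.0 * p * (1.0 - p); // BB or AB
    int *col = &g(0, j);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      col[i] = (u < t2) ? 2 : ((u < t1) ? 1 : 0);
    }
  }
  return g;
}

// Column medians with NA removal.
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix x) {
  int n = x.nrow(), m = x.ncol();
  NumericVector out(m);
  std::vector<double> buf;
  buf.reserve(n);
  for (int j = 0; j < m; ++j) {
    buf.clear();
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      if (!ISNAN(v)) buf.push_back(v);
    }
    int k = buf.size();
    if (k == 0) { out[j] = NA_REAL; continue; }
    int h = k / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (k % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[j] = med;
  }
  return out;
}

// One-sided (cases stochastically larger) Wilcoxon rank-sum test per column,
// normal approximation with midranks, tie correction and optional continuity
// correction. Returns a 4-column matrix: log upper-tail p (natural log), z,
// n_cases used, n_controls used. NA cells are dropped per column. Columns where
// either group is empty get log_p = NA; a fully tied column gets p = 1.
// [[Rcpp::export]]
NumericMatrix cpp_ranksum_logp(NumericMatrix x, LogicalVector is_case,
                               bool continuity) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(m, 4);
  std::vector<int> idx;
  idx.reserve(n);
  for (int j = 0; j < m; ++j) {
    idx.clear();
    const double *col = &x(0, j);
    for (int i = 0; i < n; ++i)
      if (!ISNAN(col[i])) idx.push_back(i);
    int N = idx.size();
    int n1 = 0;
    for (int k = 0; k < N; ++k)
      if (is_case[idx[k]]) ++n1;
    int n2 = N - n1;
    out(j, 2) = n1;
    out(j, 3) = n2;
    if (n1 == 0 || n2 == 0) {
      out(j, 0) = NA_REAL;
      out(j, 1) = NA_REAL;
      continue;
    }
    std::sort(idx.begin(), idx.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    double w1 = 0.0, tie_sum = 0.0;
    int k = 0;
    while (k < N) {
      int k2 = k;
      while (k2 + 1 < N && col[idx[k2 + 1]] == col[idx[k]]) ++k2;
      double t = k2 - k + 1;
      double midrank = 0.5 * ((k + 1) + (k2 + 1));
      for (int q = k; q <= k2; ++q)
        if (is_case[idx[q]]) w1 += midrank;
      if (t > 1) tie_sum += t * t * t - t;
      k = k2 + 1;
    }
    double dn1 = n1, dn2 = n2, dN = N;
    double mu = dn1 * (dN + 1.0) / 2.0;
    double sigma2 = (dn1 * dn2 / 12.0) *
                    ((dN + 1.0) - tie_sum / (dN * (dN - 1.0)));
    if (sigma2 <= 0.0) {
      out(j, 0) = 0.0; // p = 1, all observations tied
      out(j, 1) = 0.0;
      continue;
    }
    double cc = continuity ? 0.5 : 0.0;
    double z = (w1 - mu - cc) / std::sqrt(sigma2);
    out(j, 0) = R::pnorm(z, 0.0, 1.0, /*lower*/ 0, /*log_p*/ 1);
    out(j, 1) = z;
  }
  return out;
}
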