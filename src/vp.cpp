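#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura edit distance between two sorted spike trains.
// D[i][j] = min(D[i-1][j]+1, D[i][j-1]+1, D[i-1][j-1]+q*|a_i-b_j|),
// D[i][0]=i, D[0][j]=j.  Rolling single-row implementation, O(min(n,m)) memory.
static double vp_dp(const double* a, int na, const double* b, int nb, double q) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<double> row(nb + 1);
  for (int j = 0; j <= nb; ++j) row[j] = j;
  for (int i = 1; i <= na; ++i) {
    double diag = row[0];      // D[i-1][0]
    row[0] = i;
    for (int j = 1; j <= nb; ++j) {
      double up = row[j];      // D[i-1][j]
      double shift = diag + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = up + 1.0;
      double ins = row[j - 1] + 1.0;
      double v = shift < del ? shift : del;
      if (ins < v) v = ins;
      diag = up;
      row[j] = v;
    }
  }
  return row[nb];
}

static void check_sorted(const NumericVector& x, const char* name) {
  for (R_xlen_t i = 1; i < x.size(); ++i)
    if (x[i] < x[i - 1]) stop("spike train '%s' is not sorted", name);
}

// [[Rcpp::export(name = ".vp_distance_cpp")]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  check_sorted(a, "a");
  check_sorted(b, "b");
  return vp_dp(REAL(a), a.size(), REAL(b), b.size(), q);
}

// Full symmetric pairwise distance matrix over a list of sorted trains.
// [[Rcpp::export(name = ".vp_pairwise_cpp")]]
NumericMatrix vp_pairwise_cpp(List trains, double q) {
  int n = trains.size();
  std::vector<NumericVector> tt(n);
  for (int i = 0; i < n; ++i) {
    tt[i] = as<NumericVector>(trains[i]);
    check_sorted(tt[i], "trains[[i]]");
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = vp_dp(REAL(tt[i]), tt[i].size(), REAL(tt[j]), tt[j].size(), q);
      out(i, j) = d;
      out(j, i) = d;
    }
  return out;
}
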