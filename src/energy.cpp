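#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double soft_rep(double d2, double c, double k_rep) {
  const double c2 = c * c;
  if (d2 >= c2) return 0.0;
  const double u = 1.0 - std::sqrt(d2) / c;  // quartic inside contact
  return k_rep * u * u * u * u;
}

// Stand-in conformational energy: soft-sphere repulsion over non-bonded
// pairs (pairs NOT in the elastic-network contact list) plus an
// elastic-network term k_el * (d - d_ref)^2 over reference contacts.
// Repulsion is computed over all pairs and the contact-pair contribution
// subtracted, which is algebraically identical to excluding contact pairs.
// [[Rcpp::export]]
double standin_energy_cpp(NumericMatrix X, NumericVector contact_radius,
                          IntegerVector ci, IntegerVector cj,
                          NumericVector dref, double k_el, double k_rep) {
  const int n = X.nrow();
  const double* x = &X(0, 0);
  const double* y = &X(0, 1);
  const double* z = &X(0, 2);
  const double* cr = contact_radius.begin();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i], ri = cr[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double c = ri + cr[j];
      if (d2 < c * c) e += soft_rep(d2, c, k_rep);
    }
  }
  const int m = ci.size();
  const int* ip = ci.begin();
  const int* jp = cj.begin();
  const double* dr = dref.begin();
  for (int q = 0; q < m; ++q) {
    const int i = ip[q], j = jp[q];
    const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    const double d2 = dx * dx + dy * dy + dz * dz;
    e -= soft_rep(d2, cr[i] + cr[j], k_rep);
    const double dd = std::sqrt(d2) - dr[q];
    e += k_el * dd * dd;
  }
  return e;
}

// CSR adjacency (both directions) of the elastic contact list, for fast
// delta-energy lookups during Monte Carlo moves.
// [[Rcpp::export]]
List contacts_csr_cpp(int n, IntegerVector ci, IntegerVector cj,
                      NumericVector dref) {
  const int m = ci.size();
  std::vector<int> cnt(n + 1, 0);
  for (int q = 0; q < m; ++q) { cnt[ci[q] + 1]++; cnt[cj[q] + 1]++; }
  for (int i = 0; i < n; ++i) cnt[i + 1] += cnt[i];
  IntegerVector ptr(n + 1), idx(2 * m);
  NumericVector dr2(2 * m);
  std::vector<int> fill(cnt.begin(), cnt.end() - 1);
  for (int q = 0; q < m; ++q) {
    idx[fill[ci[q]]] = cj[q]; dr2[fill[ci[q]]++] = dref[q];
    idx[fill[cj[q]]] = ci[q]; dr2[fill[cj[q]]++] = dref[q];
  }
  for (int i = 0; i <= n; ++i) ptr[i] = cnt[i];
  // sort each neighbour row for binary search
  for (int i = 0; i < n; ++i) {
    std::vector<std::pair<int, double> > row;
    for (int q = ptr[i]; q < ptr[i + 1]; ++q)
      row.push_back(std::make_pair((int)idx[q], (double)dr2[q]));
    std::sort(row.begin(), row.end());
    for (size_t q = 0; q < row.size(); ++q) {
      idx[ptr[i] + q] = row[q].first;
      dr2[ptr[i] + q] = row[q].second;
    }
  }
  return List::create(_["ptr"] = ptr, _["idx"] = idx, _["dref"] = dr2);
}

// pair energy under the stand-in model given (possibly absent) contact dref
static inline double pair_energy(double d2, double c, double dref,
                                 bool is_contact, double k_el, double k_rep) {
  if (is_contact) {
    const double dd = std::sqrt(d2) - dref;
    return k_el * dd * dd;
  }
  return soft_rep(d2, c, k_rep);
}

// Energy change when the atoms listed in `moved` (0-based) take the
// coordinates in Xnew (all other rows of Xnew equal Xold). Only pairs with
// at least one moved member can change.
// [[Rcpp::export]]
double standin_delta_cpp(NumericMatrix Xold, NumericMatrix Xnew,
                         IntegerVector moved, NumericVector contact_radius,
                         IntegerVector ptr, IntegerVector idx,
                         NumericVector dref, double k_el, double k_rep) {
  const int n = Xold.nrow();
  const double* xo = &Xold(0, 0);
  const double* yo = &Xold(0, 1);
  const double* zo = &Xold(0, 2);
  const double* xn = &Xnew(0, 0);
  const double* yn = &Xnew(0, 1);
  const double* zn = &Xnew(0, 2);
  const double* cr = contact_radius.begin();
  std::vector<char> is_moved(n, 0);
  for (int q = 0; q < moved.size(); ++q) is_moved[moved[q]] = 1;
  double de = 0.0;
  for (int q = 0; q < moved.size(); ++q) {
    const int i = moved[q];
    const int* nb0 = idx.begin() + ptr[i];
    const int* nb1 = idx.begin() + ptr[i + 1];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (is_moved[j] && j < i) continue;  // count moved-moved pairs once
      const double dxo = xo[i] - xo[j], dyo = yo[i] - yo[j], dzo = zo[i] - zo[j];
      const double dxn = xn[i] - xn[j], dyn = yn[i] - yn[j], dzn = zn[i] - zn[j];
      const double d2o = dxo * dxo + dyo * dyo + dzo * dzo;
      const double d2n = dxn * dxn + dyn * dyn + dzn * dzn;
      const double c = cr[i] + cr[j];
      const int* hit = std::lower_bound(nb0, nb1, j);
      const bool is_contact = (hit != nb1 && *hit == j);
      if (!is_contact && d2o >= c * c && d2n >= c * c) continue;
      const double dr = is_contact ? dref[ptr[i] + (hit - nb0)] : 0.0;
      de += pair_energy(d2n, c, dr, is_contact, k_el, k_rep) -
            pair_energy(d2o, c, dr, is_contact, k_el, k_rep);
    }
  }
  return de;
}
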