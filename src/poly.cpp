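// Multilinear pseudo-Boolean polynomial kernels.
//
// Monomials are sorted vectors of 1-based variable indices; the empty
// monomial is the constant term.  Multilinearity (b^2 = b) is applied on
// construction by sorting and deduplicating indices.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::map<std::vector<int>, double> TermMap;

static void add_term(TermMap &m, std::vector<int> key, double coef) {
  std::sort(key.begin(), key.end());
  key.erase(std::unique(key.begin(), key.end()), key.end());
  m[key] += coef;
}

static List map_to_list(const TermMap &m) {
  std::vector<const std::vector<int> *> keys;
  std::vector<double> coefs;
  for (TermMap::const_iterator it = m.begin(); it != m.end(); ++it) {
    if (std::fabs(it->second) < 1e-12) continue;
    keys.push_back(&it->first);
    coefs.push_back(it->second);
  }
  List vars(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) vars[i] = wrap(*keys[i]);
  return List::create(_["vars"] = vars, _["coeffs"] = wrap(coefs));
}

// Collapse a term list: sort/uniquify each monomial, merge duplicates.
// [[Rcpp::export]]
List cpp_poly_collapse(List vars, NumericVector coefs) {
  TermMap m;
  for (int i = 0; i < vars.size(); ++i) {
    IntegerVector v = vars[i];
    add_term(m, std::vector<int>(v.begin(), v.end()), coefs[i]);
  }
  return map_to_list(m);
}

// Product of two multilinear polynomials.
// [[Rcpp::export]]
List cpp_poly_mul(List varsA, NumericVector coefA, List varsB, NumericVector coefB) {
  TermMap m;
  int na = varsA.size(), nb = varsB.size();
  std::vector<std::vector<int> > a(na), b(nb);
  for (int i = 0; i < na; ++i) {
    IntegerVector v = varsA[i];
    a[i] = std::vector<int>(v.begin(), v.end());
  }
  for (int j = 0; j < nb; ++j) {
    IntegerVector v = varsB[j];
    b[j] = std::vector<int>(v.begin(), v.end());
  }
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      std::vector<int> key(a[i]);
      key.insert(key.end(), b[j].begin(), b[j].end());
      add_term(m, key, coefA[i] * coefB[j]);
    }
  }
  return map_to_list(m);
}
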