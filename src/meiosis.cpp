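#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// A gamete on one chromosome is a founder-origin mosaic over [0, GL] in cM,
// stored as its origin at position 0 (0 = P1, 1 = P2) plus the sorted vector
// of breakpoints where the origin flips. Segments are half-open [b, b'): a
// breakpoint at b means positions >= b carry the flipped origin.

static inline int origin_at(const double* br, int nbr, int start, double x) {
  // count of breakpoints <= x
  int k = static_cast<int>(std::upper_bound(br, br + nbr, x) - br);
  return start ^ (k & 1);
}

//' @name cpp_meiose_pop
//' @title Batched meioses on one chromosome (internal)
//' @noRd
// [[Rcpp::export]]
List cpp_meiose_pop(List br_list, IntegerVector start_vec,
                    IntegerVector gidx1, IntegerVector gidx2,
                    NumericVector xo_all, IntegerVector xo_counts,
                    IntegerVector start_choice) {
  const int nm = gidx1.size();
  List out_br(nm);
  IntegerVector out_start(nm);
  int xo_off = 0;
  std::vector<double> xo, cand, child;
  for (int j = 0; j < nm; ++j) {
    NumericVector brA = br_list[gidx1[j] - 1];
    NumericVector brB = br_list[gidx2[j] - 1];
    const int sA = start_vec[gidx1[j] - 1];
    const int sB = start_vec[gidx2[j] - 1];
    const int nxo = xo_counts[j];
    xo.assign(xo_all.begin() + xo_off, xo_all.begin() + xo_off + nxo);
    xo_off += nxo;
    std::sort(xo.begin(), xo.end());

    cand.clear();
    cand.insert(cand.end(), brA.begin(), brA.end());
    cand.insert(cand.end(), brB.begin(), brB.end());
    cand.insert(cand.end(), xo.begin(), xo.end());
    std::sort(cand.begin(), cand.end());

    const int choice = start_choice[j];  // 0: begin on gamete A, 1: on B
    int cur = (choice == 0) ? sA : sB;
    out_start[j] = cur;
    child.clear();
    for (size_t t = 0; t < cand.size(); ++t) {
      const double p = cand[t];
      if (t > 0 && p == cand[t - 1]) continue;
      const int cxo = static_cast<int>(
          std::upper_bound(xo.begin(), xo.end(), p) - xo.begin());
      const int g = choice ^ (cxo & 1);
      const int o = (g == 0)
                        ? origin_at(REAL(brA), brA.size(), sA, p)
                        : origin_at(REAL(brB), brB.size(), sB, p);
      if (o != cur) {
        child.push_back(p);
        cur = o;
      }
    }
    out_br[j] = NumericVector(child.begin(), child.end());
  }
  return List::create(_["br"] = out_br, _["start"] = out_start);
}

//' @name cpp_dosage_pop
//' @title Founder-P2 allele dosage per individual at sorted positions (internal)
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_dosage_pop(List br_list, IntegerVector start_vec,
                             NumericVector pos) {
  const int ng = br_list.size();
  const int nind = ng / 2;
  const int np = pos.size();
  IntegerMatrix out(np, nind);  // positions x individuals
  int* o = INTEGER(out);
  for (int g = 0; g < ng; ++g) {
    NumericVector br = br_list[g];
    const int s = start_vec[g];
    const double* b = REAL(br);
    const int nb = br.size();
    int* col = o + static_cast<R_xlen_t>(g / 2) * np;
    int k = 0;
    for (int i = 0; i < np; ++i) {
      while (k < nb && b[k] <= pos[i]) ++k;
      col[i] += s ^ (k & 1);
    }
  }
  return out;
}

//' @name cpp_query_pop
//' @title Founder origin of each gamete at each queried cM position (internal)
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_query_pop(List br_list, IntegerVector start_vec,
                            NumericVector pos) {
  const int ng = br_list.size();
  const int np = pos.size();
  IntegerMatrix out(np, ng);
  bool sorted = true;
  for (int i = 1; i < np; ++i) {
    if (pos[i] < pos[i - 1]) { sorted = false; break; }
  }
  int* o = INTEGER(out);
  for (int g = 0; g < ng; ++g) {
    NumericVector br = br_list[g];
    const int s = start_vec[g];
    const double* b = REAL(br);
    const int nb = br.size();
    int* col = o + static_cast<R_xlen_t>(g) * np;
    if (sorted) {
      // single merge walk over breakpoints for sorted query positions
      int k = 0;
      for (int i = 0; i < np; ++i) {
        while (k < nb && b[k] <= pos[i]) ++k;
        col[i] = s ^ (k & 1);
      }
    } else {
      for (int i = 0; i < np; ++i) {
        col[i] = origin_at(b, nb, s, pos[i]);
      }
    }
  }
  return out;
}
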