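#include <Rcpp.h>
using namespace Rcpp;

// Connected components (4-connectivity) of a logical grid. Labels are
// assigned in column-major first-encounter order, background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        const int nb[4][2] = {{cr - 1, cc}, {cr + 1, cc}, {cr, cc - 1}, {cr, cc + 1}};
        for (int q = 0; q < 4; ++q) {
          const int rr = nb[q][0], c2 = nb[q][1];
          if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(rr, c2) && lab(rr, c2) == 0) {
            lab(rr, c2) = next;
            stack.push_back(c2 * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

// For each row of a (n_perm x n_bins) t-value matrix, find the largest
// positive and largest-magnitude negative cluster mass under 4-connectivity
// on a nf x nt grid. bin_row/bin_col give the (0-based) grid position of
// every column of tmat; grid cells not covered by any bin are treated as
// missing and break adjacency. NA t-values never enter a cluster.
// Returns an n_perm x 2 matrix: [max positive mass, max |negative mass|].
// [[Rcpp::export]]
NumericMatrix cpp_max_cluster_masses(NumericMatrix tmat, IntegerVector bin_row,
                                     IntegerVector bin_col, int nf, int nt,
                                     double thr) {
  const int np = tmat.nrow(), m = tmat.ncol();
  if (bin_row.size() != m || bin_col.size() != m)
    stop("bin coordinates must match ncol(tmat)");
  // grid -> bin index lookup (-1 where no bin)
  std::vector<int> grid((size_t)nf * nt, -1);
  for (int j = 0; j < m; ++j) {
    const int r = bin_row[j], c = bin_col[j];
    if (r < 0 || r >= nf || c < 0 || c >= nt) stop("bin coordinate out of range");
    grid[(size_t)c * nf + r] = j;
  }
  NumericMatrix out(np, 2);
  std::vector<int> visited(m, -1);
  std::vector<int> stack;
  for (int p = 0; p < np; ++p) {
    double maxpos = 0.0, maxneg = 0.0;
    for (int j = 0; j < m; ++j) {
      if (visited[j] == p) continue;
      const double tj = tmat(p, j);
      if (!R_finite(tj) || std::abs(tj) <= thr) continue;
      const int sign = tj > 0 ? 1 : -1;
      double mass = 0.0;
      visited[j] = p;
      stack.clear();
      stack.push_back(j);
      while (!stack.empty()) {
        const int b = stack.back();
        stack.pop_back();
        mass += tmat(p, b);
        const int cr = bin_row[b], cc = bin_col[b];
        const int nb[4][2] = {{cr - 1, cc}, {cr + 1, cc}, {cr, cc - 1}, {cr, cc + 1}};
        for (int q = 0; q < 4; ++q) {
          const int rr = nb[q][0], c2 = nb[q][1];
          if (rr < 0 || rr >= nf || c2 < 0 || c2 >= nt) continue;
          const int b2 = grid[(size_t)c2 * nf + rr];
          if (b2 < 0 || visited[b2] == p) continue;
          const double t2 = tmat(p, b2);
          if (!R_finite(t2) || std::abs(t2) <= thr) continue;
          if ((t2 > 0 ? 1 : -1) != sign) continue;
          visited[b2] = p;
          stack.push_back(b2);
        }
      }
      if (sign > 0 && mass > maxpos) maxpos = mass;
      if (sign < 0 && -mass > maxneg) maxneg = -mass;
    }
    out(p, 0) = maxpos;
    out(p, 1) = maxneg;
  }
  return out;
}
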