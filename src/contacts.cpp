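#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-list residue contact kernel. Atoms are binned into cubic cells of
// edge = cutoff; only the 27 neighbouring cells of each atom are scanned,
// so the per-frame cost is linear in atom count at fixed density.
//
// coords:   heavy-atom coordinates (n x 3, Angstrom)
// resindex: 1-based residue index per atom (residue universe order)
// resseq:   per-residue sequence position (residue numbering within chain)
// reschain: per-residue integer chain id
// Returns an IntegerMatrix of contacting residue pairs (i < j, 1-based):
// minimum heavy-atom distance <= cutoff (inclusive) and sequence separation
// |seq_i - seq_j| >= min_sep (pairs on different chains always pass the
// separation filter).
// [[Rcpp::export]]
IntegerMatrix residue_contacts_cell(NumericMatrix coords,
                                    IntegerVector resindex,
                                    IntegerVector resseq,
                                    IntegerVector reschain,
                                    double cutoff, int min_sep) {
  const int n = coords.nrow();
  const int nres = resseq.size();
  if (n == 0) stop("empty heavy-atom set");
  const double c2 = cutoff * cutoff;

  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = coords(0, d); mx[d] = coords(0, d); }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (coords(i, d) < mn[d]) mn[d] = coords(i, d);
      if (coords(i, d) > mx[d]) mx[d] = coords(i, d);
    }
  int ncell[3];
  for (int d = 0; d < 3; ++d) {
    ncell[d] = (int)std::floor((mx[d] - mn[d]) / cutoff) + 1;
    if (ncell[d] < 1) ncell[d] = 1;
  }
  auto cell_of = [&](int i, int d) {
    int c = (int)std::floor((coords(i, d) - mn[d]) / cutoff);
    if (c < 0) c = 0;
    if (c >= ncell[d]) c = ncell[d] - 1;
    return c;
  };
  std::unordered_map<long long, std::vector<int> > cells;
  auto key = [&](int cx, int cy, int cz) {
    return ((long long)cx * ncell[1] + cy) * ncell[2] + cz;
  };
  for (int i = 0; i < n; ++i)
    cells[key(cell_of(i, 0), cell_of(i, 1), cell_of(i, 2))].push_back(i);

  std::vector<char> hit((size_t)nres * nres, 0);
  for (int i = 0; i < n; ++i) {
    const int ri = resindex[i] - 1;
    const int cx = cell_of(i, 0), cy = cell_of(i, 1), cz = cell_of(i, 2);
    for (int dx = -1; dx <= 1; ++dx) {
      if (cx + dx < 0 || cx + dx >= ncell[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        if (cy + dy < 0 || cy + dy >= ncell[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          if (cz + dz < 0 || cz + dz >= ncell[2]) continue;
          auto it = cells.find(key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            const int rj = resindex[j] - 1;
            if (ri == rj) continue;
            if (reschain[ri] == reschain[rj] &&
                std::abs(resseq[ri] - resseq[rj]) < min_sep) continue;
            const int a = ri < rj ? ri : rj, b = ri < rj ? rj : ri;
            if (hit[(size_t)a * nres + b]) continue;
            double d2 = 0;
            for (int d = 0; d < 3; ++d) {
              const double t = coords(i, d) - coords(j, d);
              d2 += t * t;
            }
            if (d2 <= c2) hit[(size_t)a * nres + b] = 1;
          }
        }
      }
    }
  }
  int npair = 0;
  for (size_t k = 0; k < hit.size(); ++k) npair += hit[k];
  IntegerMatrix out(npair, 2);
  int r = 0;
  for (int a = 0; a < nres; ++a)
    for (int b = a + 1; b < nres; ++b)
      if (hit[(size_t)a * nres + b]) {
        out(r, 0) = a + 1;
        out(r, 1) = b + 1;
        ++r;
      }
  return out;
}
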