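// Affine-gap pairwise alignment with explicit traceback.
//
// Two modes:
//   "glocal": the whole pattern aligns to an internal window of the subject
//             (no end penalties on the subject side) — used to map fragments
//             and reads onto a reference CDS / consensus;
//   "local":  Smith-Waterman — used to extend seeded ortholog-search hits.
//
// Gap of length L costs gap_open + gap_extend * (L - 1).  At equal score the
// traceback prefers a diagonal step (match/mismatch), then a gap in the
// pattern (subject base unmatched), then a gap in the subject, giving a
// deterministic, reproducible alignment.

#include <Rcpp.h>
#include <cstring>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

const double NEG = -1e30;

inline double subst(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;  // N never rewards
  return (a == b) ? match : mismatch;
}

}  // namespace

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(std::string pattern, std::string subject,
                      double match, double mismatch, double gap_open,
                      double gap_extend, std::string mode) {
  const int m = pattern.size(), n = subject.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const bool local = (mode == "local");
  const double go = gap_open;  // cost of the first gap position

  const size_t W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG),
      Y((m + 1) * W, NEG);
  // traceback codes: which matrix each cell's best predecessor lives in
  // (0 = M, 1 = X (gap in subject), 2 = Y (gap in pattern), 3 = start)
  std::vector<unsigned char> tbM((m + 1) * W), tbX((m + 1) * W),
      tbY((m + 1) * W);
  auto at = [W](int i, int j) { return i * W + j; };

  for (int j = 0; j <= n; ++j) {
    M[at(0, j)] = 0.0;  // free subject prefix (and zero-start for local)
    tbM[at(0, j)] = 3;
  }
  for (int i = 1; i <= m; ++i) {
    X[at(i, 0)] = -(gap_open + gap_extend * (i - 1));
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
    if (local) { M[at(i, 0)] = 0.0; tbM[at(i, 0)] = 3; }
  }

  double best = NEG;
  int bi = m, bj = 0, bmat = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: diagonal; prefer M > Y > X among equal predecessors
      double pm = M[at(i - 1, j - 1)], py = Y[at(i - 1, j - 1)],
             px = X[at(i - 1, j - 1)];
      double pb = pm; unsigned char pc = 0;
      if (py > pb) { pb = py; pc = 2; }
      if (px > pb) { pb = px; pc = 1; }
      double sc = pb + subst(pattern[i - 1], subject[j - 1], match, mismatch);
      if (local && sc < 0) { sc = 0; pc = 3; }
      M[at(i, j)] = sc; tbM[at(i, j)] = pc;

      // X: pattern char against subject gap
      double xm = M[at(i - 1, j)] - go, xx = X[at(i - 1, j)] - gap_extend,
             xy = Y[at(i - 1, j)] - go;
      double xb = xm; unsigned char xc = 0;
      if (xy > xb) { xb = xy; xc = 2; }
      if (xx > xb) { xb = xx; xc = 1; }
      X[at(i, j)] = xb; tbX[at(i, j)] = xc;

      // Y: subject char against pattern gap
      double ym = M[at(i, j - 1)] - go, yy = Y[at(i, j - 1)] - gap_extend,
             yx = X[at(i, j - 1)] - go;
      double yb = ym; unsigned char yc = 0;
      if (yy > yb) { yb = yy; yc = 2; }
      if (yx > yb) { yb = yx; yc = 1; }
      Y[at(i, j)] = yb; tbY[at(i, j)] = yc;

      if (local) {
        if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; bmat = 0; }
      }
    }
  }
  if (!local) {
    for (int j = 0; j <= n; ++j) {  // free subject suffix; prefer M, then X
      if (M[at(m, j)] > best) { best = M[at(m, j)]; bj = j; bmat = 0; }
      if (X[at(m, j)] > best) { best = X[at(m, j)]; bj = j; bmat = 1; }
    }
    bi = m;
  }

  // traceback
  std::vector<int> pcol, scol;
  int i = bi, j = bj, mat = bmat;
  while (i > 0 || (mat != 0 && mat != 3)) {
    if (mat == 0) {
      unsigned char pc = tbM[at(i, j)];
      if (pc == 3 && (local || i == 0)) break;  // start cell reached
      pcol.push_back(i - 1); scol.push_back(j - 1);
      --i; --j; mat = pc;
      if (local && mat == 3) break;
    } else if (mat == 1) {
      pcol.push_back(i - 1); scol.push_back(NA_INTEGER);
      unsigned char pc = tbX[at(i, j)];
      --i; mat = pc;
    } else if (mat == 2) {
      pcol.push_back(NA_INTEGER); scol.push_back(j - 1);
      unsigned char pc = tbY[at(i, j)];
      --j; mat = pc;
    } else break;
    if (i == 0 && mat == 0) break;  // M row 0 is a free start
  }
  std::reverse(pcol.begin(), pcol.end());
  std::reverse(scol.begin(), scol.end());

  int nmatch = 0, nmismatch = 0;
  int p1 = NA_INTEGER, p2 = NA_INTEGER, s1 = NA_INTEGER, s2 = NA_INTEGER;
  for (size_t k = 0; k < pcol.size(); ++k) {
    if (pcol[k] != NA_INTEGER) {
      if (p1 == NA_INTEGER) p1 = pcol[k];
      p2 = pcol[k];
    }
    if (scol[k] != NA_INTEGER) {
      if (s1 == NA_INTEGER) s1 = scol[k];
      s2 = scol[k];
    }
    if (pcol[k] != NA_INTEGER && scol[k] != NA_INTEGER) {
      char pa = pattern[pcol[k]], sb = subject[scol[k]];
      if (pa == sb && pa != 'N') ++nmatch; else ++nmismatch;
    }
  }
  return List::create(_["score"] = best, _["frag_pos"] = wrap(pcol),
                      _["cds_pos"] = wrap(scol), _["p_start"] = p1,
                      _["p_end"] = p2, _["s_start"] = s1, _["s_end"] = s2,
                      _["nmatch"] = nmatch, _["nmismatch"] = nmismatch);
}
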