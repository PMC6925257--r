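// Enumeration of near-perfect direct repeats (microhomologies) on a circular
// nucleotide sequence.
//
// A candidate alignment pairs two same-strand loci and is either ungapped or
// carries a single indel (band +/-1). Columns are alignment positions; an
// indel column counts as a mismatch; first and last columns must match; N
// never matches. A candidate is reported when it is valid (columns >=
// minLen, mismatches <= maxMM, indels <= maxIndel, matches/columns >=
// minIdent) and containment-maximal: no other valid candidate covers both of
// its loci.
//
// Enumeration walks every ordered diagonal d (locus offset) and start p with
// a matching first column, extending to the furthest valid end, with a
// one-time diagonal switch d -> d+1 at every feasible split to realize the
// single indel. Mirrored enumerations and double-counted diagonals are
// collapsed by canonicalization; containment is then filtered globally.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cand {
  int s1, l1, s2, l2;  // canonical loci (s1 < s2), 0-based starts, lengths
  int cols, mm, ind;   // alignment columns, mismatches (incl indel), indels
};

inline bool containedIn(const Cand &x, const Cand &y, int L) {
  // locus containment on the circle
  auto cont = [L](int bs, int bl, int as, int al) {
    int off = bs - as; if (off < 0) off += L;
    return off + bl <= al;
  };
  return (cont(x.s1, x.l1, y.s1, y.l1) && cont(x.s2, x.l2, y.s2, y.l2)) ||
         (cont(x.s1, x.l1, y.s2, y.l2) && cont(x.s2, x.l2, y.s1, y.l1));
}

}  // namespace

// [[Rcpp::export(name = ".scanRepeats")]]
DataFrame scanRepeats(IntegerVector seq, int minLen, int maxIndel, int maxMM,
                      double minIdent) {
  const int L = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<Cand> cands;
  if (L >= 2 && minLen <= L) {
    auto match = [&](int i, int j) {
      int a = s[i % L], b = s[j % L];
      return a < 4 && b < 4 && a == b;
    };
    auto valid = [&](int cols, int mm) {
      return cols >= minLen && mm <= maxMM &&
             (double)(cols - mm) + 1e-9 >= minIdent * cols;
    };
    auto push = [&](int p, int d, int la, int lb, int cols, int mm, int ind) {
      int s1 = p % L, s2 = (p + d) % L, l1 = la, l2 = lb;
      if (s2 < s1) { std::swap(s1, s2); std::swap(l1, l2); }
      cands.push_back({s1, l1, s2, l2, cols, mm, ind});
    };
    for (int d = 1; d < L; ++d) {
      const int cap = L - d;  // keep locus b from wrapping onto locus a
      for (int p = 0; p < L; ++p) {
        if (!match(p, p + d)) continue;
        // ungapped: extend along diagonal d
        {
          int mm = 0, best = -1, bestmm = 0;
          for (int t = 0; t < cap; ++t) {
            if (!match(p + t, p + d + t)) { if (++mm > maxMM) break; }
            else if (valid(t + 1, mm)) { best = t; bestmm = mm; }
          }
          if (best >= 0) push(p, d, best + 1, best + 1, best + 1, bestmm, 0);
        }
        // one indel: prefix on d (g columns), gap, suffix on d + 1
        if (maxIndel >= 1) {
          int pmm = 0;  // mismatches among prefix columns 0..g-1
          for (int g = 1; g < cap - 1; ++g) {
            if (g >= 2 && !match(p + g - 1, p + d + g - 1)) ++pmm;
            if (pmm + 1 > maxMM) break;
            // suffix along diagonal d + 1 from a-position p + g
            int mm = pmm + 1, best = -1, bestmm = 0;
            int scap = cap - 1 - g;  // b length g+1+su <= L-d
            for (int t = 0; t < scap; ++t) {
              if (!match(p + g + t, p + d + 1 + g + t)) {
                if (++mm > maxMM) break;
              } else {
                int colsHere = g + 1 + t + 1;
                if (valid(colsHere, mm)) { best = t; bestmm = mm; }
              }
            }
            if (best >= 0) {
              int cols = g + 1 + best + 1;
              push(p, d, g + best + 1, g + best + 2, cols, bestmm, 1);
            }
          }
        }
      }
    }
  }
  // sort: larger alignments first, then fewer mismatches / indels
  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.cols != b.cols) return a.cols > b.cols;
    if (a.mm != b.mm) return a.mm < b.mm;
    if (a.ind != b.ind) return a.ind < b.ind;
    if (a.s1 != b.s1) return a.s1 < b.s1;
    if (a.s2 != b.s2) return a.s2 < b.s2;
    if (a.l1 != b.l1) return a.l1 < b.l1;
    return a.l2 < b.l2;
  });
  std::vector<Cand> kept;
  for (const Cand &c : cands) {
    bool drop = false;
    for (const Cand &k : kept)
      if (containedIn(c, k, L)) { drop = true; break; }
    if (!drop) kept.push_back(c);
  }
  int n = kept.size();
  IntegerVector s1(n), l1(n), s2(n), l2(n), cols(n), mm(n), ind(n);
  for (int i = 0; i < n; ++i) {
    s1[i] = kept[i].s1; l1[i] = kept[i].l1;
    s2[i] = kept[i].s2; l2[i] = kept[i].l2;
    cols[i] = kept[i].cols; mm[i] = kept[i].mm; ind[i] = kept[i].ind;
  }
  return DataFrame::create(_["aStart"] = s1, _["aWidth"] = l1,
                           _["bStart"] = s2, _["bWidth"] = l2,
                           _["length"] = cols, _["mismatches"] = mm,
                           _["indels"] = ind);
}
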