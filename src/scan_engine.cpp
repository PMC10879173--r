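#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Nucleotides are IUPAC bitmasks: A=1, C=2, G=4, T=8. A subject position is
// "ambiguous" when more than one bit is set; ambiguous positions are
// compatible with any constraint and any pairing but count toward the
// per-match ambiguity budget (nratio).

static inline int popcount4(int m) {
  return (m & 1) + ((m >> 1) & 1) + ((m >> 2) & 1) + ((m >> 3) & 1);
}

namespace {

struct Engine {
  const uint8_t *seq;
  int L;
  int nE;
  const int *kind;     // 0 = single strand, 1 = helix 5' strand, 2 = helix 3' strand
  const int *minl;
  const int *maxl;
  const int *partner;  // index of the 5' strand for kind==2, else -1
  const int *wobble;   // per element (only read on the 3' strand)
  std::vector<const int *> cons;   // per-element constraint masks (maxl long) or NULL
  double nratio;
  std::vector<int> sufMin;         // suffix sums of min lengths
  int maxTotal;

  // DFS state
  int start0;
  std::vector<int> lens;
  std::vector<int> epos;           // start position of each matched element
  int ambig;
  std::vector<int> *out;           // rows of (start, len_1..len_nE)
  R_xlen_t maxHits;

  bool pairOK(int x, int y, bool wob) const {
    // both concrete (single bit)
    switch (x) {
    case 1: return y == 8;                       // A-T
    case 2: return y == 4;                       // C-G
    case 4: return y == 2 || (wob && y == 8);    // G-C (+ G.T)
    case 8: return y == 1 || (wob && y == 4);    // T-A (+ T.G)
    default: return false;
    }
  }

  void record() {
    if ((R_xlen_t)(out->size() / (nE + 1)) >= maxHits)
      stop("scan: match cap exceeded (more than %d placements); "
           "descriptor is likely unconstrained", (int)maxHits);
    out->push_back(start0);
    for (int e = 0; e < nE; ++e) out->push_back(lens[e]);
  }

  void dfs(int e, int pos, int amb) {
    if (e == nE) {
      int total = pos - start0;
      if (total > 0 && amb <= nratio * total) record();
      return;
    }
    int lo = minl[e], hi = maxl[e];
    for (int l = lo; l <= hi; ++l) {
      if (pos + l + sufMin[e + 1] > L) break;
      if (kind[e] == 2 && l != lens[partner[e]]) continue;  // helix strands equal length
      int a = 0;
      bool ok = true;
      const int *cm = cons[e];
      for (int i = 0; i < l && ok; ++i) {
        int m = seq[pos + i];
        bool isAmb = popcount4(m) > 1;
        if (isAmb) {
          ++a;
        } else {
          if (cm && !(m & cm[i])) ok = false;
          if (ok && kind[e] == 2) {
            // position i of the 3' strand pairs position (l-1-i) of the 5' strand
            int p5 = epos[partner[e]] + (l - 1 - i);
            int x = seq[p5];
            if (popcount4(x) == 1 && !pairOK(x, m, wobble[e] != 0)) ok = false;
          }
        }
      }
      if (!ok) continue;
      if (amb + a > nratio * maxTotal) continue;
      epos[e] = pos;
      lens[e] = l;
      dfs(e + 1, pos + l, amb + a);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".scan_engine")]]
IntegerMatrix scan_engine(IntegerVector seq_masks, IntegerVector kind,
                          IntegerVector min_len, IntegerVector max_len,
                          List constraints, IntegerVector partner,
                          IntegerVector wobble, double nratio,
                          int max_hits = 1000000) {
  int nE = kind.size();
  Engine en;
  std::vector<uint8_t> sv(seq_masks.size());
  for (R_xlen_t i = 0; i < seq_masks.size(); ++i) sv[i] = (uint8_t)seq_masks[i];
  en.seq = sv.data();
  en.L = (int)sv.size();
  en.nE = nE;
  en.kind = INTEGER(kind);
  en.minl = INTEGER(min_len);
  en.maxl = INTEGER(max_len);
  en.partner = INTEGER(partner);
  en.wobble = INTEGER(wobble);
  en.nratio = nratio;
  en.maxHits = max_hits;

  std::vector<IntegerVector> keep;  // protect constraint vectors
  en.cons.resize(nE, (const int *)nullptr);
  for (int e = 0; e < nE; ++e) {
    SEXP c = constraints[e];
    if (!Rf_isNull(c)) {
      IntegerVector cv(c);
      if (cv.size() < max_len[e]) stop("constraint shorter than max_len");
      keep.push_back(cv);
      en.cons[e] = INTEGER(keep.back());
    }
  }

  en.sufMin.assign(nE + 1, 0);
  for (int e = nE - 1; e >= 0; --e) en.sufMin[e] = en.sufMin[e + 1] + min_len[e];
  en.maxTotal = 0;
  for (int e = 0; e < nE; ++e) en.maxTotal += max_len[e];

  std::vector<int> rows;
  en.out = &rows;
  en.lens.assign(nE, 0);
  en.epos.assign(nE, 0);

  for (int s = 0; s + en.sufMin[0] <= en.L; ++s) {
    en.start0 = s;
    en.dfs(0, s, 0);
  }

  int nrow = (int)(rows.size() / (nE + 1));
  IntegerMatrix res(nrow, nE + 1);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c <= nE; ++c) res(r, c) = rows[(R_xlen_t)r * (nE + 1) + c];
  return res;
}
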