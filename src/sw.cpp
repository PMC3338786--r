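#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) with traceback. A gap of length k costs
// gap_open + k * gap_ext, matching the convention of
// Biostrings::pairwiseAlignment(gapOpening=, gapExtension=).
// Only A/C/G/T match themselves; any other symbol scores as a mismatch.
// Integer scoring; one packed traceback byte per cell:
//   bits 0-1: H source (0 stop, 1 diag, 2 E, 3 F)
//   bit 2:    E extended (vs opened)
//   bit 3:    F extended (vs opened)

namespace {

struct AlnResult {
  int score;
  int matches, align_length;
  int qstart, qend, sstart, send;
};

inline bool base_eq(char a, char b) {
  return a == b && (a == 'A' || a == 'C' || a == 'G' || a == 'T');
}

AlnResult sw_one(const std::string& q, const std::string& s,
                 int match, int mismatch, int gap_open, int gap_ext,
                 std::vector<unsigned char>& tb) {
  const int n = q.size(), m = s.size();
  const int NEG = INT_MIN / 4;
  const size_t W = (size_t)m + 1;
  std::vector<int> Hprev(W, 0), Hcur(W, 0), Fprev(W, NEG), Fcur(W, NEG);
  tb.assign((size_t)(n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  const int go = gap_open + gap_ext;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0;
    int E = NEG;
    const char qc = q[i - 1];
    unsigned char* tbrow = &tb[(size_t)i * W];
    const int* Hp = Hprev.data();
    const int* Fp = Fprev.data();
    int* Hc = Hcur.data();
    int* Fc = Fcur.data();
    int hdiag = Hp[0];
    for (int j = 1; j <= m; ++j) {
      const int e_open = Hc[j - 1] - go;
      const int e_ext = E - gap_ext;
      unsigned char code = (unsigned char)((e_ext > e_open) << 2);
      E = e_ext > e_open ? e_ext : e_open;
      const int f_open = Hp[j] - go;
      const int f_ext = Fp[j] - gap_ext;
      code |= (unsigned char)((f_ext > f_open) << 3);
      const int F = f_ext > f_open ? f_ext : f_open;
      Fc[j] = F;
      const int diag = hdiag + (base_eq(qc, s[j - 1]) ? match : mismatch);
      hdiag = Hp[j];
      const int ef = E > F ? E : F;
      const int dz = diag > 0 ? diag : 0;
      const int h = dz > ef ? dz : ef;
      const int src = (h == 0) ? 0 : (h == diag ? 1 : (h == E ? 2 : 3));
      Hc[j] = h;
      tbrow[j] = code | (unsigned char)src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  AlnResult r;
  r.score = best;
  r.matches = 0;
  r.align_length = 0;
  r.qend = bi; r.send = bj;
  r.qstart = bi; r.sstart = bj;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const unsigned char code = tb[(size_t)i * W + j];
    if (state == 0) {
      const int src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        if (base_eq(q[i - 1], s[j - 1])) ++r.matches;
        ++r.align_length;
        r.qstart = i; r.sstart = j;
        --i; --j;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++r.align_length;
      r.sstart = j;
      --j;
      if (!(code & 4)) state = 0;
    } else {
      ++r.align_length;
      r.qstart = i;
      --i;
      if (!(code & 8)) state = 0;
    }
  }
  return r;
}

}  // namespace

// [[Rcpp::export]]
DataFrame sw_align_cpp(std::string query, CharacterVector subjects,
                       int match, int mismatch, int gap_open, int gap_ext) {
  const int ns = subjects.size();
  NumericVector score(ns);
  IntegerVector matches(ns), align_length(ns);
  IntegerVector qstart(ns), qend(ns), sstart(ns), send(ns);
  std::vector<unsigned char> tb;
  for (int k = 0; k < ns; ++k) {
    std::string s = as<std::string>(subjects[k]);
    AlnResult r = sw_one(query, s, match, mismatch, gap_open, gap_ext, tb);
    score[k] = r.score;
    matches[k] = r.matches;
    align_length[k] = r.align_length;
    qstart[k] = r.qstart; qend[k] = r.qend;
    sstart[k] = r.sstart; send[k] = r.send;
  }
  return DataFrame::create(
      _["score"] = score, _["matches"] = matches,
      _["align_length"] = align_length,
      _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send);
}
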