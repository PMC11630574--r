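#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_ext (the convention of the
// Biostrings/BLAST family: opening already pays one extension).
// Traceback tie preference, fixed and documented: diagonal, then gap in
// query (template consumed), then gap in template; within a gap state,
// opening preferred over extending. The best cell is the first maximum
// in row-major scan order.

namespace {

struct AlnResult {
  double score;
  double identity;   // % identical columns over aligned columns (gaps count)
  double coverage;   // % of template inside the local alignment
};

const int NEG = -1000000000;

// Packed traceback byte per cell:
//   bits 0-1: H state (0 stop, 1 diag, 2 from E, 3 from F)
//   bit  2  : E opened here (vs extended)
//   bit  3  : F opened here (vs extended)
struct Workspace {
  std::vector<int> Hp, H, Fprev, Fcol;
  std::vector<unsigned char> TB;
  void prepare(int n, int m) {
    size_t cells = (size_t)(n + 1) * (m + 1);
    if (TB.size() < cells) TB.resize(cells);
    Hp.assign(m + 1, 0); H.assign(m + 1, 0);
    Fprev.assign(m + 1, NEG); Fcol.assign(m + 1, NEG);
  }
};

AlnResult sw_one(const std::vector<int> &qc, const std::string &q,
                 const std::vector<int> &tc, const std::string &t,
                 const int *S, int na, int go, int ge, Workspace &w) {
  int n = qc.size(), m = tc.size();
  w.prepare(n, m);
  int *Hp = w.Hp.data(), *H = w.H.data();
  int *Fprev = w.Fprev.data(), *Fcol = w.Fcol.data();

  int best = 0, bi = 0, bj = 0;
  const int goe = go + ge;
  for (int i = 1; i <= n; ++i) {
    unsigned char *TBr = w.TB.data() + (size_t)i * (m + 1);
    const int *Srow = S + (size_t)qc[i - 1] * na;
    H[0] = 0;
    int Eij = NEG;
    int Hleft = 0;  // H[i][j-1]
    int Hdiag;      // Hp[j-1]
    for (int j = 1; j <= m; ++j) {
      // E: gap in query ending at (i,j), from (i, j-1)
      int e_open = Hleft - goe;
      int e_ext = Eij - ge;
      unsigned char te = (e_open >= e_ext) ? 4 : 0;
      Eij = te ? e_open : e_ext;
      // F: gap in template ending at (i,j), from (i-1, j)
      int f_open = Hp[j] - goe;
      int f_ext = Fprev[j] - ge;
      unsigned char tf = (f_open >= f_ext) ? 8 : 0;
      int Fij = tf ? f_open : f_ext;
      Fcol[j] = Fij;
      Hdiag = Hp[j - 1];
      int diag = Hdiag + Srow[tc[j - 1]];
      int h = diag >= 0 ? diag : 0;
      unsigned char tb = diag >= 0 ? 1 : 0;
      if (Eij > h) { h = Eij; tb = 2; }
      if (Fij > h) { h = Fij; tb = 3; }
      if (h == 0) tb = 0;
      H[j] = h;
      Hleft = h;
      TBr[j] = tb | te | tf;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(w.Hp, w.H);
    std::swap(w.Fprev, w.Fcol);
    Hp = w.Hp.data(); H = w.H.data();
    Fprev = w.Fprev.data(); Fcol = w.Fcol.data();
  }

  AlnResult r;
  if (best <= 0) { r.score = 0; r.identity = 0; r.coverage = 0; return r; }
  int i = bi, j = bj, cols = 0, ident = 0, jmin = m + 1, jmax = 0;
  int state = 0;  // 0 = in H
  while (i > 0 && j > 0) {
    unsigned char cell = w.TB[(size_t)i * (m + 1) + j];
    if (state == 0) {
      unsigned char tb = cell & 3;
      if (tb == 0) break;
      if (tb == 1) {
        ++cols;
        if (q[i - 1] == t[j - 1]) ++ident;
        if (j < jmin) jmin = j;
        if (j > jmax) jmax = j;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {   // gap in query, consume template char
      ++cols;
      if (j < jmin) jmin = j;
      if (j > jmax) jmax = j;
      bool opened = (cell & 4) != 0;
      --j;
      if (opened) state = 0;
    } else {                   // gap in template, consume query char
      ++cols;
      bool opened = (cell & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }
  r.score = best;
  r.identity = cols > 0 ? 100.0 * ident / cols : 0.0;
  r.coverage = jmax >= jmin ? 100.0 * (jmax - jmin + 1) / m : 0.0;
  return r;
}

void encode(const std::string &s, const int *code, const char *what,
            std::vector<int> &out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code[(unsigned char)s[i]];
    if (c < 0)
      stop("illegal character in %s: %s", what, std::string(1, s[i]));
    out[i] = c;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sw_align_batch")]]
DataFrame sw_align_batch(CharacterVector queries, std::string templ,
                         IntegerMatrix submat, CharacterVector alphabet,
                         int gap_open, int gap_ext) {
  int na = alphabet.size();
  if (submat.nrow() != na || submat.ncol() != na)
    stop("substitution matrix does not match alphabet");
  std::vector<int> S((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b) S[(size_t)a * na + b] = submat(a, b);
  int code[256];
  for (int c = 0; c < 256; ++c) code[c] = -1;
  for (int a = 0; a < na; ++a) {
    std::string ch = as<std::string>(alphabet[a]);
    code[(unsigned char)ch[0]] = a;
  }
  std::vector<int> tc;
  encode(templ, code, "template", tc);

  int nq = queries.size();
  NumericVector identity(nq), coverage(nq), score(nq);
  Workspace w;
  std::vector<int> qc;
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(queries[k]);
    encode(q, code, "query", qc);
    AlnResult r = sw_one(qc, q, tc, templ, S.data(), na, gap_open, gap_ext, w);
    identity[k] = r.identity;
    coverage[k] = r.coverage;
    score[k] = r.score;
  }
  return DataFrame::create(_["identity"] = identity,
                           _["coverage"] = coverage,
                           _["score"] = score);
}
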