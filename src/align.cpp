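#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Standard genetic code, codon index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3.
static const char GENETIC_CODE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int baseIdx(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static inline char translateCodon(int b1, int b2, int b3) {
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X';   // ambiguous base
  return GENETIC_CODE[16 * b1 + 4 * b2 + b3];
}

// Substitution score lookup built from an R matrix with AA dimnames.
struct SubMat {
  double s[128][128];
  double min_s;
  SubMat(const NumericMatrix& m) {
    List dn = m.attr("dimnames");
    CharacterVector rn = dn[0], cn = dn[1];
    min_s = 0.0;
    for (int i = 0; i < 128; ++i)
      for (int j = 0; j < 128; ++j) s[i][j] = -1e9;
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < m.ncol(); ++j) {
        char a = CHAR(STRING_ELT(rn, i))[0];
        char b = CHAR(STRING_ELT(cn, j))[0];
        s[(int)a][(int)b] = m(i, j);
        if (m(i, j) < min_s) min_s = m(i, j);
      }
  }
  double score(char a, char b) const {
    double v = s[(int)toupper(a)][(int)toupper(b)];
    return (v < -1e8) ? min_s : v;   // unknown residue -> worst score
  }
};

// Score for aligning protein residue `aa` to a frameshifted "codon" of
// k consumed nucleotides: k = 1 or 2 -> best completion over the
// missing bases; k = 4 or 5 -> best of the in-register triplets. Stop
// translations are skipped (a frameshift move never doubles as a stop).
static double fsMatchScore(const SubMat& SM, char aa, const std::string& dna,
                           int jend /*1-based inclusive end*/, int k) {
  double best = -1e9;
  if (k == 1) {
    int b1 = baseIdx(dna[jend - 1]);
    for (int b2 = 0; b2 < 4; ++b2)
      for (int b3 = 0; b3 < 4; ++b3) {
        char t = translateCodon(b1, b2, b3);
        if (t == '*') continue;
        double v = SM.score(aa, t);
        if (v > best) best = v;
      }
  } else if (k == 2) {
    int b1 = baseIdx(dna[jend - 2]), b2 = baseIdx(dna[jend - 1]);
    for (int b3 = 0; b3 < 4; ++b3) {
      char t = translateCodon(b1, b2, b3);
      if (t == '*') continue;
      double v = SM.score(aa, t);
      if (v > best) best = v;
    }
  } else { // k = 4 or 5: the k-2 in-register triplets
    for (int off = 0; off <= k - 3; ++off) {
      int p = jend - k + off;  // 0-based start of triplet
      char t = translateCodon(baseIdx(dna[p]), baseIdx(dna[p + 1]),
                              baseIdx(dna[p + 2]));
      if (t == '*') continue;
      double v = SM.score(aa, t);
      if (v > best) best = v;
    }
  }
  if (best < -1e8) best = SM.min_s;
  return best;
}

// Frameshift-aware local protein-to-DNA alignment (Smith-Waterman style).
//
// States per cell (i = residues consumed, j = nucleotides consumed):
//   M : residue i aligned to a codon ending at j, consuming 3 nt, or to a
//       frameshifted codon consuming 2 or 4 nt (penalty `fs`); in-frame
//       stop codons are retained with penalty `stop_pen` and recorded.
//   Ix: residue i skipped (gap in DNA), affine (open/ext).
//   Iy: codon j-2..j skipped (gap in protein), affine, consumes 3 nt.
// Local: M may restart from 0; best score is the max over M cells.
//
// [[Rcpp::export]]
List cpp_align_protein_dna(std::string prot, std::string dna,
                           NumericMatrix submat,
                           double gap_open, double gap_ext,
                           double fs_pen, double stop_pen) {
  const int m = prot.size(), n = dna.size();
  SubMat SM(submat);
  const double NEG = -1e12;
  // flattened (m+1) x (n+1)
  std::vector<double> M((m + 1) * (n + 1), NEG), Ix(M), Iy(M);
  std::vector<signed char> bM((m + 1) * (n + 1), 0), bIx(bM), bIy(bM);
  // back codes for M: 0=fresh start,1=diag3,2=fs2,3=fs4,4=stop3; plus which
  // predecessor state in high bits (0=M,1=Ix,2=Iy) via separate array
  std::vector<signed char> pM((m + 1) * (n + 1), 0), pIx(bM), pIy(bM);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0;   // local start row
  for (int i = 0; i <= m; ++i) M[at(i, 0)] = (i == 0) ? 0.0 : NEG;

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    char aa = toupper(prot[i - 1]);
    for (int j = 0; j <= n; ++j) {
      // Ix: consume residue, no nt
      double v1 = M[at(i - 1, j)] - gap_open;
      double v2 = Ix[at(i - 1, j)] - gap_ext;
      if (v1 >= v2) { Ix[at(i, j)] = v1; pIx[at(i, j)] = 0; }
      else          { Ix[at(i, j)] = v2; pIx[at(i, j)] = 1; }
      // Iy: consume 3 nt, no residue
      if (j >= 3) {
        double w1 = M[at(i, j - 3)] - gap_open;
        double w2 = Iy[at(i, j - 3)] - gap_ext;
        if (w1 >= w2) { Iy[at(i, j)] = w1; pIy[at(i, j)] = 0; }
        else          { Iy[at(i, j)] = w2; pIy[at(i, j)] = 2; }
      }
      // M: residue i consumes 3 nt (codon/stop) or 1, 2, 4, 5 nt at the
      // frameshift penalty
      double mv = 0.0; signed char mb = 0, mp = 0;  // fresh local start
      for (int k = 1; k <= 5; ++k) {
        if (j < k) continue;
        double sc; signed char code;
        if (k == 3) {
          char t = translateCodon(baseIdx(dna[j - 3]), baseIdx(dna[j - 2]),
                                  baseIdx(dna[j - 1]));
          sc = (t == '*') ? -stop_pen : SM.score(aa, t);
          code = (t == '*') ? 4 : 1;
        } else {
          sc = fsMatchScore(SM, aa, dna, j, k) - fs_pen;
          code = (signed char)(10 + k);   // frameshift consuming k nt
        }
        const int jj = j - k;
        double c0 = M[at(i - 1, jj)], c1 = Ix[at(i - 1, jj)], c2 = Iy[at(i - 1, jj)];
        double cb = c0; signed char cp = 0;
        if (c1 > cb) { cb = c1; cp = 1; }
        if (c2 > cb) { cb = c2; cp = 2; }
        if (cb + sc > mv) { mv = cb + sc; mb = code; mp = cp; }
      }
      M[at(i, j)] = mv; bM[at(i, j)] = mb; pM[at(i, j)] = mp;
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state M
  std::vector<std::string> op;
  std::vector<int> qpos, tpos, len;
  int i = bi, j = bj, state = 0;  // 0=M,1=Ix,2=Iy
  while (i > 0 || j > 0) {
    int idx = at(i, j);
    if (state == 0) {
      signed char b = bM[idx];
      if (b == 0) break;  // fresh local start
      int k = (b >= 10) ? (b - 10) : 3;
      op.push_back(b == 4 ? "stop" : (b >= 10 ? "frameshift" : "match"));
      qpos.push_back(i); tpos.push_back(j - k); len.push_back(k);
      state = pM[idx]; i -= 1; j -= k;
    } else if (state == 1) {
      op.push_back("qgap"); qpos.push_back(i);
      tpos.push_back(j); len.push_back(0);
      state = pIx[idx]; i -= 1;
    } else {
      op.push_back("tgap"); qpos.push_back(NA_INTEGER);
      tpos.push_back(j - 3); len.push_back(3);
      state = pIy[idx]; j -= 3;
    }
  }
  std::reverse(op.begin(), op.end());
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());
  std::reverse(len.begin(), len.end());

  int aligned = 0;
  for (size_t k = 0; k < op.size(); ++k)
    if (op[k] != "qgap" && op[k] != "tgap") ++aligned;

  int t_start = op.empty() ? 0 : tpos[0];
  int t_end = bj;
  int q_start = bi, q_end = bi;
  for (size_t k = 0; k < op.size(); ++k)
    if (qpos[k] != NA_INTEGER && qpos[k] < q_start) q_start = qpos[k];

  return List::create(
    _["score"] = best,
    _["coverage"] = m > 0 ? (double)aligned / m : 0.0,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["t_start"] = t_start, _["t_end"] = t_end,
    _["ops"] = DataFrame::create(_["op"] = op, _["qpos"] = qpos,
                                 _["tpos"] = tpos, _["len"] = len,
                                 _["stringsAsFactors"] = false));
}

// Plant-style miRNA target penalty: global gapped alignment of the miRNA
// (5'->3') against the reversed target site (antiparallel pairing).
// Per-pair penalty 0 (Watson-Crick), `wobble` (G:U), `mismatch` otherwise;
// indels cost `indel`. Every penalty is multiplied by `mult` at miRNA
// positions dbl_lo..dbl_hi (1-based from the miRNA 5' end).
//
// [[Rcpp::export]]
double cpp_score_target_site(std::string mirna, std::string site,
                             double mismatch, double wobble, double indel,
                             int dbl_lo, int dbl_hi, double mult) {
  const int m = mirna.size(), n = site.size();
  std::string t(site.rbegin(), site.rend());  // target read 3'->5'
  auto norm = [](char c) {
    c = toupper(c);
    return (c == 'U') ? 'T' : c;
  };
  auto pairPen = [&](char a, char b) {
    a = norm(a); b = norm(b);
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
        (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 0.0;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wobble;
    return mismatch;
  };
  auto w = [&](int i) {  // weight for miRNA position i (1-based)
    if (i < 1) i = 1;
    if (i > m) i = m;
    return (i >= dbl_lo && i <= dbl_hi) ? mult : 1.0;
  };
  std::vector<double> prev(n + 1), cur(n + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= n; ++j) prev[j] = prev[j - 1] + indel * w(1);
  for (int i = 1; i <= m; ++i) {
    cur[0] = prev[0] + indel * w(i);
    for (int j = 1; j <= n; ++j) {
      double d = prev[j - 1] + pairPen(mirna[i - 1], t[j - 1]) * w(i);
      double u = prev[j] + indel * w(i);               // miRNA base unpaired
      double l = cur[j - 1] + indel * w(i + 1);        // site bulge
      cur[j] = std::min(d, std::min(u, l));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
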