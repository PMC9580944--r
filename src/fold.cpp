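// Nearest-neighbor MFE folding engine (Turner-2004 core parameter set),
// Nussinov-style fallback oracle, maximum-weight non-crossing pair selection,
// and a structure-seeded inverse-folding hill climber.
//
// Energy model notes:
//  - energies in dacal/mol (10 cal/mol) at 37 C, as in the published
//    Turner-2004 nearest-neighbor compilation;
//  - "d2"-style dangles: every helix end in exterior and multiloops receives
//    both-side mismatch contributions regardless of neighbor pairing;
//  - special 1x1 / 2x1 / 2x2 interior-loop tables are NOT included; those
//    loops are scored by the generic interior-loop rule (size initiation +
//    Ninio asymmetry + terminal mismatches).  The engine is therefore
//    "turner2004-core", a close but not exact reimplementation of the full
//    published model.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

static const int INFE = 10000000;
static const int MAXLOOP = 30;
static const int TURN = 3; // minimum hairpin size (unpaired nt)

// base encoding: 0=N, 1=A, 2=C, 3=G, 4=U
static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 3;
  case 'U': case 'u': case 'T': case 't': return 4;
  default: return 0;
  }
}

// pair types: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
static const int BPT[5][5] = {
  {0, 0, 0, 0, 0},
  {0, 0, 0, 0, 5},
  {0, 0, 0, 1, 0},
  {0, 0, 2, 0, 3},
  {0, 6, 0, 4, 0}};

// ---- Turner 2004 core tables (37 C, dacal/mol) ----

// stack[type(i,j)][type(q,p)] with inner pair reversed
static const int STACK[7][7] = {
  {INFE, INFE, INFE, INFE, INFE, INFE, INFE},
  {INFE, -240, -330, -210, -140, -210, -210}, // CG
  {INFE, -330, -340, -250, -150, -220, -240}, // GC
  {INFE, -210, -250,  130,  -50, -140, -130}, // GU
  {INFE, -140, -150,  -50,   30,  -60, -100}, // UG
  {INFE, -210, -220, -140,  -60, -110,  -90}, // AU
  {INFE, -210, -240, -130, -100,  -90, -130}  // UA
};

// mismatch tables indexed [type][si1][sj1], bases 0..4 (0 = N / absent)
static const int MM_H[7][5][5] = {
  {{0}},
  {{-80,-100,-110,-100,-80},{-140,-150,-150,-140,-150},{-80,-100,-110,-100,-80},{-150,-230,-150,-240,-150},{-100,-100,-140,-100,-210}},
  {{-50,-110,-70,-110,-50},{-110,-110,-150,-130,-150},{-50,-110,-70,-110,-50},{-150,-250,-150,-220,-150},{-100,-110,-100,-110,-160}},
  {{20,20,-20,-10,-20},{20,20,-50,-30,-50},{-10,-10,-20,-10,-20},{-50,-100,-50,-110,-50},{-10,-10,-30,-10,-100}},
  {{0,-20,-10,-20,0},{-30,-50,-30,-60,-30},{0,-20,-10,-20,0},{-30,-90,-30,-110,-30},{-10,-20,-10,-20,-90}},
  {{-10,-10,-20,-10,-20},{-30,-30,-50,-30,-50},{-10,-10,-20,-10,-20},{-50,-120,-50,-110,-50},{-10,-10,-30,-10,-120}},
  {{0,-20,-10,-20,0},{-30,-50,-30,-50,-30},{0,-20,-10,-20,0},{-30,-150,-30,-150,-30},{-10,-20,-10,-20,-90}}
};

static const int MM_I[7][5][5] = {
  {{0}},
  {{0,0,0,0,0},{0,0,0,-80,0},{0,0,0,0,0},{0,-100,0,-100,0},{0,0,0,0,-60}},
  {{0,0,0,0,0},{0,0,0,-80,0},{0,0,0,0,0},{0,-100,0,-100,0},{0,0,0,0,-60}},
  {{70,70,70,70,70},{70,70,70,-10,70},{70,70,70,70,70},{70,-30,70,-30,70},{70,70,70,70,10}},
  {{70,70,70,70,70},{70,70,70,-10,70},{70,70,70,70,70},{70,-30,70,-30,70},{70,70,70,70,10}},
  {{70,70,70,70,70},{70,70,70,-10,70},{70,70,70,70,70},{70,-30,70,-30,70},{70,70,70,70,10}},
  {{70,70,70,70,70},{70,70,70,-10,70},{70,70,70,70,70},{70,-30,70,-30,70},{70,70,70,70,10}}
};

// 1 x n (n >= 3) interior mismatches: 0 for CG/GC closing, 70 otherwise
static inline int mm_1n(int type) { return (type == 1 || type == 2) ? 0 : 70; }

static const int MM_23[7][5][5] = {
  {{0}},
  {{0,0,0,0,0},{0,0,0,-50,0},{0,0,0,0,0},{0,-110,0,-70,0},{0,0,0,0,-30}},
  {{0,0,0,0,0},{0,0,0,0,0},{0,0,0,0,0},{0,-120,0,-70,0},{0,0,0,0,-30}},
  {{70,70,70,70,70},{70,70,70,70,70},{70,70,70,70,70},{70,-40,70,0,70},{70,70,70,70,40}},
  {{70,70,70,70,70},{70,70,70,20,70},{70,70,70,70,70},{70,-40,70,0,70},{70,70,70,70,40}},
  {{70,70,70,70,70},{70,70,70,70,70},{70,70,70,70,70},{70,-40,70,0,70},{70,70,70,70,40}},
  {{70,70,70,70,70},{70,70,70,20,70},{70,70,70,70,70},{70,-40,70,0,70},{70,70,70,70,40}}
};

// multiloop == exterior mismatches in Turner 2004
static const int MM_M[7][5][5] = {
  {{0}},
  {{-50,-110,-50,-140,-70},{-110,-110,-110,-160,-110},{-70,-150,-70,-150,-100},{-110,-130,-110,-140,-110},{-50,-150,-50,-150,-70}},
  {{-80,-140,-80,-140,-100},{-100,-150,-100,-140,-100},{-110,-150,-110,-150,-140},{-100,-140,-100,-160,-100},{-80,-150,-80,-150,-120}},
  {{-50,-80,-50,-50,-50},{-50,-100,-70,-50,-70},{-60,-80,-60,-80,-60},{-70,-110,-70,-80,-70},{-50,-80,-50,-80,-50}},
  {{-30,-30,-60,-60,-60},{-30,-30,-60,-60,-60},{-70,-100,-70,-100,-80},{-60,-80,-60,-80,-60},{-60,-100,-70,-100,-60}},
  {{-50,-80,-50,-80,-50},{-70,-100,-70,-110,-70},{-60,-80,-60,-80,-60},{-70,-110,-70,-120,-70},{-50,-80,-50,-80,-50}},
  {{-60,-80,-60,-80,-60},{-60,-80,-60,-80,-60},{-70,-100,-70,-100,-80},{-60,-80,-60,-80,-60},{-70,-100,-70,-100,-80}}
};

static const int DANGLE5[7][5] = {
  {0,0,0,0,0},
  {-10,-50,-30,-20,-10},
  {0,-20,-30,0,0},
  {-20,-30,-30,-40,-20},
  {-10,-30,-10,-20,-20},
  {-20,-30,-30,-40,-20},
  {-10,-30,-10,-20,-20}};

static const int DANGLE3[7][5] = {
  {0,0,0,0,0},
  {-40,-110,-40,-130,-60},
  {-80,-170,-80,-170,-120},
  {-10,-70,-10,-70,-10},
  {-50,-80,-50,-80,-60},
  {-10,-70,-10,-70,-10},
  {-50,-80,-50,-80,-60}};

static const int HAIRPIN_INIT[31] = {
  INFE, INFE, INFE, 540, 560, 570, 540, 600, 550, 640,
  650, 660, 670, 680, 690, 690, 700, 710, 710, 720,
  720, 730, 730, 740, 740, 750, 750, 750, 760, 760, 770};

static const int BULGE_INIT[31] = {
  INFE, 380, 280, 320, 360, 400, 440, 460, 470, 480,
  490, 500, 510, 520, 530, 540, 540, 550, 550, 560,
  570, 570, 580, 580, 580, 590, 590, 600, 600, 600, 610};

static const int INTERNAL_INIT[31] = {
  INFE, INFE, 100, 100, 110, 200, 200, 210, 230, 240,
  250, 260, 270, 280, 290, 290, 300, 310, 310, 320,
  330, 330, 340, 340, 350, 350, 350, 360, 360, 370, 370};

static const int ML_CLOSING = 930;
static const int ML_INTERN = -90;
static const int ML_BASE = 0;
static const int NINIO_F = 60;
static const int NINIO_MAX = 300;
static const int TERM_AU = 50;
static const double LXC = 107.856;

struct SpecialLoop { const char *motif; int e; };
static const SpecialLoop TETRALOOPS[] = {
  {"CAACGG", 550}, {"CCAAGG", 330}, {"CCACGG", 370}, {"CCCAGG", 340},
  {"CCGAGG", 350}, {"CCGCGG", 360}, {"CCUAGG", 370}, {"CCUCGG", 250},
  {"CUAAGG", 360}, {"CUACGG", 280}, {"CUCAGG", 370}, {"CUCCGG", 270},
  {"CUGCGG", 280}, {"CUUAGG", 350}, {"CUUCGG", 370}, {"CUUUGG", 370}};
static const SpecialLoop TRILOOPS[] = {{"CAACG", 680}, {"GUUAC", 690}};
static const SpecialLoop HEXALOOPS[] = {
  {"ACAGUACU", 280}, {"ACAGUGAU", 360}, {"ACAGUGCU", 290}, {"ACAGUGUU", 180}};

static inline int term_au(int type) { return type > 2 ? TERM_AU : 0; }

static inline int loop_ext(const int *tab, int size) {
  if (size <= 30) return tab[size];
  return tab[30] + (int)(LXC * std::log((double)size / 30.0));
}

struct FoldCtx {
  int n;
  std::string S;           // upper-case sequence
  std::vector<int> se;     // encoded bases
  std::vector<int> C, M, M1;
  std::vector<int> F;
  inline int idx(int i, int j) const { return i * n + j; }
};

static int e_hairpin(const FoldCtx &fc, int i, int j, int type) {
  int size = j - i - 1;
  if (size < TURN) return INFE;
  int e = loop_ext(HAIRPIN_INIT, size);
  if (size == 3) {
    for (const SpecialLoop &sl : TRILOOPS)
      if (fc.S.compare(i, 5, sl.motif) == 0) return sl.e;
    return e + term_au(type);
  }
  if (size == 4) {
    for (const SpecialLoop &sl : TETRALOOPS)
      if (fc.S.compare(i, 6, sl.motif) == 0) return sl.e;
  }
  if (size == 6) {
    for (const SpecialLoop &sl : HEXALOOPS)
      if (fc.S.compare(i, 8, sl.motif) == 0) return sl.e;
  }
  return e + MM_H[type][fc.se[i + 1]][fc.se[j - 1]];
}

// two-pair loop (stack / bulge / interior); type2 is the inner pair reversed
static int e_intloop(int n1, int n2, int type, int type2,
                     int si1, int sj1, int sp1, int sq1) {
  int nl = n1 > n2 ? n1 : n2;
  int ns = n1 > n2 ? n2 : n1;
  if (nl == 0) return STACK[type][type2];
  if (ns == 0) { // bulge
    int e = loop_ext(BULGE_INIT, nl);
    if (nl == 1) e += STACK[type][type2];
    else e += term_au(type) + term_au(type2);
    return e;
  }
  int e = loop_ext(INTERNAL_INIT, n1 + n2);
  int asym = (nl - ns) * NINIO_F;
  e += asym < NINIO_MAX ? asym : NINIO_MAX;
  if (ns == 1 && nl >= 3) {
    e += mm_1n(type) + mm_1n(type2);
  } else if ((ns == 2 && nl == 3)) {
    e += MM_23[type][si1][sj1] + MM_23[type2][sq1][sp1];
  } else {
    // generic rule; also covers 1x1, 2x1, 2x2 (no special tables here)
    e += MM_I[type][si1][sj1] + MM_I[type2][sq1][sp1];
  }
  return e;
}

// helix end inside a multiloop (both-side mismatch convention)
static inline int ml_stem(const FoldCtx &fc, int type, int i5, int j3) {
  int a = (i5 >= 0) ? fc.se[i5] : 0;
  int b = (j3 <= fc.n - 1 && j3 >= 0) ? fc.se[j3] : 0;
  return MM_M[type][a][b] + term_au(type) + ML_INTERN;
}

// helix end in the exterior loop
static inline int ext_stem(const FoldCtx &fc, int type, int i, int j) {
  int e = term_au(type);
  bool has5 = i > 0, has3 = j < fc.n - 1;
  if (has5 && has3) e += MM_M[type][fc.se[i - 1]][fc.se[j + 1]];
  else if (has5) e += DANGLE5[type][fc.se[i - 1]];
  else if (has3) e += DANGLE3[type][fc.se[j + 1]];
  return e;
}

static void fill_matrices(FoldCtx &fc) {
  int n = fc.n;
  fc.C.assign((size_t)n * n, INFE);
  fc.M.assign((size_t)n * n, INFE);
  fc.M1.assign((size_t)n * n, INFE);
  for (int d = TURN + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int type = BPT[fc.se[i]][fc.se[j]];
      int cij = INFE;
      if (type) {
        cij = e_hairpin(fc, i, j, type);
        int pmax = std::min(i + MAXLOOP + 1, j - TURN - 1);
        for (int p = i + 1; p <= pmax; ++p) {
          int n1 = p - i - 1;
          int qmin = std::max(p + TURN + 1, j - 1 - (MAXLOOP - n1));
          for (int q = qmin; q <= j - 1; ++q) {
            if (p == i + 1 && q == j - 1 && d == TURN + 1) continue;
            int type2 = BPT[fc.se[q]][fc.se[p]];
            if (!type2) continue;
            int cin = fc.C[fc.idx(p, q)];
            if (cin >= INFE) continue;
            int e = cin + e_intloop(n1, j - q - 1, type, type2,
                                    fc.se[i + 1], fc.se[j - 1],
                                    fc.se[p - 1], fc.se[q + 1]);
            if (e < cij) cij = e;
          }
        }
        // multiloop closing: >= 2 branches inside
        int rtype = BPT[fc.se[j]][fc.se[i]];
        int close_cost = ML_CLOSING + ml_stem(fc, rtype, j - 1, i + 1);
        for (int u = i + 1; u < j - 1; ++u) {
          int m = fc.M[fc.idx(i + 1, u)];
          int m1 = fc.M1[fc.idx(u + 1, j - 1)];
          if (m >= INFE || m1 >= INFE) continue;
          int e = m + m1 + close_cost;
          if (e < cij) cij = e;
        }
      }
      fc.C[fc.idx(i, j)] = cij;

      // M1: exactly one branch starting at i, optional unpaired tail
      int m1v = INFE;
      if (fc.M1[fc.idx(i, j - 1)] < INFE) m1v = fc.M1[fc.idx(i, j - 1)] + ML_BASE;
      if (cij < INFE) {
        int e = cij + ml_stem(fc, type, i - 1, j + 1);
        if (e < m1v) m1v = e;
      }
      fc.M1[fc.idx(i, j)] = m1v;

      // M: at least one branch anywhere in [i, j]
      int mv = INFE;
      if (fc.M[fc.idx(i, j - 1)] < INFE) mv = fc.M[fc.idx(i, j - 1)] + ML_BASE;
      for (int v = i; v <= j - TURN - 1; ++v) {
        int cvj = fc.C[fc.idx(v, j)];
        if (cvj >= INFE) continue;
        int tvj = BPT[fc.se[v]][fc.se[j]];
        int bt = cvj + ml_stem(fc, tvj, v - 1, j + 1);
        int prefix = 0;
        if (v > i) {
          prefix = (v - i) * ML_BASE;
          int mp = fc.M[fc.idx(i, v - 1)];
          if (mp < prefix) prefix = mp;
        }
        if (prefix + bt < mv) mv = prefix + bt;
      }
      fc.M[fc.idx(i, j)] = mv;
    }
  }
  fc.F.assign(n + 1, 0); // F[j+1] = best energy for prefix [0, j]
  for (int j = 0; j < n; ++j) {
    int best = fc.F[j];
    for (int v = 0; v <= j - TURN - 1; ++v) {
      int cvj = fc.C[fc.idx(v, j)];
      if (cvj >= INFE) continue;
      int t = BPT[fc.se[v]][fc.se[j]];
      int e = (v > 0 ? fc.F[v] : 0) + cvj + ext_stem(fc, t, v, j);
      if (e < best) best = e;
    }
    fc.F[j + 1] = best;
  }
}

struct TBItem { int i, j; char mat; }; // 'F' (uses j only), 'C', 'M', '1'

static void traceback(FoldCtx &fc, std::vector<int> &partner) {
  int n = fc.n;
  partner.assign(n, -1);
  std::vector<TBItem> st;
  st.push_back({0, n - 1, 'F'});
  while (!st.empty()) {
    TBItem it = st.back();
    st.pop_back();
    if (it.mat == 'F') {
      int j = it.j;
      while (j >= 0 && fc.F[j + 1] == fc.F[j]) --j;
      if (j < 0) continue;
      bool found = false;
      for (int v = 0; v <= j - TURN - 1 && !found; ++v) {
        int cvj = fc.C[fc.idx(v, j)];
        if (cvj >= INFE) continue;
        int t = BPT[fc.se[v]][fc.se[j]];
        if ((v > 0 ? fc.F[v] : 0) + cvj + ext_stem(fc, t, v, j) == fc.F[j + 1]) {
          st.push_back({v, j, 'C'});
          if (v > 0) st.push_back({0, v - 1, 'F'});
          found = true;
        }
      }
      if (!found) Rcpp::stop("traceback failure in exterior array");
    } else if (it.mat == 'C') {
      int i = it.i, j = it.j;
      partner[i] = j;
      partner[j] = i;
      int type = BPT[fc.se[i]][fc.se[j]];
      int cij = fc.C[fc.idx(i, j)];
      if (e_hairpin(fc, i, j, type) == cij) continue;
      bool found = false;
      int pmax = std::min(i + MAXLOOP + 1, j - TURN - 1);
      for (int p = i + 1; p <= pmax && !found; ++p) {
        int n1 = p - i - 1;
        int qmin = std::max(p + TURN + 1, j - 1 - (MAXLOOP - n1));
        for (int q = qmin; q <= j - 1 && !found; ++q) {
          if (p == i + 1 && q == j - 1 && j - i == TURN + 1) continue;
          int type2 = BPT[fc.se[q]][fc.se[p]];
          if (!type2) continue;
          int cin = fc.C[fc.idx(p, q)];
          if (cin >= INFE) continue;
          if (cin + e_intloop(n1, j - q - 1, type, type2,
                              fc.se[i + 1], fc.se[j - 1],
                              fc.se[p - 1], fc.se[q + 1]) == cij) {
            st.push_back({p, q, 'C'});
            found = true;
          }
        }
      }
      if (found) continue;
      int rtype = BPT[fc.se[j]][fc.se[i]];
      int close_cost = ML_CLOSING + ml_stem(fc, rtype, j - 1, i + 1);
      for (int u = i + 1; u < j - 1 && !found; ++u) {
        int m = fc.M[fc.idx(i + 1, u)];
        int m1 = fc.M1[fc.idx(u + 1, j - 1)];
        if (m >= INFE || m1 >= INFE) continue;
        if (m + m1 + close_cost == cij) {
          st.push_back({i + 1, u, 'M'});
          st.push_back({u + 1, j - 1, '1'});
          found = true;
        }
      }
      if (!found) Rcpp::stop("traceback failure in paired array");
    } else if (it.mat == '1') {
      int i = it.i, j = it.j;
      int v = fc.M1[fc.idx(i, j)];
      while (j > i && fc.M1[fc.idx(i, j - 1)] < INFE &&
             fc.M1[fc.idx(i, j - 1)] + ML_BASE == v) {
        --j;
        v = fc.M1[fc.idx(i, j)];
      }
      st.push_back({i, j, 'C'});
    } else { // 'M'
      int i = it.i, j = it.j;
      int mv = fc.M[fc.idx(i, j)];
      while (j > i && fc.M[fc.idx(i, j - 1)] < INFE &&
             fc.M[fc.idx(i, j - 1)] + ML_BASE == mv) {
        --j;
        mv = fc.M[fc.idx(i, j)];
      }
      bool found = false;
      for (int v = i; v <= j - TURN - 1 && !found; ++v) {
        int cvj = fc.C[fc.idx(v, j)];
        if (cvj >= INFE) continue;
        int tvj = BPT[fc.se[v]][fc.se[j]];
        int bt = cvj + ml_stem(fc, tvj, v - 1, j + 1);
        int prefix = 0;
        bool via_m = false;
        if (v > i) {
          prefix = (v - i) * ML_BASE;
          int mp = fc.M[fc.idx(i, v - 1)];
          if (mp < prefix) { prefix = mp; via_m = true; }
        }
        if (prefix + bt == mv) {
          st.push_back({v, j, 'C'});
          if (via_m) st.push_back({i, v - 1, 'M'});
          found = true;
        }
      }
      if (!found) Rcpp::stop("traceback failure in multiloop array");
    }
  }
}

static std::string partner_to_db(const std::vector<int> &partner) {
  std::string db(partner.size(), '.');
  for (size_t i = 0; i < partner.size(); ++i) {
    if (partner[i] > (int)i) { db[i] = '('; db[partner[i]] = ')'; }
  }
  return db;
}

static void fold_one(const std::string &seq, std::string &db, double &energy) {
  FoldCtx fc;
  fc.n = (int)seq.size();
  fc.S.resize(fc.n);
  fc.se.resize(fc.n);
  for (int i = 0; i < fc.n; ++i) {
    char c = toupper(seq[i]);
    if (c == 'T') c = 'U';
    fc.S[i] = c;
    fc.se[i] = enc_base(c);
    if (fc.se[i] == 0)
      Rcpp::stop("sequence contains a non-ACGU residue at position %d", i + 1);
  }
  if (fc.n <= TURN + 1) {
    db.assign(fc.n, '.');
    energy = 0.0;
    return;
  }
  fill_matrices(fc);
  std::vector<int> partner;
  traceback(fc, partner);
  db = partner_to_db(partner);
  energy = fc.F[fc.n] / 100.0;
}

// [[Rcpp::export(name = ".fold_turner_cpp")]]
List fold_turner_cpp(CharacterVector seqs) {
  int m = seqs.size();
  CharacterVector structs(m);
  NumericVector energies(m);
  for (int k = 0; k < m; ++k) {
    std::string db;
    double e;
    fold_one(as<std::string>(seqs[k]), db, e);
    structs[k] = db;
    energies[k] = e;
  }
  return List::create(_["structure"] = structs, _["energy"] = energies);
}

// ---- Nussinov-style base-pair maximization fallback (non-thermodynamic) ----

// [[Rcpp::export(name = ".fold_nussinov_cpp")]]
CharacterVector fold_nussinov_cpp(CharacterVector seqs, int min_hairpin = 3) {
  int m = seqs.size();
  CharacterVector out(m);
  for (int k = 0; k < m; ++k) {
    std::string seq = as<std::string>(seqs[k]);
    int n = (int)seq.size();
    std::vector<int> se(n);
    for (int i = 0; i < n; ++i) se[i] = enc_base(toupper(seq[i]));
    std::vector<int> D((size_t)n * n, 0);
    auto idx = [n](int i, int j) { return i * n + j; };
    for (int d = min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        int best = D[idx(i, j - 1)]; // j unpaired
        for (int v = i; v <= j - min_hairpin - 1; ++v) {
          if (!BPT[se[v]][se[j]]) continue;
          int sc = 1 + (v > i ? D[idx(i, v - 1)] : 0) +
                   (v + 1 <= j - 1 ? D[idx(v + 1, j - 1)] : 0);
          if (sc > best) best = sc;
        }
        D[idx(i, j)] = best;
      }
    }
    std::vector<int> partner(n, -1);
    std::vector<std::pair<int, int>> st;
    if (n > min_hairpin + 1) st.push_back({0, n - 1});
    while (!st.empty()) {
      auto [i, j] = st.back();
      st.pop_back();
      if (j - i <= min_hairpin) continue;
      if (D[idx(i, j)] == D[idx(i, j - 1)]) { st.push_back({i, j - 1}); continue; }
      bool found = false;
      for (int v = i; v <= j - min_hairpin - 1 && !found; ++v) {
        if (!BPT[se[v]][se[j]]) continue;
        int sc = 1 + (v > i ? D[idx(i, v - 1)] : 0) +
                 (v + 1 <= j - 1 ? D[idx(v + 1, j - 1)] : 0);
        if (sc == D[idx(i, j)]) {
          partner[v] = j;
          partner[j] = v;
          if (v > i) st.push_back({i, v - 1});
          if (v + 1 <= j - 1) st.push_back({v + 1, j - 1});
          found = true;
        }
      }
      if (!found) st.push_back({i, j - 1});
    }
    out[k] = partner_to_db(partner);
  }
  return out;
}

// ---- maximum-weight non-crossing subset of a pair list ----
//
// pairs: m x 2 (0-based, i < j), possibly crossing / sharing endpoints.
// Returns logical keep vector.  Ties broken by preferring inclusion of the
// pair with the smallest left endpoint, then smallest right endpoint.

// [[Rcpp::export(name = ".remove_pk_cpp")]]
LogicalVector remove_pk_cpp(IntegerMatrix pairs, NumericVector w, int n) {
  int m = pairs.nrow();
  LogicalVector keep(m);
  if (m == 0 || n == 0) return keep;
  const double eps = 1e-9;
  std::vector<std::vector<std::pair<int, int>>> at(n); // left pos -> (right, idx)
  for (int k = 0; k < m; ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    if (i < 0 || j >= n || i >= j)
      Rcpp::stop("invalid pair (%d, %d) for n = %d", i, j, n);
    at[i].push_back({j, k});
  }
  for (auto &v : at) std::sort(v.begin(), v.end());
  std::vector<double> best((size_t)n * n, 0.0);
  std::vector<int> choice((size_t)n * n, -1);
  auto idx = [n](int i, int j) { return i * n + j; };
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double b = best[idx(i + 1, j)];
      int ch = -1;
      for (auto &pr : at[i]) {
        int r = pr.first, k = pr.second;
        if (r > j) break;
        double v = w[k];
        if (r - i >= 2) v += best[idx(i + 1, r - 1)];
        if (r < j) v += best[idx(r + 1, j)];
        if (v > b + eps || (v >= b - eps && ch == -1)) {
          if (v > b) b = v;
          ch = k;
        }
      }
      best[idx(i, j)] = b;
      choice[idx(i, j)] = ch;
    }
  }
  std::vector<std::pair<int, int>> st;
  st.push_back({0, n - 1});
  while (!st.empty()) {
    auto [i, j] = st.back();
    st.pop_back();
    if (i >= j) continue;
    int ch = choice[idx(i, j)];
    if (ch < 0) { st.push_back({i + 1, j}); continue; }
    keep[ch] = true;
    int r = pairs(ch, 1);
    if (r - i >= 2) st.push_back({i + 1, r - 1});
    if (r < j) st.push_back({r + 1, j});
  }
  return keep;
}

// ---- inverse folding: structure-seeded hill climb against the engine ----

static const int PAIR_CHOICES[6][2] = {
  {3, 2}, {2, 3}, {1, 4}, {4, 1}, {3, 4}, {4, 3}}; // GC CG AU UA GU GU'
static const char BASES[5] = {'N', 'A', 'C', 'G', 'U'};

static int bp_distance_db(const std::string &a, const std::string &b) {
  // symmetric difference of the two nested pair sets
  auto pairs_of = [](const std::string &db) {
    std::vector<std::pair<int, int>> out;
    std::vector<int> st;
    for (size_t i = 0; i < db.size(); ++i) {
      if (db[i] == '(') st.push_back((int)i);
      else if (db[i] == ')') { out.push_back({st.back(), (int)i}); st.pop_back(); }
    }
    std::sort(out.begin(), out.end());
    return out;
  };
  auto pa = pairs_of(a), pb = pairs_of(b);
  size_t ia = 0, ib = 0;
  int common = 0;
  while (ia < pa.size() && ib < pb.size()) {
    if (pa[ia] == pb[ib]) { ++common; ++ia; ++ib; }
    else if (pa[ia] < pb[ib]) ++ia;
    else ++ib;
  }
  return (int)(pa.size() + pb.size()) - 2 * common;
}

// [[Rcpp::export(name = ".inverse_fold_cpp")]]
List inverse_fold_cpp(IntegerVector partner0, int tries, int max_steps,
                      int seed) {
  int n = partner0.size();
  std::string target(n, '.');
  for (int i = 0; i < n; ++i) {
    int p = partner0[i];
    if (p >= 0 && p > i) { target[i] = '('; target[p] = ')'; }
  }
  std::string best_seq;
  int best_d = INT32_MAX;
  for (int t = 0; t < tries; ++t) {
    std::mt19937 rng((uint32_t)seed + 7919u * (uint32_t)t);
    std::uniform_int_distribution<int> upos(0, n - 1);
    std::uniform_int_distribution<int> upair(0, 5);
    std::uniform_int_distribution<int> ubase(1, 4);
    std::uniform_real_distribution<double> u01(0.0, 1.0);
    // structure-aware seeding: helices GC-rich, loops A-rich
    std::string seq(n, 'A');
    for (int i = 0; i < n; ++i) {
      int p = partner0[i];
      if (p > i) {
        int c = upair(rng);
        if (u01(rng) < 0.5) c = c % 2; // bias toward GC/CG
        seq[i] = BASES[PAIR_CHOICES[c][0]];
        seq[p] = BASES[PAIR_CHOICES[c][1]];
      } else if (p < 0) {
        seq[i] = (u01(rng) < 0.55) ? 'A' : BASES[ubase(rng)];
      }
    }
    std::string db;
    double e;
    fold_one(seq, db, e);
    int d = bp_distance_db(db, target);
    for (int step = 0; step < max_steps && d > 0; ++step) {
      int pos = upos(rng);
      int p = partner0[pos];
      std::string cand = seq;
      if (p >= 0) {
        int i = std::min(pos, p), j = std::max(pos, p);
        int c = upair(rng);
        cand[i] = BASES[PAIR_CHOICES[c][0]];
        cand[j] = BASES[PAIR_CHOICES[c][1]];
      } else {
        cand[pos] = BASES[ubase(rng)];
      }
      if (cand == seq) continue;
      fold_one(cand, db, e);
      int d2 = bp_distance_db(db, target);
      if (d2 <= d) { seq = cand; d = d2; }
    }
    if (d < best_d) { best_d = d; best_seq = seq; }
    if (best_d == 0) break;
  }
  return List::create(_["sequence"] = best_seq, _["distance"] = best_d);
}
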