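// Partitioning engine for copy-number genotypes in pedigrees.
//
// Internal allele encoding shared with the R layer (see R/codes.R):
//   A with m copies -> m            (1, 2, 3, ...)
//   B with n copies -> 1000 + n
//   N (no copy)     -> 2000
// A genotype is an unordered pair of allele codes, stored canonically with
// g1 <= g2 (so A alleles sort before B, and N last).  Sentinels live at the
// genotype level: both slots -1 (undefined input) or -2 (unresolved).
//
// Per-individual status during partitioning:
//   0 = pending homozygote, 1 = converted, 2 = undefined, 3 = unresolved.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int NCODE = 2000;
static const int ST_PENDING = 0, ST_DONE = 1, ST_UNDEF = 2, ST_UNRES = 3;

// rule tally slots
enum Rule { R_STEP1 = 0, R_2A, R_2B, R_2C, R_3A, R_3B, R_3C, R_3D,
            R_3E, R_3F, R_3G, R_3H, N_RULES };

static inline int typeOf(int code) {            // 0 = A, 1 = B, 2 = N
  return code == NCODE ? 2 : (code >= 1000 ? 1 : 0);
}
static inline int cntOf(int code) {
  return code == NCODE ? 0 : (code >= 1000 ? code - 1000 : code);
}
static inline int mk(int T, int c) {            // count 0 collapses to N
  return c == 0 ? NCODE : (T == 0 ? c : 1000 + c);
}
static inline bool isHet(int x, int y) {
  int tx = typeOf(x), ty = typeOf(y);
  return (tx == 0 && ty == 1) || (tx == 1 && ty == 0);
}
static inline void canon(int &x, int &y) { if (x > y) std::swap(x, y); }

// pedigree topology in index form (1-based from R, 0 = absent)
struct Ped {
  int n;
  const int *father, *mother;          // length n
  const int *child_ptr, *child_idx;    // CSR adjacency, 1-based ids in idx
  const int *sib_ptr, *sib_idx;        // full siblings, same layout
};

// candidate collector: implements first-match (default) or conflict
// detection across the candidates of a single rule (strict mode)
struct Cand {
  bool strict, have, incons;
  int g1, g2;
  Cand(bool s) : strict(s), have(false), incons(false), g1(0), g2(0) {}
  // returns true when the caller may stop scanning
  bool add(int a1, int a2) {
    canon(a1, a2);
    if (!have) { have = true; g1 = a1; g2 = a2; return !strict; }
    if (a1 != g1 || a2 != g2) { incons = true; return true; }
    return !strict;
  }
  bool addIncons() { incons = true; return true; }
  bool conflicted() const { return incons; }
};

// outcome of a rule attempt
struct Res {
  int code;       // 0 = not converted, 1 = converted, 2 = inconsistency
  int g1, g2, rule;
};
static inline Res no_res() { Res r; r.code = 0; r.g1 = r.g2 = 0; r.rule = -1; return r; }
static inline Res ok_res(int g1, int g2, int rule) {
  canon(g1, g2); Res r; r.code = 1; r.g1 = g1; r.g2 = g2; r.rule = rule; return r;
}
static inline Res bad_res(int rule) { Res r; r.code = 2; r.g1 = r.g2 = -2; r.rule = rule; return r; }

static inline Res fromCand(const Cand &c, int rule) {
  if (c.conflicted()) return bad_res(rule);
  if (c.have) { Res r; r.code = 1; r.g1 = c.g1; r.g2 = c.g2; r.rule = rule; return r; }
  return no_res();
}

// Eq. (1): the index (type T, total copies tot) receives the T-type allele
// of count m from a relative; the second chromosome carries the remainder,
// or N when the remainder is zero.  A negative remainder is a Mendelian
// inconsistency.
static inline bool eq1(int T, int tot, int m, Cand &c) {
  int rem = tot - m;
  if (rem < 0) return c.addIncons();
  return c.add(mk(T, m), mk(T, rem));
}

// ---- type-I rules (heterozygous first-degree relatives) -----------------

// relative het genotype {A m, B n}: count of the allele matching type T
static inline int hetCountOf(int T, int x, int y) {
  return typeOf(x) == T ? cntOf(x) : cntOf(y);
}

static Res try_type1(int i, int T, int tot, const Ped &P,
                     const int *g1, const int *g2, const int *status,
                     bool strict) {
  // 2a: heterozygous parent (father first, then mother)
  {
    Cand c(strict);
    int par[2] = { P.father[i], P.mother[i] };
    bool seen = false;
    for (int k = 0; k < 2; k++) {
      int p = par[k];
      if (p == 0 || status[p - 1] != ST_DONE) continue;
      if (!isHet(g1[p - 1], g2[p - 1])) continue;
      seen = true;
      if (eq1(T, tot, hetCountOf(T, g1[p - 1], g2[p - 1]), c)) break;
    }
    if (seen) return fromCand(c, R_2A);
  }
  // 2b: heterozygous child
  {
    Cand c(strict);
    bool seen = false;
    for (int k = P.child_ptr[i]; k < P.child_ptr[i + 1]; k++) {
      int ch = P.child_idx[k];
      if (status[ch - 1] != ST_DONE || !isHet(g1[ch - 1], g2[ch - 1])) continue;
      seen = true;
      if (eq1(T, tot, hetCountOf(T, g1[ch - 1], g2[ch - 1]), c)) break;
    }
    if (seen) return fromCand(c, R_2B);
  }
  // 2c: two full siblings with distinct heterozygous genotypes whose
  // same-type allele pool has cardinality two and whose same-type counts
  // sum to the index total
  {
    Cand c(strict);
    int lo = P.sib_ptr[i], hi = P.sib_ptr[i + 1];
    bool stop = false;
    for (int k = lo; k < hi && !stop; k++) {
      int s1 = P.sib_idx[k];
      if (status[s1 - 1] != ST_DONE || !isHet(g1[s1 - 1], g2[s1 - 1])) continue;
      int m1 = hetCountOf(T, g1[s1 - 1], g2[s1 - 1]);
      for (int l = k + 1; l < hi; l++) {
        int s2 = P.sib_idx[l];
        if (status[s2 - 1] != ST_DONE || !isHet(g1[s2 - 1], g2[s2 - 1])) continue;
        int m2 = hetCountOf(T, g1[s2 - 1], g2[s2 - 1]);
        if (m1 == m2) continue;                 // pool cardinality must be 2
        if (m1 + m2 != tot) continue;           // copy conservation
        if (c.add(mk(T, m1), mk(T, m2))) { stop = true; break; }
      }
    }
    if (c.have || c.conflicted()) return fromCand(c, R_2C);
  }
  return no_res();
}

// ---- type-II rules (homozygous relatives, nuclear family) ----------------

// parent/child carries two identical CN alleles of the index type, or {N,N}
static inline bool ident_same_type(int T, int x, int y) {
  return x == y && (typeOf(x) == T || x == NCODE);
}

static Res try_type2(int i, int T, int tot, const Ped &P,
                     const int *g1, const int *g2, const int *status,
                     bool strict) {
  int fa = P.father[i], mo = P.mother[i];
  int par[2] = { fa, mo };

  // 3a: parent with two identical CN alleles of the index type (or {N,N})
  {
    Cand c(strict); bool seen = false;
    for (int k = 0; k < 2; k++) {
      int p = par[k];
      if (p == 0 || status[p - 1] != ST_DONE) continue;
      if (!ident_same_type(T, g1[p - 1], g2[p - 1])) continue;
      seen = true;
      if (eq1(T, tot, cntOf(g1[p - 1]), c)) break;
    }
    if (seen) return fromCand(c, R_3A);
  }
  // 3b: child with two identical CN alleles of the index type (or {N,N})
  {
    Cand c(strict); bool seen = false;
    for (int k = P.child_ptr[i]; k < P.child_ptr[i + 1]; k++) {
      int ch = P.child_idx[k];
      if (status[ch - 1] != ST_DONE) continue;
      if (!ident_same_type(T, g1[ch - 1], g2[ch - 1])) continue;
      seen = true;
      if (eq1(T, tot, cntOf(g1[ch - 1]), c)) break;
    }
    if (seen) return fromCand(c, R_3B);
  }
  // 3c: one heterozygous sibling plus one sibling homozygous with identical
  // non-null alleles of the opposite type; Eq. (1) with the het sibling
  {
    Cand c(strict); bool seen = false, stop = false;
    int lo = P.sib_ptr[i], hi = P.sib_ptr[i + 1];
    for (int k = lo; k < hi && !stop; k++) {
      int s1 = P.sib_idx[k];
      if (status[s1 - 1] != ST_DONE || !isHet(g1[s1 - 1], g2[s1 - 1])) continue;
      for (int l = lo; l < hi; l++) {
        int s2 = P.sib_idx[l];
        if (s2 == s1 || status[s2 - 1] != ST_DONE) continue;
        int x = g1[s2 - 1], y = g2[s2 - 1];
        if (x != y || x == NCODE || typeOf(x) != 1 - T) continue;
        seen = true;
        if (eq1(T, tot, hetCountOf(T, g1[s1 - 1], g2[s1 - 1]), c)) { stop = true; break; }
      }
    }
    if (seen) return fromCand(c, R_3C);
  }
  // 3d: a child and the co-parent spouse with distinct genotypes sharing
  // exactly one allele; the child's non-shared allele came from the index
  {
    Cand c(strict); bool seen = false;
    for (int k = P.child_ptr[i]; k < P.child_ptr[i + 1]; k++) {
      int ch = P.child_idx[k];
      if (status[ch - 1] != ST_DONE) continue;
      int chf = P.father[ch - 1], chm = P.mother[ch - 1];
      int sp = (chf == i + 1) ? chm : chf;
      if (sp == 0 || status[sp - 1] != ST_DONE) continue;
      int cx = g1[ch - 1], cy = g2[ch - 1];
      int sx = g1[sp - 1], sy = g2[sp - 1];
      if (cx == sx && cy == sy) continue;       // genotypes must be distinct
      // multiset intersection size
      int inter = 0, used_x = 0, used_y = 0;
      if (cx == sx) { inter++; used_x = 1; }
      else if (cx == sy) { inter++; used_y = 1; }
      if ((cy == sx && !used_x) || (cy == sy && !used_y)) inter++;
      if (inter != 1) continue;
      int X;                                     // non-shared child allele
      if (cx == cy) X = cx;
      else X = (cx == sx || cx == sy) ? cy : cx;
      seen = true;
      bool stop;
      if (X == NCODE) stop = c.add(NCODE, mk(T, tot));
      else if (typeOf(X) == T) stop = eq1(T, tot, cntOf(X), c);
      else stop = c.addIncons();                 // wrong allele type for index
      if (stop) break;
    }
    if (seen) return fromCand(c, R_3D);
  }
  // 3e: both parents homozygous of the index type with distinct genotypes
  // (a parent may carry one N); transmission sums decide the assignment.
  // With one parent undefined, the known parent's allele is used when the
  // Fawkes total forces a unique choice.
  if (fa != 0 && mo != 0) {
    int stf = status[fa - 1], stm = status[mo - 1];
    bool okf = stf == ST_DONE && typeOf(g1[fa - 1]) != 1 - T && typeOf(g2[fa - 1]) != 1 - T;
    bool okm = stm == ST_DONE && typeOf(g1[mo - 1]) != 1 - T && typeOf(g2[mo - 1]) != 1 - T;
    if (okf && okm) {
      int m1 = cntOf(g1[fa - 1]), n1 = cntOf(g2[fa - 1]);
      int m2 = cntOf(g1[mo - 1]), n2 = cntOf(g2[mo - 1]);
      bool distinct = !(g1[fa - 1] == g1[mo - 1] && g2[fa - 1] == g2[mo - 1]);
      if (distinct) {
        int s[4] = { m1 + m2, m1 + n2, n1 + m2, n1 + n2 };
        int pa[4] = { m1, m1, n1, n1 }, pb[4] = { m2, n2, m2, n2 };
        int su[4]; std::copy(s, s + 4, su); std::sort(su, su + 4);
        int u = 1;
        for (int k = 1; k < 4; k++) if (su[k] != su[k - 1]) u++;
        int hit = -1, nhit = 0;
        for (int k = 0; k < 4; k++) if (s[k] == tot) { hit = k; nhit++; }
        if (u == 4) {
          if (nhit == 1) return ok_res(mk(T, pa[hit]), mk(T, pb[hit]), R_3E);
        } else if (u == 3) {
          if (hit >= 0 && (tot == su[0] || tot == su[3]))
            return ok_res(mk(T, pa[hit]), mk(T, pb[hit]), R_3E);
        }
        // unmatched total or ambiguous middle sum: not converted here
      }
    } else if (okf != okm) {
      // one parent known, the other undefined in the input
      int p = okf ? fa : mo, o = okf ? mo : fa;
      if (status[o - 1] == ST_UNDEF) {
        int m = cntOf(g1[p - 1]), n = cntOf(g2[p - 1]);
        if (m != n) {                            // equal counts belong to 3a
          int rm = tot - m, rn = tot - n;
          if (rm < 0 && rn < 0) return bad_res(R_3E);
          if (rm >= 0 && rn >= 0) {
            // two Mendelian-consistent partitions: ambiguous
          } else {
            int use = rm >= 0 ? m : n;
            return ok_res(mk(T, use), mk(T, tot - use), R_3E);
          }
        }
      }
    }
  }
  // 3f: both parents homozygous with identical same-type genotypes {Tk1,Tk2}
  if (fa != 0 && mo != 0 && status[fa - 1] == ST_DONE && status[mo - 1] == ST_DONE) {
    int x = g1[fa - 1], y = g2[fa - 1];
    if (x == g1[mo - 1] && y == g2[mo - 1] &&
        typeOf(x) == T && typeOf(y) == T && x != y) {
      int k1 = std::min(cntOf(x), cntOf(y)), k2 = std::max(cntOf(x), cntOf(y));
      if (tot == 2 * k1) return ok_res(mk(T, k1), mk(T, k1), R_3F);
      if (tot == k1 + k2) return ok_res(mk(T, k1), mk(T, k2), R_3F);
      if (tot == 2 * k2) return ok_res(mk(T, k2), mk(T, k2), R_3F);
      return bad_res(R_3F);                      // no transmission sum matches
    }
  }
  // 3g: exactly one parent carries alleles of the index type (possibly one
  // N); converted only when the total equals the minimum typed count
  if (fa != 0 && mo != 0 && status[fa - 1] == ST_DONE && status[mo - 1] == ST_DONE) {
    for (int k = 0; k < 2; k++) {
      int p = par[k], o = par[1 - k];
      int px = g1[p - 1], py = g2[p - 1];
      bool typedP = (typeOf(px) == T || typeOf(py) == T) &&
                    typeOf(px) != 1 - T && typeOf(py) != 1 - T;
      bool otherHasT = typeOf(g1[o - 1]) == T || typeOf(g2[o - 1]) == T;
      if (!typedP || otherHasT) continue;
      int z;
      if (px == NCODE || py == NCODE) z = cntOf(px == NCODE ? py : px);
      else z = std::min(cntOf(px), cntOf(py));
      if (tot == z) return ok_res(mk(T, z), NCODE, R_3G);
      break;                                     // only one parent can qualify
    }
  }
  // 3h: a parent of the form {opposite-type allele, N} transmits its N;
  // the index carries all its copies on the other chromosome
  {
    for (int k = 0; k < 2; k++) {
      int p = par[k];
      if (p == 0 || status[p - 1] != ST_DONE) continue;
      int px = g1[p - 1], py = g2[p - 1];
      bool oppN = (typeOf(px) == 1 - T && py == NCODE) ||
                  (typeOf(py) == 1 - T && px == NCODE);
      if (!oppN) continue;
      int o = par[1 - k];
      if (o != 0 && status[o - 1] == ST_DONE) {
        // trio must respect Mendelian transmission: the other parent has to
        // carry the single allele holding all of the index's copies
        int want = mk(T, tot);
        if (g1[o - 1] != want && g2[o - 1] != want) continue;
      }
      return ok_res(NCODE, mk(T, tot), R_3H);
    }
  }
  return no_res();
}

// ---- per-marker driver ---------------------------------------------------

static void partition_one(const int *a, const int *b, const Ped &P, bool strict,
                          int *g1, int *g2, int *status,
                          int *ruleCount, int *classCount,
                          int *nIncons, int *nPasses) {
  int n = P.n;
  // phase 1: classification and direct conversion
  for (int i = 0; i < n; i++) {
    int ai = a[i], bi = b[i];
    if (ai == -1) {                              // undefined
      classCount[0]++; status[i] = ST_UNDEF; g1[i] = g2[i] = -1;
    } else if (ai != 0 && bi != 0) {             // heterozygous
      classCount[1]++; status[i] = ST_DONE; g1[i] = ai; g2[i] = 1000 + bi;
      ruleCount[R_STEP1]++;
    } else if (ai == 0 && bi == 0) {             // null
      classCount[2]++; status[i] = ST_DONE; g1[i] = g2[i] = NCODE;
      ruleCount[R_STEP1]++;
    } else if (ai + bi == 1) {                   // single hemizygous
      classCount[3]++; status[i] = ST_DONE;
      g1[i] = ai == 1 ? 1 : 1001; g2[i] = NCODE;
      ruleCount[R_STEP1]++;
    } else {                                     // homozygous
      classCount[4]++; status[i] = ST_PENDING; g1[i] = g2[i] = 0;
    }
  }
  // phase 2: one pass of type-I resolution, pedfile order
  for (int i = 0; i < n; i++) {
    if (status[i] != ST_PENDING) continue;
    int T = a[i] > 0 ? 0 : 1, tot = a[i] > 0 ? a[i] : b[i];
    Res r = try_type1(i, T, tot, P, g1, g2, status, strict);
    if (r.code == 1) {
      status[i] = ST_DONE; g1[i] = r.g1; g2[i] = r.g2; ruleCount[r.rule]++;
    } else if (r.code == 2) {
      status[i] = ST_UNRES; g1[i] = g2[i] = -2; (*nIncons)++;
    }
  }
  // phase 3: cycle type-II passes while at least one call is partitioned
  int passes = 0;
  bool progress = true;
  while (progress && passes < n + 1) {
    progress = false; passes++;
    for (int i = 0; i < n; i++) {
      if (status[i] != ST_PENDING) continue;
      int T = a[i] > 0 ? 0 : 1, tot = a[i] > 0 ? a[i] : b[i];
      Res r = try_type2(i, T, tot, P, g1, g2, status, strict);
      if (r.code == 1) {
        status[i] = ST_DONE; g1[i] = r.g1; g2[i] = r.g2; ruleCount[r.rule]++;
        progress = true;
      } else if (r.code == 2) {
        status[i] = ST_UNRES; g1[i] = g2[i] = -2; (*nIncons)++;
      }
    }
  }
  *nPasses = passes;
  // fixpoint: whatever is left cannot be partitioned
  for (int i = 0; i < n; i++) {
    if (status[i] == ST_PENDING) { status[i] = ST_UNRES; g1[i] = g2[i] = -2; }
  }
}

static Ped make_ped(const List &idx) {
  Ped P;
  P.n = as<IntegerVector>(idx["father"]).size();
  P.father = INTEGER(as<SEXP>(idx["father"]));
  P.mother = INTEGER(as<SEXP>(idx["mother"]));
  P.child_ptr = INTEGER(as<SEXP>(idx["child_ptr"]));
  P.child_idx = INTEGER(as<SEXP>(idx["child_idx"]));
  P.sib_ptr = INTEGER(as<SEXP>(idx["sib_ptr"]));
  P.sib_idx = INTEGER(as<SEXP>(idx["sib_idx"]));
  return P;
}

// [[Rcpp::export(name = ".cpp_partition_batch")]]
List cpp_partition_batch(IntegerMatrix A, IntegerMatrix B, List pedidx,
                         bool strict) {
  Ped P = make_ped(pedidx);
  int n = A.nrow(), m = A.ncol();
  if (n != P.n) stop("call matrix does not match pedigree size");
  IntegerMatrix G1(n, m), G2(n, m), RC(N_RULES, m), CC(5, m);
  IntegerVector incons(m), passes(m);
  std::vector<int> status(n);
  for (int j = 0; j < m; j++) {
    int ni = 0, np = 0;
    partition_one(&A(0, j), &B(0, j), P, strict,
                  &G1(0, j), &G2(0, j), status.data(),
                  &RC(0, j), &CC(0, j), &ni, &np);
    incons[j] = ni; passes[j] = np;
  }
  return List::create(_["g1"] = G1, _["g2"] = G2, _["ruleCounts"] = RC,
                      _["classCounts"] = CC, _["inconsistencies"] = incons,
                      _["passes"] = passes);
}

// Single-rule entry points used by tryType1()/tryType2(): the caller
// supplies a fully prepared context (genotype codes and statuses for every
// pedigree member) and the 1-based position of the index individual.
// [[Rcpp::export(name = ".cpp_try_rules")]]
List cpp_try_rules(int stage, int a, int b, List pedidx,
                   IntegerVector g1, IntegerVector g2, IntegerVector status,
                   int index, bool strict) {
  Ped P = make_ped(pedidx);
  int i = index - 1;
  int T = a > 0 ? 0 : 1, tot = a > 0 ? a : b;
  Res r = (stage == 1)
    ? try_type1(i, T, tot, P, g1.begin(), g2.begin(), status.begin(), strict)
    : try_type2(i, T, tot, P, g1.begin(), g2.begin(), status.begin(), strict);
  return List::create(_["code"] = r.code, _["g1"] = r.g1, _["g2"] = r.g2,
                      _["rule"] = r.rule);
}

// ---- nuclear-family Mendelian consistency checker ------------------------

static inline bool inPair(int x, int p1, int p2) { return x == p1 || x == p2; }
static inline bool isSentinel(int g) { return g < 0; }

// children: arrays of (cx, cy) for non-sentinel children only; genotypes
// searched for unknown parents are capped at maxTotal copies (<= 0: no cap)
static bool fam_consistent(int f1, int f2, bool fknown,
                           int m1, int m2, bool mknown,
                           const std::vector<int> &cx,
                           const std::vector<int> &cy, int maxTotal) {
  const bool cap = maxTotal > 0;
  size_t k = cx.size();
  if (k == 0) return true;
  if (fknown && mknown) {
    for (size_t c = 0; c < k; c++) {
      bool ok = (inPair(cx[c], f1, f2) && inPair(cy[c], m1, m2)) ||
                (inPair(cy[c], f1, f2) && inPair(cx[c], m1, m2));
      if (!ok) return false;
    }
    return true;
  }
  // candidate alleles for unknown parents can be restricted to alleles
  // observed in the children (any allele a parent transmits is seen there)
  std::vector<int> cand;
  for (size_t c = 0; c < k; c++) {
    cand.push_back(cx[c]); cand.push_back(cy[c]);
  }
  cand.push_back(NCODE);     // the untransmitted slot may always be empty
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  size_t nc = cand.size();
  if (fknown != mknown) {
    // exactly one wildcard parent: each child constrains which allele it
    // needs from the wildcard side; find a pair covering all children
    int p1 = fknown ? f1 : m1, p2 = fknown ? f2 : m2;
    std::vector<int> optA(k, -9), optB(k, -9);
    for (size_t c = 0; c < k; c++) {
      int nopt = 0;
      if (inPair(cy[c], p1, p2)) optA[c] = cx[c], nopt++;
      if (inPair(cx[c], p1, p2)) { (nopt ? optB[c] : optA[c]) = cy[c]; nopt++; }
      if (nopt == 0) return false;     // known parent cannot serve this child
    }
    for (size_t u = 0; u < nc; u++)
      for (size_t v = u; v < nc; v++) {
        if (cap && cntOf(cand[u]) + cntOf(cand[v]) > maxTotal) continue;
        bool all = true;
        for (size_t c = 0; c < k && all; c++)
          all = inPair(optA[c], cand[u], cand[v]) ||
                inPair(optB[c], cand[u], cand[v]);
        if (all) return true;
      }
    return false;
  }
  // both parents wildcard: enumerate genotypes for both from the candidates
  for (size_t u = 0; u < nc; u++)
    for (size_t v = u; v < nc; v++) {
      if (cap && cntOf(cand[u]) + cntOf(cand[v]) > maxTotal) continue;
      for (size_t s = 0; s < nc; s++)
        for (size_t t = s; t < nc; t++) {
          if (cap && cntOf(cand[s]) + cntOf(cand[t]) > maxTotal) continue;
          bool all = true;
          for (size_t c = 0; c < k && all; c++)
            all = (inPair(cx[c], cand[u], cand[v]) && inPair(cy[c], cand[s], cand[t])) ||
                  (inPair(cy[c], cand[u], cand[v]) && inPair(cx[c], cand[s], cand[t]));
          if (all) return true;
        }
    }
  return false;
}

// [[Rcpp::export(name = ".cpp_check_batch")]]
LogicalMatrix cpp_check_batch(IntegerMatrix G1, IntegerMatrix G2,
                              IntegerVector famFather, IntegerVector famMother,
                              IntegerVector childPtr, IntegerVector childIdx,
                              int maxTotal) {
  int m = G1.ncol(), nf = famFather.size();
  LogicalMatrix fail(nf, m);
  std::vector<int> cx, cy;
  for (int j = 0; j < m; j++) {
    for (int f = 0; f < nf; f++) {
      int fa = famFather[f] - 1, mo = famMother[f] - 1;
      bool fknown = !isSentinel(G1(fa, j));
      bool mknown = !isSentinel(G1(mo, j));
      cx.clear(); cy.clear();
      for (int k = childPtr[f]; k < childPtr[f + 1]; k++) {
        int ch = childIdx[k] - 1;
        if (isSentinel(G1(ch, j))) continue;
        cx.push_back(G1(ch, j)); cy.push_back(G2(ch, j));
      }
      fail(f, j) = !fam_consistent(G1(fa, j), G2(fa, j), fknown,
                                   G1(mo, j), G2(mo, j), mknown, cx, cy,
                                   maxTotal);
    }
  }
  return fail;
}
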