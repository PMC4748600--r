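// Affine-gap alignment engines: scalar reference and lane-emulated vector
// variants (striped with lazy-F, prefix scan, anti-diagonal), all sharing the
// same recurrences:
//   S[i,j] = T[i-1,j-1] + score(q_i, d_j)
//   D[i,j] = max(T[i-1,j] - open - extend, D[i-1,j] - extend)   (gap in db)
//   I[i,j] = max(T[i,j-1] - open - extend, I[i,j-1] - extend)   (gap in query)
//   T[i,j] = max(S, D, I), clamped at 0 for local (SW) alignment.
// NW boundaries follow the gap function -(open + k*extend); SG/SW boundaries
// are zero. Vector engines run in a fixed-width saturating integer domain;
// local 8-bit mode shifts the origin to the unsigned range [0, 255].

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef int64_t i64;
static const i64 BIG = (i64)1 << 61;

// cls codes: 0 = nw (global), 1 = sg (semi-global), 2 = sw (local)

struct Dom {
  i64 lo, hi;
  bool exact; // reference domain: no clamping
};

static inline i64 clampv(i64 x, const Dom& dm) {
  if (dm.exact) return x;
  if (x < dm.lo) return dm.lo;
  if (x > dm.hi) return dm.hi;
  return x;
}
static inline i64 satadd(i64 a, i64 b, const Dom& dm) { return clampv(a + b, dm); }
static inline i64 satsub(i64 a, i64 b, const Dom& dm) { return clampv(a - b, dm); }

static Dom make_dom(int width, bool biased, bool exact) {
  Dom dm;
  dm.exact = exact;
  if (exact) { dm.lo = -BIG; dm.hi = BIG; return dm; }
  if (biased) {
    // origin shift: the signed floor+1 is treated as zero, giving the full
    // unsigned range; the ceiling is reserved for overflow detection
    dm.lo = 0;
    dm.hi = ((i64)1 << width) - 1;
  } else {
    dm.lo = -((i64)1 << (width - 1));
    dm.hi = ((i64)1 << (width - 1)) - 1;
  }
  return dm;
}

struct Outcome { i64 score; int ei, ej; };
struct Stats { i64 mt, sm, ln; };

struct EngineOut {
  std::vector<i64> T;  // interior table, column-major: T[i + j*m], 0-based
  bool saturated;
  long corrective;     // lazy-F wrap-around passes (striped), summed
  long max_corrective; // worst single column
  long sweeps;         // column sweeps (scan: exactly 2 per column)
  Outcome oc;
  bool oc_set;
};

// NW boundary value at offset k (also 0 for SG/SW); flags the run as
// saturated when the exact boundary is unrepresentable in the domain
static inline i64 bnd_clamped(int cls, i64 k, i64 open, i64 ext,
                              const Dom& dm, bool* sat) {
  if (cls != 0 || k == 0) return clampv(0, dm);
  i64 v = -(open + k * ext);
  i64 cv = clampv(v, dm);
  if (cv != v) *sat = true;
  return cv;
}

// ---------------------------------------------------------------------------
// scalar reference table (exact 64-bit arithmetic)
// ---------------------------------------------------------------------------
static void ref_table(int cls, const std::vector<int>& q, const std::vector<int>& d,
                      const std::vector<int>& smat, int K, i64 open, i64 ext,
                      std::vector<i64>& T) {
  int m = (int)q.size(), n = (int)d.size();
  std::vector<i64> prevT(m + 1), curT(m + 1), Istate(m + 1, -BIG);
  for (int i = 0; i <= m; ++i)
    prevT[i] = (cls == 0 && i > 0) ? -(open + (i64)i * ext) : 0;
  for (int j = 1; j <= n; ++j) {
    curT[0] = (cls == 0) ? -(open + (i64)j * ext) : 0;
    i64 Dstate = -BIG;
    for (int i = 1; i <= m; ++i) {
      i64 S = prevT[i - 1] + smat[(size_t)q[i - 1] * K + d[j - 1]];
      Dstate = std::max(curT[i - 1] - open - ext, Dstate - ext);
      Istate[i] = std::max(prevT[i] - open - ext, Istate[i] - ext);
      i64 t = std::max(S, std::max(Dstate, Istate[i]));
      if (cls == 2 && t < 0) t = 0;
      curT[i] = t;
      T[(size_t)(i - 1) + (size_t)(j - 1) * m] = t;
    }
    std::swap(prevT, curT);
  }
}

// ---------------------------------------------------------------------------
// final score + end cell under the deterministic tie-break:
// smallest end_ref, then smallest end_query
// ---------------------------------------------------------------------------
static Outcome finalize_ends(int cls, const std::vector<i64>& T, int m, int n,
                             i64 open, i64 ext) {
  Outcome o;
  if (m == 0 || n == 0) {
    if (cls == 0) {
      int len = (m == 0) ? n : m;
      o.score = (len == 0) ? 0 : -(open + (i64)len * ext);
      o.ei = m - 1; o.ej = n - 1;
    } else {
      o.score = 0; o.ei = -1; o.ej = -1;
    }
    return o;
  }
  if (cls == 0) {
    o.score = T[(size_t)(m - 1) + (size_t)(n - 1) * m];
    o.ei = m - 1; o.ej = n - 1;
    return o;
  }
  o.score = -BIG; o.ei = -1; o.ej = -1;
  if (cls == 2) {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i) {
        i64 v = T[(size_t)i + (size_t)j * m];
        if (v > o.score) { o.score = v; o.ei = i; o.ej = j; }
      }
    return o;
  }
  // sg: maximum over last row and last column
  for (int j = 0; j < n; ++j) {
    if (j < n - 1) {
      i64 v = T[(size_t)(m - 1) + (size_t)j * m];
      if (v > o.score) { o.score = v; o.ei = m - 1; o.ej = j; }
    } else {
      for (int i = 0; i < m; ++i) {
        i64 v = T[(size_t)i + (size_t)j * m];
        if (v > o.score) { o.score = v; o.ei = i; o.ej = j; }
      }
    }
  }
  return o;
}

// ---------------------------------------------------------------------------
// alignment statistics along the tie-broken optimal path, derived from the
// converged T table by an auxiliary DP that mirrors the maximizing branch
// (precedence S, then D, then I; gap-open preferred over gap-extend on ties)
// ---------------------------------------------------------------------------
static Stats derive_stats(int cls, const std::vector<i64>& T, int m, int n,
                          const std::vector<int>& q, const std::vector<int>& d,
                          const std::vector<int>& smat, int K,
                          i64 open, i64 ext, int ei, int ej) {
  Stats zero; zero.mt = 0; zero.sm = 0; zero.ln = 0;
  if (ei < 0 || ej < 0) {
    if (cls == 0) { Stats s; s.mt = 0; s.sm = 0; s.ln = std::max(m, n); return s; }
    return zero;
  }
  std::vector<Stats> tPrev(m + 1), tCur(m + 1), iComp(m + 1, zero);
  std::vector<i64> prevT(m + 1), curT(m + 1), iVal(m + 1, -BIG);
  for (int i = 0; i <= m; ++i) {
    prevT[i] = (cls == 0 && i > 0) ? -(open + (i64)i * ext) : 0;
    tPrev[i] = zero;
    if (cls == 0) tPrev[i].ln = i;
  }
  Stats result = zero;
  for (int j = 1; j <= n; ++j) {
    curT[0] = (cls == 0) ? -(open + (i64)j * ext) : 0;
    tCur[0] = zero;
    if (cls == 0) tCur[0].ln = j;
    i64 dVal = -BIG;
    Stats dComp = zero;
    for (int i = 1; i <= m; ++i) {
      int sub = smat[(size_t)q[i - 1] * K + d[j - 1]];
      i64 S = prevT[i - 1] + sub;
      Stats sComp;
      sComp.mt = tPrev[i - 1].mt + (q[i - 1] == d[j - 1] ? 1 : 0);
      sComp.sm = tPrev[i - 1].sm + (sub > 0 ? 1 : 0);
      sComp.ln = tPrev[i - 1].ln + 1;
      i64 dOpen = curT[i - 1] - open - ext;
      if (dOpen >= dVal - ext) {
        dVal = dOpen;
        dComp = tCur[i - 1]; dComp.ln += 1;
      } else {
        dVal = dVal - ext; dComp.ln += 1;
      }
      i64 iOpen = prevT[i] - open - ext;
      if (iOpen >= iVal[i] - ext) {
        iVal[i] = iOpen;
        iComp[i] = tPrev[i]; iComp[i].ln += 1;
      } else {
        iVal[i] = iVal[i] - ext; iComp[i].ln += 1;
      }
      i64 t = T[(size_t)(i - 1) + (size_t)(j - 1) * m];
      curT[i] = t;
      Stats chosen;
      if (t == S) chosen = sComp;
      else if (t == dVal) chosen = dComp;
      else if (t == iVal[i]) chosen = iComp[i];
      else chosen = zero; // SW restart at a clamped zero
      tCur[i] = chosen;
      if (i - 1 == ei && j - 1 == ej) result = chosen;
    }
    std::swap(prevT, curT);
    std::swap(tPrev, tCur);
  }
  return result;
}

// ---------------------------------------------------------------------------
// striped query profile: lane l of segment word k holds query position
// k + l*t, t = ceil(m/lanes); padding slots hold the domain floor so a padded
// lane can never win a maximum
// ---------------------------------------------------------------------------
static void build_profile_vec(const std::vector<int>& q, const std::vector<int>& smat,
                              int K, int lanes, const Dom& dm, std::vector<i64>& P) {
  int m = (int)q.size();
  int t = (m + lanes - 1) / lanes;
  size_t W = (size_t)t * lanes;
  P.assign((size_t)K * W, dm.lo);
  for (int c = 0; c < K; ++c)
    for (int k = 0; k < t; ++k)
      for (int l = 0; l < lanes; ++l) {
        int p = k + l * t;
        if (p < m)
          P[(size_t)c * W + (size_t)k * lanes + l] = smat[(size_t)q[p] * K + c];
      }
}

// [[Rcpp::export]]
NumericMatrix cpp_build_profile(IntegerVector q_, IntegerMatrix smat_,
                                int lanes, int width, bool biased) {
  std::vector<int> q(q_.begin(), q_.end());
  int K = smat_.nrow();
  std::vector<int> smat((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smat[(size_t)i * K + j] = smat_(i, j);
  Dom dm = make_dom(width, biased, false);
  std::vector<i64> P;
  build_profile_vec(q, smat, K, lanes, dm, P);
  int m = (int)q.size();
  int t = (m + lanes - 1) / lanes;
  NumericMatrix out(K, t * lanes);
  for (int c = 0; c < K; ++c)
    for (int w = 0; w < t * lanes; ++w)
      out(c, w) = (double)P[(size_t)c * (t * lanes) + w];
  return out;
}

// ---------------------------------------------------------------------------
// striped engine (Farrar layout, lazy-F corrective loop, pointer-swapped
// auxiliary maximum column for local alignment)
// ---------------------------------------------------------------------------
static void striped_engine(int cls, const std::vector<int>& q, const std::vector<int>& d,
                           const std::vector<int>& smat, int K, i64 open, i64 ext,
                           int width, int lanes, bool biased, EngineOut& out) {
  int m = (int)q.size(), n = (int)d.size();
  Dom dm = make_dom(width, biased, false);
  int t = (m + lanes - 1) / lanes;
  size_t W = (size_t)t * lanes;
  i64 oe = open + ext;
  std::vector<i64> P;
  build_profile_vec(q, smat, K, lanes, dm, P);

  std::vector<i64> Hload(W), Hstore(W), E(W, dm.lo);
  std::vector<i64> vH(lanes), vF(lanes);
  for (int k = 0; k < t; ++k)
    for (int l = 0; l < lanes; ++l) {
      int p = k + l * t;
      if (p < m) {
        i64 b = bnd_clamped(cls, p + 1, open, ext, dm, &out.saturated);
        Hload[(size_t)k * lanes + l] = b;
        // gap opened from the boundary column: I(i, 1) = T(i, 0) - open - ext
        E[(size_t)k * lanes + l] = satsub(b, oe, dm);
      } else {
        Hload[(size_t)k * lanes + l] = dm.lo;
      }
    }

  std::vector<i64> maxcol(m), curcol(m);
  i64 best = -BIG;
  int bestj = -1;

  for (int c = 0; c < n; ++c) {
    const i64* Pc = &P[(size_t)d[c] * W];
    // shift the previous column's last segment word up one lane; the vacated
    // lane receives the row-0 boundary of the previous column
    for (int l = lanes - 1; l >= 1; --l)
      vH[l] = Hload[(size_t)(t - 1) * lanes + (l - 1)];
    vH[0] = bnd_clamped(cls, c, open, ext, dm, &out.saturated);
    for (int l = 0; l < lanes; ++l) vF[l] = dm.lo;
    vF[0] = satsub(bnd_clamped(cls, c + 1, open, ext, dm, &out.saturated), oe, dm);

    for (int k = 0; k < t; ++k) {
      size_t idx = (size_t)k * lanes;
      for (int l = 0; l < lanes; ++l) {
        i64 h = satadd(vH[l], Pc[idx + l], dm);
        if (E[idx + l] > h) h = E[idx + l];
        if (vF[l] > h) h = vF[l];
        if (cls == 2 && !biased && h < 0) h = 0;
        Hstore[idx + l] = h;
        E[idx + l] = std::max(satsub(h, oe, dm), satsub(E[idx + l], ext, dm));
        vF[l] = std::max(satsub(h, oe, dm), satsub(vF[l], ext, dm));
        vH[l] = Hload[idx + l];
      }
    }

    // lazy-F: re-inject the vertical-gap contribution across lane boundaries
    // until no retained value can change; early exit per segment word
    for (int l = lanes - 1; l >= 1; --l) vF[l] = vF[l - 1];
    vF[0] = dm.lo;
    int k = 0;
    long wraps = 0;
    while (true) {
      size_t idx = (size_t)k * lanes;
      bool any = false;
      for (int l = 0; l < lanes; ++l)
        if (vF[l] > satsub(Hstore[idx + l], oe, dm)) { any = true; break; }
      if (!any) break;
      for (int l = 0; l < lanes; ++l) {
        if (vF[l] > Hstore[idx + l]) Hstore[idx + l] = vF[l];
        i64 cand = satsub(Hstore[idx + l], oe, dm);
        if (cand > E[idx + l]) E[idx + l] = cand;
        vF[l] = satsub(vF[l], ext, dm);
      }
      if (++k == t) {
        k = 0;
        for (int l = lanes - 1; l >= 1; --l) vF[l] = vF[l - 1];
        vF[0] = dm.lo;
        if (++wraps > lanes) break; // cannot happen: lanes shifts drain vF
      }
    }
    out.corrective += wraps;
    if (wraps > out.max_corrective) out.max_corrective = wraps;
    out.sweeps += 1;

    for (int p = 0; p < m; ++p) {
      i64 v = Hstore[(size_t)(p % t) * lanes + (p / t)];
      out.T[(size_t)p + (size_t)c * m] = v;
      curcol[p] = v;
      if (v == dm.hi) out.saturated = true;
      if (cls != 2 && v == dm.lo) out.saturated = true;
    }
    if (cls == 2) {
      i64 colmax = -BIG;
      for (int p = 0; p < m; ++p) if (curcol[p] > colmax) colmax = curcol[p];
      if (colmax > best) {
        best = colmax; bestj = c;
        std::swap(maxcol, curcol); // pointer swap, not a copy
      }
    }
    std::swap(Hload, Hstore);
  }

  if (cls == 2 && m > 0 && n > 0) {
    int bi = 0;
    for (int p = 0; p < m; ++p) if (maxcol[p] == best) { bi = p; break; }
    out.oc.score = best; out.oc.ei = bi; out.oc.ej = bestj;
    out.oc_set = true;
  }
}

// ---------------------------------------------------------------------------
// prefix-scan engine: each column is swept exactly twice — a tentative pass
// ignoring the within-column vertical dependency, then a weighted prefix-max
// propagation of the vertical gap state
// ---------------------------------------------------------------------------
static void scan_engine(int cls, const std::vector<int>& q, const std::vector<int>& d,
                        const std::vector<int>& smat, int K, i64 open, i64 ext,
                        int width, int lanes, bool biased, EngineOut& out) {
  int m = (int)q.size(), n = (int)d.size();
  Dom dm = make_dom(width, biased, false);
  int t = (m + lanes - 1) / lanes;
  size_t W = (size_t)t * lanes;
  i64 oe = open + ext;
  std::vector<i64> P;
  build_profile_vec(q, smat, K, lanes, dm, P);

  std::vector<i64> Hprev(m), Hcur(m), Htent(m), Estate(m, dm.lo);
  for (int p = 0; p < m; ++p)
    Hprev[p] = bnd_clamped(cls, p + 1, open, ext, dm, &out.saturated);

  for (int c = 0; c < n; ++c) {
    const i64* Pc = &P[(size_t)d[c] * W];
    i64 bnd_prev = bnd_clamped(cls, c, open, ext, dm, &out.saturated);
    // sweep 1: tentative scores max(S, I) per lane/segment word
    out.sweeps += 1;
    for (int k = 0; k < t; ++k)
      for (int l = 0; l < lanes; ++l) {
        int p = k + l * t;
        if (p >= m) continue;
        i64 diag = (p == 0) ? bnd_prev : Hprev[p - 1];
        i64 S = satadd(diag, Pc[(size_t)k * lanes + l], dm);
        i64 e2 = std::max(satsub(Hprev[p], oe, dm), satsub(Estate[p], ext, dm));
        Estate[p] = e2;
        i64 h = std::max(S, e2);
        if (cls == 2 && !biased && h < 0) h = 0;
        Htent[p] = h;
      }
    // sweep 2: weighted prefix-max propagation of the vertical gap
    out.sweeps += 1;
    i64 F = satsub(bnd_clamped(cls, c + 1, open, ext, dm, &out.saturated), oe, dm);
    for (int p = 0; p < m; ++p) {
      i64 h = std::max(Htent[p], F);
      if (cls == 2 && !biased && h < 0) h = 0;
      Hcur[p] = h;
      out.T[(size_t)p + (size_t)c * m] = h;
      if (h == dm.hi) out.saturated = true;
      if (cls != 2 && h == dm.lo) out.saturated = true;
      F = std::max(satsub(F, ext, dm), satsub(h, oe, dm));
    }
    std::swap(Hprev, Hcur);
  }
}

// ---------------------------------------------------------------------------
// anti-diagonal wavefront engine: lanes span cells of one anti-diagonal; the
// lane count only chunks the wavefront and cannot change results
// ---------------------------------------------------------------------------
static void diag_engine(int cls, const std::vector<int>& q, const std::vector<int>& d,
                        const std::vector<int>& smat, int K, i64 open, i64 ext,
                        int width, int lanes, bool biased, EngineOut& out) {
  int m = (int)q.size(), n = (int)d.size();
  Dom dm = make_dom(width, biased, false);
  i64 oe = open + ext;
  std::vector<i64> T2(m + 1, dm.lo), T1(m + 1, dm.lo), Tc(m + 1, dm.lo);
  std::vector<i64> D1(m + 1, dm.lo), Dc(m + 1, dm.lo);
  std::vector<i64> I1(m + 1, dm.lo), Ic(m + 1, dm.lo);

  for (int s = 2; s <= m + n; ++s) {
    int ilo = std::max(1, s - n), ihi = std::min(m, s - 1);
    for (int ic = ilo; ic <= ihi; ic += lanes) {
      int iend = std::min(ihi, ic + lanes - 1); // one emulated vector op
      for (int i = ic; i <= iend; ++i) {
        int j = s - i;
        i64 diagT = (i - 1 == 0 || j - 1 == 0)
          ? bnd_clamped(cls, std::max(i - 1, j - 1), open, ext, dm, &out.saturated)
          : T2[i - 1];
        i64 upT = (i - 1 == 0)
          ? bnd_clamped(cls, j, open, ext, dm, &out.saturated) : T1[i - 1];
        i64 upD = (i - 1 == 0) ? dm.lo : D1[i - 1];
        i64 leftT = (j - 1 == 0)
          ? bnd_clamped(cls, i, open, ext, dm, &out.saturated) : T1[i];
        i64 leftI = (j - 1 == 0) ? dm.lo : I1[i];
        i64 S = satadd(diagT, smat[(size_t)q[i - 1] * K + d[j - 1]], dm);
        i64 Dv = std::max(satsub(upT, oe, dm), satsub(upD, ext, dm));
        i64 Iv = std::max(satsub(leftT, oe, dm), satsub(leftI, ext, dm));
        i64 h = std::max(S, std::max(Dv, Iv));
        if (cls == 2 && !biased && h < 0) h = 0;
        Tc[i] = h; Dc[i] = Dv; Ic[i] = Iv;
        out.T[(size_t)(i - 1) + (size_t)(j - 1) * m] = h;
        if (h == dm.hi) out.saturated = true;
        if (cls != 2 && h == dm.lo) out.saturated = true;
      }
    }
    std::swap(T2, T1); std::swap(T1, Tc);
    std::swap(D1, Dc); std::swap(I1, Ic);
    out.sweeps += 1;
  }
}

// ---------------------------------------------------------------------------
// shared entry point
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align(std::string engine, int cls, IntegerVector q_, IntegerVector d_,
               IntegerMatrix smat_, int gap_open, int gap_extend,
               int width, int lanes, bool bias,
               bool want_stats, bool want_table, bool want_rowcol) {
  std::vector<int> q(q_.begin(), q_.end()), d(d_.begin(), d_.end());
  int K = smat_.nrow();
  std::vector<int> smat((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) smat[(size_t)i * K + j] = smat_(i, j);
  int m = (int)q.size(), n = (int)d.size();
  i64 open = gap_open, ext = gap_extend;

  EngineOut out;
  out.saturated = false; out.corrective = 0; out.max_corrective = 0;
  out.sweeps = 0; out.oc_set = false;
  out.T.assign((size_t)m * n, 0);

  bool degenerate = (m == 0 || n == 0);
  if (engine == "reference" || degenerate) {
    if (!degenerate) ref_table(cls, q, d, smat, K, open, ext, out.T);
  } else if (engine == "striped") {
    striped_engine(cls, q, d, smat, K, open, ext, width, lanes, bias, out);
  } else if (engine == "scan") {
    scan_engine(cls, q, d, smat, K, open, ext, width, lanes, bias, out);
  } else if (engine == "diag") {
    diag_engine(cls, q, d, smat, K, open, ext, width, lanes, bias, out);
  } else {
    stop("unknown engine '%s'", engine.c_str());
  }

  Outcome oc = out.oc_set ? out.oc : finalize_ends(cls, out.T, m, n, open, ext);

  List res = List::create(
    _["score"] = (double)oc.score,
    _["end_query"] = oc.ei,
    _["end_ref"] = oc.ej,
    _["saturated"] = out.saturated,
    _["corrective_passes"] = (double)out.corrective,
    _["max_corrective"] = (double)out.max_corrective,
    _["sweeps"] = (double)out.sweeps,
    _["columns"] = n);

  if (want_stats) {
    Stats st = derive_stats(cls, out.T, m, n, q, d, smat, K, open, ext, oc.ei, oc.ej);
    res["matches"] = (double)st.mt;
    res["similar"] = (double)st.sm;
    res["length"] = (double)st.ln;
  }
  if (want_table) {
    IntegerMatrix tb(m, n);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < m; ++i)
        tb(i, j) = (int)out.T[(size_t)i + (size_t)j * m];
    res["table"] = tb;
  }
  if (want_rowcol) {
    IntegerVector lr(n), lc(m);
    if (m > 0)
      for (int j = 0; j < n; ++j) lr[j] = (int)out.T[(size_t)(m - 1) + (size_t)j * m];
    if (n > 0)
      for (int i = 0; i < m; ++i) lc[i] = (int)out.T[(size_t)i + (size_t)(n - 1) * m];
    res["last_row"] = lr;
    res["last_col"] = lc;
  }
  return res;
}

// ---------------------------------------------------------------------------
// enhanced suffix array over a sentinel-joined set of encoded sequences
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_esa_build(List seqs_) {
  int nseq = seqs_.size();
  if (nseq < 1) stop("cannot index an empty sequence list");
  std::vector<int> txt, origin;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector v = seqs_[s];
    for (int i = 0; i < v.size(); ++i) { txt.push_back(v[i]); origin.push_back(s); }
    txt.push_back(-(s + 1)); // distinct terminator per sequence
    origin.push_back(s);
  }
  int N = (int)txt.size();
  std::vector<int> sa(N);
  for (int i = 0; i < N; ++i) sa[i] = i;
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    while (a < N && b < N) {
      if (txt[a] != txt[b]) return txt[a] < txt[b];
      ++a; ++b;
    }
    return a > b; // shorter suffix (reaches end first) sorts first; unreachable
                  // in practice because terminators are distinct
  });
  std::vector<int> lcp(N, 0);
  for (int i = 1; i < N; ++i) {
    int a = sa[i - 1], b = sa[i], l = 0;
    while (a + l < N && b + l < N && txt[a + l] == txt[b + l] && txt[a + l] >= 0)
      ++l;
    lcp[i] = l;
  }
  IntegerVector sa_r(N), lcp_r(N), org_r(N);
  for (int i = 0; i < N; ++i) {
    sa_r[i] = sa[i];
    lcp_r[i] = lcp[i];
    org_r[i] = origin[sa[i]];
  }
  return List::create(_["sa"] = sa_r, _["lcp"] = lcp_r, _["origin"] = org_r,
                      _["n"] = N);
}

// longest substring shared by the sequences with the two given origin ids:
// maximum over suffix pairs from the two origins of the minimum LCP between
// them, computed in one scan over the suffix array
// [[Rcpp::export]]
int cpp_esa_lcs(IntegerVector lcp, IntegerVector origin, int a, int b) {
  int N = lcp.size();
  long runA = -1, runB = -1; // min LCP since the last a-/b-origin suffix
  long best = 0;
  for (int i = 0; i < N; ++i) {
    if (i > 0) {
      if (runA >= 0) runA = std::min(runA, (long)lcp[i]);
      if (runB >= 0) runB = std::min(runB, (long)lcp[i]);
    }
    if (origin[i] == a) {
      if (runB > best) best = runB;
      runA = (long)1 << 30;
    }
    if (origin[i] == b) {
      if (runA > best) best = runA;
      runB = (long)1 << 30;
    }
  }
  return (int)best;
}
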