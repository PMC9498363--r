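// Seed-and-extend local aligner for organelle-vs-nuclear homology search.
//
// Three entry points:
//   cpp_search_pair  - full search of one query strand against one subject:
//                      exact k-mer seeding, per-diagonal coverage skipping,
//                      gapped x-drop extension in both directions.
//   cpp_extend_seed  - single-seed extension (exposed for unit testing).
//   cpp_align_stats  - banded global alignment (Gotoh, affine gaps) with
//                      traceback, used to rescore a hit's clipped spans and
//                      obtain match/mismatch/gap-column counts for percent
//                      identity.
//
// Conventions: all coordinates 0-based half-open; a gap of length L costs
// gap_open + L * gap_extend (both stored as positive penalties here).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG = -1000000000;

static inline int dec_pen(int v, int p) { return v <= NEG / 2 ? NEG : v - p; }

static inline uint8_t enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return 4;  // N or anything else: never matches
}

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

struct Ext { long di, dj; int score; };

// One-directional gapped x-drop extension.  Q/S are strided views: element t
// is Q[t*qstride]; qn/sn are how many bases remain in that direction.  DP is
// row-per-query-base with a live column window; cells whose best score falls
// more than x_drop below the running maximum are pruned.
static Ext xdrop_dir(const uint8_t* Q, long qn, long qstride,
                     const uint8_t* S, long sn, long sstride,
                     int ma, int mi, int go, int ge, int X) {
  int best = 0;
  long bi = 0, bj = 0;
  if (qn < 0) qn = 0;
  if (sn < 0) sn = 0;

  long lo = 0, hi = 0;
  std::vector<int> H, E, F;
  H.push_back(0); E.push_back(NEG); F.push_back(NEG);
  {  // row 0: gap-in-query chain to the right
    int e = -(go + ge);
    long j = 1;
    while (j <= sn && e >= best - X) {
      H.push_back(e); E.push_back(e); F.push_back(NEG);
      hi = j; e -= ge; ++j;
    }
  }

  std::vector<int> Hn, En, Fn;
  for (long i = 1; i <= qn; ++i) {
    Hn.clear(); En.clear(); Fn.clear();
    long startj = lo, nlo = -1, nhi = -1;
    uint8_t qc = Q[(i - 1) * qstride];
    for (long j = startj; j <= sn; ++j) {
      int diagH = NEG, upH = NEG, upF = NEG, leftH = NEG, leftE = NEG;
      if (j - 1 >= lo && j - 1 <= hi) diagH = H[j - 1 - lo];
      if (j >= lo && j <= hi) { upH = H[j - lo]; upF = F[j - lo]; }
      if (j - 1 >= startj && (j - 1 - startj) < (long)Hn.size()) {
        leftH = Hn[j - 1 - startj]; leftE = En[j - 1 - startj];
      }
      int e = std::max(dec_pen(leftH, go + ge), dec_pen(leftE, ge));
      int f = std::max(dec_pen(upH, go + ge), dec_pen(upF, ge));
      int m = NEG;
      if (diagH > NEG / 2 && j >= 1) {
        uint8_t sc = S[(j - 1) * sstride];
        m = diagH + ((qc < 4 && sc < 4 && qc == sc) ? ma : mi);
      }
      int h = std::max(m, std::max(e, f));
      bool live = (h > NEG / 2) && (h >= best - X);
      if (!live) { h = NEG; e = NEG; f = NEG; }
      else {
        if (h > best) { best = h; bi = i; bj = j; }
        if (nlo == -1) nlo = j;
        nhi = j;
      }
      Hn.push_back(h); En.push_back(e); Fn.push_back(f);
      // beyond the previous row's window only the in-row gap chain can feed
      // further cells; once it dies the rest of the row is dead
      if (j > hi && !live) break;
    }
    if (nlo == -1) break;
    H.assign(Hn.begin() + (nlo - startj), Hn.begin() + (nhi - startj + 1));
    E.assign(En.begin() + (nlo - startj), En.begin() + (nhi - startj + 1));
    F.assign(Fn.begin() + (nlo - startj), Fn.begin() + (nhi - startj + 1));
    lo = nlo; hi = nhi;
  }
  Ext r; r.di = bi; r.dj = bj; r.score = best;
  return r;
}

struct SeedHit { long qstart, qend, sstart, send; int score; };

static SeedHit extend_from(const std::vector<uint8_t>& q,
                           const std::vector<uint8_t>& s,
                           long qpos, long spos, int k,
                           int ma, int mi, int go, int ge, int X) {
  long qlen = (long)q.size(), slen = (long)s.size();
  Ext R = xdrop_dir(q.data() + qpos + k, qlen - qpos - k, 1,
                    s.data() + spos + k, slen - spos - k, 1,
                    ma, mi, go, ge, X);
  Ext L;
  if (qpos > 0 && spos > 0) {
    L = xdrop_dir(q.data() + qpos - 1, qpos, -1,
                  s.data() + spos - 1, spos, -1,
                  ma, mi, go, ge, X);
  } else { L.di = 0; L.dj = 0; L.score = 0; }
  SeedHit h;
  h.qstart = qpos - L.di; h.sstart = spos - L.dj;
  h.qend = qpos + k + R.di; h.send = spos + k + R.dj;
  h.score = k * ma + L.score + R.score;
  return h;
}

// [[Rcpp::export]]
List cpp_extend_seed(std::string query, std::string subject,
                     int qpos, int spos, int word_size,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int x_drop) {
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  if (qpos < 0 || spos < 0 || qpos + word_size > (int)q.size() ||
      spos + word_size > (int)s.size())
    stop("seed exceeds sequence bounds");
  SeedHit h = extend_from(q, s, qpos, spos, word_size,
                          match, mismatch, -gap_open, -gap_extend, x_drop);
  return List::create(_["qstart"] = (double)h.qstart, _["qend"] = (double)h.qend,
                      _["sstart"] = (double)h.sstart, _["send"] = (double)h.send,
                      _["score"] = h.score);
}

// Banded global alignment (Gotoh) with traceback.  Returns the optimal score
// of aligning a against b end-to-end within the band, plus the column counts
// of the optimal path.  Band is widened automatically to contain the corner
// diagonal.
// [[Rcpp::export]]
List cpp_align_stats(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band = 64) {
  std::vector<uint8_t> A = encode(a), B = encode(b);
  long n = (long)A.size(), m = (long)B.size();
  int go = -gap_open, ge = -gap_extend;
  if (n == 0 || m == 0) {
    long L = std::max(n, m);
    int sc = (L == 0) ? 0 : -(go + (int)L * ge);
    return List::create(_["score"] = sc, _["matches"] = 0,
                        _["mismatches"] = 0, _["gap_cols"] = (double)L,
                        _["aln_len"] = (double)L);
  }
  long dlo = std::min<long>(0, m - n) - band;
  long dhi = std::max<long>(0, m - n) + band;
  long W = dhi - dlo + 1;
  auto idx = [&](long i, long j) { return i * W + (j - i - dlo); };
  auto inband = [&](long i, long j) {
    long d = j - i; return d >= dlo && d <= dhi && j >= 0 && j <= m;
  };
  std::vector<int> H((n + 1) * W, NEG), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // traceback: tb*[cell] encodes the predecessor state
  std::vector<uint8_t> tbH((n + 1) * W, 0), tbE((n + 1) * W, 0), tbF((n + 1) * W, 0);

  for (long i = 0; i <= n; ++i) {
    long jmin = std::max<long>(0, i + dlo), jmax = std::min<long>(m, i + dhi);
    for (long j = jmin; j <= jmax; ++j) {
      long c = idx(i, j);
      if (i == 0 && j == 0) { H[c] = 0; continue; }
      int e = NEG, f = NEG, mm = NEG;
      uint8_t te = 0, tf = 0, th = 0;
      if (j >= 1 && inband(i, j - 1)) {
        long p = idx(i, j - 1);
        int e1 = dec_pen(H[p], go + ge), e2 = dec_pen(E[p], ge);
        if (e1 >= e2) { e = e1; te = 0; } else { e = e2; te = 1; }
      }
      if (i >= 1 && inband(i - 1, j)) {
        long p = idx(i - 1, j);
        int f1 = dec_pen(H[p], go + ge), f2 = dec_pen(F[p], ge);
        if (f1 >= f2) { f = f1; tf = 0; } else { f = f2; tf = 1; }
      }
      if (i >= 1 && j >= 1 && inband(i - 1, j - 1)) {
        long p = idx(i - 1, j - 1);
        if (H[p] > NEG / 2) {
          uint8_t ac = A[i - 1], bc = B[j - 1];
          mm = H[p] + ((ac < 4 && bc < 4 && ac == bc) ? match : mismatch);
        }
      }
      E[c] = e; tbE[c] = te;
      F[c] = f; tbF[c] = tf;
      int h = mm; th = 0;
      if (e > h) { h = e; th = 1; }
      if (f > h) { h = f; th = 2; }
      H[c] = h; tbH[c] = th;
    }
  }
  long ci = n, cj = m;
  int score = H[idx(ci, cj)];
  long matches = 0, mismatches = 0, gapcols = 0;
  int state = 0;  // 0=H, 1=E, 2=F
  while (ci > 0 || cj > 0) {
    long c = idx(ci, cj);
    if (state == 0) {
      uint8_t t = tbH[c];
      if (t == 0) {
        uint8_t ac = A[ci - 1], bc = B[cj - 1];
        if (ac < 4 && bc < 4 && ac == bc) ++matches; else ++mismatches;
        --ci; --cj;
      } else state = t;  // hand over to E or F at this cell
    } else if (state == 1) {
      ++gapcols;
      uint8_t t = tbE[c];
      --cj;
      if (t == 0) state = 0;
    } else {
      ++gapcols;
      uint8_t t = tbF[c];
      --ci;
      if (t == 0) state = 0;
    }
  }
  return List::create(_["score"] = score, _["matches"] = (double)matches,
                      _["mismatches"] = (double)mismatches,
                      _["gap_cols"] = (double)gapcols,
                      _["aln_len"] = (double)(matches + mismatches + gapcols));
}

// [[Rcpp::export]]
DataFrame cpp_search_pair(std::string query, std::string subject,
                          int word_size,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int x_drop, int min_score, int max_pos_per_kmer) {
  if (word_size < 4 || word_size > 31) stop("word_size must be in [4, 31]");
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  long qlen = (long)q.size(), slen = (long)s.size();
  int go = -gap_open, ge = -gap_extend;
  uint64_t mask = (word_size == 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);

  // subject k-mer index (k-mers containing N excluded)
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    uint64_t km = 0; int run = 0;
    for (long p = 0; p < slen; ++p) {
      if (s[p] > 3) { run = 0; km = 0; continue; }
      km = ((km << 2) | s[p]) & mask;
      if (++run >= word_size) index[km].push_back((int)(p - word_size + 1));
    }
  }

  std::unordered_map<long, long> cover;  // diagonal -> subject end already extended
  std::vector<double> qs, qe, ss, se; std::vector<int> sc;
  uint64_t km = 0; int run = 0;
  for (long p = 0; p < qlen; ++p) {
    if (q[p] > 3) { run = 0; km = 0; continue; }
    km = ((km << 2) | q[p]) & mask;
    if (++run < word_size) continue;
    long qpos = p - word_size + 1;
    auto it = index.find(km);
    if (it == index.end()) continue;
    const std::vector<int>& pos = it->second;
    size_t step = 1;
    if (max_pos_per_kmer > 0 && (int)pos.size() > max_pos_per_kmer)
      step = (pos.size() + max_pos_per_kmer - 1) / max_pos_per_kmer;
    for (size_t t = 0; t < pos.size(); t += step) {
      long spos = pos[t];
      long diag = spos - qpos;
      auto cv = cover.find(diag);
      if (cv != cover.end() && spos + word_size <= cv->second) continue;
      SeedHit h = extend_from(q, s, qpos, spos, word_size,
                              match, mismatch, go, ge, x_drop);
      cover[diag] = h.send;
      if (h.score >= min_score) {
        qs.push_back((double)h.qstart); qe.push_back((double)h.qend);
        ss.push_back((double)h.sstart); se.push_back((double)h.send);
        sc.push_back(h.score);
      }
    }
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["score"] = sc);
}
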