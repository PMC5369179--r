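#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; anything outside ACGT (notably N) breaks a k-mer run.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// Rolling scan over all k-mer windows of s, calling f(pos, fwd, rc) for
// every window free of non-ACGT characters.  k must be <= 31.
template <typename F>
static void scan_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) f(i + 1 - k, fwd, rc);
  }
}

struct TEntry { int32_t count; int32_t seq; int32_t pos; uint8_t fwd; };

// Maximal runs of k-mers unique on both genomes, merged into anchors.
// Minus-strand matches are reported with the query coordinate flipped
// (position on the reverse-complemented query), so that q increases with t.
// [[Rcpp::export]]
DataFrame cpp_find_anchors(CharacterVector qseqs, CharacterVector tseqs, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");

  std::unordered_map<uint64_t, TEntry> tmap;
  tmap.reserve(1 << 20);
  for (int ti = 0; ti < tseqs.size(); ++ti) {
    std::string s = as<std::string>(tseqs[ti]);
    scan_kmers(s, k, [&](int pos, uint64_t f, uint64_t r) {
      uint64_t canon = f <= r ? f : r;
      auto it = tmap.find(canon);
      if (it == tmap.end())
        tmap[canon] = TEntry{1, (int32_t)ti, (int32_t)pos, (uint8_t)(f <= r)};
      else if (it->second.count < 2)
        it->second.count = 2;
    });
  }

  std::unordered_map<uint64_t, int32_t> qcount;
  qcount.reserve(1 << 20);
  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    scan_kmers(s, k, [&](int, uint64_t f, uint64_t r) {
      uint64_t canon = f <= r ? f : r;
      auto it = qcount.find(canon);
      if (it == qcount.end()) qcount[canon] = 1;
      else if (it->second < 2) it->second = 2;
    });
  }

  // raw single-copy matches
  std::vector<int32_t> mqi, mti, mqe, mtp;
  std::vector<uint8_t> mplus;
  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    int qlen = (int)s.size();
    scan_kmers(s, k, [&](int pos, uint64_t f, uint64_t r) {
      uint64_t canon = f <= r ? f : r;
      auto qc = qcount.find(canon);
      if (qc == qcount.end() || qc->second != 1) return;
      auto te = tmap.find(canon);
      if (te == tmap.end() || te->second.count != 1) return;
      bool qfwd = (f <= r);
      bool plus = (qfwd == (bool)te->second.fwd);
      int qe = plus ? pos : (qlen - pos - k);
      mqi.push_back(qi); mti.push_back(te->second.seq);
      mqe.push_back(qe); mtp.push_back(te->second.pos);
      mplus.push_back(plus ? 1 : 0);
    });
  }

  // sort matches by (t_seq, q_seq, strand, diagonal, t_pos) and merge runs
  const size_t nm = mtp.size();
  std::vector<size_t> ord(nm);
  for (size_t i = 0; i < nm; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (mti[a] != mti[b]) return mti[a] < mti[b];
    if (mqi[a] != mqi[b]) return mqi[a] < mqi[b];
    if (mplus[a] != mplus[b]) return mplus[a] < mplus[b];
    int64_t da = (int64_t)mqe[a] - mtp[a], db = (int64_t)mqe[b] - mtp[b];
    if (da != db) return da < db;
    return mtp[a] < mtp[b];
  });

  std::vector<int32_t> aq, at, aqs, ats, alen;
  std::vector<uint8_t> astr;
  size_t i = 0;
  while (i < nm) {
    size_t j = i;
    size_t a = ord[i];
    while (j + 1 < nm) {
      size_t b = ord[j + 1], c = ord[j];
      if (mti[b] != mti[a] || mqi[b] != mqi[a] || mplus[b] != mplus[a]) break;
      if ((int64_t)mqe[b] - mtp[b] != (int64_t)mqe[a] - mtp[a]) break;
      // same diagonal and base-level contiguous/overlapping: the union of
      // two exact matches on one diagonal is itself an exact match, even
      // when the k-mers in between were not unique
      if (mtp[b] > mtp[c] + k) break;
      ++j;
    }
    size_t last = ord[j];
    aq.push_back(mqi[a] + 1); at.push_back(mti[a] + 1);
    aqs.push_back(mqe[a]); ats.push_back(mtp[a]);
    alen.push_back(mtp[last] - mtp[a] + k);
    astr.push_back(mplus[a]);
    i = j + 1;
  }

  return DataFrame::create(
    _["q_seq_i"] = wrap(aq), _["t_seq_i"] = wrap(at),
    _["q_start"] = wrap(aqs), _["t_start"] = wrap(ats),
    _["length"] = wrap(alen),
    _["plus"] = LogicalVector(astr.begin(), astr.end()));
}

// Sparse-DP chain scores over anchors sorted by (t_start, q_start).
// score(i) = len(i) + max(0, max_j score(j) - penalty(j, i)) over compatible
// predecessors j; penalty = open + ext*|dq - dt| + diag*min(dq, dt).
// Micro-homology at variant breakpoints makes flanking anchors overlap by
// a few bases; overlaps up to ov_max are allowed by conceptually clipping
// the start of the later anchor (its lost bases are charged against the
// score, and the join gaps are measured after clipping).
// Anchors with skip[i] == TRUE are ignored.  Ties resolved to the smallest j.
// [[Rcpp::export]]
List cpp_chain_dp(IntegerVector q, IntegerVector t, IntegerVector len,
                  double open, double ext, double diagp, LogicalVector skip,
                  int ov_max = 100) {
  int n = q.size();
  NumericVector f(n);
  IntegerVector bp(n);
  for (int i = 0; i < n; ++i) {
    bp[i] = -1;
    if (skip[i]) { f[i] = R_NegInf; continue; }
    f[i] = (double)len[i];
    for (int j = 0; j < i; ++j) {
      if (skip[j]) continue;
      int tje = t[j] + len[j], qje = q[j] + len[j];
      int o = std::max(std::max(tje - t[i], qje - q[i]), 0);
      if (o > ov_max || o >= len[i]) continue;
      if (t[i] + len[i] <= tje || q[i] + len[i] <= qje) continue;
      double dt = t[i] + o - tje, dq = q[i] + o - qje;
      double pen = open + ext * std::abs(dq - dt) + diagp * std::min(dq, dt);
      double cand = f[j] + (double)(len[i] - o) - pen;
      if (cand > f[i] + 1e-9) { f[i] = cand; bp[i] = j; }
    }
  }
  return List::create(_["score"] = f, _["bp"] = bp);
}

// Global affine-gap alignment (Gotoh) of two short sequences; returns the
// two gapped strings.  Used for base-level fill of inter-anchor gaps where
// per-call overhead matters more than scoring sophistication.
// [[Rcpp::export]]
CharacterVector cpp_nw_align(std::string a, std::string b, double match,
                             double mismatch, double gap_open,
                             double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e30;
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1),
      Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // traceback: per state, predecessor state (0 = M, 1 = X(gap in b), 2 = Y)
  std::vector<uint8_t> tbM((size_t)(n + 1) * (m + 1)),
      tbX((size_t)(n + 1) * (m + 1)), tbY((size_t)(n + 1) * (m + 1));
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -gap_open - gap_ext * j;
    tbY[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -gap_open - gap_ext * i;
    tbX[at(i, 0)] = 1;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal from best of three
      double best = Mp[j - 1]; uint8_t st = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; st = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; st = 2; }
      Mc[j] = best + s; tbM[at(i, j)] = st;
      // X: gap in b (consume a[i-1])
      double xo = Mp[j] - gap_open - gap_ext, xe = Xp[j] - gap_ext;
      if (xo >= xe) { Xc[j] = xo; tbX[at(i, j)] = 0; }
      else { Xc[j] = xe; tbX[at(i, j)] = 1; }
      // Y: gap in a (consume b[j-1])
      double yo = Mc[j - 1] - gap_open - gap_ext, ye = Yc[j - 1] - gap_ext;
      if (yo >= ye) { Yc[j] = yo; tbY[at(i, j)] = 0; }
      else { Yc[j] = ye; tbY[at(i, j)] = 2; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // traceback needs full matrices; redo with stored tb only is enough:
  // choose end state
  double best = Mp[m]; uint8_t st = 0;
  if (Xp[m] > best) { best = Xp[m]; st = 1; }
  if (Yp[m] > best) { best = Yp[m]; st = 2; }
  std::string ra, rb_;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      uint8_t prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb_.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == 1) {
      uint8_t prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb_.push_back('-');
      --i; st = prev;
    } else {
      uint8_t prev = tbY[at(i, j)];
      ra.push_back('-'); rb_.push_back(b[j - 1]);
      --j; st = prev;
    }
    if (i == 0 && j > 0) st = 2;
    else if (j == 0 && i > 0) st = 1;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb_.begin(), rb_.end());
  return CharacterVector::create(ra, rb_);
}

struct Vote { int32_t n; int32_t tmin; int32_t tmax; int32_t qmin; int32_t qmax; };

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> idx;
};

static KmerIndex* build_index(CharacterVector tseqs, int k, int max_hits) {
  std::unordered_map<uint64_t, int32_t> cnt;
  cnt.reserve(1 << 20);
  for (int ti = 0; ti < tseqs.size(); ++ti) {
    std::string s = as<std::string>(tseqs[ti]);
    scan_kmers(s, k, [&](int, uint64_t f, uint64_t) { cnt[f]++; });
  }
  KmerIndex* ki = new KmerIndex();
  ki->k = k;
  ki->idx.reserve(cnt.size());
  for (int ti = 0; ti < tseqs.size(); ++ti) {
    std::string s = as<std::string>(tseqs[ti]);
    scan_kmers(s, k, [&](int pos, uint64_t f, uint64_t) {
      auto c = cnt.find(f);
      if (c != cnt.end() && c->second <= max_hits)
        ki->idx[f].push_back({(int32_t)ti, (int32_t)pos});
    });
  }
  return ki;
}

static DataFrame map_with_index(CharacterVector queries, const KmerIndex* ki);

// Reusable k-mer position index over a set of target sequences.
// [[Rcpp::export]]
SEXP cpp_kmer_index(CharacterVector tseqs, int k, int max_hits) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  XPtr<KmerIndex> p(build_index(tseqs, k, max_hits), true);
  return p;
}

// [[Rcpp::export]]
DataFrame cpp_map_indexed(CharacterVector queries, SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return map_with_index(queries, p.get());
}

// Seed-and-vote placement of query sequences on a genome: exact k-mer
// lookups voted per (target seq, strand, diagonal); the best diagonal gives
// one contiguous placement per query.  k-mers with more than max_hits
// target occurrences are skipped.  Substitution-style divergence keeps the
// diagonal exact, which is all the simulator produces.
// [[Rcpp::export]]
DataFrame cpp_map_sequences(CharacterVector queries, CharacterVector tseqs,
                            int k, int max_hits) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  KmerIndex* ki = build_index(tseqs, k, max_hits);
  DataFrame out = map_with_index(queries, ki);
  delete ki;
  return out;
}

static DataFrame map_with_index(CharacterVector queries, const KmerIndex* ki) {
  const auto& idx = ki->idx;
  const int k = ki->k;
  int nq = queries.size();
  IntegerVector o_t(nq), o_ts(nq), o_te(nq), o_qs(nq), o_qe(nq),
      o_votes(nq), o_votes2(nq);
  LogicalVector o_plus(nq);
  for (int q = 0; q < nq; ++q) {
    std::string s = as<std::string>(queries[q]);
    int qlen = (int)s.size();
    std::unordered_map<int64_t, Vote> votes;
    scan_kmers(s, k, [&](int qpos, uint64_t f, uint64_t r) {
      auto hit = idx.find(f);
      if (hit != idx.end()) {
        for (auto& p : hit->second) {
          int64_t key = (((int64_t)p.first * 2 + 1) << 32) |
                        (uint32_t)(p.second - qpos + qlen);
          auto& v = votes[key];
          if (v.n == 0) { v.tmin = v.tmax = p.second; v.qmin = v.qmax = qpos; }
          v.n++;
          v.tmin = std::min(v.tmin, p.second); v.tmax = std::max(v.tmax, p.second);
          v.qmin = std::min(v.qmin, qpos); v.qmax = std::max(v.qmax, qpos);
        }
      }
      hit = idx.find(r);
      if (hit != idx.end()) {
        for (auto& p : hit->second) {
          int64_t key = (((int64_t)p.first * 2) << 32) |
                        (uint32_t)(p.second + qpos);
          auto& v = votes[key];
          if (v.n == 0) { v.tmin = v.tmax = p.second; v.qmin = v.qmax = qpos; }
          v.n++;
          v.tmin = std::min(v.tmin, p.second); v.tmax = std::max(v.tmax, p.second);
          v.qmin = std::min(v.qmin, qpos); v.qmax = std::max(v.qmax, qpos);
        }
      }
    });
    int best = 0, second = 0;
    int64_t bkey = -1;
    Vote bv{0, 0, 0, 0, 0};
    for (auto& kv : votes) {
      if (kv.second.n > best || (kv.second.n == best && kv.first < bkey)) {
        if (kv.second.n > best) second = best;
        best = kv.second.n; bkey = kv.first; bv = kv.second;
      } else if (kv.second.n > second) {
        second = kv.second.n;
      }
    }
    if (best == 0) {
      o_t[q] = NA_INTEGER; o_ts[q] = NA_INTEGER; o_te[q] = NA_INTEGER;
      o_qs[q] = NA_INTEGER; o_qe[q] = NA_INTEGER;
      o_plus[q] = NA_LOGICAL; o_votes[q] = 0; o_votes2[q] = 0;
      continue;
    }
    o_t[q] = (int)(bkey >> 33) + 1;
    o_plus[q] = (bkey >> 32) & 1;
    o_ts[q] = bv.tmin; o_te[q] = bv.tmax + k;
    o_qs[q] = bv.qmin; o_qe[q] = bv.qmax + k;
    o_votes[q] = best; o_votes2[q] = second;
  }
  return DataFrame::create(
    _["t_seq_i"] = o_t, _["t_start"] = o_ts, _["t_end"] = o_te,
    _["q_start"] = o_qs, _["q_end"] = o_qe, _["plus"] = o_plus,
    _["votes"] = o_votes, _["votes2"] = o_votes2);
}
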