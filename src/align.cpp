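#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>
#include <cstdint>

using namespace Rcpp;

// Alignment kernels. Coordinates are 0-based half-open throughout; the
// caller handles strand by passing a reverse-complemented subject.
// Gap of length g costs gap_open + g * gap_extend (both passed positive),
// matching the BLASTN -G/-E convention of the scoring scheme.

static const int NEG = -1000000000;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1; // N and anything else: never seeds, scores as mismatch
  }
}

struct SeedHit { int q, s, d; };

struct Hsp {
  int q_start, q_end, s_start, s_end;
  int score, matches, mismatches, gap_opens, gap_bases, align_len;
};

// Banded Smith-Waterman with affine gaps restricted to query rows
// [qlo,qhi), subject cols [slo,shi) and diagonals j - i in [dlo,dhi].
// Returns best local alignment in the region, or score 0 if none.
static Hsp banded_local(const std::string &q, const std::string &s,
                        int qlo, int qhi, int slo, int shi,
                        int dlo, int dhi,
                        int match, int mismatch, int go, int ge) {
  const int W = dhi - dlo + 1;
  const int R = qhi - qlo;
  std::vector<int> H((size_t)R * W, NEG), E((size_t)R * W, NEG), F((size_t)R * W, NEG);
  std::vector<unsigned char> tH((size_t)R * W, 0), tE((size_t)R * W, 0), tF((size_t)R * W, 0);

  int best = 0, bi = -1, bj = -1;
  for (int i = qlo; i < qhi; ++i) {
    const int r = i - qlo;
    int jmin = std::max(slo, i + dlo);
    int jmax = std::min(shi - 1, i + dhi);
    for (int j = jmin; j <= jmax; ++j) {
      const int c = j - (i + dlo);
      const size_t idx = (size_t)r * W + c;
      // E: gap in query (consumes subject), predecessor (i, j-1) offset c-1
      int e = NEG;
      unsigned char te = 0;
      if (c - 1 >= 0 && j - 1 >= slo) {
        const size_t pl = (size_t)r * W + (c - 1);
        if (H[pl] > NEG / 2 && H[pl] - go - ge > e) { e = H[pl] - go - ge; te = 1; }
        if (E[pl] > NEG / 2 && E[pl] - ge > e)      { e = E[pl] - ge;      te = 0; }
      }
      // F: gap in subject (consumes query), predecessor (i-1, j) offset c+1
      int f = NEG;
      unsigned char tf = 0;
      if (r - 1 >= 0 && c + 1 < W) {
        const size_t pu = (size_t)(r - 1) * W + (c + 1);
        if (H[pu] > NEG / 2 && H[pu] - go - ge > f) { f = H[pu] - go - ge; tf = 1; }
        if (F[pu] > NEG / 2 && F[pu] - ge > f)      { f = F[pu] - ge;      tf = 0; }
      }
      // M: diagonal predecessor (i-1, j-1), same offset c
      int sub = (base_code(q[i]) >= 0 && q[i] == s[j]) ? match : mismatch;
      int m = sub; // alignment starting fresh at (i,j)
      if (r - 1 >= 0 && j - 1 >= slo) {
        const size_t pd = (size_t)(r - 1) * W + c;
        if (H[pd] > 0) m = H[pd] + sub;
      }
      int h = 0; unsigned char th = 0;
      if (m > h) { h = m; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[idx] = h; E[idx] = e; F[idx] = f;
      tH[idx] = th; tE[idx] = te; tF[idx] = tf;
      if (h > best || (h == best && bi >= 0 && j < bj)) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }

  Hsp out; out.score = 0;
  out.matches = out.mismatches = out.gap_opens = out.gap_bases = out.align_len = 0;
  if (best <= 0) return out;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int matches = 0, mism = 0, gopen = 0, gbases = 0, cols = 0;
  int qs = bi, ss = bj;
  while (true) {
    const int r = i - qlo, c = j - (i + dlo);
    const size_t idx = (size_t)r * W + c;
    if (state == 0) {
      unsigned char th = tH[idx];
      if (th == 0) break;
      if (th == 1) {
        cols++;
        if (base_code(q[i]) >= 0 && q[i] == s[j]) matches++; else mism++;
        qs = i; ss = j;
        // did the diagonal predecessor start a fresh alignment?
        bool fresh = true;
        if (r - 1 >= 0 && j - 1 >= slo) {
          const size_t pd = (size_t)(r - 1) * W + c;
          if (H[pd] > 0) fresh = false;
        }
        i--; j--;
        if (fresh) break;
      } else if (th == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap in query, consumed subject base j
      cols++; gbases++;
      if (tE[idx] == 1) { gopen++; state = 0; }
      j--;
    } else { // F: gap in subject, consumed query base i
      cols++; gbases++;
      if (tF[idx] == 1) { gopen++; state = 0; }
      i--;
    }
  }
  out.q_start = qs; out.q_end = bi + 1;
  out.s_start = ss; out.s_end = bj + 1;
  out.score = best; out.matches = matches; out.mismatches = mism;
  out.gap_opens = gopen; out.gap_bases = gbases; out.align_len = cols;
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int k, int min_score,
                          int band_pad, int margin,
                          int max_seed_occ, int seed_stride,
                          int cluster_diag_gap, int cluster_pos_gap) {
  const int n = (int)query.size(), m = (int)subject.size();
  const int go = gap_open, ge = gap_extend; // positive penalties, subtracted
  std::vector<Hsp> hsps;

  if (n >= k && m >= k) {
    // hash query k-mers (2-bit encoding, k <= 15)
    const uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    std::unordered_map<uint32_t, std::vector<int> > index;
    index.reserve((size_t)n);
    uint32_t code = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(query[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run >= k) index[code].push_back(i - k + 1);
    }

    // scan subject, thin per-diagonal
    std::vector<SeedHit> hits;
    std::unordered_map<int, int> last_on_diag;
    code = 0; run = 0;
    for (int j = 0; j < m; ++j) {
      int b = base_code(subject[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++run < k) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      if ((int)it->second.size() > max_seed_occ) continue;
      const int spos = j - k + 1;
      for (int qpos : it->second) {
        const int d = spos - qpos;
        auto lit = last_on_diag.find(d);
        if (lit != last_on_diag.end() && spos - lit->second < seed_stride) continue;
        last_on_diag[d] = spos;
        hits.push_back({qpos, spos, d});
      }
    }

    // cluster seeds: union-find over hits close in subject and diagonal
    const int H = (int)hits.size();
    std::vector<int> parent(H);
    for (int i = 0; i < H; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    std::sort(hits.begin(), hits.end(),
              [](const SeedHit &a, const SeedHit &b) { return a.s < b.s; });
    for (int i = 1; i < H; ++i) {
      for (int j = i - 1; j >= 0; --j) {
        if (hits[i].s - hits[j].s > cluster_pos_gap) break;
        if (std::abs(hits[i].d - hits[j].d) <= cluster_diag_gap) {
          int ri = find(i), rj = find(j);
          if (ri != rj) parent[ri] = rj;
        }
      }
    }
    std::unordered_map<int, std::vector<int> > clusters;
    for (int i = 0; i < H; ++i) clusters[find(i)].push_back(i);

    // cheap ungapped X-drop extension along a seed's diagonal
    const int xdrop = 40;
    auto ungapped_score = [&](const SeedHit &h) {
      int sc = 0, best = 0;
      for (int q = h.q, s = h.s; q < n && s < m; ++q, ++s) {
        sc += (base_code(query[q]) >= 0 && query[q] == subject[s])
                ? match : mismatch;
        if (sc > best) best = sc;
        if (sc < best - xdrop) break;
      }
      int left = 0; sc = 0;
      for (int q = h.q - 1, s = h.s - 1; q >= 0 && s >= 0; --q, --s) {
        sc += (base_code(query[q]) >= 0 && query[q] == subject[s])
                ? match : mismatch;
        if (sc > left) left = sc;
        if (sc < left - xdrop) break;
      }
      return best + left;
    };

    for (auto &kv : clusters) {
      int qmin = n, qmax = 0, smin = m, smax = 0, dmin = m, dmax = -m;
      for (int id : kv.second) {
        const SeedHit &h = hits[id];
        qmin = std::min(qmin, h.q); qmax = std::max(qmax, h.q + k);
        smin = std::min(smin, h.s); smax = std::max(smax, h.s + k);
        dmin = std::min(dmin, h.d); dmax = std::max(dmax, h.d);
      }
      const int qspan = qmax - qmin;
      const int n_seeds = (int)kv.second.size();
      int ug_best = 0, tried = 0;
      for (int id : kv.second) {
        ug_best = std::max(ug_best, ungapped_score(hits[id]));
        if (ug_best >= 50 || ++tried >= 32) break;
      }
      // isolated weak seeds in random background cannot reach min_score;
      // skip them instead of running gapped DP
      if (n_seeds <= 2 && ug_best < 45 && qspan < 50) continue;
      // strong or extended clusters get the full extension margin, weak
      // short ones only need a small one (the cluster already covers them)
      const int mg = (ug_best >= 50 || qspan >= 64) ? margin : 64;
      int qlo = std::max(0, qmin - mg), qhi = std::min(n, qmax + mg);
      int slo = std::max(0, smin - mg), shi = std::min(m, smax + mg);
      Hsp h = banded_local(query, subject, qlo, qhi, slo, shi,
                           dmin - band_pad, dmax + band_pad,
                           match, mismatch, go, ge);
      if (h.score >= min_score) hsps.push_back(h);
    }
  }

  // de-duplicate overlapping candidates: highest score wins, ties leftmost
  std::sort(hsps.begin(), hsps.end(), [](const Hsp &a, const Hsp &b) {
    if (a.score != b.score) return a.score > b.score;
    return a.s_start < b.s_start;
  });
  std::vector<Hsp> kept;
  for (const Hsp &h : hsps) {
    bool dup = false;
    for (const Hsp &g : kept) {
      int qov = std::min(h.q_end, g.q_end) - std::max(h.q_start, g.q_start);
      int sov = std::min(h.s_end, g.s_end) - std::max(h.s_start, g.s_start);
      int qlen = std::min(h.q_end - h.q_start, g.q_end - g.q_start);
      int slen = std::min(h.s_end - h.s_start, g.s_end - g.s_start);
      if (qov > 0 && sov > 0 && 2 * qov >= qlen && 2 * sov >= slen) { dup = true; break; }
    }
    if (!dup) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const Hsp &a, const Hsp &b) {
    if (a.s_start != b.s_start) return a.s_start < b.s_start;
    return a.q_start < b.q_start;
  });

  const int N = (int)kept.size();
  IntegerVector qs(N), qe(N), ss(N), se(N), sc(N), ma(N), mi(N), gos(N), gb(N), al(N);
  for (int i = 0; i < N; ++i) {
    qs[i] = kept[i].q_start; qe[i] = kept[i].q_end;
    ss[i] = kept[i].s_start; se[i] = kept[i].s_end;
    sc[i] = kept[i].score; ma[i] = kept[i].matches; mi[i] = kept[i].mismatches;
    gos[i] = kept[i].gap_opens; gb[i] = kept[i].gap_bases; al[i] = kept[i].align_len;
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["score"] = sc, _["matches"] = ma, _["mismatches"] = mi,
    _["gap_opens"] = gos, _["gap_bases"] = gb, _["align_len"] = al);
}

// Banded Needleman-Wunsch with affine gaps; band must contain diagonals 0
// and m - n. DP indices i in 0..n, j in 0..m count consumed prefixes.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int band_pad) {
  const int n = (int)a.size(), m = (int)b.size();
  const int go = -gap_open, ge = -gap_extend;
  const int dlo = std::min(0, m - n) - band_pad;
  const int dhi = std::max(0, m - n) + band_pad;
  const int W = dhi - dlo + 1;
  const int R = n + 1;
  std::vector<int> H((size_t)R * W, NEG), E((size_t)R * W, NEG), F((size_t)R * W, NEG);
  std::vector<unsigned char> tH((size_t)R * W, 0), tE((size_t)R * W, 0), tF((size_t)R * W, 0);
  auto at = [&](int i, int j) { return (size_t)i * W + (j - (i + dlo)); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j - i >= dlo && j - i <= dhi;
  };

  H[at(0, 0)] = 0;
  for (int j = 1; inband(0, j); ++j) {
    E[at(0, j)] = go + j * ge; tE[at(0, j)] = (j == 1) ? 1 : 0;
    H[at(0, j)] = E[at(0, j)]; tH[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) {
      F[at(i, 0)] = go + i * ge; tF[at(i, 0)] = (i == 1) ? 1 : 0;
      H[at(i, 0)] = F[at(i, 0)]; tH[at(i, 0)] = 3;
    }
    int jmin = std::max(1, i + dlo), jmax = std::min(m, i + dhi);
    for (int j = jmin; j <= jmax; ++j) {
      const size_t idx = at(i, j);
      int e = NEG; unsigned char te = 0;
      if (inband(i, j - 1)) {
        const size_t p = at(i, j - 1);
        if (H[p] > NEG / 2 && H[p] + go + ge > e) { e = H[p] + go + ge; te = 1; }
        if (E[p] > NEG / 2 && E[p] + ge > e)      { e = E[p] + ge;      te = 0; }
      }
      int f = NEG; unsigned char tf = 0;
      if (inband(i - 1, j)) {
        const size_t p = at(i - 1, j);
        if (H[p] > NEG / 2 && H[p] + go + ge > f) { f = H[p] + go + ge; tf = 1; }
        if (F[p] > NEG / 2 && F[p] + ge > f)      { f = F[p] + ge;      tf = 0; }
      }
      int mm = NEG;
      if (inband(i - 1, j - 1)) {
        const size_t p = at(i - 1, j - 1);
        if (H[p] > NEG / 2) {
          int sub = (base_code(a[i - 1]) >= 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
          mm = H[p] + sub;
        }
      }
      int h = mm; unsigned char th = 1;
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[idx] = h; E[idx] = e; F[idx] = f;
      tH[idx] = th; tE[idx] = te; tF[idx] = tf;
    }
  }
  if (!inband(n, m) || H[at(n, m)] <= NEG / 2)
    stop("band too narrow for global alignment; increase band_pad");

  // traceback into gapless blocks
  int i = n, j = m, state = 0;
  int matches = 0, cols = 0;
  std::vector<int> as, aev, bs, bev;
  int run = 0; // length of current diagonal run (ending at i,j)
  auto flush = [&](int ei, int ej) {
    if (run > 0) {
      as.push_back(ei); aev.push_back(ei + run);
      bs.push_back(ej); bev.push_back(ej + run);
      run = 0;
    }
  };
  while (i > 0 || j > 0) {
    const size_t idx = at(i, j);
    if (state == 0) {
      unsigned char th = tH[idx];
      if (th == 1) {
        cols++;
        if (base_code(a[i - 1]) >= 0 && a[i - 1] == b[j - 1]) matches++;
        run++; i--; j--;
      } else if (th == 2) { flush(i, j); state = 1; }
      else { flush(i, j); state = 2; }
    } else if (state == 1) {
      cols++;
      if (tE[idx] == 1) state = 0;
      j--;
    } else {
      cols++;
      if (tF[idx] == 1) state = 0;
      i--;
    }
  }
  flush(i, j);
  std::reverse(as.begin(), as.end()); std::reverse(aev.begin(), aev.end());
  std::reverse(bs.begin(), bs.end()); std::reverse(bev.begin(), bev.end());
  return List::create(
    _["score"] = H[at(n, m)],
    _["matches"] = matches,
    _["align_len"] = cols,
    _["blocks"] = DataFrame::create(
      _["a_start"] = as, _["a_end"] = aev,
      _["b_start"] = bs, _["b_end"] = bev));
}
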