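// Banded edit-distance alignment and k-mer seeded chunk-to-read mapping.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int INF = 1 << 28;

std::vector<int> enc(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = -1; break;
    }
  }
  return v;
}

std::vector<int> rc(const std::vector<int>& v) {
  std::vector<int> o(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    o[i] = b < 0 ? b : 3 - b;
  }
  return o;
}

// Semi-global banded edit distance: the query is consumed in full; the
// reference start/end are free when free_ends is true. The band is on the
// diagonal d = j - i, d in [dlo, dhi]. Returns {ed, ref_start, ref_end}
// (0-based half-open) or ed = INF when no in-band alignment exists.
struct AlnResult { int ed, ref_start, ref_end; };

AlnResult banded_semiglobal(const std::vector<int>& q, const std::vector<int>& r,
                            int dlo, int dhi, bool free_ends) {
  const int n = (int)q.size(), m = (int)r.size();
  const int wd = dhi - dlo + 1;
  if (wd <= 0) return {INF, -1, -1};
  std::vector<int> prev(wd, INF), cur(wd, INF);
  std::vector<int> sprev(wd, -1), scur(wd, -1);
  for (int d = dlo; d <= dhi; ++d) {
    int j = d;
    if (j < 0 || j > m) continue;
    prev[d - dlo] = free_ends ? 0 : j;
    sprev[d - dlo] = j;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int dmin = std::max(dlo, -i), dmax = std::min(dhi, m - i);
    int qi = q[i - 1];
    for (int d = dmin; d <= dmax; ++d) {
      int j = i + d;
      int idx = d - dlo;
      // diagonal (i-1, j-1): same d; up (i-1, j): d+1; left (i, j-1): d-1
      int best = (j >= 1) ? prev[idx] + (qi != r[j - 1] || qi < 0 ? 1 : 0) : INF;
      int sb = (j >= 1) ? sprev[idx] : -1;
      if (d + 1 <= dhi) {
        int c = prev[idx + 1];
        if (c < INF && c + 1 < best) { best = c + 1; sb = sprev[idx + 1]; }
      }
      if (d - 1 >= dlo) {
        int c = cur[idx - 1];
        if (c < INF && c + 1 < best) { best = c + 1; sb = scur[idx - 1]; }
      }
      cur[idx] = best;
      scur[idx] = sb;
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  int best = INF, bd = 0, sb = -1;
  for (int d = dlo; d <= dhi; ++d) {
    int j = n + d;
    if (j < 0 || j > m) continue;
    int c = prev[d - dlo];
    if (c >= INF) continue;
    if (!free_ends) c += 0;  // suffix of ref beyond j is free only with free_ends
    if (!free_ends && j != m) continue;
    if (c < best) { best = c; bd = d; sb = sprev[d - dlo]; }
  }
  if (best >= INF) return {INF, -1, -1};
  return {best, sb, n + bd};
}

inline bool kmer_at(const std::vector<int>& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int b = s[pos + t];
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".ca_edit_distance_cpp")]]
IntegerVector ca_edit_distance_cpp(std::string query, std::string ref, int dlo,
                                   int dhi, bool free_ends) {
  std::vector<int> q = enc(query), r = enc(ref);
  AlnResult a = banded_semiglobal(q, r, dlo, dhi, free_ends);
  return IntegerVector::create(a.ed >= INF ? NA_INTEGER : a.ed, a.ref_start, a.ref_end);
}

// k-mer anchors between a query and a reference (forward strands).
// Returns an integer matrix with columns (query_pos, ref_pos), 0-based.
// [[Rcpp::export(name = ".ca_anchors_cpp")]]
IntegerMatrix ca_anchors_cpp(std::string query, std::string ref, int k,
                             int max_hits, int stride) {
  std::vector<int> q = enc(query), r = enc(ref);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (int i = 0; i + k <= (int)q.size(); i += stride) {
    uint64_t v;
    if (kmer_at(q, i, k, v)) idx[v].push_back(i);
  }
  std::vector<std::pair<int, int>> hits;
  for (int j = 0; j + k <= (int)r.size(); ++j) {
    uint64_t v;
    if (!kmer_at(r, j, k, v)) continue;
    auto it = idx.find(v);
    if (it == idx.end() || (int)it->second.size() > max_hits) continue;
    for (int qp : it->second) hits.emplace_back(qp, j);
  }
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t h = 0; h < hits.size(); ++h) {
    out(h, 0) = hits[h].first;
    out(h, 1) = hits[h].second;
  }
  return out;
}

// Map every chunk to every read on both strands at relaxed identity.
// Returns parallel vectors describing retained alignments; coordinates are
// 0-based half-open on the forward read.
// [[Rcpp::export(name = ".ca_map_chunks_cpp")]]
List ca_map_chunks_cpp(CharacterVector chunks, CharacterVector reads,
                       double max_error, int k, int min_seeds, int max_kmer_hits) {
  const int nc = chunks.size(), nr = reads.size();
  std::vector<std::vector<int>> cseq(nc);
  for (int c = 0; c < nc; ++c) cseq[c] = enc(as<std::string>(chunks[c]));
  // index chunk k-mers
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i + k <= (int)cseq[c].size(); ++i) {
      uint64_t v;
      if (kmer_at(cseq[c], i, k, v)) idx[v].push_back({c, i});
    }
  }
  // drop hyper-repetitive k-mers
  for (auto& kv : idx)
    if ((int)kv.second.size() > max_kmer_hits) kv.second.clear();

  std::vector<int> o_chunk, o_read, o_start, o_end, o_ed;
  std::vector<int> o_strand;  // 0 = '+', 1 = '-'

  struct Hit { int c, j, i; };
  struct Cand { int start, end, ed, strand; };

  for (int rd = 0; rd < nr; ++rd) {
    std::vector<int> fwd = enc(as<std::string>(reads[rd]));
    const int rl = (int)fwd.size();
    // per (chunk) accepted candidates for dedup
    std::unordered_map<int, std::vector<Cand>> accepted;
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<int> seq = strand == 0 ? fwd : rc(fwd);
      std::vector<Hit> hits;
      for (int j = 0; j + k <= (int)seq.size(); ++j) {
        uint64_t v;
        if (!kmer_at(seq, j, k, v)) continue;
        auto it = idx.find(v);
        if (it == idx.end()) continue;
        for (auto& pr : it->second) hits.push_back({pr.first, j, pr.second});
      }
      std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
        return a.c != b.c ? a.c < b.c : a.j < b.j;
      });
      size_t h = 0;
      while (h < hits.size()) {
        int c = hits[h].c;
        int Lc = (int)cseq[c].size();
        int band_d = (int)(max_error * Lc) + 30;
        // cluster consecutive hits of this chunk
        size_t h2 = h;
        std::vector<size_t> cl;
        std::vector<int> ds;
        int j0 = hits[h].j, d0 = hits[h].j - hits[h].i;
        while (h2 < hits.size() && hits[h2].c == c) {
          int d = hits[h2].j - hits[h2].i;
          if (!cl.empty() && (hits[h2].j - j0 > Lc + 200 || std::abs(d - d0) > band_d)) break;
          if (cl.empty()) { j0 = hits[h2].j; d0 = d; }
          cl.push_back(h2);
          ds.push_back(d);
          ++h2;
        }
        h = h2;
        if ((int)cl.size() < min_seeds) continue;
        std::nth_element(ds.begin(), ds.begin() + ds.size() / 2, ds.end());
        int dmed = ds[ds.size() / 2];
        // adapt the verification band to the observed diagonal spread of
        // the seed chain (capped at the worst-case indel drift)
        int dspread = *std::max_element(ds.begin(), ds.end()) -
                      *std::min_element(ds.begin(), ds.end());
        int margin = std::min((int)(max_error * Lc) + 30,
                              std::max(120, 2 * dspread + 100));
        int ws = std::max(0, dmed - margin);
        int we = std::min((int)seq.size(), dmed + Lc + margin);
        if (we - ws < Lc / 2) continue;
        std::vector<int> window(seq.begin() + ws, seq.begin() + we);
        int dlo = -margin - 5, dhi = (we - ws) - Lc + margin + 5;
        AlnResult a = banded_semiglobal(cseq[c], window, dlo, dhi, true);
        if (a.ed >= INF || a.ed > (int)(max_error * Lc)) continue;
        int s_on_seq = ws + a.ref_start, e_on_seq = ws + a.ref_end;
        int fs, fe;
        if (strand == 0) { fs = s_on_seq; fe = e_on_seq; }
        else { fs = rl - e_on_seq; fe = rl - s_on_seq; }
        accepted[c].push_back({fs, fe, a.ed, strand});
      }
    }
    // dedup overlapping candidates per chunk, keep best edit distance
    for (auto& kv : accepted) {
      auto& v = kv.second;
      std::sort(v.begin(), v.end(), [](const Cand& a, const Cand& b) { return a.ed < b.ed; });
      std::vector<Cand> kept;
      for (auto& cd : v) {
        bool clash = false;
        for (auto& kp : kept) {
          int ov = std::min(cd.end, kp.end) - std::max(cd.start, kp.start);
          int shorter = std::min(cd.end - cd.start, kp.end - kp.start);
          if (ov > shorter / 2) { clash = true; break; }
        }
        if (!clash) kept.push_back(cd);
      }
      for (auto& kp : kept) {
        o_chunk.push_back(kv.first + 1);
        o_read.push_back(rd + 1);
        o_start.push_back(kp.start);
        o_end.push_back(kp.end);
        o_ed.push_back(kp.ed);
        o_strand.push_back(kp.strand);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["chunk"] = wrap(o_chunk), _["read"] = wrap(o_read),
                      _["read_start"] = wrap(o_start), _["read_end"] = wrap(o_end),
                      _["edit_distance"] = wrap(o_ed), _["strand"] = wrap(o_strand));
}
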