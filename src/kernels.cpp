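// Alignment kernels used by the concatemer decomposer and the desk-scale mapper.
// All DP is banded; scoring is match/mismatch/gap = 2/-4/-4 throughout.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <array>
#include <climits>

using namespace Rcpp;

static const int SC_MATCH = 2;
static const int SC_MISMATCH = -4;
static const int SC_GAP = -4;
static const int NEG_INF = -1000000000;

// Banded global (Needleman-Wunsch) alignment of a vs b.
// Band is centred on the interpolated diagonal j ~ i * n/m, half-width `band`.
// Returns score and identity (matches / aligned columns).
// [[Rcpp::export]]
List cpp_band_global(std::string a, std::string b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = (m + n) * SC_GAP, _["identity"] = 0.0);
  band = std::max(band, std::abs(m - n) + 2);
  const int W = 2 * band + 1;
  std::vector<int> lo(m + 1);
  for (int i = 0; i <= m; ++i) {
    int c = (int)((double)i * n / m + 0.5);
    lo[i] = std::max(0, c - band);
  }
  std::vector<int> prev(W, NEG_INF), cur(W, NEG_INF);
  std::vector<char> tb((size_t)(m + 1) * W, 0);
  // row 0
  for (int j = lo[0]; j <= std::min(n, lo[0] + W - 1); ++j) {
    prev[j - lo[0]] = j * SC_GAP;
    tb[j - lo[0]] = 'L';
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = lo[i], jhi = std::min(n, lo[i] + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG_INF; char dir = 0;
      // up: (i-1, j) gap in b
      int pj = j - lo[i - 1];
      if (pj >= 0 && pj < W && prev[pj] > NEG_INF) {
        int s = prev[pj] + SC_GAP;
        if (s > best) { best = s; dir = 'U'; }
      }
      // diag: (i-1, j-1)
      if (j >= 1) {
        int dj = j - 1 - lo[i - 1];
        if (dj >= 0 && dj < W && prev[dj] > NEG_INF) {
          int s = prev[dj] + (a[i - 1] == b[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (s > best) { best = s; dir = 'D'; }
        }
      }
      // left: (i, j-1) gap in a
      if (j >= 1) {
        int lj = j - 1 - jlo;
        if (lj >= 0 && cur[lj] > NEG_INF) {
          int s = cur[lj] + SC_GAP;
          if (s > best) { best = s; dir = 'L'; }
        }
      }
      if (dir) { cur[j - jlo] = best; tb[(size_t)i * W + (j - jlo)] = dir; }
    }
    std::swap(prev, cur);
  }
  int endIdx = n - lo[m];
  if (endIdx < 0 || endIdx >= W || prev[endIdx] <= NEG_INF)
    return List::create(_["score"] = NEG_INF, _["identity"] = 0.0);
  int score = prev[endIdx];
  // traceback for identity
  int i = m, j = n; long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    char d = tb[(size_t)i * W + (j - lo[i])];
    if (d == 'D') { cols++; if (a[i - 1] == b[j - 1]) matches++; --i; --j; }
    else if (d == 'U') { cols++; --i; }
    else if (d == 'L') { cols++; --j; }
    else break;
  }
  double ident = cols > 0 ? (double)matches / (double)cols : 0.0;
  return List::create(_["score"] = score, _["identity"] = ident);
}

// Fit alignment: the whole of `pattern` aligned against a best-matching
// substring of `text` (free start/end in text). The band is centred on
// j ~ off0 + i. Returns 0-based half-open [tstart, tend) in text, score,
// identity over the aligned region.
// [[Rcpp::export]]
List cpp_fit_align(std::string pattern, std::string text, int off0, int band) {
  const int m = (int)pattern.size(), n = (int)text.size();
  if (m == 0 || n == 0)
    return List::create(_["tstart"] = -1, _["tend"] = -1,
                        _["score"] = NEG_INF, _["identity"] = 0.0);
  const int W = 2 * band + 1;
  std::vector<int> lo(m + 1);
  for (int i = 0; i <= m; ++i) lo[i] = std::max(0, std::min(n, off0 + i - band));
  std::vector<int> prev(W, NEG_INF), cur(W, NEG_INF);
  std::vector<char> tb((size_t)(m + 1) * W, 0);
  for (int j = lo[0]; j <= std::min(n, lo[0] + W - 1); ++j) {
    prev[j - lo[0]] = 0;          // free start anywhere in text
    tb[j - lo[0]] = 'S';
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = lo[i], jhi = std::min(n, lo[i] + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG_INF; char dir = 0;
      int pj = j - lo[i - 1];
      if (pj >= 0 && pj < W && prev[pj] > NEG_INF) {
        int s = prev[pj] + SC_GAP;
        if (s > best) { best = s; dir = 'U'; }
      }
      if (j >= 1) {
        int dj = j - 1 - lo[i - 1];
        if (dj >= 0 && dj < W && prev[dj] > NEG_INF) {
          int s = prev[dj] + (pattern[i - 1] == text[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (s > best) { best = s; dir = 'D'; }
        }
        int lj = j - 1 - jlo;
        if (lj >= 0 && cur[lj] > NEG_INF) {
          int s = cur[lj] + SC_GAP;
          if (s > best) { best = s; dir = 'L'; }
        }
      }
      if (dir) { cur[j - jlo] = best; tb[(size_t)i * W + (j - jlo)] = dir; }
    }
    std::swap(prev, cur);
  }
  int bestJ = -1, bestS = NEG_INF;
  for (int j = lo[m]; j <= std::min(n, lo[m] + W - 1); ++j)
    if (prev[j - lo[m]] > bestS) { bestS = prev[j - lo[m]]; bestJ = j; }
  if (bestJ < 0)
    return List::create(_["tstart"] = -1, _["tend"] = -1,
                        _["score"] = NEG_INF, _["identity"] = 0.0);
  int i = m, j = bestJ; long matches = 0, cols = 0;
  while (i > 0) {
    char d = tb[(size_t)i * W + (j - lo[i])];
    if (d == 'D') { cols++; if (pattern[i - 1] == text[j - 1]) matches++; --i; --j; }
    else if (d == 'U') { cols++; --i; }
    else if (d == 'L') { cols++; --j; }
    else break;
  }
  double ident = cols > 0 ? (double)matches / (double)cols : 0.0;
  return List::create(_["tstart"] = j, _["tend"] = bestJ,
                      _["score"] = bestS, _["identity"] = ident);
}

// Banded global alignment of qry against ref, reported per reference column:
// cols[i] = query base aligned to ref position i ('-' if deleted in qry),
// ins[i]  = query bases inserted between ref positions i-1 and i
//           (ins has length m+1; ins[0] precedes the first ref base).
// [[Rcpp::export]]
List cpp_align_cols(std::string ref, std::string qry, int band) {
  const int m = (int)ref.size(), n = (int)qry.size();
  band = std::max(band, std::abs(m - n) + 2);
  const int W = 2 * band + 1;
  std::vector<int> lo(m + 1);
  for (int i = 0; i <= m; ++i) {
    int c = (int)((double)i * n / std::max(1, m) + 0.5);
    lo[i] = std::max(0, c - band);
  }
  std::vector<int> prev(W, NEG_INF), cur(W, NEG_INF);
  std::vector<char> tb((size_t)(m + 1) * W, 0);
  for (int j = lo[0]; j <= std::min(n, lo[0] + W - 1); ++j) {
    prev[j - lo[0]] = j * SC_GAP; tb[j - lo[0]] = 'L';
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG_INF);
    int jlo = lo[i], jhi = std::min(n, lo[i] + W - 1);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG_INF; char dir = 0;
      int pj = j - lo[i - 1];
      if (pj >= 0 && pj < W && prev[pj] > NEG_INF) {
        int s = prev[pj] + SC_GAP;
        if (s > best) { best = s; dir = 'U'; }
      }
      if (j >= 1) {
        int dj = j - 1 - lo[i - 1];
        if (dj >= 0 && dj < W && prev[dj] > NEG_INF) {
          int s = prev[dj] + (ref[i - 1] == qry[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (s > best) { best = s; dir = 'D'; }
        }
        int lj = j - 1 - jlo;
        if (lj >= 0 && cur[lj] > NEG_INF) {
          int s = cur[lj] + SC_GAP;
          if (s > best) { best = s; dir = 'L'; }
        }
      }
      if (dir) { cur[j - jlo] = best; tb[(size_t)i * W + (j - jlo)] = dir; }
    }
    std::swap(prev, cur);
  }
  int endIdx = n - lo[m];
  if (endIdx < 0 || endIdx >= W || prev[endIdx] <= NEG_INF)
    return List::create(_["ok"] = false);
  std::vector<char> cols(m, '-');
  std::vector<std::string> ins(m + 1, "");
  int i = m, j = n;
  while (i > 0 || j > 0) {
    char d = tb[(size_t)i * W + (j - lo[i])];
    if (d == 'D') { cols[i - 1] = qry[j - 1]; --i; --j; }
    else if (d == 'U') { cols[i - 1] = '-'; --i; }
    else if (d == 'L') { ins[i].insert(ins[i].begin(), qry[j - 1]); --j; }
    else break;
  }
  CharacterVector colsOut(m);
  for (int p = 0; p < m; ++p) colsOut[p] = std::string(1, cols[p]);
  return List::create(_["ok"] = true, _["cols"] = colsOut, _["ins"] = wrap(ins),
                      _["score"] = prev[endIdx]);
}

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    }
  }
  return r;
}

struct Chain {
  int qidx, chrom, strand, score;
  int qstart, qend, rstart, rend;
};

// Seed-and-chain: exact k-mer matches of each query (both strands) against the
// reference, grouped per (chrom, strand) into runs of near-constant diagonal
// (gap <= band_width). One row per chain.
// [[Rcpp::export]]
DataFrame cpp_map_chains(CharacterVector refseqs, CharacterVector queries,
                         int k, int band_width) {
  // reference k-mer index
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int nref = refseqs.size();
  for (int c = 0; c < nref; ++c) {
    std::string ref = as<std::string>(refseqs[c]);
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)ref.size(); ++p) {
      int b = baseCode(ref[p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[h].push_back({c, p - k + 1});
    }
  }
  std::vector<Chain> out;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qf = as<std::string>(queries[qi]);
    int qlen = (int)qf.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? qf : revcomp(qf);
      // hits as (chrom, diag, qpos, rpos)
      std::vector<std::array<int,4>> hits;
      uint64_t h = 0; int run = 0;
      for (int p = 0; p < (int)q.size(); ++p) {
        int b = baseCode(q[p]);
        if (b < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = index.find(h);
          if (it != index.end())
            for (auto& pr : it->second)
              hits.push_back({pr.first, pr.second - (p - k + 1), p - k + 1, pr.second});
        }
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end());
      size_t s = 0;
      for (size_t e = 1; e <= hits.size(); ++e) {
        bool brk = (e == hits.size()) || hits[e][0] != hits[s][0] ||
                   (long)hits[e][1] - (long)hits[e - 1][1] > band_width;
        if (brk) {
          int qlo = INT_MAX, qhi = INT_MIN, rlo = INT_MAX, rhi = INT_MIN;
          for (size_t t = s; t < e; ++t) {
            qlo = std::min(qlo, hits[t][2]); qhi = std::max(qhi, hits[t][2] + k);
            rlo = std::min(rlo, hits[t][3]); rhi = std::max(rhi, hits[t][3] + k);
          }
          Chain ch;
          ch.qidx = qi + 1; ch.chrom = hits[s][0] + 1;
          ch.strand = strand == 0 ? 1 : -1;
          ch.score = (int)(e - s);
          if (strand == 0) { ch.qstart = qlo; ch.qend = qhi; }
          else { ch.qstart = qlen - qhi; ch.qend = qlen - qlo; }
          ch.rstart = rlo; ch.rend = rhi;
          out.push_back(ch);
          s = e;
        }
      }
    }
  }
  int no = (int)out.size();
  IntegerVector qidx(no), chrom(no), strand(no), score(no),
      qstart(no), qend(no), rstart(no), rend(no);
  for (int i = 0; i < no; ++i) {
    qidx[i] = out[i].qidx; chrom[i] = out[i].chrom; strand[i] = out[i].strand;
    score[i] = out[i].score; qstart[i] = out[i].qstart; qend[i] = out[i].qend;
    rstart[i] = out[i].rstart; rend[i] = out[i].rend;
  }
  return DataFrame::create(_["qidx"] = qidx, _["chrom"] = chrom,
                           _["strand"] = strand, _["score"] = score,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["rstart"] = rstart, _["rend"] = rend);
}
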