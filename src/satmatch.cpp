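// k-mer index + ungapped X-drop seed-and-extend matcher.
// Coordinates are 0-based half-open throughout; conversion to/from other
// conventions happens on the R side.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
#include <array>
#include <climits>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;  // N and anything else: never indexed, never a match
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct KmerIndex {
  int k;
  std::string seq;
  std::unordered_map<uint64_t, std::vector<int> > map;
};

static void fill_index(KmerIndex& idx) {
  const std::string& s = idx.seq;
  const int k = idx.k;
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;  // length of current run of unambiguous bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx.map[key].push_back(i - k + 1);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k) {
  XPtr<KmerIndex> p(new KmerIndex(), true);
  p->k = k;
  p->seq = std::move(seq);
  fill_index(*p);
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP ptr, std::string kmer) {
  XPtr<KmerIndex> p(ptr);
  if ((int)kmer.size() != p->k) stop("k-mer length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return IntegerVector(0);
    key = (key << 2) | (uint64_t)b;
  }
  auto it = p->map.find(key);
  if (it == p->map.end()) return IntegerVector(0);
  return IntegerVector(it->second.begin(), it->second.end());
}

// [[Rcpp::export]]
int cpp_index_k(SEXP ptr) {
  XPtr<KmerIndex> p(ptr);
  return p->k;
}

struct Hit {
  int sstart, send;    // subject, 0-based half-open
  int qstart, qend;    // oriented query, 0-based half-open
  int matches, ts, tv, ncomp;
  int score;
  int strand;          // +1 / -1
};

// Ungapped X-drop extension of a seed (exact k-mer at q=qp, s=sp) along its
// diagonal; +1 match / -2 mismatch; N columns score as mismatch but are
// excluded from the comparable-column count used for identity and K2P.
// The reported span runs to the X-drop termination point (or the query /
// subject boundary), not back to the best-scoring column: this keeps hits
// over adjacent tandem copies abutting even when copy-boundary bases are
// substituted, so the merge step sees gap 0. The score reported is still
// the running maximum.
static Hit extend_seed(const std::string& q, const std::string& s,
                       int qp, int sp, int k, int xdrop, int strand) {
  const int ql = (int)q.size(), sl = (int)s.size();
  int score = k, best = k;
  int bq_r = qp + k, bs_r = sp + k;     // right boundary (exclusive)
  {
    int i = qp + k, j = sp + k;
    while (i < ql && j < sl) {
      char a = q[i], b = s[j];
      bool ok = base_code(a) >= 0 && base_code(b) >= 0 && a == b;
      score += ok ? 1 : -2;
      ++i; ++j;
      bq_r = i; bs_r = j;
      if (score > best) best = score;
      if (score < best - xdrop) break;
    }
  }
  int bq_l = qp, bs_l = sp;             // left boundary (inclusive)
  {
    int i = qp - 1, j = sp - 1;
    int cur = best;
    while (i >= 0 && j >= 0) {
      char a = q[i], b = s[j];
      bool ok = base_code(a) >= 0 && base_code(b) >= 0 && a == b;
      cur += ok ? 1 : -2;
      bq_l = i; bs_l = j;
      if (cur > best) best = cur;
      if (cur < best - xdrop) break;
      --i; --j;
    }
  }
  Hit h;
  h.qstart = bq_l; h.qend = bq_r;
  h.sstart = bs_l; h.send = bs_r;
  h.score = best;
  h.strand = strand;
  h.matches = 0; h.ts = 0; h.tv = 0; h.ncomp = 0;
  for (int i = bq_l, j = bs_l; i < bq_r; ++i, ++j) {
    char a = q[i], b = s[j];
    if (base_code(a) < 0 || base_code(b) < 0) continue;
    ++h.ncomp;
    if (a == b) { ++h.matches; continue; }
    bool transition = (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
                      (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
    if (transition) ++h.ts; else ++h.tv;
  }
  return h;
}

// All seeds of `query` (both orientations) against an indexed subject,
// extended and de-duplicated per diagonal to maximal segments.
static void match_one(const KmerIndex& idx, const std::string& query,
                      int xdrop, std::vector<Hit>& out) {
  const int k = idx.k;
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand == 0 ? query : revcomp(query);
    const int ql = (int)q.size();
    if (ql < k) continue;
    // collect seeds as (diagonal, spos, qpos)
    std::vector<std::array<int, 3> > seeds;
    uint64_t key = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < ql; ++i) {
      int c = base_code(q[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int qp = i - k + 1;
      auto it = idx.map.find(key);
      if (it == idx.map.end()) continue;
      for (int sp : it->second)
        seeds.push_back({sp - qp, sp, qp});
    }
    std::sort(seeds.begin(), seeds.end());
    int cur_diag = INT_MIN;
    int covered_end = -1;  // subject end covered on current diagonal
    for (auto& sd : seeds) {
      if (sd[0] != cur_diag) { cur_diag = sd[0]; covered_end = -1; }
      if (sd[1] + k <= covered_end) continue;  // seed inside an extension
      Hit h = extend_seed(q, idx.seq, sd[2], sd[1], k, xdrop,
                          strand == 0 ? 1 : -1);
      if (strand == 1) {  // report query coords on the original orientation
        int qs = ql - h.qend, qe = ql - h.qstart;
        h.qstart = qs; h.qend = qe;
      }
      covered_end = std::max(covered_end, h.send);
      out.push_back(h);
    }
  }
}

static DataFrame hits_to_df(const std::vector<Hit>& hits) {
  const int n = (int)hits.size();
  IntegerVector sstart(n), send(n), qstart(n), qend(n), matches(n),
      ts(n), tv(n), ncomp(n), score(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    const Hit& h = hits[i];
    sstart[i] = h.sstart; send[i] = h.send;
    qstart[i] = h.qstart; qend[i] = h.qend;
    matches[i] = h.matches; ts[i] = h.ts; tv[i] = h.tv; ncomp[i] = h.ncomp;
    score[i] = h.score;
    strand[i] = h.strand > 0 ? "+" : "-";
  }
  return DataFrame::create(
      _["sstart"] = sstart, _["send"] = send,
      _["qstart"] = qstart, _["qend"] = qend,
      _["matches"] = matches, _["transitions"] = ts,
      _["transversions"] = tv, _["comparable"] = ncomp,
      _["score"] = score, _["strand"] = strand,
      _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(SEXP ptr, std::string query, int xdrop) {
  XPtr<KmerIndex> p(ptr);
  std::vector<Hit> hits;
  match_one(*p, query, xdrop, hits);
  // drop exact duplicate subject segments (multiple diagonals rarely
  // converge on the same maximal segment; keep highest score)
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.sstart != b.sstart) return a.sstart < b.sstart;
    if (a.send != b.send) return a.send < b.send;
    return a.score > b.score;
  });
  std::vector<Hit> uniq;
  for (auto& h : hits) {
    if (!uniq.empty() && uniq.back().sstart == h.sstart &&
        uniq.back().send == h.send && uniq.back().strand == h.strand)
      continue;
    uniq.push_back(h);
  }
  return hits_to_df(uniq);
}

// Best ungapped alignment of each query sequence against a set of subject
// sequences (e.g. consensus dimers), both strands, shared k-mer index over
// all subjects. Returns the best-scoring hit per query (NA row if unseeded).
// [[Rcpp::export]]
DataFrame cpp_best_match(CharacterVector queries, CharacterVector subjects,
                         int k, int xdrop) {
  const int ns = subjects.size();
  // combined index: kmer -> (variant id, pos); variant = subject*2 + strand
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > cmap;
  std::vector<std::string> variants(2 * ns);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < ns; ++s) {
    variants[2 * s] = as<std::string>(subjects[s]);
    variants[2 * s + 1] = revcomp(variants[2 * s]);
    for (int v = 2 * s; v <= 2 * s + 1; ++v) {
      const std::string& sub = variants[v];
      uint64_t key = 0;
      int run = 0;
      for (int i = 0; i < (int)sub.size(); ++i) {
        int c = base_code(sub[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) cmap[key].push_back({v, i - k + 1});
      }
    }
  }
  const int nq = queries.size();
  IntegerVector subject_idx(nq), span(nq), matches(nq), ts(nq), tv(nq),
      ncomp(nq), score(nq), qstart(nq), qend(nq);
  CharacterVector strand(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    Hit best;
    best.score = -1;
    int best_var = -1;
    // seeds grouped per (variant, diagonal) with coverage skip
    std::vector<std::array<int, 4> > seeds;  // (variant, diag, spos, qpos)
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      int c = base_code(q[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      int qp = i - k + 1;
      auto it = cmap.find(key);
      if (it == cmap.end()) continue;
      for (auto& pr : it->second)
        seeds.push_back({pr.first, pr.second - qp, pr.second, qp});
    }
    std::sort(seeds.begin(), seeds.end());
    int cur_var = -1, cur_diag = INT_MIN, covered_end = -1;
    for (auto& sd : seeds) {
      if (sd[0] != cur_var || sd[1] != cur_diag) {
        cur_var = sd[0]; cur_diag = sd[1]; covered_end = -1;
      }
      if (sd[2] + k <= covered_end) continue;
      Hit h = extend_seed(q, variants[sd[0]], sd[3], sd[2], k, xdrop,
                          sd[0] % 2 == 0 ? 1 : -1);
      covered_end = std::max(covered_end, h.send);
      if (h.score > best.score) { best = h; best_var = sd[0]; }
    }
    if (best_var < 0) {
      subject_idx[qi] = NA_INTEGER;
      span[qi] = matches[qi] = ts[qi] = tv[qi] = ncomp[qi] = score[qi] =
          qstart[qi] = qend[qi] = NA_INTEGER;
      strand[qi] = NA_STRING;
    } else {
      subject_idx[qi] = best_var / 2 + 1;  // 1-based for R
      span[qi] = best.qend - best.qstart;
      matches[qi] = best.matches; ts[qi] = best.ts; tv[qi] = best.tv;
      ncomp[qi] = best.ncomp; score[qi] = best.score;
      qstart[qi] = best.qstart; qend[qi] = best.qend;
      strand[qi] = best.strand > 0 ? "+" : "-";
    }
  }
  return DataFrame::create(
      _["subject_idx"] = subject_idx, _["span"] = span,
      _["matches"] = matches, _["transitions"] = ts,
      _["transversions"] = tv, _["comparable"] = ncomp,
      _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
      _["strand"] = strand, _["stringsAsFactors"] = false);
}
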