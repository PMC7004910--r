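// Seed-and-extend local nucleotide aligner: 2-bit k-mer index over target
// sequences, diagonal clustering of seeds, and affine-gap Smith-Waterman
// extension inside the seed-implied window. Scoring: match +1, mismatch -1,
// gap open -2, gap extend -1 (first gap base costs 3). Also a mismatch-counting
// primer scanner used by the e-PCR module.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = 2, GAP_EXT = 1;

static inline int nt2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  int max_occ;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  // kmer code -> positions as (target, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int k, int max_occ) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->max_occ = max_occ;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < ids.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->ids.push_back(as<std::string>(ids[t]));
    uint64_t code = 0;
    int valid = 0; // consecutive valid nucleotides ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int c = nt2code(s[i]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        idx->map[code].push_back(std::make_pair((int32_t)t, (int32_t)(i - k + 1)));
      }
    }
    idx->seqs.push_back(std::move(s));
  }
  // repeat-seed cap
  for (auto it = idx->map.begin(); it != idx->map.end();) {
    if ((int)it->second.size() > max_occ) it = idx->map.erase(it);
    else ++it;
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(_["k"] = idx->k, _["max_occ"] = idx->max_occ,
                      _["n_targets"] = (int)idx->ids.size(),
                      _["n_kmers"] = (double)idx->map.size(),
                      _["target_ids"] = wrap(idx->ids));
}

// Occurrence count of a literal k-mer (0 if absent/capped/contains N).
// [[Rcpp::export]]
int cpp_kmer_count(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("kmer length != k");
  uint64_t code = 0;
  for (char c : kmer) {
    int v = nt2code(c);
    if (v < 0) return 0;
    code = (code << 2) | (uint64_t)v;
  }
  auto it = idx->map.find(code);
  return it == idx->map.end() ? 0 : (int)it->second.size();
}

struct Hit {
  int target;
  int q_start, q_end, t_start, t_end; // on searched strands
  int matches, mismatches, gap_opens, columns, score;
  char strand;
};

// Affine local SW over q[qa,qb) x t[ta,tb); returns best hit (score 0 if none).
static Hit sw_rect(const std::string &q, const std::string &t,
                   int qa, int qb, int ta, int tb) {
  int m = qb - qa, n = tb - ta;
  Hit best; best.score = 0;
  if (m <= 0 || n <= 0) return best;
  const int NEG = INT32_MIN / 4;
  std::vector<int> H(n + 1, 0), Hprev(n + 1, 0), Fv(n + 1, NEG);
  std::vector<uint8_t> tb_mat((size_t)(m + 1) * (n + 1), 0);
  int best_score = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    std::swap(Hprev, H);
    H[0] = 0;
    int Ecur = NEG; // horizontal gap state, depends on (i, j-1)
    char qc = q[qa + i - 1];
    for (int j = 1; j <= n; ++j) {
      // E: gap consuming target (horizontal, from column j-1 of this row)
      int e_open = H[j - 1] - GAP_OPEN - GAP_EXT;
      int e_ext = Ecur - GAP_EXT;
      uint8_t code = 0;
      int e;
      if (e_ext > e_open) { e = e_ext; code |= 4; } else { e = e_open; }
      Ecur = e;
      // F: gap consuming query (vertical, from row i-1 same column)
      int f_open = Hprev[j] - GAP_OPEN - GAP_EXT;
      int f_ext = Fv[j] - GAP_EXT;
      int f;
      if (f_ext > f_open) { f = f_ext; code |= 8; } else { f = f_open; }
      Fv[j] = f;
      char tc = t[ta + j - 1];
      bool isN = (nt2code(qc) < 0 || nt2code(tc) < 0);
      int sub = (!isN && qc == tc) ? MATCH : MISMATCH;
      int diag = Hprev[j - 1] + sub;
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      H[j] = h;
      tb_mat[(size_t)i * (n + 1) + j] = code | dir;
      if (h > best_score) { best_score = h; bi = i; bj = j; }
    }
  }
  if (best_score <= 0) return best;
  // traceback
  int i = bi, j = bj;
  int matches = 0, mism = 0, gaps = 0, cols = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    uint8_t cell = tb_mat[(size_t)i * (n + 1) + j];
    if (state == 0) {
      uint8_t dir = cell & 3;
      if (dir == 0) break;
      if (dir == 1) {
        char qc = q[qa + i - 1], tc = t[ta + j - 1];
        bool isN = (nt2code(qc) < 0 || nt2code(tc) < 0);
        if (!isN && qc == tc) ++matches; else ++mism;
        ++cols; --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: consumed target
      ++cols;
      bool ext = (cell & 4) != 0;
      --j;
      if (!ext) { ++gaps; state = 0; }
    } else { // F: consumed query
      ++cols;
      bool ext = (cell & 8) != 0;
      --i;
      if (!ext) { ++gaps; state = 0; }
    }
  }
  best.score = best_score;
  best.q_start = qa + i; best.q_end = qa + bi;
  best.t_start = ta + j; best.t_end = ta + bj;
  best.matches = matches; best.mismatches = mism;
  best.gap_opens = gaps; best.columns = cols;
  return best;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (char &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Seed { int target, qpos, tpos; };

static void align_one_strand(const KmerIndex &idx, const std::string &q,
                             char strand, int qlen_full,
                             double min_identity, int min_len,
                             std::vector<Hit> &out) {
  int k = idx.k;
  int qlen = (int)q.size();
  if (qlen < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<Seed> seeds;
  uint64_t code = 0; int valid = 0;
  for (int i = 0; i < qlen; ++i) {
    int c = nt2code(q[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto it = idx.map.find(code);
      if (it != idx.map.end()) {
        for (auto &p : it->second) {
          Seed s; s.target = p.first; s.qpos = i - k + 1; s.tpos = p.second;
          seeds.push_back(s);
        }
      }
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    if (a.target != b.target) return a.target < b.target;
    long da = (long)a.tpos - a.qpos, db = (long)b.tpos - b.qpos;
    if (da != db) return da < db;
    return a.qpos < b.qpos;
  });
  const int band = 100, margin = 150;
  size_t i0 = 0;
  while (i0 < seeds.size()) {
    size_t i1 = i0 + 1;
    long diag0 = (long)seeds[i0].tpos - seeds[i0].qpos;
    long diag_last = diag0;
    int qlo = seeds[i0].qpos, qhi = seeds[i0].qpos;
    int tlo = seeds[i0].tpos, thi = seeds[i0].tpos;
    while (i1 < seeds.size() && seeds[i1].target == seeds[i0].target) {
      long d = (long)seeds[i1].tpos - seeds[i1].qpos;
      if (d - diag_last > band) break;
      diag_last = d;
      qlo = std::min(qlo, seeds[i1].qpos); qhi = std::max(qhi, seeds[i1].qpos);
      tlo = std::min(tlo, seeds[i1].tpos); thi = std::max(thi, seeds[i1].tpos);
      ++i1;
    }
    int t = seeds[i0].target;
    const std::string &ts = idx.seqs[t];
    int tlen = (int)ts.size();
    int qa, qb, ta, tb;
    if (tlen <= 1000) { qa = 0; qb = qlen; ta = 0; tb = tlen; }
    else {
      qa = std::max(0, qlo - margin);
      qb = std::min(qlen, qhi + k + margin);
      ta = std::max(0, tlo - (qlo - qa) - band);
      tb = std::min(tlen, thi + k + (qb - (qhi + k)) + band);
    }
    Hit h = sw_rect(q, ts, qa, qb, ta, tb);
    if (h.score > 0) {
      double ident = (double)h.matches / h.columns;
      if (ident >= min_identity && h.columns >= min_len) {
        h.target = t;
        h.strand = strand;
        if (strand == '-') {
          // convert query coords back to the forward query strand
          int qs = qlen_full - h.q_end, qe = qlen_full - h.q_start;
          h.q_start = qs; h.q_end = qe;
        }
        out.push_back(h);
      }
    }
    i0 = i1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_local_align(SEXP xp, CharacterVector query_ids,
                          CharacterVector query_seqs,
                          double min_identity, int min_len, int merge_dist) {
  XPtr<KmerIndex> idx(xp);
  std::vector<std::string> o_query, o_target;
  std::vector<int> o_qs, o_qe, o_ts, o_te, o_match, o_mism, o_gap, o_cols, o_score;
  std::vector<std::string> o_strand;
  std::vector<double> o_ident;

  for (int qi = 0; qi < query_ids.size(); ++qi) {
    std::string q = as<std::string>(query_seqs[qi]);
    int qlen = (int)q.size();
    std::vector<Hit> hits;
    align_one_strand(*idx, q, '+', qlen, min_identity, min_len, hits);
    std::string qrc = revcomp_str(q);
    align_one_strand(*idx, qrc, '-', qlen, min_identity, min_len, hits);
    // merge: keep highest-scoring among hits on the same (target, strand)
    // whose target intervals come within merge_dist bp of each other
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      return a.score > b.score;
    });
    std::vector<Hit> kept;
    for (auto &h : hits) {
      bool drop = false;
      for (auto &kh : kept) {
        if (kh.target == h.target && kh.strand == h.strand &&
            h.t_start < kh.t_end + merge_dist && kh.t_start < h.t_end + merge_dist) {
          drop = true; break;
        }
      }
      if (!drop) kept.push_back(h);
    }
    // sort: score desc, ties by (target_id, t_start)
    std::sort(kept.begin(), kept.end(), [&](const Hit &a, const Hit &b) {
      if (a.score != b.score) return a.score > b.score;
      if (idx->ids[a.target] != idx->ids[b.target])
        return idx->ids[a.target] < idx->ids[b.target];
      return a.t_start < b.t_start;
    });
    std::string qid = as<std::string>(query_ids[qi]);
    for (auto &h : kept) {
      o_query.push_back(qid);
      o_target.push_back(idx->ids[h.target]);
      o_qs.push_back(h.q_start); o_qe.push_back(h.q_end);
      o_ts.push_back(h.t_start); o_te.push_back(h.t_end);
      o_strand.push_back(std::string(1, h.strand));
      o_match.push_back(h.matches); o_mism.push_back(h.mismatches);
      o_gap.push_back(h.gap_opens); o_cols.push_back(h.columns);
      o_ident.push_back((double)h.matches / h.columns);
      o_score.push_back(h.score);
    }
  }
  return DataFrame::create(
    _["query_id"] = o_query, _["target_id"] = o_target,
    _["q_start"] = o_qs, _["q_end"] = o_qe,
    _["t_start"] = o_ts, _["t_end"] = o_te,
    _["strand"] = o_strand,
    _["matches"] = o_match, _["mismatches"] = o_mism,
    _["gap_opens"] = o_gap, _["length"] = o_cols,
    _["identity"] = o_ident, _["score"] = o_score,
    _["stringsAsFactors"] = false);
}

// Positions (0-based) where `pattern` matches `text` with at most max_mismatch
// mismatches; if exact_right, the last three_prime_exact pattern bases must
// match exactly, else the first ones must. N never matches.
// [[Rcpp::export]]
DataFrame cpp_scan_primer(std::string text, std::string pattern,
                          int max_mismatch, int three_prime_exact,
                          bool exact_right) {
  int n = (int)text.size(), m = (int)pattern.size();
  std::vector<int> pos, mm;
  for (int i = 0; i + m <= n; ++i) {
    int mis = 0; bool ok = true;
    for (int j = 0; j < m; ++j) {
      char tc = text[i + j], pc = pattern[j];
      bool match = (tc == pc) && nt2code(tc) >= 0;
      if (!match) {
        bool in_exact = exact_right ? (j >= m - three_prime_exact)
                                    : (j < three_prime_exact);
        if (in_exact || ++mis > max_mismatch) { ok = false; break; }
      }
    }
    if (ok) { pos.push_back(i); mm.push_back(mis); }
  }
  return DataFrame::create(_["pos"] = pos, _["mismatches"] = mm);
}
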