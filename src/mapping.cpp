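// Ungapped seed-and-extend read mapping against candidate amplicons, plus
// the EM inner loops (per-cycle emission log-probabilities and
// posterior-weighted consensus updates). Substitution-only by design: the
// simulator introduces no indels, so ungapped placement is exact.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N'; break;
    }
  }
  return r;
}

// k-mer index over candidate sequences: 2-bit packed k-mer -> (cand, pos)
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
};

static void build_index(const std::vector<std::string> &cands, int k,
                        KmerIndex &idx) {
  idx.k = k;
  for (int c = 0; c < (int)cands.size(); ++c) {
    const std::string &s = cands[c];
    if ((int)s.size() < k) continue;
    uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx.map[key].emplace_back(c, i - k + 1);
    }
  }
}

// candidate placements of one string: best (fewest-mismatch) start per
// candidate, found from exact seed hits at up to three offsets
static void place_string(const std::string &s, const KmerIndex &idx,
                         const std::vector<std::string> &cands,
                         std::unordered_map<int, std::pair<int, int>> &out) {
  out.clear();
  int len = (int)s.size(), k = idx.k;
  if (len < k) return;
  int offs[3] = {0, (len - k) / 2, len - k};
  std::vector<std::pair<int, int>> tried; // (cand, start) already verified
  for (int oi = 0; oi < 3; ++oi) {
    int o = offs[oi];
    if (oi == 1 && o == offs[0]) continue;
    if (oi == 2 && (o == offs[0] || o == offs[1])) continue;
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base_code(s[o + i]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (auto &hit : it->second) {
      int c = hit.first, start = hit.second - o;
      if (start < 0 || start + len > (int)cands[c].size()) continue;
      bool seen = false;
      for (auto &t : tried)
        if (t.first == c && t.second == start) { seen = true; break; }
      if (seen) continue;
      tried.emplace_back(c, start);
      const std::string &cs = cands[c];
      int mm = 0;
      for (int i = 0; i < len; ++i)
        if (cs[start + i] != s[i]) ++mm;
      auto cur = out.find(c);
      if (cur == out.end() || mm < cur->second.second)
        out[c] = std::make_pair(start, mm);
    }
  }
}

// Map read pairs against candidates. Orientation 1: mate1 forward +
// revcomp(mate2) downstream; orientation 2: mate2 forward +
// revcomp(mate1) downstream (pair drawn from the opposite strand).
// A (pair, candidate) mapping is retained when both mates place with a
// combined mismatch rate <= max_rate; the better orientation wins.
// [[Rcpp::export]]
DataFrame cpp_map_pairs(CharacterVector cand_seqs, CharacterVector mate1,
                        CharacterVector mate2, int k = 15,
                        double max_rate = 0.06, int slack = 10) {
  std::vector<std::string> cands(cand_seqs.size());
  for (int i = 0; i < cand_seqs.size(); ++i)
    cands[i] = as<std::string>(cand_seqs[i]);
  KmerIndex idx;
  build_index(cands, k, idx);

  std::vector<int> r_pair, r_cand, r_off1, r_off2, r_mm, r_orient;
  std::unordered_map<int, std::pair<int, int>> pA, pB;

  for (int p = 0; p < mate1.size(); ++p) {
    std::string m1 = as<std::string>(mate1[p]);
    std::string m2 = as<std::string>(mate2[p]);
    int len1 = (int)m1.size(), len2 = (int)m2.size();
    double tot = (double)(len1 + len2);
    // orientation 1: m1 as-is (left), rc(m2) (right)
    std::string m2rc = revcomp_str(m2);
    std::string m1rc = revcomp_str(m1);
    place_string(m1, idx, cands, pA);
    place_string(m2rc, idx, cands, pB);
    std::unordered_map<int, std::array<int, 4>> best; // off1, off2, mm, orient
    for (auto &a : pA) {
      auto b = pB.find(a.first);
      if (b == pB.end()) continue;
      int off1 = a.second.first, off2 = b->second.first;
      if (off2 < off1 - slack) continue;
      int mm = a.second.second + b->second.second;
      if (mm > max_rate * tot) continue;
      best[a.first] = {off1, off2, mm, 1};
    }
    // orientation 2: m2 as-is (left), rc(m1) (right)
    place_string(m2, idx, cands, pA);
    place_string(m1rc, idx, cands, pB);
    for (auto &a : pA) {
      auto b = pB.find(a.first);
      if (b == pB.end()) continue;
      int off2 = a.second.first, off1 = b->second.first;
      if (off1 < off2 - slack) continue;
      int mm = a.second.second + b->second.second;
      if (mm > max_rate * tot) continue;
      auto cur = best.find(a.first);
      if (cur == best.end() || mm < cur->second[2])
        best[a.first] = {off1, off2, mm, 2};
    }
    for (auto &e : best) {
      r_pair.push_back(p + 1);
      r_cand.push_back(e.first + 1);
      r_off1.push_back(e.second[0]);
      r_off2.push_back(e.second[1]);
      r_mm.push_back(e.second[2]);
      r_orient.push_back(e.second[3]);
    }
  }
  return DataFrame::create(_["pair"] = r_pair, _["cand"] = r_cand,
                           _["off1"] = r_off1, _["off2"] = r_off2,
                           _["mm"] = r_mm, _["orient"] = r_orient);
}

// Per-mapping log emission probability under the per-cycle error model:
// log P = sum_i [ match_i ? log(1 - eps_cycle) : log(eps_cycle / 3) ].
// off1/off2 are the candidate offsets of the placed mate strings; in
// orientation 1, mate1 is placed forward (cycle = position within the
// placed string) and mate2 reverse-complemented (cycle runs backwards);
// orientation 2 is the mirror image. Also returns the current mismatch
// count of each mapping against the (possibly updated) consensus.
// [[Rcpp::export]]
List cpp_log_emissions(CharacterVector cand_seqs, CharacterVector mate1,
                       CharacterVector mate2, IntegerVector map_pair,
                       IntegerVector map_cand, IntegerVector off1,
                       IntegerVector off2, IntegerVector orient,
                       NumericVector eps) {
  int n = map_pair.size();
  NumericVector loge(n);
  IntegerVector mm_out(n);
  int ncyc = eps.size();
  std::vector<double> lmatch(ncyc), lmis(ncyc);
  for (int i = 0; i < ncyc; ++i) {
    double e = eps[i];
    if (e <= 0) e = 1e-12;
    if (e >= 1) e = 1 - 1e-12;
    lmatch[i] = std::log1p(-e);
    lmis[i] = std::log(e / 3.0);
  }
  std::vector<std::string> cands(cand_seqs.size());
  for (int i = 0; i < cand_seqs.size(); ++i)
    cands[i] = as<std::string>(cand_seqs[i]);

  int last_pair = -1;
  std::string m1, m2, m1p, m2p;
  for (int r = 0; r < n; ++r) {
    int p = map_pair[r] - 1;
    if (p != last_pair) {
      m1 = as<std::string>(mate1[p]);
      m2 = as<std::string>(mate2[p]);
      last_pair = p;
      m1p.clear(); m2p.clear();
    }
    const std::string &cs = cands[map_cand[r] - 1];
    int len1 = (int)m1.size(), len2 = (int)m2.size();
    double ll = 0; int mm = 0;
    if (orient[r] == 1) {
      // mate1 forward: placed-string pos i == sequencing cycle i
      for (int i = 0; i < len1; ++i) {
        int cyc = i < ncyc ? i : ncyc - 1;
        if (cs[off1[r] + i] == m1[i]) ll += lmatch[cyc];
        else { ll += lmis[cyc]; ++mm; }
      }
      if (m2p.empty()) m2p = revcomp_str(m2);
      // rc(mate2) pos j == sequencing cycle len2-1-j
      for (int j = 0; j < len2; ++j) {
        int cyc = len2 - 1 - j; if (cyc >= ncyc) cyc = ncyc - 1;
        if (cs[off2[r] + j] == m2p[j]) ll += lmatch[cyc];
        else { ll += lmis[cyc]; ++mm; }
      }
    } else {
      if (m1p.empty()) m1p = revcomp_str(m1);
      for (int j = 0; j < len1; ++j) {
        int cyc = len1 - 1 - j; if (cyc >= ncyc) cyc = ncyc - 1;
        if (cs[off1[r] + j] == m1p[j]) ll += lmatch[cyc];
        else { ll += lmis[cyc]; ++mm; }
      }
      for (int i = 0; i < len2; ++i) {
        int cyc = i < ncyc ? i : ncyc - 1;
        if (cs[off2[r] + i] == m2[i]) ll += lmatch[cyc];
        else { ll += lmis[cyc]; ++mm; }
      }
    }
    loge[r] = ll;
    mm_out[r] = mm;
  }
  return List::create(_["loge"] = loge, _["mm"] = mm_out);
}

// Posterior-weighted consensus update. For every candidate position the
// responsibilities of the mapped pairs vote for the base their read
// carries; the current base is replaced by the argmax base iff the
// challenger's weight is at least `ratio` times the current base's weight
// (ties keep the current base) and reaches `min_weight` posterior
// read-equivalents — a base is never rewritten on negligible evidence.
// [[Rcpp::export]]
CharacterVector cpp_consensus_update(CharacterVector cand_seqs,
                                     CharacterVector mate1,
                                     CharacterVector mate2,
                                     IntegerVector map_pair,
                                     IntegerVector map_cand,
                                     IntegerVector off1, IntegerVector off2,
                                     IntegerVector orient,
                                     NumericVector resp,
                                     double ratio = 1.5,
                                     double min_weight = 0.5) {
  int ncand = cand_seqs.size();
  std::vector<std::string> cands(ncand);
  std::vector<std::vector<double>> counts(ncand);
  for (int i = 0; i < ncand; ++i) {
    cands[i] = as<std::string>(cand_seqs[i]);
    counts[i].assign(4 * cands[i].size(), 0.0);
  }
  int n = map_pair.size();
  int last_pair = -1;
  std::string m1p, m2p;
  for (int r = 0; r < n; ++r) {
    double w = resp[r];
    if (w <= 0) continue;
    int p = map_pair[r] - 1;
    if (p != last_pair) {
      m1p = as<std::string>(mate1[p]);
      m2p = as<std::string>(mate2[p]);
      last_pair = p;
    }
    int c = map_cand[r] - 1;
    std::vector<double> &cnt = counts[c];
    std::string s1 = (orient[r] == 1) ? m1p : revcomp_str(m1p);
    std::string s2 = (orient[r] == 1) ? revcomp_str(m2p) : m2p;
    for (int i = 0; i < (int)s1.size(); ++i) {
      int b = base_code(s1[i]);
      if (b >= 0) cnt[4 * (off1[r] + i) + b] += w;
    }
    for (int i = 0; i < (int)s2.size(); ++i) {
      int b = base_code(s2[i]);
      if (b >= 0) cnt[4 * (off2[r] + i) + b] += w;
    }
  }
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(ncand);
  for (int c = 0; c < ncand; ++c) {
    std::string s = cands[c];
    const std::vector<double> &cnt = counts[c];
    for (int i = 0; i < (int)s.size(); ++i) {
      int cur = base_code(s[i]);
      double wcur = (cur >= 0) ? cnt[4 * i + cur] : 0.0;
      int bestb = -1; double wbest = 0.0;
      for (int b = 0; b < 4; ++b) {
        if (b == cur) continue;
        double w = cnt[4 * i + b];
        if (w > wbest) { wbest = w; bestb = b; }
      }
      if (bestb >= 0 && wbest >= min_weight && wbest >= ratio * wcur)
        s[i] = BASES[bestb];
    }
    out[c] = s;
  }
  return out;
}

// One E-step pass: responsibilities r(p,k) proportional to
// pi_k * P(pair p | candidate k), normalized per pair over its mapped
// candidates, plus the total log-likelihood of the mapped pairs.
// [[Rcpp::export]]
List cpp_estep(NumericVector loge, IntegerVector map_pair,
               IntegerVector map_cand, NumericVector log_pi, int n_pairs) {
  int n = loge.size();
  std::vector<double> mx(n_pairs + 1, R_NegInf);
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    w[i] = loge[i] + log_pi[map_cand[i] - 1];
    int p = map_pair[i];
    if (w[i] > mx[p]) mx[p] = w[i];
  }
  std::vector<double> denom(n_pairs + 1, 0.0);
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    e[i] = std::exp(w[i] - mx[map_pair[i]]);
    denom[map_pair[i]] += e[i];
  }
  double ll = 0;
  for (int p = 1; p <= n_pairs; ++p)
    if (R_FINITE(mx[p])) ll += std::log(denom[p]) + mx[p];
  NumericVector resp(n);
  for (int i = 0; i < n; ++i) resp[i] = e[i] / denom[map_pair[i]];
  return List::create(_["resp"] = resp, _["loglik"] = ll);
}

// Best single-read placement per read against a centroid set, scanning
// both strands. Returns one row per read that places at all: the centroid
// with the highest ungapped identity (ties: lowest centroid index).
// [[Rcpp::export]]
DataFrame cpp_map_single(CharacterVector cand_seqs, CharacterVector reads,
                         int k = 15) {
  std::vector<std::string> cands(cand_seqs.size());
  for (int i = 0; i < cand_seqs.size(); ++i)
    cands[i] = as<std::string>(cand_seqs[i]);
  KmerIndex idx;
  build_index(cands, k, idx);
  std::vector<int> r_read, r_cand, r_mm, r_len;
  std::vector<int> r_strand;
  std::unordered_map<int, std::pair<int, int>> fwd, rev;
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    std::string sr = revcomp_str(s);
    place_string(s, idx, cands, fwd);
    place_string(sr, idx, cands, rev);
    int bc = -1, bmm = 0, bstrand = 0;
    for (auto &e : fwd) {
      int c = e.first, mm = e.second.second;
      if (bc < 0 || mm < bmm || (mm == bmm && c < bc)) {
        bc = c; bmm = mm; bstrand = 1;
      }
    }
    for (auto &e : rev) {
      int c = e.first, mm = e.second.second;
      if (bc < 0 || mm < bmm || (mm == bmm && c < bc)) {
        bc = c; bmm = mm; bstrand = -1;
      }
    }
    if (bc >= 0) {
      r_read.push_back(i + 1);
      r_cand.push_back(bc + 1);
      r_mm.push_back(bmm);
      r_len.push_back((int)s.size());
      r_strand.push_back(bstrand);
    }
  }
  return DataFrame::create(_["read"] = r_read, _["cand"] = r_cand,
                           _["mm"] = r_mm, _["len"] = r_len,
                           _["strand"] = r_strand);
}

// Shared k-mer counts between each query and each reference, per strand;
// used to shortlist references (and pick the strand) before alignment.
// [[Rcpp::export]]
List cpp_kmer_hits(CharacterVector ref_seqs, CharacterVector queries,
                   int k = 12) {
  std::vector<std::string> refs(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i)
    refs[i] = as<std::string>(ref_seqs[i]);
  KmerIndex idx;
  build_index(refs, k, idx);
  IntegerMatrix fwd(queries.size(), ref_seqs.size());
  IntegerMatrix rev(queries.size(), ref_seqs.size());
  for (int q = 0; q < queries.size(); ++q) {
    for (int strand = 0; strand < 2; ++strand) {
      IntegerMatrix &out = strand == 0 ? fwd : rev;
      std::string s = as<std::string>(queries[q]);
      if (strand == 1) s = revcomp_str(s);
      if ((int)s.size() < k) continue;
      uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int run = 0;
      for (int i = 0; i < (int)s.size(); ++i) {
        int b = base_code(s[i]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto it = idx.map.find(key);
          if (it != idx.map.end()) {
            std::vector<bool> seen(ref_seqs.size(), false);
            for (auto &h : it->second)
              if (!seen[h.first]) { out(q, h.first) += 1; seen[h.first] = true; }
          }
        }
      }
    }
  }
  return List::create(_["fwd"] = fwd, _["rev"] = rev);
}
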