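#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped small-RNA alignment core. All placements are full-length,
// both strands, Hamming distance <= max_mm. 'N' never matches anything
// (including 'N'). Coordinates returned 1-based inclusive on the plus
// strand of the reference.

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break;
      case 'C': r = 'G'; break;
      case 'G': r = 'C'; break;
      case 'T': r = 'A'; break;
      default:  r = 'N';
    }
    out[i] = r;
  }
  return out;
}

// 2-bit encode a k-mer; returns false if any non-ACGT base present.
static bool encode_kmer(const char *p, int k, uint64_t &key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t v;
    switch (p[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false;
    }
    key = (key << 2) | v;
  }
  return true;
}

struct Hit {
  int ref;    // 0-based reference index
  int start;  // 0-based start
  int strand; // 0 = '+', 1 = '-'
  int mm;
};

static inline int hamming_le(const std::string &ref, int s,
                             const std::string &q, int max_mm) {
  int mm = 0;
  const int L = (int) q.size();
  for (int i = 0; i < L; ++i) {
    if (!base_match(ref[s + i], q[i])) {
      if (++mm > max_mm) return -1;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_enumerate_placements(CharacterVector reads,
                                   CharacterVector refs,
                                   int max_mm,
                                   int seed_len = 12) {
  const int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> R(n_refs);
  for (int r = 0; r < n_refs; ++r) R[r] = as<std::string>(refs[r]);

  // Seed index over reference plus strands, used for exact (tier-0) search
  // only: a 0-mismatch full-length placement forces its first seed_len-mer
  // to occur verbatim. For max_mm > 0 a clean seed window is not guaranteed
  // on short reads, so those tiers use the exhaustive scan below.
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  const bool use_index = (max_mm == 0);
  if (use_index) {
    for (int r = 0; r < n_refs; ++r) {
      const std::string &S = R[r];
      const int M = (int) S.size();
      for (int s = 0; s + seed_len <= M; ++s) {
        uint64_t key;
        if (encode_kmer(S.c_str() + s, seed_len, key))
          index[key].push_back(std::make_pair(r, s));
      }
    }
  }

  std::vector<int> o_read, o_ref, o_start, o_mm;
  std::vector<int> o_strand;

  for (int i = 0; i < n_reads; ++i) {
    const std::string fwd = as<std::string>(reads[i]);
    const std::string rev = revcomp(fwd);
    const int L = (int) fwd.size();
    std::vector<Hit> hits;

    if (use_index && L >= seed_len) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &q = strand == 0 ? fwd : rev;
        uint64_t key;
        if (!encode_kmer(q.c_str(), seed_len, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (auto &cand : it->second) {
          const std::string &S = R[cand.first];
          if (cand.second + L > (int) S.size()) continue;
          int mm = hamming_le(S, cand.second, q, 0);
          if (mm >= 0) hits.push_back({cand.first, cand.second, strand, mm});
        }
      }
    } else {
      for (int r = 0; r < n_refs; ++r) {
        const std::string &S = R[r];
        const int M = (int) S.size();
        for (int s = 0; s + L <= M; ++s) {
          int mm = hamming_le(S, s, fwd, max_mm);
          if (mm >= 0) hits.push_back({r, s, 0, mm});
          mm = hamming_le(S, s, rev, max_mm);
          if (mm >= 0) hits.push_back({r, s, 1, mm});
        }
      }
    }

    // deterministic order: ref, start, '+' before '-'
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    for (auto &h : hits) {
      o_read.push_back(i + 1);
      o_ref.push_back(h.ref + 1);
      o_start.push_back(h.start + 1);
      o_strand.push_back(h.strand);
      o_mm.push_back(h.mm);
    }
  }

  return DataFrame::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["start"] = wrap(o_start), _["minus"] = wrap(o_strand),
    _["mismatches"] = wrap(o_mm));
}

// 3' adapter trimming: leftmost read position where a prefix of the adapter
// (overlap >= min_overlap, at most max_mm mismatches) matches a window
// running to (at most) the read end. Returns kept insert lengths.
// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector reads, std::string adapter,
                               int min_overlap, int max_mm) {
  const int n = reads.size(), alen = (int) adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int L = (int) rd.size();
    int keep = L;
    for (int p = 0; p < L; ++p) {
      const int overlap = std::min(alen, L - p);
      if (overlap < min_overlap) break;
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < overlap; ++j) {
        if (!base_match(rd[p + j], adapter[j])) {
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { keep = p; break; }
    }
    out[i] = keep;
  }
  return out;
}
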