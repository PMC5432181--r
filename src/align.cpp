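#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Ungapped alignment kernels. Indels are not modelled anywhere in the
// package (negligible on the Illumina platform), so all placement is a
// sliding-offset search scored by matches - mismatches.

static inline bool base_match(char a, char b) {
  // N never matches (treated as a mismatch on both sides)
  if (a == 'N' || b == 'N') return false;
  return a == b;
}


// Best ungapped overlap between a forward read and the reverse-complemented
// mate. Offsets place the start of `b` inside `a`; the overlap is the region
// where both are defined. Returns the best-scoring offset (score =
// matches - mismatches), 0-based.
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_overlap) {
  int na = a.size(), nb = b.size();
  int best_off = -1, best_score = INT_MIN, best_mm = 0, best_len = 0;
  int max_off = na - min_overlap;
  for (int off = 0; off <= max_off; ++off) {
    int len = std::min(na - off, nb);
    if (len < min_overlap) break;
    int m = 0, mm = 0;
    for (int i = 0; i < len; ++i) {
      if (base_match(a[off + i], b[i])) ++m; else ++mm;
    }
    int score = m - mm;
    if (score > best_score) {
      best_score = score; best_off = off; best_mm = mm; best_len = len;
    }
  }
  return List::create(_["offset"] = best_off, _["score"] = best_score,
                      _["mismatches"] = best_mm, _["overlap_len"] = best_len);
}

struct KmerIndex {
  std::unordered_map<std::string, std::vector<int>> pos;
  int k;
  KmerIndex(const std::string& ref, int k_) : k(k_) {
    int n = ref.size();
    for (int i = 0; i + k <= n; ++i) pos[ref.substr(i, k)].push_back(i);
  }
};

static void score_offset(const std::string& read, const std::string& ref,
                         int off, int& mm, int& len) {
  // off may be negative or run past the reference end; only the aligned
  // portion is scored
  int n = read.size(), nr = ref.size();
  mm = 0; len = 0;
  for (int i = 0; i < n; ++i) {
    int p = off + i;
    if (p < 0 || p >= nr) continue;
    ++len;
    if (!base_match(read[i], ref[p])) ++mm;
  }
}


// Place each read at its best ungapped offset on a reference, searching both
// strands via exact k-mer anchors. Returns per read: 0-based offset on the
// chosen strand, strand (+1 forward, -1 reverse), mismatches, aligned length.
// Reads with no anchor hit anywhere get offset NA.
// [[Rcpp::export]]
DataFrame cpp_place_reads(CharacterVector reads, std::string ref_fwd,
                          std::string ref_rev, int k, int anchor_step) {
  KmerIndex idx_f(ref_fwd, k), idx_r(ref_rev, k);
  int nreads = reads.size();
  IntegerVector out_off(nreads), out_strand(nreads), out_mm(nreads),
      out_len(nreads);
  for (int r = 0; r < nreads; ++r) {
    std::string read = as<std::string>(reads[r]);
    int n = read.size();
    int best_mm = INT_MAX, best_len = 0, best_off = NA_INTEGER, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const KmerIndex& idx = strand == 0 ? idx_f : idx_r;
      const std::string& ref = strand == 0 ? ref_fwd : ref_rev;
      std::vector<int> cand;
      for (int a = 0; a + k <= n; a += anchor_step) {
        auto it = idx.pos.find(read.substr(a, k));
        if (it == idx.pos.end()) continue;
        for (int p : it->second) cand.push_back(p - a);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int off : cand) {
        int mm, len;
        score_offset(read, ref, off, mm, len);
        // prefer more aligned bases, then fewer mismatches
        if (len - mm > best_len - best_mm ||
            (len - mm == best_len - best_mm && mm < best_mm)) {
          best_mm = mm; best_len = len; best_off = off;
          best_strand = strand == 0 ? 1 : -1;
        }
      }
    }
    out_off[r] = best_off;
    out_strand[r] = best_strand;
    out_mm[r] = best_mm == INT_MAX ? NA_INTEGER : best_mm;
    out_len[r] = best_len;
  }
  return DataFrame::create(_["offset"] = out_off, _["strand"] = out_strand,
                           _["mismatches"] = out_mm,
                           _["aligned_len"] = out_len);
}


// Accumulate per-cycle mismatch and observation counts for placed reads.
// `offsets` are 0-based on the strand given by `strands` (+1/-1, vs ref_fwd /
// ref_rev); reads with NA offset are skipped. Cycle = position within the
// read, 1-based; max_cycle sizes the output.
// [[Rcpp::export]]
List cpp_cycle_mismatches(CharacterVector reads, std::string ref_fwd,
                          std::string ref_rev, IntegerVector offsets,
                          IntegerVector strands, int max_cycle) {
  IntegerVector mm(max_cycle), nobs(max_cycle);
  int nreads = reads.size();
  for (int r = 0; r < nreads; ++r) {
    if (offsets[r] == NA_INTEGER) continue;
    std::string read = as<std::string>(reads[r]);
    const std::string& ref = strands[r] == 1 ? ref_fwd : ref_rev;
    int off = offsets[r], n = read.size(), nr = ref.size();
    for (int i = 0; i < n && i < max_cycle; ++i) {
      int p = off + i;
      if (p < 0 || p >= nr) continue;
      ++nobs[i];
      if (!base_match(read[i], ref[p])) ++mm[i];
    }
  }
  return List::create(_["mismatches"] = mm, _["n"] = nobs);
}
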