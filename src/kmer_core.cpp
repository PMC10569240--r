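// Core sequence primitives shared by the k-mer QC, centromere and alignment
// anchoring modules. All k-mers are 2-bit encoded (k <= 31); any window
// containing a non-ACGT base is skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate canonical k-mer codes of one sequence; calls push(code) for each
// valid window. Canonical = min(forward code, reverse-complement code).
template <typename F>
static void for_each_canonical(const char* s, R_xlen_t n, int k, F push) {
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) push(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_hist_cpp")]]
DataFrame kmer_hist_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, j));
    for_each_canonical(s, n, k, [&](uint64_t code) { ++tab[code]; });
  }
  // histogram: depth -> number of distinct canonical k-mers at that depth
  std::unordered_map<uint32_t, uint32_t> hist;
  for (auto& kv : tab) ++hist[kv.second];
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (auto& kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector depth(depths.size()), count(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    depth[i] = depths[i];
    count[i] = hist[depths[i]];
  }
  return DataFrame::create(_["depth"] = depth, _["count"] = count);
}

// Assembly k-mer instances in total, and instances whose canonical k-mer is
// absent from the read set. Basis of the Merqury-style QV.
// [[Rcpp::export(name = ".kmer_missing_cpp")]]
NumericVector kmer_missing_cpp(CharacterVector assembly, CharacterVector reads,
                               int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> readset;
  readset.reserve(1 << 20);
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    const char* s = CHAR(STRING_ELT(reads, j));
    R_xlen_t n = LENGTH(STRING_ELT(reads, j));
    for_each_canonical(s, n, k, [&](uint64_t code) { readset.insert(code); });
  }
  double total = 0, missing = 0;
  for (R_xlen_t j = 0; j < assembly.size(); ++j) {
    const char* s = CHAR(STRING_ELT(assembly, j));
    R_xlen_t n = LENGTH(STRING_ELT(assembly, j));
    for_each_canonical(s, n, k, [&](uint64_t code) {
      total += 1;
      if (readset.find(code) == readset.end()) missing += 1;
    });
  }
  return NumericVector::create(_["total"] = total, _["missing"] = missing);
}

// Tandem-periodicity flags: position i (0-based start of a k-mer window) is
// flagged when the identical forward k-mer occurred at lag in
// [min_period, max_period] upstream. Single pass, last-occurrence table.
// Returned vector has length nchar(seq); positions with no valid k-mer are 0.
// [[Rcpp::export(name = ".tandem_flags_cpp")]]
LogicalVector tandem_flags_cpp(std::string seq, int k, int min_period,
                               int max_period) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (min_period < 1 || max_period < min_period)
    stop("invalid period range");
  R_xlen_t n = (R_xlen_t)seq.size();
  LogicalVector out(n, false);
  const uint64_t mask = ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, R_xlen_t> last;
  last.reserve(1 << 18);
  uint64_t fwd = 0;
  int valid = 0;
  const char* s = seq.c_str();
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      R_xlen_t start = i - k + 1;  // 0-based window start
      auto it = last.find(fwd);
      if (it != last.end()) {
        R_xlen_t lag = start - it->second;
        if (lag >= min_period && lag <= max_period) out[start] = true;
      }
      last[fwd] = start;
    }
  }
  return out;
}

// Positions (0-based) of k-mers that occur exactly once in ref AND exactly
// once in qry (forward strand, exact match). Returned sorted by ref position.
// stride subsamples ref positions after uniqueness is established.
// [[Rcpp::export(name = ".unique_anchors_cpp")]]
DataFrame unique_anchors_cpp(std::string ref, std::string qry, int k,
                             int stride) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (stride < 1) stop("stride must be >= 1");
  const uint64_t mask = ((1ULL << (2 * k)) - 1);
  // code -> position if unique, -1 if repeated
  auto index_seq = [&](const std::string& sq,
                       std::unordered_map<uint64_t, int64_t>& tab) {
    uint64_t fwd = 0;
    int valid = 0;
    const char* s = sq.c_str();
    R_xlen_t n = (R_xlen_t)sq.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int64_t start = i - k + 1;
        auto it = tab.find(fwd);
        if (it == tab.end()) tab[fwd] = start; else it->second = -1;
      }
    }
  };
  std::unordered_map<uint64_t, int64_t> rtab, qtab;
  rtab.reserve(1 << 18); qtab.reserve(1 << 18);
  index_seq(ref, rtab);
  index_seq(qry, qtab);
  std::vector<std::pair<int64_t, int64_t>> pairs;
  for (auto& kv : rtab) {
    if (kv.second < 0) continue;
    auto it = qtab.find(kv.first);
    if (it == qtab.end() || it->second < 0) continue;
    pairs.push_back({kv.second, it->second});
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<double> rp, qp;
  int64_t last_kept = -1;
  for (auto& p : pairs) {
    if (last_kept >= 0 && p.first - last_kept < stride) continue;
    last_kept = p.first;
    rp.push_back((double)p.first);
    qp.push_back((double)p.second);
  }
  return DataFrame::create(_["ref_pos"] = rp, _["qry_pos"] = qp);
}

// Indices (1-based) of a longest strictly increasing subsequence.
// [[Rcpp::export(name = ".lis_indices_cpp")]]
IntegerVector lis_indices_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<R_xlen_t> tail_idx;   // index of smallest tail of LIS of len l+1
  std::vector<R_xlen_t> prev(n, -1);
  for (R_xlen_t i = 0; i < n; ++i) {
    // binary search: first tail with x[tail] >= x[i]
    size_t lo = 0, hi = tail_idx.size();
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (x[tail_idx[mid]] < x[i]) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) prev[i] = tail_idx[lo - 1];
    if (lo == tail_idx.size()) tail_idx.push_back(i);
    else tail_idx[lo] = i;
  }
  std::vector<int> out;
  R_xlen_t cur = tail_idx.back();
  while (cur >= 0) { out.push_back((int)cur + 1); cur = prev[cur]; }
  std::reverse(out.begin(), out.end());
  return wrap(out);
}
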