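#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Canonical form of the k-mer starting at s[pos]: the lexicographic minimum
// of the k-mer and its reverse complement (strand-collapsed uniqueness).
static std::string canonical_kmer(const std::string &s, size_t pos, int k,
                                  bool both_strands) {
  std::string fwd = s.substr(pos, k);
  if (!both_strands) return fwd;
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[i] = comp_base(fwd[k - 1 - i]);
  return (rc < fwd) ? rc : fwd;
}

// For each chromosome, the position index of the next N at or after each
// position (sentinel = length when none). Lets us reject N-containing
// k-mers in O(1).
static std::vector<long> next_n_index(const std::string &s) {
  long n = (long)s.size();
  std::vector<long> nxt(n + 1);
  nxt[n] = n;
  for (long i = n - 1; i >= 0; --i)
    nxt[i] = (s[i] == 'N') ? i : nxt[i + 1];
  return nxt;
}

//' @noRd
// [[Rcpp::export(name = ".kmer_unique_positions")]]
List kmer_unique_positions(CharacterVector seqs, int k, bool both_strands) {
  int nchr = seqs.size();
  std::vector<std::string> chrs(nchr);
  for (int c = 0; c < nchr; ++c) chrs[c] = as<std::string>(seqs[c]);

  // pass 1: count canonical k-mers (capped at 2; only uniqueness matters)
  std::unordered_map<std::string, int> counts;
  for (int c = 0; c < nchr; ++c) {
    const std::string &s = chrs[c];
    if ((long)s.size() < k) continue;
    std::vector<long> nxt = next_n_index(s);
    long last = (long)s.size() - k;
    for (long p = 0; p <= last; ++p) {
      if (nxt[p] < p + k) continue;            // contains N
      std::string key = canonical_kmer(s, p, k, both_strands);
      auto it = counts.find(key);
      if (it == counts.end()) counts.emplace(std::move(key), 1);
      else if (it->second < 2) it->second += 1;
    }
  }

  // pass 2: mark unique starts
  List out(nchr);
  for (int c = 0; c < nchr; ++c) {
    const std::string &s = chrs[c];
    LogicalVector v(s.size(), false);
    if ((long)s.size() >= k) {
      std::vector<long> nxt = next_n_index(s);
      long last = (long)s.size() - k;
      for (long p = 0; p <= last; ++p) {
        if (nxt[p] < p + k) continue;
        std::string key = canonical_kmer(s, p, k, both_strands);
        v[p] = (counts[key] == 1);
      }
    }
    out[c] = v;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
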