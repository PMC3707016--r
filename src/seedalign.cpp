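#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact-seed + ungapped-extension aligner for short fragments against a
// small reference. Seeds are 2-bit-encoded k-mers (k <= 31) taken at
// offsets 0, k, 2k, ... along the fragment, so a fragment is found as long
// as one seed block is error-free.

static inline int code_base(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[i] = comp_base(s[s.size() - 1 - i]);
  return r;
}

struct SeedIndex {
  std::vector<std::string> chrs;
  std::vector<std::string> names;
  int k;
  // key -> (chrom, pos) pairs packed as chrom * 2^40 + pos
  std::unordered_map<uint64_t, std::vector<uint64_t> > map;
};

static bool encode_kmer(const std::string &s, size_t pos, int k, uint64_t &key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = code_base(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  key = v;
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".seed_index_build")]]
SEXP seed_index_build(CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("seed length k must be in [4, 31]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int c = 0; c < seqs.size(); ++c) {
    idx->chrs.push_back(as<std::string>(seqs[c]));
    idx->names.push_back(nm.size() ? as<std::string>(nm[c]) : std::to_string(c + 1));
  }
  for (size_t c = 0; c < idx->chrs.size(); ++c) {
    const std::string &s = idx->chrs[c];
    if ((long)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s, p, k, key)) continue;
      idx->map[key].push_back(((uint64_t)c << 40) | (uint64_t)p);
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

static int match_count(const std::string &ref, long start, const std::string &frag) {
  long n = (long)frag.size();
  if (start < 0 || start + n > (long)ref.size()) return -1;
  int m = 0;
  for (long i = 0; i < n; ++i) if (ref[start + i] == frag[i]) ++m;
  return m;
}

// Align one fragment: returns best hits over both strands.
static void align_one(const SeedIndex *idx, const std::string &frag,
                      int &best_score, int &n_best,
                      int &chrom, long &pos, int &strand) {
  best_score = -1; n_best = 0; chrom = -1; pos = -1; strand = 0;
  int k = idx->k;
  long flen = (long)frag.size();
  if (flen < k) return;
  std::string strands[2] = { frag, revcomp(frag) };
  // de-dup candidates: (strand, chrom, start)
  std::unordered_map<uint64_t, bool> seen;
  for (int st = 0; st < 2; ++st) {
    const std::string &f = strands[st];
    for (long off = 0; off + k <= flen; off += k) {
      uint64_t key;
      if (!encode_kmer(f, off, k, key)) continue;
      auto it = idx->map.find(key);
      if (it == idx->map.end()) continue;
      for (uint64_t packed : it->second) {
        int c = (int)(packed >> 40);
        long p = (long)(packed & ((1ULL << 40) - 1));
        long start = p - off;
        uint64_t sk = ((uint64_t)st << 62) | ((uint64_t)c << 40) |
                      (uint64_t)(start + (1L << 20));
        if (seen.count(sk)) continue;
        seen[sk] = true;
        int sc = match_count(idx->chrs[c], start, f);
        if (sc < 0) continue;
        if (sc > best_score) {
          best_score = sc; n_best = 1; chrom = c; pos = start;
          strand = (st == 0) ? 1 : -1;
        } else if (sc == best_score) {
          ++n_best;
          // deterministic representative: smallest (chrom, pos, strand)
          if (c < chrom || (c == chrom && (start < pos ||
              (start == pos && st == 0 && strand < 0)))) {
            chrom = c; pos = start; strand = (st == 0) ? 1 : -1;
          }
        }
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".seed_align")]]
DataFrame seed_align(SEXP index, CharacterVector fragments, double min_identity) {
  XPtr<SeedIndex> idx(index);
  int n = fragments.size();
  CharacterVector chrom(n);
  IntegerVector pos(n), mapq(n), score(n), nbest(n);
  CharacterVector strand(n);
  LogicalVector mapped(n), unique(n);
  for (int i = 0; i < n; ++i) {
    std::string f = as<std::string>(fragments[i]);
    int bs, nb, c, st; long p;
    align_one(idx, f, bs, nb, c, p, st);
    bool ok = (bs >= (int)std::ceil(min_identity * (double)f.size())) && nb >= 1;
    mapped[i] = ok;
    if (ok) {
      chrom[i] = idx->names[c];
      pos[i] = (int)p;
      strand[i] = (st > 0) ? "+" : "-";
      unique[i] = (nb == 1);
      mapq[i] = (nb == 1) ? 60 : 0;
      score[i] = bs;
      nbest[i] = nb;
    } else {
      chrom[i] = NA_STRING; pos[i] = NA_INTEGER; strand[i] = NA_STRING;
      unique[i] = false; mapq[i] = NA_INTEGER; score[i] = bs; nbest[i] = nb;
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = pos,
                           _["strand"] = strand, _["mapq"] = mapq,
                           _["score"] = score, _["n_best"] = nbest,
                           _["mapped"] = mapped, _["unique"] = unique,
                           _["stringsAsFactors"] = false);
}
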