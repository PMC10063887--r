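#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <algorithm>

using namespace Rcpp;

// complement of an upper-case base, 0 for anything not in {A,C,G,T}
static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

static inline bool valid_base(char b) {
  return b == 'A' || b == 'C' || b == 'G' || b == 'T';
}

// canonical form: lexicographic min of the k-mer and its reverse complement
static inline std::string canonical(const std::string &km) {
  std::string rc(km.size(), 'N');
  for (size_t i = 0; i < km.size(); ++i)
    rc[km.size() - 1 - i] = comp_base(km[i]);
  return std::min(km, rc);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string rc(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = comp_base(toupper(s[j]));
      rc[s.size() - 1 - j] = c ? c : 'N';
    }
    out[i] = rc;
  }
  return out;
}

// Per-position canonical k-mers of one sequence; NA where the window
// contains a non-ACGT character. Length max(L - k + 1, 0).
// [[Rcpp::export]]
CharacterVector cpp_seq_kmers(std::string seq, int k) {
  std::transform(seq.begin(), seq.end(), seq.begin(), ::toupper);
  R_xlen_t L = (R_xlen_t) seq.size();
  R_xlen_t n = L - k + 1;
  if (n < 0) n = 0;
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool ok = true;
    for (int j = 0; j < k; ++j)
      if (!valid_base(seq[i + j])) { ok = false; break; }
    if (!ok) { out[i] = NA_STRING; continue; }
    out[i] = canonical(seq.substr(i, k));
  }
  return out;
}

// Canonical k-mer multiset over a set of sequences (reads or contigs).
// Windows containing non-ACGT characters contribute nothing.
// [[Rcpp::export]]
IntegerVector cpp_kmer_counts(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> tab;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) continue;
    std::string seq = as<std::string>(seqs[s]);
    std::transform(seq.begin(), seq.end(), seq.begin(), ::toupper);
    if ((int) seq.size() < k) continue;
    for (size_t i = 0; i + k <= seq.size(); ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j)
        if (!valid_base(seq[i + j])) { ok = false; break; }
      if (!ok) continue;
      tab[canonical(seq.substr(i, k))]++;
    }
  }
  IntegerVector counts(tab.size());
  CharacterVector keys(tab.size());
  R_xlen_t i = 0;
  for (auto &kv : tab) { keys[i] = kv.first; counts[i] = kv.second; ++i; }
  counts.names() = keys;
  return counts;
}

// splitmix64 finalizer (public-domain mixing function, Vigna 2015)
static inline uint64_t mix64(uint64_t z) {
  z ^= z >> 30; z *= 0xbf58476d1ce4e5b9ULL;
  z ^= z >> 27; z *= 0x94d049bb133111ebULL;
  z ^= z >> 31;
  return z;
}

// FNV-1a 64-bit over bytes, then splitmix64 finalization; `seed` is
// folded in up front so the hash family is keyed but fixed per run.
static inline uint64_t hash_string(const std::string &s, uint64_t seed) {
  uint64_t h = 0xcbf29ce484222325ULL ^ seed;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char) c;
    h *= 0x100000001b3ULL;
  }
  return mix64(h);
}

static std::string to_hex(uint64_t v) {
  static const char *digits = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) { out[i] = digits[v & 0xf]; v >>= 4; }
  return out;
}

// 64-bit hashes of strings as fixed-width lower-case hex so that
// lexicographic order equals numeric order (R has no native uint64).
// [[Rcpp::export]]
CharacterVector cpp_hash64(CharacterVector keys, double seed) {
  uint64_t sd = (uint64_t) seed;
  CharacterVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    out[i] = to_hex(hash_string(as<std::string>(keys[i]), sd));
  return out;
}

// Truncated trapezoid integral of the EHH curve (iHH) for one focal
// site over a carrier subset: both sides walked outward, each segment's
// trapezoid added, a side stopping after the first site whose EHH falls
// below `cutoff`. Matches ihh(ehh(...)) exactly.
// [[Rcpp::export]]
double cpp_ihh(IntegerMatrix hap, int focal, IntegerVector rows,
               NumericVector pos, double cutoff) {
  int S = hap.ncol();
  int nc = rows.size();
  if (nc < 2) return NA_REAL;
  double denom = (double) nc * (nc - 1) / 2.0;
  double total = 0.0;
  for (int side = 0; side < 2; ++side) {
    std::vector<int> grp(nc, 0);
    int ngrp = 1;
    int step = side == 0 ? -1 : 1;
    double prev_e = 1.0;
    double prev_p = pos[focal - 1];
    for (int x = focal - 1 + step; x >= 0 && x < S; x += step) {
      std::unordered_map<long long, int> remap;
      std::vector<int> ng(nc);
      int next = 0;
      for (int i = 0; i < nc; ++i) {
        int a = hap(rows[i] - 1, x);
        long long key = (long long) grp[i] * 4 + a;
        auto it = remap.find(key);
        if (it == remap.end()) { remap[key] = next; ng[i] = next; ++next; }
        else ng[i] = it->second;
      }
      grp = ng; ngrp = next;
      std::vector<int> cnt(ngrp, 0);
      for (int i = 0; i < nc; ++i) cnt[grp[i]]++;
      double num = 0;
      for (int g = 0; g < ngrp; ++g) num += (double) cnt[g] * (cnt[g] - 1) / 2.0;
      double e = num / denom;
      total += std::abs(pos[x] - prev_p) * (e + prev_e) / 2.0;
      if (e < cutoff) break;
      prev_e = e; prev_p = pos[x];
    }
  }
  return total;
}

// EHH profile for one focal site over a carrier subset.
// hap: haplotypes x sites 0/1 matrix; focal, rows are 1-based.
// Returns EHH at every site: 1 at the focal site, decaying outward as the
// carriers' extended haplotypes (focal..x) differentiate; once EHH reaches
// 0 on a side it stays 0 outward.
// min_ehh > 0 stops a side early once EHH falls below it (the remaining
// values stay 0); safe for iHH integration truncated at the same cutoff.
// [[Rcpp::export]]
NumericVector cpp_ehh(IntegerMatrix hap, int focal, IntegerVector rows,
                      double min_ehh = 0.0) {
  int S = hap.ncol();
  int nc = rows.size();
  NumericVector out(S);
  if (nc < 2) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  double denom = (double) nc * (nc - 1) / 2.0;
  for (int side = 0; side < 2; ++side) {
    std::vector<int> grp(nc, 0);
    int ngrp = 1;
    int step = side == 0 ? -1 : 1;
    for (int x = focal - 1; x >= 0 && x < S; x += step) {
      if (x != focal - 1) {
        // refine groups by the allele at x
        std::unordered_map<long long, int> remap;
        std::vector<int> ng(nc);
        int next = 0;
        for (int i = 0; i < nc; ++i) {
          int a = hap(rows[i] - 1, x);
          long long key = (long long) grp[i] * 4 + a;
          auto it = remap.find(key);
          if (it == remap.end()) { remap[key] = next; ng[i] = next; ++next; }
          else ng[i] = it->second;
        }
        grp = ng; ngrp = next;
      }
      // homozygosity of current grouping
      std::vector<int> cnt(ngrp, 0);
      for (int i = 0; i < nc; ++i) cnt[grp[i]]++;
      double num = 0;
      for (int g = 0; g < ngrp; ++g) num += (double) cnt[g] * (cnt[g] - 1) / 2.0;
      out[x] = num / denom;
      if (num == 0 || out[x] < min_ehh) break; // zeros remain outward
    }
  }
  out[focal - 1] = 1.0;
  return out;
}
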