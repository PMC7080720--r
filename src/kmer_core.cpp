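#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// 2-bit base codes; -1 marks N (or any non-ACGT character, which callers
// have already validated/normalized at the R level).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE2BASE[5] = {'A', 'C', 'G', 'T', 'N'};

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_char(s[i]);
  return r;
}

// splitmix64 finalizer: cheap, well-mixed hash for 2-bit k-mer codes.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base_code(s[i]);
  return v;
}

// ---------------------------------------------------------------------------
// Vector k-mer index. Positions are 1-based left ends on the forward strand.
// For a circular vector the first k-1 bases are appended before windowing so
// every position 1..L exists; for a linear vector positions run 1..L-k+1.
// k <= 31 uses an open-addressing table over 2-bit codes; larger k falls back
// to a string-keyed map (used only at small scale).
// ---------------------------------------------------------------------------
struct KIndex {
  int k = 0;
  int npos = 0;                 // number of indexed positions
  bool fast = false;
  static constexpr uint64_t EMPTY = ~0ULL;
  std::vector<uint64_t> keys;
  std::vector<int> slot;        // index into poslist
  size_t tmask = 0;
  std::unordered_map<std::string, int> smap;
  std::vector<std::vector<int>> poslist;

  void build(const std::string& vecseq, int k_, bool circular) {
    k = k_;
    int L = (int)vecseq.size();
    std::string ext = vecseq;
    if (circular && k > 1) ext += vecseq.substr(0, (size_t)(k - 1));
    npos = circular ? L : L - k + 1;
    fast = (k <= 31);
    std::vector<int8_t> codes = encode(ext);
    if (fast) {
      size_t cap = 8;
      while (cap < (size_t)npos * 4) cap <<= 1;
      keys.assign(cap, EMPTY);
      slot.assign(cap, -1);
      tmask = cap - 1;
      uint64_t key = 0, mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
      int valid = 0;
      for (int i = 0; i < (int)codes.size(); ++i) {
        int c = codes[i];
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid >= k) {
          int p = i - k + 2;  // 1-based left end
          if (p > npos) break;
          insert_fast(key, p);
        }
      }
    } else {
      poslist.reserve(npos);
      for (int p = 1; p <= npos; ++p) {
        std::string w = ext.substr((size_t)(p - 1), (size_t)k);
        if (w.find_first_not_of("ACGT") != std::string::npos) continue;
        auto it = smap.find(w);
        if (it == smap.end()) {
          smap.emplace(w, (int)poslist.size());
          poslist.push_back({p});
        } else {
          poslist[it->second].push_back(p);
        }
      }
    }
  }

  void insert_fast(uint64_t key, int p) {
    size_t h = mix64(key) & tmask;
    while (keys[h] != EMPTY) {
      if (keys[h] == key) { poslist[slot[h]].push_back(p); return; }
      h = (h + 1) & tmask;
    }
    keys[h] = key;
    slot[h] = (int)poslist.size();
    poslist.push_back({p});
  }

  inline void lookup_add(uint64_t key, int* counts) const {
    size_t h = mix64(key) & tmask;
    while (keys[h] != EMPTY) {
      if (keys[h] == key) {
        for (int p : poslist[slot[h]]) counts[p - 1]++;
        return;
      }
      h = (h + 1) & tmask;
    }
  }
};

// Count one read (2-bit codes) against the index: all N-free windows of the
// read and of its reverse complement. `total` counts every valid extracted
// k-mer (both strands), matched or not.
static void count_read_fast(const int8_t* r, int len, const KIndex& idx,
                            int* counts, double& total) {
  const int k = idx.k;
  if (len < k) return;
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    const int c = r[i];
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (valid < k) ++valid;
    if (valid >= k) {
      total += 2;
      idx.lookup_add(fwd, counts);
      idx.lookup_add(rc, counts);
    }
  }
}

static void count_strand_slow(const std::string& r, const KIndex& idx,
                              int* counts, double& total) {
  const int k = idx.k;
  const int len = (int)r.size();
  if (len < k) return;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    if (base_code(r[i]) < 0) valid = 0; else ++valid;
    if (valid >= k) {
      total += 1;
      auto it = idx.smap.find(r.substr((size_t)(i - k + 1), (size_t)k));
      if (it != idx.smap.end())
        for (int p : idx.poslist[it->second]) counts[p - 1]++;
    }
  }
}

static void count_read_any(const std::string& r, const std::vector<int8_t>& codes,
                           const KIndex& idx, int* counts, double& total) {
  if (idx.fast) {
    count_read_fast(codes.data(), (int)codes.size(), idx, counts, total);
  } else {
    count_strand_slow(r, idx, counts, total);
    count_strand_slow(revcomp_str(r), idx, counts, total);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_position_patterns(std::string vecseq, int k, bool circular) {
  int L = (int)vecseq.size();
  std::string ext = vecseq;
  if (circular && k > 1) ext += vecseq.substr(0, (size_t)(k - 1));
  int npos = circular ? L : L - k + 1;
  CharacterVector out(npos);
  for (int p = 1; p <= npos; ++p) {
    std::string w = ext.substr((size_t)(p - 1), (size_t)k);
    if (w.find_first_not_of("ACGT") != std::string::npos)
      out[p - 1] = NA_STRING;
    else
      out[p - 1] = w;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_count_positions(CharacterVector reads, std::string vecseq, int k,
                         bool circular) {
  KIndex idx;
  idx.build(vecseq, k, circular);
  IntegerVector counts(idx.npos);
  double total = 0;
  int* cp = INTEGER(counts);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    std::vector<int8_t> codes = idx.fast ? encode(r) : std::vector<int8_t>();
    count_read_any(r, codes, idx, cp, total);
  }
  return List::create(_["counts"] = counts, _["total"] = total);
}

// ---------------------------------------------------------------------------
// Paired-end read simulation. Fragment start uniform over the forward strand,
// fragment length ~ round(Normal(mean, sd)) clipped to [read_len, space
// remaining]; R1 = first read_len bases, R2 = reverse complement of the last
// read_len bases (FR orientation). Substitutions: per read a Binomial(len,
// rate) error count, positions uniform, substituted base uniform over the
// three alternatives; template N bases are left untouched. Uses R's RNG so
// everything is reproducible from set.seed().
// ---------------------------------------------------------------------------
static void add_errors(int8_t* r, int len, double rate) {
  if (rate <= 0) return;
  int ne = (int)R::rbinom((double)len, rate);
  for (int e = 0; e < ne; ++e) {
    int p = (int)(R::unif_rand() * len);
    if (p >= len) p = len - 1;
    if (r[p] >= 0) {
      int off = 1 + (int)(R::unif_rand() * 3.0);
      if (off > 3) off = 3;
      r[p] = (int8_t)((r[p] + off) & 3);
    }
  }
}

static void sim_pair_codes(const std::vector<int8_t>& g, int read_len,
                           double frag_mean, double frag_sd, double error_rate,
                           int8_t* r1, int8_t* r2) {
  const int glen = (int)g.size();
  const int smax = glen - read_len + 1;
  int start = (int)(R::unif_rand() * smax);  // 0-based
  if (start >= smax) start = smax - 1;
  int flen = (int)std::lround(R::rnorm(frag_mean, frag_sd));
  if (flen < read_len) flen = read_len;
  if (flen > glen - start) flen = glen - start;
  for (int i = 0; i < read_len; ++i) r1[i] = g[start + i];
  const int e2 = start + flen;  // exclusive fragment end
  for (int i = 0; i < read_len; ++i) {
    int8_t c = g[e2 - 1 - i];
    r2[i] = (c < 0) ? (int8_t)-1 : (int8_t)(3 - c);
  }
  add_errors(r1, read_len, error_rate);
  add_errors(r2, read_len, error_rate);
}

static std::string codes_to_string(const int8_t* r, int len) {
  std::string s((size_t)len, 'N');
  for (int i = 0; i < len; ++i) s[i] = CODE2BASE[r[i] < 0 ? 4 : r[i]];
  return s;
}

// [[Rcpp::export]]
List cpp_simulate_pairs(std::string genome, int n_pairs, int read_len,
                        double frag_mean, double frag_sd, double error_rate) {
  std::vector<int8_t> g = encode(genome);
  CharacterVector r1(n_pairs), r2(n_pairs);
  std::vector<int8_t> b1(read_len), b2(read_len);
  for (int i = 0; i < n_pairs; ++i) {
    sim_pair_codes(g, read_len, frag_mean, frag_sd, error_rate, b1.data(), b2.data());
    r1[i] = codes_to_string(b1.data(), read_len);
    r2[i] = codes_to_string(b2.data(), read_len);
  }
  return List::create(_["r1"] = r1, _["r2"] = r2);
}

// Fused simulate + count: identical RNG stream to cpp_simulate_pairs (same
// per-pair draws, same order), but never materializes read strings. Used by
// the Monte-Carlo campaigns.
// [[Rcpp::export]]
List cpp_simulate_count(std::string genome, std::string vecseq, int k,
                        bool circular, int n_pairs, int read_len,
                        double frag_mean, double frag_sd, double error_rate) {
  std::vector<int8_t> g = encode(genome);
  KIndex idx;
  idx.build(vecseq, k, circular);
  IntegerVector counts(idx.npos);
  int* cp = INTEGER(counts);
  double total = 0;
  std::vector<int8_t> b1(read_len), b2(read_len);
  for (int i = 0; i < n_pairs; ++i) {
    sim_pair_codes(g, read_len, frag_mean, frag_sd, error_rate, b1.data(), b2.data());
    if (idx.fast) {
      count_read_fast(b1.data(), read_len, idx, cp, total);
      count_read_fast(b2.data(), read_len, idx, cp, total);
    } else {
      std::string s1 = codes_to_string(b1.data(), read_len);
      std::string s2 = codes_to_string(b2.data(), read_len);
      count_read_any(s1, std::vector<int8_t>(), idx, cp, total);
      count_read_any(s2, std::vector<int8_t>(), idx, cp, total);
    }
  }
  return List::create(_["counts"] = counts, _["total"] = total,
                      _["n_pairs"] = n_pairs);
}

// ---------------------------------------------------------------------------
// Pattern census: distinct k-mers over all windows of all sequences and
// their reverse complements (N windows skipped).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_distinct_count(CharacterVector seqs, int k) {
  if (k <= 13) {
    size_t n = (size_t)1 << (2 * k);
    std::vector<bool> seen(n, false);
    uint64_t mask = (1ULL << (2 * k)) - 1;
    int shift = 2 * (k - 1);
    double cnt = 0;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string str = as<std::string>(seqs[s]);
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (size_t i = 0; i < str.size(); ++i) {
        int c = base_code(str[i]);
        if (c < 0) { valid = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
        if (++valid >= k) {
          if (!seen[fwd]) { seen[fwd] = true; cnt += 1; }
          if (!seen[rc]) { seen[rc] = true; cnt += 1; }
        }
      }
    }
    return cnt;
  } else if (k <= 31) {
    std::unordered_set<uint64_t> seen;
    uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
    int shift = 2 * (k - 1);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string str = as<std::string>(seqs[s]);
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (size_t i = 0; i < str.size(); ++i) {
        int c = base_code(str[i]);
        if (c < 0) { valid = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
        if (++valid >= k) { seen.insert(fwd); seen.insert(rc); }
      }
    }
    return (double)seen.size();
  } else {
    std::unordered_set<std::string> seen;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string str = as<std::string>(seqs[s]);
      if ((int)str.size() < k) continue;
      std::string rcs = revcomp_str(str);
      for (const std::string* sp : {&str, &rcs}) {
        int valid = 0;
        for (size_t i = 0; i < sp->size(); ++i) {
          if (base_code((*sp)[i]) < 0) valid = 0; else ++valid;
          if (valid >= k) seen.insert(sp->substr(i - k + 1, (size_t)k));
        }
      }
    }
    return (double)seen.size();
  }
}

// Shared patterns between a genome (possibly multi-sequence) and a vector.
// The vector pattern set is closed under reverse complement; every genome
// window hitting that set is recorded with its location and strand.
// [[Rcpp::export]]
List cpp_shared_patterns(CharacterVector genome_seqs, std::string vecseq,
                         int k, bool vec_circular) {
  if (k > 31) stop("shared_patterns supports k <= 31");
  std::string ext = vecseq;
  if (vec_circular && k > 1) ext += vecseq.substr(0, (size_t)(k - 1));
  int npos = vec_circular ? (int)vecseq.size() : (int)vecseq.size() - k + 1;
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);

  // pattern key -> id; per id: pattern string and vector occurrences
  std::unordered_map<uint64_t, int> ids;
  std::vector<std::string> pat;
  std::vector<std::vector<int>> vpos;
  std::vector<std::vector<char>> vstrand;
  {
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < (int)ext.size(); ++i) {
      int c = base_code(ext[i]);
      if (c < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        int p = i - k + 2;
        if (p > npos) break;
        std::string w = ext.substr((size_t)(p - 1), (size_t)k);
        uint64_t kk[2] = {fwd, rc};
        std::string ww[2] = {w, revcomp_str(w)};
        char st[2] = {'+', '-'};
        int nrec = (fwd == rc) ? 1 : 2;
        for (int j = 0; j < nrec; ++j) {
          auto it = ids.find(kk[j]);
          int id;
          if (it == ids.end()) {
            id = (int)pat.size();
            ids.emplace(kk[j], id);
            pat.push_back(ww[j]);
            vpos.push_back({});
            vstrand.push_back({});
          } else id = it->second;
          vpos[id].push_back(p);
          vstrand[id].push_back(st[j]);
        }
      }
    }
  }

  // genome scan
  std::vector<int> g_id;
  std::vector<int> g_seq;
  std::vector<int> g_pos;
  std::vector<char> g_strand;
  std::vector<bool> hit(pat.size(), false);
  for (R_xlen_t s = 0; s < genome_seqs.size(); ++s) {
    std::string str = as<std::string>(genome_seqs[s]);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (size_t i = 0; i < str.size(); ++i) {
      int c = base_code(str[i]);
      if (c < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        int p = (int)i - k + 2;
        auto it = ids.find(fwd);
        if (it != ids.end()) {
          hit[it->second] = true;
          g_id.push_back(it->second); g_seq.push_back((int)s + 1);
          g_pos.push_back(p); g_strand.push_back('+');
        }
        if (rc != fwd) {
          it = ids.find(rc);
          if (it != ids.end()) {
            hit[it->second] = true;
            g_id.push_back(it->second); g_seq.push_back((int)s + 1);
            g_pos.push_back(p); g_strand.push_back('-');
          }
        }
      }
    }
  }

  int observed = 0;
  for (bool h : hit) observed += h ? 1 : 0;

  CharacterVector gp(g_id.size()), gs(g_id.size());
  IntegerVector gseq(g_id.size()), gpos(g_id.size());
  for (size_t i = 0; i < g_id.size(); ++i) {
    gp[i] = pat[g_id[i]];
    gseq[i] = g_seq[i];
    gpos[i] = g_pos[i];
    gs[i] = std::string(1, g_strand[i]);
  }

  // vector occurrences of the shared patterns only
  std::vector<int> keep;
  for (size_t id = 0; id < pat.size(); ++id)
    if (hit[id]) keep.push_back((int)id);
  size_t nv = 0;
  for (int id : keep) nv += vpos[id].size();
  CharacterVector vp(nv), vs(nv);
  IntegerVector vpp(nv);
  size_t j = 0;
  for (int id : keep)
    for (size_t t = 0; t < vpos[id].size(); ++t, ++j) {
      vp[j] = pat[id];
      vpp[j] = vpos[id][t];
      vs[j] = std::string(1, vstrand[id][t]);
    }

  return List::create(
    _["observed"] = observed,
    _["n_vector_distinct"] = (double)pat.size(),
    _["genome_occ"] = DataFrame::create(_["pattern"] = gp, _["seq"] = gseq,
                                        _["position"] = gpos, _["strand"] = gs,
                                        _["stringsAsFactors"] = false),
    _["vector_occ"] = DataFrame::create(_["pattern"] = vp, _["position"] = vpp,
                                        _["strand"] = vs,
                                        _["stringsAsFactors"] = false));
}
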