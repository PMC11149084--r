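#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Entry sentinels: 0 = empty, -1 = dirty (written by >= 2 distinct genomes),
// positive value = genome id. NA never occurs in the entry array.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Per-function seeds derived from the master seed by a fixed mixing
// recurrence, so an index is fully reproducible from (k, m, n, master_seed).
static std::vector<uint64_t> derive_seeds(uint64_t master_seed, int n) {
  std::vector<uint64_t> seeds(n);
  uint64_t state = master_seed ^ 0xA5A5A5A55A5A5A5AULL;
  for (int i = 0; i < n; ++i) seeds[i] = splitmix64(state);
  return seeds;
}

// FNV-1a over the k bytes, seeded, with a 64-bit avalanche finalizer.
static inline uint64_t hash_kmer(const char *s, int k, uint64_t seed) {
  uint64_t h = seed ^ 0xCBF29CE484222325ULL;
  for (int i = 0; i < k; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 0x100000001B3ULL;
  }
  h ^= h >> 33;
  h *= 0xFF51AFD7ED558CCDULL;
  h ^= h >> 33;
  h *= 0xC4CEB9FE1A85EC53ULL;
  h ^= h >> 33;
  return h;
}

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Update rule for one k-mer of genome `id` at one entry slot.
static inline void update_entry(int *entries, uint64_t pos, int id) {
  int cur = entries[pos];
  if (cur == 0) entries[pos] = id;
  else if (cur > 0 && cur != id) entries[pos] = -1;
  // cur == id or cur == -1: unchanged
}

static void insert_sequence(int *entries, uint64_t m,
                            const std::string &seq, int id, int k,
                            const std::vector<uint64_t> &seeds) {
  const int L = (int)seq.size();
  if (L < k) return;
  // `run` = length of the current suffix of valid (ACGT) bases; a window is
  // usable once run >= k, which skips every window containing an N.
  int run = 0;
  for (int i = 0; i < L; ++i) {
    run = base_ok(seq[i]) ? run + 1 : 0;
    if (run >= k) {
      const char *km = seq.data() + i - k + 1;
      for (size_t j = 0; j < seeds.size(); ++j)
        update_entry(entries, hash_kmer(km, k, seeds[j]) % m, id);
    }
  }
}

// [[Rcpp::export]]
IntegerVector mbx_insert_genome(IntegerVector entries, CharacterVector seqs,
                                int genome_id, int k, int n_hash,
                                double master_seed) {
  IntegerVector out = clone(entries);
  uint64_t m = (uint64_t)out.size();
  std::vector<uint64_t> seeds = derive_seeds((uint64_t)master_seed, n_hash);
  int *e = INTEGER(out);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string fwd = as<std::string>(seqs[s]);
    insert_sequence(e, m, fwd, genome_id, k, seeds);
    std::string rc(fwd.rbegin(), fwd.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = complement(rc[i]);
    insert_sequence(e, m, rc, genome_id, k, seeds);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector mbx_build_entries(List genome_seqs, IntegerVector genome_ids,
                                double m, int k, int n_hash,
                                double master_seed) {
  uint64_t mm = (uint64_t)m;
  IntegerVector entries((R_xlen_t)mm);  // zero-initialised
  std::vector<uint64_t> seeds = derive_seeds((uint64_t)master_seed, n_hash);
  int *e = INTEGER(entries);
  for (R_xlen_t g = 0; g < genome_seqs.size(); ++g) {
    CharacterVector seqs = genome_seqs[g];
    int id = genome_ids[g];
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      std::string fwd = as<std::string>(seqs[s]);
      insert_sequence(e, mm, fwd, id, k, seeds);
      std::string rc(fwd.rbegin(), fwd.rend());
      for (size_t i = 0; i < rc.size(); ++i) rc[i] = complement(rc[i]);
      insert_sequence(e, mm, rc, id, k, seeds);
    }
    Rcpp::checkUserInterrupt();
  }
  return entries;
}

// Unanimity verdict for one k-mer: its n entries must all hold the same
// positive genome id; any empty, dirty or disagreeing entry discards it.
static inline int query_one(const int *entries, uint64_t m, const char *km,
                            int k, const std::vector<uint64_t> &seeds) {
  int verdict = 0;
  for (int i = 0; i < k; ++i)
    if (!base_ok(km[i])) return NA_INTEGER;
  for (size_t j = 0; j < seeds.size(); ++j) {
    int v = entries[hash_kmer(km, k, seeds[j]) % m];
    if (v <= 0) return NA_INTEGER;
    if (j == 0) verdict = v;
    else if (v != verdict) return NA_INTEGER;
  }
  return verdict;
}

// [[Rcpp::export]]
IntegerVector mbx_query_kmers(IntegerVector entries, CharacterVector kmers,
                              int k, int n_hash, double master_seed) {
  uint64_t m = (uint64_t)entries.size();
  std::vector<uint64_t> seeds = derive_seeds((uint64_t)master_seed, n_hash);
  const int *e = INTEGER(entries);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *km = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer %d has length %d, expected k = %d", (int)(i + 1),
           (int)LENGTH(STRING_ELT(kmers, i)), k);
    out[i] = query_one(e, m, km, k, seeds);
  }
  return out;
}

// Vote over all quality-passing k-mer windows of each read and apply the
// strict majority rule. Qualities are Phred+33 strings ("" disables the
// gate for that read). Returns parallel vectors; predicted id is NA for
// discarded reads.
// [[Rcpp::export]]
List mbx_classify(IntegerVector entries, CharacterVector reads,
                  CharacterVector quals, int k, int n_hash,
                  double master_seed, int n_genomes,
                  double majority, double min_kmer_qual) {
  uint64_t m = (uint64_t)entries.size();
  std::vector<uint64_t> seeds = derive_seeds((uint64_t)master_seed, n_hash);
  const int *e = INTEGER(entries);
  const R_xlen_t R = reads.size();
  const bool gate = min_kmer_qual > 0;

  IntegerVector pred(R), votes_for(R), votes_total(R), skipped_qual(R);
  std::vector<int> counts(n_genomes + 1, 0);
  std::vector<int> touched;
  std::vector<int> qprefix;

  for (R_xlen_t r = 0; r < R; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    const int L = (int)LENGTH(STRING_ELT(reads, r));
    int total = 0, skipped = 0;
    touched.clear();

    if (gate) {
      const char *q = CHAR(STRING_ELT(quals, r));
      const int QL = (int)LENGTH(STRING_ELT(quals, r));
      if (QL != L && QL != 0)
        stop("read %d: quality string length %d != read length %d",
             (int)(r + 1), QL, L);
      qprefix.assign(L + 1, 0);
      for (int i = 0; i < L; ++i)
        qprefix[i + 1] = qprefix[i] + (QL ? ((int)(unsigned char)q[i] - 33) : 0);
    }

    for (int i = 0; i + k <= L; ++i) {
      if (gate && LENGTH(STRING_ELT(quals, r)) > 0) {
        double mean_q = (double)(qprefix[i + k] - qprefix[i]) / k;
        if (mean_q < min_kmer_qual) { ++skipped; continue; }
      }
      int v = query_one(e, m, s + i, k, seeds);
      if (v == NA_INTEGER) continue;
      ++total;
      if (counts[v] == 0) touched.push_back(v);
      ++counts[v];
    }

    int best = 0, best_count = 0;
    bool tie = false;
    for (size_t t = 0; t < touched.size(); ++t) {
      int id = touched[t], c = counts[id];
      if (c > best_count) { best = id; best_count = c; tie = false; }
      else if (c == best_count) tie = true;
      counts[id] = 0;
    }

    votes_total[r] = total;
    skipped_qual[r] = skipped;
    if (total > 0 && !tie && (double)best_count / total > majority) {
      pred[r] = best;
      votes_for[r] = best_count;
    } else {
      pred[r] = NA_INTEGER;
      votes_for[r] = 0;
    }
  }

  return List::create(_["predicted_id"] = pred,
                      _["votes_for"] = votes_for,
                      _["votes_total"] = votes_total,
                      _["kmers_skipped_quality"] = skipped_qual);
}
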