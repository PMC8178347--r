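#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A=0 C=1 G=2 T=3; -1 for anything else
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// enumerate canonical (strand-collapsed) k-mers of s; k <= 31
static void canonical_kmers(const std::string &s, int k,
                            std::vector<uint64_t> &out) {
  out.clear();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rcshift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << rcshift);
    if (++valid >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List cpp_match_reads(CharacterVector db_seqs, CharacterVector read_seqs,
                     int k) {
  int n_db = db_seqs.size(), n_reads = read_seqs.size();
  // k-mer -> list of db record indices holding it (deduplicated per record)
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<uint64_t> kms;
  for (int j = 0; j < n_db; ++j) {
    std::string s = as<std::string>(db_seqs[j]);
    canonical_kmers(s, k, kms);
    std::unordered_map<uint64_t, char> seen;
    for (size_t t = 0; t < kms.size(); ++t) {
      if (seen.insert(std::make_pair(kms[t], 1)).second)
        index[kms[t]].push_back(j);
    }
  }

  IntegerVector n_kmers(n_reads);
  NumericVector best_score(n_reads);
  List tied(n_reads);
  std::vector<int> counts(n_db, 0), touched;
  for (int i = 0; i < n_reads; ++i) {
    std::string s = as<std::string>(read_seqs[i]);
    canonical_kmers(s, k, kms);
    n_kmers[i] = (int)kms.size();
    touched.clear();
    for (size_t t = 0; t < kms.size(); ++t) {
      std::unordered_map<uint64_t, std::vector<int> >::iterator it =
          index.find(kms[t]);
      if (it == index.end()) continue;
      const std::vector<int> &recs = it->second;
      for (size_t r = 0; r < recs.size(); ++r) {
        if (counts[recs[r]] == 0) touched.push_back(recs[r]);
        counts[recs[r]]++;
      }
    }
    int best = 0;
    for (size_t t = 0; t < touched.size(); ++t)
      if (counts[touched[t]] > best) best = counts[touched[t]];
    std::vector<int> ties;
    for (size_t t = 0; t < touched.size(); ++t)
      if (counts[touched[t]] == best && best > 0)
        ties.push_back(touched[t] + 1);  // 1-based for R
    std::sort(ties.begin(), ties.end());
    for (size_t t = 0; t < touched.size(); ++t) counts[touched[t]] = 0;
    best_score[i] = (kms.size() > 0) ? (double)best / (double)kms.size() : 0.0;
    tied[i] = wrap(ties);
  }
  return List::create(_["n_kmers"] = n_kmers, _["score"] = best_score,
                      _["tied"] = tied);
}

// [[Rcpp::export]]
int cpp_count_distinct_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, char> seen;
  std::vector<uint64_t> kms;
  for (int j = 0; j < seqs.size(); ++j) {
    std::string s = as<std::string>(seqs[j]);
    canonical_kmers(s, k, kms);
    for (size_t t = 0; t < kms.size(); ++t)
      seen.insert(std::make_pair(kms[t], 1));
  }
  return (int)seen.size();
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Apply per-base substitution / insertion / deletion errors and emit
// phred+33 qualities. Uses R's RNG so results are reproducible under
// set.seed(). Quality centres on the phred of the total error rate with
// +/- jitter, clipped to [2, 41].
// [[Rcpp::export]]
List cpp_mutate_reads(CharacterVector seqs, double p_sub, double p_ins,
                      double p_del, int jitter) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  double p_tot = p_sub + p_ins + p_del;
  int q_centre = (p_tot <= 0) ? 41 : (int)(-10.0 * std::log10(p_tot) + 0.5);
  if (q_centre > 41) q_centre = 41;
  std::string newseq, newqual;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    newseq.clear(); newqual.clear();
    newseq.reserve(s.size() + 16); newqual.reserve(s.size() + 16);
    for (size_t j = 0; j < s.size(); ++j) {
      if (p_del > 0 && unif_rand() < p_del) continue;
      char c = s[j];
      if (p_sub > 0 && unif_rand() < p_sub) {
        int cur = base2bit(c);
        int b = (int)(unif_rand() * 3.0);
        if (b > 2) b = 2;
        c = BASES[(cur < 0 ? 0 : (cur + 1 + b) % 4)];
      }
      newseq.push_back(c);
      if (p_ins > 0 && unif_rand() < p_ins)
        newseq.push_back(BASES[(int)(unif_rand() * 4.0) % 4]);
    }
    for (size_t j = 0; j < newseq.size(); ++j) {
      int q = q_centre;
      if (jitter > 0) q += (int)(unif_rand() * (2 * jitter + 1)) - jitter;
      if (q < 2) q = 2;
      if (q > 41) q = 41;
      newqual.push_back((char)(q + 33));
    }
    out_seq[i] = newseq;
    out_qual[i] = newqual;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual);
}
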