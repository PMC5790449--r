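#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// Count mismatches of read against ref[start, start+len), early exit past cap.
static inline int mm_count(const char* read, const char* ref, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (read[i] != ref[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Ungapped all-best-hits alignment of short reads against a set of reference
// sequences.  For each read, every (reference, offset[, strand]) placement with
// at most max_mm substitutions is scanned and the placements achieving the
// minimum mismatch count are returned.  Coordinates are 0-based; a hit spans
// [start, start + nchar(read)) on the reference (of the forward strand; minus
// strand hits mean the reverse complement of the read matches there).
// [[Rcpp::export]]
DataFrame align_ungapped_cpp(CharacterVector reads, CharacterVector refs,
                             int max_mm, bool both_strands) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> ref_str(nf);
  for (int j = 0; j < nf; ++j) ref_str[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_start, out_mm;
  std::vector<char> out_strand;
  std::vector<int> cand_ref, cand_start, cand_mm;
  std::vector<char> cand_strand;

  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int len = (int) fwd.size();
    if (len == 0) continue;
    std::string rev;
    if (both_strands) rev = revcomp(fwd);
    cand_ref.clear(); cand_start.clear(); cand_mm.clear(); cand_strand.clear();
    int best = max_mm + 1;
    for (int s = 0; s < (both_strands ? 2 : 1); ++s) {
      const char* rd = (s == 0 ? fwd.c_str() : rev.c_str());
      char strand = (s == 0 ? '+' : '-');
      for (int j = 0; j < nf; ++j) {
        const std::string& ref = ref_str[j];
        int maxoff = (int) ref.size() - len;
        const char* rc = ref.c_str();
        for (int off = 0; off <= maxoff; ++off) {
          int mm = mm_count(rd, rc + off, len, best <= max_mm ? best : max_mm);
          if (mm <= max_mm && mm <= best) {
            if (mm < best) best = mm;
            cand_ref.push_back(j + 1);
            cand_start.push_back(off);
            cand_mm.push_back(mm);
            cand_strand.push_back(strand);
          }
        }
      }
    }
    if (best <= max_mm) {
      for (std::size_t k = 0; k < cand_mm.size(); ++k) {
        if (cand_mm[k] == best) {
          out_read.push_back(i + 1);
          out_ref.push_back(cand_ref[k]);
          out_start.push_back(cand_start[k]);
          out_mm.push_back(cand_mm[k]);
          out_strand.push_back(cand_strand[k]);
        }
      }
    }
  }

  int n = (int) out_read.size();
  CharacterVector strand_col(n);
  for (int k = 0; k < n; ++k) strand_col[k] = std::string(1, out_strand[k]);
  return DataFrame::create(
    _["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
    _["start"] = wrap(out_start), _["strand"] = strand_col,
    _["mismatches"] = wrap(out_mm), _["stringsAsFactors"] = false);
}

// Leftmost adapter occurrence per read.  A prefix of the adapter (or the whole
// adapter) matching at position i with overlap >= min_overlap and
// mismatches <= floor(max_error_rate * overlap) trims the read to i bases.
// Returns the number of retained bases (nchar(seq) when no match).
// [[Rcpp::export]]
IntegerVector trim_positions_cpp(CharacterVector seqs, std::string adapter,
                                 int min_overlap, double max_error_rate) {
  int n = seqs.size();
  int alen = (int) adapter.size();
  const char* ad = adapter.c_str();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int) s.size();
    const char* sc = s.c_str();
    int keep = len;
    for (int pos = 0; pos + min_overlap <= len; ++pos) {
      int overlap = std::min(alen, len - pos);
      int allowed = (int) std::floor(max_error_rate * overlap);
      int mm = mm_count(sc + pos, ad, overlap, allowed);
      if (mm <= allowed) { keep = pos; break; }
    }
    out[i] = keep;
  }
  return out;
}

// Mean Phred+33 score per quality string (NaN for empty strings).
// [[Rcpp::export]]
NumericVector mean_phred_cpp(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    if (q.empty()) { out[i] = R_NaN; continue; }
    long sum = 0;
    bool bad = false;
    for (std::size_t k = 0; k < q.size(); ++k) {
      unsigned char c = (unsigned char) q[k];
      if (c < 33 || c > 126) { bad = true; break; }
      sum += (int) c - 33;
    }
    out[i] = bad ? NA_REAL : (double) sum / (double) q.size();
  }
  return out;
}

// Substitution signature of read i against the forward strand of its
// reference at the stored offset: "pos:ref>read" (1-based position on the
// read), comma separated; "" for a perfect match.
// [[Rcpp::export]]
CharacterVector mismatch_signature_cpp(CharacterVector reads,
                                       CharacterVector refs,
                                       IntegerVector ref_idx,
                                       IntegerVector starts) {
  int n = reads.size();
  int nf = refs.size();
  std::vector<std::string> ref_str(nf);
  for (int j = 0; j < nf; ++j) ref_str[j] = as<std::string>(refs[j]);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const std::string& rf = ref_str[ref_idx[i] - 1];
    int off = starts[i];
    std::string sig;
    for (std::size_t k = 0; k < rd.size(); ++k) {
      char rb = rf[off + k];
      if (rd[k] != rb) {
        if (!sig.empty()) sig += ",";
        sig += std::to_string(k + 1) + ":" + rb + ">" + rd[k];
      }
    }
    out[i] = sig;
  }
  return out;
}

// Per-base substitutions at a fixed rate, drawn from R's RNG stream so the
// result is reproducible under set.seed().  Substituted bases move to one of
// the three other nucleotides uniformly.
// [[Rcpp::export]]
CharacterVector mutate_bases_cpp(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (std::size_t k = 0; k < s.size(); ++k) {
      if (unif_rand() < rate) {
        char cur = s[k];
        char sub = cur;
        while (sub == cur) sub = bases[(int) (unif_rand() * 4) % 4];
        s[k] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}

// Reverse complement of DNA strings (A/C/G/T/N, case preserved as upper).
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
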