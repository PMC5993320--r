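#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Base identity with N always a mismatch (conservative, deterministic).
static inline bool base_mismatch(char a, char b) {
  return (a != b) || a == 'N' || b == 'N';
}

// Hamming distance between read (possibly reverse-complemented already) and
// ref[start..start+len-1], early exit once cap is exceeded (returns cap + 1).
static inline int hamming_capped(const char* read, const char* ref, int start,
                                 int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (base_mismatch(read[i], ref[start + i])) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return out;
}

// Scan every read against every reference on both strands, keeping only the
// best (minimum-mismatch) stratum with mismatches <= max_mm. five_prime_pos
// is the 0-based plus-strand coordinate of the read's 5' end: the window
// start for '+' hits, the window end for '-' hits.
// [[Rcpp::export(name = ".scan_reads_cpp")]]
List scan_reads_cpp(CharacterVector reads, CharacterVector refs, int max_mm) {
  const int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_s(n_refs);
  for (int j = 0; j < n_refs; ++j) ref_s[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_pos, out_mm;
  std::vector<int> out_strand;  // 1 = '+', -1 = '-'

  for (int r = 0; r < n_reads; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = revcomp(fwd);
    const int len = (int)fwd.size();
    int best = max_mm + 1;
    // hits in the current best stratum: (ref, strand, window_start, mm)
    std::vector<std::array<int, 4>> hits;
    for (int j = 0; j < n_refs; ++j) {
      const char* ref = ref_s[j].c_str();
      const int L = (int)ref_s[j].size();
      if (len > L) continue;
      for (int st = 0; st + len <= L; ++st) {
        for (int strand = 0; strand < 2; ++strand) {
          const char* q = strand == 0 ? fwd.c_str() : rev.c_str();
          int mm = hamming_capped(q, ref, st, len, best);
          if (mm < best) {
            best = mm;
            hits.clear();
          }
          if (mm == best && mm <= max_mm)
            hits.push_back({j, strand == 0 ? 1 : -1, st, mm});
        }
      }
    }
    for (auto& h : hits) {
      out_read.push_back(r + 1);
      out_ref.push_back(h[0] + 1);
      out_strand.push_back(h[1]);
      // '-' hits: 5' end sits at the window's right edge in plus coordinates
      out_pos.push_back(h[1] == 1 ? h[2] : h[2] + (int)fwd.size() - 1);
      out_mm.push_back(h[3]);
    }
  }
  return List::create(_["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
                      _["strand"] = wrap(out_strand),
                      _["five_prime_pos"] = wrap(out_pos),
                      _["mismatches"] = wrap(out_mm));
}

// Uncapped best placement per read: minimal Hamming distance over all
// windows of all references, both strands, with its strand. Ties go to the
// first window in scan order (ref order, then position, '+' before '-').
// [[Rcpp::export(name = ".best_hit_cpp")]]
List best_hit_cpp(CharacterVector reads, CharacterVector refs) {
  const int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_s(n_refs);
  for (int j = 0; j < n_refs; ++j) ref_s[j] = as<std::string>(refs[j]);

  IntegerVector min_mm(n_reads), strand(n_reads), pos(n_reads), refi(n_reads);
  for (int r = 0; r < n_reads; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = revcomp(fwd);
    const int len = (int)fwd.size();
    int best = len + 1, b_strand = NA_INTEGER, b_pos = NA_INTEGER,
        b_ref = NA_INTEGER;
    for (int j = 0; j < n_refs; ++j) {
      const char* ref = ref_s[j].c_str();
      const int L = (int)ref_s[j].size();
      if (len > L) continue;
      for (int st = 0; st + len <= L; ++st) {
        for (int sd = 0; sd < 2; ++sd) {
          const char* q = sd == 0 ? fwd.c_str() : rev.c_str();
          int mm = hamming_capped(q, ref, st, len, best - 1);
          if (mm < best) {
            best = mm;
            b_strand = sd == 0 ? 1 : -1;
            b_pos = sd == 0 ? st : st + len - 1;
            b_ref = j + 1;
          }
        }
      }
    }
    min_mm[r] = best > len ? NA_INTEGER : best;
    strand[r] = b_strand;
    pos[r] = b_pos;
    refi[r] = b_ref;
  }
  return List::create(_["min_mm"] = min_mm, _["strand"] = strand,
                      _["five_prime_pos"] = pos, _["ref"] = refi);
}

// 3'-adapter search: leftmost i where the adapter prefix matches the read
// from i to its end (overlap = min(adapter length, read length - i)), with
// at most max_mm mismatches and overlap >= min_overlap. Returns the 0-based
// insert length (== i), or -1 when no adapter is found.
// [[Rcpp::export(name = ".find_adapter_cpp")]]
IntegerVector find_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, int max_mm) {
  const int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    const std::string s = as<std::string>(reads[r]);
    const int len = (int)s.size();
    int found = -1;
    for (int i = 0; i <= len - min_overlap; ++i) {
      const int ov = std::min(alen, len - i);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (base_mismatch(s[i + k], adapter[k]) && ++mm > max_mm) {
          ok = false;
          break;
        }
      }
      if (ok) {
        found = i;
        break;
      }
    }
    out[r] = found;
  }
  return out;
}
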