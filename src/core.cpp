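#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// 'N' never matches anything, including another 'N'.
static inline bool base_mismatch(char a, char b) {
  return a == 'N' || b == 'N' || a != b;
}

static std::string revcomp_str(const std::string& s) {
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

static inline int count_mm(const std::string& g, long p, const std::string& q,
                           int allowed) {
  int mm = 0;
  const size_t L = q.size();
  for (size_t j = 0; j < L; ++j) {
    if (base_mismatch(g[p + j], q[j])) {
      if (++mm > allowed) return mm;
    }
  }
  return mm;
}

// Exhaustive-equivalent end-to-end placement of each read on both strands
// of every contig, reporting exactly one alignment from the lowest-mismatch
// stratum with deterministic tie-breaking: (contig order as supplied,
// coordinate, forward before reverse). Candidate placements are generated
// by the pigeonhole principle: any placement with <= max_mismatches
// mismatches must contain an exact, N-free occurrence of one of three
// disjoint read segments (valid whenever max_mismatches <= 2), so exact
// substring search enumerates every qualifying placement. Short reads fall
// back to a full scan. Returns, per read: contig index (1-based, NA if
// unmapped), 0-based leftmost position, strand (0 = "+", 1 = "-"),
// mismatch count.
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector contig_seqs,
                   int max_mismatches) {
  const int n_reads = reads.size();
  const int n_contigs = contig_seqs.size();
  std::vector<std::string> contigs(n_contigs);
  for (int c = 0; c < n_contigs; ++c) contigs[c] = as<std::string>(contig_seqs[c]);

  IntegerVector out_contig(n_reads, NA_INTEGER);
  IntegerVector out_pos(n_reads, NA_INTEGER);
  IntegerVector out_strand(n_reads, NA_INTEGER);
  IntegerVector out_mm(n_reads, NA_INTEGER);

  const bool seeds_ok = max_mismatches <= 2;
  std::vector<long long> cand;

  for (int r = 0; r < n_reads; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = revcomp_str(fwd);
    const int L = (int)fwd.size();
    if (L == 0) continue;
    int best_mm = max_mismatches + 1;
    int best_contig = -1;
    long best_pos = -1;
    int best_strand = -1;

    if (seeds_ok && L >= 6) {
      // encode candidates as ((contig * maxlen + pos) * 2 + strand) so a
      // sorted scan visits them in exact tie order
      cand.clear();
      long long maxlen = 0;
      for (int c = 0; c < n_contigs; ++c)
        maxlen = std::max(maxlen, (long long)contigs[c].size() + 1);
      const int k = L / 3;
      for (int c = 0; c < n_contigs; ++c) {
        const std::string& g = contigs[c];
        if ((int)g.size() < L) continue;
        for (int s = 0; s < 2; ++s) {
          const std::string& q = (s == 0) ? fwd : rev;
          for (int off = 0; off <= 2 * k; off += k) {
            const std::string seed = q.substr(off, k);
            if (seed.find('N') != std::string::npos) continue;
            size_t at = g.find(seed);
            while (at != std::string::npos) {
              const long p = (long)at - off;
              if (p >= 0 && p + L <= (long)g.size())
                cand.push_back(((long long)c * maxlen + p) * 2 + s);
              at = g.find(seed, at + 1);
            }
          }
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (long long code : cand) {
        const int s = (int)(code & 1);
        const long long cp = code >> 1;
        const int c = (int)(cp / maxlen);
        const long p = (long)(cp % maxlen);
        const std::string& q = (s == 0) ? fwd : rev;
        const int allowed = best_mm - 1;  // must beat the incumbent
        const int mm = count_mm(contigs[c], p, q, allowed);
        if (mm <= allowed) {
          best_mm = mm;
          best_contig = c;
          best_pos = p;
          best_strand = s;
          if (best_mm == 0) break;  // first in tie order wins
        }
      }
    } else {
      // short reads (or a relaxed mismatch budget): full scan
      for (int c = 0; c < n_contigs && best_mm > 0; ++c) {
        const std::string& g = contigs[c];
        const long n_pos = (long)g.size() - L;
        for (long p = 0; p <= n_pos; ++p) {
          for (int s = 0; s < 2; ++s) {
            const std::string& q = (s == 0) ? fwd : rev;
            const int allowed = best_mm - 1;
            const int mm = count_mm(g, p, q, allowed);
            if (mm <= allowed) {
              best_mm = mm;
              best_contig = c;
              best_pos = p;
              best_strand = s;
              if (best_mm == 0) break;
            }
          }
          if (best_mm == 0) break;
        }
      }
    }
    if (best_contig >= 0) {
      out_contig[r] = best_contig + 1;
      out_pos[r] = (int)best_pos;
      out_strand[r] = best_strand;
      out_mm[r] = best_mm;
    }
  }
  return List::create(_["contig"] = out_contig, _["pos"] = out_pos,
                      _["strand"] = out_strand, _["mismatches"] = out_mm);
}

// cutadapt-style 3' adapter search. Placements start the adapter at every
// read position; the matched length is min(adapter length, bases left).
// Suffix-overlapping partial matches must cover >= min_overlap bases.
// Errors allowed: floor(max_error_rate * matched length). Among qualifying
// placements: fewest errors, then longest match, then leftmost start.
// Returns the 0-based position trimming starts at, or -1 for no match.
// [[Rcpp::export(name = ".trim_polya_cpp")]]
IntegerVector trim_polya_cpp(CharacterVector seqs, std::string adapter,
                             int min_overlap, double max_error_rate) {
  const int n = seqs.size();
  const int alen = (int)adapter.size();
  IntegerVector out(n, -1);
  for (int r = 0; r < n; ++r) {
    const std::string s = as<std::string>(seqs[r]);
    const int L = (int)s.size();
    int best_err = -1, best_m = -1, best_i = -1;
    for (int i = 0; i < L; ++i) {
      const int m = std::min(alen, L - i);
      if (m < min_overlap) break;  // m only shrinks as i grows
      const int allowed = (int)(max_error_rate * m);
      int err = 0;
      for (int j = 0; j < m; ++j) {
        if (base_mismatch(s[i + j], adapter[j])) {
          if (++err > allowed) break;
        }
      }
      if (err > allowed) continue;
      if (best_i < 0 || err < best_err || (err == best_err && m > best_m)) {
        best_err = err;
        best_m = m;
        best_i = i;
      }
    }
    if (best_i >= 0) out[r] = best_i;
  }
  return out;
}
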