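#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

// Hamming distance with early exit once `limit` is exceeded; returns limit+1
// if the true distance is larger than limit.
static inline int hamming_limited(const char* a, const char* b, int k, int limit) {
  int d = 0;
  for (int i = 0; i < k; ++i) {
    if (a[i] != b[i]) {
      if (++d > limit) return d;
    }
  }
  return d;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

struct Occurrence {
  int source;     // index into the combined source list (chroms then regions)
  int pos;        // 0-based start within the source
};

// One candidate sequence in the comparison universe: a k-mer occurrence read in
// one orientation. Each N-free occurrence contributes a forward and a
// reverse-complement entry, both tagged with the same occurrence id so that an
// occurrence is never compared against itself (self-exclusion covers the
// reverse-complement reading of the same genomic window as well: a palindromic
// k-mer is not disqualified by its own other-strand reading).
struct Entry {
  const char* p;
  int occ;
};

// Shared setup for both mappability implementations. Sources are the genome
// chromosomes followed by the synthetic regions; occurrences are every k-mer
// start; windows containing N are unmappable and excluded from the universe.
struct MapProblem {
  std::vector<std::string> fwd, rc;
  std::vector<Occurrence> occs;
  std::vector<std::vector<int>> occ_index;   // per source: pos -> occ id or -1
  std::vector<Entry> entries;
  int k;

  MapProblem(const std::vector<std::string>& seqs, int k_) : k(k_) {
    int nsrc = (int) seqs.size();
    fwd.reserve(nsrc); rc.reserve(nsrc);
    for (int s = 0; s < nsrc; ++s) {
      fwd.push_back(seqs[s]);
      rc.push_back(revcomp(seqs[s]));
    }
    occ_index.resize(nsrc);
    for (int s = 0; s < nsrc; ++s) {
      int L = (int) fwd[s].size();
      int nstart = L - k + 1;
      if (nstart < 0) nstart = 0;
      occ_index[s].assign(nstart, -1);
      // prefix N counts for O(1) window checks
      std::vector<int> npre(L + 1, 0);
      for (int i = 0; i < L; ++i) {
        char c = fwd[s][i];
        bool isN = !(c == 'A' || c == 'C' || c == 'G' || c == 'T');
        npre[i + 1] = npre[i] + (isN ? 1 : 0);
      }
      for (int i = 0; i < nstart; ++i) {
        if (npre[i + k] - npre[i] > 0) continue;  // window contains N
        int id = (int) occs.size();
        occs.push_back({s, i});
        occ_index[s][i] = id;
      }
    }
    entries.reserve(occs.size() * 2);
    for (size_t id = 0; id < occs.size(); ++id) {
      const Occurrence& o = occs[id];
      int L = (int) fwd[o.source].size();
      entries.push_back({fwd[o.source].data() + o.pos, (int) id});
      entries.push_back({rc[o.source].data() + (L - o.pos - k), (int) id});
    }
  }

  const char* fwd_ptr(int occ_id) const {
    const Occurrence& o = occs[occ_id];
    return fwd[o.source].data() + o.pos;
  }
};

// Accelerated neighborhood search by pigeonhole partitioning: split each k-mer
// into eps+1 segments; any pair within Hamming distance eps must agree exactly
// on at least one segment, so per-segment exact hashing yields a complete
// candidate set.
static std::vector<char> solve_pigeonhole(const MapProblem& pb, int eps) {
  int k = pb.k;
  int nchunk = eps + 1;
  std::vector<int> cb(nchunk + 1);
  for (int c = 0; c <= nchunk; ++c) cb[c] = (int) ((long long) c * k / nchunk);

  std::vector<char> unmappable(pb.occs.size(), 0);

  for (int c = 0; c < nchunk; ++c) {
    int off = cb[c], len = cb[c + 1] - cb[c];
    std::unordered_map<std::string, std::vector<int>> index;
    index.reserve(pb.entries.size() * 2);
    std::string key(len, 'A');
    for (size_t e = 0; e < pb.entries.size(); ++e) {
      key.assign(pb.entries[e].p + off, len);
      index[key].push_back((int) e);
    }
    for (size_t id = 0; id < pb.occs.size(); ++id) {
      if (unmappable[id]) continue;
      const char* a = pb.fwd_ptr((int) id);
      key.assign(a + off, len);
      auto it = index.find(key);
      if (it == index.end()) continue;
      for (int e : it->second) {
        const Entry& en = pb.entries[e];
        if (en.occ == (int) id) continue;
        if (hamming_limited(a, en.p, k, eps) <= eps) { unmappable[id] = 1; break; }
      }
    }
  }
  return unmappable;
}

// Exhaustive all-pairs comparison; the independent oracle.
static std::vector<char> solve_brute(const MapProblem& pb, int eps) {
  int k = pb.k;
  std::vector<char> unmappable(pb.occs.size(), 0);
  for (size_t id = 0; id < pb.occs.size(); ++id) {
    const char* a = pb.fwd_ptr((int) id);
    for (size_t e = 0; e < pb.entries.size(); ++e) {
      const Entry& en = pb.entries[e];
      if (en.occ == (int) id) continue;
      if (hamming_limited(a, en.p, k, eps) <= eps) { unmappable[id] = 1; break; }
    }
  }
  return unmappable;
}

static List pack_result(const MapProblem& pb, const std::vector<char>& unmappable,
                        int n_chrom, int n_region) {
  List genome(n_chrom), regions(n_region);
  for (int s = 0; s < n_chrom + n_region; ++s) {
    int nstart = (int) pb.occ_index[s].size();
    LogicalVector v(nstart, false);
    for (int i = 0; i < nstart; ++i) {
      int id = pb.occ_index[s][i];
      if (id >= 0 && !unmappable[id]) v[i] = true;
    }
    if (s < n_chrom) genome[s] = v; else regions[s - n_chrom] = v;
  }
  return List::create(_["genome"] = genome, _["regions"] = regions);
}

// [[Rcpp::export]]
List cpp_mappability(CharacterVector chrom_seqs, CharacterVector region_seqs,
                     int k, int eps, bool brute) {
  std::vector<std::string> seqs;
  seqs.reserve(chrom_seqs.size() + region_seqs.size());
  for (R_xlen_t i = 0; i < chrom_seqs.size(); ++i) seqs.push_back(as<std::string>(chrom_seqs[i]));
  for (R_xlen_t i = 0; i < region_seqs.size(); ++i) seqs.push_back(as<std::string>(region_seqs[i]));
  MapProblem pb(seqs, k);
  std::vector<char> unmappable = brute ? solve_brute(pb, eps) : solve_pigeonhole(pb, eps);
  return pack_result(pb, unmappable, (int) chrom_seqs.size(), (int) region_seqs.size());
}

// Exhaustive alignment of reads against a set of subject sequences on both
// strands, reporting every placement within max_mm mismatches. Used by the
// simulator as an idealized (heuristic-free) aligner on small genomes.
// Positions are 0-based starts on the subject's forward strand.
// [[Rcpp::export]]
DataFrame cpp_scan_hits(CharacterVector subject_seqs, CharacterVector reads, int max_mm) {
  std::vector<std::string> subj;
  for (R_xlen_t i = 0; i < subject_seqs.size(); ++i) subj.push_back(as<std::string>(subject_seqs[i]));
  std::vector<int> out_read, out_subj, out_pos, out_mm;
  std::vector<std::string> out_strand;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    std::string rdrc = revcomp(rd);
    int len = (int) rd.size();
    for (size_t s = 0; s < subj.size(); ++s) {
      int L = (int) subj[s].size();
      for (int i = 0; i + len <= L; ++i) {
        const char* p = subj[s].data() + i;
        int d = hamming_limited(rd.data(), p, len, max_mm);
        if (d <= max_mm) {
          out_read.push_back((int) r + 1); out_subj.push_back((int) s + 1);
          out_pos.push_back(i); out_mm.push_back(d); out_strand.push_back("+");
        }
        d = hamming_limited(rdrc.data(), p, len, max_mm);
        if (d <= max_mm) {
          out_read.push_back((int) r + 1); out_subj.push_back((int) s + 1);
          out_pos.push_back(i); out_mm.push_back(d); out_strand.push_back("-");
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["subject"] = out_subj,
                           _["pos"] = out_pos, _["strand"] = out_strand,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}
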