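// Seed-and-extend ungapped local alignment against a k-mer index, plus the
// hot inner loops of the small-RNA adapter trimmer. Alignment semantics are
// deliberately simple so that an exhaustive per-diagonal scan can serve as an
// exact oracle: a hit is the FULL overlap of read and reference on one
// diagonal (one placement), kept iff span >= min_span and
// mismatches <= max_mismatch_rate * span. A base pair matches only when both
// characters are equal and in {A,C,G,T}; anything else (N etc.) is a
// mismatch. Minus-strand hits report read coordinates on the
// reverse-complemented read.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

struct KIdx {
  std::string seq;
  int k;
  std::unordered_map<uint64_t, std::vector<int> > pos;
};

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if ((size_t)k > seq.size()) stop("k exceeds reference length");
  KIdx* idx = new KIdx();
  idx->seq = seq;
  idx->k = k;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < (int)seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx->pos[h].push_back(i - k + 1);
  }
  XPtr<KIdx> p(idx, true);
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_index_positions(SEXP idxp, std::string kmer) {
  XPtr<KIdx> idx(idxp);
  if ((int)kmer.size() != idx->k) stop("kmer length must equal index k");
  uint64_t h = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base_code(kmer[i]);
    if (c < 0) return IntegerVector(0);
    h = (h << 2) | (uint64_t)c;
  }
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
    idx->pos.find(h);
  if (it == idx->pos.end()) return IntegerVector(0);
  return wrap(it->second);
}

// [[Rcpp::export]]
double cpp_index_n_positions(SEXP idxp) {
  XPtr<KIdx> idx(idxp);
  double n = 0;
  for (std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
         idx->pos.begin(); it != idx->pos.end(); ++it)
    n += it->second.size();
  return n;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idxp) {
  XPtr<KIdx> idx(idxp);
  return List::create(_["k"] = idx->k,
                      _["length"] = (double)idx->seq.size());
}

struct Hit {
  int strand;  // 0 = '+', 1 = '-'
  int ref_start, ref_end, read_start, read_end, mm;
  double identity;
};

static bool hit_before(const Hit& a, const Hit& b) {
  if (a.identity != b.identity) return a.identity > b.identity;
  int sa = a.ref_end - a.ref_start, sb = b.ref_end - b.ref_start;
  if (sa != sb) return sa > sb;
  if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
  return a.strand < b.strand;
}

// candidate diagonals (ref_pos - read_pos) from exact k-mer seed matches
static void seed_diagonals(const std::string& s, const KIdx& idx,
                           std::unordered_set<long>& diags) {
  const int k = idx.k;
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t h = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        idx.pos.find(h);
      if (it != idx.pos.end()) {
        int qpos = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j)
          diags.insert((long)it->second[j] - (long)qpos);
      }
    }
  }
}

// evaluate the full-overlap placement of oriented read s on diagonal D
static bool eval_diagonal(const std::string& s, const std::string& ref,
                          long D, double max_mm_rate, int min_span,
                          int strand, Hit& out) {
  const long rl = (long)s.size(), L = (long)ref.size();
  long a = D < 0 ? -D : 0;
  long b = rl < L - D ? rl : L - D;
  long span = b - a;
  if (span < (long)min_span) return false;
  int mm = 0;
  for (long j = a; j < b; ++j) {
    char x = s[j], y = ref[D + j];
    if (x != y || base_code(x) < 0) ++mm;
  }
  if ((double)mm > max_mm_rate * (double)span + 1e-9) return false;
  out.strand = strand;
  out.ref_start = (int)(D + a);
  out.ref_end = (int)(D + b);
  out.read_start = (int)a;
  out.read_end = (int)b;
  out.mm = mm;
  out.identity = 1.0 - (double)mm / (double)span;
  return true;
}

static void align_one(const std::string& read, const KIdx& idx,
                      double max_mm_rate, int min_span,
                      std::vector<Hit>& hits) {
  for (int strand = 0; strand < 2; ++strand) {
    std::string s = strand == 0 ? read : revcomp_str(read);
    std::unordered_set<long> diags;
    seed_diagonals(s, idx, diags);
    Hit h;
    for (std::unordered_set<long>::const_iterator it = diags.begin();
         it != diags.end(); ++it)
      if (eval_diagonal(s, idx.seq, *it, max_mm_rate, min_span, strand, h))
        hits.push_back(h);
  }
  std::sort(hits.begin(), hits.end(), hit_before);
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads, SEXP idxp,
                          double max_mm_rate, int min_span) {
  XPtr<KIdx> idx(idxp);
  std::vector<int> r_read, r_refs, r_refe, r_rds, r_rde, r_mm;
  std::vector<double> r_id;
  std::vector<int> r_strand;
  for (int i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    align_one(rd, *idx, max_mm_rate, min_span, hits);
    for (size_t j = 0; j < hits.size(); ++j) {
      const Hit& h = hits[j];
      r_read.push_back(i + 1);
      r_strand.push_back(h.strand);
      r_refs.push_back(h.ref_start);
      r_refe.push_back(h.ref_end);
      r_rds.push_back(h.read_start);
      r_rde.push_back(h.read_end);
      r_mm.push_back(h.mm);
      r_id.push_back(h.identity);
    }
  }
  CharacterVector strand(r_strand.size());
  for (size_t i = 0; i < r_strand.size(); ++i)
    strand[i] = r_strand[i] == 0 ? "+" : "-";
  return DataFrame::create(
    _["read"] = wrap(r_read), _["strand"] = strand,
    _["ref_start"] = wrap(r_refs), _["ref_end"] = wrap(r_refe),
    _["read_start"] = wrap(r_rds), _["read_end"] = wrap(r_rde),
    _["mismatches"] = wrap(r_mm), _["identity"] = wrap(r_id),
    _["stringsAsFactors"] = false);
}

// best hit per read (first in sort order); hit == FALSE rows carry NAs
// [[Rcpp::export]]
DataFrame cpp_best_hits(CharacterVector reads, SEXP idxp,
                        double max_mm_rate, int min_span) {
  XPtr<KIdx> idx(idxp);
  int n = reads.size();
  LogicalVector has(n);
  CharacterVector strand(n);
  IntegerVector refs(n), refe(n), rds(n), rde(n), mm(n);
  NumericVector ident(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<Hit> hits;
    align_one(rd, *idx, max_mm_rate, min_span, hits);
    if (hits.empty()) {
      has[i] = false;
      strand[i] = NA_STRING;
      refs[i] = refe[i] = rds[i] = rde[i] = mm[i] = NA_INTEGER;
      ident[i] = NA_REAL;
    } else {
      const Hit& h = hits[0];
      has[i] = true;
      strand[i] = h.strand == 0 ? "+" : "-";
      refs[i] = h.ref_start; refe[i] = h.ref_end;
      rds[i] = h.read_start; rde[i] = h.read_end;
      mm[i] = h.mm; ident[i] = h.identity;
    }
  }
  return DataFrame::create(
    _["hit"] = has, _["strand"] = strand,
    _["ref_start"] = refs, _["ref_end"] = refe,
    _["read_start"] = rds, _["read_end"] = rde,
    _["mismatches"] = mm, _["identity"] = ident,
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
LogicalVector cpp_maps_end_to_end(CharacterVector reads, SEXP idxp,
                                  double max_mm_rate, int min_span,
                                  double end_to_end_fraction) {
  XPtr<KIdx> idx(idxp);
  int n = reads.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    double need = end_to_end_fraction * (double)rd.size() - 1e-9;
    bool found = false;
    for (int strand = 0; strand < 2 && !found; ++strand) {
      std::string s = strand == 0 ? rd : revcomp_str(rd);
      std::unordered_set<long> diags;
      seed_diagonals(s, *idx, diags);
      Hit h;
      for (std::unordered_set<long>::const_iterator it = diags.begin();
           it != diags.end(); ++it) {
        if (eval_diagonal(s, idx->seq, *it, max_mm_rate, min_span, strand, h)
            && (double)(h.read_end - h.read_start) >= need) {
          found = true;
          break;
        }
      }
    }
    out[i] = found;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// Leftmost 0-based position where a prefix of the adapter matches the read
// suffix starting there, allowing 1 mismatch per 10 nt of overlap. Overlaps
// shorter than min_overlap qualify only when they cover the full adapter.
// Returns read length when no match (i.e. keep everything).
// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector reads, std::string adapter,
                                 int min_overlap) {
  int n = reads.size();
  int al = (int)adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int rl = (int)rd.size();
    int cut = rl;
    for (int p = 0; p < rl; ++p) {
      int o = std::min(al, rl - p);
      if (o < min_overlap && o < al) continue;
      int allowed = o / 10;
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < o; ++j) {
        if (rd[p + j] != adapter[j] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { cut = p; break; }
    }
    out[i] = cut;
  }
  return out;
}
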