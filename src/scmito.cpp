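#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct Hit { int ref; int pos; };  // pos 0-based on the stored sequence

// Reference 0 is the circular mitochondrial genome stored doubled; k-mers are
// indexed over the first copy only so every origin-spanning k-mer is present
// exactly once.
struct KmerIndex {
  int k;
  int mt_len;  // circular length of ref 0 (its stored string is 2*mt_len)
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<int> klass;  // 0 = mt, 1 = nuclear
  std::unordered_map<uint64_t, std::vector<Hit>> map;
};

bool encode_kmer(const std::string& s, size_t i, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[i + j]);
    if (c < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(c);
  }
  out = v;
  return true;
}

struct WinAln {
  int score = -1;
  int ref_start = 0, ref_end = 0;    // 0-based [start, end) on stored sequence
  int read_start = 0, read_end = 0;  // 0-based [start, end) on oriented read
  std::string cigar;                 // M/I/D runs, no clips
};

// Local alignment with affine gaps over a reference window. gap_open is the
// penalty of the first gap base, gap_ext of each further base (both >= 0).
WinAln align_window(const std::string& read, const std::string& ref,
                    int wstart, int wlen,
                    int match, int mismatch, int gap_open, int gap_ext) {
  const int m = static_cast<int>(read.size());
  const int n = wlen;
  const int NEG = -100000000;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (D), 3 from F (I)
  std::vector<uint8_t> TH((m + 1) * (n + 1), 0), TE((m + 1) * (n + 1), 0),
      TF((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const char gc = ref[wstart + j - 1];
      int e_open = H[at(i, j - 1)] - gap_open;
      int e_ext = E[at(i, j - 1)] - gap_ext;
      if (e_open >= e_ext) { E[at(i, j)] = e_open; TE[at(i, j)] = 0; }
      else { E[at(i, j)] = e_ext; TE[at(i, j)] = 1; }
      int f_open = H[at(i - 1, j)] - gap_open;
      int f_ext = F[at(i - 1, j)] - gap_ext;
      if (f_open >= f_ext) { F[at(i, j)] = f_open; TF[at(i, j)] = 0; }
      else { F[at(i, j)] = f_ext; TF[at(i, j)] = 1; }
      int sub = (rc == gc && base_code(rc) >= 0) ? match : mismatch;
      int diag = H[at(i - 1, j - 1)] + sub;
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; t = 2; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; t = 3; }
      H[at(i, j)] = h; TH[at(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  WinAln out;
  out.score = best;
  if (best <= 0) { out.score = 0; return out; }
  // traceback
  std::string ops;
  int i = bi, j = bj;
  int state = 0;  // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t t = TH[at(i, j)];
      if (t == 0) break;
      if (t == 1) { ops.push_back('M'); --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t t = TE[at(i, j)];
      ops.push_back('D'); --j;
      state = (t == 1) ? 1 : 0;
    } else {
      uint8_t t = TF[at(i, j)];
      ops.push_back('I'); --i;
      state = (t == 1) ? 2 : 0;
    }
  }
  out.read_start = i; out.read_end = bi;
  out.ref_start = wstart + j; out.ref_end = wstart + bj;
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  out.cigar = cig;
  return out;
}

struct BestAln {
  bool valid = false;
  int score = -1;
  int ref = -1;
  int start0 = 0;       // 0-based canonical start on the reference
  int span = 0;         // reference bases consumed
  char strand = '+';
  std::string cigar;    // with soft clips, oriented-read order
  int n_best_starts = 1;
};

void consider(BestAln& best, const WinAln& w, int ref, char strand, int read_len,
              int mt_len, bool circular) {
  if (w.score <= 0) return;
  int start0 = w.ref_start;
  if (circular && mt_len > 0) start0 %= mt_len;
  if (w.score < best.score) return;
  if (w.score == best.score && best.valid) {
    // equal-best: keep lowest canonical start, count distinct placements
    bool same_place = (ref == best.ref && strand == best.strand &&
                       start0 == best.start0);
    if (!same_place) {
      best.n_best_starts += 1;
      if (start0 < best.start0 || (start0 == best.start0 && ref < best.ref))
        ;  // fall through to replace
      else
        return;
    } else {
      return;
    }
  } else if (w.score > best.score) {
    best.n_best_starts = 1;
  }
  best.valid = true;
  best.score = w.score;
  best.ref = ref;
  best.start0 = start0;
  best.span = w.ref_end - w.ref_start;
  best.strand = strand;
  std::string cig;
  if (w.read_start > 0) cig += std::to_string(w.read_start) + "S";
  cig += w.cigar;
  if (read_len - w.read_end > 0) cig += std::to_string(read_len - w.read_end) + "S";
  best.cigar = cig;
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names,
                     IntegerVector klass, int k, int mt_len) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->mt_len = mt_len;
  for (int r = 0; r < seqs.size(); ++r) {
    idx->names.push_back(as<std::string>(names[r]));
    idx->seqs.push_back(as<std::string>(seqs[r]));
    idx->klass.push_back(klass[r]);
  }
  int n_skipped = 0;
  for (int r = 0; r < static_cast<int>(idx->seqs.size()); ++r) {
    const std::string& s = idx->seqs[r];
    int last = static_cast<int>(s.size()) - k;
    if (r == 0 && mt_len > 0) last = std::min(last, mt_len - 1);
    for (int i = 0; i <= last; ++i) {
      uint64_t key;
      if (!encode_kmer(s, i, k, key)) { ++n_skipped; continue; }
      idx->map[key].push_back({r, i});
    }
  }
  XPtr<KmerIndex> p(idx, true);
  p.attr("n_skipped") = n_skipped;
  return p;
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  uint64_t key;
  if (static_cast<int>(kmer.size()) != idx->k || !encode_kmer(kmer, 0, idx->k, key))
    return DataFrame::create(_["ref"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  auto it = idx->map.find(key);
  if (it == idx->map.end())
    return DataFrame::create(_["ref"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  IntegerVector ref, pos;
  for (const Hit& h : it->second) {
    ref.push_back(h.ref + 1);
    int p = h.pos;
    if (h.ref == 0 && idx->mt_len > 0) p %= idx->mt_len;
    pos.push_back(p + 1);
  }
  return DataFrame::create(_["ref"] = ref, _["pos"] = pos);
}

// [[Rcpp::export]]
List cpp_align_reads(SEXP xp, CharacterVector reads, int seed_step, int band,
                     int match, int mismatch, int gap_open, int gap_ext) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const int n = reads.size();
  IntegerVector mt_score(n, NA_INTEGER), mt_start(n, NA_INTEGER),
      mt_span(n, NA_INTEGER), nuc_score(n, NA_INTEGER), nuc_ref(n, NA_INTEGER);
  CharacterVector mt_strand(n, NA_STRING), mt_cigar(n, NA_STRING);
  LogicalVector ambiguous(n, NA_LOGICAL);
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = static_cast<int>(fwd.size());
    BestAln best_mt, best_nuc;
    if (len >= k) {
      for (int si = 0; si < 2; ++si) {
        const char strand = si == 0 ? '+' : '-';
        const std::string s = si == 0 ? fwd : revcomp(fwd);
        // candidate (ref, diagonal) pairs from sampled exact seeds
        std::vector<std::pair<int, int>> cands;
        std::vector<int> offs;
        for (int o = 0; o + k <= len; o += seed_step) offs.push_back(o);
        if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
        for (int o : offs) {
          uint64_t key;
          if (!encode_kmer(s, o, k, key)) continue;
          auto it = idx->map.find(key);
          if (it == idx->map.end()) continue;
          for (const Hit& h : it->second) {
            int diag = h.pos - o;
            if (h.ref == 0 && idx->mt_len > 0)
              diag = ((diag % idx->mt_len) + idx->mt_len) % idx->mt_len;
            bool dup = false;
            for (const auto& c : cands)
              if (c.first == h.ref && std::abs(c.second - diag) <= 8) { dup = true; break; }
            if (!dup) cands.emplace_back(h.ref, diag);
          }
        }
        for (const auto& c : cands) {
          const std::string& ref = idx->seqs[c.first];
          const int rl = static_cast<int>(ref.size());
          int wstart = c.second - band;
          if (wstart < 0) {
            if (c.first == 0 && idx->mt_len > 0) wstart += idx->mt_len;
            else wstart = 0;
          }
          int wlen = std::min(len + 2 * band, rl - wstart);
          if (wlen < k) continue;
          WinAln w = align_window(s, ref, wstart, wlen, match, mismatch,
                                  gap_open, gap_ext);
          bool circ = (c.first == 0 && idx->mt_len > 0);
          if (idx->klass[c.first] == 0)
            consider(best_mt, w, c.first, strand, len, idx->mt_len, circ);
          else
            consider(best_nuc, w, c.first, strand, len, idx->mt_len, circ);
        }
      }
    }
    if (best_mt.valid) {
      mt_score[r] = best_mt.score;
      mt_start[r] = best_mt.start0 + 1;
      mt_span[r] = best_mt.span;
      mt_strand[r] = std::string(1, best_mt.strand);
      mt_cigar[r] = best_mt.cigar;
      ambiguous[r] = best_mt.n_best_starts > 1;
    }
    if (best_nuc.valid) {
      nuc_score[r] = best_nuc.score;
      nuc_ref[r] = best_nuc.ref + 1;
    }
  }
  return List::create(
      _["mt_score"] = mt_score, _["mt_start"] = mt_start, _["mt_span"] = mt_span,
      _["mt_strand"] = mt_strand, _["mt_cigar"] = mt_cigar,
      _["ambiguous"] = ambiguous, _["nuc_score"] = nuc_score,
      _["nuc_ref"] = nuc_ref);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// Pileup over the circular reference. seq/qual must already be in reference
// orientation; start is the 1-based position of the first aligned base.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector start, CharacterVector cigar, CharacterVector seq,
                CharacterVector qual, int L, int min_q) {
  IntegerMatrix counts(4, L);  // rows A,C,G,T; quality-filtered
  IntegerVector raw(L);
  std::vector<int> ins_pos, ins_dist, ins_read, del_pos, del_len, del_dist, del_read;
  std::vector<std::string> ins_seq;
  for (int r = 0; r < start.size(); ++r) {
    if (IntegerVector::is_na(start[r])) continue;
    const std::string cg = as<std::string>(cigar[r]);
    const std::string sq = as<std::string>(seq[r]);
    const std::string ql = as<std::string>(qual[r]);
    const int read_len = static_cast<int>(sq.size());
    int refp = start[r];  // 1-based
    if (refp < 1 || refp > L) stop("alignment start outside [1, L]");
    int rp = 0;           // read bases consumed
    size_t i = 0;
    bool anchored = false;
    while (i < cg.size()) {
      int n = 0;
      while (i < cg.size() && isdigit(cg[i])) n = n * 10 + (cg[i++] - '0');
      char op = cg[i++];
      if (op == 'S') {
        rp += n;
      } else if (op == 'M') {
        for (int t = 0; t < n; ++t) {
          int p = refp - 1;
          raw[p] += 1;
          int code = base_code(sq[rp]);
          int q = static_cast<int>(ql[rp]) - 33;
          if (code >= 0 && q >= min_q) counts(code, p) += 1;
          ++rp;
          refp = (refp == L) ? 1 : refp + 1;
        }
        anchored = true;
      } else if (op == 'I') {
        if (anchored) {
          int anchor = refp - 1;            // previous ref position, 1-based
          if (anchor == 0) anchor = L;
          int dist = std::min(rp, read_len - (rp + n));
          ins_pos.push_back(anchor);
          ins_seq.push_back(sq.substr(rp, n));
          ins_dist.push_back(dist);
          ins_read.push_back(r + 1);
        }
        rp += n;
      } else if (op == 'D') {
        if (anchored) {
          int anchor = refp - 1;
          if (anchor == 0) anchor = L;
          int dist = std::min(rp, read_len - rp);
          del_pos.push_back(anchor);
          del_len.push_back(n);
          del_dist.push_back(dist);
          del_read.push_back(r + 1);
        }
        for (int t = 0; t < n; ++t) refp = (refp == L) ? 1 : refp + 1;
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }
  return List::create(
      _["counts"] = counts, _["raw"] = raw,
      _["ins"] = DataFrame::create(_["pos"] = wrap(ins_pos), _["seq"] = wrap(ins_seq),
                                   _["end_dist"] = wrap(ins_dist),
                                   _["read"] = wrap(ins_read),
                                   _["stringsAsFactors"] = false),
      _["del"] = DataFrame::create(_["pos"] = wrap(del_pos), _["len"] = wrap(del_len),
                                   _["end_dist"] = wrap(del_dist),
                                   _["read"] = wrap(del_read)));
}

// Depth over circular coordinates from (start, len) intervals.
// [[Rcpp::export]]
IntegerVector cpp_interval_depth(IntegerVector start, IntegerVector len, int L) {
  IntegerVector d(L);
  for (int i = 0; i < start.size(); ++i) {
    int p = start[i];
    for (int t = 0; t < len[i]; ++t) {
      d[p - 1] += 1;
      p = (p == L) ? 1 : p + 1;
    }
  }
  return d;
}
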