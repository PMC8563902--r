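#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <map>
#include <unordered_map>
#include <utility>
#include <cstdint>
using namespace Rcpp;

static const int NEG = -100000000;

struct DpResult {
  bool ok;
  int score;
  int ref_start;
  int nmm;
  std::string cigar;
};

static std::string rle_cigar(int lead, const std::string &ops_rev, int trail) {
  // ops_rev holds M/I/D ops in reverse order
  std::string out;
  char cur = 0;
  int run = 0;
  std::string ops(ops_rev.rbegin(), ops_rev.rend());
  if (lead > 0) { out += std::to_string(lead); out += 'S'; }
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] == cur) { run++; }
    else {
      if (run > 0) { out += std::to_string(run); out += cur; }
      cur = ops[k]; run = 1;
    }
  }
  if (run > 0) { out += std::to_string(run); out += cur; }
  if (trail > 0) { out += std::to_string(trail); out += 'S'; }
  return out;
}

// Glocal affine alignment: read end-to-end (except up to `clip` bases free at
// either read end), reference ends free.  A gap of length L costs
// gap_open + L * gap_extend.  'N' in read or reference scores 0 and is never
// a mismatch.
static DpResult glocal_dp(const std::string &rd, const std::string &rf,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int clip) {
  int m = rd.size(), n = rf.size();
  DpResult res; res.ok = false; res.score = NEG; res.ref_start = -1; res.nmm = 0;
  if (m == 0 || n == 0) return res;
  int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  std::vector<unsigned char> tM((m + 1) * W, 0), tX((m + 1) * W, 0), tY((m + 1) * W, 0);
  for (int i = 1; i <= m; ++i) {
    char a = rd[i - 1];
    for (int j = 0; j <= n; ++j) {
      int idx = i * W + j, up = (i - 1) * W + j;
      // X: gap in reference (read base consumed)
      {
        int fromM = M[up] <= NEG ? NEG : M[up] + gap_open + gap_ext;
        int fromX = X[up] <= NEG ? NEG : X[up] + gap_ext;
        if (fromM >= fromX) { X[idx] = fromM; tX[idx] = 1; }
        else { X[idx] = fromX; tX[idx] = 2; }
      }
      if (j >= 1) {
        int diag = (i - 1) * W + (j - 1);
        char b = rf[j - 1];
        bool isn = (a == 'N' || b == 'N');
        int s = isn ? 0 : ((a == b) ? match : mismatch);
        int start = (i - 1 <= clip) ? 0 : NEG;
        int best = start; unsigned char tb = 0;
        if (M[diag] > best) { best = M[diag]; tb = 1; }
        if (X[diag] > best) { best = X[diag]; tb = 2; }
        if (Y[diag] > best) { best = Y[diag]; tb = 3; }
        if (best > NEG) { M[idx] = best + s; tM[idx] = tb; }
        // Y: gap in read (reference base consumed)
        int left = i * W + (j - 1);
        int fromM = M[left] <= NEG ? NEG : M[left] + gap_open + gap_ext;
        int fromY = Y[left] <= NEG ? NEG : Y[left] + gap_ext;
        if (fromM >= fromY) { Y[idx] = fromM; tY[idx] = 1; }
        else { Y[idx] = fromY; tY[idx] = 2; }
      }
    }
  }
  int bi = -1, bj = -1, bs = NEG;
  for (int i = std::max(1, m - clip); i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      int v = M[i * W + j];
      if (v > bs) { bs = v; bi = i; bj = j; }
    }
  if (bs <= NEG) return res;
  // traceback (end in M state: trailing gaps never improve the score)
  std::string ops;
  int i = bi, j = bj, state = 0, nmm = 0;
  while (true) {
    int idx = i * W + j;
    if (state == 0) {
      unsigned char tb = tM[idx];
      char a = rd[i - 1], b = rf[j - 1];
      ops.push_back('M');
      if (a != 'N' && b != 'N' && a != b) nmm++;
      i--; j--;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char tb = tX[idx];
      ops.push_back('I'); i--;
      state = (tb == 1) ? 0 : 1;
    } else {
      unsigned char tb = tY[idx];
      ops.push_back('D'); j--;
      state = (tb == 1) ? 0 : 2;
    }
  }
  res.ok = true;
  res.score = bs;
  res.ref_start = j;
  res.nmm = nmm;
  res.cigar = rle_cigar(i, ops, m - bi);
  return res;
}

// [[Rcpp::export]]
List cpp_align_one(std::string read, CharacterVector refs,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int clip) {
  int nr = refs.size();
  IntegerVector score(nr), ref_start(nr), nmm(nr);
  LogicalVector ok(nr);
  CharacterVector cigar(nr);
  for (int r = 0; r < nr; ++r) {
    DpResult d = glocal_dp(read, as<std::string>(refs[r]), match, mismatch,
                           gap_open, gap_ext, clip);
    ok[r] = d.ok;
    score[r] = d.ok ? d.score : NA_INTEGER;
    ref_start[r] = d.ok ? d.ref_start : NA_INTEGER;
    nmm[r] = d.ok ? d.nmm : NA_INTEGER;
    if (d.ok) cigar[r] = d.cigar; else cigar[r] = NA_STRING;
  }
  return List::create(_["score"] = score, _["ref_start"] = ref_start,
                      _["n_mismatch"] = nmm, _["cigar"] = cigar, _["ok"] = ok);
}

// 2-bit k-mer encoding; returns false when the window contains a non-ACGT
static bool encode_kmer(const std::string &s, int pos, int k, uint32_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    char c = s[pos + i];
    uint32_t b;
    switch (c) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    code = (code << 2) | b;
  }
  return true;
}

typedef std::unordered_map<uint32_t, std::vector<std::pair<int, int> > > KmerIndex;

static const KmerIndex &get_index(std::map<int, KmerIndex> &cache,
                                  const std::vector<std::string> &R, int k) {
  std::map<int, KmerIndex>::iterator it = cache.find(k);
  if (it != cache.end()) return it->second;
  KmerIndex idx;
  for (size_t r = 0; r < R.size(); ++r) {
    int n = R[r].size();
    for (int p = 0; p + k <= n; ++p) {
      uint32_t code;
      if (encode_kmer(R[r], p, k, code))
        idx[code].push_back(std::make_pair((int)r, p));
    }
  }
  return cache.insert(std::make_pair(k, idx)).first->second;
}

// Batch aligner over a read set.  Fast path: ungapped placements (with end
// clips) located by exact seed k-mers, accepted only when no gapped
// alignment could score higher (best >= m*match + gap_open + gap_extend);
// any alignment admissible under that bound has <= 2 mismatches in its
// window, so at least one of three disjoint interior seed k-mers is exact
// and the candidate set is complete.  Everything else gets full DP over all
// references.
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, CharacterVector refs,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int clip, double min_frac) {
  int nreads = reads.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  std::map<int, KmerIndex> index_cache;
  IntegerVector o_ref(nreads), o_start(nreads), o_score(nreads), o_nmm(nreads),
      o_nbest(nreads);
  CharacterVector o_cigar(nreads);
  // abort mismatch counting once a window can no longer reach the safe bound
  int abort_mm = (match > mismatch)
      ? (-(gap_open + gap_ext)) / (match - mismatch) + 2 * clip + 1
      : 4;
  bool refs_have_n = false;
  for (int r = 0; r < nr; ++r)
    if (R[r].find('N') != std::string::npos) refs_have_n = true;
  std::vector<int> mmpos, npos;
  for (int q = 0; q < nreads; ++q) {
    std::string rd = as<std::string>(reads[q]);
    int m = rd.size();
    int safe_bound = m * match + gap_open + gap_ext;
    int best_s = NEG, best_r = -1, best_o = 0, best_cs = 0, best_ce = 0,
        best_mm = 0;
    std::vector<int> ref_best(nr, NEG);
    bool short_ref_risk = false;
    for (int r = 0; r < nr; ++r) {
      int n = (int)R[r].size();
      if (n < m - 2 * clip) {
        // too short to hold the read even fully clipped; a gapped alignment
        // is bounded by n matches minus the cost of the unplaceable bases
        int upper = n * match + gap_open + gap_ext * (m - 2 * clip - n);
        if (upper >= safe_bound) short_ref_risk = true;
      }
    }
    // evaluate one ungapped diagonal placement (read base k on ref d + k)
    // over all admissible end-clip combinations
    auto eval_diag = [&](int r, int d) {
      const std::string &rf = R[r];
      int n = (int)rf.size();
      if (d < -clip || d > n - m + clip) return;
      int fcs = d < 0 ? -d : 0;
      int fce = (d + m > n) ? d + m - n : 0;
      if (fcs > clip || fce > clip || fcs + fce >= m) return;
      mmpos.clear(); npos.clear();
      for (int k = fcs; k < m - fce; ++k) {
        char a = rd[k], b = rf[d + k];
        if (a == 'N' || b == 'N') { npos.push_back(k); continue; }
        if (a != b) {
          mmpos.push_back(k);
          if ((int)mmpos.size() >= abort_mm) return;
        }
      }
      for (int cs = fcs; cs <= clip && cs < m; ++cs) {
        for (int ce = fce; ce <= clip && cs + ce < m; ++ce) {
          int wl = m - cs - ce;
          int mmw = 0, nw = 0;
          for (size_t t = 0; t < mmpos.size(); ++t)
            if (mmpos[t] >= cs && mmpos[t] < m - ce) mmw++;
          for (size_t t = 0; t < npos.size(); ++t)
            if (npos[t] >= cs && npos[t] < m - ce) nw++;
          int sc = (wl - mmw - nw) * match + mmw * mismatch;
          if (sc > ref_best[r]) ref_best[r] = sc;
          if (sc > best_s) {
            best_s = sc; best_r = r; best_o = d + cs; best_cs = cs;
            best_ce = ce; best_mm = mmw;
          }
        }
      }
    };
    int kseed = std::min(13, (m - 2 * clip) / 3);
    bool seeded = false;
    if (!refs_have_n && kseed >= 6) {
      uint32_t c0, c1, c2;
      int off0 = clip;
      if (encode_kmer(rd, off0, kseed, c0) &&
          encode_kmer(rd, off0 + kseed, kseed, c1) &&
          encode_kmer(rd, off0 + 2 * kseed, kseed, c2)) {
        const KmerIndex &idx = get_index(index_cache, R, kseed);
        std::vector<std::pair<int, int> > cand;  // (ref, diagonal)
        uint32_t codes[3] = { c0, c1, c2 };
        int offs[3] = { off0, off0 + kseed, off0 + 2 * kseed };
        for (int s = 0; s < 3; ++s) {
          KmerIndex::const_iterator it = idx.find(codes[s]);
          if (it == idx.end()) continue;
          for (size_t t = 0; t < it->second.size(); ++t)
            cand.push_back(std::make_pair(it->second[t].first,
                                          it->second[t].second - offs[s]));
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (size_t t = 0; t < cand.size(); ++t)
          eval_diag(cand[t].first, cand[t].second);
        seeded = true;
      }
    }
    if (!seeded) {
      for (int r = 0; r < nr; ++r) {
        int n = (int)R[r].size();
        for (int d = -clip; d <= n - m + clip; ++d) eval_diag(r, d);
      }
    }
    bool shortcut = (best_r >= 0) && !short_ref_risk && (best_s >= safe_bound);
    if (shortcut) {
      int nb = 0;
      for (int r = 0; r < nr; ++r) if (ref_best[r] == best_s) nb++;
      double minscore = min_frac * m * match;
      if ((double)best_s < minscore) {
        o_ref[q] = NA_INTEGER; o_start[q] = NA_INTEGER; o_score[q] = NA_INTEGER;
        o_nmm[q] = NA_INTEGER; o_cigar[q] = NA_STRING; o_nbest[q] = 0;
      } else {
        o_ref[q] = best_r + 1;
        o_start[q] = best_o;
        o_score[q] = best_s;
        o_nmm[q] = best_mm;
        std::string cg;
        if (best_cs > 0) { cg += std::to_string(best_cs); cg += 'S'; }
        cg += std::to_string(m - best_cs - best_ce); cg += 'M';
        if (best_ce > 0) { cg += std::to_string(best_ce); cg += 'S'; }
        o_cigar[q] = cg;
        o_nbest[q] = nb;
      }
    } else {
      // full DP over all references
      int bs = NEG, br = -1, nb = 0;
      DpResult bd;
      for (int r = 0; r < nr; ++r) {
        DpResult d = glocal_dp(rd, R[r], match, mismatch, gap_open, gap_ext, clip);
        if (!d.ok) continue;
        if (d.score > bs) { bs = d.score; br = r; bd = d; nb = 1; }
        else if (d.score == bs) nb++;
      }
      double minscore = min_frac * m * match;
      if (br < 0 || (double)bs < minscore) {
        o_ref[q] = NA_INTEGER; o_start[q] = NA_INTEGER; o_score[q] = NA_INTEGER;
        o_nmm[q] = NA_INTEGER; o_cigar[q] = NA_STRING; o_nbest[q] = 0;
      } else {
        o_ref[q] = br + 1;
        o_start[q] = bd.ref_start;
        o_score[q] = bs;
        o_nmm[q] = bd.nmm;
        o_cigar[q] = bd.cigar;
        o_nbest[q] = nb;
      }
    }
  }
  return List::create(_["ref"] = o_ref, _["ref_start"] = o_start,
                      _["score"] = o_score, _["n_mismatch"] = o_nmm,
                      _["cigar"] = o_cigar, _["n_best"] = o_nbest);
}

// Per-reference base counts from alignment records.
// Returns one 5 x ref_len matrix per reference (rows A, C, G, T, del).
// [[Rcpp::export]]
List cpp_pileup(IntegerVector ref_idx, IntegerVector ref_start,
                CharacterVector cigar, CharacterVector seq,
                IntegerVector ref_len) {
  int nref = ref_len.size();
  std::vector<IntegerMatrix> mats;
  for (int r = 0; r < nref; ++r) mats.push_back(IntegerMatrix(5, ref_len[r]));
  int n = ref_idx.size();
  for (int q = 0; q < n; ++q) {
    if (ref_idx[q] == NA_INTEGER) continue;
    int r = ref_idx[q] - 1;
    IntegerMatrix &Mt = mats[r];
    std::string cg = as<std::string>(cigar[q]);
    std::string sq = as<std::string>(seq[q]);
    int ri = ref_start[q], qi = 0;
    size_t k = 0;
    while (k < cg.size()) {
      int len = 0;
      while (k < cg.size() && isdigit(cg[k])) { len = len * 10 + (cg[k] - '0'); k++; }
      char op = cg[k]; k++;
      if (op == 'S' || op == 'I') { qi += len; }
      else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          if (ri + t >= 0 && ri + t < ref_len[r]) Mt(4, ri + t)++;
        }
        ri += len;
      } else if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          char b = sq[qi + t];
          int row = -1;
          if (b == 'A') row = 0; else if (b == 'C') row = 1;
          else if (b == 'G') row = 2; else if (b == 'T') row = 3;
          if (row >= 0 && ri + t >= 0 && ri + t < ref_len[r]) Mt(row, ri + t)++;
        }
        ri += len; qi += len;
      }
    }
  }
  List out(nref);
  for (int r = 0; r < nref; ++r) out[r] = mats[r];
  return out;
}

// BWA-style 3' quality trimming: returns the kept length for each read.
// [[Rcpp::export]]
IntegerVector cpp_qual_trim(CharacterVector qual, int cutoff, int offset) {
  int n = qual.size();
  IntegerVector keep(n);
  for (int q = 0; q < n; ++q) {
    std::string qs = as<std::string>(qual[q]);
    int len = qs.size();
    int s = 0, max_s = 0, pos = len;
    for (int i = len - 1; i >= 0; --i) {
      s += cutoff - (qs[i] - offset);
      if (s < 0) break;
      if (s > max_s) { max_s = s; pos = i; }
    }
    keep[q] = pos;
  }
  return keep;
}

// Earliest (hence longest-overlap) position where a prefix of `adapter`
// matches the read suffix with at most floor(tol * overlap) mismatches and
// overlap >= min_overlap.  Returns 0-based adapter start, or read length.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap, double tol) {
  int n = reads.size(), alen = adapter.size();
  IntegerVector pos(n);
  for (int q = 0; q < n; ++q) {
    std::string rd = as<std::string>(reads[q]);
    int len = rd.size();
    int found = len;
    for (int i = 0; i <= len - min_overlap; ++i) {
      int overlap = std::min(alen, len - i);
      int allowed = (int)(tol * overlap);
      int mm = 0;
      bool okm = true;
      for (int k = 0; k < overlap; ++k) {
        if (rd[i + k] != adapter[k]) {
          mm++;
          if (mm > allowed) { okm = false; break; }
        }
      }
      if (okm) { found = i; break; }
    }
    pos[q] = found;
  }
  return pos;
}
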