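// Core sequence kernels: DUST low-complexity masking and a seed-and-extend
// nucleotide local aligner (exact k-mer seeding, ungapped X-drop extension,
// banded affine-gap Smith-Waterman with traceback).
#include <Rcpp.h>
#include <unordered_map>
#include <tuple>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// ---------------------------------------------------------------------------
// DUST masking
//
// Normative semantics: a run of bases is masked when some sub-interval of
// triplets, fitting inside a window of `window` bases, has triplet score
// sum_t c_t(c_t-1)/2 / (k-1) > level/10 (k = number of triplets, k >= 2).
// Equivalent to enumerating every window placement and every sub-window.
// Non-ACGT characters break triplets. Integer arithmetic throughout:
// score > level/10  <=>  10*num > level*(k-1).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_dust_mask(std::string seq, int window, int level, int linker) {
  const int n = (int)seq.size();
  std::vector<std::pair<int,int>> raw;

  int chunk_start = 0;
  while (chunk_start < n) {
    while (chunk_start < n && base_code(seq[chunk_start]) == 4) chunk_start++;
    int chunk_end = chunk_start;
    while (chunk_end < n && base_code(seq[chunk_end]) != 4) chunk_end++;
    const int L = chunk_end - chunk_start;
    if (L >= 4) {
      const int ntrip = L - 2;                 // triplet i covers bases [i, i+3)
      std::vector<uint8_t> trip(ntrip);
      for (int i = 0; i < ntrip; i++) {
        trip[i] = (uint8_t)(base_code(seq[chunk_start + i]) * 16 +
                            base_code(seq[chunk_start + i + 1]) * 4 +
                            base_code(seq[chunk_start + i + 2]));
      }
      const int max_span_trip = window - 2;    // triplets fitting in `window` bases
      std::vector<int> cnt(64, 0);
      for (int i = 0; i < ntrip; i++) {
        std::fill(cnt.begin(), cnt.end(), 0);
        long long num = 0;
        int best_j = -1;
        int jmax = std::min(ntrip - 1, i + max_span_trip - 1);
        for (int j = i; j <= jmax; j++) {
          num += cnt[trip[j]];
          cnt[trip[j]]++;
          int k = j - i + 1;
          if (k >= 2 && 10LL * num > (long long)level * (k - 1)) best_j = j;
        }
        if (best_j >= 0)
          raw.push_back({chunk_start + i, chunk_start + best_j + 3});
      }
    }
    chunk_start = chunk_end;
  }

  if (raw.empty()) return IntegerMatrix(0, 2);
  std::sort(raw.begin(), raw.end());
  std::vector<std::pair<int,int>> merged;
  for (auto &iv : raw) {
    if (!merged.empty() && iv.first - merged.back().second <= linker)
      merged.back().second = std::max(merged.back().second, iv.second);
    else
      merged.push_back(iv);
  }
  IntegerMatrix out((int)merged.size(), 2);
  for (int i = 0; i < (int)merged.size(); i++) {
    out(i, 0) = merged[i].first;
    out(i, 1) = merged[i].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed index
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  long long total_len;
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t>> code;    // 0-3, 4 = invalid (N / non-ACGT)
  std::vector<std::vector<uint8_t>> masked;  // 1 = soft-masked (lowercase)
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t>>> kmap;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (seqs.size() == 0) stop("cannot build a seed index from an empty database");
  if (k < 4 || k > 31) stop("seed word size k must be in [4, 31]");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  idx->total_len = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < seqs.size(); s++) {
    std::string sq = as<std::string>(seqs[s]);
    const int n = (int)sq.size();
    idx->names.push_back(as<std::string>(names[s]));
    idx->total_len += n;
    std::vector<uint8_t> code(n), msk(n);
    for (int i = 0; i < n; i++) {
      code[i] = (uint8_t)base_code(sq[i]);
      msk[i] = (sq[i] >= 'a' && sq[i] <= 'z') ? 1 : 0;
    }
    uint64_t h = 0;
    int run = 0;  // length of current valid, unmasked run
    for (int i = 0; i < n; i++) {
      if (code[i] == 4 || msk[i]) { run = 0; h = 0; continue; }
      h = ((h << 2) | code[i]) & mask;
      run++;
      if (run >= k)
        idx->kmap[h].push_back({(int32_t)s, (int32_t)(i - k + 1)});
    }
    idx->code.push_back(std::move(code));
    idx->masked.push_back(std::move(msk));
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_n_seeds(SEXP ptr_) {
  XPtr<SeedIndex> ptr(ptr_);
  long long tot = 0;
  for (auto &kv : ptr->kmap) tot += (long long)kv.second.size();
  return (int)tot;
}

// ---------------------------------------------------------------------------
// Banded affine-gap Smith-Waterman with traceback.
// Gap of length L costs gap_open + L * gap_extend (both negative).
// ---------------------------------------------------------------------------

struct AlnResult {
  int score, q0, q1, s0, s1, nident, alen, nmis, ngapopen;
};

static const int NEG = -1000000000;

static bool banded_sw(const std::vector<uint8_t> &q, int q0r, int q1r,
                      const std::vector<uint8_t> &s, int s0r, int s1r,
                      int diag0, int band,
                      int match, int mismatch, int gap_open, int gap_extend,
                      AlnResult &res) {
  const int nq = q1r - q0r, W = 2 * band + 1;
  if (nq <= 0 || s1r <= s0r) return false;
  // row i (query index q0r+i); allowed subject j in
  // [(q0r+i) - diag0 - band, (q0r+i) - diag0 + band] intersect [s0r, s1r)
  std::vector<int> H((size_t)W), E((size_t)W), F((size_t)W);
  std::vector<int> Hp((size_t)W), Ep((size_t)W), Fp((size_t)W);
  std::vector<uint8_t> tbH((size_t)nq * W), tbE((size_t)nq * W), tbF((size_t)nq * W);
  // tbH: 0 = start (from 0), 1 = diagonal, 2 = from E (gap in subject), 3 = from F
  // tbE: 0 = opened from H above, 1 = extended; tbF: 0 = opened from H left, 1 = extended
  int best = 0, bi = -1, bo = -1;
  for (int o = 0; o < W; o++) { Hp[o] = NEG; Ep[o] = NEG; Fp[o] = NEG; }
  for (int i = 0; i < nq; i++) {
    const int qi = q0r + i;
    const int base_j = qi - diag0 - band;      // subject index at offset 0
    const int prev_base_j = base_j - 1;        // previous row's offset-0 subject index
    for (int o = 0; o < W; o++) {
      const int sj = base_j + o;
      if (sj < s0r || sj >= s1r) { H[o] = NEG; E[o] = NEG; F[o] = NEG; continue; }
      // E: gap in subject (consume query): from previous row, same sj
      const int po = sj - prev_base_j;  // == o + 1
      int e = NEG; uint8_t te = 0;
      if (po >= 0 && po < W) {
        const int open_e = (Hp[po] > NEG / 2) ? Hp[po] + gap_open + gap_extend : NEG;
        const int ext_e  = (Ep[po] > NEG / 2) ? Ep[po] + gap_extend : NEG;
        if (ext_e > open_e) { e = ext_e; te = 1; } else { e = open_e; te = 0; }
      }
      // F: gap in query (consume subject): from same row, sj-1 (offset o-1)
      int f = NEG; uint8_t tf = 0;
      if (o - 1 >= 0 && base_j + o - 1 >= s0r) {
        const int open_f = (H[o - 1] > NEG / 2) ? H[o - 1] + gap_open + gap_extend : NEG;
        const int ext_f  = (F[o - 1] > NEG / 2) ? F[o - 1] + gap_extend : NEG;
        if (ext_f > open_f) { f = ext_f; tf = 1; } else { f = open_f; tf = 0; }
      }
      // H: diagonal from previous row, sj-1 (previous-row offset po-1 == o)
      int d = NEG;
      const int dpo = (sj - 1) - prev_base_j;  // == o
      const bool diag_ok = (sj - 1 >= s0r) && dpo >= 0 && dpo < W;
      const int sub = (q[qi] < 4 && q[qi] == s[sj]) ? match : mismatch;
      if (diag_ok && Hp[dpo] > NEG / 2) d = Hp[dpo] + sub;
      else if (i == 0 || !diag_ok || Hp[dpo] <= NEG / 2) d = sub;  // fresh start
      int h = 0; uint8_t th = 0;
      if (d > h) { h = d; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      // a fresh diagonal start is th==1 with underlying Hp==NEG or i==0;
      // mark it 1 but remember: traceback stops when H reaches a cell whose
      // predecessor contribution was a fresh start -- handled by checking
      // recomputed predecessor below.
      H[o] = h; E[o] = e; F[o] = f;
      tbH[(size_t)i * W + o] = th; tbE[(size_t)i * W + o] = te; tbF[(size_t)i * W + o] = tf;
      if (h > best) { best = h; bi = i; bo = o; }
    }
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
  }
  if (best <= 0) return false;
  // traceback
  int i = bi, o = bo, state = 0;  // 0=H, 1=E, 2=F
  int nident = 0, nmis = 0, ngapopen = 0, alen = 0;
  int cur_i = bi, cur_sj = (q0r + bi) - diag0 - band + bo;
  const int end_qi = q0r + bi, end_sj = cur_sj;
  int start_qi = end_qi, start_sj = end_sj;
  while (true) {
    const int qi = q0r + i;
    const int sj = qi - diag0 - band + o;
    if (state == 0) {
      uint8_t th = tbH[(size_t)i * W + o];
      if (th == 0) break;  // score 0: alignment starts after this cell
      if (th == 1) {
        alen++;
        const bool id = (qi >= 0 && q[qi] < 4 && q[qi] == s[sj]);
        if (id) nident++; else nmis++;
        start_qi = qi; start_sj = sj;
        // move to predecessor cell (i-1, sj-1); offset stays o
        if (i == 0 || sj - 1 < 0) break;
        const int ppo = (sj - 1) - ((qi - 1) - diag0 - band);
        if (ppo < 0 || ppo >= W) break;
        // fresh-start detection: if predecessor H was not positive-path we stop
        i--; o = ppo;
        uint8_t pth = tbH[(size_t)i * W + o];
        (void)pth;
        // check predecessor H value sign by recomputation is costly; rely on
        // tbH==0 at zero cells (set when h==0). Continue loop.
        continue;
      } else if (th == 2) { state = 1; continue; }
      else { state = 2; continue; }
    } else if (state == 1) {  // E: gap in subject, consumed q[qi]
      uint8_t te = tbE[(size_t)i * W + o];
      alen++;
      if (te == 0) ngapopen++;
      start_qi = qi; start_sj = sj + 1;  // this column's sj not consumed
      // predecessor: (i-1, same sj) => offset o+1
      i--; o = o + 1;
      state = (te == 0) ? 0 : 1;
      continue;
    } else {  // F: gap in query, consumed s[sj]
      uint8_t tf = tbF[(size_t)i * W + o];
      alen++;
      start_qi = qi + 1; start_sj = sj;
      o = o - 1;
      state = (tf == 0) ? 0 : 2;
      continue;
    }
  }
  res.score = best;
  res.q0 = start_qi; res.q1 = end_qi + 1;
  res.s0 = start_sj; res.s1 = end_sj + 1;
  res.nident = nident; res.alen = alen; res.nmis = nmis; res.ngapopen = ngapopen;
  return true;
}

// ---------------------------------------------------------------------------
// search: seed -> merge co-diagonal -> ungapped X-drop -> banded gapped SW
// ---------------------------------------------------------------------------

struct RawHit {
  int subj, strand;  // strand: +1 / -1 (query strand)
  AlnResult a;
};

static void search_one_strand(const std::vector<uint8_t> &q, int strand,
                              const SeedIndex &idx,
                              int match, int mismatch, int gap_open, int gap_extend,
                              int xdrop, int gapped_trigger, int min_score, int band,
                              std::vector<RawHit> &out) {
  const int m = (int)q.size();
  const int k = idx.k;
  if (m < k) return;
  const uint64_t hmask = (1ULL << (2 * k)) - 1;
  // gather seed matches grouped by (subject, diagonal)
  std::vector<std::tuple<int32_t,int32_t,int32_t>> seeds;  // subj, diag, qpos
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < m; i++) {
    if (q[i] == 4) { run = 0; h = 0; continue; }
    h = ((h << 2) | q[i]) & hmask;
    run++;
    if (run < k) continue;
    auto it = idx.kmap.find(h);
    if (it == idx.kmap.end()) continue;
    const int qpos = i - k + 1;
    for (auto &ps : it->second)
      seeds.push_back({ps.first, qpos - ps.second, qpos});
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end());

  size_t a = 0;
  while (a < seeds.size()) {
    size_t b = a;
    const int subj = std::get<0>(seeds[a]);
    const int diag = std::get<1>(seeds[a]);
    while (b < seeds.size() && std::get<0>(seeds[b]) == subj &&
           std::get<1>(seeds[b]) == diag) b++;
    const std::vector<uint8_t> &s = idx.code[subj];
    const int n = (int)s.size();
    int cover_end = -1;
    for (size_t t = a; t < b; t++) {
      const int qpos = std::get<2>(seeds[t]);
      if (qpos < cover_end) continue;
      const int spos = qpos - diag;
      // ungapped X-drop extension around the exact seed
      int sc = k * match, bestsc = sc;
      int qi = qpos + k, sj = spos + k;
      int best_r = 0, cum = 0;
      while (qi < m && sj < n) {
        cum += (q[qi] < 4 && q[qi] == s[sj]) ? match : mismatch;
        if (cum > best_r) best_r = cum;
        if (cum < best_r - xdrop) break;
        qi++; sj++;
      }
      int best_l = 0; cum = 0;
      qi = qpos - 1; sj = spos - 1;
      while (qi >= 0 && sj >= 0) {
        cum += (q[qi] < 4 && q[qi] == s[sj]) ? match : mismatch;
        if (cum > best_l) best_l = cum;
        if (cum < best_l - xdrop) break;
        qi--; sj--;
      }
      const int hsp_score = k * match + best_r + best_l;
      // locate HSP bounds (positions achieving best_r / best_l)
      int r_ext = 0, l_ext = 0;
      if (best_r > 0) { // re-walk to find extent
        int c = 0, br = 0, pos = 0;
        qi = qpos + k; sj = spos + k;
        while (qi < m && sj < n) {
          c += (q[qi] < 4 && q[qi] == s[sj]) ? match : mismatch;
          pos++;
          if (c > br) { br = c; r_ext = pos; }
          if (c < br - xdrop) break;
          qi++; sj++;
        }
      }
      if (best_l > 0) {
        int c = 0, bl = 0, pos = 0;
        qi = qpos - 1; sj = spos - 1;
        while (qi >= 0 && sj >= 0) {
          c += (q[qi] < 4 && q[qi] == s[sj]) ? match : mismatch;
          pos++;
          if (c > bl) { bl = c; l_ext = pos; }
          if (c < bl - xdrop) break;
          qi--; sj--;
        }
      }
      const int hq0 = qpos - l_ext, hq1 = qpos + k + r_ext;
      cover_end = hq1;
      if (hsp_score < gapped_trigger) continue;
      // banded gapped extension around the HSP
      const int pad = band;
      const int q0r = std::max(0, hq0 - pad), q1r = std::min(m, hq1 + pad);
      const int s0r = std::max(0, (hq0 - diag) - pad), s1r = std::min(n, (hq1 - diag) + pad);
      AlnResult res;
      if (!banded_sw(q, q0r, q1r, s, s0r, s1r, diag, band,
                     match, mismatch, gap_open, gap_extend, res)) continue;
      if (res.score < min_score) continue;
      RawHit rh; rh.subj = subj; rh.strand = strand; rh.a = res;
      out.push_back(rh);
    }
    a = b;
  }
}

// [[Rcpp::export]]
DataFrame cpp_search(std::string query, SEXP ptr_,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int xdrop, int gapped_trigger, int min_score, int band) {
  XPtr<SeedIndex> idx(ptr_);
  const int m = (int)query.size();
  std::vector<uint8_t> qf(m), qr(m);
  for (int i = 0; i < m; i++) qf[i] = (uint8_t)base_code(query[i]);
  for (int i = 0; i < m; i++) {
    uint8_t c = qf[m - 1 - i];
    qr[i] = (c == 4) ? 4 : (uint8_t)(3 - c);
  }
  std::vector<RawHit> hits;
  search_one_strand(qf, +1, *idx, match, mismatch, gap_open, gap_extend,
                    xdrop, gapped_trigger, min_score, band, hits);
  search_one_strand(qr, -1, *idx, match, mismatch, gap_open, gap_extend,
                    xdrop, gapped_trigger, min_score, band, hits);
  // map minus-strand query coordinates back to the forward query
  for (auto &h : hits) {
    if (h.strand < 0) {
      const int nq0 = m - h.a.q1, nq1 = m - h.a.q0;
      h.a.q0 = nq0; h.a.q1 = nq1;
    }
  }
  // non-redundant: per subject+strand keep best-scoring among query-overlapping
  std::sort(hits.begin(), hits.end(), [](const RawHit &x, const RawHit &y) {
    if (x.a.score != y.a.score) return x.a.score > y.a.score;
    if (x.subj != y.subj) return x.subj < y.subj;
    if (x.a.q0 != y.a.q0) return x.a.q0 < y.a.q0;
    if (x.strand != y.strand) return x.strand > y.strand;
    return x.a.s0 < y.a.s0;
  });
  std::vector<RawHit> kept;
  for (auto &h : hits) {
    bool clash = false;
    for (auto &kh : kept) {
      if (kh.subj == h.subj && kh.strand == h.strand &&
          h.a.q0 < kh.a.q1 && kh.a.q0 < h.a.q1 &&
          h.a.s0 < kh.a.s1 && kh.a.s0 < h.a.s1) { clash = true; break; }
    }
    if (!clash) kept.push_back(h);
  }
  const int nh = (int)kept.size();
  IntegerVector subj(nh), strand(nh), q0(nh), q1(nh), s0(nh), s1(nh),
    score(nh), nident(nh), alen(nh), nmis(nh), ngap(nh);
  for (int i = 0; i < nh; i++) {
    subj[i] = kept[i].subj + 1;
    strand[i] = kept[i].strand;
    q0[i] = kept[i].a.q0; q1[i] = kept[i].a.q1;
    s0[i] = kept[i].a.s0; s1[i] = kept[i].a.s1;
    score[i] = kept[i].a.score;
    nident[i] = kept[i].a.nident; alen[i] = kept[i].a.alen;
    nmis[i] = kept[i].a.nmis; ngap[i] = kept[i].a.ngapopen;
  }
  return DataFrame::create(
    _["subject_i"] = subj, _["strand"] = strand,
    _["qstart"] = q0, _["qend"] = q1, _["sstart"] = s0, _["send"] = s1,
    _["score"] = score, _["nident"] = nident, _["length"] = alen,
    _["mismatch"] = nmis, _["gapopen"] = ngap);
}
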