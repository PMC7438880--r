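// Alignment engine: seed-and-extend scanning, affine-gap pairwise DP,
// ungapped diagonal anchors, and profile-profile alignment for the
// progressive MSA.  Gap convention matches the usual affine scheme where a
// gap of length L costs gap_open + L * gap_ext (the first gapped position
// pays both).  All returned coordinates are 1-based inclusive.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else
  }
}

// ---------------------------------------------------------------------------
// Affine-gap local alignment (Smith-Waterman) of a vs b with full traceback.
// N (code -1) scores as a mismatch against everything, including another N.
struct AlnResult {
  double score;
  int a_start, a_end, b_start, b_end; // 1-based inclusive; 0s if empty
  int matches, aln_len;
  std::string a_aln, b_aln;
};

static AlnResult affine_align(const std::string& a, const std::string& b,
                              double match, double mismatch,
                              double gap_open, double gap_ext,
                              bool local, bool want_strings) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1), Hcur(n + 1), Eprev(n + 1), Ecur(n + 1),
      Fcur(n + 1), Fprev(n + 1);
  // traceback: 2 bits H-source (0 stop/boundary,1 diag,2 fromE(gap in a),3 fromF(gap in b))
  // bit 2: E opened from H; bit 3: F opened from H
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  double go = gap_open + gap_ext;

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;

  std::fill(Ecur.begin(), Ecur.end(), NEG);
  std::fill(Fprev.begin(), Fprev.end(), NEG);
  // row 0
  for (int j = 0; j <= n; ++j) {
    Eprev[j] = NEG;
    Hprev[j] = local ? 0.0 : (j == 0 ? 0.0 : -(gap_open + gap_ext * j));
    if (!local && j > 0) tb[(size_t)j] = 2; // gap in a along row 0
  }
  for (int i = 1; i <= m; ++i) {
    Fcur[0] = NEG;
    Hcur[0] = local ? 0.0 : -(gap_open + gap_ext * i);
    if (!local) tb[(size_t)i * (n + 1)] = 3;
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (consume b[j])
      double e_open = Hcur[j - 1] - go, e_ext = Ecur[j - 1] - gap_ext;
      // note Ecur[j-1]/Hcur[j-1] are current row, column j-1
      double E = std::max(e_open, e_ext);
      // F: gap in b (consume a[i])
      double f_open = Hprev[j] - go, f_ext = Fprev[j] - gap_ext;
      double F = std::max(f_open, f_ext);
      int ca = base_code(a[(size_t)i - 1]), cb = base_code(b[(size_t)j - 1]);
      double s = (ca >= 0 && ca == cb) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double H = diag;
      uint8_t dir = 1;
      if (E > H) { H = E; dir = 2; }
      if (F > H) { H = F; dir = 3; }
      if (local && H < 0) { H = 0; dir = 0; }
      uint8_t cell = dir;
      if (e_open >= e_ext) cell |= 4;
      if (f_open >= f_ext) cell |= 8;
      tb[(size_t)i * (n + 1) + j] = cell;
      Hcur[j] = H; Ecur[j] = E; Fcur[j] = F;
      if (local) {
        if (H > best) { best = H; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
  }
  if (!local) { best = Hprev[n]; bi = m; bj = n; }

  AlnResult res;
  res.score = best;
  res.matches = 0; res.aln_len = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  if (local && best <= 0) return res;

  // traceback
  int i = bi, j = bj;
  res.a_end = i; res.b_end = j;
  std::string aa, bb;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 || j > 0) {
    uint8_t cell = tb[(size_t)i * (n + 1) + j];
    uint8_t dir = cell & 3;
    if (state == 0) {
      if (local && dir == 0) break;
      if (!local && i == 0) dir = 2;
      if (!local && j == 0 && i > 0) dir = 3;
      if (dir == 1) {
        int ca = base_code(a[(size_t)i - 1]), cb = base_code(b[(size_t)j - 1]);
        if (ca >= 0 && ca == cb) res.matches++;
        res.aln_len++;
        if (want_strings) { aa.push_back(a[(size_t)i - 1]); bb.push_back(b[(size_t)j - 1]); }
        --i; --j;
      } else if (dir == 2) {
        state = 2;
      } else if (dir == 3) {
        state = 3;
      } else break;
    } else if (state == 2) { // gap in a, consume b[j]
      res.aln_len++;
      if (want_strings) { aa.push_back('-'); bb.push_back(b[(size_t)j - 1]); }
      bool opened = (cell & 4) != 0;
      --j;
      if (opened) state = 0;
    } else { // state == 3: gap in b, consume a[i]
      res.aln_len++;
      if (want_strings) { aa.push_back(a[(size_t)i - 1]); bb.push_back('-'); }
      bool opened = (cell & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }
  res.a_start = i + 1; res.b_start = j + 1;
  if (want_strings) {
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    res.a_aln = aa; res.b_aln = bb;
  }
  return res;
}

// [[Rcpp::export(rng = false)]]
List cpp_pair_local(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_ext, bool strings = false) {
  AlnResult r = affine_align(a, b, match, mismatch, gap_open, gap_ext, true, strings);
  return List::create(_["score"] = r.score, _["a_start"] = r.a_start,
                      _["a_end"] = r.a_end, _["b_start"] = r.b_start,
                      _["b_end"] = r.b_end, _["matches"] = r.matches,
                      _["aln_len"] = r.aln_len, _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln);
}

// [[Rcpp::export(rng = false)]]
List cpp_pair_global(std::string a, std::string b, double match, double mismatch,
                     double gap_open, double gap_ext, bool strings = true) {
  AlnResult r = affine_align(a, b, match, mismatch, gap_open, gap_ext, false, strings);
  return List::create(_["score"] = r.score, _["matches"] = r.matches,
                      _["aln_len"] = r.aln_len, _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln);
}

// ---------------------------------------------------------------------------
// Rolling 2-bit k-mer scan of a subject against an index of query k-mers.
// Seeds are clustered by diagonal, clusters define candidate windows, and
// each window is resolved by full local alignment of the query against it.

// [[Rcpp::export(rng = false)]]
DataFrame cpp_scan(CharacterVector queries, std::string subject, int k,
                   double match, double mismatch, double gap_open,
                   double gap_ext, double min_score, int band = 32,
                   int min_seeds = 2) {
  const int nq = queries.size();
  std::vector<std::string> qs(nq);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);

  // query k-mer index: kmer -> list of (query idx, qpos 0-based)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int qi = 0; qi < nq; ++qi) {
    const std::string& q = qs[qi];
    if ((int)q.size() < k) continue;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)q.size(); ++p) {
      int c = base_code(q[(size_t)p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[key].push_back(std::make_pair(qi, p - k + 1));
    }
  }

  // collect seeds per query as (diag, spos)
  std::vector<std::vector<std::pair<long,long> > > seeds(nq);
  {
    uint64_t key = 0; int run = 0;
    const int n = (int)subject.size();
    for (int p = 0; p < n; ++p) {
      int c = base_code(subject[(size_t)p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::iterator it = idx.find(key);
        if (it != idx.end()) {
          int spos = p - k + 1;
          for (size_t t = 0; t < it->second.size(); ++t) {
            int qi = it->second[t].first, qp = it->second[t].second;
            seeds[qi].push_back(std::make_pair((long)spos - qp, (long)spos));
          }
        }
      }
    }
  }

  std::vector<int> out_q, out_qs, out_qe, out_ss, out_se, out_match, out_len;
  std::vector<double> out_score;
  const long slen = (long)subject.size();

  for (int qi = 0; qi < nq; ++qi) {
    std::vector<std::pair<long,long> >& sd = seeds[qi];
    if (sd.empty()) continue;
    std::sort(sd.begin(), sd.end());
    const long qlen = (long)qs[qi].size();
    const long pad = std::max(64L, qlen / 8);
    // cluster by diagonal proximity
    std::vector<std::pair<long,long> > windows; // candidate [lo, hi) subject spans
    size_t c0 = 0;
    for (size_t t = 1; t <= sd.size(); ++t) {
      bool brk = (t == sd.size()) || (sd[t].first - sd[t - 1].first > band);
      if (brk) {
        // two-hit style filter: isolated single seeds are overwhelmingly
        // random collisions on desk-scale genomes and are not extended
        if ((long)(t - c0) >= (long)min_seeds) {
          long lo = slen, hi = 0;
          for (size_t u = c0; u < t; ++u) {
            long d = sd[u].first;
            lo = std::min(lo, d);
            hi = std::max(hi, d + qlen);
          }
          windows.push_back(std::make_pair(std::max(0L, lo - pad),
                                           std::min(slen, hi + pad)));
        }
        c0 = t;
      }
    }
    std::sort(windows.begin(), windows.end());
    // merge overlapping windows
    std::vector<std::pair<long,long> > merged;
    for (size_t t = 0; t < windows.size(); ++t) {
      if (!merged.empty() && windows[t].first <= merged.back().second)
        merged.back().second = std::max(merged.back().second, windows[t].second);
      else merged.push_back(windows[t]);
    }
    for (size_t t = 0; t < merged.size(); ++t) {
      long lo = merged[t].first, hi = merged[t].second;
      std::string win = subject.substr((size_t)lo, (size_t)(hi - lo));
      AlnResult r = affine_align(qs[qi], win, match, mismatch, gap_open,
                                 gap_ext, true, false);
      if (r.score >= min_score && r.aln_len > 0) {
        out_q.push_back(qi + 1);
        out_qs.push_back(r.a_start);
        out_qe.push_back(r.a_end);
        out_ss.push_back((int)(lo + r.b_start));
        out_se.push_back((int)(lo + r.b_end));
        out_match.push_back(r.matches);
        out_len.push_back(r.aln_len);
        out_score.push_back(r.score);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["q_start"] = out_qs,
                           _["q_end"] = out_qe, _["s_start"] = out_ss,
                           _["s_end"] = out_se, _["matches"] = out_match,
                           _["aln_len"] = out_len, _["score"] = out_score);
}

// ---------------------------------------------------------------------------
// Ungapped diagonal anchors between two long sequences (dot-plot machinery).
// Exact k-mer hits on one diagonal are merged into runs, runs are extended
// with an x-drop rule, and spans passing length/identity thresholds are kept.

// [[Rcpp::export(rng = false)]]
DataFrame cpp_anchors(std::string q, std::string s, int k, int min_len,
                      double min_id, int max_seed_gap = 300, double xdrop = 30,
                      double ext_match = 1.0, double ext_mismatch = -3.0) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const long qlen = (long)q.size(), slen = (long)s.size();
  {
    uint64_t key = 0; int run = 0;
    for (long p = 0; p < qlen; ++p) {
      int c = base_code(q[(size_t)p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[key].push_back((int)(p - k + 1));
    }
  }
  // hits grouped by diagonal
  std::vector<std::pair<long,long> > hits; // (diag, qpos)
  {
    uint64_t key = 0; int run = 0;
    for (long p = 0; p < slen; ++p) {
      int c = base_code(s[(size_t)p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(key);
        if (it != idx.end()) {
          long spos = p - k + 1;
          for (size_t t = 0; t < it->second.size(); ++t)
            hits.push_back(std::make_pair(spos - it->second[t],
                                          (long)it->second[t]));
        }
      }
    }
  }
  std::sort(hits.begin(), hits.end());

  std::vector<int> aqs, aqe, ass, ase, alen;
  std::vector<double> aid;

  size_t t0 = 0;
  for (size_t t = 1; t <= hits.size(); ++t) {
    bool brk = (t == hits.size()) || hits[t].first != hits[t - 1].first ||
               hits[t].second - hits[t - 1].second > max_seed_gap;
    if (!brk) continue;
    long diag = hits[t0].first;
    long q0 = hits[t0].second, q1 = hits[t - 1].second + k - 1;
    // x-drop extension left
    {
      double cur = 0, bestsc = 0; long bestp = q0;
      long p = q0 - 1;
      while (p >= 0 && p + diag >= 0) {
        int ca = base_code(q[(size_t)p]), cb = base_code(s[(size_t)(p + diag)]);
        cur += (ca >= 0 && ca == cb) ? ext_match : ext_mismatch;
        if (cur > bestsc) { bestsc = cur; bestp = p; }
        if (bestsc - cur > xdrop) break;
        --p;
      }
      q0 = bestp;
    }
    // x-drop extension right
    {
      double cur = 0, bestsc = 0; long bestp = q1;
      long p = q1 + 1;
      while (p < qlen && p + diag < slen) {
        int ca = base_code(q[(size_t)p]), cb = base_code(s[(size_t)(p + diag)]);
        cur += (ca >= 0 && ca == cb) ? ext_match : ext_mismatch;
        if (cur > bestsc) { bestsc = cur; bestp = p; }
        if (bestsc - cur > xdrop) break;
        ++p;
      }
      q1 = bestp;
    }
    long len = q1 - q0 + 1;
    if (len >= min_len) {
      long matches = 0;
      for (long p = q0; p <= q1; ++p) {
        int ca = base_code(q[(size_t)p]), cb = base_code(s[(size_t)(p + diag)]);
        if (ca >= 0 && ca == cb) ++matches;
      }
      double ident = (double)matches / (double)len;
      if (ident >= min_id) {
        aqs.push_back((int)(q0 + 1)); aqe.push_back((int)(q1 + 1));
        ass.push_back((int)(q0 + diag + 1)); ase.push_back((int)(q1 + diag + 1));
        alen.push_back((int)len); aid.push_back(ident);
      }
    }
    t0 = t;
  }
  return DataFrame::create(_["q_start"] = aqs, _["q_end"] = aqe,
                           _["s_start"] = ass, _["s_end"] = ase,
                           _["length"] = alen, _["identity"] = aid);
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment for the progressive MSA.  Columns are
// scored by expected pairwise substitution score under per-column ACGT
// frequencies (gaps and Ns contribute nothing); gap penalties are scaled by
// the non-gap fraction of the column being skipped, so that aligning two
// single sequences reduces exactly to standard affine-gap global alignment.
// Returns the merge operations as a string over {M, A, B}: M consumes a
// column from both profiles, A only from the first, B only from the second.

// [[Rcpp::export(rng = false)]]
std::string cpp_profile_align(CharacterVector rows_a, CharacterVector rows_b,
                              double match, double mismatch, double gap_open,
                              double gap_ext) {
  int na = rows_a.size(), nb = rows_b.size();
  std::vector<std::string> A(na), B(nb);
  for (int i = 0; i < na; ++i) A[i] = as<std::string>(rows_a[i]);
  for (int i = 0; i < nb; ++i) B[i] = as<std::string>(rows_b[i]);
  int La = na ? (int)A[0].size() : 0, Lb = nb ? (int)B[0].size() : 0;

  // per-column ACGT frequencies (normalised by number of rows) and weights
  std::vector<double> fa(4 * (size_t)La, 0.0), fb(4 * (size_t)Lb, 0.0);
  std::vector<double> wa(La, 0.0), wb(Lb, 0.0);
  for (int j = 0; j < La; ++j) {
    for (int i = 0; i < na; ++i) {
      int c = base_code(A[(size_t)i][(size_t)j]);
      if (c >= 0) { fa[4 * (size_t)j + c] += 1.0; wa[j] += 1.0; }
    }
    for (int c = 0; c < 4; ++c) fa[4 * (size_t)j + c] /= na;
    wa[j] /= na;
  }
  for (int j = 0; j < Lb; ++j) {
    for (int i = 0; i < nb; ++i) {
      int c = base_code(B[(size_t)i][(size_t)j]);
      if (c >= 0) { fb[4 * (size_t)j + c] += 1.0; wb[j] += 1.0; }
    }
    for (int c = 0; c < 4; ++c) fb[4 * (size_t)j + c] /= nb;
    wb[j] /= nb;
  }

  const double NEG = -1e18;
  const double go = gap_open + gap_ext;
  size_t W = (size_t)Lb + 1;
  std::vector<double> M((size_t)(La + 1) * W, NEG), Ia((size_t)(La + 1) * W, NEG),
      Ib((size_t)(La + 1) * W, NEG);
  std::vector<uint8_t> tbM((size_t)(La + 1) * W, 0), tbA((size_t)(La + 1) * W, 0),
      tbB((size_t)(La + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    double cost = (i == 1 ? go : gap_ext) * wa[i - 1];
    Ia[(size_t)i * W] = (i == 1 ? M[0] : Ia[(size_t)(i - 1) * W]) - cost;
    tbA[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= Lb; ++j) {
    double cost = (j == 1 ? go : gap_ext) * wb[j - 1];
    Ib[(size_t)j] = (j == 1 ? M[0] : Ib[(size_t)(j - 1)]) - cost;
    tbB[(size_t)j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      size_t c = (size_t)i * W + j, cd = (size_t)(i - 1) * W + (j - 1),
             cu = (size_t)(i - 1) * W + j, cl = (size_t)i * W + (j - 1);
      double sc = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          sc += fa[4 * (size_t)(i - 1) + x] * fb[4 * (size_t)(j - 1) + y] *
                (x == y ? match : mismatch);
      // M
      double m0 = M[cd], m1 = Ia[cd], m2 = Ib[cd];
      double mbest = m0; uint8_t msrc = 0;
      if (m1 > mbest) { mbest = m1; msrc = 1; }
      if (m2 > mbest) { mbest = m2; msrc = 2; }
      M[c] = mbest + sc; tbM[c] = msrc;
      // Ia: consume A column i (gap in B), cost scaled by wa[i-1]
      double aopen = std::max(M[cu], Ib[cu]) - go * wa[i - 1];
      double aext = Ia[cu] - gap_ext * wa[i - 1];
      bool afromM = M[cu] >= Ib[cu];
      if (aopen >= aext) { Ia[c] = aopen; tbA[c] = afromM ? 0 : 2; }
      else { Ia[c] = aext; tbA[c] = 1; }
      // Ib: consume B column j (gap in A)
      double bopen = std::max(M[cl], Ia[cl]) - go * wb[j - 1];
      double bext = Ib[cl] - gap_ext * wb[j - 1];
      bool bfromM = M[cl] >= Ia[cl];
      if (bopen >= bext) { Ib[c] = bopen; tbB[c] = bfromM ? 0 : 2; }
      else { Ib[c] = bext; tbB[c] = 1; }
    }
  }
  // traceback from best terminal state
  int i = La, j = Lb;
  size_t c = (size_t)i * W + j;
  int state = 0;
  double bestv = M[c];
  if (Ia[c] > bestv) { bestv = Ia[c]; state = 1; }
  if (Ib[c] > bestv) { bestv = Ib[c]; state = 2; }
  std::string ops;
  while (i > 0 || j > 0) {
    c = (size_t)i * W + j;
    if (i == 0) { ops.push_back('B'); --j; state = 2; continue; }
    if (j == 0) { ops.push_back('A'); --i; state = 1; continue; }
    if (state == 0) {
      ops.push_back('M');
      state = tbM[c] == 0 ? 0 : (tbM[c] == 1 ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      ops.push_back('A');
      uint8_t src = tbA[c];
      --i;
      state = (src == 1) ? 1 : (src == 0 ? 0 : 2);
    } else {
      ops.push_back('B');
      uint8_t src = tbB[c];
      --j;
      state = (src == 1) ? 2 : (src == 0 ? 0 : 1);
    }
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}
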