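// Seeded local alignment engine used by every similarity-search stage:
// repeat-coverage self-search (word 15), co-annotation CDS mapping (word 20),
// CDS anchor scoring (word 20) and gene-space CNS alignment (word 7).
//
// Alignments are seeded by exact w-mers, extended ungapped with an X-drop,
// and extended with affine gaps (Gotoh) when the ungapped score reaches the
// gap trigger. A gap of length L costs gap_open + L * gap_extend. 'N' is a
// hard mask: no alignment column may consume an N on either sequence, so no
// reported hit interval ever overlaps masked sequence.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <tuple>
#include <cstdint>

using namespace Rcpp;

static const double NEG = -1e15;

// ---- encoding -------------------------------------------------------------

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4;
    }
  }
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t a = v[v.size() - 1 - i];
    r[i] = (a < 4) ? (uint8_t)(3 - a) : (uint8_t)4;
  }
  return r;
}

// ---- gapped X-drop extension (anchored start, free end) --------------------
//
// q and s address the extension region outward from the seed edge; step = +1
// extends rightward, -1 leftward (pointers at the first character consumed).
// Affine Gotoh DP with X-drop pruning of cells scoring more than xdrop below
// the running best. Returns the best extension score (>= 0; the empty
// extension is allowed) and writes the consumed query/subject character
// counts to *bi / *bj. Ties resolved toward the shorter extension.

struct ExtParams {
  double match, mismatch, gap_open, gap_ext, xdrop;
};

// reusable DP buffers (allocated once per search, grown on demand)
struct ExtBuf {
  std::vector<double> H, Hn, Fv;
  void ensure(int width) {
    if ((int)H.size() < width) {
      H.assign(width, NEG); Hn.assign(width, NEG); Fv.assign(width, NEG);
    }
  }
};

static double xdrop_extend(const uint8_t* q, int qn, int qstep,
                           const uint8_t* s, int sn, int sstep,
                           const ExtParams& p, ExtBuf& buf, int* bi, int* bj) {
  *bi = 0; *bj = 0;
  if (qn <= 0 || sn <= 0) return 0.0;
  double best = 0.0;

  buf.ensure(sn + 8);
  std::vector<double>& H = buf.H;
  std::vector<double>& Hn = buf.Hn;
  std::vector<double>& Fv = buf.Fv;

  // row 0: leading gap consuming subject characters only
  H[0] = 0.0;
  int lo = 0, hi = 0;
  for (int j = 1; j <= sn; ++j) {
    if (s[(j - 1) * sstep] == 4) break;
    double v = -(p.gap_open + j * p.gap_ext);
    if (v < best - p.xdrop) break;
    H[j] = v; hi = j;
  }
  // clear the margins the first rows may read (buffers are reused)
  for (int j = hi + 1; j <= std::min(sn, hi + 4); ++j) H[j] = NEG;
  for (int j = 0; j <= std::min(sn, hi + 4); ++j) Fv[j] = NEG;

  for (int i = 1; i <= qn; ++i) {
    uint8_t qc = q[(i - 1) * qstep];
    if (qc == 4) break; // every cell of this row would consume the N

    int jstart = lo, nlo = -1, nhi = -1, lastj = -1;
    double Eprev = NEG;

    if (jstart == 0) {
      // column 0: leading gap consuming query characters only
      double v = -(p.gap_open + i * p.gap_ext); // q[0..i-1] are N-free (row break above)
      if (v >= best - p.xdrop) {
        Hn[0] = v; Fv[0] = v; nlo = 0; nhi = 0;
      } else {
        Hn[0] = NEG; Fv[0] = NEG;
      }
      lastj = 0;
      jstart = 1;
    } else {
      Hn[jstart - 1] = NEG; // same-row E reads Hn[j-1] at the first column
    }

    for (int j = jstart; j <= sn; ++j) {
      uint8_t sc = s[(j - 1) * sstep];
      double sub = (sc == 4) ? NEG : ((qc == sc) ? p.match : p.mismatch);
      double M = (H[j - 1] > NEG / 2 && sub > NEG / 2) ? H[j - 1] + sub : NEG;
      double Ev = NEG;
      if (sc != 4) {
        double a = (Hn[j - 1] > NEG / 2) ? Hn[j - 1] - (p.gap_open + p.gap_ext) : NEG;
        double b = (Eprev > NEG / 2) ? Eprev - p.gap_ext : NEG;
        Ev = std::max(a, b);
      }
      double Fvv;
      {
        double a = (H[j] > NEG / 2) ? H[j] - (p.gap_open + p.gap_ext) : NEG;
        double b = (Fv[j] > NEG / 2) ? Fv[j] - p.gap_ext : NEG;
        Fvv = std::max(a, b);
      }
      double Hv = std::max(M, std::max(Ev, Fvv));
      lastj = j;
      if (Hv < best - p.xdrop) {
        Hn[j] = NEG; Fv[j] = NEG; Eprev = NEG;
        if (j > hi + 1) break; // nothing right of here can be reached
        continue;
      }
      Hn[j] = Hv; Fv[j] = Fvv; Eprev = Ev;
      if (nlo < 0) nlo = j;
      nhi = j;
      if (Hv > best) { best = Hv; *bi = i; *bj = j; }
    }
    if (nlo < 0) break; // row entirely dead
    // clear cells the next row may read but this row never wrote
    for (int j = lastj + 1; j <= std::min(sn, nhi + 3); ++j) {
      Hn[j] = NEG; Fv[j] = NEG;
    }
    lo = nlo; hi = nhi;
    std::swap(H, Hn);
  }
  return best;
}

// ---- hit container ---------------------------------------------------------

struct Hit {
  int qidx, sidx, strand;  // strand +1 / -1
  int qs, qe, ss, se;      // 0-based half-open; subject in forward coordinates
  double raw;
};

// ---- main seeded search -----------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_map_hits(CharacterVector query_seqs, CharacterVector subject_seqs,
                       int word, double match, double mismatch,
                       double gap_open, double gap_ext,
                       double min_raw, double trigger_raw,
                       double xdrop_ungapped, double xdrop_gapped,
                       bool both_strands, bool self_mode,
                       Nullable<List> query_seed_mask = R_NilValue) {
  int nq = query_seqs.size(), ns = subject_seqs.size();
  std::vector<std::vector<uint8_t>> Q(nq), S(ns), SR(ns);
  for (int i = 0; i < nq; ++i) Q[i] = encode_seq(as<std::string>(query_seqs[i]));
  for (int j = 0; j < ns; ++j) {
    S[j] = encode_seq(as<std::string>(subject_seqs[j]));
    if (both_strands) SR[j] = revcomp_codes(S[j]);
  }

  std::vector<std::vector<int>> qmask(nq); // per-position seed exclusion
  if (query_seed_mask.isNotNull()) {
    List qm(query_seed_mask);
    for (int i = 0; i < nq && i < qm.size(); ++i) {
      if (Rf_isNull(qm[i])) continue;
      LogicalVector lv = qm[i];
      qmask[i].assign(lv.begin(), lv.end());
    }
  }

  // word index over subjects (both orientations)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  uint64_t wmask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1ULL);
  for (int j = 0; j < ns; ++j) {
    for (int ori = 0; ori < (both_strands ? 2 : 1); ++ori) {
      const std::vector<uint8_t>& seq = ori ? SR[j] : S[j];
      int n = (int)seq.size();
      uint64_t code = 0; int run = 0;
      for (int p = 0; p < n; ++p) {
        if (seq[p] > 3) { run = 0; code = 0; continue; }
        code = ((code << 2) | seq[p]) & wmask;
        if (++run >= word) index[code].push_back({j * 2 + ori, p - word + 1});
      }
    }
  }

  ExtParams gp{match, mismatch, gap_open, gap_ext, xdrop_gapped};
  ExtBuf buf;

  std::vector<Hit> hits;
  std::unordered_map<uint64_t, int> diag_end; // seed skipping per diagonal
  std::set<std::tuple<int,int,int,int,int,int,int>> seen;

  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<uint8_t>& q = Q[qi];
    int qn = (int)q.size();
    if (qn < word) continue;
    uint64_t code = 0; int run = 0;
    for (int p = 0; p < qn; ++p) {
      if (q[p] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | q[p]) & wmask;
      if (++run < word) continue;
      int qpos = p - word + 1;
      if (!qmask[qi].empty()) {
        bool masked = false;
        for (int k = qpos; k <= p; ++k) if (qmask[qi][k]) { masked = true; break; }
        if (masked) continue;
      }
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (auto& pr : it->second) {
        int sj = pr.first / 2, ori = pr.first % 2;
        int spos = pr.second;
        const std::vector<uint8_t>& s = ori ? SR[sj] : S[sj];
        int sn = (int)s.size();

        if (self_mode) {
          // compare each unordered pair of loci once; drop identity diagonal
          if (sj < qi) continue;
          if (ori == 0) {
            if (sj == qi && spos <= qpos) continue;
          } else {
            int fwd_start = sn - spos - word;
            if (sj == qi && fwd_start < qpos) continue;
          }
        }

        uint64_t dkey = ((uint64_t)qi << 44) ^ ((uint64_t)pr.first << 25)
                        ^ (uint64_t)(qpos - spos + (1 << 24));
        auto de = diag_end.find(dkey);
        if (de != diag_end.end() && qpos < de->second) continue;

        // ungapped X-drop extension
        double best_r = 0, best_l = 0;
        int len_r = 0, len_l = 0, explored = qpos + word;
        {
          double cur = 0, bst = 0; int bl = 0;
          for (int k = 0; ; ++k) {
            int a = qpos + word + k, b = spos + word + k;
            if (a >= qn || b >= sn || q[a] > 3 || s[b] > 3) break;
            cur += (q[a] == s[b]) ? match : mismatch;
            if (cur > bst) { bst = cur; bl = k + 1; }
            explored = a + 1;
            if (cur < bst - xdrop_ungapped) break;
          }
          best_r = bst; len_r = bl;
          cur = 0; bst = 0; bl = 0;
          for (int k = 1; ; ++k) {
            int a = qpos - k, b = spos - k;
            if (a < 0 || b < 0 || q[a] > 3 || s[b] > 3) break;
            cur += (q[a] == s[b]) ? match : mismatch;
            if (cur > bst) { bst = cur; bl = k; }
            if (cur < bst - xdrop_ungapped) break;
          }
          best_l = bst; len_l = bl;
        }
        double sc = word * match + best_r + best_l;
        diag_end[dkey] = explored;

        int qs, qe, ss, se; double raw;
        if (sc >= trigger_raw) {
          int bi, bj, li, lj;
          double R = xdrop_extend(q.data() + qpos + word, qn - qpos - word, 1,
                                  s.data() + spos + word, sn - spos - word, 1,
                                  gp, buf, &bi, &bj);
          double L = xdrop_extend(q.data() + qpos - 1, qpos, -1,
                                  s.data() + spos - 1, spos, -1,
                                  gp, buf, &li, &lj);
          raw = word * match + R + L;
          qs = qpos - li; qe = qpos + word + bi;
          ss = spos - lj; se = spos + word + bj;
        } else {
          raw = sc;
          qs = qpos - len_l; qe = qpos + word + len_r;
          ss = spos - len_l; se = spos + word + len_r;
        }
        if (raw < min_raw) continue;

        int fss = ss, fse = se;
        if (ori) { fss = sn - se; fse = sn - ss; }
        auto key = std::make_tuple(qi, sj, ori, qs, qe, fss, fse);
        if (!seen.insert(key).second) continue;
        hits.push_back({qi + 1, sj + 1, ori ? -1 : 1, qs, qe, fss, fse, raw});
      }
    }
  }

  int n = (int)hits.size();
  IntegerVector oq(n), os(n), ostr(n), oqs(n), oqe(n), oss(n), ose(n);
  NumericVector oraw(n);
  for (int i = 0; i < n; ++i) {
    oq[i] = hits[i].qidx; os[i] = hits[i].sidx; ostr[i] = hits[i].strand;
    oqs[i] = hits[i].qs; oqe[i] = hits[i].qe;
    oss[i] = hits[i].ss; ose[i] = hits[i].se; oraw[i] = hits[i].raw;
  }
  return DataFrame::create(_["query"] = oq, _["subject"] = os,
                           _["strand"] = ostr,
                           _["qstart"] = oqs, _["qend"] = oqe,
                           _["sstart"] = oss, _["send"] = ose,
                           _["raw"] = oraw);
}

// ---- exhaustive Smith-Waterman oracle ---------------------------------------
//
// Full-matrix Gotoh local alignment restricted to alignments that contain an
// exact word-length match. For every exact w-mer match at (i, j) the best
// score through that seed is w * match + (best local alignment ending at
// (i, j)) + (best local alignment starting at (i + w, j + w)). No heuristics;
// used as an independent reference in tests. Forward strand only.

static void sw_end_matrix(const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                          double match, double mismatch, double open, double ext,
                          std::vector<double>& Hout) {
  int qn = (int)q.size(), sn = (int)s.size();
  Hout.assign((size_t)(qn + 1) * (sn + 1), 0.0);
  std::vector<double> E((size_t)(qn + 1) * (sn + 1), NEG);
  std::vector<double> F((size_t)(qn + 1) * (sn + 1), NEG);
  auto at = [sn](int i, int j) { return (size_t)i * (sn + 1) + j; };
  for (int i = 1; i <= qn; ++i) {
    for (int j = 1; j <= sn; ++j) {
      double sub = (q[i-1] > 3 || s[j-1] > 3) ? NEG
                   : ((q[i-1] == s[j-1]) ? match : mismatch);
      double M = (sub > NEG/2) ? Hout[at(i-1,j-1)] + sub : NEG;
      double Ev = NEG, Fvv = NEG;
      if (s[j-1] <= 3) {
        double a = Hout[at(i,j-1)] - (open + ext);
        double b = (E[at(i,j-1)] > NEG/2) ? E[at(i,j-1)] - ext : NEG;
        Ev = std::max(a, b);
      }
      if (q[i-1] <= 3) {
        double a = Hout[at(i-1,j)] - (open + ext);
        double b = (F[at(i-1,j)] > NEG/2) ? F[at(i-1,j)] - ext : NEG;
        Fvv = std::max(a, b);
      }
      E[at(i,j)] = Ev; F[at(i,j)] = Fvv;
      Hout[at(i,j)] = std::max(0.0, std::max(M, std::max(Ev, Fvv)));
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_sw_seeded_oracle(std::string query, std::string subject, int word,
                               double match, double mismatch,
                               double gap_open, double gap_ext) {
  std::vector<uint8_t> q = encode_seq(query), s = encode_seq(subject);
  int qn = (int)q.size(), sn = (int)s.size();
  std::vector<double> Hend, Hrev;
  sw_end_matrix(q, s, match, mismatch, gap_open, gap_ext, Hend);
  std::vector<uint8_t> qr(q.rbegin(), q.rend()), sr(s.rbegin(), s.rend());
  sw_end_matrix(qr, sr, match, mismatch, gap_open, gap_ext, Hrev);
  auto at = [sn](int i, int j) { return (size_t)i * (sn + 1) + j; };

  std::vector<int> oq, os; std::vector<double> ob;
  for (int i = 0; i + word <= qn; ++i) {
    for (int j = 0; j + word <= sn; ++j) {
      bool ok = true;
      for (int k = 0; k < word; ++k) {
        if (q[i+k] > 3 || q[i+k] != s[j+k]) { ok = false; break; }
      }
      if (!ok) continue;
      double left = Hend[at(i, j)];
      double right = Hrev[at(qn - i - word, sn - j - word)];
      oq.push_back(i); os.push_back(j);
      ob.push_back(word * match + left + right);
    }
  }
  return DataFrame::create(_["qpos"] = wrap(oq), _["spos"] = wrap(os),
                           _["best"] = wrap(ob));
}

// ---- DUST-style low-complexity mask -----------------------------------------
//
// Sliding 64 bp windows; score = sum over triplet counts of c * (c - 1) / 2.
// A window is masked when 10 * score / (n_triplets - 1) > threshold
// (threshold 20 mirrors the usual DUST default). Triplets containing N are
// not counted.

// [[Rcpp::export]]
LogicalVector cpp_dust_mask(std::string seq, int window = 64, double threshold = 20.0) {
  std::vector<uint8_t> v = encode_seq(seq);
  int n = (int)v.size();
  LogicalVector mask(n, false);
  if (n < 3) return mask;
  int W = std::min(window, n);
  std::vector<int> tri(n - 2, -1);
  for (int i = 0; i + 2 < n; ++i) {
    if (v[i] > 3 || v[i+1] > 3 || v[i+2] > 3) continue;
    tri[i] = v[i] * 16 + v[i+1] * 4 + v[i+2];
  }
  std::vector<int> cnt(64, 0);
  long long score = 0; int ntri = 0;
  auto add = [&](int t) { if (t >= 0) { score += cnt[t]; cnt[t]++; ntri++; } };
  auto rem = [&](int t) { if (t >= 0) { cnt[t]--; score -= cnt[t]; ntri--; } };
  int ntriw = W - 2;
  for (int i = 0; i < ntriw && i < (int)tri.size(); ++i) add(tri[i]);
  for (int start = 0; start + W <= n; ++start) {
    if (start > 0) {
      rem(tri[start - 1]);
      int newi = start + W - 3;
      if (newi < (int)tri.size()) add(tri[newi]);
    }
    if (ntri >= 2 && 10.0 * (double)score / (double)(ntri - 1) > threshold) {
      for (int k = start; k < start + W; ++k) mask[k] = true;
    }
  }
  return mask;
}
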