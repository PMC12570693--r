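#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small utilities
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

struct CigOp { char op; int len; };

static std::vector<CigOp> parse_cigar(const std::string& cig) {
  std::vector<CigOp> ops;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
    } else {
      if (len <= 0) stop("malformed CIGAR: '%s'", cig.c_str());
      ops.push_back({c, len});
      len = 0;
    }
  }
  if (len != 0) stop("malformed CIGAR: '%s'", cig.c_str());
  return ops;
}

static std::string build_cigar(const std::vector<CigOp>& ops) {
  std::string out;
  for (const auto& o : ops) {
    if (o.len > 0) { out += std::to_string(o.len); out += o.op; }
  }
  return out;
}

// merge adjacent equal ops, drop zero-length ops
static std::vector<CigOp> normalize_ops(const std::vector<CigOp>& ops) {
  std::vector<CigOp> out;
  for (const auto& o : ops) {
    if (o.len == 0) continue;
    if (!out.empty() && out.back().op == o.op) out.back().len += o.len;
    else out.push_back(o);
  }
  return out;
}

// ---------------------------------------------------------------------------
// semi-global affine-gap alignment (global in the read, free end gaps in the
// reference).  Gap of length k costs gap_open + k * gap_extend.  Banded when
// the problem is large, guided by exact k-mer seeds; full DP otherwise.
// Traceback tie-break: M over D over I; alignment end at the smallest
// reference column among score ties.
// ---------------------------------------------------------------------------

struct AlnResult {
  double score;
  int ref_start;      // 0-based
  std::string cigar;
  bool ok;
};

static const double NEG = -1e18;

static AlnResult align_core(const std::string& r, const std::string& s,
                            double match, double mismatch,
                            double gap_open, double gap_extend,
                            int d0, int halfwidth, bool banded) {
  const int m = (int)r.size(), n = (int)s.size();
  AlnResult res; res.ok = false; res.score = NEG; res.ref_start = 0;
  if (m == 0) return res;

  // per-row reference column range [jlo[i], jhi[i]]
  std::vector<int> jlo(m + 1), jhi(m + 1), rowoff(m + 1);
  int total = 0;
  for (int i = 0; i <= m; ++i) {
    if (banded) {
      jlo[i] = std::max(0, i + d0 - halfwidth);
      jhi[i] = std::min(n, i + d0 + halfwidth);
      if (jlo[i] > jhi[i]) { jlo[i] = 0; jhi[i] = -1; }
    } else {
      jlo[i] = 0; jhi[i] = n;
    }
    rowoff[i] = total;
    total += std::max(0, jhi[i] - jlo[i] + 1);
  }
  if (total == 0) return res;

  std::vector<double> M(total, NEG), I(total, NEG), D(total, NEG);
  // traceback codes: M: 0=from M,1=from I,2=from D,3=start
  //                  I: 0=open(from M),1=extend,3=start
  //                  D: 0=open(from M),1=extend
  std::vector<uint8_t> tbM(total, 0), tbI(total, 0), tbD(total, 0);

  auto idx = [&](int i, int j) { return rowoff[i] + (j - jlo[i]); };
  auto inband = [&](int i, int j) { return j >= jlo[i] && j <= jhi[i]; };

  const double open1 = gap_open + gap_extend;

  for (int i = 1; i <= m; ++i) {
    const char rb = r[i - 1];
    for (int j = jlo[i]; j <= jhi[i]; ++j) {
      const int c = idx(i, j);
      // M: consume r[i-1] and s[j-1]
      if (j >= 1) {
        double prev = NEG; uint8_t code = 0;
        if (i == 1) { prev = 0.0; code = 3; }
        else if (inband(i - 1, j - 1)) {
          const int p = idx(i - 1, j - 1);
          prev = M[p]; code = 0;
          if (I[p] > prev) { prev = I[p]; code = 1; }
          if (D[p] > prev) { prev = D[p]; code = 2; }
        }
        if (prev > NEG / 2) {
          const char sb = s[j - 1];
          const double sub = (rb == sb && rb != 'N') ? match : mismatch;
          M[c] = prev + sub; tbM[c] = code;
        }
      }
      // I: consume r[i-1] only (gap in reference)
      {
        double best = NEG; uint8_t code = 0;
        if (i == 1) { best = open1; code = 3; }
        else if (inband(i - 1, j)) {
          const int p = idx(i - 1, j);
          const double o = M[p] + open1, e = I[p] + gap_extend;
          if (o >= e) { best = o; code = 0; } else { best = e; code = 1; }
        }
        if (best > NEG / 2) { I[c] = best; tbI[c] = code; }
      }
      // D: consume s[j-1] only (gap in read)
      if (j >= 1 && inband(i, j - 1)) {
        const int p = idx(i, j - 1);
        const double o = M[p] + open1, e = D[p] + gap_extend;
        uint8_t code; double best;
        if (o >= e) { best = o; code = 0; } else { best = e; code = 1; }
        if (best > NEG / 2) { D[c] = best; tbD[c] = code; }
      }
    }
  }

  // end: best state in row m, ties -> M over D over I, then smallest j
  double best = NEG; int bj = -1; char bstate = 'M';
  for (int j = jlo[m]; j <= jhi[m]; ++j) {
    const int c = idx(m, j);
    const double cand[3] = { M[c], D[c], I[c] };
    const char st[3] = { 'M', 'D', 'I' };
    for (int k = 0; k < 3; ++k) {
      if (cand[k] > best) { best = cand[k]; bj = j; bstate = st[k]; }
    }
  }
  if (bj < 0 || best <= NEG / 2) return res;

  // traceback
  std::vector<CigOp> rev;
  int i = m, j = bj; char st = bstate;
  auto push = [&](char op) {
    if (!rev.empty() && rev.back().op == op) rev.back().len++;
    else rev.push_back({op, 1});
  };
  while (i > 0) {
    const int c = idx(i, j);
    if (st == 'M') {
      const uint8_t code = tbM[c];
      push('M');
      if (code == 3) { i = 0; j = j - 1; break; }
      st = (code == 0) ? 'M' : (code == 1) ? 'I' : 'D';
      --i; --j;
    } else if (st == 'I') {
      const uint8_t code = tbI[c];
      push('I');
      if (code == 3) { i = 0; break; }
      st = (code == 0) ? 'M' : 'I';
      --i;
    } else { // D
      const uint8_t code = tbD[c];
      push('D');
      st = (code == 0) ? 'M' : 'D';
      --j;
    }
  }
  res.ref_start = j;        // first reference column consumed (0-based)
  std::reverse(rev.begin(), rev.end());
  res.cigar = build_cigar(normalize_ops(rev));
  res.score = best;
  res.ok = true;
  return res;
}

// exact k-mer seeding: modal diagonal (ref_pos - read_pos) over seed hits
static bool seed_diagonal(const std::string& r,
                          const std::unordered_map<uint64_t, std::vector<int> >& index,
                          int k, int& d0) {
  const int m = (int)r.size();
  if (m < k) return false;
  std::unordered_map<int, int> votes;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  const int stride = 7;
  for (int i = 0; i < m; ++i) {
    int code;
    switch (r[i]) {
      case 'A': code = 0; break; case 'C': code = 1; break;
      case 'G': code = 2; break; case 'T': code = 3; break;
      default: code = -1;
    }
    if (code < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)code) & mask;
    if (++run >= k) {
      const int start = i - k + 1;
      if (start % stride == 0) {
        auto it = index.find(h);
        if (it != index.end()) {
          for (int rp : it->second) votes[rp - start]++;
        }
      }
    }
  }
  if (votes.empty()) return false;
  int bestd = 0, bestc = -1;
  for (const auto& kv : votes) {
    if (kv.second > bestc || (kv.second == bestc && kv.first < bestd)) {
      bestc = kv.second; bestd = kv.first;
    }
  }
  d0 = bestd;
  return true;
}

static std::unordered_map<uint64_t, std::vector<int> >
build_kmer_index(const std::string& s, int k) {
  std::unordered_map<uint64_t, std::vector<int> > index;
  const int n = (int)s.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int code;
    switch (s[i]) {
      case 'A': code = 0; break; case 'C': code = 1; break;
      case 'G': code = 2; break; case 'T': code = 3; break;
      default: code = -1;
    }
    if (code < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)code) & mask;
    if (++run >= k) index[h].push_back(i - k + 1);
  }
  return index;
}

// [[Rcpp::export]]
List cpp_align_many(CharacterVector seqs, std::string ref,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    int band, int seed_k, int max_expansion,
                    int full_dp_cells) {
  const int nread = seqs.size();
  const int n = (int)ref.size();
  auto index = build_kmer_index(ref, seed_k);

  CharacterVector strand(nread), cigar(nread), status(nread);
  IntegerVector ref_start(nread);
  NumericVector score(nread);

  for (int t = 0; t < nread; ++t) {
    const std::string r_plus = as<std::string>(seqs[t]);
    const int m = (int)r_plus.size();
    strand[t] = "+"; cigar[t] = ""; ref_start[t] = NA_INTEGER;
    score[t] = NA_REAL;
    if (m == 0) { status[t] = "unmapped"; continue; }
    if (m > n + max_expansion) { status[t] = "too_long"; continue; }

    const bool small = ((double)(m + 1) * (double)(n + 1) <= (double)full_dp_cells);
    const std::string r_minus = revcomp(r_plus);

    AlnResult best; best.ok = false; best.score = NEG;
    char best_strand = '+';
    bool any_seed = false;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& r = (ori == 0) ? r_plus : r_minus;
      AlnResult a;
      if (small) {
        a = align_core(r, ref, match, mismatch, gap_open, gap_extend,
                       0, 0, false);
        any_seed = true;
      } else {
        int d0 = 0;
        if (!seed_diagonal(r, index, seed_k, d0)) continue;
        any_seed = true;
        a = align_core(r, ref, match, mismatch, gap_open, gap_extend,
                       d0, band, true);
      }
      if (a.ok && (a.score > best.score ||
                   (a.score == best.score && ori == 0 && best_strand == '-'))) {
        // ties broken toward '+' (plus evaluated first, strict > keeps it)
        best = a; best_strand = (ori == 0) ? '+' : '-';
      }
    }
    if (!best.ok) {
      status[t] = any_seed ? "unmapped" : "no_seed";
      continue;
    }
    strand[t] = std::string(1, best_strand);
    ref_start[t] = best.ref_start;
    cigar[t] = best.cigar;
    score[t] = best.score;
    status[t] = "aligned";
  }
  return List::create(_["strand"] = strand, _["ref_start"] = ref_start,
                      _["cigar"] = cigar, _["score"] = score,
                      _["status"] = status);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// indel left-normalisation: every I/D run is shifted to its leftmost
// equivalent position (shifted-out and shifted-in bases equal); score and
// op multiset unchanged; idempotent.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_left_align(CharacterVector cigars, IntegerVector ref_starts,
                    CharacterVector readseqs, std::string ref) {
  const int nn = cigars.size();
  CharacterVector out_cig(nn);
  for (int t = 0; t < nn; ++t) {
    if (CharacterVector::is_na(cigars[t]) || cigars[t] == "") {
      out_cig[t] = cigars[t]; continue;
    }
    std::vector<CigOp> ops = parse_cigar(as<std::string>(cigars[t]));
    const std::string r = as<std::string>(readseqs[t]);
    const int rs = ref_starts[t];
    bool changed = true;
    while (changed) {
      changed = false;
      ops = normalize_ops(ops);
      // absolute read / ref cursors at the start of each op
      int q = 0, p = rs;
      for (size_t k = 0; k < ops.size(); ++k) {
        CigOp& o = ops[k];
        if ((o.op == 'D' || o.op == 'I') && k > 0 && ops[k - 1].op == 'M') {
          CigOp& prevM = ops[k - 1];
          int shifted = 0;
          if (o.op == 'D') {
            // deletion over ref [p, p+len)
            int pp = p;
            while (prevM.len - shifted > 0 && pp >= 1 &&
                   ref[pp - 1] == ref[pp + o.len - 1]) {
              ++shifted; --pp;
            }
            if (shifted > 0) {
              prevM.len -= shifted;
              p -= shifted;
              // re-anchor: columns move to after the deletion as M
              if (k + 1 < ops.size() && ops[k + 1].op == 'M') {
                ops[k + 1].len += shifted;
              } else {
                ops.insert(ops.begin() + k + 1, CigOp{'M', shifted});
              }
              changed = true;
            }
          } else { // I: insertion over read [q, q+len)
            int qq = q;
            while (prevM.len - shifted > 0 && qq >= 1 &&
                   r[qq - 1] == r[qq + o.len - 1]) {
              ++shifted; --qq;
            }
            if (shifted > 0) {
              prevM.len -= shifted;
              q -= shifted;
              if (k + 1 < ops.size() && ops[k + 1].op == 'M') {
                ops[k + 1].len += shifted;
              } else {
                ops.insert(ops.begin() + k + 1, CigOp{'M', shifted});
              }
              changed = true;
            }
          }
          if (changed) break;  // restart the scan with fresh cursors
        }
        if (o.op == 'M') { q += o.len; p += o.len; }
        else if (o.op == 'I' || o.op == 'S') { q += o.len; }
        else if (o.op == 'D') { p += o.len; }
      }
    }
    out_cig[t] = build_cigar(normalize_ops(ops));
  }
  return List::create(_["cigar"] = out_cig);
}

// ---------------------------------------------------------------------------
// CIGAR walking: reference span, coverage test, segment extraction,
// per-position base lookup
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_ref_span(CharacterVector cigars, IntegerVector ref_starts) {
  const int nn = cigars.size();
  IntegerVector out(nn);
  for (int t = 0; t < nn; ++t) {
    if (CharacterVector::is_na(cigars[t]) || cigars[t] == "") {
      out[t] = NA_INTEGER; continue;
    }
    int span = 0;
    for (const auto& o : parse_cigar(as<std::string>(cigars[t])))
      if (o.op == 'M' || o.op == 'D') span += o.len;
    out[t] = ref_starts[t] + span;  // end (exclusive, 0-based local)
  }
  return out;
}

// Extract the read content over reference columns [a, b) (0-based local,
// half-open).  Returns, per alignment:
//   columns : one char per reference column (base for M, '-' for D)
//   gapped  : columns with inserted read bases spliced in before their
//             anchor column (anchor = the next reference column; an I
//             anchored at column a belongs to the segment, at column b not)
//   ungapped: gapped with '-' removed
//   covered : TRUE iff all columns of [a, b) lie within the alignment span
// [[Rcpp::export]]
List cpp_extract(CharacterVector cigars, IntegerVector ref_starts,
                 CharacterVector readseqs, int a, int b) {
  const int nn = cigars.size();
  CharacterVector columns(nn), gapped(nn), ungapped(nn);
  LogicalVector covered(nn);
  for (int t = 0; t < nn; ++t) {
    covered[t] = false;
    columns[t] = NA_STRING; gapped[t] = NA_STRING; ungapped[t] = NA_STRING;
    if (CharacterVector::is_na(cigars[t]) || cigars[t] == "") continue;
    const std::string r = as<std::string>(readseqs[t]);
    const std::vector<CigOp> ops = parse_cigar(as<std::string>(cigars[t]));
    int p = ref_starts[t], q = 0;
    int span_end = p;
    for (const auto& o : ops)
      if (o.op == 'M' || o.op == 'D') span_end += o.len;
    if (!(ref_starts[t] <= a && b <= span_end)) continue;
    covered[t] = true;

    std::string col(b - a, '.');
    // inserted bases keyed by anchor column
    std::vector<std::string> ins(b - a + 1);
    p = ref_starts[t]; q = 0;
    for (const auto& o : ops) {
      if (o.op == 'M') {
        for (int x = 0; x < o.len; ++x) {
          if (p >= a && p < b) col[p - a] = r[q];
          ++p; ++q;
        }
      } else if (o.op == 'D') {
        for (int x = 0; x < o.len; ++x) {
          if (p >= a && p < b) col[p - a] = '-';
          ++p;
        }
      } else if (o.op == 'I' || o.op == 'S') {
        if (o.op == 'I' && p >= a && p < b) ins[p - a] += r.substr(q, o.len);
        q += o.len;
      }
    }
    std::string gap;
    for (int c = 0; c < b - a; ++c) {
      if (!ins[c].empty()) gap += ins[c];
      gap += col[c];
    }
    std::string ungap;
    for (char c : gap) if (c != '-') ungap += c;
    columns[t] = col; gapped[t] = gap; ungapped[t] = ungap;
  }
  return List::create(_["columns"] = columns, _["gapped"] = gapped,
                      _["ungapped"] = ungapped, _["covered"] = covered);
}

// Base carried by each read at one reference column (0-based local):
// base for M, '-' for D, '.' if the column is outside the alignment span.
// [[Rcpp::export]]
CharacterVector cpp_base_at(CharacterVector cigars, IntegerVector ref_starts,
                            CharacterVector readseqs, int col) {
  const int nn = cigars.size();
  CharacterVector out(nn);
  for (int t = 0; t < nn; ++t) {
    out[t] = ".";
    if (CharacterVector::is_na(cigars[t]) || cigars[t] == "") continue;
    const std::string r = as<std::string>(readseqs[t]);
    int p = ref_starts[t], q = 0;
    for (const auto& o : parse_cigar(as<std::string>(cigars[t]))) {
      if (o.op == 'M') {
        if (col >= p && col < p + o.len) { out[t] = std::string(1, r[q + (col - p)]); break; }
        p += o.len; q += o.len;
      } else if (o.op == 'D') {
        if (col >= p && col < p + o.len) { out[t] = "-"; break; }
        p += o.len;
      } else { // I or S
        q += o.len;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// greedy incremental clustering (CD-HIT style): identity of the shorter
// sequence slid ungapped along the longer; identity = matches / shorter len
// ---------------------------------------------------------------------------

static double sliding_identity(const std::string& a, const std::string& b) {
  const std::string& s = (a.size() <= b.size()) ? a : b;
  const std::string& l = (a.size() <= b.size()) ? b : a;
  const int ls = (int)s.size(), ll = (int)l.size();
  if (ls == 0) return 0.0;
  int best = 0;
  for (int off = 0; off + ls <= ll; ++off) {
    int mm = 0;
    for (int i = 0; i < ls; ++i)
      if (s[i] == l[off + i] && s[i] != 'N') ++mm;
    if (mm > best) best = mm;
  }
  return (double)best / (double)ls;
}

// [[Rcpp::export]]
double cpp_sliding_identity(std::string a, std::string b) {
  return sliding_identity(a, b);
}

// seqs must already be in processing order (length desc, then lexicographic);
// returns 1-based cluster id per sequence (cluster = first member's index)
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold) {
  const int nn = seqs.size();
  IntegerVector assign(nn);
  std::vector<std::string> reps;
  std::vector<int> rep_id;
  for (int t = 0; t < nn; ++t) {
    const std::string s = as<std::string>(seqs[t]);
    int hit = -1;
    for (size_t k = 0; k < reps.size(); ++k) {
      if (sliding_identity(s, reps[k]) >= threshold) { hit = (int)k; break; }
    }
    if (hit < 0) {
      reps.push_back(s);
      rep_id.push_back(t + 1);
      assign[t] = t + 1;
    } else {
      assign[t] = rep_id[hit];
    }
  }
  return assign;
}

// ---------------------------------------------------------------------------
// read trimming
// ---------------------------------------------------------------------------

// 3' running-sum quality trimming: scanning from the 3' end accumulate
// (threshold - q); cut at the leftmost position where the partial sum is
// maximal and positive.  Returns the number of bases to keep.
// [[Rcpp::export]]
IntegerVector cpp_qual_cut(CharacterVector quals, double threshold) {
  const int nn = quals.size();
  IntegerVector keep(nn);
  for (int t = 0; t < nn; ++t) {
    const std::string q = as<std::string>(quals[t]);
    const int L = (int)q.size();
    double run = 0.0, best = 0.0;
    int cut = L;  // keep everything
    for (int i = L - 1; i >= 0; --i) {
      run += threshold - (double)((unsigned char)q[i] - 33);
      if (run >= best && run > 0) { best = run; cut = i; }
    }
    keep[t] = cut;
  }
  return keep;
}

// 3' adapter search: best-scoring occurrence of the adapter as a full
// internal match or a partial 3' suffix overlap (>= min_overlap), with at
// most floor(rate * matched_length) mismatches.  Score = matches; ties go
// to the leftmost start (longest removal).  Returns the cut position
// (bases to keep), or the read length when no acceptable occurrence exists.
// [[Rcpp::export]]
IntegerVector cpp_adapter_cut(CharacterVector seqs, std::string adapter,
                              double rate, int min_overlap) {
  const int nn = seqs.size();
  const int A = (int)adapter.size();
  IntegerVector keep(nn);
  for (int t = 0; t < nn; ++t) {
    const std::string s = as<std::string>(seqs[t]);
    const int L = (int)s.size();
    int best_score = -1, best_p = L;
    for (int p = 0; p < L; ++p) {
      const int matched = std::min(A, L - p);
      if (matched < A && matched < min_overlap) break;  // shrinking overlap
      int mm = 0;
      for (int i = 0; i < matched; ++i)
        if (s[p + i] != adapter[i]) ++mm;
      if (mm <= (int)std::floor(rate * matched)) {
        const int sc = matched - mm;
        if (sc > best_score) { best_score = sc; best_p = p; }
      }
    }
    keep[t] = best_p;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// repeat-unit counting: longest run of exact unit copies within a tract
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_unit_run(CharacterVector tracts, std::string unit) {
  const int nn = tracts.size();
  const int u = (int)unit.size();
  IntegerVector out(nn);
  for (int t = 0; t < nn; ++t) {
    if (CharacterVector::is_na(tracts[t])) { out[t] = NA_INTEGER; continue; }
    const std::string s = as<std::string>(tracts[t]);
    const int L = (int)s.size();
    int best = 0;
    for (int i = 0; i + u <= L; ++i) {
      int k = 0;
      while (i + (k + 1) * u <= L &&
             s.compare(i + k * u, u, unit) == 0) ++k;
      if (k > best) best = k;
    }
    out[t] = best;
  }
  return out;
}
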