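#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Wraparound dynamic programming: align a sequence window against an
// unbounded tandem concatenation of a single consensus period.  The
// alignment path may wrap from the last consensus position back to the
// first.  Affine gap costs (a gap of length L costs open + L * extend;
// open = 0 gives the linear model of the repeat-finder score formula).
//
// State (i, j): i seq characters consumed, next consensus position to
// consume is j.  Three layers: M (diagonal), X (gap in consensus =
// insertion in seq), Y (gap in seq = deletion of consensus positions).
// Y has a cyclic within-row dependency in j, resolved by two sweeps
// per row: an optimal deletion chain never wraps a full period
// (deleting p + x positions reaches the same state as deleting x at
// strictly lower score).
//
// mode: global = the whole window is aligned (free start/end phase in
// the consensus); local = Smith-Waterman in the window dimension
// (fresh starts into M), returning the maximal-scoring sub-window.

static const int NEG_INF = -1000000000;

// move codes (predecessor state): 0 = start, 1 = from M, 2 = from X,
// 3 = from Y
// [[Rcpp::export]]
List cpp_wrap_align(std::string seq, std::string cons,
                    int match, int mismatch, int gap_open, int gap_extend,
                    bool global) {
  const int n = (int)seq.size();
  const int p = (int)cons.size();
  if (p < 1) stop("empty consensus");
  if (n < 1) stop("empty sequence window");
  if ((double)(n + 1) * p > 1.2e7)
    stop("alignment problem too large (%d x %d cells)", n + 1, p);
  const int go = gap_open, ge = gap_extend;

  std::vector<uint8_t> mvM((size_t)(n + 1) * p, 0),
      mvX((size_t)(n + 1) * p, 0), mvY((size_t)(n + 1) * p, 0);
  std::vector<int> Mprev(p, NEG_INF), Xprev(p, NEG_INF), Yprev(p, NEG_INF);
  std::vector<int> Mcur(p, NEG_INF), Xcur(p, NEG_INF), Ycur(p, NEG_INF);
  auto idx = [p](int i, int j) { return (size_t)i * p + j; };

  // row 0: free start at any phase (M "start" with score 0); leading
  // deletions (Y in row 0) are never beneficial with non-negative gap
  // costs, and a free start phase makes them redundant.
  for (int j = 0; j < p; ++j) { Mprev[j] = 0; mvM[idx(0, j)] = 0; }

  int bestScore = NEG_INF, bi = -1, bj = -1, bs = 1;  // local tracking
  if (!global) { bestScore = 0; }

  for (int i = 1; i <= n; ++i) {
    char sc = seq[i - 1];
    // M and X depend on row i-1 only
    for (int j = 0; j < p; ++j) {
      int jm = (j == 0) ? p - 1 : j - 1;
      int sub = (sc == cons[jm] && sc != 'N') ? match : -mismatch;
      int best = NEG_INF; uint8_t m = 0;
      if (Mprev[jm] > NEG_INF && Mprev[jm] + sub > best) {
        best = Mprev[jm] + sub; m = 1;
      }
      if (Xprev[jm] > NEG_INF && Xprev[jm] + sub > best) {
        best = Xprev[jm] + sub; m = 2;
      }
      if (Yprev[jm] > NEG_INF && Yprev[jm] + sub > best) {
        best = Yprev[jm] + sub; m = 3;
      }
      if (!global && sub > best) { best = sub; m = 0; }  // local fresh start
      Mcur[j] = best; mvM[idx(i, j)] = m;

      int bx = NEG_INF; uint8_t mx = 1;
      if (Mprev[j] > NEG_INF && Mprev[j] - go - ge > bx) {
        bx = Mprev[j] - go - ge; mx = 1;
      }
      if (Xprev[j] > NEG_INF && Xprev[j] - ge > bx) {
        bx = Xprev[j] - ge; mx = 2;
      }
      if (Yprev[j] > NEG_INF && Yprev[j] - go - ge > bx) {
        bx = Yprev[j] - go - ge; mx = 3;
      }
      Xcur[j] = bx; mvX[idx(i, j)] = mx;
      Ycur[j] = NEG_INF;
    }
    // Y: two cyclic sweeps
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int j = 0; j < p; ++j) {
        int jm = (j == 0) ? p - 1 : j - 1;
        int by = Ycur[j]; uint8_t my = mvY[idx(i, j)];
        if (Mcur[jm] > NEG_INF && Mcur[jm] - go - ge > by) {
          by = Mcur[jm] - go - ge; my = 1;
        }
        if (Xcur[jm] > NEG_INF && Xcur[jm] - go - ge > by) {
          by = Xcur[jm] - go - ge; my = 2;
        }
        if (Ycur[jm] > NEG_INF && Ycur[jm] - ge > by) {
          by = Ycur[jm] - ge; my = 3;
        }
        Ycur[j] = by; mvY[idx(i, j)] = my;
      }
    }
    if (!global) {
      for (int j = 0; j < p; ++j) {
        if (Mcur[j] > bestScore) { bestScore = Mcur[j]; bi = i; bj = j; bs = 1; }
      }
    }
    Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
  }

  if (global) {
    for (int j = 0; j < p; ++j) {
      if (Mprev[j] > bestScore) { bestScore = Mprev[j]; bj = j; bs = 1; }
      if (Xprev[j] > bestScore) { bestScore = Xprev[j]; bj = j; bs = 2; }
      if (Yprev[j] > bestScore) { bestScore = Yprev[j]; bj = j; bs = 3; }
    }
    bi = n;
  }

  std::vector<int> ops;        // 1=match, 2=mismatch, 3=ins(seq), 4=del(cons)
  std::vector<int> spos, cpos; // 0-based positions (-1 where not applicable)
  if (bi >= 0 && bestScore > NEG_INF && !(bi == 0)) {
    int i = bi, j = bj, s = bs;
    while (true) {
      int jm = (j == 0) ? p - 1 : j - 1;
      if (s == 1) {           // M: consumed seq[i-1] against cons[jm]
        uint8_t m = mvM[idx(i, j)];
        bool ismatch = (seq[i - 1] == cons[jm] && seq[i - 1] != 'N');
        ops.push_back(ismatch ? 1 : 2);
        spos.push_back(i - 1); cpos.push_back(jm);
        i -= 1; j = jm;
        if (m == 0) break;    // fresh start (local) or row-0 start
        s = m;
        if (i == 0) break;
      } else if (s == 2) {    // X: consumed seq[i-1] as insertion
        uint8_t m = mvX[idx(i, j)];
        ops.push_back(3); spos.push_back(i - 1); cpos.push_back(-1);
        i -= 1; s = m;
        if (i == 0) break;
      } else {                // Y: consumed cons[jm] as deletion
        uint8_t m = mvY[idx(i, j)];
        ops.push_back(4); spos.push_back(-1); cpos.push_back(jm);
        j = jm; s = m;
      }
    }
    std::reverse(ops.begin(), ops.end());
    std::reverse(spos.begin(), spos.end());
    std::reverse(cpos.begin(), cpos.end());
  }

  int nmatch = 0, nmis = 0, nindel = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] == 1) ++nmatch;
    else if (ops[k] == 2) ++nmis;
    else ++nindel;
  }
  int seq_start = 0, seq_end = 0;
  for (size_t k = 0; k < spos.size(); ++k) if (spos[k] >= 0) {
    if (seq_start == 0 || spos[k] + 1 < seq_start) seq_start = spos[k] + 1;
    if (spos[k] + 1 > seq_end) seq_end = spos[k] + 1;
  }

  return List::create(
    _["score"] = bestScore,
    _["seq_start"] = seq_start, _["seq_end"] = seq_end,
    _["n_match"] = nmatch, _["n_mismatch"] = nmis, _["n_indel"] = nindel,
    _["ops"] = IntegerVector(ops.begin(), ops.end()),
    _["seq_pos"] = IntegerVector(spos.begin(), spos.end()),
    _["cons_pos"] = IntegerVector(cpos.begin(), cpos.end()));
}

// k-mer seeding for the tandem repeat scanner: for every pair of exact
// matching k-mers at distance <= max_period, emit (position, distance).
// A per-position cap bounds output on low-complexity sequence; the cap
// keeps the nearest previous occurrences, which always include the true
// period distance of a tandem array.
// [[Rcpp::export]]
List cpp_kmer_seeds(std::string seq, int k, int max_period, int max_hits_per_pos) {
  const int n = (int)seq.size();
  std::vector<int> outpos, outdist;
  if (n < 2 * k || k < 1 || k > 31)
    return List::create(_["pos"] = IntegerVector(0),
                        _["dist"] = IntegerVector(0));
  std::unordered_map<uint64_t, std::vector<int> > occ;
  occ.reserve((size_t)n * 2);
  uint64_t code = 0, mask = (1ULL << (2 * k)) - 1;
  int valid = 0;  // length of current run without N
  for (int i = 0; i < n; ++i) {
    int b;
    switch (seq[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    int pos = i - k + 1;  // 0-based start of this k-mer
    std::vector<int> &v = occ[code];
    size_t keep = 0;      // prune stale occurrences
    for (size_t t = 0; t < v.size(); ++t)
      if (v[t] >= pos - max_period) v[keep++] = v[t];
    v.resize(keep);
    int emitted = 0;
    for (size_t t = v.size(); t-- > 0 && emitted < max_hits_per_pos; ) {
      int d = pos - v[t];
      if (d >= 1 && d <= max_period) {
        outpos.push_back(pos); outdist.push_back(d); ++emitted;
      }
    }
    v.push_back(pos);
  }
  return List::create(_["pos"] = IntegerVector(outpos.begin(), outpos.end()),
                      _["dist"] = IntegerVector(outdist.begin(), outdist.end()));
}
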