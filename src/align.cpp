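#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two short segments with unit
// scores (match +1, mismatch -1, gap -1). Appends the aligned base pairs
// (match or mismatch columns) to q_out/t_out as 0-based coordinates and
// accumulates match / column counts. Tie-breaking is fixed: diagonal, then
// up (gap in t), then left.
static void nw_fill(const std::string &q, const std::string &t,
                    int q0, int q1, int t0, int t1,
                    std::vector<int> &q_out, std::vector<int> &t_out,
                    long &nmatch, long &ncol) {
  const int n = q1 - q0, m = t1 - t0;
  if (n == 0 && m == 0) return;
  if (n == 0 || m == 0) { ncol += n + m; return; }
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> ptr((n + 1) * (size_t)(m + 1), 0);
  for (int j = 0; j <= m; ++j) prev[j] = -j;
  for (int j = 1; j <= m; ++j) ptr[j] = 3;
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    ptr[i * (size_t)(m + 1)] = 2;
    const char qc = q[q0 + i - 1];
    for (int j = 1; j <= m; ++j) {
      int s = prev[j - 1] + (qc == t[t0 + j - 1] ? 1 : -1);
      int up = prev[j] - 1;
      int left = cur[j - 1] - 1;
      int v; unsigned char p;
      if (s >= up && s >= left) { v = s; p = 1; }
      else if (up >= left) { v = up; p = 2; }
      else { v = left; p = 3; }
      cur[j] = v;
      ptr[i * (size_t)(m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  // traceback
  std::vector<int> qi, ti;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[i * (size_t)(m + 1) + j];
    ++ncol;
    if (p == 1) {
      --i; --j;
      qi.push_back(q0 + i); ti.push_back(t0 + j);
      if (q[q0 + i] == t[t0 + j]) ++nmatch;
    } else if (p == 2) --i;
    else --j;
  }
  for (size_t r = qi.size(); r > 0; --r) {
    q_out.push_back(qi[r - 1]);
    t_out.push_back(ti[r - 1]);
  }
}

// Chain collinear seed matches between a query and a target and fill the
// gaps between consecutive seeds with global alignment. Seeds are 0-based
// start positions of exact k-mer matches, strictly increasing in both
// coordinates (the R caller guarantees monotonicity; seeds that rewind on
// one side are skipped, same-diagonal overlapping seeds extend the match
// run). Ends are extended by greedy exact match beyond the outermost
// seeds. Gaps larger than max_gap abort with an error (the caller splits
// chains beforehand).
//
// Returns matched/mismatched column coordinates (q, t; 0-based), the
// number of matching bases, and the total alignment column count.
// [[Rcpp::export]]
List cpp_chain_fill(std::string q, std::string t,
                    IntegerVector qpos, IntegerVector tpos,
                    int k, int max_gap = 5000) {
  const int ns = qpos.size();
  if (ns == 0 || tpos.size() != qpos.size())
    stop("need a non-empty, equal-length seed set");
  std::vector<int> q_out, t_out;
  q_out.reserve(q.size()); t_out.reserve(q.size());
  long nmatch = 0, ncol = 0;
  // greedy exact extension left of the first seed
  {
    int qi = qpos[0] - 1, ti = tpos[0] - 1;
    int ext = 0;
    while (qi >= 0 && ti >= 0 && q[qi] == t[ti]) { --qi; --ti; ++ext; }
    for (int e = ext; e > 0; --e) {
      q_out.push_back(qpos[0] - e);
      t_out.push_back(tpos[0] - e);
      ++nmatch; ++ncol;
    }
  }
  int qcur = qpos[0], tcur = tpos[0];  // next un-emitted position
  for (int s = 0; s < ns; ++s) {
    int qs = qpos[s], ts = tpos[s];
    if (qs < qcur || ts < tcur) {
      // same diagonal and still advancing: extend the match run
      if (qs - qcur == ts - tcur && qs + k > qcur) { qs = qcur; ts = tcur; }
      else continue;  // conflicting seed, skip
    } else {
      int qg = qs - qcur, tg = ts - tcur;
      if (qg > max_gap || tg > max_gap)
        stop("seed gap exceeds max_gap; split the chain");
      nw_fill(q, t, qcur, qs, tcur, ts, q_out, t_out, nmatch, ncol);
    }
    int end = qpos[s] + k;  // emit the (rest of the) seed as matches
    for (int qi = qs, ti = ts; qi < end; ++qi, ++ti) {
      q_out.push_back(qi); t_out.push_back(ti);
      ++nmatch; ++ncol;
    }
    qcur = qpos[s] + k; tcur = tpos[s] + k;
  }
  // greedy exact extension right of the last seed
  {
    int qi = qcur, ti = tcur;
    while (qi < (int)q.size() && ti < (int)t.size() && q[qi] == t[ti]) {
      q_out.push_back(qi); t_out.push_back(ti);
      ++nmatch; ++ncol; ++qi; ++ti;
    }
  }
  return List::create(_["q"] = wrap(q_out), _["t"] = wrap(t_out),
                      _["nmatch"] = (double)nmatch,
                      _["ncol"] = (double)ncol);
}

// Heaviest source-to-sink path in a layered DAG. Nodes belong to layers
// 0..max(layer); every edge advances exactly one layer. All layer-0 nodes
// are sources with score 0; the best-scoring node in the maximal layer is
// the sink. Edges must be pre-sorted by from-node layer; ties on equal
// candidate scores keep the first-seen predecessor, so the caller's edge
// order fixes the tie-break. Returns the 1-based edge index sequence of
// the heaviest path (empty when no node beyond layer 0 is reachable).
// [[Rcpp::export]]
IntegerVector cpp_heaviest_path(IntegerVector node_layer,
                                IntegerVector efrom, IntegerVector eto,
                                NumericVector ew) {
  const int n = node_layer.size();
  const R_xlen_t ne = efrom.size();
  const double NEG = -1e300;
  std::vector<double> score(n, NEG);
  std::vector<R_xlen_t> pred(n, -1);
  int max_layer = 0;
  for (int i = 0; i < n; ++i) {
    if (node_layer[i] == 0) score[i] = 0.0;
    if (node_layer[i] > max_layer) max_layer = node_layer[i];
  }
  for (R_xlen_t e = 0; e < ne; ++e) {
    int u = efrom[e] - 1, v = eto[e] - 1;
    if (score[u] <= NEG / 2) continue;
    double cand = score[u] + ew[e];
    if (cand > score[v]) { score[v] = cand; pred[v] = e; }
  }
  // best node in the deepest reachable layer
  int best = -1; int best_layer = -1; double best_score = NEG;
  for (int i = 0; i < n; ++i) {
    if (score[i] <= NEG / 2) continue;
    if (node_layer[i] > best_layer ||
        (node_layer[i] == best_layer && score[i] > best_score)) {
      best = i; best_layer = node_layer[i]; best_score = score[i];
    }
  }
  std::vector<int> path;
  int v = best;
  while (v >= 0 && pred[v] >= 0) {
    path.push_back((int)(pred[v] + 1));
    v = efrom[pred[v]] - 1;
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
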