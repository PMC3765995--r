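#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Quality-guided region-growing 2D phase unwrapper.
//
// Starting from the highest-quality pixel of each 4-connected mask component,
// pixels are integrated in decreasing order of quality; each new pixel's phase
// is adjusted by the 2*pi multiple that brings it closest to the already-solved
// neighbour it was reached from.  Every output value therefore differs from the
// input by an exact integer multiple of 2*pi.
// [[Rcpp::export]]
NumericMatrix unwrap_qg_cpp(NumericMatrix phase, LogicalMatrix mask,
                            NumericMatrix quality) {
  const int nr = phase.nrow(), nc = phase.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> state(nr * nc, 0); // 0 = untouched, 2 = solved
  const double TWOPI = 2.0 * M_PI;

  typedef std::pair<double, std::pair<int, int> > Node; // (quality, (pixel, source))
  std::priority_queue<Node> pq;

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  for (;;) {
    // seed: best-quality unsolved masked pixel (starts a new component)
    double best = R_NegInf;
    int seed = -1;
    for (int idx = 0; idx < nr * nc; ++idx) {
      if (mask[idx] && state[idx] != 2 && quality[idx] > best) {
        best = quality[idx];
        seed = idx;
      }
    }
    if (seed < 0) break;

    out[seed] = phase[seed];
    state[seed] = 2;
    int current = seed;

    for (;;) {
      // push unsolved masked neighbours of `current`
      int ci = current % nr, cj = current / nr;
      for (int k = 0; k < 4; ++k) {
        int ii = ci + di[k], jj = cj + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int nidx = ii + jj * nr;
        if (!mask[nidx] || state[nidx] == 2) continue;
        pq.push(std::make_pair(quality[nidx], std::make_pair(nidx, current)));
      }
      // pop highest-quality pending pixel
      int nxt = -1, src = -1;
      while (!pq.empty()) {
        Node nd = pq.top();
        pq.pop();
        if (state[nd.second.first] != 2) {
          nxt = nd.second.first;
          src = nd.second.second;
          break;
        }
      }
      if (nxt < 0) break; // component exhausted
      double d = phase[nxt] - out[src];
      double adj = d - TWOPI * std::floor(d / TWOPI + 0.5);
      out[nxt] = out[src] + adj;
      state[nxt] = 2;
      current = nxt;
    }
  }
  return out;
}

// 4-connected component labelling of a logical mask; 0 outside the mask.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < nr * nc; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int ci = cur % nr, cj = cur / nr;
      for (int k = 0; k < 4; ++k) {
        int ii = ci + di[k], jj = cj + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int nidx = ii + jj * nr;
        if (mask[nidx] && lab[nidx] == 0) {
          lab[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  return lab;
}
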