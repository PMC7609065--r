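#include <Rcpp.h>
using namespace Rcpp;

// Markov state path: from any state, jump to each *other* state with
// probability `trans_prob` per frame, otherwise stay. A single uniform
// draw decides both whether to leave and the destination.
// [[Rcpp::export(name = ".state_seq_cpp")]]
IntegerVector state_seq_cpp(int n_frames, int n_states, double trans_prob) {
  IntegerVector s(n_frames);
  if (n_frames == 0) return s;
  int cur = (int)std::floor(unif_rand() * n_states);
  if (cur >= n_states) cur = n_states - 1;
  for (int t = 0; t < n_frames; ++t) {
    s[t] = cur + 1;  // 1-based for R
    if (n_states > 1 && trans_prob > 0.0) {
      double u = unif_rand();
      double leave = trans_prob * (n_states - 1);
      if (u < leave) {
        int j = (int)std::floor(u / trans_prob);  // 0 .. n_states-2
        if (j > n_states - 2) j = n_states - 2;
        cur = (j >= cur) ? j + 1 : j;
      }
    }
  }
  return s;
}

// First window start (1-based) where >= min_hits of the frames
// [i, i+window-1] (truncated at the end) satisfy `hit`; NA if none.
// [[Rcpp::export(name = ".window_scan_cpp")]]
int window_scan_cpp(LogicalVector hit, int window, int min_hits) {
  int n = hit.size();
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n, i + window);
    int cnt = 0;
    for (int j = i; j < hi; ++j) if (hit[j]) ++cnt;
    if (cnt >= min_hits) return i + 1;
  }
  return NA_INTEGER;
}
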