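#include <Rcpp.h>
#include <vector>

// Streaming lexicographic enumeration of all k-subsets of {1..n}: the index
// vector is advanced through every subset and counted, without materialising
// anything. Returned as double because counts exceed 32-bit range for
// moderate n.
// [[Rcpp::export]]
double stream_ksubset_count(int n, int k) {
  if (k < 0 || n < 0 || k > n) Rcpp::stop("need 0 <= k <= n");
  if (k == 0) return 1.0;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  double count = 0.0;
  for (;;) {
    ++count;
    int i = k - 1;
    while (i >= 0 && idx[i] == n - k + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return count;
}
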