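#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weights on the DNA-convention alphabet: GC=3, AT(AU)=2, GT(GU)=1.
// -1 marks a non-pairable combination.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return -1;
}

// Base-pair maximization (Nussinov-style) with a secondary objective:
// the DP value is 1000 * pairs + sum of pair weights, so the optimum
// maximizes the pair count first and, among max-pair structures, the
// weighted pair score (i.e. minimizes the fold energy -weight).
// Valid while 3 * n/2 < 1000, enforced below.
//
// [[Rcpp::export]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  if (n > 600) stop("nussinov_cpp: sequence longer than 600 nt");
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["structure"] = "", _["pairs"] = 0, _["weight"] = 0);

  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i][j - 1];           // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        int w = pair_weight(seq[k], seq[j]);
        if (w < 0) continue;
        int v = 1000 + w + (k > i ? dp[i][k - 1] : 0) + dp[k + 1][j - 1];
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }

  // deterministic traceback: prefer leaving j unpaired, then the
  // smallest k pairing with j
  std::vector<std::pair<int, int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    std::pair<int, int> ij = todo.back();
    todo.pop_back();
    int i = ij.first, j = ij.second;
    if (i >= j) continue;
    if (dp[i][j] == dp[i][j - 1]) {
      todo.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = pair_weight(seq[k], seq[j]);
      if (w < 0) continue;
      int v = 1000 + w + (k > i ? dp[i][k - 1] : 0) + dp[k + 1][j - 1];
      if (v == dp[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) todo.push_back(std::make_pair(i, k - 1));
        todo.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  int total = dp[0][n - 1];
  return List::create(_["structure"] = db,
                      _["pairs"] = total / 1000,
                      _["weight"] = total % 1000);
}
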