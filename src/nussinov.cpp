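#include <Rcpp.h>
#include <string>
#include <vector>

// Base-pair maximization folding (Nussinov-style dynamic program) with a
// minimum hairpin loop size. Deterministic traceback: pairing (i,j) is
// preferred over bifurcation at equal score, and the smallest split point
// wins ties. Returns the dot-bracket string and the pair count.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T' || b == 'U';
  case 'T': case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T' || b == 'U';
  case 'C': return b == 'G';
  default: return false;
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) seq[i] = std::toupper(seq[i]);
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i + 1][j];  // i unpaired
      if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
        int v = 1 + (i + 1 <= j - 1 ? dp[i + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = dp[i][k] + dp[k + 1][j];
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }

  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (dp[i][j] == 0) continue;
    if (dp[i][j] == dp[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (can_pair(seq[i], seq[j]) && j - i > min_loop &&
        dp[i][j] == 1 + (i + 1 <= j - 1 ? dp[i + 1][j - 1] : 0)) {
      db[i] = '(';
      db[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (dp[i][j] == dp[i][k] + dp[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        split = true;
        break;
      }
    }
    if (!split) stack.push_back(std::make_pair(i + 1, j));
  }

  int score = (n > 0) ? dp[0][n - 1] : 0;
  return Rcpp::List::create(Rcpp::Named("structure") = db,
                            Rcpp::Named("score") = score);
}
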