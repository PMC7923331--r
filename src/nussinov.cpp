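#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T/U=3, anything else = -1 (never pairs).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

// Watson-Crick plus G.U wobble.
static inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  int s = a + b;
  if (s == 3 && (a == 0 || a == 3 || a == 1 || a == 2)) {
    // A+T=3, C+G=3
    return (a == 0 && b == 3) || (a == 3 && b == 0) ||
           (a == 1 && b == 2) || (a == 2 && b == 1);
  }
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return true; // G.U
  return false;
}

// Maximum base-pairing (Nussinov) with a minimum hairpin loop size.
// Traceback is deterministic: when co-optimal, the outermost admissible
// pairing (smallest k for position j) is preferred over leaving j unpaired,
// which favours long contiguous stems.
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
  int n = (int) seq.size();
  if (n > 10000) stop("window longer than 10000 nt");
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    if (code[i] < 0) stop("non-nucleotide character '%s' at position %d",
                          std::string(1, seq[i]).c_str(), i + 1);
  }
  if (n == 0)
    return List::create(_["max_pairs"] = 0,
                        _["dot_bracket"] = "",
                        _["pairs"] = IntegerMatrix(0, 2));

  // dp[i][j] over 0-based inclusive windows, stored as vector of rows.
  std::vector<std::vector<short>> dp(n, std::vector<short>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      short best = dp[i][j - 1]; // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(code[k], code[j])) {
          short cand = (short) ((k > i ? dp[i][k - 1] : 0) +
                                (j - k > 1 ? dp[k + 1][j - 1] : 0) + 1);
          if (cand > best) best = cand;
        }
      }
      dp[i][j] = best;
    }
  }

  // Traceback.
  std::string db(n, '.');
  std::vector<std::pair<int,int>> pairs;
  std::stack<std::pair<int,int>> st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    std::pair<int,int> w = st.top(); st.pop();
    int i = w.first, j = w.second;
    if (i >= j || j - i <= min_loop) continue;
    bool done = false;
    for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
      if (!can_pair(code[k], code[j])) continue;
      short cand = (short) ((k > i ? dp[i][k - 1] : 0) +
                            (j - k > 1 ? dp[k + 1][j - 1] : 0) + 1);
      if (cand == dp[i][j]) {
        db[k] = '('; db[j] = ')';
        pairs.push_back(std::make_pair(k + 1, j + 1));
        if (k > i) st.push(std::make_pair(i, k - 1));
        if (j - k > 1) st.push(std::make_pair(k + 1, j - 1));
        done = true;
      }
    }
    if (!done) st.push(std::make_pair(i, j - 1)); // j unpaired
  }

  IntegerMatrix pm((int) pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["max_pairs"] = (int) dp[0][n - 1],
                      _["dot_bracket"] = db,
                      _["pairs"] = pm);
}

// Fraction of antiparallel columns of b1 vs b2 that form WC or G.U pairs.
// [[Rcpp::export(name = ".pair_fraction_cpp")]]
double pair_fraction_cpp(std::string b1, std::string b2) {
  int n1 = (int) b1.size(), n2 = (int) b2.size();
  int n = n1 < n2 ? n1 : n2;
  if (n == 0) return 0.0;
  int hits = 0;
  for (int i = 0; i < n; ++i) {
    if (can_pair(base_code(b1[i]), base_code(b2[n2 - 1 - i]))) ++hits;
  }
  return (double) hits / (double) n;
}
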