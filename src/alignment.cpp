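#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Bit costs of the four edit operations. U and D are bare 2-bit op codes;
// I and S additionally record the original symbol in 8-bit ASCII.
static const int COST_U = 2;
static const int COST_D = 2;
static const int COST_I = 10;
static const int COST_S = 10;

// Plain Levenshtein distance, two-row DP.
static int lev_core(const std::string& a, const std::string& b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lev_cpp(std::string a, std::string b) {
  return lev_core(a, b);
}

// Minimal bit cost 2*P' + 8*R of an edit script transforming c into q
// (index term excluded). Two-row DP.
static int align_cost_core(const std::string& q, const std::string& c) {
  const size_t n = c.size(), m = q.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j * COST_I;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i * COST_D;
    const char ci = c[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (ci == q[j - 1] ? COST_U : COST_S);
      int del = prev[j] + COST_D;
      int ins = cur[j - 1] + COST_I;
      cur[j] = std::min(diag, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int align_cost_cpp(std::string q, std::string c) {
  return align_cost_core(q, c);
}

// Full DP with traceback. Returns the op string (over "UIDS") and the
// recorded symbols (for I and S ops, in script order). Ties during
// traceback are broken U > D > I > S so scripts are deterministic and
// biased away from recorded symbols.
// [[Rcpp::export]]
List align_ops_cpp(std::string q, std::string c) {
  const size_t n = c.size(), m = q.size();
  std::vector<std::vector<int> > dp(n + 1, std::vector<int>(m + 1));
  for (size_t j = 0; j <= m; ++j) dp[0][j] = (int)j * COST_I;
  for (size_t i = 1; i <= n; ++i) {
    dp[i][0] = (int)i * COST_D;
    const char ci = c[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int diag = dp[i - 1][j - 1] + (ci == q[j - 1] ? COST_U : COST_S);
      int del = dp[i - 1][j] + COST_D;
      int ins = dp[i][j - 1] + COST_I;
      dp[i][j] = std::min(diag, std::min(del, ins));
    }
  }
  std::string ops, rec;
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    const int cell = dp[i][j];
    if (i > 0 && j > 0 && c[i - 1] == q[j - 1] &&
        cell == dp[i - 1][j - 1] + COST_U) {
      ops.push_back('U');
      --i; --j;
    } else if (i > 0 && cell == dp[i - 1][j] + COST_D) {
      ops.push_back('D');
      --i;
    } else if (j > 0 && cell == dp[i][j - 1] + COST_I) {
      ops.push_back('I');
      rec.push_back(q[j - 1]);
      --j;
    } else {
      ops.push_back('S');
      rec.push_back(q[j - 1]);
      --i; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(rec.begin(), rec.end());
  return List::create(_["ops"] = ops, _["recorded"] = rec,
                      _["cost"] = dp[n][m]);
}

// Sum over sequences of the approximate encoded size
// index_bits + 2*|Q_k| + 4*lev(C, Q_k).
// [[Rcpp::export]]
double corpus_approx_cost_cpp(std::string cvec, CharacterVector seqs,
                              int index_bits) {
  double total = 0.0;
  for (R_xlen_t k = 0; k < seqs.size(); ++k) {
    const std::string qk = as<std::string>(seqs[k]);
    total += index_bits + 2.0 * qk.size() + 4.0 * lev_core(cvec, qk);
  }
  return total;
}

// Index (1-based) of the code vector with minimal exact bit cost against q,
// ties broken by lowest index; returns c(index, cost).
// [[Rcpp::export]]
IntegerVector best_vector_cpp(CharacterVector vectors, std::string q) {
  int best = -1, best_cost = 0;
  for (R_xlen_t i = 0; i < vectors.size(); ++i) {
    const int cost = align_cost_core(q, as<std::string>(vectors[i]));
    if (best < 0 || cost < best_cost) {
      best = (int)i;
      best_cost = cost;
    }
  }
  return IntegerVector::create(best + 1, best_cost);
}

// Batch Levenshtein of one string against many (used by tests/metrics).
// [[Rcpp::export]]
IntegerVector lev_many_cpp(std::string a, CharacterVector b) {
  IntegerVector out(b.size());
  for (R_xlen_t i = 0; i < b.size(); ++i)
    out[i] = lev_core(a, as<std::string>(b[i]));
  return out;
}
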