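#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization over nested structures (Nussinov-style DP).
// Constraints: hairpin loop >= min_loop unpaired bases between a pair;
// allowed pairs: AU/UA, GC/CG, GU/UG (T treated as U); N pairs with nothing.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

static inline bool can_pair(int a, int b) {
  if (a > 3 || b > 3 || a < 0 || b < 0) return false;
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (lo == 0 && hi == 3) ||  // A-U
         (lo == 1 && hi == 2) ||  // C-G
         (lo == 2 && hi == 3);    // G-U
}

static std::string fold_one(const std::string& seq, int min_loop) {
  const int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    if (code[i] < 0)
      stop("fold: invalid character '%s' at offset %d",
           std::string(1, seq[i]).c_str(), i);
  }
  std::string db(n, '.');
  if (n == 0) return db;
  // dp[i][j]: max pairs in [i, j], flattened row-major.
  std::vector<int> dp((size_t)n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(code[i], code[k])) continue;
        int v = 1 + (k - i >= 2 ? dp[(size_t)(i + 1) * n + (k - 1)] : 0) +
                (k + 1 <= j ? dp[(size_t)(k + 1) * n + j] : 0);
        if (v > best) best = v;
      }
      dp[(size_t)i * n + j] = best;
    }
  }
  // Traceback; ties prefer pairing the smallest i, and for that i the
  // largest partner j achieving the optimum.
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    int opt = dp[(size_t)i * n + j];
    if (opt == 0) continue;
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {  // largest partner first
      if (!can_pair(code[i], code[k])) continue;
      int v = 1 + (k - i >= 2 ? dp[(size_t)(i + 1) * n + (k - 1)] : 0) +
              (k + 1 <= j ? dp[(size_t)(k + 1) * n + j] : 0);
      if (v == opt) { chosen = k; break; }
    }
    if (chosen >= 0) {
      db[i] = '(';
      db[chosen] = ')';
      if (chosen - i >= 2) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 <= j) stack.push_back(std::make_pair(chosen + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return db;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
CharacterVector nussinov_fold_cpp(CharacterVector seqs, int min_loop = 3) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) stop("fold: empty sequence (element %d)", (int)(i + 1));
    out[i] = fold_one(s, min_loop);
  }
  return out;
}

// [[Rcpp::export(name = ".nussinov_pair_count")]]
IntegerVector nussinov_pair_count_cpp(CharacterVector seqs, int min_loop = 3) {
  const R_xlen_t n = seqs.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string db = fold_one(as<std::string>(seqs[i]), min_loop);
    int c = 0;
    for (size_t k = 0; k < db.size(); ++k) if (db[k] == '(') ++c;
    out[i] = c;
  }
  return out;
}
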