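// Exact frequency distribution of the number of inversions (Kendall-Tau
// distance q) over permutations of n items, via the recurrence
//   f(q, n) = sum_{j=0}^{min(q, n-1)} f(q - j, n - 1)
// computed with a sliding-window sum. Counts reach n! (~7e306 at n = 170),
// beyond exact double range, so arithmetic uses non-negative big integers
// stored as little-endian limbs in base 1e18.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> Big;
static const uint64_t BASE = 1000000000000000000ULL;

static void add_to(Big &a, const Big &b) {
  size_t n = a.size() > b.size() ? a.size() : b.size();
  a.resize(n, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = a[i] + carry + (i < b.size() ? b[i] : 0);
    if (s >= BASE) { a[i] = s - BASE; carry = 1; } else { a[i] = s; carry = 0; }
  }
  if (carry) a.push_back(1);
}

// a -= b; requires a >= b (holds: window sums only shed terms they contain)
static void sub_from(Big &a, const Big &b) {
  uint64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t bi = (i < b.size() ? b[i] : 0) + borrow;
    if (a[i] >= bi) { a[i] -= bi; borrow = 0; }
    else { a[i] += BASE - bi; borrow = 1; }
  }
  while (a.size() > 1 && a.back() == 0) a.pop_back();
}

static double big_to_double(const Big &a) {
  double v = 0.0;
  for (size_t i = a.size(); i-- > 0;) v = v * 1e18 + (double)a[i];
  return v;
}

static std::string big_to_string(const Big &a) {
  std::string s = std::to_string(a.back());
  char buf[19];
  for (size_t i = a.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%018llu", (unsigned long long)a[i]);
    s += buf;
  }
  return s;
}

// full row f(., n)
static std::vector<Big> freq_row(int n) {
  std::vector<Big> prev(1, Big(1, 1));  // n = 1: f(0,1) = 1
  for (int k = 2; k <= n; ++k) {
    size_t qmax = (size_t)k * (k - 1) / 2;
    std::vector<Big> cur(qmax + 1);
    Big wsum(1, 0);
    for (size_t q = 0; q <= qmax; ++q) {
      if (q < prev.size()) add_to(wsum, prev[q]);
      if (q >= (size_t)k) sub_from(wsum, prev[q - k]);
      cur[q] = wsum;
    }
    prev.swap(cur);
  }
  return prev;
}

// [[Rcpp::export]]
NumericVector kendall_freq_table_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<Big> row = freq_row(n);
  NumericVector out(row.size());
  for (size_t i = 0; i < row.size(); ++i) out[i] = big_to_double(row[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector kendall_freq_exact_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<Big> row = freq_row(n);
  CharacterVector out(row.size());
  for (size_t i = 0; i < row.size(); ++i) out[i] = big_to_string(row[i]);
  return out;
}

// Lower-tail p-values P(Q <= q) = cum f / n!, exact big-integer cumulation
// converted to double only at the final ratio.
// [[Rcpp::export]]
NumericVector kendall_cum_pvalues_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<Big> row = freq_row(n);
  Big tot(1, 0);
  for (size_t i = 0; i < row.size(); ++i) add_to(tot, row[i]);
  double tot_d = big_to_double(tot);
  NumericVector out(row.size());
  Big cum(1, 0);
  for (size_t i = 0; i < row.size(); ++i) {
    add_to(cum, row[i]);
    out[i] = big_to_double(cum) / tot_d;
  }
  return out;
}
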