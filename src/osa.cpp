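#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance over
// integer-coded token sequences: unit-cost insertion, deletion,
// substitution and adjacent transposition, no substring edited twice.

static int osa_core(const int *a, int la, const int *b, int lb,
                    std::vector<int> &buf) {
    // three rolling rows of length lb + 1
    buf.resize(3 * (lb + 1));
    int *prev2 = buf.data(), *prev = prev2 + (lb + 1), *cur = prev + (lb + 1);
    for (int j = 0; j <= lb; ++j) prev[j] = j;
    for (int i = 1; i <= la; ++i) {
        cur[0] = i;
        for (int j = 1; j <= lb; ++j) {
            const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
            int d = prev[j - 1] + cost;                       // substitution
            if (prev[j] + 1 < d) d = prev[j] + 1;             // deletion
            if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;       // insertion
            if (i > 1 && j > 1 && a[i - 1] == b[j - 2] &&
                a[i - 2] == b[j - 1] && prev2[j - 2] + 1 < d)
                d = prev2[j - 2] + 1;                         // transposition
            cur[j] = d;
        }
        int *tmp = prev2; prev2 = prev; prev = cur; cur = tmp;
    }
    return prev[lb];
}

// [[Rcpp::export(name = ".osa_dist_cpp")]]
int osa_dist_cpp(IntegerVector a, IntegerVector b) {
    std::vector<int> buf;
    return osa_core(a.begin(), a.size(), b.begin(), b.size(), buf);
}

// [[Rcpp::export(name = ".osa_dist_matrix_cpp")]]
IntegerMatrix osa_dist_matrix_cpp(List seqs) {
    const int n = seqs.size();
    std::vector<std::vector<int>> xs(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector v = seqs[i];
        xs[i].assign(v.begin(), v.end());
    }
    IntegerMatrix out(n, n);
    std::vector<int> buf;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            const int d = osa_core(xs[i].data(), (int)xs[i].size(),
                                   xs[j].data(), (int)xs[j].size(), buf);
            out(i, j) = d; out(j, i) = d;
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}

// ---- independent oracle: memoized recursion on the OSA recurrence ----
// Written top-down over prefix lengths, separately from the row-rolling
// matrix loop above, for equivalence checking.

#define ORACLE_MAX 16

struct OracleCtx {
    const int *a, *b;
    int memo[ORACLE_MAX + 1][ORACLE_MAX + 1];
};

static int oracle_rec(OracleCtx &c, int i, int j) {
    if (i == 0) return j;
    if (j == 0) return i;
    int &m = c.memo[i][j];
    if (m >= 0) return m;
    int d = oracle_rec(c, i - 1, j - 1) + (c.a[i - 1] == c.b[j - 1] ? 0 : 1);
    int d2 = oracle_rec(c, i - 1, j) + 1;
    if (d2 < d) d = d2;
    d2 = oracle_rec(c, i, j - 1) + 1;
    if (d2 < d) d = d2;
    if (i > 1 && j > 1 && c.a[i - 1] == c.b[j - 2] && c.a[i - 2] == c.b[j - 1]) {
        d2 = oracle_rec(c, i - 2, j - 2) + 1;
        if (d2 < d) d = d2;
    }
    return m = d;
}

// [[Rcpp::export(name = ".osa_oracle_cpp")]]
int osa_oracle_cpp(IntegerVector a, IntegerVector b) {
    if (a.size() > ORACLE_MAX || b.size() > ORACLE_MAX)
        stop("oracle limited to token strings of length <= %d", ORACLE_MAX);
    OracleCtx c;
    c.a = a.begin(); c.b = b.begin();
    std::memset(c.memo, -1, sizeof(c.memo));
    return oracle_rec(c, a.size(), b.size());
}

// Exhaustive equivalence harness: enumerate every token string of length
// 0..max_len over an alphabet of n_tokens symbols and compare the matrix
// implementation with the recursive oracle on every ordered pair.
// Returns c(n_strings, n_pairs, n_mismatches).
// [[Rcpp::export(name = ".osa_exhaustive_check_cpp")]]
NumericVector osa_exhaustive_check_cpp(int n_tokens, int max_len) {
    if (max_len > 8 || n_tokens > 8) stop("harness limited to small spaces");
    std::vector<std::vector<int>> strs;
    strs.push_back({});
    size_t lo = 0;
    for (int len = 1; len <= max_len; ++len) {
        const size_t hi = strs.size();
        for (size_t k = lo; k < hi; ++k)
            for (int t = 1; t <= n_tokens; ++t) {
                std::vector<int> s = strs[k];
                s.push_back(t);
                strs.push_back(std::move(s));
            }
        lo = hi;
    }
    const size_t n = strs.size();
    double n_pairs = 0, n_bad = 0;
    std::vector<int> buf;
    OracleCtx c;
    for (size_t i = 0; i < n; ++i) {
        for (size_t j = 0; j < n; ++j) {
            const int d = osa_core(strs[i].data(), (int)strs[i].size(),
                                   strs[j].data(), (int)strs[j].size(), buf);
            c.a = strs[i].data(); c.b = strs[j].data();
            std::memset(c.memo, -1, sizeof(c.memo));
            const int o = oracle_rec(c, (int)strs[i].size(), (int)strs[j].size());
            if (d != o) ++n_bad;
            ++n_pairs;
        }
        if (i % 32 == 0) Rcpp::checkUserInterrupt();
    }
    return NumericVector::create((double)n, n_pairs, n_bad);
}
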