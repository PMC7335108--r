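#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment under match +1 / mismatch 0 /
// linear gap -1, reporting percent identity as
//   100 * matches / alignment columns (end gaps included).
//
// Among co-optimal alignments the one with the most matches is taken;
// the DP therefore carries (score, matches) with lexicographic max.
// Given optimal score S and matches M the column count is determined:
//   S = M - (la + lb - 2 * paired)  =>  columns = (la + lb + M - S) / 2
// so no traceback is needed and the value is symmetric in (a, b).

static double nw_identity_core(const std::string &a, const std::string &b) {
    const int la = (int)a.size(), lb = (int)b.size();
    std::vector<int> Sprev(lb + 1), Mprev(lb + 1), Scur(lb + 1), Mcur(lb + 1);
    for (int j = 0; j <= lb; ++j) { Sprev[j] = -j; Mprev[j] = 0; }
    for (int i = 1; i <= la; ++i) {
        Scur[0] = -i; Mcur[0] = 0;
        const char ai = a[i - 1];
        for (int j = 1; j <= lb; ++j) {
            const int m = (ai == b[j - 1]) ? 1 : 0;
            int s = Sprev[j - 1] + m, mm = Mprev[j - 1] + m;   // diagonal
            int s2 = Sprev[j] - 1, m2 = Mprev[j];              // gap in b
            if (s2 > s || (s2 == s && m2 > mm)) { s = s2; mm = m2; }
            s2 = Scur[j - 1] - 1; m2 = Mcur[j - 1];            // gap in a
            if (s2 > s || (s2 == s && m2 > mm)) { s = s2; mm = m2; }
            Scur[j] = s; Mcur[j] = mm;
        }
        std::swap(Sprev, Scur); std::swap(Mprev, Mcur);
    }
    const int S = Sprev[lb], M = Mprev[lb];
    const double columns = (la + lb + M - S) / 2.0;
    return columns > 0 ? 100.0 * M / columns : 100.0;
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
    if (a.empty() || b.empty())
        stop("sequences must be non-empty");
    return nw_identity_core(a, b);
}

// Batch identities of every query against every reference. Pairs whose
// length ratio caps the identity below `min_identity` are skipped and
// reported as that (strict) upper bound: matches <= min(la, lb) and
// columns >= max(la, lb), so identity <= 100 * min / max. With
// min_identity = 0 every cell is computed exactly.
// [[Rcpp::export(name = ".nw_identity_batch_cpp")]]
NumericMatrix nw_identity_batch_cpp(CharacterVector queries,
                                    CharacterVector refs,
                                    double min_identity = 0.0) {
    const int nq = queries.size(), nr = refs.size();
    std::vector<std::string> qs(nq), rs(nr);
    for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
    NumericMatrix out(nq, nr);
    for (int i = 0; i < nq; ++i) {
        const int la = (int)qs[i].size();
        for (int j = 0; j < nr; ++j) {
            const int lb = (int)rs[j].size();
            const int mn = la < lb ? la : lb, mx = la < lb ? lb : la;
            const double ub = mx > 0 ? 100.0 * mn / mx : 100.0;
            out(i, j) = (ub < min_identity) ? ub : nw_identity_core(qs[i], rs[j]);
        }
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
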