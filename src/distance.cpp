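#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Unit-cost Levenshtein distance between two integer-coded sequences.
// Two-row dynamic programme; sequences need not have equal length.
static int lev_dp(const std::vector<int>& a, const std::vector<int>& b,
                  std::vector<int>& prev, std::vector<int>& curr) {
    const int na = a.size(), nb = b.size();
    prev.resize(nb + 1);
    curr.resize(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
        curr[0] = i;
        for (int j = 1; j <= nb; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = curr[j - 1] + 1;
            curr[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, curr);
    }
    return prev[nb];
}

static std::vector<std::vector<int> > rows_of(const IntegerMatrix& m) {
    std::vector<std::vector<int> > out(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
        out[i].resize(m.ncol());
        for (int j = 0; j < m.ncol(); ++j) out[i][j] = m(i, j);
    }
    return out;
}

// [[Rcpp::export]]
int edit_dist_pair_cpp(IntegerVector a, IntegerVector b) {
    std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
    std::vector<int> prev, curr;
    return lev_dp(va, vb, prev, curr);
}

// Cross matrix of edit distances: rows of x vs rows of y.
// [[Rcpp::export]]
IntegerMatrix edit_dist_cross_cpp(IntegerMatrix x, IntegerMatrix y) {
    std::vector<std::vector<int> > vx = rows_of(x), vy = rows_of(y);
    IntegerMatrix out(x.nrow(), y.nrow());
    std::vector<int> prev, curr;
    for (int i = 0; i < x.nrow(); ++i)
        for (int j = 0; j < (int)vy.size(); ++j)
            out(i, j) = lev_dp(vx[i], vy[j], prev, curr);
    return out;
}

// Tag-tag edit distance of each row of x against the reference rows s:
// the minimum distance to any member of s distinct from the query.
// Identical sequences (distance 0) are excluded per the TTE definition;
// NA is returned when s holds no distinct member (infinity sentinel).
// [[Rcpp::export]]
IntegerVector tte_cpp(IntegerMatrix x, IntegerMatrix s) {
    std::vector<std::vector<int> > vx = rows_of(x), vs = rows_of(s);
    IntegerVector out(x.nrow());
    std::vector<int> prev, curr;
    for (int i = 0; i < (int)vx.size(); ++i) {
        int best = NA_INTEGER;
        for (int j = 0; j < (int)vs.size(); ++j) {
            int d = lev_dp(vx[i], vs[j], prev, curr);
            if (d == 0) continue;  // u_i != v_j requirement
            if (best == NA_INTEGER || d < best) best = d;
            if (best == 1) break;  // cannot get lower for distinct words
        }
        out[i] = best;
    }
    return out;
}

// Longest homopolymer run per row.
// [[Rcpp::export]]
IntegerVector longest_run_cpp(IntegerMatrix x) {
    IntegerVector out(x.nrow());
    for (int i = 0; i < x.nrow(); ++i) {
        int best = 1, run = 1;
        for (int j = 1; j < x.ncol(); ++j) {
            run = (x(i, j) == x(i, j - 1)) ? run + 1 : 1;
            if (run > best) best = run;
        }
        out[i] = x.ncol() == 0 ? 0 : best;
    }
    return out;
}
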