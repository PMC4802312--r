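#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sequences handled here are orderings of distinct column indices (rows of the
// index matrix, or consensus column sequences drawn from them).  Because all
// elements are distinct, the length of the longest common subsequence of a
// sequence `a` and an ordering `b` equals the length of the longest strictly
// increasing run of a's elements mapped to their positions in `b`.  Length-only
// scans therefore use O(len log len) patience sorting; the actual subsequence,
// when needed, is recovered by the O(la*lb) dynamic program with a fixed
// traceback so results are bit-reproducible.

namespace {

int lis_length(const std::vector<int>& x) {
    std::vector<int> tails;
    tails.reserve(x.size());
    for (size_t i = 0; i < x.size(); ++i) {
        std::vector<int>::iterator it =
            std::lower_bound(tails.begin(), tails.end(), x[i]);
        if (it == tails.end()) tails.push_back(x[i]);
        else *it = x[i];
    }
    return (int)tails.size();
}

// positions (0-based) of each column value 1..m within ordering `ord`
void fill_pos(const int* ord, int m, std::vector<int>& pos) {
    for (int p = 0; p < m; ++p) pos[ord[p]] = p;
}

// LCS length of sequence a against an ordering with position table pos
int lcs_len_pos(const int* a, int la, const std::vector<int>& pos) {
    std::vector<int> t(la);
    for (int i = 0; i < la; ++i) t[i] = pos[a[i]];
    return lis_length(t);
}

// as above but against the reversed ordering (positions negated)
int lcs_len_pos_rev(const int* a, int la, const std::vector<int>& pos) {
    std::vector<int> t(la);
    for (int i = 0; i < la; ++i) t[i] = -pos[a[i]];
    return lis_length(t);
}

// Full DP with deterministic traceback.  On a match the diagonal is always
// taken (optimal for distinct elements); otherwise the move goes to the cell
// with the larger value, preferring a step in `a` on ties.
std::vector<int> lcs_traceback(const int* a, int la, const int* b, int lb) {
    std::vector<int> L((size_t)(la + 1) * (lb + 1), 0);
    const size_t W = (size_t)lb + 1;
    for (int i = 1; i <= la; ++i) {
        for (int j = 1; j <= lb; ++j) {
            if (a[i - 1] == b[j - 1])
                L[i * W + j] = L[(i - 1) * W + (j - 1)] + 1;
            else
                L[i * W + j] = std::max(L[(i - 1) * W + j], L[i * W + (j - 1)]);
        }
    }
    std::vector<int> seq;
    int i = la, j = lb;
    while (i > 0 && j > 0) {
        if (a[i - 1] == b[j - 1]) {
            seq.push_back(a[i - 1]);
            --i; --j;
        } else if (L[(i - 1) * W + j] >= L[i * W + (j - 1)]) {
            --i;
        } else {
            --j;
        }
    }
    std::reverse(seq.begin(), seq.end());
    return seq;
}

} // namespace

// [[Rcpp::export(name = ".lcs_seq_cpp")]]
IntegerVector lcs_seq_cpp(IntegerVector a, IntegerVector b) {
    std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
    std::vector<int> seq = lcs_traceback(av.data(), (int)av.size(),
                                         bv.data(), (int)bv.size());
    return wrap(seq);
}

// LCS lengths of paired permutations (row i of A against row i of B)
// [[Rcpp::export(name = ".lcs_pair_lengths_cpp")]]
IntegerVector lcs_pair_lengths_cpp(IntegerMatrix A, IntegerMatrix B) {
    int N = A.nrow(), m = A.ncol();
    if (B.nrow() != N || B.ncol() != m)
        stop("permutation matrices must have identical dimensions");
    IntegerVector out(N);
    std::vector<int> pos(m + 1), arow(m);
    for (int i = 0; i < N; ++i) {
        std::vector<int> brow(m);
        for (int p = 0; p < m; ++p) {
            arow[p] = A(i, p);
            brow[p] = B(i, p);
        }
        fill_pos(brow.data(), m, pos);
        out[i] = lcs_len_pos(arow.data(), m, pos);
    }
    return out;
}

// All within-group row pairs of the index matrix whose LCS reaches the
// significance threshold, with the chosen subsequence for each.
// Y: n x m, rows are orderings of 1..m.  groups: list of 1-based row indices.
// [[Rcpp::export(name = ".generate_seeds_cpp")]]
List generate_seeds_cpp(IntegerMatrix Y, List groups, int threshold) {
    int n = Y.nrow(), m = Y.ncol();
    // copy rows once into contiguous storage
    std::vector<int> rows((size_t)n * m);
    for (int i = 0; i < n; ++i)
        for (int p = 0; p < m; ++p) rows[(size_t)i * m + p] = Y(i, p);

    std::vector<int> ra, rb, len;
    std::vector<int> pos(m + 1);
    for (int g = 0; g < groups.size(); ++g) {
        IntegerVector grp = groups[g];
        std::vector<int> idx(grp.begin(), grp.end());
        std::sort(idx.begin(), idx.end());
        for (size_t u = 0; u + 1 < idx.size(); ++u) {
            int i = idx[u] - 1;
            for (size_t v = u + 1; v < idx.size(); ++v) {
                int j = idx[v] - 1;
                fill_pos(&rows[(size_t)j * m], m, pos);
                int L = lcs_len_pos(&rows[(size_t)i * m], m, pos);
                if (L >= threshold) {
                    ra.push_back(i + 1);
                    rb.push_back(j + 1);
                    len.push_back(L);
                }
            }
        }
    }
    List seqs(ra.size());
    for (size_t s = 0; s < ra.size(); ++s) {
        std::vector<int> seq = lcs_traceback(&rows[(size_t)(ra[s] - 1) * m], m,
                                             &rows[(size_t)(rb[s] - 1) * m], m);
        seqs[s] = wrap(seq);
    }
    return List::create(_["row_a"] = wrap(ra), _["row_b"] = wrap(rb),
                        _["length"] = wrap(len), _["sequence"] = seqs);
}

// Greedy strict order-preserving growth from a two-row seed.  Adds, at each
// stage, the row whose ordering retains the longest consensus subsequence
// (ties: smaller row index); the consensus shrinks to that subsequence.  Growth
// stops, rolling back nothing (the candidate is simply not committed), when the
// block would have more rows than consensus columns or when no candidate
// retains at least 3 columns.
// [[Rcpp::export(name = ".grow_strict_cpp")]]
List grow_strict_cpp(IntegerMatrix Y, int row_a, int row_b,
                     IntegerVector seed_seq) {
    int n = Y.nrow(), m = Y.ncol();
    std::vector<int> rows((size_t)n * m);
    for (int i = 0; i < n; ++i)
        for (int p = 0; p < m; ++p) rows[(size_t)i * m + p] = Y(i, p);

    std::vector<bool> in_block(n, false);
    std::vector<int> members;
    members.push_back(row_a - 1);
    members.push_back(row_b - 1);
    in_block[row_a - 1] = in_block[row_b - 1] = true;
    std::vector<int> cons(seed_seq.begin(), seed_seq.end());

    std::vector<int> pos(m + 1);
    for (;;) {
        int best_len = -1, best_row = -1;
        for (int g = 0; g < n; ++g) {
            if (in_block[g]) continue;
            fill_pos(&rows[(size_t)g * m], m, pos);
            int L = lcs_len_pos(cons.data(), (int)cons.size(), pos);
            if (L > best_len) {
                best_len = L;
                best_row = g;
            }
        }
        if (best_row < 0 || best_len < 3) break;
        if ((int)members.size() + 1 > best_len) break; // rows would exceed columns
        cons = lcs_traceback(cons.data(), (int)cons.size(),
                             &rows[(size_t)best_row * m], m);
        members.push_back(best_row);
        in_block[best_row] = true;
    }
    std::sort(members.begin(), members.end());
    for (size_t i = 0; i < members.size(); ++i) members[i] += 1;
    return List::create(_["rows"] = wrap(members), _["cols"] = wrap(cons));
}

// For every row of Y, the LCS length of `cons` against the row's ordering
// (column 1) and against its reverse (column 2).
// [[Rcpp::export(name = ".consensus_lcs_scan_cpp")]]
IntegerMatrix consensus_lcs_scan_cpp(IntegerMatrix Y, IntegerVector cons) {
    int n = Y.nrow(), m = Y.ncol();
    std::vector<int> cv(cons.begin(), cons.end());
    IntegerMatrix out(n, 2);
    std::vector<int> pos(m + 1), row(m);
    for (int g = 0; g < n; ++g) {
        for (int p = 0; p < m; ++p) row[p] = Y(g, p);
        fill_pos(row.data(), m, pos);
        out(g, 0) = lcs_len_pos(cv.data(), (int)cv.size(), pos);
        out(g, 1) = lcs_len_pos_rev(cv.data(), (int)cv.size(), pos);
    }
    return out;
}
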