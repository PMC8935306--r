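#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Unit-cost global alignment primitives shared by read clustering, consensus
// calling and the center-star MSA. Banded variants keep read-scale work
// cheap; the band is widened automatically to cover the length difference,
// and band <= 0 means full dynamic programming.

static const int BIG = std::numeric_limits<int>::max() / 4;

// Banded global edit distance, two rows with boundary sentinels.
static int edit_distance_band(const std::string& a, const std::string& b, int band) {
    const int la = a.size(), lb = b.size();
    if (la == 0) return lb;
    if (lb == 0) return la;
    const int w = (band <= 0) ? (la + lb) : band + std::abs(la - lb);
    std::vector<int> prev(lb + 2, BIG), cur(lb + 2, BIG);
    for (int j = 0; j <= std::min(lb, w); ++j) prev[j] = j;
    for (int i = 1; i <= la; ++i) {
        const int lo = std::max(1, i - w), hi = std::min(lb, i + w);
        cur[lo - 1] = (lo == 1) ? i : BIG;
        const char ai = a[i - 1];
        for (int j = lo; j <= hi; ++j) {
            int m = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
            const int d = prev[j] + 1;
            if (d < m) m = d;
            const int ins = cur[j - 1] + 1;
            if (ins < m) m = ins;
            cur[j] = m;
        }
        if (hi < lb + 1) cur[hi + 1] = BIG;
        std::swap(prev, cur);
    }
    return prev[lb];
}

// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b, int band = 0) {
    return edit_distance_band(a, b, band);
}

// Global alignment with traceback; banded when band > 0.
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, int band = 0) {
    const int la = a.size(), lb = b.size();
    const int w = (band <= 0) ? (la + lb) : band + std::abs(la - lb);
    const int W = lb + 1;
    std::vector<int> dp((la + 1) * W, BIG);
    std::vector<unsigned char> tb((la + 1) * W, 0);
    for (int j = 0; j <= std::min(lb, w); ++j) { dp[j] = j; tb[j] = 2; }
    for (int i = 0; i <= std::min(la, w); ++i) { dp[i * W] = i; tb[i * W] = 1; }
    tb[0] = 0;
    for (int i = 1; i <= la; ++i) {
        const int lo = std::max(1, i - w), hi = std::min(lb, i + w);
        const char ai = a[i - 1];
        for (int j = lo; j <= hi; ++j) {
            int best = dp[(i - 1) * W + j - 1] + (ai == b[j - 1] ? 0 : 1);
            unsigned char t = 0;
            const int d = dp[(i - 1) * W + j] + 1;
            if (d < best) { best = d; t = 1; }
            const int ins = dp[i * W + j - 1] + 1;
            if (ins < best) { best = ins; t = 2; }
            dp[i * W + j] = best; tb[i * W + j] = t;
        }
    }
    std::string aa, bb;
    aa.reserve(la + lb); bb.reserve(la + lb);
    int i = la, j = lb;
    while (i > 0 || j > 0) {
        const unsigned char t = tb[i * W + j];
        if (i > 0 && j > 0 && t == 0) {
            aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && (t == 1 || j == 0)) {
            aa.push_back(a[i - 1]); bb.push_back('-'); --i;
        } else {
            aa.push_back('-'); bb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(aa.begin(), aa.end());
    std::reverse(bb.begin(), bb.end());
    return List::create(_["dist"] = dp[la * W + lb],
                        _["a"] = aa, _["b"] = bb,
                        _["length"] = (int)aa.size());
}

// Distance from every read to every centroid (banded).
// [[Rcpp::export(name = ".dist_to_centroids_cpp")]]
IntegerMatrix dist_to_centroids_cpp(CharacterVector reads, CharacterVector cents, int band) {
    const int n = reads.size(), k = cents.size();
    std::vector<std::string> cs(k);
    for (int c = 0; c < k; ++c) cs[c] = as<std::string>(cents[c]);
    IntegerMatrix out(n, k);
    for (int i = 0; i < n; ++i) {
        const std::string r = as<std::string>(reads[i]);
        for (int c = 0; c < k; ++c) out(i, c) = edit_distance_band(r, cs[c], band);
    }
    return out;
}

// All-pairs banded edit distance.
// [[Rcpp::export(name = ".pairwise_edit_cpp")]]
IntegerMatrix pairwise_edit_cpp(CharacterVector seqs, int band) {
    const int n = seqs.size();
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            const int d = edit_distance_band(ss[i], ss[j], band);
            out(i, j) = d; out(j, i) = d;
        }
    return out;
}

// p-distance on aligned rows: proportion of differing sites over columns
// where both rows are A/C/G/T (gaps and Ns excluded pairwise). Optional
// per-column weights (bootstrap resampling); empty weights = all ones.
// [[Rcpp::export(name = ".pdist_aln_cpp")]]
List pdist_aln_cpp(CharacterVector rows, IntegerVector weights) {
    const int n = rows.size();
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) ss[i] = as<std::string>(rows[i]);
    const int L = n ? (int)ss[0].size() : 0;
    for (int i = 1; i < n; ++i)
        if ((int)ss[i].size() != L) stop("alignment rows differ in length");
    const bool wt = weights.size() > 0;
    if (wt && weights.size() != L) stop("weights length must equal alignment width");
    NumericMatrix p(n, n), comp(n, n);
    std::vector<unsigned char> ok(n * L);
    for (int i = 0; i < n; ++i)
        for (int c = 0; c < L; ++c) {
            const char x = std::toupper(ss[i][c]);
            ok[i * L + c] = (x == 'A' || x == 'C' || x == 'G' || x == 'T');
        }
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double diff = 0, tot = 0;
            const std::string &x = ss[i], &y = ss[j];
            const unsigned char *oi = &ok[i * L], *oj = &ok[j * L];
            for (int c = 0; c < L; ++c) {
                if (!oi[c] || !oj[c]) continue;
                const double wv = wt ? (double)weights[c] : 1.0;
                if (wv == 0) continue;
                tot += wv;
                if (std::toupper(x[c]) != std::toupper(y[c])) diff += wv;
            }
            const double pv = tot > 0 ? diff / tot : NA_REAL;
            p(i, j) = pv; p(j, i) = pv;
            comp(i, j) = tot; comp(j, i) = tot;
        }
    }
    return List::create(_["p"] = p, _["n"] = comp);
}
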