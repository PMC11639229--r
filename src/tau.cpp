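#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// pairs tied within runs of equal values; v must be sorted
static double tie_pairs(const std::vector<double>& v) {
    double t = 0.0;
    std::size_t i = 0, n = v.size();
    while (i < n) {
        std::size_t j = i;
        while (j < n && v[j] == v[i]) ++j;
        double c = static_cast<double>(j - i);
        t += c * (c - 1.0) / 2.0;
        i = j;
    }
    return t;
}

// merge sort counting exchanges (Knight 1966)
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          std::size_t lo, std::size_t hi) {
    if (hi - lo < 2) return 0.0;
    std::size_t mid = lo + (hi - lo) / 2;
    double sw = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
    std::size_t i = lo, j = mid, k = lo;
    while (i < mid && j < hi) {
        if (y[j] < y[i]) {
            sw += static_cast<double>(mid - i);
            buf[k++] = y[j++];
        } else {
            buf[k++] = y[i++];
        }
    }
    while (i < mid) buf[k++] = y[i++];
    while (j < hi)  buf[k++] = y[j++];
    std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    return sw;
}

//' Tie-corrected Kendall tau-b in O(n log n)
//'
//' @param x,y numeric vectors of equal length (no NAs).
//' @return tau-b; NaN when either vector is constant.
//' @keywords internal
// [[Rcpp::export]]
double tau_b_knight(NumericVector x, NumericVector y) {
    std::size_t n = x.size();
    if (n != static_cast<std::size_t>(y.size()))
        stop("x and y must have equal length");
    if (n < 2) stop("need at least two observations");

    std::vector<std::size_t> idx(n);
    for (std::size_t i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](std::size_t a, std::size_t b) {
        if (x[a] != x[b]) return x[a] < x[b];
        return y[a] < y[b];
    });

    std::vector<double> xs(n), ys(n);
    for (std::size_t i = 0; i < n; ++i) { xs[i] = x[idx[i]]; ys[i] = y[idx[i]]; }

    double n0 = static_cast<double>(n) * (n - 1.0) / 2.0;
    double n1 = tie_pairs(xs);

    // joint ties: runs of equal (x, y)
    double n3 = 0.0;
    {
        std::size_t i = 0;
        while (i < n) {
            std::size_t j = i;
            while (j < n && xs[j] == xs[i] && ys[j] == ys[i]) ++j;
            double c = static_cast<double>(j - i);
            n3 += c * (c - 1.0) / 2.0;
            i = j;
        }
    }

    std::vector<double> buf(n);
    double swaps = merge_count(ys, buf, 0, n);  // ys now sorted
    double n2 = tie_pairs(ys);

    double S = n0 - n1 - n2 + n3 - 2.0 * swaps;
    double denom = std::sqrt((n0 - n1) * (n0 - n2));
    if (denom == 0.0) return R_NaN;
    return S / denom;
}
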