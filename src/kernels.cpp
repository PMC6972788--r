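#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of v[0..n-1], destroys v
static double med_inplace(std::vector<double>& v) {
    const std::size_t n = v.size();
    const std::size_t h = n / 2;
    std::nth_element(v.begin(), v.begin() + h, v.end());
    double m = v[h];
    if (n % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + h);
        m = (m + lo) / 2.0;
    }
    return m;
}

// column medians of a numeric matrix (no NA handling; callers guarantee
// finite input)
// [[Rcpp::export]]
NumericVector cpp_col_medians(NumericMatrix x) {
    const int nr = x.nrow(), nc = x.ncol();
    if (nr == 0) stop("cpp_col_medians: empty matrix");
    NumericVector out(nc);
    std::vector<double> buf(nr);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
        out[j] = med_inplace(buf);
        buf.resize(nr);
    }
    return out;
}

// column maxima of |x|
// [[Rcpp::export]]
NumericVector cpp_col_max_abs(NumericMatrix x) {
    const int nr = x.nrow(), nc = x.ncol();
    NumericVector out(nc);
    for (int j = 0; j < nc; ++j) {
        double m = 0.0;
        for (int i = 0; i < nr; ++i) {
            double a = std::abs(x(i, j));
            if (a > m) m = a;
        }
        out[j] = m;
    }
    return out;
}

// K medians of uniform random subsets (without replacement, size `size`) of
// `delta`; uses R's RNG via unif_rand so draws are reproducible under
// set.seed
// [[Rcpp::export]]
NumericVector cpp_random_set_medians(NumericVector delta, int size, int K) {
    const int n = delta.size();
    if (size < 1 || size > n)
        stop("cpp_random_set_medians: set size outside 1..n");
    NumericVector out(K);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<double> buf(size);
    for (int k = 0; k < K; ++k) {
        // partial Fisher-Yates; carrying the permuted state between draws
        // keeps each draw uniform
        for (int j = 0; j < size; ++j) {
            int r = j + (int)(unif_rand() * (n - j));
            if (r >= n) r = n - 1;  // guard against unif_rand() == 1.0
            std::swap(idx[j], idx[r]);
            buf[j] = delta[idx[j]];
        }
        out[k] = med_inplace(buf);
        buf.resize(size);
    }
    return out;
}
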