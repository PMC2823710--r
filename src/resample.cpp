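#include <Rcpp.h>
using namespace Rcpp;

// Resampling core for confidence attribution. Uses R's RNG (unif_rand)
// so results are reproducible from set.seed() on the R side.

// population mean/sd of subset = value v plus vals[pool[0..m-2]]
static inline void subset_stats(double v, const double *vals,
                                const int *pool, int m1,
                                double &mu, double &sd) {
    double s = v, ss = v * v;
    for (int j = 0; j < m1; ++j) {
        double x = vals[pool[j]];
        s += x;
        ss += x * x;
    }
    int m = m1 + 1;
    mu = s / m;
    double var = ss / m - mu * mu;
    sd = var > 0 ? std::sqrt(var) : 0.0;
}

static inline bool degenerate(double sd, double mu) {
    return sd <= 1e-12 * std::max(1.0, std::fabs(mu));
}

// draw m items into the front of pool (size n) by partial Fisher-Yates
static inline void draw_front(std::vector<int> &pool, int m) {
    int n = (int) pool.size();
    for (int j = 0; j < m; ++j) {
        int r = j + (int) (unif_rand() * (n - j));
        if (r >= n) r = n - 1;
        std::swap(pool[j], pool[r]);
    }
}

// [[Rcpp::export(name = ".cppCalibrate")]]
NumericVector cpp_calibrate(NumericVector values, int nRuns,
                            int subsetSize) {
    int n = values.size();
    int iMax = 0, iMin = 0;
    for (int i = 1; i < n; ++i) {
        if (values[i] > values[iMax]) iMax = i;
        if (values[i] < values[iMin]) iMin = i;
    }
    std::vector<int> pool;
    pool.reserve(n);
    for (int i = 0; i < n; ++i)
        if (i != iMax && i != iMin) pool.push_back(i);
    int m1 = subsetSize - 2;           // random picks beyond the extremes
    if (m1 > (int) pool.size()) m1 = (int) pool.size();
    double kHigh = R_PosInf, kLow = R_NegInf;
    std::vector<int> sub(m1 + 1);
    const double *vals = values.begin();
    for (int run = 0; run < nRuns; ++run) {
        draw_front(pool, m1);
        for (int j = 0; j < m1; ++j) sub[j] = pool[j];
        sub[m1] = iMin;                 // max enters via subset_stats' v
        double mu, sd;
        subset_stats(values[iMax], vals, sub.data(), m1 + 1, mu, sd);
        if (degenerate(sd, mu)) continue;
        double kmax = (values[iMax] - mu) / sd;
        double kmin = (values[iMin] - mu) / sd;
        if (kmax < kHigh) kHigh = kmax;
        if (kmin > kLow) kLow = kmin;
    }
    return NumericVector::create(kHigh, kLow);
}

static inline double gamma_inc(double k, double kHigh, double kLow) {
    if (k >= kHigh) return 1.0;
    if (k <= kLow) return -1.0;
    return k >= 0 ? k / kHigh : -k / kLow;
}

// [[Rcpp::export(name = ".cppAttribute")]]
NumericVector cpp_attribute(NumericVector values, int nTrial,
                            int subsetSize, double kHigh, double kLow) {
    int n = values.size();
    int m1 = subsetSize - 1;           // random companions of residue i
    if (m1 > n - 1) m1 = n - 1;
    NumericVector rho(n);
    const double *vals = values.begin();
    std::vector<int> pool(n - 1);
    for (int i = 0; i < n; ++i) {
        int p = 0;
        for (int j = 0; j < n; ++j)
            if (j != i) pool[p++] = j;
        double alpha = 0.0;
        for (int t = 0; t < nTrial; ++t) {
            draw_front(pool, m1);
            double mu, sd;
            subset_stats(values[i], vals, pool.data(), m1, mu, sd);
            if (degenerate(sd, mu)) continue;   // Gamma = 0
            alpha += gamma_inc((values[i] - mu) / sd, kHigh, kLow);
        }
        rho[i] = alpha / nTrial;
    }
    return rho;
}
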