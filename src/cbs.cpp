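#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core: maximal two-sample t statistic over
// circular arc boundaries, and its permutation p-value.
//
// A candidate split of a segment of length n is a pair of boundaries
// 0 < b0 < b1 <= n defining the arc (b0, b1].  Every resulting piece
// (left [1..b0], arc, right [b1+1..n]) must contain at least min_width
// observations (an empty right piece, b1 == n, is a plain two-piece
// split).  Requiring b0 > 0 makes the representation canonical: a
// two-piece split at cut c appears once, as the arc (c, n], never as the
// equivalent (0, c].  The statistic compares the
// arc mean against the complement mean, scaled by the segment SD, which
// is permutation-invariant and therefore cancels in the p-value but is
// kept so the reported t is on the usual scale.
//
// For arc length k with sum Sa, total sum T and segment SD s,
//   t = |Sa/k - (T-Sa)/(n-k)| / (s * sqrt(1/k + 1/(n-k)))
//     = |Sa * a[k] - b[k]|
// with a[k] = (1/k + 1/(n-k)) * w[k], b[k] = T/(n-k) * w[k],
// w[k] = 1 / (s * sqrt(1/k + 1/(n-k))).  a and b depend only on k and on
// permutation-invariant quantities, so they are precomputed once per
// segment and shared by all permutations.

struct ScanTables {
    int n;
    int min_width;
    std::vector<double> a, b;  // indexed by arc length k
};

static ScanTables make_tables(const double* x, int n, int min_width,
                              double* s_out)
{
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += x[i];
    mean /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
        double d = x[i] - mean;
        ss += d * d;
    }
    double s = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
    *s_out = s;

    ScanTables tb;
    tb.n = n;
    tb.min_width = min_width;
    tb.a.assign(n + 1, 0.0);
    tb.b.assign(n + 1, 0.0);
    if (s > 0.0) {
        double total = mean * n;
        for (int k = 1; k < n; ++k) {
            double inv = 1.0 / k + 1.0 / (n - k);
            double w = 1.0 / (s * std::sqrt(inv));
            tb.a[k] = inv * w;
            tb.b[k] = total / (n - k) * w;
        }
    }
    return tb;
}

static void prefix_sums(const double* x, int n, std::vector<double>& S)
{
    S.resize(n + 1);
    S[0] = 0.0;
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

static double scan_max(const std::vector<double>& S, const ScanTables& tb,
                       int* best_b0, int* best_b1)
{
    const int n = tb.n, mw = tb.min_width;
    double best_t = 0.0;
    *best_b0 = -1;
    *best_b1 = -1;
    for (int b0 = mw; b0 <= n - mw; ++b0) {
        for (int b1 = b0 + mw; b1 <= n; ++b1) {
            int right = n - b1;
            if (right != 0 && right < mw) continue;
            int k = b1 - b0;
            double t = std::fabs((S[b1] - S[b0]) * tb.a[k] - tb.b[k]);
            if (t > best_t) {
                best_t = t;
                *best_b0 = b0;
                *best_b1 = b1;
            }
        }
    }
    return best_t;
}

// does any admissible arc reach the threshold?  (early exit)
static bool scan_exceeds(const std::vector<double>& S, const ScanTables& tb,
                         double thresh)
{
    const int n = tb.n, mw = tb.min_width;
    for (int b0 = mw; b0 <= n - mw; ++b0) {
        for (int b1 = b0 + mw; b1 <= n; ++b1) {
            int right = n - b1;
            if (right != 0 && right < mw) continue;
            int k = b1 - b0;
            double t = std::fabs((S[b1] - S[b0]) * tb.a[k] - tb.b[k]);
            if (t >= thresh) return true;
        }
    }
    return false;
}

// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_width)
{
    int n = x.size();
    double s;
    ScanTables tb = make_tables(x.begin(), n, min_width, &s);
    std::vector<double> S;
    prefix_sums(x.begin(), n, S);
    int b0, b1;
    double t = (s > 0.0) ? scan_max(S, tb, &b0, &b1) : (b0 = b1 = -1, 0.0);
    return List::create(_["b0"] = b0, _["b1"] = b1, _["t"] = t);
}

// Permutation p-value with early stopping: once the exceedance count
// rules out p <= alpha the remaining permutations cannot change the
// accept/reject decision and are skipped.  Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cbs_perm_cpp(NumericVector x, int min_width, int nperm, double alpha)
{
    int n = x.size();
    double s;
    ScanTables tb = make_tables(x.begin(), n, min_width, &s);
    std::vector<double> S;
    prefix_sums(x.begin(), n, S);
    int b0 = -1, b1 = -1;
    double t_obs = (s > 0.0) ? scan_max(S, tb, &b0, &b1) : 0.0;

    if (t_obs <= 0.0 || b0 < 0) {
        return List::create(_["b0"] = b0, _["b1"] = b1, _["t"] = t_obs,
                            _["p"] = 1.0, _["nperm_used"] = 0);
    }

    std::vector<double> y(x.begin(), x.end());
    std::vector<double> Sp;
    const double cutoff = alpha * (nperm + 1.0);
    const double thresh = t_obs - 1e-12;
    int exceed = 0, done = 0;
    for (int p = 0; p < nperm; ++p) {
        // Fisher-Yates shuffle driven by R's RNG
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(y[i], y[j]);
        }
        prefix_sums(y.data(), n, Sp);
        ++done;
        if (scan_exceeds(Sp, tb, thresh)) {
            ++exceed;
            if (exceed + 1.0 > cutoff) break;  // cannot reach significance
        }
    }
    double pval = (exceed + 1.0) / (done + 1.0);
    return List::create(_["b0"] = b0, _["b1"] = b1, _["t"] = t_obs,
                        _["p"] = pval, _["nperm_used"] = done);
}
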