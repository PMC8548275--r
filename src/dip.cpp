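#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Hartigan & Hartigan dip statistic for unimodality.
//
// The dip of an empirical distribution function F_n is
//   D(F_n) = min_{G unimodal cdf} sup_x | F_n(x) - G(x) |.
// The algorithm iteratively refines a candidate modal interval [low, high],
// computing the greatest convex minorant (GCM) and least concave majorant
// (LCM) of F_n on it, and accumulates the largest deviation of F_n from the
// unimodal envelope outside the modal interval. All deviations are kept in
// count units (multiples of 1/n); the final division by 2n yields the dip.
// Validated during development against an exact linear-programming oracle
// over all mode placements (see tests for frozen oracle values).

static double dip_sorted(const std::vector<double>& x)
{
    const int n = (int) x.size();
    if (n < 2 || x[n - 1] == x[0]) return 0.0;

    // mn[j]: previous touch point of the GCM ending at j (0-based).
    // mj[k]: next touch point of the LCM starting at k.
    std::vector<int> mn(n), mj(n);
    mn[0] = 0;
    for (int j = 1; j < n; ++j) {
        mn[j] = j - 1;
        for (;;) {
            int mnj = mn[j], mnmnj = mn[mnj];
            if (mnj == 0 ||
                (x[j] - x[mnj]) * (mnj - mnmnj) <
                (x[mnj] - x[mnmnj]) * (j - mnj)) break;
            mn[j] = mnmnj;
        }
    }
    mj[n - 1] = n - 1;
    for (int k = n - 2; k >= 0; --k) {
        mj[k] = k + 1;
        for (;;) {
            int mjk = mj[k], mjmjk = mj[mjk];
            if (mjk == n - 1 ||
                (x[k] - x[mjk]) * (mjk - mjmjk) <
                (x[mjk] - x[mjmjk]) * (k - mjk)) break;
            mj[k] = mjmjk;
        }
    }

    std::vector<int> gcm(n + 1), lcm(n + 1); // 1-based lists of touch points
    int low = 0, high = n - 1;
    double dip = 1.0; // in count units; minimum attainable dip is 1/(2n)

    for (;;) {
        // GCM touch points from high down to low.
        gcm[1] = high;
        int l_gcm;
        for (l_gcm = 1; gcm[l_gcm] > low; ++l_gcm)
            gcm[l_gcm + 1] = mn[gcm[l_gcm]];
        int ig = l_gcm, ix = l_gcm - 1;

        // LCM touch points from low up to high.
        lcm[1] = low;
        int l_lcm;
        for (l_lcm = 1; lcm[l_lcm] < high; ++l_lcm)
            lcm[l_lcm + 1] = mj[lcm[l_lcm]];
        int ih = l_lcm, iv = 2;

        // Largest distance between the GCM and the LCM inside [low, high].
        double d = 0.0;
        if (l_gcm != 2 || l_lcm != 2) {
            do {
                int gcmix = gcm[ix], lcmiv = lcm[iv];
                double dx;
                if (gcmix > lcmiv) {
                    // deviation of the LCM touch point from the GCM chord
                    int gcmi1 = gcm[ix + 1];
                    dx = (lcmiv - gcmi1 + 1)
                        - (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1)
                          / (x[gcmix] - x[gcmi1]);
                    ++iv;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
                } else {
                    // deviation of the GCM touch point from the LCM chord
                    int lcmiv1 = lcm[iv - 1];
                    dx = (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1)
                          / (x[lcmiv] - x[lcmiv1])
                        - (gcmix - lcmiv1 - 1);
                    --ix;
                    if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
                }
                if (ix < 1) ix = 1;
                if (iv > l_lcm) iv = l_lcm;
            } while (gcm[ix] != lcm[iv]);
        } else {
            d = 1.0;
        }
        if (d < dip) break;

        // Largest deviation of F_n below the GCM between low and the new low.
        double dip_l = 0.0;
        for (int j = ig; j < l_gcm; ++j) {
            double max_t = 1.0;
            int jb = gcm[j + 1], je = gcm[j];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (jj - jb + 1) - (x[jj] - x[jb]) * C;
                    if (max_t < t) max_t = t;
                }
            }
            if (dip_l < max_t) dip_l = max_t;
        }

        // Largest deviation of F_n above the LCM between the new high and high.
        double dip_u = 0.0;
        for (int j = ih; j < l_lcm; ++j) {
            double max_t = 1.0;
            int jb = lcm[j], je = lcm[j + 1];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (x[jj] - x[jb]) * C - (jj - jb - 1);
                    if (max_t < t) max_t = t;
                }
            }
            if (dip_u < max_t) dip_u = max_t;
        }

        double dipnew = (dip_l < dip_u) ? dip_u : dip_l;
        if (dip < dipnew) dip = dipnew;

        int new_low = gcm[ig], new_high = lcm[ih];
        if (new_low == low && new_high == high) break; // no further refinement
        low = new_low;
        high = new_high;
    }
    return dip / (2.0 * n);
}

//' @useDynLib rachis, .registration = TRUE
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(Rcpp::NumericVector x)
{
    std::vector<double> xs(x.begin(), x.end());
    std::sort(xs.begin(), xs.end());
    return dip_sorted(xs);
}

// Dip statistics of B samples of size n drawn from the standard uniform
// distribution, using R's RNG stream (responds to set.seed()).
// [[Rcpp::export(name = ".dip_null_cpp")]]
Rcpp::NumericVector dip_null_cpp(int n, int B)
{
    Rcpp::NumericVector out(B);
    std::vector<double> xs(n);
    for (int b = 0; b < B; ++b) {
        for (int i = 0; i < n; ++i) xs[i] = R::unif_rand();
        std::sort(xs.begin(), xs.end());
        out[b] = dip_sorted(xs);
    }
    return out;
}
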