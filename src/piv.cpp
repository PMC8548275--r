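#include <Rcpp.h>
#include <cmath>

// Particle image velocimetry by zero-normalized cross-correlation (ZNCC)
// template matching with 3-point parabolic sub-pixel refinement.
//
// Frames are matrices indexed [row = y, col = x]. For each template window
// of side `tmpl` placed on a grid with spacing `step` and fully inside the
// mask, the displacement maximizing the ZNCC against frame_b over integer
// shifts within +/- `search` px is located, then refined independently in x
// and y by fitting a parabola through the peak and its two neighbours.
// Windows whose correlation peak falls below `min_corr`, or whose peak sits
// on the search border, are flagged invalid.

static double zncc(const Rcpp::NumericMatrix& a, const Rcpp::NumericMatrix& b,
                   int y0, int x0, int dy, int dx, int tmpl)
{
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    const int npx = tmpl * tmpl;
    for (int yy = 0; yy < tmpl; ++yy) {
        for (int xx = 0; xx < tmpl; ++xx) {
            double va = a(y0 + yy, x0 + xx);
            double vb = b(y0 + yy + dy, x0 + xx + dx);
            sa += va; sb += vb;
            saa += va * va; sbb += vb * vb; sab += va * vb;
        }
    }
    double cov = sab - sa * sb / npx;
    double va = saa - sa * sa / npx;
    double vb = sbb - sb * sb / npx;
    if (va <= 0 || vb <= 0) return 0.0;
    return cov / std::sqrt(va * vb);
}

static double subpixel(double cm, double c0, double cp)
{
    double denom = cm - 2.0 * c0 + cp;
    if (denom >= 0) return 0.0; // not a proper maximum
    double s = 0.5 * (cm - cp) / denom;
    if (s > 1.0) s = 1.0; else if (s < -1.0) s = -1.0;
    return s;
}

// [[Rcpp::export(name = ".piv_cpp")]]
Rcpp::List piv_cpp(Rcpp::NumericMatrix frame_a, Rcpp::NumericMatrix frame_b,
                   Rcpp::LogicalMatrix mask, int tmpl, int step, int search,
                   double min_corr)
{
    const int ny = frame_a.nrow(), nx = frame_a.ncol();
    std::vector<int> gx, gy;
    for (int x0 = search; x0 + tmpl + search <= nx; x0 += step) gx.push_back(x0);
    for (int y0 = search; y0 + tmpl + search <= ny; y0 += step) gy.push_back(y0);
    const int ngx = (int) gx.size(), ngy = (int) gy.size();

    Rcpp::NumericMatrix u(ngy, ngx), v(ngy, ngx), peak(ngy, ngx);
    Rcpp::LogicalMatrix valid(ngy, ngx);
    Rcpp::NumericVector cx(ngx), cy(ngy);
    for (int i = 0; i < ngx; ++i) cx[i] = gx[i] + (tmpl - 1) / 2.0;
    for (int i = 0; i < ngy; ++i) cy[i] = gy[i] + (tmpl - 1) / 2.0;

    const int w = 2 * search + 1;
    std::vector<double> cc(w * w);

    for (int iy = 0; iy < ngy; ++iy) {
        for (int ix = 0; ix < ngx; ++ix) {
            int x0 = gx[ix], y0 = gy[iy];
            // template must lie fully inside the mask
            bool inside = true;
            for (int yy = 0; yy < tmpl && inside; ++yy)
                for (int xx = 0; xx < tmpl; ++xx)
                    if (!mask(y0 + yy, x0 + xx)) { inside = false; break; }
            if (!inside) {
                valid(iy, ix) = false; u(iy, ix) = NA_REAL; v(iy, ix) = NA_REAL;
                peak(iy, ix) = NA_REAL;
                continue;
            }
            int best_dy = 0, best_dx = 0; double best = -2.0;
            for (int dy = -search; dy <= search; ++dy) {
                for (int dx = -search; dx <= search; ++dx) {
                    double c = zncc(frame_a, frame_b, y0, x0, dy, dx, tmpl);
                    cc[(dy + search) * w + (dx + search)] = c;
                    if (c > best) { best = c; best_dy = dy; best_dx = dx; }
                }
            }
            bool on_border = (std::abs(best_dy) == search ||
                              std::abs(best_dx) == search);
            double du = 0, dv = 0;
            if (!on_border) {
                int r = best_dy + search, c = best_dx + search;
                du = subpixel(cc[r * w + (c - 1)], cc[r * w + c], cc[r * w + (c + 1)]);
                dv = subpixel(cc[(r - 1) * w + c], cc[r * w + c], cc[(r + 1) * w + c]);
            }
            u(iy, ix) = best_dx + du;
            v(iy, ix) = best_dy + dv;
            peak(iy, ix) = best;
            valid(iy, ix) = (!on_border && best >= min_corr);
        }
    }
    return Rcpp::List::create(
        Rcpp::Named("u") = u, Rcpp::Named("v") = v,
        Rcpp::Named("peak") = peak, Rcpp::Named("valid") = valid,
        Rcpp::Named("cx") = cx, Rcpp::Named("cy") = cy);
}
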