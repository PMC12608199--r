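#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Double-double ("dd") arithmetic (~31 significant digits) used to polish
// partition-polynomial roots by Newton iteration on the exact integer
// coefficients, to verify root reconstruction, and to evaluate Vieta sums.
// Coefficients are exact conformation counts (< 2^53) and are therefore
// representable exactly in the high double.

namespace {

struct dd { double hi, lo; };

inline dd dd_make(double h, double l = 0.0) { return {h, l}; }

inline dd two_sum(double a, double b) {
    double s = a + b;
    double bb = s - a;
    double err = (a - (s - bb)) + (b - bb);
    return {s, err};
}

inline dd quick_two_sum(double a, double b) {
    double s = a + b;
    return {s, b - (s - a)};
}

inline dd two_prod(double a, double b) {
    double p = a * b;
    double err = std::fma(a, b, -p);
    return {p, err};
}

inline dd dd_add(dd a, dd b) {
    dd s = two_sum(a.hi, b.hi);
    s.lo += a.lo + b.lo;
    return quick_two_sum(s.hi, s.lo);
}

inline dd dd_neg(dd a) { return {-a.hi, -a.lo}; }
inline dd dd_sub(dd a, dd b) { return dd_add(a, dd_neg(b)); }

inline dd dd_mul(dd a, dd b) {
    dd p = two_prod(a.hi, b.hi);
    p.lo += a.hi * b.lo + a.lo * b.hi;
    return quick_two_sum(p.hi, p.lo);
}

inline dd dd_div(dd a, dd b) {
    double q1 = a.hi / b.hi;
    dd r = dd_sub(a, dd_mul(b, dd_make(q1)));
    double q2 = r.hi / b.hi;
    r = dd_sub(r, dd_mul(b, dd_make(q2)));
    double q3 = r.hi / b.hi;
    dd q = quick_two_sum(q1, q2);
    return dd_add(q, dd_make(q3));
}

struct cdd { dd re, im; };

inline cdd c_make(double re_hi, double re_lo, double im_hi, double im_lo) {
    return {{re_hi, re_lo}, {im_hi, im_lo}};
}
inline cdd c_add(cdd a, cdd b) { return {dd_add(a.re, b.re), dd_add(a.im, b.im)}; }
inline cdd c_sub(cdd a, cdd b) { return {dd_sub(a.re, b.re), dd_sub(a.im, b.im)}; }
inline cdd c_mul(cdd a, cdd b) {
    return {dd_sub(dd_mul(a.re, b.re), dd_mul(a.im, b.im)),
            dd_add(dd_mul(a.re, b.im), dd_mul(a.im, b.re))};
}
inline cdd c_div(cdd a, cdd b) {
    dd den = dd_add(dd_mul(b.re, b.re), dd_mul(b.im, b.im));
    dd re = dd_add(dd_mul(a.re, b.re), dd_mul(a.im, b.im));
    dd im = dd_sub(dd_mul(a.im, b.re), dd_mul(a.re, b.im));
    return {dd_div(re, den), dd_div(im, den)};
}
inline double c_abs(cdd a) { return std::hypot(a.re.hi, a.im.hi); }

// Horner evaluation of p and p' at z; coefficients c[0..M] exact doubles
inline void horner2(const std::vector<double>& c, cdd z, cdd& p, cdd& dp) {
    int M = (int)c.size() - 1;
    p = c_make(c[M], 0, 0, 0);
    dp = c_make(0, 0, 0, 0);
    for (int m = M - 1; m >= 0; --m) {
        dp = c_add(c_mul(dp, z), p);
        p = c_add(c_mul(p, z), c_make(c[m], 0, 0, 0));
    }
}

} // namespace

// Newton-polish roots at double-double precision; returns refined roots,
// relative residuals |p(z)| / sum_m |c_m| |z|^m, and split hi/lo parts for
// downstream dd computations.
// [[Rcpp::export(name = ".dd_polish_cpp")]]
List dd_polish_cpp(NumericVector coef, NumericVector re, NumericVector im,
                   int max_iter = 12) {
    int M = re.size();
    std::vector<double> c(coef.begin(), coef.end());
    NumericVector re_hi(M), re_lo(M), im_hi(M), im_lo(M), resid(M);

    for (int k = 0; k < M; ++k) {
        cdd z = c_make(re[k], 0, im[k], 0);
        cdd p, dp;
        double prev = R_PosInf;
        for (int it = 0; it < max_iter; ++it) {
            horner2(c, z, p, dp);
            double ap = c_abs(p);
            if (!(ap < prev) || c_abs(dp) == 0.0) break;
            prev = ap;
            z = c_sub(z, c_div(p, dp));
        }
        horner2(c, z, p, dp);
        // residual scaled by the value the polynomial would have with all
        // cancellation removed
        double az = c_abs(z), scale = 0.0, zp = 1.0;
        for (size_t m = 0; m < c.size(); ++m) { scale += std::fabs(c[m]) * zp; zp *= az; }
        resid[k] = c_abs(p) / scale;
        re_hi[k] = z.re.hi; re_lo[k] = z.re.lo;
        im_hi[k] = z.im.hi; im_lo[k] = z.im.lo;
    }
    return List::create(_["re"] = re_hi, _["re_lo"] = re_lo,
                        _["im"] = im_hi, _["im_lo"] = im_lo,
                        _["residual"] = resid);
}

// Expand leading * prod_k (x - z_k) in dd arithmetic and compare with the
// original coefficients; also report Vieta aggregates (root sum and product)
// at dd precision.
// [[Rcpp::export(name = ".dd_verify_cpp")]]
List dd_verify_cpp(NumericVector coef,
                   NumericVector re_hi, NumericVector re_lo,
                   NumericVector im_hi, NumericVector im_lo) {
    int M = re_hi.size();
    std::vector<cdd> a(M + 1);
    for (auto& v : a) v = c_make(0, 0, 0, 0);
    a[0] = c_make(coef[M], 0, 0, 0);      // start from the leading coefficient

    cdd zero = c_make(0, 0, 0, 0);
    cdd zsum = zero, zprod = c_make(1, 0, 0, 0);
    for (int k = 0; k < M; ++k) {
        cdd z = c_make(re_hi[k], re_lo[k], im_hi[k], im_lo[k]);
        zsum = c_add(zsum, z);
        zprod = c_mul(zprod, z);
        // multiply the accumulated polynomial (ascending coefficients,
        // current degree k) by (x - z)
        for (int j = k + 1; j >= 1; --j)
            a[j] = c_sub(a[j - 1], c_mul(z, a[j]));
        a[0] = c_sub(zero, c_mul(z, a[0]));
    }

    double recon = 0.0;
    for (int j = 0; j <= M; ++j) {
        dd diff = dd_sub(a[j].re, dd_make(coef[j]));
        double err = std::fabs(diff.hi) + std::fabs(a[j].im.hi);
        double rel = err / std::max(1.0, std::fabs(coef[j]));
        if (rel > recon) recon = rel;
    }
    return List::create(
        _["recon_rel_max"] = recon,
        _["root_sum"] = Rcomplex{zsum.re.hi, zsum.im.hi},
        _["root_prod"] = Rcomplex{zprod.re.hi, zprod.im.hi});
}
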