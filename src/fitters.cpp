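// Levenberg-damped Gauss-Newton fitters for single-molecule PSF windows.
// Models: symmetric Gaussian (x0, y0, A, sigma, b) and rotated elliptical
// Gaussian (x0, y0, A, sx, sy, theta, b), least squares under Gaussian noise.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void model_sym(const arma::vec& p, const arma::vec& gx,
                      const arma::vec& gy, arma::vec& f, arma::mat& J) {
  const double x0 = p(0), y0 = p(1), A = p(2), s = p(3), b = p(4);
  const double is2 = 1.0 / (s * s);
  for (arma::uword i = 0; i < gx.n_elem; ++i) {
    const double dx = gx(i) - x0, dy = gy(i) - y0;
    const double r2 = dx * dx + dy * dy;
    const double e = std::exp(-0.5 * r2 * is2);
    f(i) = b + A * e;
    J(i, 0) = A * e * dx * is2;
    J(i, 1) = A * e * dy * is2;
    J(i, 2) = e;
    J(i, 3) = A * e * r2 * is2 / s;
    J(i, 4) = 1.0;
  }
}

// symmetric Gaussian with fixed radius: params (x0, y0, A, b)
static void model_sym_fixed(const arma::vec& p, double s, const arma::vec& gx,
                            const arma::vec& gy, arma::vec& f, arma::mat& J) {
  const double x0 = p(0), y0 = p(1), A = p(2), b = p(3);
  const double is2 = 1.0 / (s * s);
  for (arma::uword i = 0; i < gx.n_elem; ++i) {
    const double dx = gx(i) - x0, dy = gy(i) - y0;
    const double e = std::exp(-0.5 * (dx * dx + dy * dy) * is2);
    f(i) = b + A * e;
    J(i, 0) = A * e * dx * is2;
    J(i, 1) = A * e * dy * is2;
    J(i, 2) = e;
    J(i, 3) = 1.0;
  }
}

static void model_rot(const arma::vec& p, const arma::vec& gx,
                      const arma::vec& gy, arma::vec& f, arma::mat& J) {
  const double x0 = p(0), y0 = p(1), A = p(2), sx = p(3), sy = p(4),
               th = p(5), b = p(6);
  const double ct = std::cos(th), st = std::sin(th);
  const double isx2 = 1.0 / (sx * sx), isy2 = 1.0 / (sy * sy);
  for (arma::uword i = 0; i < gx.n_elem; ++i) {
    const double dx = gx(i) - x0, dy = gy(i) - y0;
    const double u = dx * ct + dy * st, v = -dx * st + dy * ct;
    const double e = std::exp(-0.5 * (u * u * isx2 + v * v * isy2));
    f(i) = b + A * e;
    const double du_dx0 = -ct, dv_dx0 = st, du_dy0 = -st, dv_dy0 = -ct;
    const double gu = -A * e * u * isx2, gv = -A * e * v * isy2;
    J(i, 0) = gu * du_dx0 + gv * dv_dx0;
    J(i, 1) = gu * du_dy0 + gv * dv_dy0;
    J(i, 2) = e;
    J(i, 3) = A * e * u * u * isx2 / sx;
    J(i, 4) = A * e * v * v * isy2 / sy;
    J(i, 5) = gu * (-dx * st + dy * ct) + gv * (-dx * ct - dy * st);
    J(i, 6) = 1.0;
  }
}

// mode: 0 symmetric, 1 rotated elliptical, 2 symmetric with fixed radius
// [[Rcpp::export]]
List fp_fit_gauss_mode(NumericMatrix win, double x_start, double y_start,
                       double sigma_start, int mode, int max_iter = 50) {
  const int nr = win.nrow(), nc = win.ncol();
  const int n = nr * nc;
  arma::vec y(n), gx(n), gy(n);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      y(k) = win(i, j);
      gx(k) = i;            // row index = x (0-based within the window)
      gy(k) = j;
      ++k;
    }
  const double bg0 = arma::median(y);
  double amp0 = y.max() - bg0;
  if (amp0 <= 0) amp0 = 1e-3;
  const int np = (mode == 1) ? 7 : ((mode == 2) ? 4 : 5);
  arma::vec p(np);
  if (mode == 1) {
    // slightly anisotropic start: at sx == sy the angle direction is
    // degenerate and the first damped step can leave the basin
    p = {x_start, y_start, amp0, 1.05 * sigma_start, 0.95 * sigma_start,
         0.3, bg0};
  } else if (mode == 2) {
    p = {x_start, y_start, amp0, bg0};
  } else {
    p = {x_start, y_start, amp0, sigma_start, bg0};
  }
  arma::vec f(n), r(n);
  arma::mat J(n, np);
  double lambda = 1e-3;
  double rss = arma::datum::inf;
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    if (mode == 1) model_rot(p, gx, gy, f, J);
    else if (mode == 2) model_sym_fixed(p, sigma_start, gx, gy, f, J);
    else model_sym(p, gx, gy, f, J);
    r = y - f;
    rss = arma::dot(r, r);
    arma::mat H = J.t() * J;
    arma::vec g = J.t() * r;
    bool stepped = false;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H;
      Hd.diag() += lambda * H.diag();
      arma::vec dp;
      if (!arma::solve(dp, Hd, g, arma::solve_opts::no_approx)) {
        lambda *= 10; continue;
      }
      arma::vec pn = p + dp;
      // the detection stage already localized the peak to an integer pixel:
      // the sub-pixel refinement must stay in its neighbourhood
      pn(0) = std::min(std::max(pn(0), x_start - 2.5), x_start + 2.5);
      pn(1) = std::min(std::max(pn(1), y_start - 2.5), y_start + 2.5);
      if (mode != 2) {
        // radii bounded by the optically plausible range (the modelled PSFs
        // stay below ~2.5 px even defocused); wider "fits" are background
        pn(3) = std::min(std::max(pn(3), 0.3), 4.0);
        if (mode == 1) pn(4) = std::min(std::max(pn(4), 0.3), 4.0);
      }
      arma::vec fn(n);
      arma::mat Jn(n, np);
      if (mode == 1) model_rot(pn, gx, gy, fn, Jn);
      else if (mode == 2) model_sym_fixed(pn, sigma_start, gx, gy, fn, Jn);
      else model_sym(pn, gx, gy, fn, Jn);
      const double rss_n = arma::dot(y - fn, y - fn);
      if (rss_n < rss) {
        if (std::abs(rss - rss_n) < 1e-9 * (rss + 1e-12) ||
            arma::norm(dp) < 1e-7) converged = true;
        p = pn; lambda = std::max(lambda * 0.3, 1e-12);
        stepped = true;
        break;
      }
      lambda *= 10;
    }
    if (!stepped || converged) { if (!stepped) converged = true; break; }
  }
  double volume, sigma_eff;
  if (mode == 1) {
    volume = 2.0 * M_PI * p(2) * p(3) * p(4);
    sigma_eff = std::sqrt(p(3) * p(4));
  } else if (mode == 2) {
    volume = 2.0 * M_PI * p(2) * sigma_start * sigma_start;
    sigma_eff = sigma_start;
  } else {
    volume = 2.0 * M_PI * p(2) * p(3) * p(3);
    sigma_eff = p(3);
  }
  return List::create(_["par"] = p, _["intensity"] = volume,
                      _["sigma"] = sigma_eff, _["rss"] = rss,
                      _["bg"] = p(np - 1), _["converged"] = converged,
                      _["iterations"] = it + 1);
}

// GLRT statistic map for one frame: at each pixel, compare H1 (fixed-width
// Gaussian peak + offset) vs H0 (offset only) by windowed linear least
// squares; returns T = N log(SS0/SS1) (and the fitted amplitude sign).
// [[Rcpp::export]]
List fp_glrt_map(NumericMatrix img, int half, NumericMatrix kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = 2 * half + 1;
  const int N = w * w;
  // kernel statistics (kern is w x w, arbitrary scale)
  double gsum = 0, g2sum = 0;
  for (int j = 0; j < w; ++j) for (int i = 0; i < w; ++i) {
    gsum += kern(i, j); g2sum += kern(i, j) * kern(i, j);
  }
  const double gbar = gsum / N;
  const double Sgg = g2sum - N * gbar * gbar;
  NumericMatrix T(nr, nc), Amp(nr, nc);
  for (int cx = half; cx < nr - half; ++cx) {
    for (int cy = half; cy < nc - half; ++cy) {
      double sy = 0, syy = 0, sgy = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i) {
          const double v = img(cx + i, cy + j);
          sy += v; syy += v * v;
          sgy += kern(i + half, j + half) * v;
        }
      const double ybar = sy / N;
      const double SS0 = syy - N * ybar * ybar;
      const double Sgy = sgy - gbar * sy;
      const double A = (Sgg > 0) ? Sgy / Sgg : 0.0;
      double SS1 = SS0 - A * Sgy;
      if (SS1 < 1e-12) SS1 = 1e-12;
      T(cx, cy) = (SS0 > 0) ? N * std::log(SS0 / SS1) : 0.0;
      Amp(cx, cy) = A;
    }
  }
  return List::create(_["T"] = T, _["amplitude"] = Amp);
}
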