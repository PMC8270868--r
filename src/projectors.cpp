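// Ray-driven (Joseph) projectors and pixel-driven fan-beam backprojection.
// Conventions: image row 0 is the top row; pixel (i, j) center sits at
// x = (j - (W-1)/2) * spacing, y = ((H-1)/2 - i) * spacing (mm), isocenter at
// the image center. View k places the source at angle beta = 2*pi*k/n_views
// on a circle of radius `sad` (mm); detector bin b subtends fan angle
// gamma_b = (b + 0.5 - n_bins/2) * dgamma so the central ray falls midway
// between the two middle bins. Attenuation values are in 1/cm; path lengths
// are converted from mm to cm so line integrals are dimensionless.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double joseph_ray(const mat& img, double spacing,
                                double sx, double sy, double dx, double dy) {
  const int H = img.n_rows, W = img.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  double acc = 0.0;
  if (std::fabs(dx) >= std::fabs(dy)) {
    for (int j = 0; j < W; ++j) {
      const double xj = (j - cx) * spacing;
      const double t = (xj - sx) / dx;
      const double y = sy + t * dy;
      const double r = cy - y / spacing;
      const int i0 = (int)std::floor(r);
      const double f = r - i0;
      if (i0 >= 0 && i0 < H) acc += img(i0, j) * (1.0 - f);
      if (i0 + 1 >= 0 && i0 + 1 < H) acc += img(i0 + 1, j) * f;
    }
    acc *= spacing / std::fabs(dx);
  } else {
    for (int i = 0; i < H; ++i) {
      const double yi = (cy - i) * spacing;
      const double t = (yi - sy) / dy;
      const double x = sx + t * dx;
      const double c = x / spacing + cx;
      const int j0 = (int)std::floor(c);
      const double f = c - j0;
      if (j0 >= 0 && j0 < W) acc += img(i, j0) * (1.0 - f);
      if (j0 + 1 >= 0 && j0 + 1 < W) acc += img(i, j0 + 1) * f;
    }
    acc *= spacing / std::fabs(dy);
  }
  return acc * 0.1; // mm -> cm
}

// [[Rcpp::export]]
arma::mat cpp_fan_forward(const arma::mat& img, double spacing,
                          int n_views, int n_bins, double sad, double dgamma) {
  mat out(n_views, n_bins, fill::zeros);
  for (int v = 0; v < n_views; ++v) {
    const double beta = 2.0 * M_PI * v / n_views;
    const double sx = sad * std::cos(beta), sy = sad * std::sin(beta);
    for (int b = 0; b < n_bins; ++b) {
      const double gamma = (b + 0.5 - n_bins / 2.0) * dgamma;
      const double phi = beta + M_PI + gamma;
      out(v, b) = joseph_ray(img, spacing, sx, sy, std::cos(phi), std::sin(phi));
    }
  }
  return out;
}

// Backprojection step of equi-angular fan-beam FBP: accumulates the filtered,
// cosine-weighted projections q with inverse-square distance weighting
// (L in cm). The caller applies the pre-weighting and ramp filtering.
// [[Rcpp::export]]
arma::mat cpp_fan_backproject(const arma::mat& q, double spacing,
                              int H, int W, double sad, double dgamma) {
  const int n_views = q.n_rows, n_bins = q.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double dbeta = 2.0 * M_PI / n_views;
  mat out(H, W, fill::zeros);
  for (int v = 0; v < n_views; ++v) {
    const double beta = 2.0 * M_PI * v / n_views;
    const double sx = sad * std::cos(beta), sy = sad * std::sin(beta);
    const double ca = std::cos(beta + M_PI), sa = std::sin(beta + M_PI);
    for (int j = 0; j < W; ++j) {
      const double px = (j - cx) * spacing;
      for (int i = 0; i < H; ++i) {
        const double py = (cy - i) * spacing;
        const double vx = px - sx, vy = py - sy;
        const double L2 = (vx * vx + vy * vy) * 0.01; // cm^2
        const double along = vx * ca + vy * sa;
        const double perp = -vx * sa + vy * ca;
        const double gamma = std::atan2(perp, along);
        const double bb = gamma / dgamma + n_bins / 2.0 - 0.5;
        const int b0 = (int)std::floor(bb);
        const double f = bb - b0;
        double val = 0.0;
        if (b0 >= 0 && b0 < n_bins) val += q(v, b0) * (1.0 - f);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) val += q(v, b0 + 1) * f;
        out(i, j) += val / L2;
      }
    }
  }
  return out * dbeta;
}

// Parallel-beam Joseph projector over 180 degrees (emission model for PET).
// Detector coordinate t_d = (d + 0.5 - n_det/2) * det_spacing; the ray for
// angle theta_a = pi*a/n_ang passes through t_d*(cos,sin) with direction
// (-sin, cos). cpp_par_backward is the exact adjoint (same weights, scatter).
// [[Rcpp::export]]
arma::mat cpp_par_forward(const arma::mat& img, double spacing,
                          int n_ang, int n_det, double det_spacing) {
  mat out(n_ang, n_det, fill::zeros);
  for (int a = 0; a < n_ang; ++a) {
    const double th = M_PI * a / n_ang;
    const double dx = -std::sin(th), dy = std::cos(th);
    for (int d = 0; d < n_det; ++d) {
      const double td = (d + 0.5 - n_det / 2.0) * det_spacing;
      out(a, d) = joseph_ray(img, spacing, td * std::cos(th), td * std::sin(th), dx, dy);
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_par_backward(const arma::mat& sino, double spacing, int H, int W,
                           double det_spacing) {
  const int n_ang = sino.n_rows, n_det = sino.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  mat out(H, W, fill::zeros);
  for (int a = 0; a < n_ang; ++a) {
    const double th = M_PI * a / n_ang;
    const double dx = -std::sin(th), dy = std::cos(th);
    for (int d = 0; d < n_det; ++d) {
      const double td = (d + 0.5 - n_det / 2.0) * det_spacing;
      const double sx = td * std::cos(th), sy = td * std::sin(th);
      const double g = sino(a, d);
      if (g == 0.0) continue;
      if (std::fabs(dx) >= std::fabs(dy)) {
        const double w = g * spacing / std::fabs(dx) * 0.1;
        for (int j = 0; j < W; ++j) {
          const double xj = (j - cx) * spacing;
          const double t = (xj - sx) / dx;
          const double y = sy + t * dy;
          const double r = cy - y / spacing;
          const int i0 = (int)std::floor(r);
          const double f = r - i0;
          if (i0 >= 0 && i0 < H) out(i0, j) += w * (1.0 - f);
          if (i0 + 1 >= 0 && i0 + 1 < H) out(i0 + 1, j) += w * f;
        }
      } else {
        const double w = g * spacing / std::fabs(dy) * 0.1;
        for (int i = 0; i < H; ++i) {
          const double yi = (cy - i) * spacing;
          const double t = (yi - sy) / dy;
          const double x = sx + t * dx;
          const double c = x / spacing + cx;
          const int j0 = (int)std::floor(c);
          const double f = c - j0;
          if (j0 >= 0 && j0 < W) out(i, j0) += w * (1.0 - f);
          if (j0 + 1 >= 0 && j0 + 1 < W) out(i, j0 + 1) += w * f;
        }
      }
    }
  }
  return out;
}
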