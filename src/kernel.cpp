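// Time-stepping kernels for the k-space pseudospectral solver.
//
// R precomputes the spectral derivative operators (i k kappa with staggered
// shifts), the split-field PML factors, staggered densities and the
// stationary-loss factor; these kernels run the leapfrog update loop and
// record the per-voxel maximum pressure plus optional sensor time series.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static cx_mat fft2d(const cx_mat& x) {
  return strans(fft(strans(fft(x))));
}

static cx_mat ifft2d(const cx_mat& x) {
  return strans(ifft(strans(ifft(x))));
}

static cx_cube fft3d(const cx_cube& x) {
  uword n0 = x.n_rows, n1 = x.n_cols, n2 = x.n_slices;
  cx_cube y = x;
  for (uword s = 0; s < n2; ++s) {
    y.slice(s) = strans(fft(strans(fft(y.slice(s)))));
  }
  cx_mat m(n2, n0 * n1);
  for (uword s = 0; s < n2; ++s) {
    m.row(s) = cx_rowvec(y.slice(s).memptr(), n0 * n1);
  }
  m = fft(m);
  for (uword s = 0; s < n2; ++s) {
    cx_rowvec r = m.row(s);
    y.slice(s) = cx_mat(r.memptr(), n0, n1);
  }
  return y;
}

static cx_cube ifft3d(const cx_cube& x) {
  uword n0 = x.n_rows, n1 = x.n_cols, n2 = x.n_slices;
  cx_cube y = x;
  for (uword s = 0; s < n2; ++s) {
    y.slice(s) = strans(ifft(strans(ifft(y.slice(s)))));
  }
  cx_mat m(n2, n0 * n1);
  for (uword s = 0; s < n2; ++s) {
    m.row(s) = cx_rowvec(y.slice(s).memptr(), n0 * n1);
  }
  m = ifft(m);
  for (uword s = 0; s < n2; ++s) {
    cx_rowvec r = m.row(s);
    y.slice(s) = cx_mat(r.memptr(), n0, n1);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List fus_kernel2(const arma::cx_mat& ddxp_x, const arma::cx_mat& ddxp_y,
                       const arma::cx_mat& ddxn_x, const arma::cx_mat& ddxn_y,
                       const arma::mat& pml_x, const arma::mat& pml_y,
                       const arma::mat& rho_sg_x, const arma::mat& rho_sg_y,
                       const arma::mat& rho0,
                       const arma::mat& abs_fac, const arma::mat& c2,
                       double dt, const arma::uvec& src_idx,
                       const arma::vec& src_coef_a, const arma::vec& src_coef_b,
                       const arma::vec& signal_a, const arma::vec& signal_b,
                       int record_start, const arma::uvec& sensor_idx,
                       bool lossy) {
  const uword n_steps = signal_a.n_elem;
  mat ux(size(c2), fill::zeros), uy(size(c2), fill::zeros);
  mat rx(size(c2), fill::zeros), ry(size(c2), fill::zeros);
  mat p(size(c2), fill::zeros), max_p(size(c2), fill::zeros);
  mat sensors(n_steps, sensor_idx.n_elem, fill::zeros);

  for (uword step = 0; step < n_steps; ++step) {
    cx_mat ph = fft2d(conv_to<cx_mat>::from(p));
    ux = pml_x % (pml_x % ux - (dt / rho_sg_x) % real(ifft2d(ddxp_x % ph)));
    uy = pml_y % (pml_y % uy - (dt / rho_sg_y) % real(ifft2d(ddxp_y % ph)));
    if (lossy) { ux %= abs_fac; uy %= abs_fac; }
    mat dux = real(ifft2d(ddxn_x % fft2d(conv_to<cx_mat>::from(ux))));
    mat duy = real(ifft2d(ddxn_y % fft2d(conv_to<cx_mat>::from(uy))));
    rx = pml_x % (pml_x % rx - dt * rho0 % dux);
    ry = pml_y % (pml_y % ry - dt * rho0 % duy);
    const double s_a = signal_a(step), s_b = signal_b(step);
    for (uword k = 0; k < src_idx.n_elem; ++k) {
      const double inj = s_a * src_coef_a(k) + s_b * src_coef_b(k);
      rx(src_idx(k)) += inj;
      ry(src_idx(k)) += inj;
    }
    if (lossy) { rx %= abs_fac; ry %= abs_fac; }
    p = c2 % (rx + ry);
    if ((int)step + 1 > record_start) max_p = arma::max(max_p, p);
    for (uword k = 0; k < sensor_idx.n_elem; ++k) {
      sensors(step, k) = p(sensor_idx(k));
    }
    if (step % 50 == 49 && !p.is_finite()) {
      Rcpp::stop("solver divergence: non-finite field at step %d",
                 (int)step + 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("max_pressure") = max_p,
                            Rcpp::Named("sensor_data") = sensors);
}

// [[Rcpp::export]]
Rcpp::List fus_kernel3(const arma::cx_cube& ddxp_x, const arma::cx_cube& ddxp_y,
                       const arma::cx_cube& ddxp_z,
                       const arma::cx_cube& ddxn_x, const arma::cx_cube& ddxn_y,
                       const arma::cx_cube& ddxn_z,
                       const arma::cube& pml_x, const arma::cube& pml_y,
                       const arma::cube& pml_z,
                       const arma::cube& rho_sg_x, const arma::cube& rho_sg_y,
                       const arma::cube& rho_sg_z, const arma::cube& rho0,
                       const arma::cube& abs_fac, const arma::cube& c2,
                       double dt, const arma::uvec& src_idx,
                       const arma::vec& src_coef_a, const arma::vec& src_coef_b,
                       const arma::vec& signal_a, const arma::vec& signal_b,
                       int record_start, const arma::uvec& sensor_idx,
                       bool lossy) {
  const uword n_steps = signal_a.n_elem;
  cube ux(size(c2), fill::zeros), uy(size(c2), fill::zeros),
       uz(size(c2), fill::zeros);
  cube rx(size(c2), fill::zeros), ry(size(c2), fill::zeros),
       rz(size(c2), fill::zeros);
  cube p(size(c2), fill::zeros), max_p(size(c2), fill::zeros);
  mat sensors(n_steps, sensor_idx.n_elem, fill::zeros);

  for (uword step = 0; step < n_steps; ++step) {
    cx_cube ph = fft3d(conv_to<cx_cube>::from(p));
    ux = pml_x % (pml_x % ux - (dt / rho_sg_x) % real(ifft3d(ddxp_x % ph)));
    uy = pml_y % (pml_y % uy - (dt / rho_sg_y) % real(ifft3d(ddxp_y % ph)));
    uz = pml_z % (pml_z % uz - (dt / rho_sg_z) % real(ifft3d(ddxp_z % ph)));
    if (lossy) { ux %= abs_fac; uy %= abs_fac; uz %= abs_fac; }
    cube dux = real(ifft3d(ddxn_x % fft3d(conv_to<cx_cube>::from(ux))));
    cube duy = real(ifft3d(ddxn_y % fft3d(conv_to<cx_cube>::from(uy))));
    cube duz = real(ifft3d(ddxn_z % fft3d(conv_to<cx_cube>::from(uz))));
    rx = pml_x % (pml_x % rx - dt * rho0 % dux);
    ry = pml_y % (pml_y % ry - dt * rho0 % duy);
    rz = pml_z % (pml_z % rz - dt * rho0 % duz);
    const double s_a = signal_a(step), s_b = signal_b(step);
    for (uword k = 0; k < src_idx.n_elem; ++k) {
      const double inj = s_a * src_coef_a(k) + s_b * src_coef_b(k);
      rx(src_idx(k)) += inj;
      ry(src_idx(k)) += inj;
      rz(src_idx(k)) += inj;
    }
    if (lossy) { rx %= abs_fac; ry %= abs_fac; rz %= abs_fac; }
    p = c2 % (rx + ry + rz);
    if ((int)step + 1 > record_start) max_p = arma::max(max_p, p);
    for (uword k = 0; k < sensor_idx.n_elem; ++k) {
      sensors(step, k) = p(sensor_idx(k));
    }
    if (step % 50 == 49 && !p.is_finite()) {
      Rcpp::stop("solver divergence: non-finite field at step %d",
                 (int)step + 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("max_pressure") = max_p,
                            Rcpp::Named("sensor_data") = sensors);
}
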