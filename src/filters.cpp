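#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradient-descent orientation filter for a 6-axis IMU (gyroscope +
// accelerometer, no magnetometer). Quaternion q = (w, x, y, z) rotates
// sensor-frame vectors into the world frame; world z is up, so a static
// sensor reads specific force (0, 0, g).
//
// Each step integrates the gyroscope rate and subtracts the beta-scaled
// normalised gradient of the gravity-alignment objective
//   f(q) = R(q)^T (0,0,1) - accel_hat.
// A zero-norm accelerometer sample skips the gradient step (gyro-only).
//
// [[Rcpp::export]]
NumericMatrix madgwick_filter_cpp(NumericMatrix gyro, NumericMatrix accel,
                                  double dt, double beta, NumericVector q0) {
  const int n = gyro.nrow();
  if (accel.nrow() != n) stop("gyro and accel must have equal length");
  if (dt <= 0) stop("dt must be positive");
  NumericMatrix out(n, 4);
  double q0w = q0[0], q0x = q0[1], q0y = q0[2], q0z = q0[3];
  double w = q0w, x = q0x, y = q0y, z = q0z;

  for (int i = 0; i < n; ++i) {
    const double gx = gyro(i, 0), gy = gyro(i, 1), gz = gyro(i, 2);
    double ax = accel(i, 0), ay = accel(i, 1), az = accel(i, 2);

    // quaternion rate from angular velocity: 0.5 * q x (0, omega)
    double qDotW = 0.5 * (-x * gx - y * gy - z * gz);
    double qDotX = 0.5 * ( w * gx + y * gz - z * gy);
    double qDotY = 0.5 * ( w * gy - x * gz + z * gx);
    double qDotZ = 0.5 * ( w * gz + x * gy - y * gx);

    const double anorm = std::sqrt(ax * ax + ay * ay + az * az);
    if (anorm > 0.0 && beta > 0.0) {
      ax /= anorm; ay /= anorm; az /= anorm;
      const double f1 = 2.0 * (x * z - w * y) - ax;
      const double f2 = 2.0 * (w * x + y * z) - ay;
      const double f3 = 1.0 - 2.0 * (x * x + y * y) - az;
      double s0 = -2.0 * y * f1 + 2.0 * x * f2;
      double s1 =  2.0 * z * f1 + 2.0 * w * f2 - 4.0 * x * f3;
      double s2 = -2.0 * w * f1 + 2.0 * z * f2 - 4.0 * y * f3;
      double s3 =  2.0 * x * f1 + 2.0 * y * f2;
      const double snorm = std::sqrt(s0 * s0 + s1 * s1 + s2 * s2 + s3 * s3);
      if (snorm > 0.0) {
        qDotW -= beta * s0 / snorm;
        qDotX -= beta * s1 / snorm;
        qDotY -= beta * s2 / snorm;
        qDotZ -= beta * s3 / snorm;
      }
    }

    w += qDotW * dt; x += qDotX * dt; y += qDotY * dt; z += qDotZ * dt;
    const double qn = std::sqrt(w * w + x * x + y * y + z * z);
    w /= qn; x /= qn; y /= qn; z /= qn;
    out(i, 0) = w; out(i, 1) = x; out(i, 2) = y; out(i, 3) = z;
  }
  return out;
}

// Direct-form II transposed IIR filter with initial conditions, the kernel
// of the zero-phase forward-backward filtering. a[0] must be 1.
//
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nf = std::max(nb, na);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (std::abs(aa[0] - 1.0) > 1e-12) stop("a[0] must equal 1");
  if (zi.size() != nf - 1) stop("zi must have length max(len(a),len(b)) - 1");
  for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];

  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j) {
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    }
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
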