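#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gated sinusoid with raised-cosine (Hann) envelope, n_cycles long at fc.
// t measured from pulse start; zero outside [0, n_cycles/fc].
// The carrier phase is centred on the envelope so the pulse is
// antisymmetric about its midpoint and therefore exactly zero-mean
// (a band-pass transducer transmits no DC; a DC-bearing pulse floods the
// beamformed image with low-frequency haze that breaks speckle tracking).
static inline double pulse_wave(double t, double fc, double n_cycles) {
  double T = n_cycles / fc;
  if (t < 0.0 || t > T) return 0.0;
  double env = 0.5 * (1.0 - std::cos(2.0 * M_PI * t / T));
  return env * std::sin(2.0 * M_PI * fc * (t - 0.5 * T));
}

// Plane-wave echo simulation for one transmit.
// Scatterer echo delay at element e: tau = (z cos(th) + x sin(th))/c + dist(e, s)/c.
// [[Rcpp::export]]
NumericMatrix rf_simulate_cpp(NumericVector sx, NumericVector sz,
                              NumericVector refl, NumericVector ex,
                              double angle_rad, double c, double fs,
                              double fc, double tx_cycles,
                              int n_samples, double t0) {
  int ns = sx.size(), ne = ex.size();
  NumericMatrix out(n_samples, ne); // time x element
  double sth = std::sin(angle_rad), cth = std::cos(angle_rad);
  double T = tx_cycles / fc;
  for (int e = 0; e < ne; ++e) {
    double xe = ex[e];
    for (int s = 0; s < ns; ++s) {
      double dx = sx[s] - xe;
      double tau = (sz[s] * cth + sx[s] * sth) / c +
                   std::sqrt(dx * dx + sz[s] * sz[s]) / c;
      // sample window overlapping the pulse support
      int i0 = (int)std::floor((tau - t0) * fs);
      int i1 = (int)std::ceil((tau + T - t0) * fs);
      if (i0 < 0) i0 = 0;
      if (i1 >= n_samples) i1 = n_samples - 1;
      for (int i = i0; i <= i1; ++i) {
        double t = t0 + i / fs - tau;
        out(i, e) += refl[s] * pulse_wave(t, fc, tx_cycles);
      }
    }
  }
  return out;
}

// Delay-and-sum reconstruction of one plane-wave transmit onto a pixel grid.
// rf: time x element matrix. Returns axial(z) x lateral(x) image.
// Delays beyond the recorded trace contribute zero; their count is attached
// on the R side via the separate counter output.
// [[Rcpp::export]]
List das_beamform_cpp(NumericMatrix rf, NumericVector ex,
                      double angle_rad, NumericVector gx, NumericVector gz,
                      double c, double fs, double t0, double f_number) {
  int nt = rf.nrow(), ne = rf.ncol();
  int nx = gx.size(), nz = gz.size();
  NumericMatrix img(nz, nx);
  double sth = std::sin(angle_rad), cth = std::cos(angle_rad);
  long long clipped = 0;
  for (int ix = 0; ix < nx; ++ix) {
    double x = gx[ix];
    for (int iz = 0; iz < nz; ++iz) {
      double z = gz[iz];
      double tau_tx = (z * cth + x * sth) / c;
      double half_ap = f_number > 0 ? z / (2.0 * f_number) : -1.0;
      double acc = 0.0;
      for (int e = 0; e < ne; ++e) {
        double dx = x - ex[e];
        if (half_ap > 0 && std::fabs(dx) > half_ap) continue;
        double tau = tau_tx + std::sqrt(dx * dx + z * z) / c;
        double fi = (tau - t0) * fs;
        int i = (int)std::floor(fi);
        if (i < 0 || i + 1 >= nt) { ++clipped; continue; }
        double w = fi - i;
        acc += (1.0 - w) * rf(i, e) + w * rf(i + 1, e);
      }
      img(iz, ix) = acc;
    }
  }
  return List::create(_["image"] = img, _["n_clipped"] = (double)clipped);
}
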