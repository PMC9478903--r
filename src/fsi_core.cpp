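#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Serpentine Floyd-Steinberg error diffusion on a [0,1] grayscale matrix.
// Rows are scanned top to bottom; even rows (0-based) left-to-right, odd rows
// right-to-left. The classic 7/16, 3/16, 5/16, 1/16 weights are mirrored with
// the scan direction; error falling outside the grid is dropped (clamped
// borders). Threshold: value >= 0.5 -> 1.
static void dither_core(std::vector<double>& buf, int M, int N,
                        std::vector<double>& out) {
  // buf, out are row-major M x N
  for (int x = 0; x < M; ++x) {
    int dir = (x % 2 == 0) ? 1 : -1;
    int y0 = (dir == 1) ? 0 : N - 1;
    for (int k = 0; k < N; ++k) {
      int y = y0 + dir * k;
      double old = buf[x * N + y];
      double bit = (old >= 0.5) ? 1.0 : 0.0;
      out[x * N + y] = bit;
      double err = old - bit;
      int yf = y + dir;   // ahead in scan direction
      int yb = y - dir;   // behind
      if (yf >= 0 && yf < N) buf[x * N + yf] += err * 7.0 / 16.0;
      if (x + 1 < M) {
        if (yb >= 0 && yb < N) buf[(x + 1) * N + yb] += err * 3.0 / 16.0;
        buf[(x + 1) * N + y] += err * 5.0 / 16.0;
        if (yf >= 0 && yf < N) buf[(x + 1) * N + yf] += err * 1.0 / 16.0;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_dither_fs(NumericMatrix gray) {
  int M = gray.nrow(), N = gray.ncol();
  std::vector<double> buf((size_t)M * N), out((size_t)M * N);
  for (int x = 0; x < M; ++x)
    for (int y = 0; y < N; ++y)
      buf[x * N + y] = gray(x, y);
  dither_core(buf, M, N, out);
  NumericMatrix res(M, N);
  for (int x = 0; x < M; ++x)
    for (int y = 0; y < N; ++y)
      res(x, y) = out[x * N + y];
  return res;
}

// Noiseless bucket-detector responses for a whole sampling plan.
// For each frequency (u[k], v[k]) and each phase in {0, 2pi/3, 4pi/3} the
// basis pattern P(x,y) = 1/2 + 1/2 cos(2*pi*u*x/M + 2*pi*v*y/N + phase) is
// synthesized (and optionally binarized by Floyd-Steinberg dithering), then
// reduced to D = sum_x sum_y I(x,y) * P(x,y). Returns a K x 3 matrix.
// [[Rcpp::export]]
NumericMatrix cpp_acquire_noiseless(NumericMatrix scene, IntegerVector u,
                                    IntegerVector v, bool use_binary) {
  int M = scene.nrow(), N = scene.ncol();
  int K = u.size();
  NumericMatrix D(K, 3);
  const double phases[3] = {0.0, 2.0 * M_PI / 3.0, 4.0 * M_PI / 3.0};
  std::vector<double> scn((size_t)M * N);
  for (int x = 0; x < M; ++x)
    for (int y = 0; y < N; ++y)
      scn[x * N + y] = scene(x, y);
  std::vector<double> ax(M), by(N), pat((size_t)M * N), bin((size_t)M * N);
  for (int k = 0; k < K; ++k) {
    for (int x = 0; x < M; ++x) ax[x] = 2.0 * M_PI * (double)u[k] * x / M;
    double db = 2.0 * M_PI * (double)v[k] / N;
    double cd = std::cos(db), sdv = std::sin(db);
    for (int p = 0; p < 3; ++p) {
      double ph = phases[p];
      for (int x = 0; x < M; ++x) {
        // rotate (cos, sin) along the row instead of calling cos per pixel
        double c = std::cos(ax[x] + ph), s = std::sin(ax[x] + ph);
        double* row = &pat[(size_t)x * N];
        for (int y = 0; y < N; ++y) {
          row[y] = 0.5 + 0.5 * c;
          double cn = c * cd - s * sdv;
          s = s * cd + c * sdv;
          c = cn;
        }
      }
      double d = 0.0;
      if (use_binary) {
        dither_core(pat, M, N, bin);
        for (size_t i = 0; i < scn.size(); ++i) d += scn[i] * bin[i];
      } else {
        for (size_t i = 0; i < scn.size(); ++i) d += scn[i] * pat[i];
      }
      D(k, p) = d;
    }
  }
  return D;
}
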