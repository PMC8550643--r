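#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Self-contained PCG32 stream (O'Neill 2014) feeding a Marsaglia-Tsang
// ziggurat normal sampler. Deterministic across platforms and fast enough
// to draw the ~10^8 latent normals a desk-scale cohort needs;
// R's set.seed/sample.int supplies the 31-bit seed upstream.
namespace {

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  explicit Pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform in (0,1)
  double unif() {
    return (static_cast<double>(next()) + 0.5) * (1.0 / 4294967296.0);
  }
};

// 128-strip ziggurat for the standard normal (Marsaglia & Tsang 2000).
struct ZigNormal {
  Pcg32 rng;
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit ZigNormal(uint64_t seed) : rng(seed) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double draw() {
    for (;;) {
      int32_t hz = static_cast<int32_t>(rng.next());
      uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      uint32_t ahz = static_cast<uint32_t>(
          hz < 0 ? -static_cast<int64_t>(hz) : hz);
      if (ahz < kn[iz]) return hz * wn[iz];
      if (iz == 0u) {  // tail beyond +/- r
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

}  // namespace

// Haplotypes follow a stationary latent Gaussian AR(1) across SNP index,
// thresholded at qnorm(f_j) so each SNP's carrier frequency is f_j; the
// genotype is the sum of the individual's two independent haplotypes.
// [[Rcpp::export]]
List cpp_sim_dosages(NumericVector thresh, double rho, int n, double seed,
                     bool keep_haplotypes) {
  const int m = thresh.size();
  if (n < 1) stop("n must be >= 1");
  if (rho < 0.0 || rho >= 1.0) stop("ld_rho must be in [0, 1)");
  ZigNormal gen(static_cast<uint64_t>(seed));
  NumericMatrix dos(n, m);
  IntegerMatrix hap =
      keep_haplotypes ? IntegerMatrix(2 * n, m) : IntegerMatrix(0, 0);
  std::vector<double> z(2 * static_cast<size_t>(n));
  const double s = std::sqrt(1.0 - rho * rho);
  for (int j = 0; j < m; ++j) {
    const double t = thresh[j];
    double *col = &dos(0, j);
    for (int i = 0; i < n; ++i) {
      double z1, z2;
      if (j == 0) {
        z1 = gen.draw();
        z2 = gen.draw();
      } else {
        z1 = rho * z[2 * i] + s * gen.draw();
        z2 = rho * z[2 * i + 1] + s * gen.draw();
      }
      z[2 * i] = z1;
      z[2 * i + 1] = z2;
      const int h1 = z1 < t ? 1 : 0;
      const int h2 = z2 < t ? 1 : 0;
      col[i] = h1 + h2;
      if (keep_haplotypes) {
        hap(2 * i, j) = h1;
        hap(2 * i + 1, j) = h2;
      }
    }
  }
  if (keep_haplotypes)
    return List::create(_["dosages"] = dos, _["haplotypes"] = hap);
  return List::create(_["dosages"] = dos);
}

// out(i, d+1) = sum_l a(l, i) * b(l, i+d) for d = 0..w (0 past the edge).
// With columns standardized to mean 0 / sd 1 this gives (L-1) * r(i, i+d).
// [[Rcpp::export]]
NumericMatrix cpp_lag_crossprod(NumericMatrix a, NumericMatrix b, int w) {
  const int L = a.nrow(), m = a.ncol();
  if (b.nrow() != L || b.ncol() != m) stop("matrices must share dimensions");
  if (w < 0) stop("window must be >= 0");
  NumericMatrix out(m, w + 1);
  for (int d = 0; d <= w; ++d) {
    for (int i = 0; i + d < m; ++i) {
      const double *x = &a(0, i);
      const double *y = &b(0, i + d);
      // four accumulators keep the FP adds pipelined
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
      int l = 0;
      for (; l + 3 < L; l += 4) {
        s0 += x[l] * y[l];
        s1 += x[l + 1] * y[l + 1];
        s2 += x[l + 2] * y[l + 2];
        s3 += x[l + 3] * y[l + 3];
      }
      for (; l < L; ++l) s0 += x[l] * y[l];
      out(i, d) = s0 + s1 + s2 + s3;
    }
  }
  return out;
}
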