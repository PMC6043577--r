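#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

// 2x2 complex matrix, column-major: m00 m10 m01 m11
struct C22 {
  cd a, c, b, d; // [[a, b], [c, d]]
};

static inline C22 mul(const C22 &x, const C22 &y) {
  C22 r;
  r.a = x.a * y.a + x.b * y.c;
  r.c = x.c * y.a + x.d * y.c;
  r.b = x.a * y.b + x.b * y.d;
  r.d = x.c * y.b + x.d * y.d;
  return r;
}

static inline C22 conj2(const C22 &x) {
  C22 r;
  r.a = std::conj(x.a); r.b = std::conj(x.b);
  r.c = std::conj(x.c); r.d = std::conj(x.d);
  return r;
}

// exp(M*t) for 2x2 complex M, closed form via the Cayley-Hamilton split
// M = m*I + N with tr(N) = 0: exp(M t) = e^{m t} (cosh(D t) I + sinh(D t)/D * N),
// D^2 = ((a-d)/2)^2 + b*c.
static C22 expm2(const C22 &m, double t) {
  cd mean = 0.5 * (m.a + m.d);
  cd p = 0.5 * (m.a - m.d);
  cd D2 = p * p + m.b * m.c;
  cd D = std::sqrt(D2);
  cd ch, shD; // cosh(D t), sinh(D t)/D
  cd Dt = D * t;
  if (std::abs(Dt) < 1e-6) {
    // series: cosh(x) ~ 1 + x^2/2, sinh(x)/x ~ 1 + x^2/6
    ch = 1.0 + 0.5 * Dt * Dt;
    shD = t * (1.0 + Dt * Dt / 6.0);
  } else {
    ch = std::cosh(Dt);
    shD = std::sinh(Dt) / D;
  }
  cd e = std::exp(mean * t);
  C22 r;
  r.a = e * (ch + shD * p);
  r.d = e * (ch - shD * p);
  r.b = e * shD * m.b;
  r.c = e * shD * m.c;
  return r;
}

// matrix power by binary exponentiation
static C22 mpow(C22 base, int n) {
  C22 r; r.a = 1.0; r.b = 0.0; r.c = 0.0; r.d = 1.0;
  while (n > 0) {
    if (n & 1) r = mul(r, base);
    base = mul(base, base);
    n >>= 1;
  }
  return r;
}

// Single-point numerical two-state CPMG R2,eff.
// Magnetization (M_A, M_B) evolves under
//   L = [[-kab - r20,            kba          ],
//        [ kab,        -kba - r20 + i*dw_rad ]]
// with ideal instantaneous 180-degree pulses (complex conjugation) every
// 2*tau, tau = T/(4*n_blocks) per quarter... here one echo block is
// tau - 180 - tau with tau = T/(2*n) / 2; n blocks fill T exactly.
// The two-block propagator is the palindromic P * P~ * P~ * P.
static double bm_one(double kab, double kba, double dw_rad, double r20,
                     double nu, double t_relax) {
  double nb_real = 2.0 * t_relax * nu;      // echo blocks in T_relax
  int n = (int)std::lround(nb_real);
  if (n < 1) n = 1;
  double tau = t_relax / (2.0 * n);         // half of one echo block
  // Free-precession Liouvillian (r20 split out additively: L = L0 - r20*I)
  C22 L;
  L.a = cd(-kab, 0.0);
  L.b = cd(kba, 0.0);
  L.c = cd(kab, 0.0);
  L.d = cd(-kba, dw_rad);
  C22 P = expm2(L, tau);
  C22 Pc = conj2(P);
  // propagator over two echo blocks (duration 4*tau)
  C22 V = mul(mul(P, Pc), mul(Pc, P));
  int half = n / 2;
  C22 U = mpow(V, half);
  if (n % 2 == 1) {
    // leftover single block: P * conj(P); outer conjugation does not
    // change magnitudes
    C22 Q = mul(P, Pc);
    U = mul(Q, U);
  }
  double pB = kab / (kab + kba);
  double pA = 1.0 - pB;
  cd MA = U.a * pA + U.b * pB;
  double mag = std::abs(MA) / pA;
  if (!(mag > 0.0) || !std::isfinite(mag))
    return NA_REAL;
  return r20 - std::log(mag) / t_relax;
}

//' @noRd
// [[Rcpp::export(name = ".bm_r2eff_cpp")]]
NumericVector bm_r2eff_cpp(NumericVector kab, NumericVector kba,
                           NumericVector dw_rad, NumericVector r20,
                           NumericVector nu_cpmg, double t_relax) {
  R_xlen_t nn = nu_cpmg.size();
  bool scalar_par = (kab.size() == 1);
  if (scalar_par) {
    if (kba.size() != 1 || dw_rad.size() != 1 || r20.size() != 1)
      stop("parameter vectors must all be length 1 or all match nu_cpmg");
  } else {
    if (kab.size() != nn || kba.size() != nn || dw_rad.size() != nn ||
        r20.size() != nn)
      stop("parameter vectors must all be length 1 or all match nu_cpmg");
  }
  NumericVector out(nn);
  for (R_xlen_t i = 0; i < nn; ++i) {
    R_xlen_t j = scalar_par ? 0 : i;
    out[i] = bm_one(kab[j], kba[j], dw_rad[j], r20[j], nu_cpmg[i], t_relax);
  }
  return out;
}
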