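// Molecular integrals over generalized contracted Cartesian Gaussians
// via the McMurchie-Davidson scheme (Hermite expansion + Boys function).
//
// A basis function is a sum of primitive terms c * x^i y^j z^k exp(-a r^2)
// centred at a point; contracted AOs use one monomial and several exponents,
// real solid-harmonic projection functions use several monomials and one
// exponent.  The flat representation (nterm, centres, exponents, coeffs,
// monomials) is assembled on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_n(x), n = 0..nmax, by downward recursion (series at the top
// order) for moderate x and upward recursion from erf for large x.
static void boys(int nmax, double x, std::vector<double> &F) {
  F.assign(nmax + 1, 0.0);
  if (x < 1e-14) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x > 35.0) {
    // upward: stable since exp(-x) is negligible relative to F_n
    F[0] = 0.5 * std::sqrt(PI / x) * std::erf(std::sqrt(x));
    double ex = std::exp(-x);
    for (int n = 1; n <= nmax; ++n)
      F[n] = ((2.0 * n - 1.0) * F[n - 1] - ex) / (2.0 * x);
    return;
  }
  // series for F_nmax: F_m(x) = exp(-x) * sum_k (2m-1)!! (2x)^k / (2m+2k+1)!!
  double ex = std::exp(-x);
  double term = 1.0 / (2.0 * nmax + 1.0);
  double sum = term;
  for (int k = 1; k < 200; ++k) {
    term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[nmax] = ex * sum;
  double ex2 = std::exp(-x);
  for (int n = nmax - 1; n >= 0; --n)
    F[n] = (2.0 * x * F[n + 1] + ex2) / (2.0 * n + 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficient E_t^{ij} for the product of two 1D Cartesian
// Gaussians, Qx = Ax - Bx (Helgaker-Taylor recursion).
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b;
  double q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b) -
           (q * Qx / a) * Ecoef(i - 1, j, t, Qx, a, b) +
           (t + 1.0) * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b) +
         (q * Qx / b) * Ecoef(i, j - 1, t, Qx, a, b) +
         (t + 1.0) * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Hermite Coulomb integral R^n_{tuv}
static double Rtuv(int t, int u, int v, int n, double p, double PCx,
                   double PCy, double PCz, const std::vector<double> &F) {
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    for (int k = 0; k < n; ++k) val *= -2.0 * p;
    return val;
  }
  if (t > 0) {
    double val = PCx * Rtuv(t - 1, u, v, n + 1, p, PCx, PCy, PCz, F);
    if (t > 1) val += (t - 1) * Rtuv(t - 2, u, v, n + 1, p, PCx, PCy, PCz, F);
    return val;
  }
  if (u > 0) {
    double val = PCy * Rtuv(t, u - 1, v, n + 1, p, PCx, PCy, PCz, F);
    if (u > 1) val += (u - 1) * Rtuv(t, u - 2, v, n + 1, p, PCx, PCy, PCz, F);
    return val;
  }
  double val = PCz * Rtuv(t, u, v - 1, n + 1, p, PCx, PCy, PCz, F);
  if (v > 1) val += (v - 1) * Rtuv(t, u, v - 2, n + 1, p, PCx, PCy, PCz, F);
  return val;
}

// ---------------------------------------------------------------------------
// primitive 1D overlap pieces and 3D primitive integrals

static double prim_overlap(double a, const double *A, const int *la, double b,
                           const double *B, const int *lb) {
  double p = a + b;
  double s = std::pow(PI / p, 1.5);
  for (int d = 0; d < 3; ++d)
    s *= Ecoef(la[d], lb[d], 0, A[d] - B[d], a, b);
  return s;
}

static double prim_kinetic(double a, const double *A, const int *la, double b,
                           const double *B, const int *lb) {
  int l2 = lb[0], m2 = lb[1], n2 = lb[2];
  int lp[3];
  double term = b * (2.0 * (l2 + m2 + n2) + 3.0) *
                prim_overlap(a, A, la, b, B, lb);
  for (int d = 0; d < 3; ++d) {
    lp[0] = l2; lp[1] = m2; lp[2] = n2;
    lp[d] += 2;
    term -= 2.0 * b * b * prim_overlap(a, A, la, b, B, lp);
    if (lb[d] >= 2) {
      lp[d] -= 4;
      term -= 0.5 * lb[d] * (lb[d] - 1.0) * prim_overlap(a, A, la, b, B, lp);
    }
  }
  return term;
}

static double prim_nuclear(double a, const double *A, const int *la, double b,
                           const double *B, const int *lb, const double *C) {
  double p = a + b;
  double P[3];
  for (int d = 0; d < 3; ++d) P[d] = (a * A[d] + b * B[d]) / p;
  double PC2 = 0.0;
  for (int d = 0; d < 3; ++d) PC2 += (P[d] - C[d]) * (P[d] - C[d]);
  int nmax = la[0] + la[1] + la[2] + lb[0] + lb[1] + lb[2];
  std::vector<double> F;
  boys(nmax, p * PC2, F);
  double val = 0.0;
  for (int t = 0; t <= la[0] + lb[0]; ++t)
    for (int u = 0; u <= la[1] + lb[1]; ++u)
      for (int v = 0; v <= la[2] + lb[2]; ++v) {
        double E = Ecoef(la[0], lb[0], t, A[0] - B[0], a, b) *
                   Ecoef(la[1], lb[1], u, A[1] - B[1], a, b) *
                   Ecoef(la[2], lb[2], v, A[2] - B[2], a, b);
        if (E == 0.0) continue;
        val += E * Rtuv(t, u, v, 0, p, P[0] - C[0], P[1] - C[1], P[2] - C[2], F);
      }
  return val * 2.0 * PI / p;
}

// ---------------------------------------------------------------------------
// flat basis representation handed over from R

struct Basis {
  std::vector<int> start;           // term offset per function
  std::vector<int> nterm;
  std::vector<double> cx, cy, cz;   // per-term centre
  std::vector<double> alpha, coef;  // per-term exponent / coefficient
  std::vector<int> li, lj, lk;      // per-term monomial
  int n;                            // number of functions
};

static Basis unpack(const List &b) {
  Basis out;
  IntegerVector nterm = b["nterm"];
  NumericVector cx = b["cx"], cy = b["cy"], cz = b["cz"];
  NumericVector alpha = b["alpha"], coef = b["coef"];
  IntegerVector li = b["li"], lj = b["lj"], lk = b["lk"];
  out.n = nterm.size();
  out.nterm.assign(nterm.begin(), nterm.end());
  out.cx.assign(cx.begin(), cx.end());
  out.cy.assign(cy.begin(), cy.end());
  out.cz.assign(cz.begin(), cz.end());
  out.alpha.assign(alpha.begin(), alpha.end());
  out.coef.assign(coef.begin(), coef.end());
  out.li.assign(li.begin(), li.end());
  out.lj.assign(lj.begin(), lj.end());
  out.lk.assign(lk.begin(), lk.end());
  out.start.resize(out.n);
  int s = 0;
  for (int f = 0; f < out.n; ++f) { out.start[f] = s; s += out.nterm[f]; }
  return out;
}

// [[Rcpp::export(name = ".ints_overlap")]]
NumericMatrix ints_overlap(List basisA, List basisB) {
  Basis A = unpack(basisA), B = unpack(basisB);
  NumericMatrix S(A.n, B.n);
  for (int f = 0; f < A.n; ++f)
    for (int g = 0; g < B.n; ++g) {
      double s = 0.0;
      for (int t = A.start[f]; t < A.start[f] + A.nterm[f]; ++t) {
        double Ac[3] = {A.cx[t], A.cy[t], A.cz[t]};
        int la[3] = {A.li[t], A.lj[t], A.lk[t]};
        for (int u = B.start[g]; u < B.start[g] + B.nterm[g]; ++u) {
          double Bc[3] = {B.cx[u], B.cy[u], B.cz[u]};
          int lb[3] = {B.li[u], B.lj[u], B.lk[u]};
          s += A.coef[t] * B.coef[u] *
               prim_overlap(A.alpha[t], Ac, la, B.alpha[u], Bc, lb);
        }
      }
      S(f, g) = s;
    }
  return S;
}

// [[Rcpp::export(name = ".ints_kinetic")]]
NumericMatrix ints_kinetic(List basis) {
  Basis A = unpack(basis);
  NumericMatrix T(A.n, A.n);
  for (int f = 0; f < A.n; ++f)
    for (int g = f; g < A.n; ++g) {
      double s = 0.0;
      for (int t = A.start[f]; t < A.start[f] + A.nterm[f]; ++t) {
        double Ac[3] = {A.cx[t], A.cy[t], A.cz[t]};
        int la[3] = {A.li[t], A.lj[t], A.lk[t]};
        for (int u = A.start[g]; u < A.start[g] + A.nterm[g]; ++u) {
          double Bc[3] = {A.cx[u], A.cy[u], A.cz[u]};
          int lb[3] = {A.li[u], A.lj[u], A.lk[u]};
          s += A.coef[t] * A.coef[u] *
               prim_kinetic(A.alpha[t], Ac, la, A.alpha[u], Bc, lb);
        }
      }
      T(f, g) = s;
      T(g, f) = s;
    }
  return T;
}

// [[Rcpp::export(name = ".ints_nuclear")]]
NumericMatrix ints_nuclear(List basis, NumericVector charges,
                           NumericMatrix centres) {
  Basis A = unpack(basis);
  int nat = charges.size();
  NumericMatrix V(A.n, A.n);
  for (int f = 0; f < A.n; ++f)
    for (int g = f; g < A.n; ++g) {
      double s = 0.0;
      for (int t = A.start[f]; t < A.start[f] + A.nterm[f]; ++t) {
        double Ac[3] = {A.cx[t], A.cy[t], A.cz[t]};
        int la[3] = {A.li[t], A.lj[t], A.lk[t]};
        for (int u = A.start[g]; u < A.start[g] + A.nterm[g]; ++u) {
          double Bc[3] = {A.cx[u], A.cy[u], A.cz[u]};
          int lb[3] = {A.li[u], A.lj[u], A.lk[u]};
          double cc = A.coef[t] * A.coef[u];
          for (int at = 0; at < nat; ++at) {
            double C[3] = {centres(at, 0), centres(at, 1), centres(at, 2)};
            s -= cc * charges[at] *
                 prim_nuclear(A.alpha[t], Ac, la, A.alpha[u], Bc, lb, C);
          }
        }
      }
      V(f, g) = s;
      V(g, f) = s;
    }
  return V;
}

// ---------------------------------------------------------------------------
// ERI: per ordered function pair, precompute the Hermite distribution
// Lambda_{tuv} (summed over primitive term pairs sharing one p and centre P is
// NOT possible across term pairs, so we keep one distribution per term pair).

struct HermDist {
  double p;          // total exponent
  double P[3];       // product centre
  int tmax[3];       // Hermite orders per dimension
  std::vector<double> lam;  // Lambda_{tuv}, dims (tmax+1)
};

static void pair_dists(const Basis &A, int f, int g,
                       std::vector<HermDist> &out) {
  out.clear();
  for (int t = A.start[f]; t < A.start[f] + A.nterm[f]; ++t) {
    double Ac[3] = {A.cx[t], A.cy[t], A.cz[t]};
    int la[3] = {A.li[t], A.lj[t], A.lk[t]};
    for (int u = A.start[g]; u < A.start[g] + A.nterm[g]; ++u) {
      double Bc[3] = {A.cx[u], A.cy[u], A.cz[u]};
      int lb[3] = {A.li[u], A.lj[u], A.lk[u]};
      double a = A.alpha[t], b = A.alpha[u];
      HermDist hd;
      hd.p = a + b;
      for (int d = 0; d < 3; ++d) {
        hd.P[d] = (a * Ac[d] + b * Bc[d]) / hd.p;
        hd.tmax[d] = la[d] + lb[d];
      }
      double cc = A.coef[t] * A.coef[u];
      int n0 = hd.tmax[0] + 1, n1 = hd.tmax[1] + 1, n2 = hd.tmax[2] + 1;
      hd.lam.assign(n0 * n1 * n2, 0.0);
      for (int tt = 0; tt < n0; ++tt) {
        double Ex = Ecoef(la[0], lb[0], tt, Ac[0] - Bc[0], a, b);
        if (Ex == 0.0) continue;
        for (int uu = 0; uu < n1; ++uu) {
          double Ey = Ecoef(la[1], lb[1], uu, Ac[1] - Bc[1], a, b);
          if (Ey == 0.0) continue;
          for (int vv = 0; vv < n2; ++vv) {
            double Ez = Ecoef(la[2], lb[2], vv, Ac[2] - Bc[2], a, b);
            hd.lam[(tt * n1 + uu) * n2 + vv] = cc * Ex * Ey * Ez;
          }
        }
      }
      out.push_back(hd);
    }
  }
}

// [[Rcpp::export(name = ".ints_eri")]]
NumericVector ints_eri(List basis) {
  Basis A = unpack(basis);
  int n = A.n;
  // Hermite distributions for every unordered pair
  int npair = n * (n + 1) / 2;
  std::vector<std::vector<HermDist> > dists(npair);
  std::vector<std::pair<int, int> > pairs(npair);
  int idx = 0;
  for (int f = 0; f < n; ++f)
    for (int g = f; g < n; ++g) {
      pair_dists(A, f, g, dists[idx]);
      pairs[idx] = std::make_pair(f, g);
      ++idx;
    }
  NumericVector out((R_xlen_t)n * n * n * n);
  std::vector<double> F;
  for (int pq = 0; pq < npair; ++pq) {
    for (int rs = pq; rs < npair; ++rs) {
      double val = 0.0;
      for (size_t d1 = 0; d1 < dists[pq].size(); ++d1) {
        const HermDist &h1 = dists[pq][d1];
        for (size_t d2 = 0; d2 < dists[rs].size(); ++d2) {
          const HermDist &h2 = dists[rs][d2];
          double alpha = h1.p * h2.p / (h1.p + h2.p);
          double PQ[3] = {h1.P[0] - h2.P[0], h1.P[1] - h2.P[1],
                          h1.P[2] - h2.P[2]};
          double R2 = PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2];
          int nmax = h1.tmax[0] + h1.tmax[1] + h1.tmax[2] + h2.tmax[0] +
                     h2.tmax[1] + h2.tmax[2];
          boys(nmax, alpha * R2, F);
          double fac = 2.0 * std::pow(PI, 2.5) /
                       (h1.p * h2.p * std::sqrt(h1.p + h2.p));
          int n11 = h1.tmax[1] + 1, n12 = h1.tmax[2] + 1;
          int n21 = h2.tmax[1] + 1, n22 = h2.tmax[2] + 1;
          double acc = 0.0;
          for (int t = 0; t <= h1.tmax[0]; ++t)
            for (int u = 0; u <= h1.tmax[1]; ++u)
              for (int v = 0; v <= h1.tmax[2]; ++v) {
                double l1 = h1.lam[(t * n11 + u) * n12 + v];
                if (l1 == 0.0) continue;
                for (int tau = 0; tau <= h2.tmax[0]; ++tau)
                  for (int nu = 0; nu <= h2.tmax[1]; ++nu)
                    for (int ph = 0; ph <= h2.tmax[2]; ++ph) {
                      double l2 = h2.lam[(tau * n21 + nu) * n22 + ph];
                      if (l2 == 0.0) continue;
                      double sgn = ((tau + nu + ph) % 2 == 0) ? 1.0 : -1.0;
                      acc += l1 * l2 * sgn *
                             Rtuv(t + tau, u + nu, v + ph, 0, alpha, PQ[0],
                                  PQ[1], PQ[2], F);
                    }
              }
          val += fac * acc;
        }
      }
      // scatter with 8-fold permutational symmetry
      int f = pairs[pq].first, g = pairs[pq].second;
      int r = pairs[rs].first, s = pairs[rs].second;
      R_xlen_t N = n;
      int fi[8] = {f, g, f, g, r, r, s, s};
      int gi[8] = {g, f, g, f, s, s, r, r};
      int ri[8] = {r, r, s, s, f, g, f, g};
      int si[8] = {s, s, r, r, g, f, g, f};
      for (int k = 0; k < 8; ++k) {
        R_xlen_t off = fi[k] + N * (gi[k] + N * (ri[k] + N * (R_xlen_t)si[k]));
        out[off] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}
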