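// Finite-volume kernels for the axisymmetric flushing solver.
//
// Staggered (MAC) grid in cylindrical (r, z), SI units:
//   cells:    nr x nz, centres r0+(i+1/2)dr, z0+(j+1/2)dz
//   ur:      (nr+1) x nz   radial faces
//   uz:       nr x (nz+1)  axial faces
//   solid:    nr x nz, 1 = blocked (guiding catheter wall)
// Scheme: semi-Lagrangian momentum advection (RK2, bilinear), implicit
// direction-split viscous diffusion (tridiagonal), dimension-split MUSCL
// (minmod) conservative species advection, conservative implicit scalar
// diffusion. The pressure projection lives in R (cached sparse Cholesky).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double x, double a, double b) {
  return x < a ? a : (x > b ? b : x);
}

static inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::fabs(a) < std::fabs(b) ? a : b;
}

// bilinear sample of matrix m whose node (i,j) sits at (x0+i*dx, y0+j*dy)
static double bilin(const NumericMatrix& m, double x0, double dx,
                    double y0, double dy, double x, double y) {
  int n1 = m.nrow(), n2 = m.ncol();
  double fi = clampd((x - x0) / dx, 0.0, (double)(n1 - 1));
  double fj = clampd((y - y0) / dy, 0.0, (double)(n2 - 1));
  int i0 = std::min((int)fi, n1 - 2); if (i0 < 0) i0 = 0;
  int j0 = std::min((int)fj, n2 - 2); if (j0 < 0) j0 = 0;
  double a = fi - i0, b = fj - j0;
  if (n1 == 1) { i0 = 0; a = 0.0; }
  if (n2 == 1) { j0 = 0; b = 0.0; }
  int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1);
  return (1 - a) * (1 - b) * m(i0, j0) + a * (1 - b) * m(i1, j0)
       + (1 - a) * b * m(i0, j1) + a * b * m(i1, j1);
}

static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d) {
  int n = (int)d.size();
  for (int k = 1; k < n; ++k) {
    double m = a[k] / b[k - 1];
    b[k] -= m * c[k - 1];
    d[k] -= m * d[k - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int k = n - 2; k >= 0; --k) d[k] = (d[k] - c[k] * d[k + 1]) / b[k];
}

// ---------------------------------------------------------------- advection

// [[Rcpp::export]]
List sl_advect_cpp(const NumericMatrix& ur, const NumericMatrix& uz,
                   double dt, double r0, double z0, double dr, double dz) {
  int nr = uz.nrow(), nz = ur.ncol();
  NumericMatrix urn(nr + 1, nz), uzn(nr, nz + 1);
  double rmin = r0, rmax = r0 + nr * dr, zmin = z0, zmax = z0 + nz * dz;
  auto velR = [&](double r, double z) {
    return bilin(ur, r0, dr, z0 + 0.5 * dz, dz, r, z);
  };
  auto velZ = [&](double r, double z) {
    return bilin(uz, r0 + 0.5 * dr, dr, z0, dz, r, z);
  };
  auto depart = [&](double r, double z, double& rd, double& zd) {
    double u1 = velR(r, z), w1 = velZ(r, z);
    double rm = clampd(r - 0.5 * dt * u1, rmin, rmax);
    double zm = clampd(z - 0.5 * dt * w1, zmin, zmax);
    double u2 = velR(rm, zm), w2 = velZ(rm, zm);
    rd = clampd(r - dt * u2, rmin, rmax);
    zd = clampd(z - dt * w2, zmin, zmax);
  };
  for (int j = 0; j < nz; ++j) {
    double z = z0 + (j + 0.5) * dz;
    for (int i = 0; i <= nr; ++i) {
      double rd, zd;
      depart(r0 + i * dr, z, rd, zd);
      urn(i, j) = velR(rd, zd);
    }
  }
  for (int j = 0; j <= nz; ++j) {
    double z = z0 + j * dz;
    for (int i = 0; i < nr; ++i) {
      double rd, zd;
      depart(r0 + (i + 0.5) * dr, z, rd, zd);
      uzn(i, j) = velZ(rd, zd);
    }
  }
  return List::create(_["ur"] = urn, _["uz"] = uzn);
}

// semi-Lagrangian advection of a cell-centred scalar (used by the k-omega
// closure; the species uses the conservative MUSCL kernel below)
// [[Rcpp::export]]
NumericMatrix scalar_sl_cpp(const NumericMatrix& f, const NumericMatrix& ur,
                            const NumericMatrix& uz, double dt, double r0,
                            double z0, double dr, double dz,
                            const IntegerMatrix& solid) {
  int nr = f.nrow(), nz = f.ncol();
  NumericMatrix out(nr, nz);
  double rmin = r0, rmax = r0 + nr * dr, zmin = z0, zmax = z0 + nz * dz;
  auto velR = [&](double r, double z) {
    return bilin(ur, r0, dr, z0 + 0.5 * dz, dz, r, z);
  };
  auto velZ = [&](double r, double z) {
    return bilin(uz, r0 + 0.5 * dr, dr, z0, dz, r, z);
  };
  for (int j = 0; j < nz; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (solid(i, j)) { out(i, j) = f(i, j); continue; }
      double r = r0 + (i + 0.5) * dr, z = z0 + (j + 0.5) * dz;
      double u1 = velR(r, z), w1 = velZ(r, z);
      double rm = clampd(r - 0.5 * dt * u1, rmin, rmax);
      double zm = clampd(z - 0.5 * dt * w1, zmin, zmax);
      double rd = clampd(r - dt * velR(rm, zm), rmin, rmax);
      double zd = clampd(z - dt * velZ(rm, zm), zmin, zmax);
      out(i, j) = bilin(f, r0 + 0.5 * dr, dr, z0 + 0.5 * dz, dz, rd, zd);
    }
  }
  return out;
}

// ------------------------------------------------------- viscous diffusion

// Implicit direction-split viscous step for both velocity components.
// nu: cell-centred effective kinematic viscosity. Boundary handling:
//  - walls / solid: no-slip (Dirichlet 0, half-cell ghost where staggered)
//  - inlet (j = 0 axial face): uz prescribed, ur = 0 at the inlet plane
//  - outlet: zero gradient
// [[Rcpp::export]]
List visc_diffuse_cpp(const NumericMatrix& ur0, const NumericMatrix& uz0,
                      const NumericMatrix& nu, double dt, double r0,
                      double dr, double dz, const IntegerMatrix& solid) {
  int nr = nu.nrow(), nz = nu.ncol();
  NumericMatrix ur = clone(ur0), uz = clone(uz0);
  auto fluid = [&](int i, int j) {
    return i >= 0 && i < nr && j >= 0 && j < nz && !solid(i, j);
  };
  // node activity
  auto uzAct = [&](int i, int j) { // j in 0..nz
    if (j == 0) return false;                       // prescribed inlet
    if (j == nz) return fluid(i, nz - 1);           // outlet face
    return fluid(i, j - 1) && fluid(i, j);
  };
  auto urAct = [&](int i, int j) { // i in 0..nr
    if (i == 0 || i == nr) return false;            // catheter / vessel wall
    return fluid(i - 1, j) && fluid(i, j);
  };
  auto nuUz = [&](int i, int j) { // viscosity at a uz node
    if (j == 0) return nu(i, 0);
    if (j == nz) return nu(i, nz - 1);
    double s = 0; int n = 0;
    if (fluid(i, j - 1)) { s += nu(i, j - 1); ++n; }
    if (fluid(i, j)) { s += nu(i, j); ++n; }
    return n ? s / n : 0.0;
  };
  auto nuUr = [&](int i, int j) {
    double s = 0; int n = 0;
    if (fluid(i - 1, j)) { s += nu(i - 1, j); ++n; }
    if (fluid(i, j)) { s += nu(i, j); ++n; }
    return n ? s / n : 0.0;
  };

  std::vector<double> A, B, C, D; std::vector<int> idx;
  A.reserve(nr + nz + 2); B.reserve(nr + nz + 2);
  C.reserve(nr + nz + 2); D.reserve(nr + nz + 2); idx.reserve(nr + nz + 2);

  // --- uz radial sweep: (1/r) d/dr ( r nu du/dr ), nodes at cell radii
  for (int j = 1; j <= nz; ++j) {
    int i = 0;
    while (i < nr) {
      if (!uzAct(i, j)) { ++i; continue; }
      int a = i; while (i < nr && uzAct(i, j)) ++i; int b = i - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int ii = a + k;
        double rc = r0 + (ii + 0.5) * dr;
        double rfm = r0 + ii * dr, rfp = r0 + (ii + 1) * dr;
        double nlo = (k == 0) ? nuUz(ii, j)
                              : 0.5 * (nuUz(ii, j) + nuUz(ii - 1, j));
        double nhi = (k == n - 1) ? nuUz(ii, j)
                                  : 0.5 * (nuUz(ii, j) + nuUz(ii + 1, j));
        double clo = dt * rfm * nlo / (rc * dr * dr);
        double chi = dt * rfp * nhi / (rc * dr * dr);
        B[k] = 1.0 + clo + chi;
        // wall ends use a second-order one-sided gradient through the two
        // nearest nodes and the no-slip wall value: du/dr|w = (9u1-u2)/(3 dr)
        if (k > 0) A[k] = -clo;
        else if (n > 1) { B[k] += 2.0 * clo; C[k] -= clo / 3.0; }
        else B[k] += clo; // single-node segment: half-cell ghost
        if (k < n - 1) C[k] += -chi;
        else if (n > 1) { B[k] += 2.0 * chi; A[k] -= chi / 3.0; }
        else B[k] += chi;
        D[k] = uz(ii, j);
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) uz(a + k, j) = D[k];
    }
  }
  // --- uz axial sweep: d/dz ( nu du/dz ), node spacing dz
  for (int i = 0; i < nr; ++i) {
    int j = 1;
    while (j <= nz) {
      if (!uzAct(i, j)) { ++j; continue; }
      int a = j; while (j <= nz && uzAct(i, j)) ++j; int b = j - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int jj = a + k;
        double nlo = (jj >= 1) ? nu(i, std::min(jj - 1, nz - 1)) : nu(i, 0);
        double nhi = (jj < nz) ? nu(i, jj) : nu(i, nz - 1);
        double clo = dt * nlo / (dz * dz);
        double chi = dt * nhi / (dz * dz);
        B[k] = 1.0 + clo + chi;
        D[k] = uz(i, jj);
        if (k > 0) A[k] = -clo;
        else D[k] += clo * uz(i, a - 1);   // known face below (inlet or 0)
        if (k < n - 1) C[k] = -chi;
        else if (b < nz) D[k] += chi * uz(i, b + 1); // known 0 face above
        else B[k] -= chi;                  // outlet: zero gradient
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) uz(i, a + k) = D[k];
    }
  }
  // --- ur radial sweep: nu (u'' + u'/r - u/r^2), nodes at radial faces
  for (int j = 0; j < nz; ++j) {
    int i = 1;
    while (i < nr) {
      if (!urAct(i, j)) { ++i; continue; }
      int a = i; while (i < nr && urAct(i, j)) ++i; int b = i - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int ii = a + k;
        double rn = r0 + ii * dr;
        double nuk = nuUr(ii, j);
        double c2 = dt * nuk / (dr * dr);
        double c1 = dt * nuk / (2.0 * rn * dr);
        B[k] = 1.0 + 2.0 * c2 + dt * nuk / (rn * rn);
        if (k > 0) A[k] = -(c2 - c1);      // neighbour value 0 otherwise
        if (k < n - 1) C[k] = -(c2 + c1);
        D[k] = ur(ii, j);
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) ur(a + k, j) = D[k];
    }
  }
  // --- ur axial sweep: d/dz ( nu du/dz ), nodes at cell-centre z
  for (int i = 1; i < nr; ++i) {
    int j = 0;
    while (j < nz) {
      if (!urAct(i, j)) { ++j; continue; }
      int a = j; while (j < nz && urAct(i, j)) ++j; int b = j - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int jj = a + k;
        double nlo = (k == 0) ? nuUr(i, jj)
                              : 0.5 * (nuUr(i, jj) + nuUr(i, jj - 1));
        double nhi = (k == n - 1) ? nuUr(i, jj)
                                  : 0.5 * (nuUr(i, jj) + nuUr(i, jj + 1));
        double clo = dt * nlo / (dz * dz);
        double chi = dt * nhi / (dz * dz);
        B[k] = 1.0 + clo + chi;
        D[k] = ur(i, jj);
        if (k > 0) A[k] = -clo;
        else if (a == 0) B[k] += clo;      // inlet plane: ghost -u
        // else: neighbour inactive node value 0 (Dirichlet, nothing to add)
        if (k < n - 1) C[k] = -chi;
        else if (b == nz - 1) B[k] -= chi; // outlet: zero gradient
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) ur(i, a + k) = D[k];
    }
  }
  return List::create(_["ur"] = ur, _["uz"] = uz);
}

// --------------------------------------------------------- species advection

// Dimension-split conservative MUSCL (minmod) advection of the erythrocyte
// mass fraction. Inlet composition prescribed per radial cell (w_inlet),
// outlet is upwinded (outflow). Returns the advected field and the scalar
// volume transported through the inlet/outlet boundary over the whole call
// (per unit azimuthal angle, m^3 of "w" units).
// [[Rcpp::export]]
List species_advect_cpp(const NumericMatrix& w0, const NumericMatrix& ur,
                        const NumericMatrix& uz, double dt, int nsub,
                        double r0, double dr, double dz,
                        const IntegerMatrix& solid,
                        const NumericVector& w_inlet) {
  int nr = w0.nrow(), nz = w0.ncol();
  NumericMatrix w = clone(w0);
  double in_tot = 0.0, out_tot = 0.0;
  double dts = dt / nsub;
  auto fl = [&](int i, int j) { return !solid(i, j); };

  std::vector<double> F(std::max(nr, nz) + 1);
  for (int s = 0; s < nsub; ++s) {
    bool zfirst = (s % 2 == 0);
    for (int pass = 0; pass < 2; ++pass) {
      bool doZ = (pass == 0) == zfirst;
      if (doZ) {
        // axial sweep, column by column
        for (int i = 0; i < nr; ++i) {
          double rc = r0 + (i + 0.5) * dr;
          for (int j = 0; j <= nz; ++j) {
            double u = uz(i, j);
            double wf;
            if (u == 0.0) { F[j] = 0.0; continue; }
            if (u > 0.0) {
              if (j == 0) wf = w_inlet[i];
              else {
                wf = w(i, j - 1);
                if (j >= 2 && j <= nz - 1 && fl(i, j - 1) && fl(i, j - 2) && fl(i, std::min(j, nz - 1)))
                  wf += 0.5 * minmod(w(i, j - 1) - w(i, j - 2),
                                     w(i, std::min(j, nz - 1)) - w(i, j - 1));
              }
            } else {
              if (j == nz) wf = w(i, nz - 1);        // zero-gradient backflow
              else {
                wf = w(i, j);
                if (j >= 1 && j <= nz - 2 && fl(i, j) && fl(i, j + 1) && fl(i, j - 1))
                  wf += 0.5 * minmod(w(i, j) - w(i, j + 1),
                                     w(i, j - 1) - w(i, j));
              }
            }
            F[j] = u * wf;
          }
          for (int j = 0; j < nz; ++j) {
            if (!fl(i, j)) continue;
            w(i, j) -= dts / dz * (F[j + 1] - F[j]);
          }
          in_tot += dts * rc * dr * F[0];
          out_tot += dts * rc * dr * F[nz];
        }
      } else {
        // radial sweep, row by row (walls carry ur = 0: no boundary flux)
        for (int j = 0; j < nz; ++j) {
          for (int i = 0; i <= nr; ++i) {
            double u = ur(i, j);
            if (u == 0.0) { F[i] = 0.0; continue; }
            double wf;
            if (u > 0.0) {
              wf = w(i - 1, j);
              if (i >= 2 && i <= nr - 1 && fl(i - 1, j) && fl(i - 2, j) && fl(std::min(i, nr - 1), j))
                wf += 0.5 * minmod(w(i - 1, j) - w(i - 2, j),
                                   w(std::min(i, nr - 1), j) - w(i - 1, j));
            } else {
              wf = w(i, j);
              if (i >= 1 && i <= nr - 2 && fl(i, j) && fl(i + 1, j) && fl(i - 1, j))
                wf += 0.5 * minmod(w(i, j) - w(i + 1, j),
                                   w(i - 1, j) - w(i, j));
            }
            F[i] = u * wf;
          }
          for (int i = 0; i < nr; ++i) {
            if (!fl(i, j)) continue;
            double rc = r0 + (i + 0.5) * dr;
            double rfm = r0 + i * dr, rfp = r0 + (i + 1) * dr;
            w(i, j) -= dts / (rc * dr) * (rfp * F[i + 1] - rfm * F[i]);
          }
        }
      }
    }
  }
  return List::create(_["w"] = w, _["influx"] = in_tot, _["outflux"] = out_tot);
}

// ------------------------------------------------- scalar implicit diffusion

// Conservative implicit (direction-split) diffusion of a cell-centred
// scalar with cell diffusivity D; zero-flux at every wall and at the
// inlet/outlet (transport through open boundaries is advective).
// [[Rcpp::export]]
NumericMatrix scalar_adi_cpp(const NumericMatrix& f0, const NumericMatrix& Dc,
                             double dt, double r0, double dr, double dz,
                             const IntegerMatrix& solid) {
  int nr = f0.nrow(), nz = f0.ncol();
  NumericMatrix f = clone(f0);
  auto fl = [&](int i, int j) {
    return i >= 0 && i < nr && j >= 0 && j < nz && !solid(i, j);
  };
  std::vector<double> A, B, C, D;
  // radial sweep
  for (int j = 0; j < nz; ++j) {
    int i = 0;
    while (i < nr) {
      if (!fl(i, j)) { ++i; continue; }
      int a = i; while (i < nr && fl(i, j)) ++i; int b = i - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int ii = a + k;
        double rc = r0 + (ii + 0.5) * dr;
        double rfm = r0 + ii * dr, rfp = r0 + (ii + 1) * dr;
        double dlo = (k == 0) ? 0.0 : 0.5 * (Dc(ii, j) + Dc(ii - 1, j));
        double dhi = (k == n - 1) ? 0.0 : 0.5 * (Dc(ii, j) + Dc(ii + 1, j));
        double clo = dt * rfm * dlo / (rc * dr * dr);
        double chi = dt * rfp * dhi / (rc * dr * dr);
        B[k] = 1.0 + clo + chi;
        if (k > 0) A[k] = -clo;
        if (k < n - 1) C[k] = -chi;
        D[k] = f(ii, j);
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) f(a + k, j) = D[k];
    }
  }
  // axial sweep
  for (int i = 0; i < nr; ++i) {
    int j = 0;
    while (j < nz) {
      if (!fl(i, j)) { ++j; continue; }
      int a = j; while (j < nz && fl(i, j)) ++j; int b = j - 1;
      int n = b - a + 1;
      A.assign(n, 0); B.assign(n, 0); C.assign(n, 0); D.assign(n, 0);
      for (int k = 0; k < n; ++k) {
        int jj = a + k;
        double dlo = (k == 0) ? 0.0 : 0.5 * (Dc(i, jj) + Dc(i, jj - 1));
        double dhi = (k == n - 1) ? 0.0 : 0.5 * (Dc(i, jj) + Dc(i, jj + 1));
        double clo = dt * dlo / (dz * dz);
        double chi = dt * dhi / (dz * dz);
        B[k] = 1.0 + clo + chi;
        if (k > 0) A[k] = -clo;
        if (k < n - 1) C[k] = -chi;
        D[k] = f(i, jj);
      }
      thomas(A, B, C, D);
      for (int k = 0; k < n; ++k) f(i, a + k) = D[k];
    }
  }
  return f;
}

// --------------------------------------------------------------turbulence

// Strain-rate magnitude |S| = sqrt(2 S_ij S_ij) at cell centres (axisymmetric,
// no swirl), with one-sided half-cell gradients against no-slip walls.
// [[Rcpp::export]]
NumericMatrix strain_rate_cpp(const NumericMatrix& ur, const NumericMatrix& uz,
                              double r0, double dr, double dz,
                              const IntegerMatrix& solid) {
  int nr = uz.nrow(), nz = ur.ncol();
  NumericMatrix S(nr, nz);
  auto fl = [&](int i, int j) {
    return i >= 0 && i < nr && j >= 0 && j < nz && !solid(i, j);
  };
  auto uzc = [&](int i, int j) { return 0.5 * (uz(i, j) + uz(i, j + 1)); };
  auto urc = [&](int i, int j) { return 0.5 * (ur(i, j) + ur(i + 1, j)); };
  for (int j = 0; j < nz; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!fl(i, j)) { S(i, j) = 0.0; continue; }
      double rc = r0 + (i + 0.5) * dr;
      double durdr = (ur(i + 1, j) - ur(i, j)) / dr;
      double duzdz = (uz(i, j + 1) - uz(i, j)) / dz;
      double uor = urc(i, j) / rc;
      double duzdr, durdz;
      bool lo = fl(i - 1, j), hi = fl(i + 1, j);
      if (lo && hi) duzdr = (uzc(i + 1, j) - uzc(i - 1, j)) / (2 * dr);
      else if (hi) duzdr = (uzc(i, j) - 0.0) / (0.5 * dr);  // wall half-cell below
      else if (lo) duzdr = (0.0 - uzc(i, j)) / (0.5 * dr);  // wall half-cell above
      else duzdr = 0.0;
      bool zlo = fl(i, j - 1), zhi = fl(i, j + 1);
      if (zlo && zhi) durdz = (urc(i, j + 1) - urc(i, j - 1)) / (2 * dz);
      else if (zhi) durdz = (urc(i, j + 1) - urc(i, j)) / dz;
      else if (zlo) durdz = (urc(i, j) - urc(i, j - 1)) / dz;
      else durdz = 0.0;
      double s2 = 2.0 * (durdr * durdr + uor * uor + duzdz * duzdz)
                + (duzdr + durdz) * (duzdr + durdz);
      S(i, j) = std::sqrt(s2);
    }
  }
  return S;
}
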