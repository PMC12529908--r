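// Becke molecular quadrature grid and GGA exchange-correlation evaluation
// (PBE exchange + PBE correlation, closed shell).  Functional derivatives
// are obtained by complex-step differentiation of the energy density,
// which is exact to machine precision for the analytic PBE forms.
#include <RcppArmadillo.h>
#include <complex>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- Gauss-Legendre nodes/weights on [-1, 1] -------------------------
static void gauss_legendre(int n, std::vector<double>& x,
                           std::vector<double>& w) {
  x.resize(n); w.resize(n);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p1 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    x[i] = -z; x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

static double becke_s(double mu) {
  // three iterations of f(x) = 1.5x - 0.5x^3
  for (int k = 0; k < 3; ++k) mu = 1.5 * mu - 0.5 * mu * mu * mu;
  return 0.5 * (1.0 - mu);
}

// centers: nat x 3 (Bohr); radii: per-atom radial scale (Bohr)
// Murray-Handy-Laming radial map r = R q^2/(1-q)^2, product angular grid.
// [[Rcpp::export]]
List cpp_becke_grid(arma::mat centers, arma::vec radii, int nrad, int ntheta) {
  int nat = centers.n_rows;
  std::vector<double> xt, wt;
  int nphi = 2 * ntheta;
  gauss_legendre(ntheta, xt, wt);
  int ntheta_in = std::max(6, ntheta / 2), nphi_in = 2 * ntheta_in;
  std::vector<double> xt_in, wt_in;
  gauss_legendre(ntheta_in, xt_in, wt_in);

  std::vector<double> px, py, pz, pw;
  std::vector<int> patom;
  for (int A = 0; A < nat; ++A) {
    double R = radii[A];
    for (int ir = 1; ir <= nrad; ++ir) {
      double q = (double)ir / (nrad + 1.0);
      double r = R * q * q / ((1.0 - q) * (1.0 - q));
      double drdq = 2.0 * R * q / std::pow(1.0 - q, 3);
      double wrad = drdq * r * r / (nrad + 1.0);
      bool inner = (3 * ir < nrad); // coarser angular set near nucleus
      const std::vector<double>& ct = inner ? xt_in : xt;
      const std::vector<double>& cw = inner ? wt_in : wt;
      int np = inner ? nphi_in : nphi;
      for (size_t it = 0; it < ct.size(); ++it) {
        double cth = ct[it], sth = std::sqrt(1.0 - cth * cth);
        for (int ip = 0; ip < np; ++ip) {
          double phi = 2.0 * M_PI * ip / np;
          double ux = sth * std::cos(phi), uy = sth * std::sin(phi), uz = cth;
          double x = centers(A, 0) + r * ux, y = centers(A, 1) + r * uy,
                 z = centers(A, 2) + r * uz;
          double wang = cw[it] * (2.0 * M_PI / np);
          double w = wrad * wang;
          if (nat > 1) {
            // Becke fuzzy-cell weight
            double Psum = 0.0, PA = 0.0;
            std::vector<double> d(nat);
            for (int B = 0; B < nat; ++B) {
              double dx = x - centers(B, 0), dy = y - centers(B, 1),
                     dz = z - centers(B, 2);
              d[B] = std::sqrt(dx * dx + dy * dy + dz * dz);
            }
            for (int B = 0; B < nat; ++B) {
              double P = 1.0;
              for (int C = 0; C < nat; ++C) {
                if (C == B) continue;
                double dx = centers(B, 0) - centers(C, 0),
                       dy = centers(B, 1) - centers(C, 1),
                       dz = centers(B, 2) - centers(C, 2);
                double RBC = std::sqrt(dx * dx + dy * dy + dz * dz);
                P *= becke_s((d[B] - d[C]) / RBC);
              }
              Psum += P;
              if (B == A) PA = P;
            }
            if (Psum <= 0.0) continue;
            w *= PA / Psum;
          }
          if (w < 1e-16) continue;
          px.push_back(x); py.push_back(y); pz.push_back(z);
          pw.push_back(w); patom.push_back(A + 1);
        }
      }
    }
  }
  int n = px.size();
  arma::mat pts(n, 3);
  arma::vec w(n);
  IntegerVector at(n);
  for (int i = 0; i < n; ++i) {
    pts(i, 0) = px[i]; pts(i, 1) = py[i]; pts(i, 2) = pz[i];
    w[i] = pw[i]; at[i] = patom[i];
  }
  return List::create(_["points"] = pts, _["weights"] = w, _["atom"] = at);
}

// ---- PBE energy density (per volume), templated for complex step ------
template <typename T>
static T tpow(const T& x, double e) { return exp(e * log(x)); }

template <typename T>
static T pbe_exc(const T& rho, const T& sigma, double xs, double cs) {
  const double kappa = 0.804, mu_x = 0.2195149727645171;
  const double Cx = -0.7385587663820224; // -(3/4)(3/pi)^(1/3)
  T e(0.0);
  if (xs != 0.0) {
    T rho43 = tpow(rho, 4.0 / 3.0);
    T s2 = sigma / (4.0 * std::pow(3.0 * M_PI * M_PI, 2.0 / 3.0) *
                    tpow(rho, 8.0 / 3.0));
    T F = 1.0 + kappa - kappa / (1.0 + mu_x * s2 / kappa);
    e += xs * Cx * rho43 * F;
  }
  if (cs != 0.0) {
    // PW92 unpolarized epsilon_c
    const double Ac = 0.0310907, a1 = 0.21370, b1 = 7.5957, b2 = 3.5876,
                 b3 = 1.6382, b4 = 0.49294;
    T rs = tpow(3.0 / (4.0 * M_PI) / rho, 1.0 / 3.0);
    T rs12 = sqrt(rs);
    T den = 2.0 * Ac * (b1 * rs12 + b2 * rs + b3 * rs * rs12 + b4 * rs * rs);
    T eps = -2.0 * Ac * (1.0 + a1 * rs) * log(1.0 + 1.0 / den);
    // PBE gradient correction H
    const double beta = 0.06672455060314922;
    const double gamma = 0.031090690869654895; // (1 - ln 2)/pi^2
    T kF = tpow(3.0 * M_PI * M_PI * rho, 1.0 / 3.0);
    T ks = sqrt(4.0 * kF / M_PI);
    T t2 = sigma / (4.0 * ks * ks * rho * rho);
    T A = beta / gamma / (exp(-eps / gamma) - 1.0);
    T num = 1.0 + A * t2;
    T H = gamma * log(1.0 + beta / gamma * t2 * num /
                            (num + A * A * t2 * t2));
    e += cs * rho * (eps + H);
  }
  return e;
}

static void pbe_point(double rho, double sigma, double xs, double cs,
                      double& e, double& vrho, double& vsigma) {
  typedef std::complex<double> C;
  const double h = 1e-30;
  e = pbe_exc<double>(rho, sigma, xs, cs);
  vrho = pbe_exc<C>(C(rho, h), C(sigma, 0.0), xs, cs).imag() / h;
  vsigma = pbe_exc<C>(C(rho, 0.0), C(sigma, h), xs, cs).imag() / h;
}

// ---- AO shell evaluation helpers -------------------------------------
struct GShell {
  int l, ptr, nsph, ncart;
  std::vector<double> exps, coefs;
  double cx, cy, cz, ext2; // squared screening radius
};

static std::vector<GShell> unpack_gshells(const List& sh) {
  IntegerVector l = sh["l"], ptr = sh["ptr"], nprim = sh["nprim"],
                poff = sh["poff"];
  NumericVector exps = sh["exps"], coefs = sh["coefs"];
  NumericMatrix cen = sh["centers"];
  int n = l.size();
  std::vector<GShell> out(n);
  for (int i = 0; i < n; ++i) {
    GShell& s = out[i];
    s.l = l[i]; s.ptr = ptr[i];
    s.nsph = 2 * s.l + 1; s.ncart = (s.l + 1) * (s.l + 2) / 2;
    for (int k = 0; k < nprim[i]; ++k) {
      s.exps.push_back(exps[poff[i] + k]);
      s.coefs.push_back(coefs[poff[i] + k]);
    }
    s.cx = cen(i, 0); s.cy = cen(i, 1); s.cz = cen(i, 2);
    // screening extent: |coef| r^l exp(-a r^2) < 1e-12
    double ext = 1.0;
    for (double r = 1.0; r < 40.0; r += 0.5) {
      double v = 0.0;
      for (size_t k = 0; k < s.exps.size(); ++k)
        v += std::fabs(s.coefs[k]) * std::pow(r, s.l) *
             std::exp(-s.exps[k] * r * r);
      ext = r;
      if (v < 1e-12) break;
    }
    s.ext2 = ext * ext;
  }
  return out;
}

static void c2s_rows(int l, int m, int* idx, double* cf, int* ncf) {
  // sparse rows of the cart->sph transform (same tables as integrals.cpp)
  const double s3 = std::sqrt(3.0);
  if (l == 0) { idx[0] = 0; cf[0] = 1.0; *ncf = 1; return; }
  if (l == 1) { idx[0] = m; cf[0] = 1.0; *ncf = 1; return; }
  switch (m) {
    case 0: idx[0] = 1; cf[0] = s3; *ncf = 1; break;            // xy
    case 1: idx[0] = 4; cf[0] = s3; *ncf = 1; break;            // yz
    case 2: idx[0] = 0; cf[0] = -0.5; idx[1] = 3; cf[1] = -0.5;
            idx[2] = 5; cf[2] = 1.0; *ncf = 3; break;           // z2
    case 3: idx[0] = 2; cf[0] = s3; *ncf = 1; break;            // xz
    default: idx[0] = 0; cf[0] = 0.5 * s3; idx[1] = 3; cf[1] = -0.5 * s3;
             *ncf = 2; break;                                   // x2-y2
  }
}

// Evaluate E_xc and V_xc for closed-shell density D over kept shells.
// keep: 0-based indices of kept shells; D indexed on the kept function set
// (functions ordered by kept shells).  scale = (x_scale, c_scale).
// [[Rcpp::export]]
List cpp_xc_eval(List shlist, IntegerVector keep, arma::mat D, arma::mat pts,
                 arma::vec wts, double x_scale, double c_scale) {
  std::vector<GShell> all = unpack_gshells(shlist);
  std::vector<GShell> sh;
  int off = 0;
  for (int i = 0; i < keep.size(); ++i) {
    GShell s = all[keep[i]];
    s.ptr = off; // re-point into the kept function set
    off += s.nsph;
    sh.push_back(s);
  }
  int nf = off;
  if ((int)D.n_rows != nf) stop("density dimension mismatch with kept shells");
  arma::mat V(nf, nf, arma::fill::zeros);
  double Exc = 0.0, Ne = 0.0;
  const int BLK = 128;
  int npts = pts.n_rows;
  for (int b0 = 0; b0 < npts; b0 += BLK) {
    int nb = std::min(BLK, npts - b0);
    // bounding sphere of the block
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < nb; ++i) {
      mx += pts(b0 + i, 0); my += pts(b0 + i, 1); mz += pts(b0 + i, 2);
    }
    mx /= nb; my /= nb; mz /= nb;
    double br2 = 0;
    for (int i = 0; i < nb; ++i) {
      double dx = pts(b0 + i, 0) - mx, dy = pts(b0 + i, 1) - my,
             dz = pts(b0 + i, 2) - mz;
      br2 = std::max(br2, dx * dx + dy * dy + dz * dz);
    }
    double br = std::sqrt(br2);
    std::vector<int> loc;       // local shell list
    std::vector<int> lmap;      // function offsets
    int nloc = 0;
    for (size_t s = 0; s < sh.size(); ++s) {
      double dx = sh[s].cx - mx, dy = sh[s].cy - my, dz = sh[s].cz - mz;
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      double reach = std::sqrt(sh[s].ext2) + br;
      if (dist * dist <= reach * reach) {
        loc.push_back(s); lmap.push_back(nloc); nloc += sh[s].nsph;
      }
    }
    if (nloc == 0) continue;
    arma::mat Phi(nb, nloc, arma::fill::zeros), Gx(nb, nloc, arma::fill::zeros),
        Gy(nb, nloc, arma::fill::zeros), Gz(nb, nloc, arma::fill::zeros);
    for (size_t si = 0; si < loc.size(); ++si) {
      const GShell& s = sh[loc[si]];
      int col0 = lmap[si];
      for (int i = 0; i < nb; ++i) {
        double x = pts(b0 + i, 0) - s.cx, y = pts(b0 + i, 1) - s.cy,
               z = pts(b0 + i, 2) - s.cz;
        double r2 = x * x + y * y + z * z;
        if (r2 > s.ext2 * 1.2 + 1.0) continue;
        double R = 0.0, Rp = 0.0;
        for (size_t k = 0; k < s.exps.size(); ++k) {
          double g = s.coefs[k] * std::exp(-s.exps[k] * r2);
          R += g; Rp += -2.0 * s.exps[k] * g;
        }
        // cartesian values and gradients
        double cv[6], cgx[6], cgy[6], cgz[6];
        int nc = s.ncart, ci = 0;
        for (int lx = s.l; lx >= 0; --lx)
          for (int ly = s.l - lx; ly >= 0; --ly) {
            int lz = s.l - lx - ly;
            double ppx = (lx == 0) ? 1.0 : ((lx == 1) ? x : x * x);
            double ppy = (ly == 0) ? 1.0 : ((ly == 1) ? y : y * y);
            double ppz = (lz == 0) ? 1.0 : ((lz == 1) ? z : z * z);
            double mono = ppx * ppy * ppz;
            cv[ci] = mono * R;
            double dmx = (lx == 0) ? 0.0 : lx * ((lx == 1) ? 1.0 : x);
            double dmy = (ly == 0) ? 0.0 : ly * ((ly == 1) ? 1.0 : y);
            double dmz = (lz == 0) ? 0.0 : lz * ((lz == 1) ? 1.0 : z);
            cgx[ci] = dmx * ppy * ppz * R + mono * x * Rp;
            cgy[ci] = ppx * dmy * ppz * R + mono * y * Rp;
            cgz[ci] = ppx * ppy * dmz * R + mono * z * Rp;
            ++ci;
          }
        (void)nc;
        // spherical transform
        int idx[3], ncf; double cf[3];
        for (int m = 0; m < s.nsph; ++m) {
          c2s_rows(s.l, m, idx, cf, &ncf);
          double v = 0, gx = 0, gy = 0, gz = 0;
          for (int t = 0; t < ncf; ++t) {
            v += cf[t] * cv[idx[t]];
            gx += cf[t] * cgx[idx[t]];
            gy += cf[t] * cgy[idx[t]];
            gz += cf[t] * cgz[idx[t]];
          }
          Phi(i, col0 + m) = v; Gx(i, col0 + m) = gx;
          Gy(i, col0 + m) = gy; Gz(i, col0 + m) = gz;
        }
      }
    }
    // local density sub-block
    arma::uvec lidx(nloc);
    {
      int t = 0;
      for (size_t si = 0; si < loc.size(); ++si)
        for (int m = 0; m < sh[loc[si]].nsph; ++m) lidx[t++] = sh[loc[si]].ptr + m;
    }
    arma::mat Dl = D.submat(lidx, lidx);
    arma::mat X = Phi * Dl;             // nb x nloc
    arma::vec rho = arma::sum(X % Phi, 1);
    arma::vec grx = 2.0 * arma::sum(X % Gx, 1);
    arma::vec gry = 2.0 * arma::sum(X % Gy, 1);
    arma::vec grz = 2.0 * arma::sum(X % Gz, 1);
    arma::vec wr(nb, arma::fill::zeros), ws(nb, arma::fill::zeros);
    for (int i = 0; i < nb; ++i) {
      double r = rho[i];
      if (r < 1e-12) continue;
      double sg = grx[i] * grx[i] + gry[i] * gry[i] + grz[i] * grz[i];
      double e, vr, vs;
      pbe_point(r, sg, x_scale, c_scale, e, vr, vs);
      double w = wts[b0 + i];
      Exc += w * e;
      Ne += w * r;
      wr[i] = w * vr;
      ws[i] = w * vs;
    }
    // V contribution: Phi^T diag(wr) Phi + sym(Phi^T diag(2 ws) (g.G))
    arma::mat A = Phi.each_col() % (0.5 * wr);
    A += (Gx.each_col() % (2.0 * ws % grx)) +
         (Gy.each_col() % (2.0 * ws % gry)) +
         (Gz.each_col() % (2.0 * ws % grz));
    arma::mat Vl = Phi.t() * A;
    Vl += Vl.t();
    V.submat(lidx, lidx) += Vl;
  }
  return List::create(_["exc"] = Exc, _["vxc"] = V, _["n_elec"] = Ne);
}
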