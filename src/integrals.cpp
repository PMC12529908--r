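// McMurchie-Davidson Gaussian integral engine over contracted spherical
// shells (l <= 2).  Shells arrive from R as flat vectors; contraction
// coefficients are expected to already contain primitive normalization
// (final contracted normalization is applied on the R side by rescaling
// with the overlap/metric diagonal).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int LMAX = 2;

struct Shell {
  int l, atom, ptr, nsph, ncart;
  std::vector<double> exps, coefs;
  double cx, cy, cz;
};

struct CartList { int n; int lx[10], ly[10], lz[10]; };

static CartList cart_list(int l) {
  CartList c; c.n = 0;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) {
      c.lx[c.n] = lx; c.ly[c.n] = ly; c.lz[c.n] = l - lx - ly; ++c.n;
    }
  return c;
}

// rows: spherical m (equal-norm real solid harmonics), cols: cartesian
static arma::mat c2s_mat(int l) {
  if (l == 0) return arma::mat(1, 1, arma::fill::ones);
  if (l == 1) return arma::eye(3, 3); // order x, y, z
  const double s3 = std::sqrt(3.0);
  arma::mat m(5, 6, arma::fill::zeros); // cart: xx xy xz yy yz zz
  m(0, 1) = s3;                       // xy
  m(1, 4) = s3;                       // yz
  m(2, 0) = -0.5; m(2, 3) = -0.5; m(2, 5) = 1.0; // 3z^2 - r^2 (scaled)
  m(3, 2) = s3;                       // xz
  m(4, 0) = 0.5 * s3; m(4, 3) = -0.5 * s3;       // x^2 - y^2
  return m;
}

static std::vector<Shell> unpack_shells(const List& sh) {
  IntegerVector l = sh["l"], atom = sh["atom"], ptr = sh["ptr"],
                nprim = sh["nprim"], poff = sh["poff"];
  NumericVector exps = sh["exps"], coefs = sh["coefs"];
  NumericMatrix cen = sh["centers"]; // nshell x 3
  int n = l.size();
  std::vector<Shell> out(n);
  for (int i = 0; i < n; ++i) {
    Shell& s = out[i];
    s.l = l[i]; s.atom = atom[i]; s.ptr = ptr[i];
    s.nsph = 2 * s.l + 1; s.ncart = (s.l + 1) * (s.l + 2) / 2;
    if (s.l > LMAX) stop("angular momentum above d is not supported");
    for (int k = 0; k < nprim[i]; ++k) {
      s.exps.push_back(exps[poff[i] + k]);
      s.coefs.push_back(coefs[poff[i] + k]);
    }
    s.cx = cen(i, 0); s.cy = cen(i, 1); s.cz = cen(i, 2);
  }
  return out;
}

static int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (const auto& s : sh) n += s.nsph;
  return n;
}

// ---- Boys function: fills F[0..m] ------------------------------------
static void boys(int m, double T, double* F) {
  if (T < 1e-14) {
    for (int k = 0; k <= m; ++k) F[k] = 1.0 / (2.0 * k + 1.0);
    return;
  }
  if (T > 36.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int k = 0; k < m; ++k) F[k + 1] = ((2 * k + 1) * F[k] - eT) / (2.0 * T);
    return;
  }
  // series for highest order, then downward recursion
  double eT = std::exp(-T);
  double num = 1.0, den = 2.0 * m + 1.0, term = num / den, sum = term;
  for (int k = 1; k < 200; ++k) {
    term *= 2.0 * T / (2.0 * m + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[m] = sum * eT;
  for (int k = m; k > 0; --k) F[k - 1] = (2.0 * T * F[k] + eT) / (2.0 * k - 1.0);
}

// ---- Hermite expansion coefficients ----------------------------------
// E[i][j][t] for one cartesian direction; imax,jmax <= 4, t <= imax+jmax
struct Etab { double v[5][5][9]; };

static void ecoef(int imax, int jmax, double a, double b,
                  double AB, double PA, double PB, Etab& E) {
  double p = a + b, mu = a * b / p;
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j)
      for (int t = 0; t <= imax + jmax; ++t) E.v[i][j][t] = 0.0;
  E.v[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 0; i < imax; ++i)
    for (int t = 0; t <= i; ++t) {
      E.v[i + 1][0][t]     += PA * E.v[i][0][t] + (t + 1) * E.v[i][0][t + 1];
      E.v[i + 1][0][t + 1] += E.v[i][0][t] / (2.0 * p);
    }
  for (int j = 0; j < jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        E.v[i][j + 1][t]     += PB * E.v[i][j][t] + (t + 1) * E.v[i][j][t + 1];
        E.v[i][j + 1][t + 1] += E.v[i][j][t] / (2.0 * p);
      }
}

// ---- Hermite Coulomb repulsion tensor R^0_{tuv} ----------------------
struct Rtab {
  int L;
  double v[9][9][9];
};

static void rtensor(int L, double alpha, double X, double Y, double Z,
                    Rtab& R) {
  double T = alpha * (X * X + Y * Y + Z * Z);
  double F[17];
  boys(L, T, F);
  // work array over auxiliary order n
  static thread_local double W[9][9][9][9]; // [n][t][u][v] up to L=8
  for (int n = 0; n <= L; ++n) {
    double pref = std::pow(-2.0 * alpha, n);
    W[n][0][0][0] = pref * F[n];
  }
  for (int tot = 1; tot <= L; ++tot)
    for (int n = 0; n <= L - tot; ++n)
      for (int t = 0; t <= tot; ++t)
        for (int u = 0; u <= tot - t; ++u) {
          int v = tot - t - u;
          double val;
          if (t > 0) {
            val = X * W[n + 1][t - 1][u][v];
            if (t > 1) val += (t - 1) * W[n + 1][t - 2][u][v];
          } else if (u > 0) {
            val = Y * W[n + 1][t][u - 1][v];
            if (u > 1) val += (u - 1) * W[n + 1][t][u - 2][v];
          } else {
            val = Z * W[n + 1][t][u][v - 1];
            if (v > 1) val += (v - 1) * W[n + 1][t][u][v - 2];
          }
          W[n][t][u][v] = val;
        }
  R.L = L;
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int v = 0; v <= L - t - u; ++v) R.v[t][u][v] = W[0][t][u][v];
}

// ---- overlap / kinetic shell-pair blocks (cartesian) -----------------
static void pair_ST(const Shell& A, const Shell& B, arma::mat& S, arma::mat& T) {
  CartList ca = cart_list(A.l), cb = cart_list(B.l);
  S.zeros(A.ncart, B.ncart); T.zeros(A.ncart, B.ncart);
  double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
  for (size_t ka = 0; ka < A.exps.size(); ++ka)
    for (size_t kb = 0; kb < B.exps.size(); ++kb) {
      double a = A.exps[ka], b = B.exps[kb], p = a + b;
      double c = A.coefs[ka] * B.coefs[kb];
      double Px = (a * A.cx + b * B.cx) / p, Py = (a * A.cy + b * B.cy) / p,
             Pz = (a * A.cz + b * B.cz) / p;
      Etab Ex, Ey, Ez;
      ecoef(A.l, B.l + 2, a, b, ABx, Px - A.cx, Px - B.cx, Ex);
      ecoef(A.l, B.l + 2, a, b, ABy, Py - A.cy, Py - B.cy, Ey);
      ecoef(A.l, B.l + 2, a, b, ABz, Pz - A.cz, Pz - B.cz, Ez);
      double sq = std::sqrt(M_PI / p);
      auto S1 = [&](const Etab& E, int i, int j) -> double {
        if (i < 0 || j < 0) return 0.0;
        return E.v[i][j][0] * sq;
      };
      auto T1 = [&](const Etab& E, int i, int j) -> double {
        double t = -2.0 * b * b * S1(E, i, j + 2) +
                   b * (2.0 * j + 1.0) * S1(E, i, j);
        if (j >= 2) t -= 0.5 * j * (j - 1.0) * S1(E, i, j - 2);
        return t;
      };
      for (int ia = 0; ia < ca.n; ++ia)
        for (int ib = 0; ib < cb.n; ++ib) {
          double sx = S1(Ex, ca.lx[ia], cb.lx[ib]);
          double sy = S1(Ey, ca.ly[ia], cb.ly[ib]);
          double sz = S1(Ez, ca.lz[ia], cb.lz[ib]);
          double tx = T1(Ex, ca.lx[ia], cb.lx[ib]);
          double ty = T1(Ey, ca.ly[ia], cb.ly[ib]);
          double tz = T1(Ez, ca.lz[ia], cb.lz[ib]);
          S(ia, ib) += c * sx * sy * sz;
          T(ia, ib) += c * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
        }
    }
}

static arma::mat sph_block(const arma::mat& cart, const Shell& A, const Shell& B) {
  return c2s_mat(A.l) * cart * c2s_mat(B.l).t();
}

// [[Rcpp::export]]
arma::mat cpp_overlap(List shlist) {
  std::vector<Shell> sh = unpack_shells(shlist);
  int n = nbf_total(sh);
  arma::mat S(n, n, arma::fill::zeros);
  arma::mat sc, tc;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      pair_ST(sh[i], sh[j], sc, tc);
      arma::mat blk = sph_block(sc, sh[i], sh[j]);
      S.submat(sh[i].ptr, sh[j].ptr, sh[i].ptr + sh[i].nsph - 1,
               sh[j].ptr + sh[j].nsph - 1) = blk;
      if (i != j)
        S.submat(sh[j].ptr, sh[i].ptr, sh[j].ptr + sh[j].nsph - 1,
                 sh[i].ptr + sh[i].nsph - 1) = blk.t();
    }
  return S;
}

// one-electron: S, kinetic T, nuclear+point-charge attraction V
// charges: matrix (x, y, z, q) including both nuclei and point charges
// [[Rcpp::export]]
List cpp_one_electron(List shlist, arma::mat charges) {
  std::vector<Shell> sh = unpack_shells(shlist);
  int n = nbf_total(sh);
  arma::mat S(n, n, arma::fill::zeros), T(n, n, arma::fill::zeros),
      V(n, n, arma::fill::zeros);
  arma::mat sc, tc;
  Rtab R;
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      const Shell &A = sh[i], &B = sh[j];
      pair_ST(A, B, sc, tc);
      CartList ca = cart_list(A.l), cb = cart_list(B.l);
      arma::mat vc(A.ncart, B.ncart, arma::fill::zeros);
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      int L = A.l + B.l;
      for (size_t ka = 0; ka < A.exps.size(); ++ka)
        for (size_t kb = 0; kb < B.exps.size(); ++kb) {
          double a = A.exps[ka], b = B.exps[kb], p = a + b;
          double c = A.coefs[ka] * B.coefs[kb];
          double mu = a * b / p;
          double r2 = ABx * ABx + ABy * ABy + ABz * ABz;
          if (mu * r2 > 46.0) continue; // exp(-46) ~ 1e-20
          double Px = (a * A.cx + b * B.cx) / p,
                 Py = (a * A.cy + b * B.cy) / p,
                 Pz = (a * A.cz + b * B.cz) / p;
          Etab Ex, Ey, Ez;
          ecoef(A.l, B.l, a, b, ABx, Px - A.cx, Px - B.cx, Ex);
          ecoef(A.l, B.l, a, b, ABy, Py - A.cy, Py - B.cy, Ey);
          ecoef(A.l, B.l, a, b, ABz, Pz - A.cz, Pz - B.cz, Ez);
          double pref = c * 2.0 * M_PI / p;
          for (arma::uword kc = 0; kc < charges.n_rows; ++kc) {
            double q = charges(kc, 3);
            if (q == 0.0) continue;
            rtensor(L, p, Px - charges(kc, 0), Py - charges(kc, 1),
                    Pz - charges(kc, 2), R);
            for (int ia = 0; ia < ca.n; ++ia)
              for (int ib = 0; ib < cb.n; ++ib) {
                double s = 0.0;
                for (int t = 0; t <= ca.lx[ia] + cb.lx[ib]; ++t)
                  for (int u = 0; u <= ca.ly[ia] + cb.ly[ib]; ++u)
                    for (int v = 0; v <= ca.lz[ia] + cb.lz[ib]; ++v)
                      s += Ex.v[ca.lx[ia]][cb.lx[ib]][t] *
                           Ey.v[ca.ly[ia]][cb.ly[ib]][u] *
                           Ez.v[ca.lz[ia]][cb.lz[ib]][v] * R.v[t][u][v];
                vc(ia, ib) -= pref * q * s;
              }
          }
        }
      arma::mat sb = sph_block(sc, A, B), tb = sph_block(tc, A, B),
                vb = sph_block(vc, A, B);
      int i0 = A.ptr, i1 = A.ptr + A.nsph - 1, j0 = B.ptr,
          j1 = B.ptr + B.nsph - 1;
      S.submat(i0, j0, i1, j1) = sb;
      T.submat(i0, j0, i1, j1) = tb;
      V.submat(i0, j0, i1, j1) = vb;
      if (i != j) {
        S.submat(j0, i0, j1, i1) = sb.t();
        T.submat(j0, i0, j1, i1) = tb.t();
        V.submat(j0, i0, j1, i1) = vb.t();
      }
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ---- generic 4-shell ERI block in spherical basis --------------------
// D may be a dummy unit s shell (single primitive, exponent 0, coef 1)
// for 3- and 2-center integrals.
struct PrimPair {
  double p, Px, Py, Pz, c;
  Etab Ex, Ey, Ez;
};

static std::vector<PrimPair> make_pairs(const Shell& A, const Shell& B) {
  std::vector<PrimPair> out;
  double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
  double r2 = ABx * ABx + ABy * ABy + ABz * ABz;
  for (size_t ka = 0; ka < A.exps.size(); ++ka)
    for (size_t kb = 0; kb < B.exps.size(); ++kb) {
      double a = A.exps[ka], b = B.exps[kb], p = a + b;
      if (a * b / p * r2 > 46.0) continue;
      PrimPair pp;
      pp.p = p;
      pp.c = A.coefs[ka] * B.coefs[kb];
      pp.Px = (a * A.cx + b * B.cx) / p;
      pp.Py = (a * A.cy + b * B.cy) / p;
      pp.Pz = (a * A.cz + b * B.cz) / p;
      ecoef(A.l, B.l, a, b, ABx, pp.Px - A.cx, pp.Px - B.cx, pp.Ex);
      ecoef(A.l, B.l, a, b, ABy, pp.Py - A.cy, pp.Py - B.cy, pp.Ey);
      ecoef(A.l, B.l, a, b, ABz, pp.Pz - A.cz, pp.Pz - B.cz, pp.Ez);
      out.push_back(pp);
    }
  return out;
}

// cartesian ERI block (ab|cd); dims ncart(A)*ncart(B) x ncart(C)*ncart(D)
static void eri_block_cart(const Shell& A, const Shell& B, const Shell& C,
                           const Shell& D, arma::mat& out) {
  CartList ca = cart_list(A.l), cb = cart_list(B.l), cc = cart_list(C.l),
           cd = cart_list(D.l);
  out.zeros(ca.n * cb.n, cc.n * cd.n);
  std::vector<PrimPair> bra = make_pairs(A, B), ket = make_pairs(C, D);
  int Lb = A.l + B.l, Lk = C.l + D.l, L = Lb + Lk;
  Rtab R;
  for (const auto& pb : bra)
    for (const auto& pk : ket) {
      double p = pb.p, q = pk.p;
      double alpha = p * q / (p + q);
      double pref = pb.c * pk.c * 2.0 * std::pow(M_PI, 2.5) /
                    (p * q * std::sqrt(p + q));
      rtensor(L, alpha, pb.Px - pk.Px, pb.Py - pk.Py, pb.Pz - pk.Pz, R);
      // K[tuv][ketcart] = sum_{tau nu phi} (-1)^... Eket * R
      double K[9][9][9][36];
      for (int t = 0; t <= Lb; ++t)
        for (int u = 0; u <= Lb - t; ++u)
          for (int v = 0; v <= Lb - t - u; ++v)
            for (int ic = 0; ic < cc.n; ++ic)
              for (int id = 0; id < cd.n; ++id) {
                double s = 0.0;
                int lxs = cc.lx[ic] + cd.lx[id], lys = cc.ly[ic] + cd.ly[id],
                    lzs = cc.lz[ic] + cd.lz[id];
                for (int tt = 0; tt <= lxs; ++tt)
                  for (int uu = 0; uu <= lys; ++uu)
                    for (int vv = 0; vv <= lzs; ++vv) {
                      double sign = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                      s += sign * pk.Ex.v[cc.lx[ic]][cd.lx[id]][tt] *
                           pk.Ey.v[cc.ly[ic]][cd.ly[id]][uu] *
                           pk.Ez.v[cc.lz[ic]][cd.lz[id]][vv] *
                           R.v[t + tt][u + uu][v + vv];
                    }
                K[t][u][v][ic * cd.n + id] = s;
              }
      for (int ia = 0; ia < ca.n; ++ia)
        for (int ib = 0; ib < cb.n; ++ib) {
          int row = ia * cb.n + ib;
          int lxs = ca.lx[ia] + cb.lx[ib], lys = ca.ly[ia] + cb.ly[ib],
              lzs = ca.lz[ia] + cb.lz[ib];
          for (int kk = 0; kk < cc.n * cd.n; ++kk) {
            double s = 0.0;
            for (int t = 0; t <= lxs; ++t)
              for (int u = 0; u <= lys; ++u)
                for (int v = 0; v <= lzs; ++v)
                  s += pb.Ex.v[ca.lx[ia]][cb.lx[ib]][t] *
                       pb.Ey.v[ca.ly[ia]][cb.ly[ib]][u] *
                       pb.Ez.v[ca.lz[ia]][cb.lz[ib]][v] * K[t][u][v][kk];
            out(row, kk) += pref * s;
          }
        }
    }
}

static Shell dummy_s(double x, double y, double z) {
  Shell d;
  d.l = 0; d.atom = 0; d.ptr = 0; d.nsph = 1; d.ncart = 1;
  d.exps.push_back(0.0); d.coefs.push_back(1.0);
  d.cx = x; d.cy = y; d.cz = z;
  return d;
}

// spherical ERI block: (AB|CD) reshaped nsphA*nsphB x nsphC*nsphD
static arma::mat eri_block_sph(const Shell& A, const Shell& B, const Shell& C,
                               const Shell& D) {
  arma::mat cart;
  eri_block_cart(A, B, C, D, cart);
  arma::mat TA = c2s_mat(A.l), TB = c2s_mat(B.l), TC = c2s_mat(C.l),
            TD = c2s_mat(D.l);
  arma::mat bra = arma::kron(TA, TB); // row (ia,ib) cart -> (ma,mb) sph
  arma::mat ket = arma::kron(TC, TD);
  return bra * cart * ket.t();
}

// two-center Coulomb metric (P|Q) over auxiliary shells
// [[Rcpp::export]]
arma::mat cpp_metric2c(List shlist) {
  std::vector<Shell> sh = unpack_shells(shlist);
  int n = nbf_total(sh);
  arma::mat M(n, n, arma::fill::zeros);
  for (size_t i = 0; i < sh.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      Shell di = dummy_s(sh[i].cx, sh[i].cy, sh[i].cz),
            dj = dummy_s(sh[j].cx, sh[j].cy, sh[j].cz);
      arma::mat blk = eri_block_sph(sh[i], di, sh[j], dj);
      M.submat(sh[i].ptr, sh[j].ptr, sh[i].ptr + sh[i].nsph - 1,
               sh[j].ptr + sh[j].nsph - 1) = blk;
      if (i != j)
        M.submat(sh[j].ptr, sh[i].ptr, sh[j].ptr + sh[j].nsph - 1,
                 sh[i].ptr + sh[i].nsph - 1) = blk.t();
    }
  return M;
}

// three-center integrals (mu nu | P), packed lower triangle mu >= nu.
// Returns matrix npair x naux with pair index pq = mu*(mu+1)/2 + nu.
// [[Rcpp::export]]
arma::mat cpp_eri3c(List ao_shlist, List aux_shlist) {
  std::vector<Shell> ao = unpack_shells(ao_shlist);
  std::vector<Shell> aux = unpack_shells(aux_shlist);
  int nao = nbf_total(ao), naux = nbf_total(aux);
  arma::mat out(nao * (nao + 1) / 2, naux, arma::fill::zeros);
  for (size_t i = 0; i < ao.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      // screen negligible shell pairs by primitive gaussian prefactor
      std::vector<PrimPair> test = make_pairs(ao[i], ao[j]);
      if (test.empty()) continue;
      for (size_t k = 0; k < aux.size(); ++k) {
        Shell dk = dummy_s(aux[k].cx, aux[k].cy, aux[k].cz);
        arma::mat blk = eri_block_sph(ao[i], ao[j], aux[k], dk);
        for (int ia = 0; ia < ao[i].nsph; ++ia)
          for (int ib = 0; ib < ao[j].nsph; ++ib) {
            int mu = ao[i].ptr + ia, nu = ao[j].ptr + ib;
            if (mu < nu) continue;
            long pq = (long)mu * (mu + 1) / 2 + nu;
            for (int ic = 0; ic < aux[k].nsph; ++ic)
              out(pq, aux[k].ptr + ic) = blk(ia * ao[j].nsph + ib, ic);
          }
      }
    }
  return out;
}

// full four-center tensor for tiny systems (test oracle support)
// returns nao^2 x nao^2 matrix, row = mu*nao+nu, col = la*nao+si
// [[Rcpp::export]]
arma::mat cpp_eri4c(List ao_shlist) {
  std::vector<Shell> ao = unpack_shells(ao_shlist);
  int nao = nbf_total(ao);
  if (nao > 40) stop("four-center tensor is restricted to tiny systems");
  arma::mat out(nao * nao, nao * nao, arma::fill::zeros);
  for (size_t i = 0; i < ao.size(); ++i)
    for (size_t j = 0; j < ao.size(); ++j)
      for (size_t k = 0; k < ao.size(); ++k)
        for (size_t l = 0; l < ao.size(); ++l) {
          arma::mat blk = eri_block_sph(ao[i], ao[j], ao[k], ao[l]);
          for (int ia = 0; ia < ao[i].nsph; ++ia)
            for (int ib = 0; ib < ao[j].nsph; ++ib)
              for (int ic = 0; ic < ao[k].nsph; ++ic)
                for (int id = 0; id < ao[l].nsph; ++id)
                  out((ao[i].ptr + ia) * nao + ao[j].ptr + ib,
                      (ao[k].ptr + ic) * nao + ao[l].ptr + id) =
                      blk(ia * ao[j].nsph + ib, ic * ao[l].nsph + id);
        }
  return out;
}

// diagonal four-center integrals (mu nu | mu nu), full nao x nao matrix
// [[Rcpp::export]]
arma::mat cpp_eri_diag(List ao_shlist) {
  std::vector<Shell> ao = unpack_shells(ao_shlist);
  int nao = nbf_total(ao);
  arma::mat out(nao, nao, arma::fill::zeros);
  for (size_t i = 0; i < ao.size(); ++i)
    for (size_t j = 0; j <= i; ++j) {
      std::vector<PrimPair> test = make_pairs(ao[i], ao[j]);
      if (test.empty()) continue;
      arma::mat blk = eri_block_sph(ao[i], ao[j], ao[i], ao[j]);
      for (int ia = 0; ia < ao[i].nsph; ++ia)
        for (int ib = 0; ib < ao[j].nsph; ++ib) {
          int row = ia * ao[j].nsph + ib;
          double v = blk(row, row);
          out(ao[i].ptr + ia, ao[j].ptr + ib) = v;
          out(ao[j].ptr + ib, ao[i].ptr + ia) = v;
        }
    }
  return out;
}

// nuclear repulsion among rows of charges (x,y,z,q); pairs within
// `skip_from` onward (point charges) are excluded.
// [[Rcpp::export]]
double cpp_nuclear_repulsion(arma::mat charges, int n_nuclei) {
  double e = 0.0;
  int n = charges.n_rows;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (i >= n_nuclei && j >= n_nuclei) continue; // MM-MM self energy
      double dx = charges(i, 0) - charges(j, 0),
             dy = charges(i, 1) - charges(j, 1),
             dz = charges(i, 2) - charges(j, 2);
      e += charges(i, 3) * charges(j, 3) /
           std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return e;
}
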