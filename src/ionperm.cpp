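// Core energy model and samplers for the toy channel.
//
// The R side flattens a channel model + particle roster into a plain list
// ("sys") of vectors; everything here works on that flat representation.
// Units: kcal/mol, Angstrom, ps, charges in e.  All randomness comes from
// the R RNG (set.seed() on the R side gives bit-identical trajectories).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Sys {
  int n;
  std::vector<double> q, rad, amp, tk;
  std::vector<double> ax, ay, az;        // tether anchors
  std::vector<int> conf, wellm;          // masks
  int lys;                               // 0-based index, -1 none
  double lx0, ly0, lklat, lz0, la, lh;   // lysine lateral + axial double-well
  int well_type;                         // 0 none, 1 quartic, 2 profile
  double wz0, wa, wh;                    // quartic well params
  std::vector<double> pedges, pvals;     // piecewise-constant profile
  std::vector<double> cz, cR;            // radial confinement profile nodes
  double kwall, eps, kC, rmin;
  double bx, by, bz;                     // box edge lengths (walls at +-L/2)
  std::vector<int> mobile;               // samplers move only these
  int restr_idx;                         // 0-based restrained particle, -1 none
  double rcx, rcy, rcz, rrad, rk;        // restraint center, flat radius, k
};

static Sys parse_sys(const List& s) {
  Sys y;
  y.q   = as<std::vector<double> >(s["q"]);
  y.n   = (int)y.q.size();
  y.rad = as<std::vector<double> >(s["rad"]);
  y.amp = as<std::vector<double> >(s["amp"]);
  y.tk  = as<std::vector<double> >(s["tether_k"]);
  NumericMatrix A = s["tether_anchor"];
  y.ax.resize(y.n); y.ay.resize(y.n); y.az.resize(y.n);
  for (int i = 0; i < y.n; i++) { y.ax[i]=A(i,0); y.ay[i]=A(i,1); y.az[i]=A(i,2); }
  y.conf  = as<std::vector<int> >(s["conf_mask"]);
  y.wellm = as<std::vector<int> >(s["well_mask"]);
  y.lys   = as<int>(s["lys_idx"]) - 1;
  NumericVector lp = s["lys_par"];       // x0 y0 klat z_up z_down barrier
  y.lx0=lp[0]; y.ly0=lp[1]; y.lklat=lp[2];
  y.lz0 = 0.5*(lp[3]+lp[4]); y.la = 0.5*(lp[3]-lp[4]); y.lh = lp[5];
  y.well_type = as<int>(s["well_type"]);
  if (y.well_type == 1) {
    NumericVector wp = s["well_par"];    // z_a z_b barrier (minima)
    y.wz0 = 0.5*(wp[0]+wp[1]); y.wa = 0.5*(wp[1]-wp[0]); y.wh = wp[2];
  } else { y.wz0 = y.wa = y.wh = 0.0; }
  if (y.well_type == 2) {
    y.pedges = as<std::vector<double> >(s["profile_edges"]);
    y.pvals  = as<std::vector<double> >(s["profile_values"]);
  }
  y.cz = as<std::vector<double> >(s["conf_z"]);
  y.cR = as<std::vector<double> >(s["conf_R"]);
  y.kwall = as<double>(s["k_wall"]);
  y.eps   = as<double>(s["dielectric"]);
  y.kC    = as<double>(s["coulomb_k"]);
  y.rmin  = as<double>(s["r_cap"]);
  NumericVector b = s["box"];
  y.bx=b[0]; y.by=b[1]; y.bz=b[2];
  y.mobile = as<std::vector<int> >(s["mobile"]);
  y.restr_idx = as<int>(s["restr_idx"]) - 1;
  NumericVector rp = s["restr_par"];     // cx cy cz radius k
  y.rcx=rp[0]; y.rcy=rp[1]; y.rcz=rp[2]; y.rrad=rp[3]; y.rk=rp[4];
  return y;
}

static inline double conf_R_at(const Sys& y, double z, double* slope = 0) {
  int m = (int)y.cz.size();
  if (z <= y.cz[0])   { if (slope) *slope = 0; return y.cR[0]; }
  if (z >= y.cz[m-1]) { if (slope) *slope = 0; return y.cR[m-1]; }
  int k = 1; while (y.cz[k] < z) k++;
  double t = (z - y.cz[k-1]) / (y.cz[k] - y.cz[k-1]);
  if (slope) *slope = (y.cR[k] - y.cR[k-1]) / (y.cz[k] - y.cz[k-1]);
  return y.cR[k-1] + t * (y.cR[k] - y.cR[k-1]);
}

// piecewise-constant external profile; +Inf outside its support
static inline double profile_at(const Sys& y, double z) {
  int m = (int)y.pvals.size();
  if (z < y.pedges[0] || z > y.pedges[m]) return R_PosInf;
  int lo = 0, hi = m;                      // find bin by binary search
  while (hi - lo > 1) { int mid=(lo+hi)/2; if (y.pedges[mid] <= z) lo=mid; else hi=mid; }
  return y.pvals[lo];
}

// single-particle (self) energy terms: tether/lys/wall/external
static double self_u(const Sys& y, int i, double x, double yv, double z) {
  double u = 0.0;
  if (y.tk[i] > 0) {
    double dx=x-y.ax[i], dy=yv-y.ay[i], dz=z-y.az[i];
    u += 0.5*y.tk[i]*(dx*dx+dy*dy+dz*dz);
  }
  if (i == y.lys) {
    double dx=x-y.lx0, dy=yv-y.ly0;
    u += 0.5*y.lklat*(dx*dx+dy*dy);
    double s = (z-y.lz0)*(z-y.lz0) - y.la*y.la;
    u += y.lh * s*s / (y.la*y.la*y.la*y.la);
  }
  if (y.conf[i]) {
    double rho = std::sqrt(x*x+yv*yv), R = conf_R_at(y, z);
    if (rho > R) { double d = rho-R; u += 0.5*y.kwall*d*d; }
  }
  if (y.wellm[i]) {
    if (y.well_type == 1) {
      double s = (z-y.wz0)*(z-y.wz0) - y.wa*y.wa;
      u += y.wh * s*s / (y.wa*y.wa*y.wa*y.wa);
    } else if (y.well_type == 2) {
      double p = profile_at(y, z);
      if (!R_FINITE(p)) return R_PosInf;
      u += p;
    }
  }
  if (i == y.restr_idx) {
    double dx=x-y.rcx, dy=yv-y.rcy, dz=z-y.rcz;
    double d = std::sqrt(dx*dx+dy*dy+dz*dz);
    if (d > y.rrad) { double e = d - y.rrad; u += 0.5*y.rk*e*e; }
  }
  return u;
}

static double pair_u(const Sys& y, int i, int j, double r) {
  double re = r < y.rmin ? y.rmin : r;
  double u = 0.0;
  if (y.q[i] != 0 && y.q[j] != 0) u += y.kC * y.q[i]*y.q[j] / (y.eps * re);
  double sig = y.rad[i] + y.rad[j];
  double A = std::sqrt(y.amp[i]*y.amp[j]);
  if (A > 0 && sig > 0) { double s = sig/re; double s3=s*s*s; double s6=s3*s3; u += A*s6*s6; }
  return u;
}

static double total_u(const Sys& y, const double* X, bool* capped = 0) {
  double u = 0.0;
  for (int i = 0; i < y.n; i++) {
    double ui = self_u(y, i, X[i], X[i+y.n], X[i+2*y.n]);
    if (!R_FINITE(ui)) return R_PosInf;
    u += ui;
    for (int j = i+1; j < y.n; j++) {
      double dx=X[i]-X[j], dy=X[i+y.n]-X[j+y.n], dz=X[i+2*y.n]-X[j+2*y.n];
      double r = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (capped && r < y.rmin) *capped = true;
      u += pair_u(y, i, j, r);
    }
  }
  return u;
}

// gradient (kcal/mol/A); profile external (well_type 2) has no gradient and
// is rejected at the R level for Langevin
static void grad_u(const Sys& y, const double* X, double* G) {
  int n = y.n;
  for (int k = 0; k < 3*n; k++) G[k] = 0.0;
  for (int i = 0; i < n; i++) {
    double x=X[i], yv=X[i+n], z=X[i+2*n];
    if (y.tk[i] > 0) {
      G[i]     += y.tk[i]*(x - y.ax[i]);
      G[i+n]   += y.tk[i]*(yv - y.ay[i]);
      G[i+2*n] += y.tk[i]*(z - y.az[i]);
    }
    if (i == y.lys) {
      G[i]   += y.lklat*(x - y.lx0);
      G[i+n] += y.lklat*(yv - y.ly0);
      double zz = z - y.lz0;
      G[i+2*n] += 4.0*y.lh*zz*(zz*zz - y.la*y.la)/(y.la*y.la*y.la*y.la);
    }
    if (y.conf[i]) {
      double slope = 0.0, R = conf_R_at(y, z, &slope);
      double rho = std::sqrt(x*x + yv*yv);
      if (rho > R && rho > 1e-12) {
        double f = y.kwall*(rho - R);
        G[i]     += f * x/rho;
        G[i+n]   += f * yv/rho;
        G[i+2*n] += -f * slope;
      }
    }
    if (y.wellm[i] && y.well_type == 1) {
      double zz = z - y.wz0;
      G[i+2*n] += 4.0*y.wh*zz*(zz*zz - y.wa*y.wa)/(y.wa*y.wa*y.wa*y.wa);
    }
    if (i == y.restr_idx) {
      double dx=x-y.rcx, dy=yv-y.rcy, dz=z-y.rcz;
      double d = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (d > y.rrad && d > 1e-12) {
        double f = y.rk*(d - y.rrad)/d;
        G[i] += f*dx; G[i+n] += f*dy; G[i+2*n] += f*dz;
      }
    }
    for (int j = i+1; j < n; j++) {
      double dx=x-X[j], dy=yv-X[j+n], dz=z-X[j+2*n];
      double r = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (r < y.rmin) continue;               // inside the cap: flat
      double dudr = 0.0;
      if (y.q[i] != 0 && y.q[j] != 0) dudr += -y.kC*y.q[i]*y.q[j]/(y.eps*r*r);
      double sig = y.rad[i]+y.rad[j], A = std::sqrt(y.amp[i]*y.amp[j]);
      if (A > 0 && sig > 0) {
        double s = sig/r; double s3=s*s*s; double s6=s3*s3;
        dudr += -12.0*A*s6*s6/r;
      }
      double f = dudr/r;
      G[i]     += f*dx;   G[j]     -= f*dx;
      G[i+n]   += f*dy;   G[j+n]   -= f*dy;
      G[i+2*n] += f*dz;   G[j+2*n] -= f*dz;
    }
  }
}

// [[Rcpp::export(name = ".cpp_energy")]]
double cpp_energy(List sys, NumericMatrix X) {
  Sys y = parse_sys(sys);
  if (X.nrow() != y.n || X.ncol() != 3) stop("coordinate matrix must be n x 3");
  std::vector<double> x(3*y.n);
  for (int i = 0; i < y.n; i++) { x[i]=X(i,0); x[i+y.n]=X(i,1); x[i+2*y.n]=X(i,2); }
  bool capped = false;
  double u = total_u(y, x.data(), &capped);
  if (capped) warning("coincident particles: pair distance below cap radius; energy capped");
  return u;
}

// [[Rcpp::export(name = ".cpp_energy_terms")]]
NumericVector cpp_energy_terms(List sys, NumericMatrix X) {
  Sys y = parse_sys(sys);
  int n = y.n;
  double coul=0, rep=0, teth=0, lysu=0, wall=0, ext=0;
  for (int i = 0; i < n; i++) {
    double x=X(i,0), yv=X(i,1), z=X(i,2);
    if (y.tk[i] > 0) {
      double dx=x-y.ax[i], dy=yv-y.ay[i], dz=z-y.az[i];
      teth += 0.5*y.tk[i]*(dx*dx+dy*dy+dz*dz);
    }
    if (i == y.lys) {
      double dx=x-y.lx0, dy=yv-y.ly0;
      lysu += 0.5*y.lklat*(dx*dx+dy*dy);
      double s=(z-y.lz0)*(z-y.lz0)-y.la*y.la;
      lysu += y.lh*s*s/(y.la*y.la*y.la*y.la);
    }
    if (y.conf[i]) {
      double rho=std::sqrt(x*x+yv*yv), R=conf_R_at(y,z);
      if (rho>R){double d=rho-R; wall += 0.5*y.kwall*d*d;}
    }
    if (y.wellm[i]) {
      if (y.well_type==1){double s=(z-y.wz0)*(z-y.wz0)-y.wa*y.wa; ext += y.wh*s*s/(y.wa*y.wa*y.wa*y.wa);}
      else if (y.well_type==2) ext += profile_at(y,z);
    }
    if (i == y.restr_idx) {
      double dx=x-y.rcx, dy=yv-y.rcy, dz=z-y.rcz;
      double d = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (d > y.rrad) { double e=d-y.rrad; ext += 0.5*y.rk*e*e; }
    }
    for (int j = i+1; j < n; j++) {
      double dx=x-X(j,0), dy=yv-X(j,1), dz=z-X(j,2);
      double r=std::sqrt(dx*dx+dy*dy+dz*dz);
      double re = r < y.rmin ? y.rmin : r;
      if (y.q[i]!=0 && y.q[j]!=0) coul += y.kC*y.q[i]*y.q[j]/(y.eps*re);
      double sig=y.rad[i]+y.rad[j], A=std::sqrt(y.amp[i]*y.amp[j]);
      if (A>0 && sig>0){double s=sig/re; double s3=s*s*s; double s6=s3*s3; rep += A*s6*s6;}
    }
  }
  return NumericVector::create(_["coulomb"]=coul, _["repulsion"]=rep,
    _["tether"]=teth, _["lysine"]=lysu, _["wall"]=wall, _["external"]=ext);
}

// evaluate U for each frame of an n x 3 x nf array (for FEP delta-U)
// [[Rcpp::export(name = ".cpp_energy_frames")]]
NumericVector cpp_energy_frames(List sys, NumericVector frames) {
  Sys y = parse_sys(sys);
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  if (n != y.n) stop("frame array does not match roster size");
  NumericVector out(nf);
  std::vector<double> x(3*n);
  for (int t = 0; t < nf; t++) {
    for (int i = 0; i < n; i++)
      for (int k = 0; k < 3; k++) x[i+k*n] = frames[i + k*n + t*3*n];
    out[t] = total_u(y, x.data());
  }
  return out;
}

static inline double reflect(double v, double lo, double hi) {
  // fold into [lo, hi] by reflection
  double L = hi - lo;
  if (L <= 0) return v;
  while (v < lo || v > hi) {
    if (v < lo) v = 2*lo - v;
    if (v > hi) v = 2*hi - v;
  }
  return v;
}

// Overdamped Langevin (Euler-Maruyama), reflecting box walls.
// [[Rcpp::export(name = ".cpp_langevin")]]
List cpp_langevin(List sys, NumericMatrix X0, int nsteps, double dt,
                  double D, double kBT, int stride) {
  Sys y = parse_sys(sys);
  int n = y.n;
  if (y.well_type == 2) stop("piecewise-constant external profile has no gradient; use the metropolis sampler");
  std::vector<double> x(3*n), g(3*n);
  for (int i=0;i<n;i++){x[i]=X0(i,0);x[i+n]=X0(i,1);x[i+2*n]=X0(i,2);}
  int nf = nsteps / stride;
  NumericVector frames(Dimension(n, 3, nf));
  NumericVector uout(nf);
  double mob = D*dt/kBT, noise = std::sqrt(2.0*D*dt);
  double hx=y.bx/2, hy=y.by/2, hz=y.bz/2;
  int t = 0;
  for (int s = 1; s <= nsteps; s++) {
    grad_u(y, x.data(), g.data());
    for (int i = 0; i < n; i++) {
      if (!y.mobile[i]) continue;
      for (int k = 0; k < 3; k++)
        x[i+k*n] += -mob*g[i+k*n] + noise*norm_rand();
      x[i]     = reflect(x[i],     -hx, hx);
      x[i+n]   = reflect(x[i+n],   -hy, hy);
      x[i+2*n] = reflect(x[i+2*n], -hz, hz);
    }
    if (s % stride == 0) {
      for (int i=0;i<n;i++) for (int k=0;k<3;k++) frames[i + k*n + t*3*n] = x[i+k*n];
      uout[t] = total_u(y, x.data());
      t++;
    }
  }
  return List::create(_["frames"]=frames, _["energy"]=uout);
}

// Metropolis MC with single-particle symmetric Gaussian displacement
// proposals; with probability p_big the proposal uses step_big instead of
// step_sd (a symmetric mixture, so detailed balance is preserved), which
// decorrelates hops between degenerate binding basins. Moves leaving the
// box (or the support of a piecewise profile) are rejected.
// [[Rcpp::export(name = ".cpp_metropolis")]]
List cpp_metropolis(List sys, NumericMatrix X0, int nsweeps, double step_sd,
                    double kBT, int stride,
                    double p_big = 0.0, double step_big = 0.0) {
  Sys y = parse_sys(sys);
  int n = y.n;
  std::vector<double> x(3*n);
  for (int i=0;i<n;i++){x[i]=X0(i,0);x[i+n]=X0(i,1);x[i+2*n]=X0(i,2);}
  int nf = nsweeps / stride;
  NumericVector frames(Dimension(n, 3, nf));
  double hx=y.bx/2, hy=y.by/2, hz=y.bz/2;
  long acc = 0, tot = 0;
  int t = 0;
  for (int s = 1; s <= nsweeps; s++) {
    for (int i = 0; i < n; i++) {
      if (!y.mobile[i]) continue;
      double ox=x[i], oy=x[i+n], oz=x[i+2*n];
      double sdv = (p_big > 0.0 && unif_rand() < p_big) ? step_big : step_sd;
      double nx=ox+sdv*norm_rand(), ny=oy+sdv*norm_rand(), nz=oz+sdv*norm_rand();
      tot++;
      if (nx < -hx || nx > hx || ny < -hy || ny > hy || nz < -hz || nz > hz) continue;
      double du = self_u(y,i,nx,ny,nz) - self_u(y,i,ox,oy,oz);
      if (R_FINITE(du)) {
        for (int j = 0; j < n; j++) {
          if (j == i) continue;
          double dxn=nx-x[j], dyn=ny-x[j+n], dzn=nz-x[j+2*n];
          double dxo=ox-x[j], dyo=oy-x[j+n], dzo=oz-x[j+2*n];
          du += pair_u(y,i,j,std::sqrt(dxn*dxn+dyn*dyn+dzn*dzn))
              - pair_u(y,i,j,std::sqrt(dxo*dxo+dyo*dyo+dzo*dzo));
        }
      }
      if (R_FINITE(du) && (du <= 0.0 || unif_rand() < std::exp(-du/kBT))) {
        x[i]=nx; x[i+n]=ny; x[i+2*n]=nz; acc++;
      }
    }
    if (s % stride == 0) {
      for (int i=0;i<n;i++) for (int k=0;k<3;k++) frames[i + k*n + t*3*n] = x[i+k*n];
      t++;
    }
  }
  return List::create(_["frames"]=frames, _["acceptance"]=(double)acc/(double)tot);
}
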