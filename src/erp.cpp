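// Fixed-step RK4 integrator for the convolution-based 'ERP' neural mass
// network. Each region has three subpopulations (spiny stellate,
// inhibitory interneurons, pyramidal); state columns per region:
//   0 x1 stellate PSP        1 x1'
//   2 x2 pyramidal exc. PSP  3 x2'
//   4 x3 pyramidal inh. PSP  5 x3'
//   6 x7 interneuron PSP     7 x7'
//   8 x9 pyramidal depolarization (integral of x2' - x3')
// Extrinsic routing: forward -> stellate; backward -> pyramidal (exc.)
// and interneurons; lateral -> all three. Exogenous input drives the
// stellate population of input regions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ErpSys {
  const mat *AFL;  // forward + lateral (drives stellate)
  const mat *ABL;  // backward + lateral (drives pyramidal + interneurons)
  const vec *C;    // input gain per region
  double ke, ki, He, Hi, g1, g2, g3, g4, r;
  int n;
  // workspaces
  vec S9, S1, S7, aff_f, aff_b;

  void init(int n_) {
    n = n_;
    S9.set_size(n); S1.set_size(n); S7.set_size(n);
    aff_f.set_size(n); aff_b.set_size(n);
  }

  inline void sig(const double *x, vec &out) const {
    for (int i = 0; i < n; ++i)
      out(i) = 1.0 / (1.0 + std::exp(-r * x[i])) - 0.5;
  }

  // f <- dx/dt at state x, input u
  void deriv(const mat &x, double u, mat &f) {
    sig(x.colptr(8), S9);
    sig(x.colptr(0), S1);
    sig(x.colptr(6), S7);
    aff_f = (*AFL) * S9;
    aff_b = (*ABL) * S9;
    const double ke2 = ke * ke, ki2 = ki * ki;
    for (int i = 0; i < n; ++i) {
      f(i, 0) = x(i, 1);
      f(i, 1) = ke * He * (aff_f(i) + g1 * S9(i) + (*C)(i) * u)
              - 2.0 * ke * x(i, 1) - ke2 * x(i, 0);
      f(i, 2) = x(i, 3);
      f(i, 3) = ke * He * (aff_b(i) + g2 * S1(i))
              - 2.0 * ke * x(i, 3) - ke2 * x(i, 2);
      f(i, 4) = x(i, 5);
      f(i, 5) = ki * Hi * (g4 * S7(i))
              - 2.0 * ki * x(i, 5) - ki2 * x(i, 4);
      f(i, 6) = x(i, 7);
      f(i, 7) = ke * He * (aff_b(i) + g3 * S9(i))
              - 2.0 * ke * x(i, 7) - ke2 * x(i, 6);
      f(i, 8) = x(i, 3) - x(i, 5);
    }
  }
};

void integrate_into(ErpSys &sys, const vec &u_fine, double dt,
                    int oversample, mat &out) {
  const int nt_fine = u_fine.n_elem;
  const int n = sys.n;
  mat x(n, 9, fill::zeros), xtmp(n, 9);
  mat k1(n, 9), k2(n, 9), k3(n, 9), k4(n, 9);
  out.col(0) = x.col(8);
  int iout = 1;
  for (int i = 0; i < nt_fine - 1; ++i) {
    // input at sub-steps: linear interpolation of the fine-grid samples
    double u0 = u_fine(i), u1 = u_fine(i + 1), um = 0.5 * (u0 + u1);
    sys.deriv(x, u0, k1);
    xtmp = x + (0.5 * dt) * k1;
    sys.deriv(xtmp, um, k2);
    xtmp = x + (0.5 * dt) * k2;
    sys.deriv(xtmp, um, k3);
    xtmp = x + dt * k3;
    sys.deriv(xtmp, u1, k4);
    x += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if ((i + 1) % oversample == 0) {
      out.col(iout) = x.col(8);
      ++iout;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".erp_integrate")]]
arma::mat erp_integrate(const arma::mat &AFL, const arma::mat &ABL,
                        const arma::vec &C, const arma::vec &constants,
                        const arma::vec &u_fine, double dt,
                        int oversample) {
  ErpSys sys;
  sys.AFL = &AFL; sys.ABL = &ABL; sys.C = &C;
  sys.ke = constants(0); sys.ki = constants(1);
  sys.He = constants(2); sys.Hi = constants(3);
  sys.g1 = constants(4); sys.g2 = constants(5);
  sys.g3 = constants(6); sys.g4 = constants(7);
  sys.r  = constants(8);
  sys.init(AFL.n_rows);
  const int nt_out = (u_fine.n_elem - 1) / oversample + 1;
  mat out(sys.n, nt_out);
  integrate_into(sys, u_fine, dt, oversample, out);
  return out;
}

// Batched forward sweep used by the Gauss-Newton Jacobian: integrates
// the model for many (AFL, ABL, C) triples (stacked in lists) and
// returns gain-projected channel predictions, one column per triple.
// [[Rcpp::export(name = ".erp_sweep")]]
arma::mat erp_sweep(const Rcpp::List &AFLs, const Rcpp::List &ABLs,
                    const Rcpp::List &Cs, const arma::vec &constants,
                    const arma::vec &u_fine, double dt, int oversample,
                    const arma::mat &gain) {
  const int m = AFLs.size();
  ErpSys sys;
  sys.ke = constants(0); sys.ki = constants(1);
  sys.He = constants(2); sys.Hi = constants(3);
  sys.g1 = constants(4); sys.g2 = constants(5);
  sys.g3 = constants(6); sys.g4 = constants(7);
  sys.r  = constants(8);
  const int nt_out = (u_fine.n_elem - 1) / oversample + 1;
  mat out;
  mat res(gain.n_rows * nt_out, m);
  for (int j = 0; j < m; ++j) {
    mat AFL = Rcpp::as<mat>(AFLs[j]);
    mat ABL = Rcpp::as<mat>(ABLs[j]);
    vec C = Rcpp::as<vec>(Cs[j]);
    sys.AFL = &AFL; sys.ABL = &ABL; sys.C = &C;
    sys.init(AFL.n_rows);
    out.set_size(sys.n, nt_out);
    integrate_into(sys, u_fine, dt, oversample, out);
    mat proj = gain * out;  // channels x time
    res.col(j) = vectorise(proj);
  }
  return res;
}
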