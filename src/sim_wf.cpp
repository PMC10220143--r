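#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of the two-locus Wright-Fisher SDE
//
//   X(t+dt) = X(t) + [c(X) + a(X; rho)] dt + sigma(X) [W(t+dt) - W(t)]
//
// with the bounded symmetric square root sigma_ij = sqrt(x_i)(delta_ij -
// sqrt(x_i x_j)) (d driving Brownian coordinates), streaming accumulation of
// the likelihood functionals at full step resolution, and the boundary
// policy: if any coordinate of the proposal is <= 0 it is clipped to 0, the
// state renormalized to the simplex, the information flagged as infinite
// (explosion), and simulation continues.  Functional accumulation stops at
// the last interval whose right endpoint is still interior; the clipped step
// is excluded because 1/x is undefined there.
//
// Accumulators (two-locus, left-point Ito convention, dXtilde = dX - c dt):
//   Y      score integral  sum_ij (x_i. x_.j / x_ij) dXtilde_ij
//   Yd     same via the LD form -sum_i (D_i/x_i) dXtilde_i (algebraically equal)
//   I1     information  sum_ij D_ij^2 / x_ij dt
//   I2raw  expanded form sum_ij x_i.^2 x_.j^2 / x_ij dt  (I2 = I2raw - T_eff)
//   N      error martingale -sum_i (D_i/x_i) (sigma dW)_i
// Optional joint-selection functionals for genic selection on allele k at
// locus A (compensated by the mutation drift only):
//   Ysel   (1/2) sum dXtilde_{k.}
//   Isel   (1/4) int x_k.(1 - x_k.) dt
//   Icross int sum_i Zrho_i Zsel_i / x_i dt  (should vanish: diagonal info)
//
// The mutation drift is passed as the linear map Cmat (c(x) = Cmat x); the
// optional selection drift as the dense stacked tensor Smat.  sel_in_c
// controls whether selection is part of the known compensator (confounder
// case) or excluded from it (joint-estimation case).

// [[Rcpp::export]]
List sim_wf_cpp(NumericVector x0, int K, int L,
                NumericMatrix Cmat, bool has_mut,
                NumericMatrix Smat, bool has_sel, bool sel_in_c,
                double rho,
                double dt, int nsteps, int thin,
                bool store_path, bool store_dw, bool zero_noise,
                int sel_k) {
  const int d = x0.size();
  if (d != K * L) stop("state length does not match K*L");
  const double sdt = std::sqrt(dt);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xa(K), xb(L), m(d), D(d), cmut(d), csel(d),
      drift(d), noise(d), dw(d), xnew(d);

  // storage
  int nstore = store_path ? (nsteps / thin + 2) : 2;
  NumericMatrix X(nstore, d);
  IntegerVector step_idx(nstore);
  NumericVector runY(nstore), runI(nstore);
  NumericMatrix dW(store_dw ? nsteps : 0, store_dw ? d : 0);

  int row = 0;
  for (int i = 0; i < d; ++i) X(row, i) = x[i];
  step_idx[row] = 0; runY[row] = 0.0; runI[row] = 0.0; ++row;

  double Y = 0.0, Yd = 0.0, I1 = 0.0, I2raw = 0.0, N = 0.0;
  double Ysel = 0.0, Isel = 0.0, Icross = 0.0;
  bool exploded = false;
  int explosion_step = 0;      // 1-based step index of the clipped state
  long n_eff = 0;              // number of accumulated intervals

  for (int step = 0; step < nsteps; ++step) {
    // marginals and LD
    for (int i = 0; i < K; ++i) xa[i] = 0.0;
    for (int j = 0; j < L; ++j) xb[j] = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < L; ++j) xa[i] += x[i * L + j];
    for (int j = 0; j < L; ++j)
      for (int i = 0; i < K; ++i) xb[j] += x[i * L + j];
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < L; ++j) {
        int f = i * L + j;
        m[f] = xa[i] * xb[j];
        D[f] = x[f] - m[f];
      }

    // known drift: mutation (linear) and optional selection
    for (int i = 0; i < d; ++i) cmut[i] = 0.0;
    if (has_mut)
      for (int jcol = 0; jcol < d; ++jcol) {
        double xj = x[jcol];
        if (xj != 0.0)
          for (int i = 0; i < d; ++i) cmut[i] += Cmat(i, jcol) * xj;
      }
    if (has_sel) {
      double meanfit = 0.0;
      for (int i = 0; i < d; ++i) {
        double mf = 0.0;
        for (int k = 0; k < d; ++k) mf += Smat(i, k) * x[k];
        csel[i] = mf;               // marginal fitness for now
        meanfit += x[i] * mf;
      }
      for (int i = 0; i < d; ++i) csel[i] = 0.5 * x[i] * (csel[i] - meanfit);
    } else {
      for (int i = 0; i < d; ++i) csel[i] = 0.0;
    }

    for (int i = 0; i < d; ++i)
      drift[i] = cmut[i] + csel[i] - rho * D[i];

    // noise: (sigma dW)_i = sqrt(x_i) dw_i - x_i * sum_j sqrt(x_j) dw_j
    if (zero_noise) {
      for (int i = 0; i < d; ++i) { dw[i] = 0.0; noise[i] = 0.0; }
    } else {
      double s1 = 0.0;
      for (int i = 0; i < d; ++i) {
        dw[i] = sdt * norm_rand();
        s1 += std::sqrt(std::max(x[i], 0.0)) * dw[i];
      }
      for (int i = 0; i < d; ++i) {
        double sx = std::sqrt(std::max(x[i], 0.0));
        noise[i] = sx * dw[i] - x[i] * s1;
      }
    }
    if (store_dw)
      for (int i = 0; i < d; ++i) dW(step, i) = dw[i];

    bool clipped = false;
    double tot = 0.0;
    for (int i = 0; i < d; ++i) {
      xnew[i] = x[i] + drift[i] * dt + noise[i];
      if (xnew[i] <= 0.0) { xnew[i] = 0.0; clipped = true; }
      tot += xnew[i];
    }
    for (int i = 0; i < d; ++i) xnew[i] /= tot;   // exact simplex renorm

    if (clipped && !exploded) {
      exploded = true;
      explosion_step = step + 1;
    }

    // accumulate this interval only while the path is still interior
    if (!exploded) {
      double i1 = 0.0, i2 = 0.0, y = 0.0, yd = 0.0, nn = 0.0;
      for (int i = 0; i < d; ++i) {
        double xi = x[i];
        double dx = xnew[i] - x[i];
        double comp = cmut[i] + (sel_in_c ? csel[i] : 0.0);
        double dxt = dx - comp * dt;
        i1 += D[i] * D[i] / xi;
        i2 += m[i] * m[i] / xi;
        y  += m[i] / xi * dxt;
        yd -= D[i] / xi * dxt;
        nn -= D[i] / xi * noise[i];
      }
      I1 += i1 * dt;
      I2raw += i2 * dt;
      Y += y; Yd += yd; N += nn;
      if (sel_k > 0) {
        int k0 = sel_k - 1;
        double xk = xa[k0];
        Isel += 0.25 * xk * (1.0 - xk) * dt;
        double dxtk = 0.0, rowD = 0.0, sumD = 0.0;
        for (int j = 0; j < L; ++j) {
          int f = k0 * L + j;
          dxtk += (xnew[f] - x[f]) - cmut[f] * dt;
          rowD += D[f];
        }
        for (int i = 0; i < d; ++i) sumD += D[i];
        Ysel += 0.5 * dxtk;
        Icross += -0.5 * (rowD - xk * sumD) * dt;
      }
      ++n_eff;
    }

    for (int i = 0; i < d; ++i) x[i] = xnew[i];

    bool at_store = store_path && ((step + 1) % thin == 0);
    if ((at_store || step + 1 == nsteps) && row < nstore) {
      for (int i = 0; i < d; ++i) X(row, i) = x[i];
      step_idx[row] = step + 1;
      runY[row] = Y; runI[row] = I1;
      ++row;
    }
  }

  // trim storage to rows actually used
  NumericMatrix Xout(row, d);
  IntegerVector idx_out(row);
  NumericVector runY_out(row), runI_out(row);
  for (int r = 0; r < row; ++r) {
    for (int i = 0; i < d; ++i) Xout(r, i) = X(r, i);
    idx_out[r] = step_idx[r];
    runY_out[r] = runY[r];
    runI_out[r] = runI[r];
  }

  List out = List::create(
      _["X"] = Xout, _["step_idx"] = idx_out,
      _["Y"] = Y, _["Yd"] = Yd, _["I1"] = I1, _["I2raw"] = I2raw,
      _["N"] = N, _["Ysel"] = Ysel, _["Isel"] = Isel, _["Icross"] = Icross,
      _["n_eff"] = (double)n_eff,
      _["exploded"] = exploded, _["explosion_step"] = explosion_step,
      _["run_Y"] = runY_out, _["run_I"] = runI_out);
  if (store_dw) out["dW"] = dW;
  return out;
}
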