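#include <Rcpp.h>
using namespace Rcpp;

// Logistic transfer relating depolarization to firing rate.
static inline double fsig(double u, double beta, double theta) {
  return 1.0 / (1.0 + std::exp(-beta * (u - theta)));
}

// One explicit-Euler substep of the two-layer field equations.
//   tauE duE/dt = -uE + hE + (Mee f_e)(x) - gIE f_i(uI) + s(x)
//   tauI duI/dt = -uI + hI + (Mei f_e)(x)
// Mee/Mei are dense coupling matrices with gain and pixel pitch folded in;
// the inhibitory-to-excitatory coupling is strictly local (no kernel).
static void euler_substep(const NumericMatrix& Mee, const NumericMatrix& Mei,
                          std::vector<double>& ue, std::vector<double>& ui,
                          const double* s, double dt,
                          double tauE, double tauI, double hE, double hI,
                          double gIE, double betaE, double betaI,
                          double thetaE, double thetaI,
                          std::vector<double>& fe, std::vector<double>& due,
                          std::vector<double>& dui) {
  const int n = ue.size();
  for (int i = 0; i < n; ++i) fe[i] = fsig(ue[i], betaE, thetaE);
  // column-major matvecs accumulated over columns for cache friendliness
  std::fill(due.begin(), due.end(), 0.0);
  std::fill(dui.begin(), dui.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double fj = fe[j];
    if (fj == 0.0) continue;
    const double* ceeCol = &Mee(0, j);
    const double* ceiCol = &Mei(0, j);
    for (int i = 0; i < n; ++i) {
      due[i] += ceeCol[i] * fj;
      dui[i] += ceiCol[i] * fj;
    }
  }
  for (int i = 0; i < n; ++i) {
    const double fi = fsig(ui[i], betaI, thetaI);
    const double rhsE = -ue[i] + hE + due[i] - gIE * fi + (s ? s[i] : 0.0);
    const double rhsI = -ui[i] + hI + dui[i];
    ue[i] += dt / tauE * rhsE;
    ui[i] += dt / tauI * rhsI;
  }
}

// [[Rcpp::export(name = ".nf_relax")]]
List nf_relax(NumericMatrix Mee, NumericMatrix Mei,
              NumericVector ue0, NumericVector ui0,
              int nSteps, double dt,
              double tauE, double tauI, double hE, double hI,
              double gIE, double betaE, double betaI,
              double thetaE, double thetaI) {
  const int n = ue0.size();
  std::vector<double> ue(ue0.begin(), ue0.end()), ui(ui0.begin(), ui0.end());
  std::vector<double> fe(n), due(n), dui(n), uePrev(n), uiPrev(n);
  for (int k = 0; k < nSteps; ++k) {
    uePrev = ue; uiPrev = ui;
    euler_substep(Mee, Mei, ue, ui, nullptr, dt, tauE, tauI, hE, hI,
                  gIE, betaE, betaI, thetaE, thetaI, fe, due, dui);
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(ue[i]) || !std::isfinite(ui[i]))
        stop("field integration diverged during relaxation (non-finite state at step %d)", k + 1);
  }
  double drift = 0.0;  // max |du/dt| over both layers at the final step, mV/ms
  for (int i = 0; i < n; ++i) {
    drift = std::max(drift, std::abs(ue[i] - uePrev[i]) / dt);
    drift = std::max(drift, std::abs(ui[i] - uiPrev[i]) / dt);
  }
  return List::create(_["ue"] = NumericVector(ue.begin(), ue.end()),
                      _["ui"] = NumericVector(ui.begin(), ui.end()),
                      _["drift"] = drift);
}

// Integrate the stimulus window (plus any motion lead-in). S holds one column
// per frame interval; the input is held constant over the `sub` substeps of an
// interval. Output frame 1 is the state entering the window (after `nLead`
// lead intervals); frame f is the state after `nLead + f - 1` intervals.
// [[Rcpp::export(name = ".nf_window")]]
List nf_window(NumericMatrix Mee, NumericMatrix Mei,
               NumericVector ue0, NumericVector ui0,
               NumericMatrix S, int nLead, int nFrames, int sub, double dt,
               double tauE, double tauI, double hE, double hI,
               double gIE, double betaE, double betaI,
               double thetaE, double thetaI) {
  const int n = ue0.size();
  if (S.ncol() < nLead + nFrames - 1)
    stop("input field has %d columns; need at least %d", S.ncol(), nLead + nFrames - 1);
  std::vector<double> ue(ue0.begin(), ue0.end()), ui(ui0.begin(), ui0.end());
  std::vector<double> fe(n), due(n), dui(n);
  NumericMatrix UE(n, nFrames), UI(n, nFrames);
  if (nLead == 0)
    for (int i = 0; i < n; ++i) { UE(i, 0) = ue[i]; UI(i, 0) = ui[i]; }
  const int nIntervals = nLead + nFrames - 1;
  for (int k = 0; k < nIntervals; ++k) {
    const double* s = &S(0, k);
    for (int m = 0; m < sub; ++m)
      euler_substep(Mee, Mei, ue, ui, s, dt, tauE, tauI, hE, hI,
                    gIE, betaE, betaI, thetaE, thetaI, fe, due, dui);
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(ue[i]) || !std::isfinite(ui[i]))
        stop("field integration diverged at interval %d (non-finite state)", k + 1);
    const int f = k - nLead + 1;  // window frame index written after interval k
    if (f >= 0 && f < nFrames)
      for (int i = 0; i < n; ++i) { UE(i, f) = ue[i]; UI(i, f) = ui[i]; }
  }
  return List::create(_["uE"] = UE, _["uI"] = UI);
}
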