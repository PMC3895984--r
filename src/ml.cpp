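#include <Rcpp.h>
using namespace Rcpp;

// Morris-Lecar right-hand side, classic two-variable formulation.
// Units: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2.
struct MLParams {
  double C, gL, gCa, gK, VL, VCa, VK, v1, v2, v3, v4, phi;
};

static inline void ml_deriv(const MLParams& p, double I,
                            double V, double w, double& dV, double& dw) {
  double minf = 0.5 * (1.0 + std::tanh((V - p.v1) / p.v2));
  double winf = 0.5 * (1.0 + std::tanh((V - p.v3) / p.v4));
  double tauw = 1.0 / std::cosh((V - p.v3) / (2.0 * p.v4));
  dV = (I - p.gL * (V - p.VL) - p.gCa * minf * (V - p.VCa)
          - p.gK * w * (V - p.VK)) / p.C;
  dw = p.phi * (winf - w) / tauw;
}

static MLParams unpack(const List& params) {
  MLParams p;
  p.C   = params["C"];   p.gL  = params["gL"];  p.gCa = params["gCa"];
  p.gK  = params["gK"];  p.VL  = params["VL"];  p.VCa = params["VCa"];
  p.VK  = params["VK"];  p.v1  = params["v1"];  p.v2  = params["v2"];
  p.v3  = params["v3"];  p.v4  = params["v4"];  p.phi = params["phi"];
  return p;
}

// Fixed-step RK4 integration of a bank of uncoupled ML neurons that differ
// only in bias current. Records the voltage every `stride` steps and returns
// upward crossings of `v_thresh` (linearly interpolated) as spike times.
// [[Rcpp::export(name = ".ml_bank_rk4")]]
List ml_bank_rk4(List params, NumericVector I_bias, double duration_ms,
                 double dt_ms, int stride, double v_thresh,
                 double v0, double w0) {
  MLParams p = unpack(params);
  const int n = I_bias.size();
  const long nsteps = (long)std::llround(duration_ms / dt_ms);
  const long nrec = nsteps / stride + 1;

  NumericMatrix V_rec(nrec, n);
  std::vector<std::vector<double>> spikes(n);
  std::vector<double> V(n, v0), w(n, w0);

  for (int i = 0; i < n; ++i) V_rec(0, i) = v0;

  long irec = 1;
  for (long k = 0; k < nsteps; ++k) {
    for (int i = 0; i < n; ++i) {
      double I = I_bias[i];
      double k1V, k1w, k2V, k2w, k3V, k3w, k4V, k4w;
      double Vi = V[i], wi = w[i];
      ml_deriv(p, I, Vi, wi, k1V, k1w);
      ml_deriv(p, I, Vi + 0.5 * dt_ms * k1V, wi + 0.5 * dt_ms * k1w, k2V, k2w);
      ml_deriv(p, I, Vi + 0.5 * dt_ms * k2V, wi + 0.5 * dt_ms * k2w, k3V, k3w);
      ml_deriv(p, I, Vi + dt_ms * k3V, wi + dt_ms * k3w, k4V, k4w);
      double Vn = Vi + dt_ms / 6.0 * (k1V + 2 * k2V + 2 * k3V + k4V);
      double wn = wi + dt_ms / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
      if (!std::isfinite(Vn) || !std::isfinite(wn)) {
        stop("Morris-Lecar integration blew up (non-finite state) at t = %f ms",
             (k + 1) * dt_ms);
      }
      if (Vi < v_thresh && Vn >= v_thresh) {
        // linear interpolation of the crossing time
        double frac = (v_thresh - Vi) / (Vn - Vi);
        spikes[i].push_back((k + frac) * dt_ms);
      }
      V[i] = Vn; w[i] = wn;
    }
    if ((k + 1) % stride == 0 && irec < nrec) {
      for (int i = 0; i < n; ++i) V_rec(irec, i) = V[i];
      ++irec;
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = NumericVector(spikes[i].begin(),
                                                     spikes[i].end());
  NumericVector Vend(V.begin(), V.end()), wend(w.begin(), w.end());
  return List::create(_["voltage"] = V_rec, _["spikes"] = spk,
                      _["V_end"] = Vend, _["w_end"] = wend);
}
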