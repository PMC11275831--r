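// Vectorized developmental rollout engine.
//
// Must stay draw-for-draw identical to the R reference loop
// (rollout_reference in R/engine.R): per step it consumes first n_cells
// gate uniforms, then n_cells * nc noise normals (column-major over
// channels), regardless of pd / noise / actions_enabled, using R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
List rollout_engine_cpp(NumericMatrix state0, NumericVector theta,
                        int arch_code, int s, int m, int r_copies,
                        int cycles, int nx, int ny, int ng, int nc,
                        int steps, double noise, double pd,
                        bool actions_enabled, bool gate_memory,
                        double lc_lo, double lc_hi,
                        double la_lo, double la_hi,
                        bool keep_states) {
  const int nj = nx * ny;
  RNGScope scope;

  // theta layout mirrors unpack_theta(): sensor (s x nc) column-major,
  // then per copy: ff -> w_out (nc x s); rgrn -> w_in (m x s),
  // w_rec (m x m), w_out (nc x m), b (nc); all column-major.
  const double *th = theta.begin();
  const double *w_s = th;
  int off = s * nc;
  const int per_copy = (arch_code == 0) ? nc * s
                                        : (s * m + m * m + m * nc + nc);

  // neighbor indices incl self (-1 = virtual zero boundary cell)
  std::vector<int> nbr(nj * 9);
  {
    const int dr[9] = {0, -1, -1, -1, 0, 0, 1, 1, 1};
    const int dc[9] = {0, -1, 0, 1, -1, 1, -1, 0, 1};
    for (int row = 0; row < ny; ++row)
      for (int col = 0; col < nx; ++col) {
        int i = row * nx + col;
        for (int k = 0; k < 9; ++k) {
          int r2 = row + dr[k], c2 = col + dc[k];
          nbr[i * 9 + k] = (r2 >= 0 && r2 < ny && c2 >= 0 && c2 < nx)
                               ? r2 * nx + c2 : -1;
        }
      }
  }

  NumericVector states(Dimension(nj, nc, keep_states ? steps + 1 : 1));
  IntegerMatrix types(nj, steps + 1);   // 0-based argmax over the ng indicators
  LogicalMatrix gates(nj, steps);
  std::vector<double> state(nj * nc), nstate(nj * nc); // column-major nj x nc
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nj; ++i) {
      double v = clip(state0(i, c), lc_lo, lc_hi);
      state[c * nj + i] = v;
      states[c * nj + i] = v;
    }
  auto readout = [&](const std::vector<double> &st, int k) {
    for (int i = 0; i < nj; ++i) {
      int arg = 0;
      double best = st[i];
      for (int c = 1; c < ng; ++c)
        if (st[c * nj + i] > best) { best = st[c * nj + i]; arg = c; }
      types(i, k) = arg;
    }
  };
  readout(state, 0);

  std::vector<double> mem(std::max(1, r_copies * m) * nj, 0.0); // copy-major
  std::vector<double> emb(nj * s), ctx(nj * s), act(nj * nc);
  std::vector<double> mem_r(std::max(1, m)), mem_new(std::max(1, m));

  for (int k = 0; k < steps; ++k) {
    NumericVector u = runif(nj);
    NumericVector eps = rnorm(nj * nc);

    std::fill(act.begin(), act.end(), 0.0);
    if (actions_enabled && pd > 0) {  // pd == 0: no gate can open, skip agency
      // sensor embeddings for every real cell: tanh(W_s * state_i)
      for (int i = 0; i < nj; ++i)
        for (int e = 0; e < s; ++e) {
          double acc = 0.0;
          for (int c = 0; c < nc; ++c)
            acc += w_s[c * s + e] * state[c * nj + i];
          emb[i * s + e] = std::tanh(acc);
        }
      // context: mean over the 9 perceived states (virtual cells embed to 0)
      for (int i = 0; i < nj; ++i)
        for (int e = 0; e < s; ++e) {
          double acc = 0.0;
          for (int q = 0; q < 9; ++q) {
            int j = nbr[i * 9 + q];
            if (j >= 0) acc += emb[j * s + e];
          }
          ctx[i * s + e] = acc / 9.0;
        }
      for (int i = 0; i < nj; ++i) {
        bool gate_i = u[i] < pd;
        gates(i, k) = gate_i;
        if (gate_memory && !gate_i && arch_code == 1) continue;
        // average the r_copies controller outputs
        for (int r = 0; r < r_copies; ++r) {
          const double *cp = th + s * nc + r * per_copy;
          if (arch_code == 0) { // ff: w_out (nc x s)
            for (int a = 0; a < nc; ++a) {
              double acc = 0.0;
              for (int e = 0; e < s; ++e)
                acc += cp[e * nc + a] * ctx[i * s + e];
              act[a * nj + i] += acc;
            }
          } else {              // rgrn
            const double *w_in = cp;
            const double *w_rec = cp + m * s;
            const double *w_out = cp + m * s + m * m;
            const double *b = cp + m * s + m * m + nc * m;
            for (int q = 0; q < m; ++q)
              mem_r[q] = mem[(r * m + q) * nj + i];
            for (int cyc = 0; cyc < cycles; ++cyc) {
              for (int q = 0; q < m; ++q) {
                double acc = 0.0;
                for (int e = 0; e < s; ++e)
                  acc += w_in[e * m + q] * ctx[i * s + e];
                for (int p = 0; p < m; ++p)
                  acc += w_rec[p * m + q] * mem_r[p];
                mem_new[q] = std::tanh(acc);
              }
              std::copy(mem_new.begin(), mem_new.begin() + m, mem_r.begin());
            }
            for (int q = 0; q < m; ++q)
              mem[(r * m + q) * nj + i] = mem_r[q];
            for (int a = 0; a < nc; ++a) {
              double acc = b[a];
              for (int q = 0; q < m; ++q)
                acc += w_out[q * nc + a] * mem_r[q];
              act[a * nj + i] += acc;
            }
          }
        }
        for (int a = 0; a < nc; ++a)
          act[a * nj + i] = clip(act[a * nj + i] / r_copies, la_lo, la_hi);
      }
    }

    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < nj; ++i) {
        double a = (actions_enabled && gates(i, k)) ? act[c * nj + i] : 0.0;
        double v = state[c * nj + i] + a + noise * eps[c * nj + i];
        v = clip(v, lc_lo, lc_hi);
        nstate[c * nj + i] = v;
        if (keep_states)
          states[(size_t)(k + 1) * nj * nc + c * nj + i] = v;
      }
    std::swap(state, nstate);
    readout(state, k + 1);
  }
  if (!keep_states)  // retain the final state in the single kept slot
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < nj; ++i)
        states[c * nj + i] = state[c * nj + i];

  return List::create(_["states"] = states, _["types"] = types,
                      _["gates"] = gates);
}
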