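#include <Rcpp.h>
using namespace Rcpp;

// Explicit 7-point-stencil diffusion-reaction marching on a regular grid.
//
// Regions: 0 = biofilm (D = f_bio * D_water), 1 = boundary layer (D_water),
// 2 = bulk (pinned Dirichlet cells, never updated). Face diffusivities are
// harmonic means of the two cell values, which keeps the scheme
// flux-conservative across the biofilm/boundary-layer interface; since a
// cell's diffusivity takes only two values the three possible face values
// are precomputed. Boundaries: periodic in x and y, zero-flux Neumann at
// the bottom and top z faces (the top planes are bulk cells in practice,
// so the top boundary is effectively Dirichlet through the region labels).
//
// conc, rates: lists of 3-D arrays (nx x ny x nz), mol/L and mol/L/h.
// D_um2_h: per-species water diffusivity in um^2/h; h_um: grid spacing.
// dt_h <= 0 selects the per-species stability-bound step (safety 0.9).
// Negative concentrations produced by stiff sinks are clipped to zero and
// the clipped mass is accumulated in `deficit` (mol/L summed over cells).
// [[Rcpp::export]]
List cpp_diffuse_chunk(List conc, List rates, IntegerVector region,
                       NumericVector D_um2_h, double f_bio,
                       double h_um, int nsteps, double dt_h = -1.0) {
  IntegerVector dims = region.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny, ncell = nxy * nz;
  const int ns = conc.size();
  const double h2 = h_um * h_um;
  const int *reg = INTEGER(region);

  // diffusivity class per cell: 0 = biofilm, 1 = water (BL and bulk)
  std::vector<unsigned char> cls(ncell);
  int kmax = 0;            // highest plane containing non-bulk cells
  for (int k = 0; k < nz; ++k)
    for (int c = k * nxy; c < (k + 1) * nxy; ++c) {
      cls[c] = (reg[c] == 0) ? 0 : 1;
      if (reg[c] != 2) kmax = k;
    }
  const int kmax1 = std::min(kmax + 1, nz - 1);  // include first bulk plane as neighbor

  List out(ns);
  NumericVector delta(ns), deficit(ns);
  std::vector<double> buf(ncell);

  for (int s = 0; s < ns; ++s) {
    NumericVector C = clone(as<NumericVector>(conc[s]));
    const NumericVector R = as<NumericVector>(rates[s]);
    const double *Rp = REAL(R);
    const double Dw = D_um2_h[s], Db = f_bio * Dw;
    // face diffusivity by class pair (harmonic mean)
    double fD[2][2];
    fD[0][0] = Db; fD[1][1] = Dw;
    fD[0][1] = fD[1][0] = 2.0 * Db * Dw / (Db + Dw);
    const double dt = dt_h > 0 ? dt_h : 0.9 * h2 / (6.0 * Dw);
    const double a = dt / h2;
    double *Cp = REAL(C);
    double lastmax = 0.0, fieldmax = 0.0, def = 0.0;

    for (int step = 0; step < nsteps; ++step) {
      const bool last = (step == nsteps - 1);
      if (last) { lastmax = 0.0; fieldmax = 0.0; }
      std::copy(Cp, Cp + (kmax1 + 1) * nxy, buf.begin());
      for (int k = 0; k <= kmax; ++k) {
        const int koff = nxy * k;
        for (int j = 0; j < ny; ++j) {
          const int joff = nx * j + koff;
          const int jm = nx * (j == 0 ? ny - 1 : j - 1) + koff;
          const int jp = nx * (j == ny - 1 ? 0 : j + 1) + koff;
          for (int i = 0; i < nx; ++i) {
            const int c = i + joff;
            if (reg[c] == 2) continue;           // bulk: pinned
            const unsigned char cc = cls[c];
            const double bc = buf[c];
            double flux = 0.0;
            int nb = (i == 0 ? nx - 1 : i - 1) + joff;
            flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            nb = (i == nx - 1 ? 0 : i + 1) + joff;
            flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            nb = i + jm;
            flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            nb = i + jp;
            flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            if (k > 0) {                         // Neumann at the bottom
              nb = c - nxy;
              flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            }
            if (k < nz - 1) {                    // Neumann at the top
              nb = c + nxy;
              flux += fD[cc][cls[nb]] * (buf[nb] - bc);
            }
            double cn = bc + a * flux + dt * Rp[c];
            if (cn < 0.0) { def += -cn; cn = 0.0; }
            if (last) {
              const double d = cn > bc ? cn - bc : bc - cn;
              if (d > lastmax) lastmax = d;
            }
            Cp[c] = cn;
          }
        }
      }
      if (last)
        for (int c = 0; c < ncell; ++c)
          if (Cp[c] > fieldmax) fieldmax = Cp[c];
    }
    delta[s] = fieldmax > 0 ? lastmax / fieldmax : lastmax;
    deficit[s] = def;
    out[s] = C;
  }
  out.attr("names") = conc.attr("names");
  return List::create(_["conc"] = out, _["delta"] = delta,
                      _["deficit"] = deficit);
}
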