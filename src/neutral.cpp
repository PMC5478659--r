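#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Zero-sum spatially explicit neutral dynamics on an L x L torus.
// Each event: a uniformly chosen individual dies; with probability nu the
// site is taken by a brand-new species (point speciation), otherwise by an
// offspring of a parent drawn from the dispersal kernel centred on the dead
// site. kernel: 0 = global (any other site, uniform), 1 = gaussian(sigma)
// discretised on integer offsets and renormalised (self offset excluded),
// 2 = nearest neighbour (von Neumann 4-neighbourhood).
// Uses R's RNG so runs are reproducible via set.seed().

static inline int wrap(int a, int L) {
  a %= L;
  return a < 0 ? a + L : a;
}

// [[Rcpp::export(name = ".neutral_sim_cpp")]]
IntegerMatrix neutral_sim_cpp(int L, double nu, int kernel, double sigma,
                              int generations) {
  if (L < 2) stop("L must be >= 2");
  if (nu < 0.0 || nu > 1.0) stop("speciation rate must be in [0, 1]");
  const long long J = (long long)L * L;
  std::vector<int> land((size_t)J, 1);
  std::unordered_map<int, long long> abund;
  abund[1] = J;
  int next_species = 2;

  // discretised gaussian kernel: offsets within 5 sigma (capped at L/2),
  // weight exp(-(dx^2+dy^2)/(2 sigma^2)), (0,0) excluded
  std::vector<int> kdx, kdy;
  std::vector<double> kcum;
  if (kernel == 1) {
    if (sigma <= 0.0) stop("sigma must be positive for the gaussian kernel");
    int r = (int)std::ceil(5.0 * sigma);
    if (r > L / 2) r = L / 2;
    if (r < 1) r = 1;
    double tot = 0.0;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy) {
        if (dx == 0 && dy == 0) continue;
        double w = std::exp(-(double)(dx * dx + dy * dy) /
                            (2.0 * sigma * sigma));
        tot += w;
        kdx.push_back(dx);
        kdy.push_back(dy);
        kcum.push_back(tot);
      }
    }
    for (size_t i = 0; i < kcum.size(); ++i) kcum[i] /= tot;
  }
  const int ndx[4] = {1, -1, 0, 0};
  const int ndy[4] = {0, 0, 1, -1};

  NumericVector richness(generations);
  GetRNGstate();
  for (int g = 0; g < generations; ++g) {
    for (long long e = 0; e < J; ++e) {
      long long dead = (long long)(unif_rand() * J);
      if (dead >= J) dead = J - 1;
      int sp_dead = land[(size_t)dead];
      int sp_new;
      if (unif_rand() < nu) {
        sp_new = next_species++;
      } else {
        long long parent;
        if (kernel == 0) {
          do {
            parent = (long long)(unif_rand() * J);
            if (parent >= J) parent = J - 1;
          } while (parent == dead);
        } else {
          int x = (int)(dead % L), y = (int)(dead / L);
          int dx, dy;
          if (kernel == 1) {
            double u = unif_rand();
            size_t i = std::lower_bound(kcum.begin(), kcum.end(), u) -
                       kcum.begin();
            if (i >= kdx.size()) i = kdx.size() - 1;
            dx = kdx[i];
            dy = kdy[i];
          } else {
            int i = (int)(unif_rand() * 4);
            if (i > 3) i = 3;
            dx = ndx[i];
            dy = ndy[i];
          }
          parent = (long long)wrap(x + dx, L) + (long long)L * wrap(y + dy, L);
        }
        sp_new = land[(size_t)parent];
      }
      if (sp_new != sp_dead) {
        land[(size_t)dead] = sp_new;
        if (--abund[sp_dead] == 0) abund.erase(sp_dead);
        ++abund[sp_new];
      }
    }
    richness[g] = (double)abund.size();
  }
  PutRNGstate();

  IntegerMatrix out(L, L);
  for (long long i = 0; i < J; ++i) out[(R_xlen_t)i] = land[(size_t)i];
  out.attr("richness_trace") = richness;
  return out;
}
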