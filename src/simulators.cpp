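#include <Rcpp.h>
using namespace Rcpp;

// Driven branching process: A_{t+1} ~ Poisson(m * A_t) + Poisson(h).
// The sum of the two independent Poissons is Poisson(m*A_t + h), which is
// what gets drawn. Uses R's RNG, so set.seed() on the R side governs.
// [[Rcpp::export]]
IntegerVector branching_core(int steps, double m, double h, double init,
                             int burn_in) {
  IntegerVector out(steps);
  double a = init;
  int total = steps + burn_in;
  for (int t = 0; t < total; ++t) {
    a = R::rpois(m * a + h);
    if (t >= burn_in) out[t - burn_in] = (int)a;
  }
  return out;
}

// Lattice branching network on a periodic side x side square grid. Each
// event at a unit independently triggers an event at each of its 4
// neighbours next step with probability p (implied branching ratio 4p).
// Drive: the population receives Poisson(n * h_unit) external events per
// step, assigned to uniformly random units. Unit counts are event tallies
// (can exceed 1 per bin). Rows of the returned matrix are the units listed
// in `record` (0-based), columns are post-burn-in time steps.
// [[Rcpp::export]]
IntegerMatrix lattice_core(int side, double p, double h_unit, int steps,
                           int burn_in, IntegerVector record,
                           int init_total) {
  const int n = side * side;
  std::vector<int> counts(n, 0), nxt(n, 0);
  // neighbour index tables (up, down, left, right with wrap-around)
  std::vector<int> nb(4 * n);
  for (int i = 0; i < n; ++i) {
    int r = i / side, c = i % side;
    nb[4 * i + 0] = ((r + side - 1) % side) * side + c;
    nb[4 * i + 1] = ((r + 1) % side) * side + c;
    nb[4 * i + 2] = r * side + (c + side - 1) % side;
    nb[4 * i + 3] = r * side + (c + 1) % side;
  }
  for (int k = 0; k < init_total; ++k)
    counts[(int)(unif_rand() * n) % n] += 1;

  const int nrec = record.size();
  IntegerMatrix out(nrec, steps);
  const double drive_rate = n * h_unit;
  const int total = steps + burn_in;
  for (int t = 0; t < total; ++t) {
    std::fill(nxt.begin(), nxt.end(), 0);
    int k_drive = (int)R::rpois(drive_rate);
    for (int k = 0; k < k_drive; ++k)
      nxt[(int)(unif_rand() * n) % n] += 1;
    for (int i = 0; i < n; ++i) {
      int c = counts[i];
      if (c == 0) continue;
      for (int j = 0; j < 4; ++j)
        nxt[nb[4 * i + j]] += (int)R::rbinom(c, p);
    }
    counts.swap(nxt);
    if (t >= burn_in) {
      int col = t - burn_in;
      for (int r = 0; r < nrec; ++r)
        out(r, col) = counts[record[r]];
    }
  }
  return out;
}
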