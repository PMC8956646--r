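#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static inline double mi1(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

static inline double dist2_mi(const NumericMatrix &x, int i, int j,
                              const NumericVector &box) {
  double dx = mi1(x(i, 0) - x(j, 0), box[0]);
  double dy = mi1(x(i, 1) - x(j, 1), box[1]);
  double dz = mi1(x(i, 2) - x(j, 2), box[2]);
  return dx * dx + dy * dy + dz * dz;
}

// Histogram of reference-partner minimum-image distances for one frame.
// ref/partner are 0-based index vectors; mol maps atom -> molecule id.
// [[Rcpp::export]]
NumericVector rdf_hist_cpp(NumericMatrix coords, NumericVector box,
                           IntegerVector ref, IntegerVector partner,
                           IntegerVector mol, double bin_width, int nbins,
                           bool exclude_intra) {
  NumericVector counts(nbins);
  double rmax2 = (bin_width * nbins) * (bin_width * nbins);
  for (int a = 0; a < ref.size(); ++a) {
    int i = ref[a];
    for (int b = 0; b < partner.size(); ++b) {
      int j = partner[b];
      if (i == j) continue;
      if (exclude_intra && mol[i] == mol[j]) continue;
      double r2 = dist2_mi(coords, i, j, box);
      if (r2 >= rmax2) continue;
      int bin = (int)std::floor(std::sqrt(r2) / bin_width);
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}

static inline long long pair_key(int i, int j, int n) {
  int a = i < j ? i : j, b = i < j ? j : i;
  return (long long)a * (long long)n + (long long)b;
}

// Coulomb + LJ(12-6, R_min form) sum over inter-group pairs within cutoff.
// Combining rules: well depth geometric, R_min arithmetic of per-atom values.
// excl: 0-based pair matrix of bonded 1-2/1-3 exclusions (used only when
// include_intra is true).
// [[Rcpp::export]]
NumericVector energy_frame_cpp(NumericMatrix coords, NumericVector box,
                               NumericVector q, NumericVector eps,
                               NumericVector rmin2, IntegerVector mol,
                               IntegerVector ga, IntegerVector gb,
                               double cutoff, bool include_intra,
                               IntegerMatrix excl, double coulomb_k) {
  int n = coords.nrow();
  std::vector<char> in_a(n, 0), in_b(n, 0);
  for (int k = 0; k < ga.size(); ++k) in_a[ga[k]] = 1;
  for (int k = 0; k < gb.size(); ++k) in_b[gb[k]] = 1;
  std::unordered_set<long long> excl_set;
  for (int k = 0; k < excl.nrow(); ++k)
    excl_set.insert(pair_key(excl(k, 0), excl(k, 1), n));
  double cut2 = cutoff * cutoff;
  double ec = 0.0, ev = 0.0;
  for (int a = 0; a < ga.size(); ++a) {
    int i = ga[a];
    for (int b = 0; b < gb.size(); ++b) {
      int j = gb[b];
      if (i == j) continue;
      // count each unordered pair once when memberships overlap
      if (in_b[i] && in_a[j] && j < i) continue;
      bool same_mol = mol[i] == mol[j];
      if (same_mol) {
        if (!include_intra) continue;
        if (excl_set.count(pair_key(i, j, n))) continue;
      }
      double r2 = dist2_mi(coords, i, j, box);
      if (r2 > cut2) continue;
      double r = std::sqrt(r2);
      ec += coulomb_k * q[i] * q[j] / r;
      double d0 = std::sqrt(eps[i] * eps[j]);
      if (d0 > 0.0) {
        double r0 = rmin2[i] + rmin2[j];
        double s6 = std::pow(r0 / r, 6.0);
        ev += d0 * (s6 * s6 - 2.0 * s6);
      }
    }
  }
  return NumericVector::create(_["coulomb"] = ec, _["vdw"] = ev);
}

// Full pressure-tensor numerator K + W (kcal/mol) for one frame:
// kinetic term sum m v_a v_b (converted by ke_conv) plus pair virial
// sum r_a F_b from LJ + Coulomb forces within cutoff under minimum image.
// [[Rcpp::export]]
NumericMatrix virial_frame_cpp(NumericMatrix coords, NumericMatrix vel,
                               NumericVector box, NumericVector q,
                               NumericVector eps, NumericVector rmin2,
                               NumericVector mass, IntegerVector mol,
                               double cutoff, bool include_intra,
                               IntegerMatrix excl, double coulomb_k,
                               double ke_conv) {
  int n = coords.nrow();
  NumericMatrix P(3, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        P(a, b) += mass[i] * vel(i, a) * vel(i, b) * ke_conv;
  std::unordered_set<long long> excl_set;
  for (int k = 0; k < excl.nrow(); ++k)
    excl_set.insert(pair_key(excl(k, 0), excl(k, 1), n));
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same_mol = mol[i] == mol[j];
      if (same_mol) {
        if (!include_intra) continue;
        if (excl_set.count(pair_key(i, j, n))) continue;
      }
      double dx = mi1(coords(i, 0) - coords(j, 0), box[0]);
      double dy = mi1(coords(i, 1) - coords(j, 1), box[1]);
      double dz = mi1(coords(i, 2) - coords(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2 || r2 == 0.0) continue;
      double r = std::sqrt(r2);
      // dU/dr
      double dudr = -coulomb_k * q[i] * q[j] / r2;
      double d0 = std::sqrt(eps[i] * eps[j]);
      if (d0 > 0.0) {
        double r0 = rmin2[i] + rmin2[j];
        double s6 = std::pow(r0 / r, 6.0);
        dudr += -12.0 * d0 / r * (s6 * s6 - s6);
      }
      double fmag = -dudr / r;  // F_i = fmag * r_ij (force on i from j)
      double rv[3] = {dx, dy, dz};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          P(a, b) += rv[a] * fmag * rv[b];
    }
  }
  return P;
}

static double lj_energy_one(const NumericMatrix &x, int i,
                            const NumericVector &pos_i,
                            const NumericVector &box, double eps, double r0,
                            double cut2) {
  double e = 0.0;
  for (int j = 0; j < x.nrow(); ++j) {
    if (j == i) continue;
    double dx = mi1(pos_i[0] - x(j, 0), box[0]);
    double dy = mi1(pos_i[1] - x(j, 1), box[1]);
    double dz = mi1(pos_i[2] - x(j, 2), box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) continue;
    double s6 = std::pow(r0 * r0 / r2, 3.0);
    e += eps * (s6 * s6 - 2.0 * s6);
  }
  return e;
}

// Metropolis Monte Carlo for a single-site LJ fluid (R_min form, plain
// cutoff). Draws come from the R RNG so runs are reproducible via set.seed.
// Returns sampled configurations plus total energies and acceptance ratio.
// [[Rcpp::export]]
List lj_mc_cpp(NumericMatrix init, NumericVector box, double eps, double r0,
               double beta, double cutoff, double max_disp,
               int n_equil_sweeps, int n_samples, int sweeps_per_sample) {
  NumericMatrix x = clone(init);
  int n = x.nrow();
  double cut2 = cutoff * cutoff;
  long accepted = 0, attempted = 0;
  List frames(n_samples);
  NumericVector energies(n_samples);
  RNGScope scope;
  int total_sweeps = n_equil_sweeps + n_samples * sweeps_per_sample;
  int sample_idx = 0;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int move = 0; move < n; ++move) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      NumericVector old_pos = NumericVector::create(x(i, 0), x(i, 1), x(i, 2));
      NumericVector new_pos(3);
      for (int d = 0; d < 3; ++d) {
        double p = old_pos[d] + (unif_rand() * 2.0 - 1.0) * max_disp;
        p -= box[d] * std::floor(p / box[d]);
        new_pos[d] = p;
      }
      double e_old = lj_energy_one(x, i, old_pos, box, eps, r0, cut2);
      double e_new = lj_energy_one(x, i, new_pos, box, eps, r0, cut2);
      ++attempted;
      if (e_new <= e_old || unif_rand() < std::exp(-beta * (e_new - e_old))) {
        x(i, 0) = new_pos[0]; x(i, 1) = new_pos[1]; x(i, 2) = new_pos[2];
        ++accepted;
      }
    }
    if (sweep >= n_equil_sweeps &&
        (sweep - n_equil_sweeps + 1) % sweeps_per_sample == 0 &&
        sample_idx < n_samples) {
      frames[sample_idx] = clone(x);
      double e = 0.0;
      for (int i = 0; i < n; ++i) {
        NumericVector pos_i = NumericVector::create(x(i, 0), x(i, 1), x(i, 2));
        e += lj_energy_one(x, i, pos_i, box, eps, r0, cut2);
      }
      energies[sample_idx] = e / 2.0;
      ++sample_idx;
    }
  }
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["acceptance"] = (double)accepted / (double)attempted);
}
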