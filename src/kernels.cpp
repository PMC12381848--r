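#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate arrays are numeric arrays with dim (n_frames, n_residues, 3),
// i.e. element (f, r, d) lives at f + F*r + F*R*d (0-based, column-major).

static inline double sq(double x) { return x * x; }

// Internal Ca-Ca distances for every frame. Pair order: (i, j) with i < j,
// i outer, j inner (0-based); matches pair_separations().
// [[Rcpp::export]]
NumericMatrix cpp_internal_distances(NumericVector coords, bool exclude_adjacent) {
  IntegerVector dim = coords.attr("dim");
  const int F = dim[0], R = dim[1];
  const double *c = coords.begin();
  int np = 0;
  for (int i = 0; i < R - 1; ++i)
    for (int j = i + 1; j < R; ++j)
      if (!exclude_adjacent || j - i > 1) ++np;
  NumericMatrix D(F, np);
  for (int f = 0; f < F; ++f) {
    int p = 0;
    for (int i = 0; i < R - 1; ++i) {
      for (int j = i + 1; j < R; ++j) {
        if (exclude_adjacent && j - i == 1) continue;
        double dx = c[f + F * i] - c[f + F * j];
        double dy = c[f + F * i + F * R] - c[f + F * j + F * R];
        double dz = c[f + F * i + 2 * F * R] - c[f + F * j + 2 * F * R];
        D(f, p++) = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
  }
  return D;
}

// Sequence separations |i - j| in the same pair order as cpp_internal_distances.
// [[Rcpp::export]]
IntegerVector cpp_pair_separations(int n_residues, bool exclude_adjacent) {
  std::vector<int> sep;
  for (int i = 0; i < n_residues - 1; ++i)
    for (int j = i + 1; j < n_residues; ++j)
      if (!exclude_adjacent || j - i > 1) sep.push_back(j - i);
  return wrap(sep);
}

// Pairwise dissimilarity delta = 1 - Q_w over rows of the internal-distance
// matrix; sigma2 holds 2*sigma_ij^2 per pair.
// [[Rcpp::export]]
NumericMatrix cpp_delta_matrix(NumericMatrix D, NumericVector two_sigma2) {
  const int N = D.nrow(), P = D.ncol();
  NumericMatrix out(N, N);
  for (int k = 0; k < N; ++k) {
    out(k, k) = 0.0;
    for (int l = k + 1; l < N; ++l) {
      double s = 0.0;
      for (int p = 0; p < P; ++p)
        s += std::exp(-sq(D(k, p) - D(l, p)) / two_sigma2[p]);
      double d = 1.0 - s / P;
      if (d < 0) d = 0;
      out(k, l) = d;
      out(l, k) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Pairwise distance-RMSD over rows of the internal-distance matrix.
// [[Rcpp::export]]
NumericMatrix cpp_drmsd_matrix(NumericMatrix D) {
  const int N = D.nrow(), P = D.ncol();
  NumericMatrix out(N, N);
  for (int k = 0; k < N; ++k) {
    out(k, k) = 0.0;
    for (int l = k + 1; l < N; ++l) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) s += sq(D(k, p) - D(l, p));
      double d = std::sqrt(s / P);
      out(k, l) = d;
      out(l, k) = d;
    }
  }
  return out;
}

// Force-scheme layout: Gauss-Seidel sweeps moving each point toward/away from
// every other so planar distances approach the target dissimilarities.
// Learning rate decays linearly from lr0 to lr1 over n_iter sweeps.
// Returns the final layout and the stress sum_{k<l} (d2D - delta)^2 recorded
// after every sweep.
// [[Rcpp::export]]
List cpp_force_scheme(NumericMatrix delta, NumericMatrix x0, int n_iter,
                      double lr0, double lr1) {
  const int N = delta.nrow();
  const double eps = 1e-9;
  NumericMatrix X = clone(x0);
  NumericVector stress(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    double lr = lr0 + (lr1 - lr0) * (n_iter > 1 ? (double)it / (n_iter - 1) : 0.0);
    for (int k = 0; k < N; ++k) {
      double xk = X(k, 0), yk = X(k, 1);
      double fx = 0.0, fy = 0.0;  // mean residual force on point k
      for (int l = 0; l < N; ++l) {
        if (l == k) continue;
        double vx = X(l, 0) - xk, vy = X(l, 1) - yk;
        double d = std::sqrt(vx * vx + vy * vy);
        double move = (d - delta(k, l)) / std::max(d, eps);
        fx += move * vx;
        fy += move * vy;
      }
      X(k, 0) = xk + lr * fx / (N - 1);
      X(k, 1) = yk + lr * fy / (N - 1);
    }
    double s = 0.0;
    for (int k = 0; k < N - 1; ++k)
      for (int l = k + 1; l < N; ++l)
        s += sq(std::sqrt(sq(X(k, 0) - X(l, 0)) + sq(X(k, 1) - X(l, 1))) - delta(k, l));
    stress[it] = s;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["coords"] = X, _["stress"] = stress);
}

// Local (basin) sampling around a template chain: each frame applies
// `n_pivots` small pivot rotations (tail beyond a random bead rotated by a
// Gaussian angle about a random axis) to the template; bond lengths are
// preserved exactly, excluded volume and motif contacts re-checked by
// rejection. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_basin_frames(NumericMatrix templ, int n_frames, int n_pivots,
                               double angle_sd, double excluded,
                               IntegerMatrix motif_pairs,
                               NumericVector motif_cutoffs,
                               int max_frame_retries) {
  const int R = templ.nrow();
  const double ev2 = excluded * excluded;
  const int nm = motif_pairs.nrow();
  NumericVector coords(Dimension(n_frames, R, 3));
  std::vector<double> px(R), py(R), pz(R);
  for (int f = 0; f < n_frames; ++f) {
    bool ok = false;
    for (int attempt = 0; attempt < max_frame_retries && !ok; ++attempt) {
      for (int i = 0; i < R; ++i) {
        px[i] = templ(i, 0); py[i] = templ(i, 1); pz[i] = templ(i, 2);
      }
      for (int m = 0; m < n_pivots; ++m) {
        int r = 1 + (int)(unif_rand() * (R - 2));
        if (r > R - 2) r = R - 2;
        double ax[3];
        double a1 = norm_rand(), a2 = norm_rand(), a3 = norm_rand();
        double an = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3);
        if (an < 1e-9) continue;
        ax[0] = a1 / an; ax[1] = a2 / an; ax[2] = a3 / an;
        double th = angle_sd * norm_rand();
        double ct = std::cos(th), st = std::sin(th);
        for (int i = r + 1; i < R; ++i) {
          double vx = px[i] - px[r], vy = py[i] - py[r], vz = pz[i] - pz[r];
          double dot = ax[0] * vx + ax[1] * vy + ax[2] * vz;
          double cx = ax[1] * vz - ax[2] * vy;
          double cy = ax[2] * vx - ax[0] * vz;
          double cz = ax[0] * vy - ax[1] * vx;
          px[i] = px[r] + vx * ct + cx * st + ax[0] * dot * (1 - ct);
          py[i] = py[r] + vy * ct + cy * st + ax[1] * dot * (1 - ct);
          pz[i] = pz[r] + vz * ct + cz * st + ax[2] * dot * (1 - ct);
        }
      }
      bool clash = false;
      for (int i = 0; i < R - 2 && !clash; ++i)
        for (int j = i + 2; j < R && !clash; ++j)
          clash = sq(px[i] - px[j]) + sq(py[i] - py[j]) + sq(pz[i] - pz[j]) < ev2;
      if (clash) continue;
      bool motif_ok = true;
      for (int m = 0; m < nm && motif_ok; ++m) {
        int a = motif_pairs(m, 0) - 1, b = motif_pairs(m, 1) - 1;
        motif_ok = sq(px[a] - px[b]) + sq(py[a] - py[b]) + sq(pz[a] - pz[b]) <=
          sq(motif_cutoffs[m]);
      }
      if (!motif_ok) continue;
      for (int i = 0; i < R; ++i) {
        coords[f + (R_xlen_t)n_frames * i] = px[i];
        coords[f + (R_xlen_t)n_frames * (i + R)] = py[i];
        coords[f + (R_xlen_t)n_frames * (i + 2 * R)] = pz[i];
      }
      ok = true;
    }
    if (!ok)
      stop("could not sample a basin frame within %d attempts at frame %d (pivot amplitude too large for the constraints?)",
           max_frame_retries, f + 1);
    if (f % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return coords;
}

static void random_unit(double *u) {
  double n2 = 0.0;
  do {
    n2 = 0.0;
    for (int d = 0; d < 3; ++d) {
      u[d] = norm_rand();
      n2 += u[d] * u[d];
    }
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  for (int d = 0; d < 3; ++d) u[d] /= n;
}

// Self-avoiding-biased random walk with centroid-attraction whose strength
// maps from `compactness`; fixed bond length, hard excluded-volume core
// between non-bonded beads, optional pair-contact motifs enforced by
// rejection sampling. Uses R's RNG, so set.seed() makes output reproducible.
// [[Rcpp::export]]
NumericVector cpp_polymer_frames(int n_frames, int n_res, double bond,
                                 double compactness, double excluded,
                                 IntegerMatrix motif_pairs,
                                 NumericVector motif_cutoffs,
                                 int max_bead_trials, int max_frame_retries) {
  NumericVector coords(Dimension(n_frames, n_res, 3));
  const double lambda = 2.0;  // strength of the confinement bias
  // confinement radius: beads beyond it feel the full inward pull, beads
  // near the centroid walk almost isotropically (avoids forced clashes)
  const double r_conf = 0.8 * bond * std::cbrt((double)n_res);
  const double ev2 = excluded * excluded;
  std::vector<double> px(n_res), py(n_res), pz(n_res);
  const int nm = motif_pairs.nrow();
  for (int f = 0; f < n_frames; ++f) {
    bool frame_ok = false;
    for (int attempt = 0; attempt < max_frame_retries && !frame_ok; ++attempt) {
      px[0] = py[0] = pz[0] = 0.0;
      double cx = 0, cy = 0, cz = 0;  // running centroid of placed beads
      bool walk_ok = true;
      for (int i = 1; i < n_res && walk_ok; ++i) {
        bool placed = false;
        for (int t = 0; t < max_bead_trials && !placed; ++t) {
          double u[3];
          random_unit(u);
          // guide the walk toward already-placed motif partners that are
          // still out of reach; the final motif check below stays exact
          for (int m = 0; m < nm; ++m) {
            int a = motif_pairs(m, 0) - 1, b = motif_pairs(m, 1) - 1;
            int src = std::min(a, b), tgt = std::max(a, b);
            if (src > i - 1 || tgt < i) continue;  // partner not placed / pair done
            double gx = px[src] - px[i - 1];
            double gy = py[src] - py[i - 1];
            double gz = pz[src] - pz[i - 1];
            double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
            if (gn < 1e-9) continue;
            double w = 0.0;
            if (tgt == i) {
              // placing the motif bead itself: pull inside the cutoff
              double slack = gn - 0.6 * motif_cutoffs[m];
              if (slack > 0) w = std::min(3.0, 2.0 * slack / bond);
            } else {
              // en route: keep the partner within the remaining reach
              double reach = (tgt - i) * bond;
              double deficit = gn - 0.7 * reach;
              if (deficit > 0) w = std::min(3.0, 2.0 * deficit / bond);
            }
            if (w > 0) {
              u[0] += w * gx / gn; u[1] += w * gy / gn; u[2] += w * gz / gn;
            }
          }
          double un0 = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
          for (int d = 0; d < 3; ++d) u[d] /= un0;
          if (compactness > 0 && i >= 2) {
            double bx = cx - px[i - 1], by = cy - py[i - 1], bz = cz - pz[i - 1];
            double bn = std::sqrt(bx * bx + by * by + bz * bz);
            if (bn > 1e-9) {
              double w = lambda * compactness * std::min(bn / r_conf, 2.0) / bn;
              u[0] += w * bx;
              u[1] += w * by;
              u[2] += w * bz;
              double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
              for (int d = 0; d < 3; ++d) u[d] /= un;
            }
          }
          double qx = px[i - 1] + bond * u[0];
          double qy = py[i - 1] + bond * u[1];
          double qz = pz[i - 1] + bond * u[2];
          bool clash = false;
          for (int j = 0; j <= i - 2 && !clash; ++j)
            clash = sq(qx - px[j]) + sq(qy - py[j]) + sq(qz - pz[j]) < ev2;
          if (!clash) {
            px[i] = qx; py[i] = qy; pz[i] = qz;
            placed = true;
          }
        }
        if (!placed) walk_ok = false;
        else {
          cx = (cx * i + px[i]) / (i + 1);
          cy = (cy * i + py[i]) / (i + 1);
          cz = (cz * i + pz[i]) / (i + 1);
        }
      }
      if (!walk_ok) continue;
      bool motif_ok = true;
      for (int m = 0; m < nm && motif_ok; ++m) {
        int a = motif_pairs(m, 0) - 1, b = motif_pairs(m, 1) - 1;
        double d2 = sq(px[a] - px[b]) + sq(py[a] - py[b]) + sq(pz[a] - pz[b]);
        motif_ok = d2 <= sq(motif_cutoffs[m]);
      }
      if (!motif_ok) continue;
      for (int i = 0; i < n_res; ++i) {
        coords[f + (R_xlen_t)n_frames * i] = px[i];
        coords[f + (R_xlen_t)n_frames * (i + n_res)] = py[i];
        coords[f + (R_xlen_t)n_frames * (i + 2 * n_res)] = pz[i];
      }
      frame_ok = true;
    }
    if (!frame_ok) {
      if (nm > 0)
        stop("could not satisfy motif constraint on pair (%d, %d) within %d attempts at frame %d",
             motif_pairs(0, 0), motif_pairs(0, 1), max_frame_retries, f + 1);
      stop("could not grow a self-avoiding chain at frame %d; relax excluded volume or compactness",
           f + 1);
    }
    if (f % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return coords;
}
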