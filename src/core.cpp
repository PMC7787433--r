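// Core geometry/compute kernels: NeRF internal-coordinate chain extension,
// excluded-volume Monte-Carlo chain building with backtracking, spatial-grid
// van der Waals clash counting, and CA contact counting.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator-(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 scale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }
inline Vec3 unit(const Vec3 &a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}
inline double dist2(const Vec3 &a, const Vec3 &b) {
  Vec3 d = a - b;
  return dot(d, d);
}

const double DEG = M_PI / 180.0;

// Natural extension reference frame placement: position atom d given the
// three preceding atoms a-b-c, the bond length c-d, the bond angle b-c-d
// (degrees) and the torsion a-b-c-d (degrees).
Vec3 nerf_place(const Vec3 &a, const Vec3 &b, const Vec3 &c, double bond,
                double angle_deg, double torsion_deg) {
  double ang = angle_deg * DEG, tor = torsion_deg * DEG;
  Vec3 bc = unit(c - b);
  Vec3 n = unit(cross(b - a, bc));
  Vec3 m = cross(n, bc);
  Vec3 d2 = {-bond * std::cos(ang), bond * std::sin(ang) * std::cos(tor),
             bond * std::sin(ang) * std::sin(tor)};
  return {c.x + d2.x * bc.x + d2.y * m.x + d2.z * n.x,
          c.y + d2.x * bc.y + d2.y * m.y + d2.z * n.y,
          c.z + d2.x * bc.z + d2.y * m.z + d2.z * n.z};
}

// Hash grid over 3D points with a fixed cell size. Cell size must be at
// least the largest clash query distance so that the 27 neighbouring cells
// cover every possible clash partner.
struct HashGrid {
  double cell;
  std::unordered_map<long long, std::vector<int>> cells;

  explicit HashGrid(double cell_size) : cell(cell_size) {}

  static long long key3(long long ix, long long iy, long long iz) {
    return ((ix + 1048576LL) << 42) | ((iy + 1048576LL) << 21) |
           (iz + 1048576LL);
  }
  long long key(const Vec3 &p) const {
    return key3((long long)std::floor(p.x / cell),
                (long long)std::floor(p.y / cell),
                (long long)std::floor(p.z / cell));
  }
  void insert(const Vec3 &p, int idx) { cells[key(p)].push_back(idx); }
  void remove(const Vec3 &p, int idx) {
    auto it = cells.find(key(p));
    if (it == cells.end()) return;
    auto &v = it->second;
    for (size_t k = v.size(); k-- > 0;) {
      if (v[k] == idx) {
        v.erase(v.begin() + k);
        break;
      }
    }
  }
  template <typename F>
  void visit_neighbours(const Vec3 &p, F f) const {
    long long ix = (long long)std::floor(p.x / cell);
    long long iy = (long long)std::floor(p.y / cell);
    long long iz = (long long)std::floor(p.z / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key3(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int idx : it->second) f(idx);
        }
  }
};

// Truncated gaussian jitter: |draw| <= 3 sd, exact when sd == 0.
double jitter_draw(double sd) {
  if (sd <= 0) return 0.0;
  for (int i = 0; i < 100; ++i) {
    double x = norm_rand() * sd;
    if (std::fabs(x) <= 3.0 * sd) return x;
  }
  return 0.0;
}

}  // namespace

// Count cross-set van der Waals clashes: pairs (i in A, j in B) with
// distance < ra[i] + rb[j] - overlap_tol. Grid-accelerated.
// [[Rcpp::export(name = ".count_clashes_cpp")]]
int count_clashes_cpp(NumericMatrix ax, NumericVector ra, NumericMatrix bx,
                      NumericVector rb, double overlap_tol) {
  int na = ax.nrow(), nb = bx.nrow();
  if (na == 0 || nb == 0) return 0;
  double rmax_a = 0, rmax_b = 0;
  for (int i = 0; i < na; ++i) rmax_a = std::max(rmax_a, ra[i]);
  for (int j = 0; j < nb; ++j) rmax_b = std::max(rmax_b, rb[j]);
  double cell = std::max(rmax_a + rmax_b - overlap_tol, 1.0);
  HashGrid grid(cell);
  std::vector<Vec3> A(na);
  for (int i = 0; i < na; ++i) {
    A[i] = {ax(i, 0), ax(i, 1), ax(i, 2)};
    grid.insert(A[i], i);
  }
  int count = 0;
  for (int j = 0; j < nb; ++j) {
    Vec3 p = {bx(j, 0), bx(j, 1), bx(j, 2)};
    double rj = rb[j];
    grid.visit_neighbours(p, [&](int i) {
      double lim = ra[i] + rj - overlap_tol;
      if (lim > 0 && dist2(p, A[i]) < lim * lim) ++count;
    });
  }
  return count;
}

// Count intra-chain clashes between atoms at least min_sep residues apart.
// [[Rcpp::export(name = ".count_self_clashes_cpp")]]
int count_self_clashes_cpp(NumericMatrix x, NumericVector r,
                           IntegerVector res_index, int min_sep,
                           double overlap_tol) {
  int n = x.nrow();
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cell = std::max(2 * rmax - overlap_tol, 1.0);
  HashGrid grid(cell);
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) {
    P[i] = {x(i, 0), x(i, 1), x(i, 2)};
    grid.insert(P[i], i);
  }
  int count = 0;
  for (int j = 0; j < n; ++j) {
    grid.visit_neighbours(P[j], [&](int i) {
      if (i >= j) return;
      if (std::abs(res_index[i] - res_index[j]) < min_sep) return;
      double lim = r[i] + r[j] - overlap_tol;
      if (lim > 0 && dist2(P[i], P[j]) < lim * lim) ++count;
    });
  }
  return count;
}

// Count CA-CA contacts closer than cutoff with sequence separation
// >= min_sep (compactness score used by the default energy scorer).
// [[Rcpp::export(name = ".ca_contact_count_cpp")]]
int ca_contact_count_cpp(NumericMatrix ca, double cutoff, int min_sep) {
  int n = ca.nrow();
  double c2 = cutoff * cutoff;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_sep; j < n; ++j) {
      double dx = ca(i, 0) - ca(j, 0), dy = ca(i, 1) - ca(j, 1),
             dz = ca(i, 2) - ca(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return count;
}

// Deterministic rebuild of chain coordinates from per-residue dihedrals.
// phi[0] and the torsion reference of the first residue are irrelevant to
// the internal geometry. Returns the atom coordinate matrix in build order
// (N, CA, C, O, [SC] per residue).
// [[Rcpp::export(name = ".rebuild_coords_cpp")]]
NumericMatrix rebuild_coords_cpp(NumericVector phi, NumericVector psi,
                                 IntegerVector sc_present,
                                 NumericVector sc_dist, NumericVector geom) {
  int nres = phi.size();
  double b_n_ca = geom[0], b_ca_c = geom[1], b_c_n = geom[2], b_c_o = geom[3];
  double a_n_ca_c = geom[4], a_ca_c_n = geom[5], a_c_n_ca = geom[6],
         a_ca_c_o = geom[7], omega = geom[8], a_c_ca_sc = geom[9],
         t_n_c_ca_sc = geom[10];
  int natoms = 0;
  for (int i = 0; i < nres; ++i) natoms += 4 + (sc_present[i] ? 1 : 0);
  NumericMatrix out(natoms, 3);
  std::vector<Vec3> N(nres), CA(nres), C(nres);
  int row = 0;
  auto push = [&](const Vec3 &p) {
    out(row, 0) = p.x;
    out(row, 1) = p.y;
    out(row, 2) = p.z;
    ++row;
  };
  for (int i = 0; i < nres; ++i) {
    if (i == 0) {
      N[0] = {0, 0, 0};
      CA[0] = {b_n_ca, 0, 0};
      Vec3 ref = {0, 1, 0};
      C[0] = nerf_place(ref, N[0], CA[0], b_ca_c, a_n_ca_c, 0.0);
    } else {
      N[i] = nerf_place(N[i - 1], CA[i - 1], C[i - 1], b_c_n, a_ca_c_n,
                        psi[i - 1]);
      CA[i] = nerf_place(CA[i - 1], C[i - 1], N[i], b_n_ca, a_c_n_ca, omega);
      C[i] = nerf_place(C[i - 1], N[i], CA[i], b_ca_c, a_n_ca_c, phi[i]);
    }
    Vec3 O = nerf_place(N[i], CA[i], C[i], b_c_o, a_ca_c_o, psi[i] + 180.0);
    push(N[i]);
    push(CA[i]);
    push(C[i]);
    push(O);
    if (sc_present[i]) {
      push(nerf_place(N[i], C[i], CA[i], sc_dist[i], a_c_ca_sc, t_n_c_ca_sc));
    }
  }
  return out;
}

// Excluded-volume Monte-Carlo chain builder.
//
// Per residue, (phi, psi) is drawn from a weighted mixture of gaussian
// Ramachandran basins (basin table rows: weight, phi, psi, sd_phi, sd_psi,
// flattened over residues with offsets). A residue whose atoms clash with
// atoms >= min_sep residues back is resampled up to max_resample times,
// then the last unwind_len residues are discarded; after max_unwind
// unwinds the whole chain restarts. Uses R's RNG.
// [[Rcpp::export(name = ".build_chain_cpp")]]
List build_chain_cpp(IntegerVector sc_present, NumericVector sc_dist,
                     NumericVector sc_radius, NumericMatrix basin_table,
                     IntegerVector basin_offset, IntegerVector basin_count,
                     NumericVector geom, NumericVector bb_radii,
                     double overlap_tol, int min_sep, int max_resample,
                     int unwind_len, int max_unwind, int max_restart) {
  int nres = sc_present.size();
  double b_n_ca = geom[0], b_ca_c = geom[1], b_c_n = geom[2], b_c_o = geom[3];
  double a_n_ca_c = geom[4], a_ca_c_n = geom[5], a_c_n_ca = geom[6],
         a_ca_c_o = geom[7], omega = geom[8], a_c_ca_sc = geom[9],
         t_n_c_ca_sc = geom[10];

  double rmax = 0;
  for (int k = 0; k < 4; ++k) rmax = std::max(rmax, bb_radii[k]);
  for (int i = 0; i < nres; ++i) rmax = std::max(rmax, sc_radius[i]);
  double cell = std::max(2 * rmax - overlap_tol, 1.0);

  std::vector<Vec3> N(nres), CA(nres), C(nres), O(nres), SC(nres);
  NumericVector phi(nres), psi(nres);

  HashGrid grid(cell);
  grid.cells.reserve(4096);
  // atom ids: residue * 5 + slot (0=N,1=CA,2=C,3=O,4=SC)
  auto atom_res = [](int id) { return id / 5; };
  std::vector<Vec3> atom_pos(nres * 5);
  std::vector<double> atom_rad(nres * 5);

  int restarts = 0, unwinds = 0;
  int i = 0;
  int stuck = -1;

  auto clear_residue = [&](int r) {
    for (int s = 0; s < 5; ++s) {
      if (s == 4 && !sc_present[r]) continue;
      grid.remove(atom_pos[r * 5 + s], r * 5 + s);
    }
  };

  while (i < nres) {
    if (restarts > max_restart) break;
    bool placed = false;
    for (int attempt = 0; attempt < max_resample; ++attempt) {
      // draw a basin and dihedrals
      int nb = basin_count[i], off = basin_offset[i];
      double u = unif_rand(), acc = 0;
      int b = off;
      for (int k = 0; k < nb; ++k) {
        acc += basin_table(off + k, 0);
        if (u <= acc || k == nb - 1) {
          b = off + k;
          break;
        }
      }
      double ph = basin_table(b, 1) + jitter_draw(basin_table(b, 3));
      double ps = basin_table(b, 2) + jitter_draw(basin_table(b, 4));

      Vec3 n_i, ca_i, c_i;
      if (i == 0) {
        n_i = {0, 0, 0};
        ca_i = {b_n_ca, 0, 0};
        Vec3 ref = {0, 1, 0};
        c_i = nerf_place(ref, n_i, ca_i, b_ca_c, a_n_ca_c, 0.0);
      } else {
        n_i = nerf_place(N[i - 1], CA[i - 1], C[i - 1], b_c_n, a_ca_c_n,
                         psi[i - 1]);
        ca_i = nerf_place(CA[i - 1], C[i - 1], n_i, b_n_ca, a_c_n_ca, omega);
        c_i = nerf_place(C[i - 1], n_i, ca_i, b_ca_c, a_n_ca_c, ph);
      }
      Vec3 o_i = nerf_place(n_i, ca_i, c_i, b_c_o, a_ca_c_o, ps + 180.0);
      Vec3 sc_i = {0, 0, 0};
      if (sc_present[i]) {
        sc_i = nerf_place(n_i, c_i, ca_i, sc_dist[i], a_c_ca_sc, t_n_c_ca_sc);
      }

      // clash check against residues <= i - min_sep
      Vec3 cand[5] = {n_i, ca_i, c_i, o_i, sc_i};
      double crad[5] = {bb_radii[0], bb_radii[1], bb_radii[2], bb_radii[3],
                        sc_radius[i]};
      int nat = sc_present[i] ? 5 : 4;
      bool clash = false;
      for (int s = 0; s < nat && !clash; ++s) {
        grid.visit_neighbours(cand[s], [&](int id) {
          if (clash) return;
          if (i - atom_res(id) < min_sep) return;
          double lim = atom_rad[id] + crad[s] - overlap_tol;
          if (lim > 0 && dist2(cand[s], atom_pos[id]) < lim * lim)
            clash = true;
        });
      }
      if (clash) continue;

      N[i] = n_i;
      CA[i] = ca_i;
      C[i] = c_i;
      O[i] = o_i;
      SC[i] = sc_i;
      phi[i] = ph;
      psi[i] = ps;
      for (int s = 0; s < nat; ++s) {
        int id = i * 5 + s;
        atom_pos[id] = cand[s];
        atom_rad[id] = crad[s];
        grid.insert(cand[s], id);
      }
      placed = true;
      break;
    }

    if (placed) {
      ++i;
      continue;
    }

    stuck = i;
    ++unwinds;
    if (unwinds > max_unwind) {
      // whole-chain restart
      for (int r = 0; r < i; ++r) clear_residue(r);
      i = 0;
      unwinds = 0;
      ++restarts;
      continue;
    }
    int back = std::min(unwind_len, i);
    if (back == 0) {
      ++restarts;
      continue;
    }
    for (int r = i - back; r < i; ++r) clear_residue(r);
    i -= back;
  }

  if (i < nres) {
    return List::create(Named("ok") = false,
                        Named("stuck") = stuck + 1,
                        Named("restarts") = restarts);
  }

  int natoms = 0;
  for (int r = 0; r < nres; ++r) natoms += 4 + (sc_present[r] ? 1 : 0);
  NumericMatrix coords(natoms, 3);
  int row = 0;
  for (int r = 0; r < nres; ++r) {
    Vec3 atoms[5] = {N[r], CA[r], C[r], O[r], SC[r]};
    int nat = sc_present[r] ? 5 : 4;
    for (int s = 0; s < nat; ++s) {
      coords(row, 0) = atoms[s].x;
      coords(row, 1) = atoms[s].y;
      coords(row, 2) = atoms[s].z;
      ++row;
    }
  }
  phi[0] = NA_REAL;
  return List::create(Named("ok") = true, Named("coords") = coords,
                      Named("phi") = phi, Named("psi") = psi,
                      Named("restarts") = restarts);
}

// Batched clash counting: one conformer against k pre-placed ligand
// copies (stacked row-wise in `lig`, each `nlig` atoms). The conformer
// grid is built once and reused for all k placements.
// [[Rcpp::export(name = ".dock_counts_cpp")]]
IntegerVector dock_counts_cpp(NumericMatrix ax, NumericVector ra,
                              NumericMatrix lig, int nlig,
                              NumericVector lig_radii, double overlap_tol) {
  int na = ax.nrow();
  int k = lig.nrow() / nlig;
  double rmax_a = 0, rmax_b = 0;
  for (int i = 0; i < na; ++i) rmax_a = std::max(rmax_a, ra[i]);
  for (int j = 0; j < nlig; ++j) rmax_b = std::max(rmax_b, lig_radii[j]);
  double cell = std::max(rmax_a + rmax_b - overlap_tol, 1.0);
  HashGrid grid(cell);
  grid.cells.reserve(2048);
  std::vector<Vec3> A(na);
  for (int i = 0; i < na; ++i) {
    A[i] = {ax(i, 0), ax(i, 1), ax(i, 2)};
    grid.insert(A[i], i);
  }
  IntegerVector out(k);
  for (int c = 0; c < k; ++c) {
    int count = 0;
    for (int j = 0; j < nlig; ++j) {
      Vec3 p = {lig(c * nlig + j, 0), lig(c * nlig + j, 1),
                lig(c * nlig + j, 2)};
      double rj = lig_radii[j];
      grid.visit_neighbours(p, [&](int i) {
        double lim = ra[i] + rj - overlap_tol;
        if (lim > 0 && dist2(p, A[i]) < lim * lim) ++count;
      });
    }
    out[c] = count;
  }
  return out;
}

namespace {

// blob charge asymmetry delta for a ternary charge vector
double blob_delta_c(const std::vector<int> &q, int g) {
  int n = (int)q.size();
  if (n < g) return NA_REAL;
  int np = 0, nm = 0;
  for (int v : q) {
    if (v > 0) ++np;
    else if (v < 0) ++nm;
  }
  double fp = (double)np / n, fm = (double)nm / n;
  double sig_seq = (fp + fm) > 0 ? (fp - fm) * (fp - fm) / (fp + fm) : 0.0;
  int wp = 0, wm = 0;
  double acc = 0.0;
  for (int i = 0; i < g; ++i) {
    if (q[i] > 0) ++wp;
    else if (q[i] < 0) ++wm;
  }
  int nw = n - g + 1;
  for (int i = 0;; ++i) {
    double fwp = (double)wp / g, fwm = (double)wm / g;
    double sig = (fwp + fwm) > 0 ? (fwp - fwm) * (fwp - fwm) / (fwp + fwm)
                                 : 0.0;
    double d = sig - sig_seq;
    acc += d * d;
    if (i == nw - 1) break;
    if (q[i] > 0) --wp; else if (q[i] < 0) --wm;
    if (q[i + g] > 0) ++wp; else if (q[i + g] < 0) ++wm;
  }
  return acc / nw;
}

}  // namespace

// Deterministic delta_max search over segregated block arrangements:
// [Sa][Z1][Other][Z2][Sb][Z3] for S = the split species (+ or -), all
// end-splits of S and all three-way splits of the neutral block.
// [[Rcpp::export(name = ".delta_max_cpp")]]
double delta_max_scan_cpp(int n_plus, int n_minus, int n_zero, int g) {
  int L = n_plus + n_minus + n_zero;
  if (L < g) return NA_REAL;
  double best = -1.0;
  std::vector<int> q(L);
  for (int species = 0; species < 2; ++species) {
    int nS = species == 0 ? n_plus : n_minus;
    int nO = species == 0 ? n_minus : n_plus;
    int sv = species == 0 ? 1 : -1;
    int ov = -sv;
    for (int sa = 0; sa <= nS; ++sa) {
      for (int z1 = 0; z1 <= n_zero; ++z1) {
        for (int z2 = 0; z2 + z1 <= n_zero; ++z2) {
          int z3 = n_zero - z1 - z2;
          int pos = 0;
          for (int i = 0; i < sa; ++i) q[pos++] = sv;
          for (int i = 0; i < z1; ++i) q[pos++] = 0;
          for (int i = 0; i < nO; ++i) q[pos++] = ov;
          for (int i = 0; i < z2; ++i) q[pos++] = 0;
          for (int i = 0; i < nS - sa; ++i) q[pos++] = sv;
          for (int i = 0; i < z3; ++i) q[pos++] = 0;
          double d = blob_delta_c(q, g);
          if (d > best) best = d;
        }
      }
    }
  }
  return best;
}
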