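#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Simulation state lives in an R environment with reference semantics.
// All arrays are column-major; cell sites at 5 um pitch, community voxels at
// 15 um (3x3x3 sites), agarose voxels at 60 um (4x4 community columns).
// Units: um, hr, fmole, fmole/um^3.

namespace {

struct Geo {
  int nx, ny, nz;        // cell sites
  int ncx, ncy, ncz;     // community voxels
  int nax, nay, naz;     // agarose voxels
  double Vc, Va;         // voxel volumes (um^3)
  double hc, ha;         // grid spacings (um)
};

inline int wrap(int i, int n) { int m = i % n; return m < 0 ? m + n : m; }

Geo read_geo(Environment st) {
  List g = st["geo"];
  Geo geo;
  geo.nx = g["nx"]; geo.ny = g["ny"]; geo.nz = g["nz"];
  geo.ncx = g["ncx"]; geo.ncy = g["ncy"]; geo.ncz = g["ncz"];
  geo.nax = g["nax"]; geo.nay = g["nay"]; geo.naz = g["naz"];
  geo.Vc = g["Vc"]; geo.Va = g["Va"];
  geo.hc = g["hc"]; geo.ha = g["ha"];
  return geo;
}

inline int cidx(const Geo& g, int i, int j, int k) {
  return i + g.nx * (j + g.ny * k);
}
inline int vox_of_site(const Geo& g, int i, int j, int k) {
  return (i / 3) + g.ncx * ((j / 3) + g.ncy * (k / 3));
}

// metabolite codes: 0 = adenine (A), 1 = lysine (L), 2 = glucose (G)

struct Params {
  NumericVector vm_req, K_req, quota_req;
  IntegerVector req_is_A;
  NumericVector vm_glc, K_glc, quota_glc;
  NumericVector rel_cont_A, rel_cont_L, rel_death_A, rel_death_L, death_rate;
  double tu_hr, tau_hr, D_ag_hr, D_max_hr;
  int n_tu, n_sub, enclosure_radius;
  double p_up;
  bool instant;
};

Params read_par(Environment st) {
  List p = st["par"];
  Params q;
  q.vm_req = p["vm_req"]; q.K_req = p["K_req"]; q.quota_req = p["quota_req"];
  q.req_is_A = p["req_is_A"];
  q.vm_glc = p["vm_glc"]; q.K_glc = p["K_glc"]; q.quota_glc = p["quota_glc"];
  q.rel_cont_A = p["rel_cont_A"]; q.rel_cont_L = p["rel_cont_L"];
  q.rel_death_A = p["rel_death_A"]; q.rel_death_L = p["rel_death_L"];
  q.death_rate = p["death_rate"];
  q.tu_hr = p["tu_hr"]; q.tau_hr = p["tau_hr"];
  q.D_ag_hr = p["D_ag_hr"]; q.D_max_hr = p["D_max_hr"];
  q.n_tu = p["n_tu"]; q.n_sub = p["n_sub"];
  q.enclosure_radius = p["enclosure_radius"];
  q.p_up = p["p_up"];
  q.instant = as<int>(p["instant"]) != 0;
  return q;
}

const double QUOTA_EPS = 1e-9;

// highest occupied cell layer (exclusive bound); tracked in the state so
// per-tau scans skip empty sky
int get_kmax(Environment st, const Geo& g) {
  int z = as<int>(st["zmax"]);
  if (z < 1) z = 1;
  if (z > g.nz) z = g.nz;
  return z;
}

// ---- diffusion ------------------------------------------------------------

struct Face { int a, b; double coef; }; // dS_a/dt += coef*(S_b - S_a), symmetric

// faces with harmonic-mean D, skipping D = 0 (air and agarose-sealed voxels)
void build_comm_faces(const Geo& g, const NumericVector& D,
                      std::vector<Face>& faces) {
  faces.clear();
  double h2 = g.hc * g.hc;
  for (int k = 0; k < g.ncz; ++k)
    for (int j = 0; j < g.ncy; ++j)
      for (int i = 0; i < g.ncx; ++i) {
        int a = i + g.ncx * (j + g.ncy * k);
        double Da = D[a];
        if (Da <= 0) continue;
        int nb[3][3] = { { wrap(i + 1, g.ncx), j, k },
                         { i, wrap(j + 1, g.ncy), k },
                         { i, j, k + 1 } };
        for (int f = 0; f < 3; ++f) {
          if (f == 2 && k + 1 >= g.ncz) continue; // no-flow top
          int b = nb[f][0] + g.ncx * (nb[f][1] + g.ncy * nb[f][2]);
          double Db = D[b];
          if (Db <= 0) continue;
          faces.push_back({ a, b, 2.0 * Da * Db / (Da + Db) / h2 });
        }
      }
}

void build_ag_faces(const Geo& g, double D_ag, std::vector<Face>& faces) {
  faces.clear();
  double c = D_ag / (g.ha * g.ha);
  for (int k = 0; k < g.naz; ++k)
    for (int j = 0; j < g.nay; ++j)
      for (int i = 0; i < g.nax; ++i) {
        int a = i + g.nax * (j + g.nay * k);
        int bx = wrap(i + 1, g.nax) + g.nax * (j + g.nay * k);
        int by = i + g.nax * (wrap(j + 1, g.nay) + g.nay * k);
        faces.push_back({ a, bx, c });
        faces.push_back({ a, by, c });
        if (k + 1 < g.naz)
          faces.push_back({ a, i + g.nax * (j + g.nay * (k + 1)), c });
      }
}

// interface: agarose top voxel <-> each overlying community bottom voxel
struct IFace { int c, a; double coef; }; // flux density coef (um/hr per um^2)

void build_iface(const Geo& g, const NumericVector& D, double D_ag,
                 std::vector<IFace>& faces) {
  faces.clear();
  double dist = 0.5 * (g.ha + g.hc); // 37.5 um center-to-center
  double area = g.hc * g.hc;
  for (int j = 0; j < g.ncy; ++j)
    for (int i = 0; i < g.ncx; ++i) {
      int c = i + g.ncx * j; // k = 0
      double Dc = D[c];
      if (Dc <= 0) continue; // sealed under air
      int a = (i / 4) + g.nax * ((j / 4) + g.nay * (g.naz - 1));
      double Dh = 2.0 * Dc * D_ag / (Dc + D_ag);
      faces.push_back({ c, a, Dh * area / dist });
    }
}

// active: community voxels touched by any face (others carry no flux)
void diffuse_substeps(NumericVector& Sc, NumericVector& Sa,
                      const std::vector<Face>& fc, const std::vector<Face>& fa,
                      const std::vector<IFace>& fi,
                      const std::vector<int>& active, const Geo& g,
                      double dt, int n_sub,
                      std::vector<double>& dC, std::vector<double>& dA) {
  for (int s = 0; s < n_sub; ++s) {
    for (int v : active) dC[v] = 0.0;
    std::fill(dA.begin(), dA.end(), 0.0);
    for (const Face& f : fc) {
      double q = f.coef * (Sc[f.b] - Sc[f.a]);
      dC[f.a] += q; dC[f.b] -= q;
    }
    for (const Face& f : fa) {
      double q = f.coef * (Sa[f.b] - Sa[f.a]);
      dA[f.a] += q; dA[f.b] -= q;
    }
    for (const IFace& f : fi) {
      double Q = f.coef * (Sa[f.a] - Sc[f.c]); // fmole/hr
      dC[f.c] += Q / g.Vc;
      dA[f.a] -= Q / g.Va;
    }
    for (int v : active) Sc[v] += dt * dC[v];
    for (size_t i = 0; i < dA.size(); ++i) Sa[i] += dt * dA[i];
  }
}

void check_field(const NumericVector& S, const char* name, double t_hr) {
  for (R_xlen_t i = 0; i < S.size(); ++i) {
    if (!R_finite(S[i]) || S[i] < -1e-12)
      stop("numerical instability in field %s at voxel %d (value %g, t = %g hr)",
           name, (int)i + 1, S[i], t_hr);
  }
}

} // namespace

// ---- death ---------------------------------------------------------------

// Binomial deaths at rate*tau per live cell; dying cells flagged (negative
// strain code) and their on-death release accumulated per community voxel.
// [[Rcpp::export]]
IntegerVector cpp_death_step(Environment st) {
  Geo g = read_geo(st);
  Params p = read_par(st);
  IntegerVector strain = st["strain"];
  NumericVector srcA = st["death_src_A"], srcL = st["death_src_L"];
  int nS = p.death_rate.size();
  IntegerVector deaths(nS);
  int kmax = get_kmax(st, g);
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int idx = cidx(g, i, j, k);
        int s = strain[idx];
        if (s <= 0) continue;
        double pr = p.death_rate[s - 1] * p.tau_hr;
        if (pr > 1.0) stop("invalid-config: death probability %g > 1", pr);
        if (pr > 0 && unif_rand() < pr) {
          strain[idx] = -s;
          int v = vox_of_site(g, i, j, k);
          srcA[v] += p.rel_death_A[s - 1];
          srcL[v] += p.rel_death_L[s - 1];
          deaths[s - 1] += 1;
        }
      }
  return deaths;
}

// ---- fields (uptake + release + diffusion) --------------------------------

// Advances all three fields by n_tu physical steps of t_u, each internally
// sub-stepped n_sub times for stability. Per t_u: Michaelis-Menten uptake
// (clamped to remaining quota and to voxel content, shared proportionally to
// unclamped demand), continuous release, death release (the window total in
// death_src_* is spread evenly over the n_tu steps and then cleared),
// then diffusion. Ledgers updated.
// [[Rcpp::export]]
void cpp_step_fields(Environment st, int n_tu) {
  Geo g = read_geo(st);
  Params p = read_par(st);
  IntegerVector strain = st["strain"];
  NumericVector store_req = st["store_req"], store_glc = st["store_glc"];
  NumericVector SA_c = st["SA_c"], SL_c = st["SL_c"], SG_c = st["SG_c"];
  NumericVector SA_a = st["SA_a"], SL_a = st["SL_a"], SG_a = st["SG_a"];
  NumericVector D_c = st["D_c"];
  NumericVector srcA = st["death_src_A"], srcL = st["death_src_L"];
  // clone: R may share identical constants across bindings
  NumericVector led_rel = clone(as<NumericVector>(st["led_rel"]));
  NumericVector led_con = clone(as<NumericVector>(st["led_con"]));
  double t_hr = st["time_hr"];

  int nvox = g.ncx * g.ncy * g.ncz;

  // live-cell list (static within a tau window: divisions happen between)
  std::vector<int> cell_site, cell_vox, cell_strain;
  int kmax = get_kmax(st, g);
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int idx = cidx(g, i, j, k);
        if (strain[idx] > 0) {
          cell_site.push_back(idx);
          cell_vox.push_back(vox_of_site(g, i, j, k));
          cell_strain.push_back(strain[idx]);
        }
      }
  size_t ncell = cell_site.size();

  // continuous release per voxel (fmole/hr)
  std::vector<double> relA(nvox, 0.0), relL(nvox, 0.0);
  double relA_tot = 0.0, relL_tot = 0.0;
  for (size_t c = 0; c < ncell; ++c) {
    int s = cell_strain[c] - 1;
    relA[cell_vox[c]] += p.rel_cont_A[s];
    relL[cell_vox[c]] += p.rel_cont_L[s];
    relA_tot += p.rel_cont_A[s];
    relL_tot += p.rel_cont_L[s];
  }

  std::vector<Face> fc, fa;
  std::vector<IFace> fi;
  build_comm_faces(g, D_c, fc);
  build_ag_faces(g, p.D_ag_hr, fa);
  build_iface(g, D_c, p.D_ag_hr, fi);

  // community voxels touched by flux or by cells (all others stay inert)
  std::vector<char> touched(nvox, 0);
  for (const Face& f : fc) { touched[f.a] = 1; touched[f.b] = 1; }
  for (const IFace& f : fi) touched[f.c] = 1;
  std::vector<int> occ_vox(cell_vox);
  std::sort(occ_vox.begin(), occ_vox.end());
  occ_vox.erase(std::unique(occ_vox.begin(), occ_vox.end()), occ_vox.end());
  for (int v : occ_vox) touched[v] = 1;
  std::vector<int> active;
  for (int v = 0; v < nvox; ++v) if (touched[v]) active.push_back(v);

  std::vector<double> dC(nvox, 0.0), dA(g.nax * g.nay * g.naz);
  std::vector<double> demand(nvox, 0.0), desire(ncell), desire_g(ncell);
  std::vector<double> taken(nvox, 0.0);
  double dt_sub = p.tu_hr / p.n_sub;
  double inv_ntu = 1.0 / n_tu;

  for (int t = 0; t < n_tu; ++t) {
    // -- uptake of the required metabolite (A or L per strain) --
    // pass 1: unclamped-but-quota-limited demand per voxel
    for (int m = 0; m < 2; ++m) { // 0 = A-requirers, 1 = L-requirers
      NumericVector& S = (m == 0) ? SA_c : SL_c;
      for (int v : occ_vox) demand[v] = 0.0;
      for (size_t c = 0; c < ncell; ++c) {
        int s = cell_strain[c] - 1;
        if (p.req_is_A[s] != (m == 0 ? 1 : 0)) { desire[c] = 0.0; continue; }
        // stop-consuming rule at t_u granularity: a cell at quota takes
        // nothing; below quota it takes the full MM amount for this t_u
        // (tiny overshoot <= v t_u carries over after division, keeping
        // division timing continuous rather than tau-quantized)
        if (store_req[cell_site[c]] >= p.quota_req[s] - QUOTA_EPS) {
          desire[c] = 0.0; continue;
        }
        double Sv = S[cell_vox[c]];
        double d = p.vm_req[s] * Sv / (Sv + p.K_req[s]) * p.tu_hr;
        desire[c] = d;
        demand[cell_vox[c]] += d;
      }
      // pass 2: proportional split of available mass, apply
      for (int v : occ_vox) taken[v] = 0.0;
      double con = 0.0;
      for (size_t c = 0; c < ncell; ++c) {
        if (desire[c] <= 0) continue;
        int v = cell_vox[c];
        double avail = S[v] * g.Vc;
        double scale = (demand[v] > avail) ? (avail / demand[v]) : 1.0;
        double u = desire[c] * scale;
        store_req[cell_site[c]] += u;
        taken[v] += u;
        con += u;
      }
      for (int v : occ_vox)
        if (taken[v] > 0) S[v] -= taken[v] / g.Vc;
      led_con[m == 0 ? 0 : 1] += con;
    }
    // -- glucose (all live cells) --
    {
      for (int v : occ_vox) demand[v] = 0.0;
      for (size_t c = 0; c < ncell; ++c) {
        int s = cell_strain[c] - 1;
        if (store_glc[cell_site[c]] >= p.quota_glc[s] - QUOTA_EPS) {
          desire_g[c] = 0.0; continue;
        }
        double Sv = SG_c[cell_vox[c]];
        double d = p.vm_glc[s] * Sv / (Sv + p.K_glc[s]) * p.tu_hr;
        desire_g[c] = d;
        demand[cell_vox[c]] += d;
      }
      for (int v : occ_vox) taken[v] = 0.0;
      double con = 0.0;
      for (size_t c = 0; c < ncell; ++c) {
        if (desire_g[c] <= 0) continue;
        int v = cell_vox[c];
        double avail = SG_c[v] * g.Vc;
        double scale = (demand[v] > avail) ? (avail / demand[v]) : 1.0;
        double u = desire_g[c] * scale;
        store_glc[cell_site[c]] += u;
        taken[v] += u;
        con += u;
      }
      for (int v : occ_vox)
        if (taken[v] > 0) SG_c[v] -= taken[v] / g.Vc;
      led_con[2] += con;
    }

    // -- release: continuous gamma plus this window's death release --
    // (sources only ever sit at voxels holding or having held cells; dead
    // cells still count as occupied sites so occ_vox covers them... death
    // sources were deposited before this window at voxels of dying cells,
    // which remain occupied; scan the full array once per window instead)
    for (int v = 0; v < nvox; ++v) {
      double mA = relA[v] * p.tu_hr + srcA[v] * inv_ntu;
      double mL = relL[v] * p.tu_hr + srcL[v] * inv_ntu;
      if (mA > 0) SA_c[v] += mA / g.Vc;
      if (mL > 0) SL_c[v] += mL / g.Vc;
    }
    led_rel[0] += relA_tot * p.tu_hr;
    led_rel[1] += relL_tot * p.tu_hr;

    // -- diffusion --
    diffuse_substeps(SA_c, SA_a, fc, fa, fi, active, g, dt_sub, p.n_sub, dC, dA);
    diffuse_substeps(SL_c, SL_a, fc, fa, fi, active, g, dt_sub, p.n_sub, dC, dA);
    diffuse_substeps(SG_c, SG_a, fc, fa, fi, active, g, dt_sub, p.n_sub, dC, dA);

    if (p.instant) {
      // released metabolites instantly distributed: replace each field by its
      // volume-weighted mean over the community + agarose domains
      double Vtot = g.Vc * nvox + g.Va * SA_a.size();
      NumericVector* cs[3] = { &SA_c, &SL_c, &SG_c };
      NumericVector* as[3] = { &SA_a, &SL_a, &SG_a };
      for (int f = 0; f < 3; ++f) {
        double mass = 0.0;
        for (R_xlen_t i = 0; i < cs[f]->size(); ++i) mass += (*cs[f])[i] * g.Vc;
        for (R_xlen_t i = 0; i < as[f]->size(); ++i) mass += (*as[f])[i] * g.Va;
        double mean = mass / Vtot;
        std::fill(cs[f]->begin(), cs[f]->end(), mean);
        std::fill(as[f]->begin(), as[f]->end(), mean);
      }
    }
  }

  // death sources for this window fully injected; clear
  double inj_A = 0.0, inj_L = 0.0;
  for (int v = 0; v < nvox; ++v) { inj_A += srcA[v]; inj_L += srcL[v]; }
  led_rel[0] += inj_A;
  led_rel[1] += inj_L;
  std::fill(srcA.begin(), srcA.end(), 0.0);
  std::fill(srcL.begin(), srcL.end(), 0.0);
  st["led_rel"] = led_rel;
  st["led_con"] = led_con;

  check_field(SA_c, "adenine/community", t_hr);
  check_field(SL_c, "lysine/community", t_hr);
  check_field(SG_c, "glucose/community", t_hr);
  check_field(SA_a, "adenine/agarose", t_hr);
  check_field(SL_a, "lysine/agarose", t_hr);
  check_field(SG_a, "glucose/agarose", t_hr);
}

// ---- division & rearrangement --------------------------------------------

namespace {

struct Placement {
  int daughter;            // site index
  std::vector<int> chain;  // pushed sites, in push order (old positions)
  int mode;                // 0 lateral push, 1 bud up, 2 side displaced up
  int top_z;               // highest z index occupied after the event
  bool ok;
};

const int DX[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
const int DY[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };

void move_cell(IntegerVector& strain, NumericVector& sr, NumericVector& sg,
               int from, int to) {
  strain[to] = strain[from];
  sr[to] = sr[from];
  sg[to] = sg[from];
  strain[from] = 0; sr[from] = 0.0; sg[from] = 0.0;
}

// settle a cell downward until supported (budded over an edge -> it falls)
int settle_site(const Geo& g, IntegerVector& strain, NumericVector& sr,
                NumericVector& sg, int x, int y, int z) {
  while (z > 0 && strain[cidx(g, x, y, z - 1)] == 0) {
    move_cell(strain, sr, sg, cidx(g, x, y, z), cidx(g, x, y, z - 1));
    --z;
  }
  return cidx(g, x, y, z);
}

// The rearrangement rule: bud laterally along the shortest straight ray to
// empty space within the enclosure radius, pushing the intervening chain one
// site outward; once enclosed, bud straight up with probability p_up, else
// displace a random lateral neighbor (and its column) upward. Cells moved
// laterally above an unoccupied site settle downward until supported, so
// no cell ever floats.
Placement place_daughter_impl(const Geo& g, const Params& p,
                              IntegerVector& strain, NumericVector& sr,
                              NumericVector& sg, int mx, int my, int mz) {
  Placement out; out.ok = true;
  int best = p.enclosure_radius + 1;
  std::vector<int> tied;
  for (int d = 0; d < 8; ++d) {
    for (int r = 1; r <= p.enclosure_radius; ++r) {
      int x = wrap(mx + r * DX[d], g.nx), y = wrap(my + r * DY[d], g.ny);
      if (strain[cidx(g, x, y, mz)] == 0) {
        if (r < best) { best = r; tied.clear(); tied.push_back(d); }
        else if (r == best) tied.push_back(d);
        break;
      }
    }
  }
  if (!tied.empty()) {
    int d = tied[(int)(unif_rand() * tied.size())];
    // shift chain outward: cells at radii best-1 .. 1 move to best .. 2,
    // then settle outermost-first (a cell pushed over an edge falls)
    for (int r = best; r >= 2; --r) {
      int xf = wrap(mx + (r - 1) * DX[d], g.nx), yf = wrap(my + (r - 1) * DY[d], g.ny);
      int xt = wrap(mx + r * DX[d], g.nx), yt = wrap(my + r * DY[d], g.ny);
      move_cell(strain, sr, sg, cidx(g, xf, yf, mz), cidx(g, xt, yt, mz));
      out.chain.push_back(cidx(g, xf, yf, mz));
    }
    for (int r = best; r >= 2; --r) {
      int xt = wrap(mx + r * DX[d], g.nx), yt = wrap(my + r * DY[d], g.ny);
      if (strain[cidx(g, xt, yt, mz)] != 0)
        settle_site(g, strain, sr, sg, xt, yt, mz);
    }
    int dx1 = wrap(mx + DX[d], g.nx), dy1 = wrap(my + DY[d], g.ny);
    int dz1 = mz;
    while (dz1 > 0 && strain[cidx(g, dx1, dy1, dz1 - 1)] == 0) --dz1;
    out.daughter = cidx(g, dx1, dy1, dz1);
    out.mode = 0;
    out.top_z = mz;
    return out;
  }
  // enclosed: vertical rules
  if (unif_rand() < p.p_up) {
    int top = mz;
    while (top + 1 < g.nz && strain[cidx(g, mx, my, top + 1)] != 0) ++top;
    if (top + 1 >= g.nz) stop("simulation-domain-overflow: z ceiling reached");
    for (int z = top; z > mz; --z) {
      move_cell(strain, sr, sg, cidx(g, mx, my, z), cidx(g, mx, my, z + 1));
      out.chain.push_back(cidx(g, mx, my, z));
    }
    out.daughter = cidx(g, mx, my, mz + 1);
    out.mode = 1;
    out.top_z = top + 1;
  } else {
    int d = (int)(unif_rand() * 8);
    int x = wrap(mx + DX[d], g.nx), y = wrap(my + DY[d], g.ny);
    int top = mz;
    while (top + 1 < g.nz && strain[cidx(g, x, y, top + 1)] != 0) ++top;
    if (top + 1 >= g.nz) stop("simulation-domain-overflow: z ceiling reached");
    for (int z = top; z >= mz; --z) {
      move_cell(strain, sr, sg, cidx(g, x, y, z), cidx(g, x, y, z + 1));
      out.chain.push_back(cidx(g, x, y, z));
    }
    out.daughter = cidx(g, x, y, mz);
    out.mode = 2;
    out.top_z = top + 1;
  }
  return out;
}

} // namespace

// Standalone placement (no store bookkeeping) for unit tests and event logs.
// mother_idx0 is a 0-based site index. Returns 1-based indices.
// [[Rcpp::export]]
List cpp_place_daughter(Environment st, int mother_idx0) {
  Geo g = read_geo(st);
  Params p = read_par(st);
  IntegerVector strain = st["strain"];
  NumericVector sr = st["store_req"], sg = st["store_glc"];
  if (strain[mother_idx0] <= 0) stop("mother site empty or dead");
  int mz = mother_idx0 / (g.nx * g.ny);
  int rem = mother_idx0 % (g.nx * g.ny);
  int my = rem / g.nx, mx = rem % g.nx;
  Placement pl = place_daughter_impl(g, p, strain, sr, sg, mx, my, mz);
  strain[pl.daughter] = strain[mother_idx0];
  sr[pl.daughter] = 0.0; sg[pl.daughter] = 0.0;
  int kmax = get_kmax(st, g);
  if (pl.top_z + 2 > kmax) st["zmax"] = std::min(pl.top_z + 2, g.nz);
  IntegerVector chain(pl.chain.size());
  for (size_t i = 0; i < pl.chain.size(); ++i) chain[i] = pl.chain[i] + 1;
  return List::create(_["daughter"] = pl.daughter + 1, _["chain"] = chain,
                      _["mode"] = pl.mode);
}

// Every live cell whose required-metabolite and glucose quotas are met
// divides exactly once this window; order randomized. Repeated shuffled
// passes catch mothers displaced mid-window by other divisions.
// [[Rcpp::export]]
List cpp_attempt_divisions(Environment st) {
  Geo g = read_geo(st);
  Params p = read_par(st);
  IntegerVector strain = st["strain"];
  NumericVector sr = st["store_req"], sg = st["store_glc"];
  int nS = p.vm_req.size();
  IntegerVector births(nS);
  std::vector<int> ev_mother, ev_daughter, ev_pushed, ev_mode;

  auto eligible = [&](int idx) {
    int s = strain[idx];
    if (s <= 0) return false;
    return sr[idx] >= p.quota_req[s - 1] - QUOTA_EPS &&
           sg[idx] >= p.quota_glc[s - 1] - QUOTA_EPS;
  };

  int kmax = get_kmax(st, g);
  for (int pass = 0; pass < 1000; ++pass) {
    std::vector<int> cand;
    int bound = std::min((R_xlen_t)(g.nx * g.ny * kmax), strain.size());
    for (int idx = 0; idx < bound; ++idx)
      if (eligible(idx)) cand.push_back(idx);
    if (cand.empty()) break;
    // Fisher-Yates shuffle with the R RNG
    for (int i = (int)cand.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(cand[i], cand[j]);
    }
    for (int idx : cand) {
      if (!eligible(idx)) continue; // moved or already divided
      int s = strain[idx];
      int mz = idx / (g.nx * g.ny);
      int rem = idx % (g.nx * g.ny);
      int my = rem / g.nx, mx = rem % g.nx;
      Placement pl = place_daughter_impl(g, p, strain, sr, sg, mx, my, mz);
      strain[pl.daughter] = s;
      sr[pl.daughter] = 0.0; sg[pl.daughter] = 0.0;
      sr[idx] -= p.quota_req[s - 1];
      if (sr[idx] < 0) sr[idx] = 0;
      sg[idx] -= p.quota_glc[s - 1];
      if (sg[idx] < 0) sg[idx] = 0;
      births[s - 1] += 1;
      ev_mother.push_back(idx + 1);
      ev_daughter.push_back(pl.daughter + 1);
      ev_pushed.push_back((int)pl.chain.size());
      ev_mode.push_back(pl.mode);
      if (pl.top_z + 2 > kmax) kmax = std::min(pl.top_z + 2, g.nz);
    }
  }
  st["zmax"] = kmax;
  return List::create(
    _["births"] = births,
    _["events"] = DataFrame::create(
      _["mother"] = wrap(ev_mother), _["daughter"] = wrap(ev_daughter),
      _["n_pushed"] = wrap(ev_pushed), _["mode"] = wrap(ev_mode)));
}

// ---- diffusivity update ---------------------------------------------------

// D in each community voxel is proportional to its occupancy (live or dead,
// out of 27 sites), from 0 to D_max.
// [[Rcpp::export]]
void cpp_update_D(Environment st) {
  Geo g = read_geo(st);
  Params p = read_par(st);
  IntegerVector strain = st["strain"];
  NumericVector D_c = st["D_c"];
  std::fill(D_c.begin(), D_c.end(), 0.0);
  int kmax = get_kmax(st, g);
  for (int k = 0; k < kmax; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        if (strain[cidx(g, i, j, k)] != 0)
          D_c[vox_of_site(g, i, j, k)] += 1.0;
  for (R_xlen_t v = 0; v < D_c.size(); ++v)
    D_c[v] = D_c[v] / 27.0 * p.D_max_hr;
}

// Occupancy fraction per community voxel (live + dead, /27).
// [[Rcpp::export]]
NumericVector cpp_occupancy(Environment st) {
  Geo g = read_geo(st);
  IntegerVector strain = st["strain"];
  NumericVector occ(g.ncx * g.ncy * g.ncz);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        if (strain[cidx(g, i, j, k)] != 0)
          occ[vox_of_site(g, i, j, k)] += 1.0;
  for (R_xlen_t v = 0; v < occ.size(); ++v) occ[v] /= 27.0;
  occ.attr("dim") = IntegerVector::create(g.ncx, g.ncy, g.ncz);
  return occ;
}
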