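// Quadric-error-metric edge-collapse mesh simplification with exact
// face-count enforcement: collapse edges in increasing-error order until the
// face count is <= target, then split longest edges (+2 interior / +1
// boundary) until the count is exactly target. Deterministic: the candidate
// heap is ordered by (cost, vertex ids) and splits scan in index order.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <set>
#include <cmath>
#include <array>

using namespace Rcpp;

typedef std::array<double, 10> Quadric; // symmetric 4x4: aa ab ac ad bb bc bd cc cd dd

static inline void q_add(Quadric &a, const Quadric &b) {
  for (int i = 0; i < 10; ++i) a[i] += b[i];
}

static inline double q_eval(const Quadric &q, double x, double y, double z) {
  return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
       + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
       + q[7]*z*z + 2*q[8]*z + q[9];
}

struct Cand {
  double cost;
  int u, v;
  int uver, vver;
  double px, py, pz;
};

struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;   // min-heap
    if (a.u != b.u) return a.u > b.u;
    return a.v > b.v;
  }
};

struct MeshState {
  std::vector<std::array<double,3> > pos;
  std::vector<std::array<int,3> > fv;
  std::vector<char> falive;
  std::vector<char> valive;
  std::vector<int> vver;
  std::vector<Quadric> Q;
  std::vector<std::vector<int> > vfaces;
  int nfaces_alive;
};

static void face_normal(const MeshState &M, int f,
                        const double *override_pos, int override_v,
                        double *n) {
  double p[3][3];
  for (int k = 0; k < 3; ++k) {
    int vi = M.fv[f][k];
    if (vi == override_v && override_pos) {
      p[k][0] = override_pos[0]; p[k][1] = override_pos[1]; p[k][2] = override_pos[2];
    } else {
      p[k][0] = M.pos[vi][0]; p[k][1] = M.pos[vi][1]; p[k][2] = M.pos[vi][2];
    }
  }
  double ux = p[1][0]-p[0][0], uy = p[1][1]-p[0][1], uz = p[1][2]-p[0][2];
  double vx = p[2][0]-p[0][0], vy = p[2][1]-p[0][1], vz = p[2][2]-p[0][2];
  n[0] = uy*vz - uz*vy;
  n[1] = uz*vx - ux*vz;
  n[2] = ux*vy - uy*vx;
}

// optimal collapse position for quadric q, edge (u, v); returns cost
static double optimal_point(const MeshState &M, const Quadric &q,
                            int u, int v, double *out) {
  double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
  double b[3] = {-q[3], -q[6], -q[8]};
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  double scale = std::fabs(A[0][0]) + std::fabs(A[1][1]) + std::fabs(A[2][2]);
  if (std::fabs(det) > 1e-10 * scale * scale * scale + 1e-300) {
    double x = (b[0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
              - A[0][1]*(b[1]*A[2][2]-A[1][2]*b[2])
              + A[0][2]*(b[1]*A[2][1]-A[1][1]*b[2])) / det;
    double y = (A[0][0]*(b[1]*A[2][2]-A[1][2]*b[2])
              - b[0]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
              + A[0][2]*(A[1][0]*b[2]-b[1]*A[2][0])) / det;
    double z = (A[0][0]*(A[1][1]*b[2]-b[1]*A[2][1])
              - A[0][1]*(A[1][0]*b[2]-b[1]*A[2][0])
              + b[0]*(A[1][0]*A[2][1]-A[1][1]*A[2][0])) / det;
    if (std::isfinite(x) && std::isfinite(y) && std::isfinite(z)) {
      out[0] = x; out[1] = y; out[2] = z;
      return q_eval(q, x, y, z);
    }
  }
  // fallback: best of endpoints and midpoint
  double cand[3][3] = {
    {M.pos[u][0], M.pos[u][1], M.pos[u][2]},
    {M.pos[v][0], M.pos[v][1], M.pos[v][2]},
    {0.5*(M.pos[u][0]+M.pos[v][0]), 0.5*(M.pos[u][1]+M.pos[v][1]),
     0.5*(M.pos[u][2]+M.pos[v][2])}};
  double best = R_PosInf; int bi = 2;
  for (int i = 0; i < 3; ++i) {
    double c = q_eval(q, cand[i][0], cand[i][1], cand[i][2]);
    if (c < best) { best = c; bi = i; }
  }
  out[0] = cand[bi][0]; out[1] = cand[bi][1]; out[2] = cand[bi][2];
  return best;
}

static void push_edge(MeshState &M,
                      std::priority_queue<Cand, std::vector<Cand>, CandCmp> &heap,
                      int u, int v) {
  if (u > v) std::swap(u, v);
  Quadric q = M.Q[u];
  q_add(q, M.Q[v]);
  Cand c;
  c.u = u; c.v = v; c.uver = M.vver[u]; c.vver = M.vver[v];
  double p[3];
  c.cost = optimal_point(M, q, u, v, p);
  c.px = p[0]; c.py = p[1]; c.pz = p[2];
  heap.push(c);
}

static void seed_heap(MeshState &M,
                      std::priority_queue<Cand, std::vector<Cand>, CandCmp> &heap) {
  std::set<std::pair<int,int> > edges;
  for (size_t f = 0; f < M.fv.size(); ++f) {
    if (!M.falive[f]) continue;
    for (int k = 0; k < 3; ++k) {
      int a = M.fv[f][k], b = M.fv[f][(k+1)%3];
      if (a > b) std::swap(a, b);
      edges.insert(std::make_pair(a, b));
    }
  }
  for (std::set<std::pair<int,int> >::iterator it = edges.begin();
       it != edges.end(); ++it)
    push_edge(M, heap, it->first, it->second);
}

// returns true if collapsing (u,v) to p would flip any surviving face normal
static bool would_flip(const MeshState &M, int u, int v, const double *p) {
  const int vs[2] = {u, v};
  for (int s = 0; s < 2; ++s) {
    int w = vs[s];
    for (size_t i = 0; i < M.vfaces[w].size(); ++i) {
      int f = M.vfaces[w][i];
      if (!M.falive[f]) continue;
      bool has_u = false, has_v = false;
      for (int k = 0; k < 3; ++k) {
        if (M.fv[f][k] == u) has_u = true;
        if (M.fv[f][k] == v) has_v = true;
      }
      if (has_u && has_v) continue;     // face disappears
      if (s == 1 && has_u) continue;    // visited from u's list already
      double n0[3], n1[3];
      face_normal(M, f, NULL, -1, n0);
      face_normal(M, f, p, w, n1);
      double l0 = std::sqrt(n0[0]*n0[0]+n0[1]*n0[1]+n0[2]*n0[2]);
      if (l0 < 1e-30) continue;
      double d = n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2];
      if (d <= 0) return true;
    }
  }
  return false;
}

static void compact_vfaces(MeshState &M, int u) {
  std::vector<int> keep;
  keep.reserve(M.vfaces[u].size());
  for (size_t i = 0; i < M.vfaces[u].size(); ++i) {
    int f = M.vfaces[u][i];
    if (!M.falive[f]) continue;
    bool dup = false;
    for (size_t j = 0; j < keep.size(); ++j)
      if (keep[j] == f) { dup = true; break; }
    if (!dup) keep.push_back(f);
  }
  M.vfaces[u].swap(keep);
}

static void run_collapses(MeshState &M, int target, bool check_flip) {
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> heap;
  seed_heap(M, heap);
  while (M.nfaces_alive > target && !heap.empty()) {
    Cand c = heap.top(); heap.pop();
    int u = c.u, v = c.v;
    if (!M.valive[u] || !M.valive[v]) continue;
    if (M.vver[u] != c.uver || M.vver[v] != c.vver) continue;
    // edge must still be spanned by an alive face
    bool connected = false;
    for (size_t i = 0; i < M.vfaces[u].size() && !connected; ++i) {
      int f = M.vfaces[u][i];
      if (!M.falive[f]) continue;
      for (int k = 0; k < 3; ++k)
        if (M.fv[f][k] == v) { connected = true; break; }
    }
    if (!connected) continue;
    double p[3] = {c.px, c.py, c.pz};
    if (check_flip && would_flip(M, u, v, p)) continue;

    // collapse v into u at p
    M.pos[u][0] = p[0]; M.pos[u][1] = p[1]; M.pos[u][2] = p[2];
    q_add(M.Q[u], M.Q[v]);
    for (size_t i = 0; i < M.vfaces[v].size(); ++i) {
      int f = M.vfaces[v][i];
      if (!M.falive[f]) continue;
      bool has_u = false;
      for (int k = 0; k < 3; ++k) if (M.fv[f][k] == u) has_u = true;
      if (has_u) {
        M.falive[f] = 0;
        --M.nfaces_alive;
      } else {
        for (int k = 0; k < 3; ++k) if (M.fv[f][k] == v) M.fv[f][k] = u;
        M.vfaces[u].push_back(f);
      }
    }
    M.valive[v] = 0;
    ++M.vver[u]; ++M.vver[v];
    compact_vfaces(M, u);
    // re-seed candidate edges around u
    std::set<int> nbrs;
    for (size_t i = 0; i < M.vfaces[u].size(); ++i) {
      int f = M.vfaces[u][i];
      for (int k = 0; k < 3; ++k)
        if (M.fv[f][k] != u) nbrs.insert(M.fv[f][k]);
    }
    for (std::set<int>::iterator it = nbrs.begin(); it != nbrs.end(); ++it)
      push_edge(M, heap, u, *it);
  }
}

// split the longest edge; boundary_only restricts to edges with exactly one
// incident face (+1 face); otherwise interior edges (+2) are preferred.
// Returns faces added (0 on failure).
static int split_longest_edge(MeshState &M, bool boundary_only) {
  std::map<std::pair<int,int>, std::vector<int> > emap;
  for (size_t f = 0; f < M.fv.size(); ++f) {
    if (!M.falive[f]) continue;
    for (int k = 0; k < 3; ++k) {
      int a = M.fv[f][k], b = M.fv[f][(k+1)%3];
      if (a > b) std::swap(a, b);
      emap[std::make_pair(a, b)].push_back((int)f);
    }
  }
  std::pair<int,int> best(-1, -1);
  double best_len = -1.0;
  for (std::map<std::pair<int,int>, std::vector<int> >::iterator it =
         emap.begin(); it != emap.end(); ++it) {
    size_t deg = it->second.size();
    if (boundary_only && deg != 1) continue;
    int a = it->first.first, b = it->first.second;
    double dx = M.pos[a][0]-M.pos[b][0], dy = M.pos[a][1]-M.pos[b][1],
           dz = M.pos[a][2]-M.pos[b][2];
    double len = dx*dx + dy*dy + dz*dz;
    if (len > best_len) { best_len = len; best = it->first; }
  }
  if (best.first < 0) return 0;
  int u = best.first, v = best.second;
  std::array<double,3> mid;
  for (int k = 0; k < 3; ++k) mid[k] = 0.5*(M.pos[u][k] + M.pos[v][k]);
  int w = (int)M.pos.size();
  M.pos.push_back(mid);
  M.valive.push_back(1);
  M.vver.push_back(0);
  M.Q.push_back(M.Q[u]);
  M.vfaces.push_back(std::vector<int>());
  const std::vector<int> &facelist = emap[best];
  int added = 0;
  for (size_t i = 0; i < facelist.size(); ++i) {
    int f = facelist[i];
    std::array<int,3> nf = M.fv[f];
    for (int k = 0; k < 3; ++k) if (M.fv[f][k] == v) M.fv[f][k] = w; // (u,w,x)
    for (int k = 0; k < 3; ++k) if (nf[k] == u) nf[k] = w;           // (w,v,x)
    M.fv.push_back(nf);
    M.falive.push_back(1);
    int f2 = (int)M.fv.size() - 1;
    M.vfaces[w].push_back(f);
    M.vfaces[w].push_back(f2);
    M.vfaces[v].push_back(f2);
    ++M.nfaces_alive;
    ++added;
  }
  return added;
}

// [[Rcpp::export]]
List qem_decimate(NumericMatrix V, IntegerMatrix F, int target) {
  int nv = V.nrow(), nf = F.nrow();
  if (target < 1) stop("target face count must be positive");
  if (nf < target) stop("mesh has fewer faces than the target");

  MeshState M;
  M.pos.resize(nv);
  for (int i = 0; i < nv; ++i) {
    M.pos[i][0] = V(i, 0); M.pos[i][1] = V(i, 1); M.pos[i][2] = V(i, 2);
  }
  M.fv.resize(nf);
  M.falive.assign(nf, 1);
  M.valive.assign(nv, 1);
  M.vver.assign(nv, 0);
  M.vfaces.resize(nv);
  M.nfaces_alive = nf;
  Quadric zq; zq.fill(0.0);
  M.Q.assign(nv, zq);

  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      M.fv[f][k] = F(f, k);                // already 0-based from R wrapper
      M.vfaces[M.fv[f][k]].push_back(f);
    }
    // area-weighted plane quadric
    double n[3];
    face_normal(M, f, NULL, -1, n);
    double a2 = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]); // 2*area
    if (a2 < 1e-30) continue;
    double nx = n[0]/a2, ny = n[1]/a2, nz = n[2]/a2;
    const std::array<double,3> &p0 = M.pos[M.fv[f][0]];
    double d = -(nx*p0[0] + ny*p0[1] + nz*p0[2]);
    double w = 0.5 * a2; // face area
    Quadric q = {w*nx*nx, w*nx*ny, w*nx*nz, w*nx*d,
                 w*ny*ny, w*ny*nz, w*ny*d,
                 w*nz*nz, w*nz*d, w*d*d};
    for (int k = 0; k < 3; ++k) q_add(M.Q[M.fv[f][k]], q);
  }

  run_collapses(M, target, true);
  if (M.nfaces_alive > target)   // flip guard exhausted the heap: relax it
    run_collapses(M, target, false);
  if (M.nfaces_alive > target)
    stop("decimation stalled above the target face count");

  int guard = 0;
  while (M.nfaces_alive < target) {
    int deficit = target - M.nfaces_alive;
    int added = 0;
    if (deficit == 1) {
      added = split_longest_edge(M, true);
      if (added == 0)
        stop("cannot reach the requested face count exactly: the surface is "
             "closed (even face count forced) and the target is off by one");
    } else {
      added = split_longest_edge(M, false);
      if (added == 0) stop("edge split failed during exact-count adjustment");
      if (M.nfaces_alive > target) stop("exact-count adjustment overshot");
    }
    if (++guard > target + 16) stop("exact-count adjustment did not converge");
  }

  // compact output
  std::vector<int> vmap(M.pos.size(), -1);
  int nv_out = 0;
  for (size_t f = 0; f < M.fv.size(); ++f) {
    if (!M.falive[f]) continue;
    for (int k = 0; k < 3; ++k)
      if (vmap[M.fv[f][k]] < 0) vmap[M.fv[f][k]] = nv_out++;
  }
  NumericMatrix Vout(nv_out, 3);
  for (size_t i = 0; i < vmap.size(); ++i)
    if (vmap[i] >= 0)
      for (int k = 0; k < 3; ++k) Vout(vmap[i], k) = M.pos[i][k];
  IntegerMatrix Fout(M.nfaces_alive, 3);
  int fi = 0;
  for (size_t f = 0; f < M.fv.size(); ++f) {
    if (!M.falive[f]) continue;
    for (int k = 0; k < 3; ++k) Fout(fi, k) = vmap[M.fv[f][k]];
    ++fi;
  }
  return List::create(Named("vertices") = Vout, Named("faces") = Fout);
}
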