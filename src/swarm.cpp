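// 2D stochastic agent-based model of M. xanthus cells as three-node bendable
// rods on a periodic square domain. Each step a motile cell may reverse
// polarity, picks a direction from a weighted sum of A-motility (long axis),
// S-motility (alignment with forward neighbours), slime-trail memory and
// noise, advances its head at constant speed, and relaxes its trailing nodes
// by Metropolis sampling of the harmonic bending/stretching energy with
// capsule collision tests against other cells and spores. Aligned (<30 deg)
// end-to-end contacts increment C-signal counters; at the threshold a cell
// freezes into a circular spore obstacle.
//
// Randomness comes from R's RNG (reproducible via set.seed()).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Cfg {
  double domain;
  double l0, width, speed, dt;
  double kb, ks;
  double wA, wS, wT, wN;
  double revMean, revSd;
  double cosAlign;       // cos(alignment_angle_max)
  int threshold;
  double contactDist, sporeR, temp;
  double slimeRes, slimeDecay, slimeSense;
  int budget;
  double propSd;
  double senseLen;       // S-motility sensing radius (one cell length)
  int nslime;            // slime grid cells per side
  int nbin;              // hash bins per side
  double binSize;
};

Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.domain = as<double>(cfg["domain"]);
  c.l0 = as<double>(cfg["l0"]);
  c.width = as<double>(cfg["width"]);
  c.speed = as<double>(cfg["speed"]);
  c.dt = as<double>(cfg["dt"]);
  c.kb = as<double>(cfg["kb"]);
  c.ks = as<double>(cfg["ks"]);
  c.wA = as<double>(cfg["wA"]);
  c.wS = as<double>(cfg["wS"]);
  c.wT = as<double>(cfg["wT"]);
  c.wN = as<double>(cfg["wN"]);
  c.revMean = as<double>(cfg["revMean"]);
  c.revSd = as<double>(cfg["revSd"]);
  double deg = as<double>(cfg["alignMaxDeg"]);
  c.cosAlign = std::cos(deg * M_PI / 180.0);
  c.threshold = as<int>(cfg["threshold"]);
  c.contactDist = as<double>(cfg["contactDist"]);
  c.sporeR = as<double>(cfg["sporeRadius"]);
  c.temp = as<double>(cfg["temperature"]);
  c.slimeRes = as<double>(cfg["slimeRes"]);
  double hl = as<double>(cfg["slimeHalfLife"]);
  c.slimeDecay = (hl > 0) ? std::exp(-M_LN2 * c.dt / hl) : 0.0;
  c.slimeSense = as<double>(cfg["slimeSense"]);
  c.budget = as<int>(cfg["proposalBudget"]);
  c.propSd = as<double>(cfg["proposalSd"]);
  c.senseLen = 2.0 * c.l0;
  c.nslime = std::max(1, (int)std::lround(c.domain / c.slimeRes));
  c.binSize = 3.0 * c.l0;
  c.nbin = std::max(1, (int)std::floor(c.domain / c.binSize));
  c.binSize = c.domain / c.nbin;
  return c;
}

inline double wrap0(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;
  if (y < 0) y = 0;
  return y;
}
inline double mi(double d, double L) { return d - L * std::nearbyint(d / L); }

struct Vec {
  double x, y;
};
inline Vec operator-(Vec a, Vec b) { return {a.x - b.x, a.y - b.y}; }
inline Vec operator+(Vec a, Vec b) { return {a.x + b.x, a.y + b.y}; }
inline Vec operator*(double s, Vec a) { return {s * a.x, s * a.y}; }
inline double dot(Vec a, Vec b) { return a.x * b.x + a.y * b.y; }
inline double cross(Vec a, Vec b) { return a.x * b.y - a.y * b.x; }
inline double norm(Vec a) { return std::sqrt(dot(a, a)); }
inline Vec unit(Vec a) {
  double n = norm(a);
  if (n < 1e-12) return {0.0, 0.0};
  return {a.x / n, a.y / n};
}

double pt_seg_dist(Vec p, Vec a, Vec b) {
  Vec ab = b - a;
  double L2 = dot(ab, ab);
  double t = (L2 > 0) ? dot(p - a, ab) / L2 : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  Vec q = a + t * ab;
  return norm(p - q);
}

double seg_seg_dist(Vec a0, Vec a1, Vec b0, Vec b1) {
  // check for proper intersection
  Vec r = a1 - a0, s = b1 - b0;
  double rxs = cross(r, s);
  Vec qp = b0 - a0;
  if (std::fabs(rxs) > 1e-14) {
    double t = cross(qp, s) / rxs;
    double u = cross(qp, r) / rxs;
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1) return 0.0;
  }
  double d = pt_seg_dist(a0, b0, b1);
  d = std::min(d, pt_seg_dist(a1, b0, b1));
  d = std::min(d, pt_seg_dist(b0, a0, a1));
  d = std::min(d, pt_seg_dist(b1, a0, a1));
  return d;
}

double elastic_H(Vec n0, Vec n1, Vec n2, double kb, double ks, double l0) {
  Vec s1 = n1 - n0, s2 = n2 - n1;
  double l1 = norm(s1), l2 = norm(s2);
  double theta = std::atan2(std::fabs(cross(s1, s2)), dot(s1, s2));
  return 0.5 * kb * theta * theta +
         0.5 * ks * ((l1 - l0) * (l1 - l0) + (l2 - l0) * (l2 - l0));
}

double draw_trunc_norm(double mean, double sd) {
  double x;
  do {
    x = mean + sd * norm_rand();
  } while (x <= 0.0);
  return x;
}

struct Swarm {
  int n;
  // node k of cell i at (X[3i+k], Y[3i+k]); node1 is the middle node
  std::vector<double> X, Y;
  std::vector<char> head0;  // node0 is the head
  std::vector<int> counter;
  std::vector<char> spore;
  std::vector<double> nextRev;
  // slime grid (column-major nslime^2); trail memory is nematic: deposits
  // accumulate angle-doubled components (cos 2phi, sin 2phi) so opposing
  // traffic on the same trail reinforces rather than cancels the axis
  std::vector<double> sc2, ss2, sw;
  long steps;
  Cfg c;

  // spatial hash over midpoints
  std::vector<std::vector<int> > bins;
  std::vector<int> binOf;

  Vec node(int i, int k) const { return {X[3 * i + k], Y[3 * i + k]}; }
  void setNode(int i, int k, Vec v) {
    X[3 * i + k] = v.x;
    Y[3 * i + k] = v.y;
  }
  Vec headNode(int i) const { return node(i, head0[i] ? 0 : 2); }
  Vec tailNode(int i) const { return node(i, head0[i] ? 2 : 0); }
  int headIdx(int i) const { return head0[i] ? 0 : 2; }
  int tailIdx(int i) const { return head0[i] ? 2 : 0; }
  Vec axisHat(int i) const { return unit(headNode(i) - tailNode(i)); }

  int binIndex(double x, double y) const {
    int bx = (int)(wrap0(x, c.domain) / c.binSize);
    int by = (int)(wrap0(y, c.domain) / c.binSize);
    if (bx >= c.nbin) bx = c.nbin - 1;
    if (by >= c.nbin) by = c.nbin - 1;
    return bx + c.nbin * by;
  }
  void buildHash() {
    bins.assign(c.nbin * c.nbin, std::vector<int>());
    binOf.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int b = binIndex(X[3 * i + 1], Y[3 * i + 1]);
      binOf[i] = b;
      bins[b].push_back(i);
    }
  }
  void rehash(int i) {
    int b = binIndex(X[3 * i + 1], Y[3 * i + 1]);
    if (b == binOf[i]) return;
    std::vector<int>& old = bins[binOf[i]];
    for (size_t k = 0; k < old.size(); ++k)
      if (old[k] == i) {
        old[k] = old.back();
        old.pop_back();
        break;
      }
    bins[b].push_back(i);
    binOf[i] = b;
  }
  // collect cells in the 3x3 bin neighbourhood of (x,y), excluding `self`
  void neighbours(double x, double y, int self, std::vector<int>& out) const {
    out.clear();
    int bx = (int)(wrap0(x, c.domain) / c.binSize);
    int by = (int)(wrap0(y, c.domain) / c.binSize);
    if (bx >= c.nbin) bx = c.nbin - 1;
    if (by >= c.nbin) by = c.nbin - 1;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int qx = (bx + dx + c.nbin) % c.nbin;
        int qy = (by + dy + c.nbin) % c.nbin;
        const std::vector<int>& b = bins[qx + c.nbin * qy];
        for (size_t k = 0; k < b.size(); ++k)
          if (b[k] != self) out.push_back(b[k]);
      }
    if (c.nbin <= 3) {
      // bins may repeat after wrapping: deduplicate
      std::sort(out.begin(), out.end());
      out.erase(std::unique(out.begin(), out.end()), out.end());
    }
  }

  // shift cell j's nodes into i's local (minimum-image) frame
  void localNodes(Vec refMid, int j, Vec out[3]) const {
    Vec mj = node(j, 1);
    double ox = mi(mj.x - refMid.x, c.domain) - (mj.x - refMid.x);
    double oy = mi(mj.y - refMid.y, c.domain) - (mj.y - refMid.y);
    for (int k = 0; k < 3; ++k) {
      Vec nk = node(j, k);
      out[k] = {nk.x + ox, nk.y + oy};
    }
  }

  // min distance from a 3-node body (given explicitly) to cell/spore j
  double bodyDist(const Vec nd[3], Vec refMid, int j) const {
    Vec oj[3];
    localNodes(refMid, j, oj);
    if (spore[j]) {
      double d = pt_seg_dist(oj[1], nd[0], nd[1]);
      d = std::min(d, pt_seg_dist(oj[1], nd[1], nd[2]));
      return d;
    }
    double d = seg_seg_dist(nd[0], nd[1], oj[0], oj[1]);
    d = std::min(d, seg_seg_dist(nd[0], nd[1], oj[1], oj[2]));
    d = std::min(d, seg_seg_dist(nd[1], nd[2], oj[0], oj[1]));
    d = std::min(d, seg_seg_dist(nd[1], nd[2], oj[1], oj[2]));
    return d;
  }

  int slimeCell(double x, double y) const {
    int gx = (int)(wrap0(x, c.domain) / c.slimeRes);
    int gy = (int)(wrap0(y, c.domain) / c.slimeRes);
    if (gx >= c.nslime) gx = c.nslime - 1;
    if (gy >= c.nslime) gy = c.nslime - 1;
    return gx + c.nslime * gy;
  }

  // axis of the accumulated nematic trail memory near p (zero if none)
  Vec slimeAxisAt(Vec p) const {
    int gx = (int)(wrap0(p.x, c.domain) / c.slimeRes);
    int gy = (int)(wrap0(p.y, c.domain) / c.slimeRes);
    double a2 = 0.0, b2 = 0.0;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int qx = (gx + dx + c.nslime) % c.nslime;
        int qy = (gy + dy + c.nslime) % c.nslime;
        int g = qx + c.nslime * qy;
        a2 += sc2[g];
        b2 += ss2[g];
      }
    double mag = std::sqrt(a2 * a2 + b2 * b2);
    if (mag < 1e-12) return {0.0, 0.0};
    double phi = 0.5 * std::atan2(b2, a2);
    return {std::cos(phi), std::sin(phi)};
  }

  void depositSlime(int i) {
    Vec a = axisHat(i);
    if (norm(a) < 1e-12) return;
    double c2 = a.x * a.x - a.y * a.y;
    double s2 = 2.0 * a.x * a.y;
    double spacing = 0.5 * c.slimeRes;
    for (int seg = 0; seg < 2; ++seg) {
      Vec p0 = node(i, seg), p1 = node(i, seg + 1);
      double len = norm(p1 - p0);
      int ns = std::max(1, (int)std::ceil(len / spacing));
      for (int k = 0; k <= ns; ++k) {
        double t = (double)k / ns;
        Vec p = p0 + t * (p1 - p0);
        int g = slimeCell(p.x, p.y);
        sc2[g] += c2;
        ss2[g] += s2;
        sw[g] += 1.0;
      }
    }
  }

  Vec computeDirection(int i) {
    Vec a = axisHat(i);
    Vec h = headNode(i);
    Vec d = c.wA * a;
    if (c.wS > 0) {
      Vec center = h + (0.5 * c.senseLen) * a;
      Vec s = {0.0, 0.0};
      std::vector<int> nb;
      neighbours(center.x, center.y, i, nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (spore[j]) continue;
        Vec oj[3];
        localNodes(center, j, oj);
        bool in = false;
        for (int m = 0; m < 3 && !in; ++m) {
          Vec rel = oj[m] - h;
          if (norm(oj[m] - center) <= c.senseLen && dot(rel, a) > 0) in = true;
        }
        if (!in) continue;
        Vec u = axisHat(j);
        if (dot(u, a) < 0) u = (-1.0) * u;
        s = s + u;
      }
      d = d + c.wS * unit(s);
    }
    if (c.wT > 0) {
      Vec t = slimeAxisAt(h);
      if (norm(t) > 1e-12) {
        t = unit(t);
        if (dot(t, a) < 0) t = (-1.0) * t;
        d = d + c.wT * t;
      }
    }
    if (c.wN > 0) {
      double ang = 2.0 * M_PI * unif_rand();
      Vec e = {std::cos(ang), std::sin(ang)};
      d = d + c.wN * e;
    }
    if (norm(d) < 1e-9) return a;
    return unit(d);
  }

  // Move head of cell i along d, then Metropolis-relax the trailing nodes.
  // Returns true if the move was committed, false if the cell stalled.
  bool moveCell(int i, Vec d) {
    int hi = headIdx(i), ti = tailIdx(i);
    Vec oldNodes[3] = {node(i, 0), node(i, 1), node(i, 2)};
    Vec mid = oldNodes[1];
    Vec newHead = node(i, hi) + (c.speed * c.dt) * d;

    std::vector<int> nb;
    neighbours(mid.x, mid.y, i, nb);
    // baseline distances from the existing configuration
    std::vector<double> dcur(nb.size());
    for (size_t k = 0; k < nb.size(); ++k)
      dcur[k] = bodyDist(oldNodes, mid, nb[k]);

    Vec curCfg[3] = {oldNodes[0], oldNodes[1], oldNodes[2]};
    curCfg[hi] = newHead;
    double Hcur = elastic_H(curCfg[0], curCfg[1], curCfg[2], c.kb, c.ks, c.l0);

    for (int p = 0; p < c.budget; ++p) {
      Vec cmid, ctail;
      if (p == 0) {
        // deterministic follow-the-leader relaxation to rest geometry
        Vec u1 = unit(newHead - oldNodes[1]);
        if (norm(u1) < 1e-12) u1 = axisHat(i);
        cmid = newHead - c.l0 * u1;
        Vec u2 = unit(cmid - oldNodes[ti]);
        if (norm(u2) < 1e-12) u2 = u1;
        ctail = cmid - c.l0 * u2;
      } else {
        cmid = {oldNodes[1].x + c.propSd * norm_rand(),
                oldNodes[1].y + c.propSd * norm_rand()};
        ctail = {oldNodes[ti].x + c.propSd * norm_rand(),
                 oldNodes[ti].y + c.propSd * norm_rand()};
      }
      Vec cand[3];
      cand[hi] = newHead;
      cand[1] = cmid;
      cand[ti] = ctail;
      double Hc = elastic_H(cand[0], cand[1], cand[2], c.kb, c.ks, c.l0);
      double dH = Hc - Hcur;
      if (dH > 0) {
        double acc = (c.temp > 0) ? std::exp(-dH / c.temp) : 0.0;
        if (unif_rand() >= acc) continue;
      }
      bool collide = false;
      for (size_t k = 0; k < nb.size() && !collide; ++k) {
        int j = nb[k];
        double lim = spore[j] ? (0.5 * c.width + c.sporeR) : c.width;
        double dc = bodyDist(cand, mid, j);
        if (dc < lim && dc < dcur[k] - 1e-9) collide = true;
      }
      if (collide) continue;
      setNode(i, hi, cand[hi]);
      setNode(i, 1, cand[1]);
      setNode(i, ti, cand[ti]);
      rehash(i);
      return true;
    }
    return false;  // stall: head displacement reverted (nodes untouched)
  }

  void maybeReverse(int i, double now, std::vector<double>& revTimes,
                    std::vector<int>& revCells) {
    while (nextRev[i] <= now) {
      head0[i] = !head0[i];
      revTimes.push_back(nextRev[i]);
      revCells.push_back(i + 1);
      nextRev[i] += draw_trunc_norm(c.revMean, c.revSd);
    }
  }

  void detectContacts(std::vector<int>& pi, std::vector<int>& pj) {
    pi.clear();
    pj.clear();
    std::vector<int> nb;
    for (int i = 0; i < n; ++i) {
      if (spore[i]) continue;
      Vec mid = node(i, 1);
      Vec ai = axisHat(i);
      neighbours(mid.x, mid.y, i, nb);
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (j <= i || spore[j]) continue;
        Vec aj = axisHat(j);
        if (std::fabs(dot(ai, aj)) <= c.cosAlign) continue;  // angle >= 30 deg
        Vec oj[3];
        localNodes(mid, j, oj);
        double midDist = norm(oj[1] - mid);
        if (midDist <= c.l0) continue;  // lateral overlap: no signal
        double dmin = 1e300;
        for (int a = 0; a <= 2; a += 2)
          for (int b = 0; b <= 2; b += 2)
            dmin = std::min(dmin, norm(node(i, a) - oj[b]));
        if (dmin <= c.contactDist) {
          pi.push_back(i);
          pj.push_back(j);
        }
      }
    }
  }

  void applySignals(const std::vector<int>& pi, const std::vector<int>& pj,
                    std::vector<int>& convCell, std::vector<int>& convStep,
                    std::vector<double>& convX, std::vector<double>& convY) {
    for (size_t k = 0; k < pi.size(); ++k) {
      counter[pi[k]]++;
      counter[pj[k]]++;
    }
    for (int i = 0; i < n; ++i) {
      if (!spore[i] && counter[i] >= c.threshold) {
        Vec m = node(i, 1);
        setNode(i, 0, m);
        setNode(i, 2, m);
        spore[i] = 1;
        convCell.push_back(i + 1);
        convStep.push_back((int)steps + 1);
        convX.push_back(wrap0(m.x, c.domain));
        convY.push_back(wrap0(m.y, c.domain));
      }
    }
  }

  void decaySlime() {
    for (size_t g = 0; g < sw.size(); ++g) {
      sc2[g] *= c.slimeDecay;
      ss2[g] *= c.slimeDecay;
      sw[g] *= c.slimeDecay;
    }
  }
};

void parse_state(const List& state, const Cfg& c, Swarm& s) {
  NumericMatrix nodes = state["nodes"];
  s.n = nodes.nrow();
  s.c = c;
  s.X.resize(3 * s.n);
  s.Y.resize(3 * s.n);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) {
      s.X[3 * i + k] = nodes(i, 2 * k);
      s.Y[3 * i + k] = nodes(i, 2 * k + 1);
    }
  LogicalVector h0 = state["head0"];
  LogicalVector sp = state["spore"];
  IntegerVector ct = state["counter"];
  NumericVector nr = state["nextRev"];
  s.head0.resize(s.n);
  s.spore.resize(s.n);
  s.counter.resize(s.n);
  s.nextRev.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.head0[i] = h0[i] ? 1 : 0;
    s.spore[i] = sp[i] ? 1 : 0;
    s.counter[i] = ct[i];
    s.nextRev[i] = nr[i];
  }
  s.steps = as<double>(state["steps"]);
  int ng = c.nslime * c.nslime;
  s.sc2.assign(ng, 0.0);
  s.ss2.assign(ng, 0.0);
  s.sw.assign(ng, 0.0);
  if (state.containsElementNamed("slime") &&
      !Rf_isNull(state["slime"])) {
    List sl = state["slime"];
    if (!sl.containsElementNamed("c2")) return s.buildHash();
    NumericVector c2 = sl["c2"], s2 = sl["s2"], w = sl["w"];
    if (c2.size() == ng)
      for (int g = 0; g < ng; ++g) {
        s.sc2[g] = c2[g];
        s.ss2[g] = s2[g];
        s.sw[g] = w[g];
      }
  }
  s.buildHash();
}

List export_state(const Swarm& s) {
  NumericMatrix nodes(s.n, 6);
  for (int i = 0; i < s.n; ++i) {
    // wrap the middle node into the domain, shift end nodes coherently
    double ox = wrap0(s.X[3 * i + 1], s.c.domain) - s.X[3 * i + 1];
    double oy = wrap0(s.Y[3 * i + 1], s.c.domain) - s.Y[3 * i + 1];
    for (int k = 0; k < 3; ++k) {
      nodes(i, 2 * k) = s.X[3 * i + k] + ox;
      nodes(i, 2 * k + 1) = s.Y[3 * i + k] + oy;
    }
  }
  LogicalVector h0(s.n), sp(s.n);
  IntegerVector ct(s.n);
  NumericVector nr(s.n);
  for (int i = 0; i < s.n; ++i) {
    h0[i] = s.head0[i] != 0;
    sp[i] = s.spore[i] != 0;
    ct[i] = s.counter[i];
    nr[i] = s.nextRev[i];
  }
  int ng = s.c.nslime * s.c.nslime;
  NumericVector c2(ng), s2(ng), w(ng);
  for (int g = 0; g < ng; ++g) {
    c2[g] = s.sc2[g];
    s2[g] = s.ss2[g];
    w[g] = s.sw[g];
  }
  return List::create(
      _["nodes"] = nodes, _["head0"] = h0, _["spore"] = sp, _["counter"] = ct,
      _["nextRev"] = nr, _["steps"] = (double)s.steps,
      _["slime"] = List::create(_["c2"] = c2, _["s2"] = s2, _["w"] = w));
}

}  // namespace

// [[Rcpp::export(name = ".swarm_run_cpp")]]
List swarm_run_cpp(List state, List cfg, int nSteps, int snapshotEvery,
                   int stopSpores) {
  RNGScope scope;
  Cfg c = parse_cfg(cfg);
  Swarm s;
  parse_state(state, c, s);

  std::vector<double> revTimes;
  std::vector<int> revCells;
  std::vector<int> convCell, convStep;
  std::vector<double> convX, convY;
  List snapshots;
  std::vector<int> order(s.n);
  for (int i = 0; i < s.n; ++i) order[i] = i;
  std::vector<int> pi, pj;

  int stepsRun = 0;
  for (int st = 0; st < nSteps; ++st) {
    double now = (double)s.steps * c.dt;
    // shuffle update order
    for (int k = s.n - 1; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(order[k], order[j]);
    }
    for (int k = 0; k < s.n; ++k) {
      int i = order[k];
      if (s.spore[i]) continue;
      s.maybeReverse(i, now, revTimes, revCells);
      Vec d = s.computeDirection(i);
      s.moveCell(i, d);
      s.depositSlime(i);
    }
    s.detectContacts(pi, pj);
    s.applySignals(pi, pj, convCell, convStep, convX, convY);
    s.decaySlime();
    s.steps++;
    stepsRun++;
    if (snapshotEvery > 0 && (s.steps % snapshotEvery == 0)) {
      List snap = export_state(s);
      snapshots.push_back(List::create(_["step"] = (double)s.steps,
                                       _["nodes"] = snap["nodes"],
                                       _["head0"] = snap["head0"],
                                       _["spore"] = snap["spore"],
                                       _["counter"] = snap["counter"]));
    }
    if (stopSpores > 0) {
      int tot = 0;
      for (int i = 0; i < s.n; ++i) tot += s.spore[i] ? 1 : 0;
      if (tot >= stopSpores) break;
    }
    if (st % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["state"] = export_state(s), _["stepsRun"] = stepsRun,
      _["reversalTimes"] = NumericVector(revTimes.begin(), revTimes.end()),
      _["reversalCells"] = IntegerVector(revCells.begin(), revCells.end()),
      _["convCell"] = IntegerVector(convCell.begin(), convCell.end()),
      _["convStep"] = IntegerVector(convStep.begin(), convStep.end()),
      _["convX"] = NumericVector(convX.begin(), convX.end()),
      _["convY"] = NumericVector(convY.begin(), convY.end()),
      _["snapshots"] = snapshots);
}

// [[Rcpp::export(name = ".swarm_energy_cpp")]]
double swarm_energy_cpp(NumericMatrix nodes, double kb, double ks, double l0) {
  if (nodes.nrow() != 3 || nodes.ncol() != 2)
    stop("`nodes` must be a 3x2 matrix");
  Vec n0 = {nodes(0, 0), nodes(0, 1)};
  Vec n1 = {nodes(1, 0), nodes(1, 1)};
  Vec n2 = {nodes(2, 0), nodes(2, 1)};
  if (norm(n1 - n0) < 1e-12 || norm(n2 - n1) < 1e-12)
    stop("degenerate (zero-length) segment");
  return elastic_H(n0, n1, n2, kb, ks, l0);
}

// [[Rcpp::export(name = ".swarm_contacts_cpp")]]
IntegerMatrix swarm_contacts_cpp(List state, List cfg) {
  Cfg c = parse_cfg(cfg);
  Swarm s;
  parse_state(state, c, s);
  std::vector<int> pi, pj;
  s.detectContacts(pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k] + 1;
    out(k, 1) = pj[k] + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".swarm_direction_cpp")]]
NumericVector swarm_direction_cpp(List state, List cfg, int i) {
  RNGScope scope;
  Cfg c = parse_cfg(cfg);
  Swarm s;
  parse_state(state, c, s);
  if (i < 1 || i > s.n) stop("cell index out of range");
  Vec d = s.computeDirection(i - 1);
  return NumericVector::create(d.x, d.y);
}
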