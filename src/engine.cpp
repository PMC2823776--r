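// Discrete-tick agent-based engine for the endotoxin inflammation model.
//
// The world is a toroidal patch grid holding composite macrophages (membrane
// ring, nucleus, embedded receptors, intracellular NF-kB/IkBa/IKK agents),
// T-helper cells, and mobile molecule agents (LPS, TNF-a, IL-12, IL-4,
// IKK-inhibitor).  One call to tick() advances the world by one tick through a
// fixed phase order; all stochastic rule draws go through inline helpers that
// are also exported as trial functions so rule frequencies can be measured on
// exactly the code path the engine runs.
//
// The RNG is a self-contained xoshiro256** stream (seeded via splitmix64) so
// that snapshots can serialize the generator state and resumed runs are
// bit-identical to uninterrupted ones.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <cstdio>
#include <cinttypes>

using namespace Rcpp;

namespace {

constexpr double TWO_PI = 6.283185307179586476925287;

// ---------------------------------------------------------------- RNG -----

struct Rng {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // integer uniform on 0..n-1 (modulo bias negligible for n << 2^64)
  int rint(int n) { return (int)(next() % (uint64_t)n); }
  bool bern(double p) { return unif() < p; }

  std::vector<std::string> to_hex() const {
    std::vector<std::string> out(4);
    char buf[20];
    for (int i = 0; i < 4; ++i) {
      std::snprintf(buf, sizeof(buf), "%016" PRIx64, s[i]);
      out[i] = buf;
    }
    return out;
  }
  void from_hex(const std::vector<std::string>& v) {
    for (int i = 0; i < 4; ++i) {
      uint64_t x = 0;
      for (char c : v[i]) {
        int d = (c >= '0' && c <= '9') ? c - '0' :
                (c >= 'a' && c <= 'f') ? c - 'a' + 10 :
                (c >= 'A' && c <= 'F') ? c - 'A' + 10 : -1;
        if (d < 0) stop("invalid RNG state string");
        x = (x << 4) | (uint64_t)d;
      }
      s[i] = x;
    }
  }
};

// ----------------------------------------------------------- parameters ----

struct Par {
  double width, height;
  int    cell_move_interval;
  double cell_step, lps_step, mol_step, intra_step, contact_radius;
  double cell_radius, nucleus_radius, energy_switch_frac;
  double th0_entry_threshold;
  int    th0_entry_interval, th0_cap;
  int    th1_secretion_interval, th2_secretion_interval, th_life;
  int    sensitivity_max;
  bool   sensitivity_inclusive;
  int    sensitivity_recovery_ticks;
  int    lps_bound_decay_min, lps_bound_decay_max;
  int    tlr4_prod_interval, tlr4_activation_window;
  int    tnf_life, tnf_bound_decay, tnf_bound_decay_il4;
  bool   il4_speeds_tnf_decay;
  int    ikk_prod_interval, ikk_life_max;
  double p_bind_ikk;
  int    ikk_bind_ticks;
  int    transcription_interval;
  double p_il12;
  int    tnf_amplified;
  int    il4_burst;
  double p_il4;
  int    il4_interval_max;
  int    a_boost;
  int    il12_life, il4_life, il4_bound_duration, ikba_life;
  int    energy_recovery_ticks;
  double ikba_seek_radius, ikba_kill_radius, p_ikba_starved;
};

double getd(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<double>(p[nm]);
}
int geti(const List& p, const char* nm) { return (int)std::lround(getd(p, nm)); }
bool getb(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<bool>(p[nm]);
}

Par parse_par(const List& p) {
  Par q;
  q.width = getd(p, "width");  q.height = getd(p, "height");
  q.cell_move_interval = geti(p, "cell_move_interval");
  q.cell_step = getd(p, "cell_step");
  q.lps_step = getd(p, "lps_step");
  q.mol_step = getd(p, "mol_step");
  q.intra_step = getd(p, "intra_step");
  q.contact_radius = getd(p, "contact_radius");
  q.cell_radius = getd(p, "cell_radius");
  q.nucleus_radius = getd(p, "nucleus_radius");
  q.energy_switch_frac = getd(p, "energy_switch_frac");
  q.th0_entry_threshold = getd(p, "th0_entry_threshold");
  q.th0_entry_interval = geti(p, "th0_entry_interval");
  q.th0_cap = geti(p, "th0_cap");
  q.th1_secretion_interval = geti(p, "th1_secretion_interval");
  q.th2_secretion_interval = geti(p, "th2_secretion_interval");
  q.th_life = geti(p, "th_life");
  q.sensitivity_max = geti(p, "sensitivity_max");
  q.sensitivity_inclusive = getb(p, "sensitivity_inclusive");
  q.sensitivity_recovery_ticks = geti(p, "sensitivity_recovery_ticks");
  q.lps_bound_decay_min = geti(p, "lps_bound_decay_min");
  q.lps_bound_decay_max = geti(p, "lps_bound_decay_max");
  q.tlr4_prod_interval = geti(p, "tlr4_prod_interval");
  q.tlr4_activation_window = geti(p, "tlr4_activation_window");
  q.tnf_life = geti(p, "tnf_life");
  q.tnf_bound_decay = geti(p, "tnf_bound_decay");
  q.tnf_bound_decay_il4 = geti(p, "tnf_bound_decay_il4");
  q.il4_speeds_tnf_decay = getb(p, "il4_speeds_tnf_decay");
  q.ikk_prod_interval = geti(p, "ikk_prod_interval");
  q.ikk_life_max = geti(p, "ikk_life_max");
  q.p_bind_ikk = getd(p, "p_bind_ikk");
  q.ikk_bind_ticks = geti(p, "ikk_bind_ticks");
  q.transcription_interval = geti(p, "transcription_interval");
  q.p_il12 = getd(p, "p_il12");
  q.tnf_amplified = geti(p, "tnf_amplified");
  q.il4_burst = geti(p, "il4_burst");
  q.p_il4 = getd(p, "p_il4");
  q.il4_interval_max = geti(p, "il4_interval_max");
  q.a_boost = geti(p, "a_boost");
  q.il12_life = geti(p, "il12_life");
  q.il4_life = geti(p, "il4_life");
  q.il4_bound_duration = geti(p, "il4_bound_duration");
  q.ikba_life = geti(p, "ikba_life");
  q.energy_recovery_ticks = geti(p, "energy_recovery_ticks");
  q.ikba_seek_radius = getd(p, "ikba_seek_radius");
  q.ikba_kill_radius = getd(p, "ikba_kill_radius");
  q.p_ikba_starved = getd(p, "p_ikba_starved");
  return q;
}

// -------------------------------------------------------- rule draws -------
// Shared by the engine and by the exported *_trials functions.

// TLR4 sensitivity rule: draw an integer 1..sensitivity_max; binding succeeds
// when the draw is strictly below the receptor's current sensitivity (an
// inclusive variant is available for sensitivity studies).
inline bool lps_bind_draw(Rng& r, int sens, const Par& P) {
  int u = 1 + r.rint(P.sensitivity_max);
  return P.sensitivity_inclusive ? (u <= sens) : (u < sens);
}

inline bool ikk_bind_draw(Rng& r, const Par& P) { return r.bern(P.p_bind_ikk); }

struct TransOut { int il12; int tnf; int ikba; };
inline TransOut transcribe_draw(Rng& r, const Par& P, bool switch_on) {
  TransOut o;
  o.il12 = r.bern(P.p_il12) ? 1 : 0;
  o.tnf = switch_on ? P.tnf_amplified : 1;
  // energy-starved cells amplify TNF-a output and can no longer keep up
  // IkBa resynthesis: the negative feedback weakens below the threshold
  o.ikba = (!switch_on || r.bern(P.p_ikba_starved)) ? 1 : 0;
  return o;
}

inline int il4_yield_draw(Rng& r, const Par& P, bool boost) {
  if (!r.bern(P.p_il4)) return 0;
  return P.il4_burst * (boost ? P.a_boost : 1);
}
inline int il4_interval_draw(Rng& r, const Par& P) {
  return 1 + r.rint(P.il4_interval_max);
}
inline int ikk_life_draw(Rng& r, const Par& P) { return 1 + r.rint(P.ikk_life_max); }
inline int lps_decay_draw(Rng& r, const Par& P) {
  int span = P.lps_bound_decay_max - P.lps_bound_decay_min + 1;
  return P.lps_bound_decay_min + r.rint(span);
}

// ------------------------------------------------------------ agents -------

enum MolType { M_LPS = 0, M_TNF = 1, M_IL12 = 2, M_IL4 = 3,
               M_IKK = 4, M_NFKB = 5, M_IKBA = 6, M_INH = 7, M_DEAD = -1 };

// state meanings by type:
//  LPS : 0 free | 1 bound (t1 = decay left, partner = receptor)
//  TNF : 0 free (t1 = age budget) | 1 bound (t1 = decay left, partner = receptor)
//  IL12/IL4/INH : 0 free (t1 = lifetime left; INH has none)
//  IKK : 0 inactive | 1 active | 2 complexed with NF-kB (t2 countdown) | 3 deactivated
//        (t1 = lifetime left)
//  NFKB: 0 inactive complexed with IkBa | 1 held by IKK | 2 active cytosolic |
//        3 active nuclear (t2 = transcription clock)
//  IKBA: 0 activated (free, seeking)
struct Mol {
  int type, state, mac;
  double x, y;
  int t1, t2, partner;
};

struct Rec {  // receptor embedded in a macrophage membrane; type 0 TLR4, 1 TNFR, 2 IL4R
  int mac, type;
  double angle;
  int sens;
  int lps_left;       // >0: bound LPS present (occupied)
  int act_left;       // TLR4 activation window remaining
  long act_accum;     // total active ticks (drives every-100-ticks production)
  int recov;          // ticks since last sensitivity recovery
  int tnf_left;       // >0: TNF-TNFR complex present (occupied)
  int il4_left;       // >0: bound IL-4 present (occupied)
};

struct MacA {
  double cx, cy, heading, energy, energy_init;
  bool sw;
};

struct ThA { double x, y; int kind, il12, il4, clock, age; };  // kind 0 Th0, 1 Th1, 2 Th2

struct Dose { int tick, type, amount; };

// ------------------------------------------------------------- world -------

struct World {
  Par P;
  Rng rng;
  long tick = 0;
  int il4_timer = -1;   // ticks until next IL-4 production cycle (-1: not drawn)
  std::vector<MacA> macs;
  std::vector<Rec>  recs;
  std::vector<Mol>  mols;
  std::vector<ThA>  ths;
  std::vector<Dose> doses;
  size_t dose_ptr = 0;
  // running tallies for ledger-style invariant checks
  double ikba_ubiq = 0, ikba_made = 0, ikba_rebound = 0, ikba_decayed = 0;

  double dirx[1024], diry[1024];

  void init_dirs() {
    for (int i = 0; i < 1024; ++i) {
      double a = TWO_PI * i / 1024.0;
      dirx[i] = std::cos(a); diry[i] = std::sin(a);
    }
  }

  double wrapc(double v, double L) const {
    // displacements are small relative to L, so the loop runs at most twice
    while (v >= L) v -= L;
    while (v < 0) v += L;
    return v;
  }
  double wdelta(double from, double to, double L) const {
    double d = to - from;
    if (d > L * 0.5) d -= L;
    else if (d < -L * 0.5) d += L;
    return d;
  }
  double dist2(double x1, double y1, double x2, double y2) const {
    double dx = wdelta(x1, x2, P.width), dy = wdelta(y1, y2, P.height);
    return dx * dx + dy * dy;
  }

  int mac_at(double x, double y) const {  // index of macrophage whose membrane disk contains (x,y)
    double r2 = P.cell_radius * P.cell_radius;
    for (size_t m = 0; m < macs.size(); ++m)
      if (dist2(x, y, macs[m].cx, macs[m].cy) < r2) return (int)m;
    return -1;
  }
  bool in_nucleus(double x, double y) const {
    double r2 = P.nucleus_radius * P.nucleus_radius;
    for (size_t m = 0; m < macs.size(); ++m)
      if (dist2(x, y, macs[m].cx, macs[m].cy) < r2) return true;
    return false;
  }
  void rec_pos(const Rec& r, double& x, double& y) const {
    const MacA& m = macs[r.mac];
    x = wrapc(m.cx + P.cell_radius * std::cos(r.angle), P.width);
    y = wrapc(m.cy + P.cell_radius * std::sin(r.angle), P.height);
  }

  void rand_extracellular(double& x, double& y) {
    for (int tries = 0; tries < 10000; ++tries) {
      x = rng.unif() * P.width; y = rng.unif() * P.height;
      if (mac_at(x, y) < 0) return;
    }
    stop("could not sample an extracellular position (world overfull of cells)");
  }
  void rand_cytosol(int m, double& x, double& y) {
    double rn2 = P.nucleus_radius * P.nucleus_radius;
    double R2 = P.cell_radius * P.cell_radius;
    double r = std::sqrt(rn2 + rng.unif() * (R2 - rn2) * 0.96);  // margin off the membrane
    double a = rng.unif() * TWO_PI;
    x = wrapc(macs[m].cx + r * std::cos(a), P.width);
    y = wrapc(macs[m].cy + r * std::sin(a), P.height);
  }
  void spawn_outside(int m, double& x, double& y) {  // just outside the membrane
    double a = rng.unif() * TWO_PI;
    double r = P.cell_radius + 2.0 + rng.unif();
    x = wrapc(macs[m].cx + r * std::cos(a), P.width);
    y = wrapc(macs[m].cy + r * std::sin(a), P.height);
  }
  void spawn_at_receptor_outside(const Rec& rc, double& x, double& y) {
    const MacA& m = macs[rc.mac];
    double r = P.cell_radius + 2.0 + rng.unif();
    x = wrapc(m.cx + r * std::cos(rc.angle), P.width);
    y = wrapc(m.cy + r * std::sin(rc.angle), P.height);
  }

  void add_mol(int type, int state, int mac, double x, double y,
               int t1 = 0, int t2 = 0, int partner = -1) {
    mols.push_back(Mol{type, state, mac, x, y, t1, t2, partner});
  }

  // --- movement -------------------------------------------------------

  // Random-walk proposal; returns false (agent stays put, per the published
  // movement-restriction rule: face another direction until the next move)
  // when the proposal violates containment for the agent class.
  bool walk_free(Mol& g, double step, bool block_membrane, bool block_nucleus) {
    int d = rng.rint(1024);
    double nx = wrapc(g.x + step * dirx[d], P.width);
    double ny = wrapc(g.y + step * diry[d], P.height);
    if (block_membrane) {
      if (mac_at(nx, ny) >= 0) return false;
    } else if (block_nucleus) {
      if (in_nucleus(nx, ny)) return false;
    }
    g.x = nx; g.y = ny;
    return true;
  }

  // Cytosol-confined walk (inside own membrane, outside nucleus unless allowed).
  bool walk_cytosol(Mol& g, double step, bool nucleus_ok) {
    int d = rng.rint(1024);
    double nx = wrapc(g.x + step * dirx[d], P.width);
    double ny = wrapc(g.y + step * diry[d], P.height);
    const MacA& m = macs[g.mac];
    double d2 = dist2(nx, ny, m.cx, m.cy);
    if (d2 >= P.cell_radius * P.cell_radius) return false;
    if (!nucleus_ok && d2 < P.nucleus_radius * P.nucleus_radius) return false;
    g.x = nx; g.y = ny;
    return true;
  }

  void step_towards(Mol& g, double tx, double ty, double step) {
    double dx = wdelta(g.x, tx, P.width), dy = wdelta(g.y, ty, P.height);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-12) return;
    double s = std::min(step, d) / d;
    g.x = wrapc(g.x + dx * s, P.width);
    g.y = wrapc(g.y + dy * s, P.height);
  }

  // --- one tick -------------------------------------------------------

  void run_tick() {
    const double cr2 = P.contact_radius * P.contact_radius;
    const double near2 = (P.cell_radius + P.contact_radius + 1.0) *
                         (P.cell_radius + P.contact_radius + 1.0);
    long t = tick;

    // per-type index lists over molecules present at phase start
    std::vector<int> iLPS, iTNF, iIL12, iIL4, iIKK, iNFKB, iIKBA, iINH;
    size_t n0 = mols.size();
    for (size_t i = 0; i < n0; ++i) {
      switch (mols[i].type) {
        case M_LPS:  iLPS.push_back((int)i); break;
        case M_TNF:  iTNF.push_back((int)i); break;
        case M_IL12: iIL12.push_back((int)i); break;
        case M_IL4:  iIL4.push_back((int)i); break;
        case M_IKK:  iIKK.push_back((int)i); break;
        case M_NFKB: iNFKB.push_back((int)i); break;
        case M_IKBA: iIKBA.push_back((int)i); break;
        case M_INH:  iINH.push_back((int)i); break;
        default: break;
      }
    }
    size_t nmac = macs.size();
    std::vector<std::vector<int>> nfkb_of(nmac), ikk_of(nmac);
    for (int i : iNFKB) if (mols[i].mac >= 0) nfkb_of[mols[i].mac].push_back(i);
    for (int i : iIKK)  if (mols[i].mac >= 0) ikk_of[mols[i].mac].push_back(i);

    // (1) due doses: spawn at uniform extracellular positions; injected
    //     agents idle this tick and act from the next one
    while (dose_ptr < doses.size() && doses[dose_ptr].tick <= t) {
      const Dose& D = doses[dose_ptr];
      for (int k = 0; k < D.amount; ++k) {
        double x, y; rand_extracellular(x, y);
        int t1 = (D.type == M_TNF) ? P.tnf_life :
                 (D.type == M_IL12) ? P.il12_life :
                 (D.type == M_IL4) ? P.il4_life : 0;
        add_mol(D.type, 0, -1, x, y, t1);
      }
      ++dose_ptr;
    }

    // (2) LPS movement + receptor binding
    for (int i : iLPS) {
      Mol& g = mols[i];
      if (g.state == 1) {                    // bound: degrade 1-2 ticks after binding
        if (--g.t1 <= 0) {
          recs[g.partner].lps_left = 0;      // receptor freed (stays in activation window)
          g.type = M_DEAD;
        }
        continue;
      }
      // the published movement routine: head to a random direction and move
      // several steps forward; receptor contact is checked after each step so
      // fast molecules cannot tunnel through the membrane contact band
      int nsub = (int)std::ceil(P.lps_step);
      double sub = (nsub > 0) ? P.lps_step / nsub : 0.0;
      int d = rng.rint(1024);
      for (int ss = 0; ss < nsub && g.state == 0; ++ss) {
        double nx = wrapc(g.x + sub * dirx[d], P.width);
        double ny = wrapc(g.y + sub * diry[d], P.height);
        if (mac_at(nx, ny) >= 0) break;  // bounce: face elsewhere next tick
        g.x = nx; g.y = ny;
        for (size_t m = 0; m < nmac && g.state == 0; ++m) {
          if (dist2(g.x, g.y, macs[m].cx, macs[m].cy) > near2) continue;
          for (size_t rix = 0; rix < recs.size(); ++rix) {
            Rec& rc = recs[rix];
            if (rc.mac != (int)m || rc.type != 0 || rc.lps_left > 0) continue;
            double rx, ry; rec_pos(rc, rx, ry);
            if (dist2(g.x, g.y, rx, ry) > cr2) continue;
            if (lps_bind_draw(rng, rc.sens, P)) {
              g.state = 1; g.partner = (int)rix; g.mac = (int)m;
              g.x = rx; g.y = ry;
              g.t1 = lps_decay_draw(rng, P);
              rc.lps_left = g.t1;
              rc.sens = std::max(0, rc.sens - 1);
              rc.act_left = P.tlr4_activation_window;  // renewable activation window
              double sx, sy; spawn_at_receptor_outside(rc, sx, sy);
              add_mol(M_TNF, 0, -1, sx, sy, P.tnf_life);  // immediate 1 unit of TNF-a
            }
            break;  // one contact attempt per substep whether or not it succeeded
          }
        }
      }
    }

    // (3) TLR4 activation-window production + sensitivity recovery
    for (Rec& rc : recs) {
      if (rc.type == 0) {
        if (rc.act_left > 0) {
          --rc.act_left;
          ++rc.act_accum;
          if (rc.act_accum % P.tlr4_prod_interval == 0) {
            double sx, sy; spawn_at_receptor_outside(rc, sx, sy);
            add_mol(M_TNF, 0, -1, sx, sy, P.tnf_life);
          }
        }
        if (++rc.recov >= P.sensitivity_recovery_ticks) {
          rc.recov = 0;
          rc.sens = std::min(P.sensitivity_max, rc.sens + 1);
        }
      } else if (rc.type == 1 && rc.tnf_left > 0) {
        --rc.tnf_left;      // TNF-TNFR complex countdown (partner molecule mirrors it)
      } else if (rc.type == 2 && rc.il4_left > 0) {
        --rc.il4_left;
      }
    }

    // (4) TNF-a movement / decay / TNFR binding
    std::vector<char> complex_formed(nmac, 0);
    for (int i : iTNF) {
      Mol& g = mols[i];
      if (g.state == 1) {
        if (--g.t1 <= 0) { recs[g.partner].tnf_left = 0; g.type = M_DEAD; }
        continue;
      }
      if (--g.t1 <= 0) { g.type = M_DEAD; continue; }  // natural 600-tick budget
      walk_free(g, P.mol_step, false, true);           // membrane-permeable, nucleus excluded
      for (size_t m = 0; m < nmac && g.state == 0; ++m) {
        double dc2 = dist2(g.x, g.y, macs[m].cx, macs[m].cy);
        if (dc2 > near2) continue;
        for (size_t rix = 0; rix < recs.size(); ++rix) {
          Rec& rc = recs[rix];
          if (rc.mac != (int)m || rc.type != 1 || rc.tnf_left > 0) continue;
          double rx, ry; rec_pos(rc, rx, ry);
          if (dist2(g.x, g.y, rx, ry) > cr2) continue;
          // bound IL-4 on the same macrophage modulates complex lifetime
          bool il4_near = false;
          for (const Rec& r2 : recs)
            if (r2.mac == (int)m && r2.type == 2 && r2.il4_left > 0) { il4_near = true; break; }
          int dk;
          if (!P.il4_speeds_tnf_decay)
            dk = il4_near ? P.tnf_bound_decay_il4 : P.tnf_bound_decay;
          else
            dk = il4_near ? P.tnf_bound_decay : P.tnf_bound_decay_il4;
          g.state = 1; g.partner = (int)rix; g.mac = (int)m;
          g.x = rx; g.y = ry; g.t1 = dk;
          rc.tnf_left = dk;
          complex_formed[m] = 1;
          break;
        }
      }
    }


    // (5) macrophage IKK production + chemotactic movement when due
    for (size_t m = 0; m < nmac; ++m) {
      MacA& M = macs[m];
      if (P.ikk_prod_interval > 0 && t % P.ikk_prod_interval == 0) {
        double x, y; rand_cytosol((int)m, x, y);
        add_mol(M_IKK, 0, (int)m, x, y, ikk_life_draw(rng, P));
      }
      if (P.cell_move_interval > 0 && t > 0 && t % P.cell_move_interval == 0) {
        // 8-sector census of free LPS within (5 + cell radius)
        double sense2 = (5.0 + P.cell_radius) * (5.0 + P.cell_radius);
        int cnt[8] = {0, 0, 0, 0, 0, 0, 0, 0};
        for (int i : iLPS) {
          const Mol& g = mols[i];
          if (g.type != M_LPS || g.state != 0) continue;
          double dx = wdelta(M.cx, g.x, P.width), dy = wdelta(M.cy, g.y, P.height);
          if (dx * dx + dy * dy > sense2) continue;
          double a = std::atan2(dy, dx);
          int s = (int)std::floor((a + TWO_PI / 16.0) / (TWO_PI / 8.0));
          cnt[((s % 8) + 8) % 8]++;
        }
        int best = -1, bc = 0;
        for (int s = 0; s < 8; ++s) if (cnt[s] > bc) { bc = cnt[s]; best = s; }
        if (best >= 0) M.heading = best * (TWO_PI / 8.0);  // ties: lowest index wins
        double dx = P.cell_step * std::cos(M.heading);
        double dy = P.cell_step * std::sin(M.heading);
        double nx = wrapc(M.cx + dx, P.width), ny = wrapc(M.cy + dy, P.height);
        bool ok = true;
        double mind = 2.0 * (P.cell_radius + 1.0);
        for (size_t o = 0; o < nmac; ++o)
          if (o != m && dist2(nx, ny, macs[o].cx, macs[o].cy) < mind * mind) { ok = false; break; }
        if (ok) {
          M.cx = nx; M.cy = ny;
          // constituents and bound surface molecules translate rigidly
          for (Mol& g : mols) {
            if (g.type == M_DEAD) continue;
            bool intra = (g.type == M_IKK || g.type == M_NFKB || g.type == M_IKBA);
            if ((intra && g.mac == (int)m) || (g.state == 1 && g.mac == (int)m)) {
              g.x = wrapc(g.x + dx, P.width);
              g.y = wrapc(g.y + dy, P.height);
            }
          }
        }
      }
    }

    // (6) IKK: degradation, activation by TNF-TNFR complexes, movement,
    //     NF-kB complex binding and 10-tick dissociation
    for (int i : iIKK) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      if (g.state != 2) {
        if (--g.t1 <= 0) { g.type = M_DEAD; continue; }
      } else {
        --g.t1;  // lifetime keeps running; removal deferred to dissociation
      }
      if (g.state == 0 && complex_formed[g.mac]) g.state = 1;
      if (g.state != 2) walk_cytosol(g, P.intra_step, false);
      if (g.state == 1) {
        for (int j : nfkb_of[g.mac]) {
          Mol& nb = mols[j];
          if (nb.state != 0) continue;
          if (dist2(g.x, g.y, nb.x, nb.y) > cr2) continue;
          if (ikk_bind_draw(rng, P)) {
            g.state = 2; g.t2 = P.ikk_bind_ticks; g.partner = j;
            nb.state = 1; nb.partner = i;
          }
          break;  // single contact attempt per tick
        }
      } else if (g.state == 2) {
        if (--g.t2 <= 0) {
          Mol& nb = mols[g.partner];
          nb.state = 2;            // NF-kB freed and activated
          nb.partner = -1;
          ikba_ubiq += 1;          // the complexed IkBa is ubiquitinated
          g.partner = -1;
          g.state = 1;
          if (g.t1 <= 0) g.type = M_DEAD;
        }
      }
    }

    // (7) NF-kB: cytosolic diffusion, nuclear translocation, transcription
    for (int i : iNFKB) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      MacA& M = macs[g.mac];
      if (g.state == 0) {
        walk_cytosol(g, P.intra_step, false);
      } else if (g.state == 2) {
        step_towards(g, M.cx, M.cy, P.intra_step);
        if (dist2(g.x, g.y, M.cx, M.cy) < P.nucleus_radius * P.nucleus_radius) {
          g.state = 3; g.t2 = 0;
        }
      } else if (g.state == 3) {
        walk_cytosol(g, P.intra_step, true);
        if (++g.t2 % P.transcription_interval == 0) {
          TransOut o = transcribe_draw(rng, P, M.sw);
          double x, y;
          if (o.ikba) {
            rand_cytosol(g.mac, x, y);
            add_mol(M_IKBA, 0, g.mac, x, y, P.ikba_life);
            ikba_made += 1;
          }
          if (o.il12) { spawn_outside(g.mac, x, y); add_mol(M_IL12, 0, -1, x, y, P.il12_life); }
          for (int k = 0; k < o.tnf; ++k) {
            spawn_outside(g.mac, x, y); add_mol(M_TNF, 0, -1, x, y, P.tnf_life);
          }
          M.energy = std::max(0.0, M.energy - 1.0);
        }
      }
    }

    // (8) IkBa: seek activated NF-kB within radius 1, re-form the inactive
    //     complex in the cytosol; free IkBa also deactivates IKK on contact
    for (int i : iIKBA) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      if (--g.t1 <= 0) { g.type = M_DEAD; ikba_decayed += 1; continue; }  // proteasomal turnover
      // chase the nearest activated NF-kB, but only within the seek horizon;
      // otherwise patrol the cytosol (where stray IKK gets shut down)
      int tgt = -1; double td2 = P.ikba_seek_radius * P.ikba_seek_radius;
      for (int j : nfkb_of[g.mac]) {
        const Mol& nb = mols[j];
        if (nb.state != 2 && nb.state != 3) continue;
        double d2 = dist2(g.x, g.y, nb.x, nb.y);
        if (d2 <= td2) { td2 = d2; tgt = j; }
      }
      if (tgt >= 0 && td2 <= cr2) {
        Mol& nb = mols[tgt];
        nb.state = 0;                        // inactive complex again...
        double x, y; rand_cytosol(g.mac, x, y);
        nb.x = x; nb.y = y;                  // ...relocated to the cytoplasmic region
        ikba_rebound += 1;
        g.type = M_DEAD;
        continue;
      }
      if (tgt >= 0) step_towards(g, mols[tgt].x, mols[tgt].y, P.intra_step);
      else walk_cytosol(g, P.intra_step, true);   // patrol includes the nucleus
      // transcriptionally produced IkBa also shuts down IKK inside its zone
      // of influence, including kinase currently processing an NF-kB complex
      // (the complex partner reverts to its inactive state)
      double sr2 = P.ikba_kill_radius * P.ikba_kill_radius;
      for (int j : ikk_of[g.mac]) {
        Mol& kk = mols[j];
        if (kk.type == M_DEAD || (kk.state != 1 && kk.state != 2)) continue;
        if (dist2(g.x, g.y, kk.x, kk.y) <= sr2) {
          if (kk.state == 2) {
            Mol& nb = mols[kk.partner];
            nb.state = 0; nb.partner = -1;
            kk.partner = -1;
          }
          kk.state = 3;       // deactivated for good; degrades on schedule
          if (kk.t1 <= 0) kk.type = M_DEAD;
        }
      }
    }

    // (9) cytokines: IL-12 / IL-4 movement, decay, receptor binding;
    //     world-level IL-4 production cycle; IKK-inhibitor action
    for (int i : iIL12) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      if (--g.t1 <= 0) { g.type = M_DEAD; continue; }
      walk_free(g, P.mol_step, true, false);
      for (ThA& th : ths) {
        if (th.kind != 0) continue;
        if (dist2(g.x, g.y, th.x, th.y) <= cr2) { th.il12++; g.type = M_DEAD; break; }
      }
    }
    for (int i : iIL4) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      if (--g.t1 <= 0) { g.type = M_DEAD; continue; }
      walk_free(g, P.mol_step, true, false);
      bool used = false;
      for (size_t m = 0; m < nmac && !used; ++m) {
        if (dist2(g.x, g.y, macs[m].cx, macs[m].cy) > near2) continue;
        for (size_t rix = 0; rix < recs.size(); ++rix) {
          Rec& rc = recs[rix];
          if (rc.mac != (int)m || rc.type != 2 || rc.il4_left > 0) continue;
          double rx, ry; rec_pos(rc, rx, ry);
          if (dist2(g.x, g.y, rx, ry) > cr2) continue;
          rc.il4_left = P.il4_bound_duration;
          // +1 energy per binding; the energetic level is a bounded health
          // indicator and saturates at its homeostatic initial value
          macs[m].energy = std::min(macs[m].energy + 1.0, macs[m].energy_init);
          g.type = M_DEAD; used = true;
          break;
        }
      }
      if (!used) {
        for (ThA& th : ths) {
          if (th.kind != 0) continue;
          if (dist2(g.x, g.y, th.x, th.y) <= cr2) { th.il4++; g.type = M_DEAD; break; }
        }
      }
    }
    // IL-4 production: every 1..5 ticks, if free IL-12 exists, 86% chance of a
    // 3-unit burst (amount boosted while any energy switch is on)
    {
      if (il4_timer < 0) il4_timer = il4_interval_draw(rng, P);
      if (--il4_timer <= 0) {
        bool any_il12 = false;
        for (int i : iIL12) if (mols[i].type == M_IL12) { any_il12 = true; break; }
        if (any_il12) {
          bool boost = false;
          for (const MacA& M : macs) if (M.sw) { boost = true; break; }
          int k = il4_yield_draw(rng, P, boost);
          for (int j = 0; j < k; ++j) {
            double x, y; rand_extracellular(x, y);
            add_mol(M_IL4, 0, -1, x, y, P.il4_life);
          }
        }
        il4_timer = il4_interval_draw(rng, P);
      }
    }
    for (int i : iINH) {
      Mol& g = mols[i];
      if (g.type == M_DEAD) continue;
      walk_free(g, P.mol_step, false, true);   // diffuses into the cytoplasm
      int m = mac_at(g.x, g.y);
      if (m < 0) continue;
      for (int j : ikk_of[m]) {
        Mol& kk = mols[j];
        if (kk.type == M_DEAD || (kk.state != 0 && kk.state != 1)) continue;
        if (dist2(g.x, g.y, kk.x, kk.y) <= cr2) {
          kk.state = 3;        // permanent deactivation, 1:1 stoichiometry
          g.type = M_DEAD;
          break;
        }
      }
    }

    // (10) T-helper cells: recruitment, differentiation, secretion, movement
    {
      int p_count = 0;
      for (int i : iIL12) if (mols[i].type == M_IL12) ++p_count;
      if (p_count > P.th0_entry_threshold &&
          P.th0_entry_interval > 0 && t % P.th0_entry_interval == 0 &&
          (int)ths.size() < P.th0_cap) {
        double x, y; rand_extracellular(x, y);
        ths.push_back(ThA{x, y, 0, 0, 0, 0, 0});
      }
      bool any_sw = false;
      for (const MacA& M : macs) if (M.sw) { any_sw = true; break; }
      size_t wt = 0;   // Th cells leave the world after th_life ticks
      for (size_t k = 0; k < ths.size(); ++k)
        if (++ths[k].age <= P.th_life) ths[wt++] = ths[k];
      ths.resize(wt);
      for (ThA& th : ths) {
        if (th.kind == 0 && th.il12 + th.il4 >= 25) {
          th.kind = (th.il12 > th.il4) ? 1 : 2;  // ties fall to Th2 ("otherwise")
          th.clock = 0;
        }
        if (th.kind == 1) {
          if (++th.clock >= P.th1_secretion_interval) {
            th.clock = 0;
            double x = th.x, y = th.y;
            add_mol(M_IL12, 0, -1, x, y, P.il12_life);
          }
        } else if (th.kind == 2) {
          int iv = any_sw ? std::max(1, P.th2_secretion_interval / P.a_boost)
                          : P.th2_secretion_interval;
          if (++th.clock >= iv) {
            th.clock = 0;
            add_mol(M_IL4, 0, -1, th.x, th.y, P.il4_life);
          }
        }
        if (P.cell_move_interval > 0 && t > 0 && t % P.cell_move_interval == 0) {
          int d = rng.rint(1024);
          double nx = wrapc(th.x + P.cell_step * dirx[d], P.width);
          double ny = wrapc(th.y + P.cell_step * diry[d], P.height);
          if (mac_at(nx, ny) < 0) { th.x = nx; th.y = ny; }
        }
      }
    }

    // (11) basal bioenergetic recovery and energy switch update (switch is
    //      on strictly below the 25% threshold)
    for (MacA& M : macs) {
      if (P.energy_recovery_ticks > 0 && t > 0 && t % P.energy_recovery_ticks == 0)
        M.energy = std::min(M.energy + 1.0, M.energy_init);
      M.sw = (M.energy < P.energy_switch_frac * M.energy_init);
    }

    // (12) compaction + tick increment (census is taken by the caller)
    compact();
    ++tick;
  }

  void compact() {
    std::vector<int> remap(mols.size(), -1);
    size_t w = 0;
    for (size_t i = 0; i < mols.size(); ++i) {
      if (mols[i].type == M_DEAD) continue;
      remap[i] = (int)w;
      if (w != i) mols[w] = mols[i];
      ++w;
    }
    mols.resize(w);
    for (Mol& g : mols) {
      if ((g.type == M_IKK && g.state == 2) || (g.type == M_NFKB && g.state == 1)) {
        g.partner = remap[g.partner];
        if (g.partner < 0) stop("internal error: dangling complex partner");
      }
    }
  }

  // census row: lps_total tnf_free P A E nfkb_active ikk_active ikba_active th0 th1 th2
  void census(double* row) const {
    double lps = 0, tnf = 0, p = 0, a = 0, nf = 0, kk = 0, ib = 0;
    for (const Mol& g : mols) {
      switch (g.type) {
        case M_LPS:  lps += 1; break;
        case M_TNF:  if (g.state == 0) tnf += 1; break;
        case M_IL12: p += 1; break;
        case M_IL4:  a += 1; break;
        case M_NFKB: if (g.state == 2 || g.state == 3) nf += 1; break;
        case M_IKK:  if (g.state == 1 || g.state == 2) kk += 1; break;
        case M_IKBA: ib += 1; break;
        default: break;
      }
    }
    for (const Rec& rc : recs) if (rc.type == 2 && rc.il4_left > 0) a += 1;
    double e = 0; for (const MacA& M : macs) e += M.energy;
    double t0 = 0, t1 = 0, t2 = 0;
    for (const ThA& th : ths) {
      if (th.kind == 0) t0 += 1; else if (th.kind == 1) t1 += 1; else t2 += 1;
    }
    row[0] = (double)tick; row[1] = lps; row[2] = tnf; row[3] = p; row[4] = a;
    row[5] = e; row[6] = nf; row[7] = kk; row[8] = ib;
    row[9] = t0; row[10] = t1; row[11] = t2;
  }

  void audit() const {  // invariant breach = engine bug, not user error
    for (const Mol& g : mols) {
      if (g.x < 0 || g.x >= P.width || g.y < 0 || g.y >= P.height)
        stop("invariant breach: molecule position out of world bounds");
      if (g.type == M_TNF && g.state == 0 && g.t1 > P.tnf_life)
        stop("invariant breach: free TNF-a above its tick budget");
      if ((g.type == M_IKK || g.type == M_NFKB || g.type == M_IKBA) && g.mac >= 0) {
        double d2 = dist2(g.x, g.y, macs[g.mac].cx, macs[g.mac].cy);
        if (d2 > (P.cell_radius + 1e-6) * (P.cell_radius + 1e-6))
          stop("invariant breach: intracellular agent outside its membrane");
      }
    }
  }
};

// -------------------------------------------------------- marshalling ------

IntegerVector iv(const List& df, const char* nm) { return as<IntegerVector>(as<List>(df)[nm]); }
NumericVector nv(const List& df, const char* nm) { return as<NumericVector>(as<List>(df)[nm]); }

World from_list(const List& state, const List& params) {
  World w;
  w.P = parse_par(params);
  w.init_dirs();
  w.tick = as<double>(state["tick"]);
  w.il4_timer = as<int>(state["il4_timer"]);
  if (state.containsElementNamed("rng") && !Rf_isNull(state["rng"])) {
    std::vector<std::string> hx = as<std::vector<std::string>>(state["rng"]);
    w.rng.from_hex(hx);
  } else {
    w.rng.seed((uint64_t)as<double>(state["seed"]));
  }
  List macs = as<List>(state["macs"]);
  if (macs.size() > 0) {
    NumericVector cx = nv(macs, "cx"), cy = nv(macs, "cy"), hd = nv(macs, "heading"),
                  en = nv(macs, "energy"), ei = nv(macs, "energy_init");
    LogicalVector sw = as<LogicalVector>(macs["sw"]);
    for (int i = 0; i < cx.size(); ++i)
      w.macs.push_back(MacA{cx[i], cy[i], hd[i], en[i], ei[i], (bool)sw[i]});
  }
  List recs = as<List>(state["receptors"]);
  if (recs.size() > 0) {
    IntegerVector mac = iv(recs, "mac"), type = iv(recs, "type"), sens = iv(recs, "sens"),
                  lps = iv(recs, "lps_left"), act = iv(recs, "act_left"),
                  acc = iv(recs, "act_accum"), rec2 = iv(recs, "recov"),
                  tnf = iv(recs, "tnf_left"), il4 = iv(recs, "il4_left");
    NumericVector ang = nv(recs, "angle");
    for (int i = 0; i < mac.size(); ++i)
      w.recs.push_back(Rec{mac[i], type[i], ang[i], sens[i], lps[i], act[i],
                           (long)acc[i], rec2[i], tnf[i], il4[i]});
  }
  List mols = as<List>(state["mols"]);
  if (mols.size() > 0) {
    IntegerVector type = iv(mols, "type"), st = iv(mols, "state"), mac = iv(mols, "mac"),
                  t1 = iv(mols, "t1"), t2 = iv(mols, "t2"), pr = iv(mols, "partner");
    NumericVector x = nv(mols, "x"), y = nv(mols, "y");
    for (int i = 0; i < type.size(); ++i)
      w.mols.push_back(Mol{type[i], st[i], mac[i], x[i], y[i], t1[i], t2[i], pr[i]});
  }
  List ths = as<List>(state["ths"]);
  if (ths.size() > 0) {
    IntegerVector kind = iv(ths, "kind"), il12 = iv(ths, "il12"), il4 = iv(ths, "il4"),
                  clock = iv(ths, "clock"), age = iv(ths, "age");
    NumericVector x = nv(ths, "x"), y = nv(ths, "y");
    for (int i = 0; i < kind.size(); ++i)
      w.ths.push_back(ThA{x[i], y[i], kind[i], il12[i], il4[i], clock[i], age[i]});
  }
  List doses = as<List>(state["doses"]);
  if (doses.size() > 0) {
    IntegerVector tk = iv(doses, "tick"), ty = iv(doses, "type"), am = iv(doses, "amount");
    for (int i = 0; i < tk.size(); ++i)
      w.doses.push_back(Dose{tk[i], ty[i], am[i]});
  }
  if (state.containsElementNamed("counters") && !Rf_isNull(state["counters"])) {
    NumericVector ct = as<NumericVector>(state["counters"]);
    w.ikba_ubiq = ct[0]; w.ikba_made = ct[1]; w.ikba_rebound = ct[2];
    if (ct.size() > 3) w.ikba_decayed = ct[3];
  }
  return w;
}

List to_list(const World& w) {
  size_t nm = w.macs.size(), nr = w.recs.size(), ng = w.mols.size(), nt = w.ths.size();
  NumericVector cx(nm), cy(nm), hd(nm), en(nm), ei(nm);
  LogicalVector sw(nm);
  for (size_t i = 0; i < nm; ++i) {
    cx[i] = w.macs[i].cx; cy[i] = w.macs[i].cy; hd[i] = w.macs[i].heading;
    en[i] = w.macs[i].energy; ei[i] = w.macs[i].energy_init; sw[i] = w.macs[i].sw;
  }
  IntegerVector rmac(nr), rtype(nr), rsens(nr), rlps(nr), ract(nr), racc(nr),
                rrec(nr), rtnf(nr), ril4(nr);
  NumericVector rang(nr);
  for (size_t i = 0; i < nr; ++i) {
    const Rec& r = w.recs[i];
    rmac[i] = r.mac; rtype[i] = r.type; rang[i] = r.angle; rsens[i] = r.sens;
    rlps[i] = r.lps_left; ract[i] = r.act_left; racc[i] = (int)r.act_accum;
    rrec[i] = r.recov; rtnf[i] = r.tnf_left; ril4[i] = r.il4_left;
  }
  IntegerVector gtype(ng), gst(ng), gmac(ng), gt1(ng), gt2(ng), gpr(ng);
  NumericVector gx(ng), gy(ng);
  for (size_t i = 0; i < ng; ++i) {
    const Mol& g = w.mols[i];
    gtype[i] = g.type; gst[i] = g.state; gmac[i] = g.mac;
    gx[i] = g.x; gy[i] = g.y; gt1[i] = g.t1; gt2[i] = g.t2; gpr[i] = g.partner;
  }
  IntegerVector tkind(nt), til12(nt), til4(nt), tclock(nt), tage(nt);
  NumericVector tx(nt), ty(nt);
  for (size_t i = 0; i < nt; ++i) {
    const ThA& th = w.ths[i];
    tkind[i] = th.kind; til12[i] = th.il12; til4[i] = th.il4; tclock[i] = th.clock;
    tage[i] = th.age;
    tx[i] = th.x; ty[i] = th.y;
  }
  size_t ndose = w.doses.size() - w.dose_ptr;
  IntegerVector dtk(ndose), dty(ndose), dam(ndose);
  for (size_t i = 0; i < ndose; ++i) {
    const Dose& d = w.doses[w.dose_ptr + i];
    dtk[i] = d.tick; dty[i] = d.type; dam[i] = d.amount;
  }
  return List::create(
    _["tick"] = (double)w.tick,
    _["il4_timer"] = w.il4_timer,
    _["rng"] = wrap(w.rng.to_hex()),
    _["macs"] = DataFrame::create(_["cx"] = cx, _["cy"] = cy, _["heading"] = hd,
                                  _["energy"] = en, _["energy_init"] = ei, _["sw"] = sw),
    _["receptors"] = DataFrame::create(_["mac"] = rmac, _["type"] = rtype, _["angle"] = rang,
                                       _["sens"] = rsens, _["lps_left"] = rlps,
                                       _["act_left"] = ract, _["act_accum"] = racc,
                                       _["recov"] = rrec, _["tnf_left"] = rtnf,
                                       _["il4_left"] = ril4),
    _["mols"] = DataFrame::create(_["type"] = gtype, _["state"] = gst, _["mac"] = gmac,
                                  _["x"] = gx, _["y"] = gy, _["t1"] = gt1, _["t2"] = gt2,
                                  _["partner"] = gpr),
    _["ths"] = DataFrame::create(_["kind"] = tkind, _["x"] = tx, _["y"] = ty,
                                 _["il12"] = til12, _["il4"] = til4, _["clock"] = tclock,
                                 _["age"] = tage),
    _["doses"] = DataFrame::create(_["tick"] = dtk, _["type"] = dty, _["amount"] = dam),
    _["counters"] = NumericVector::create(w.ikba_ubiq, w.ikba_made, w.ikba_rebound,
                                          w.ikba_decayed));
}

}  // namespace

// ------------------------------------------------------------ exports ------

// [[Rcpp::export]]
List cpp_run(List state, List params, int nticks, bool record, bool audit = false) {
  World w = from_list(state, params);
  int ncol = 12;
  NumericMatrix series(record ? (nticks + 1) : 0, record ? ncol : 0);
  std::vector<double> row(ncol);
  if (record) {
    w.census(row.data());
    for (int c = 0; c < ncol; ++c) series(0, c) = row[c];
  }
  for (int k = 0; k < nticks; ++k) {
    w.run_tick();
    if (audit) w.audit();
    if (record) {
      w.census(row.data());
      for (int c = 0; c < ncol; ++c) series(k + 1, c) = row[c];
    }
  }
  return List::create(_["series"] = series, _["state"] = to_list(w));
}

// Rule-frequency trial harnesses.  Each calls the same inline draw helper the
// engine's tick loop uses, under a fresh seeded stream.

// [[Rcpp::export]]
int cpp_lps_bind_trials(int n, int sensitivity, double seed, List params) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  int succ = 0;
  for (int i = 0; i < n; ++i) if (lps_bind_draw(r, sensitivity, P)) ++succ;
  return succ;
}

// [[Rcpp::export]]
int cpp_ikk_bind_trials(int n, double seed, List params) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  int succ = 0;
  for (int i = 0; i < n; ++i) if (ikk_bind_draw(r, P)) ++succ;
  return succ;
}

// [[Rcpp::export]]
List cpp_transcribe_trials(int n, double seed, List params, bool switch_on) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  long il12 = 0, tnf = 0;
  for (int i = 0; i < n; ++i) {
    TransOut o = transcribe_draw(r, P, switch_on);
    il12 += o.il12; tnf += o.tnf;
  }
  return List::create(_["il12"] = (double)il12, _["ikba"] = (double)n,
                      _["tnf"] = (double)tnf);
}

// [[Rcpp::export]]
List cpp_il4_cycle_trials(int n, double seed, List params, bool boost) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  IntegerVector yields(n), intervals(n);
  for (int i = 0; i < n; ++i) {
    yields[i] = il4_yield_draw(r, P, boost);
    intervals[i] = il4_interval_draw(r, P);
  }
  return List::create(_["yields"] = yields, _["intervals"] = intervals);
}

// [[Rcpp::export]]
IntegerVector cpp_ikk_lifetime_draws(int n, double seed, List params) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ikk_life_draw(r, P);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_lps_decay_draws(int n, double seed, List params) {
  Par P = parse_par(params);
  Rng r; r.seed((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lps_decay_draw(r, P);
  return out;
}
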