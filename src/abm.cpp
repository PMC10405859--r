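// Core lattice engine for the prostate-cancer agent-based model.
//
// All stochastic simulation happens here, driven by R's RNG (set.seed()
// upstream gives bit-identical trajectories).  One grid space holds at most
// one cellular agent; basement membrane (BM) and extracellular matrix (ECM)
// are passive layers that agents can degrade but never co-occupy.
//
// Time unit: 1 step = 12 h.  All probabilities are per-step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// agent kinds (keep in sync with R's kind_levels())
static const int K_LUM = 0, K_BAS = 1, K_STEM = 2, K_TU = 3,
                 K_FIB = 4, K_CAF = 5, K_M1 = 6, K_M2 = 7;
static const int N_KINDS = 8;

// passive layer codes
static const int P_EMPTY = 0, P_BM = 1, P_ECM = 2;

// event type codes (keep in sync with R's event_levels())
static const int EV_BIRTH = 1, EV_DEATH = 2, EV_MUT = 3, EV_DIFF = 4,
                 EV_BREAK = 5, EV_MIG = 6, EV_KILL = 7, EV_INFLUX = 8,
                 EV_EMT = 9;

// death detail codes
static const int D_SPONT = 0, D_EXHAUST = 1, D_KILLED = 2, D_DETACH = 3;

// simulation modes
static const int MODEL_MINIMAL = 0, MODEL_ACINUS = 1, MODEL_CULTURE = 2;

static const int DIV_INF = -1;  // divisions_left sentinel: unlimited (stem)

struct Agent {
  int id, kind, row, col, mut, div_left, kills, age;
  bool emt, alive;
};

struct Params {
  double TUpprol, TUpmig, TUpdeath, TUpmut, TUaddedProl, TUmutEscalation,
      TUpkill, TUpMdiff, TUpMMP;
  int TUpmax, TUaddedMax, TUthrshBM, TUthrshM, TUthrshMMP;
  double LCpprol, LCpdeath, BCpprol, BCpdeath;
  double Fdiff, Fpprol, Fpdeath;
  int Fpmax;
  double CFpprol, CFpdeath, CFmmp, CFmdiff, CFemt, CFprom;
  double M1influxProb, M1influxadd, M1pkill, M1pdeath, M1pmig, M2pkill,
      M2TUadd, M2emt;
  int M1kmax, M2kmax;
  int sensing_radius, caf_induction_range, macrophage_move_range;
  double SCrenew;          // probability a stem division yields two stem cells
  double SCpdeath;         // spontaneous death of cancer stem cells
  bool sticky_detection;   // macrophage tumor detection is irreversible
  bool stem_mutation;      // stem cells may acquire mutations
};

static double getd(const List& p, const char* nm) {
  return as<double>(p[nm]);
}
static int geti(const List& p, const char* nm) {
  return as<int>(p[nm]);
}

static Params read_params(const List& p) {
  Params P;
  P.TUpprol = getd(p, "TUpprol");
  P.TUpmig = getd(p, "TUpmig");
  P.TUpdeath = getd(p, "TUpdeath");
  P.TUpmut = getd(p, "TUpmut");
  P.TUaddedProl = getd(p, "TUaddedProl");
  P.TUmutEscalation = getd(p, "TUmutEscalation");
  P.TUpkill = getd(p, "TUpkill");
  P.TUpMdiff = getd(p, "TUpMdiff");
  P.TUpMMP = getd(p, "TUpMMP");
  P.TUpmax = geti(p, "TUpmax");
  P.TUaddedMax = geti(p, "TUaddedMax");
  P.TUthrshBM = geti(p, "TUthrshBM");
  P.TUthrshM = geti(p, "TUthrshM");
  P.TUthrshMMP = geti(p, "TUthrshMMP");
  P.LCpprol = getd(p, "LCpprol");
  P.LCpdeath = getd(p, "LCpdeath");
  P.BCpprol = getd(p, "BCpprol");
  P.BCpdeath = getd(p, "BCpdeath");
  P.Fdiff = getd(p, "Fdiff");
  P.Fpprol = getd(p, "Fpprol");
  P.Fpdeath = getd(p, "Fpdeath");
  P.Fpmax = geti(p, "Fpmax");
  P.CFpprol = getd(p, "CFpprol");
  P.CFpdeath = getd(p, "CFpdeath");
  P.CFmmp = getd(p, "CFmmp");
  P.CFmdiff = getd(p, "CFmdiff");
  P.CFemt = getd(p, "CFemt");
  P.CFprom = getd(p, "CFprom");
  P.M1influxProb = getd(p, "M1influxProb");
  P.M1influxadd = getd(p, "M1influxadd");
  P.M1pkill = getd(p, "M1pkill");
  P.M1pdeath = getd(p, "M1pdeath");
  P.M1pmig = getd(p, "M1pmig");
  P.M2pkill = getd(p, "M2pkill");
  P.M2TUadd = getd(p, "M2TUadd");
  P.M2emt = getd(p, "M2emt");
  P.M1kmax = geti(p, "M1kmax");
  P.M2kmax = geti(p, "M2kmax");
  P.sensing_radius = geti(p, "sensing_radius");
  P.caf_induction_range = geti(p, "caf_induction_range");
  P.macrophage_move_range = geti(p, "macrophage_move_range");
  P.SCrenew = getd(p, "SCrenew");
  P.SCpdeath = getd(p, "SCpdeath");
  P.sticky_detection = as<bool>(p["sticky_detection"]);
  P.stem_mutation = as<bool>(p["stem_mutation"]);
  return P;
}

static inline bool bern(double p) { return unif_rand() < p; }
static inline int ri(int n) {  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}
static inline double clamp01(double p) { return p > 1.0 ? 1.0 : p; }

class Sim {
 public:
  int W, H, model, step;
  Params P;
  std::vector<int> occ;       // agent index + 1, 0 = free
  std::vector<int> pas;       // passive layer code
  std::vector<uint8_t> lumreg, basreg;  // physiologic regions (acinus)
  std::vector<int> regcode;             // initial ring code (acinus)
  std::vector<std::pair<int, int> > entries;  // macrophage entry positions
  std::vector<Agent> agents;
  int counts[N_KINDS];
  int n_mutated;   // tumor cells + mutated stem cells
  int bm_count, bm_initial;
  long cum_tu_deaths;
  bool detection;
  int next_id;
  int extinction_step;  // minimal model: first step with no tumor/stem left

  // milestones, -1 = not reached (step index)
  int ms_first_mutation, ms_first_basal, ms_first_caf, ms_first_m2,
      ms_bm_breakdown, ms_first_emt, ms_first_invasion;
  double inv_caf, inv_mut_load, inv_m2m1;  // covariates at BM breakdown

  bool record_events;
  std::vector<int> ev_step, ev_type, ev_kind, ev_id, ev_row, ev_col, ev_detail;

  // timeseries
  int record_every;
  std::vector<double> ts;  // flattened rows
  enum { TS_NCOL = 16 };

  inline int idx(int r, int c) const { return r * W + c; }
  inline bool inside(int r, int c) const {
    return r >= 0 && r < H && c >= 0 && c < W;
  }
  inline bool is_tumoral(const Agent& a) const {
    return a.kind == K_TU || (a.kind == K_STEM && a.mut > 0);
  }

  void event(int type, const Agent& a, int detail) {
    if (!record_events) return;
    ev_step.push_back(step);
    ev_type.push_back(type);
    ev_kind.push_back(a.kind);
    ev_id.push_back(a.id);
    ev_row.push_back(a.row);
    ev_col.push_back(a.col);
    ev_detail.push_back(detail);
  }
  void event_at(int type, const Agent& a, int r, int c, int detail) {
    if (!record_events) return;
    ev_step.push_back(step);
    ev_type.push_back(type);
    ev_kind.push_back(a.kind);
    ev_id.push_back(a.id);
    ev_row.push_back(r);
    ev_col.push_back(c);
    ev_detail.push_back(detail);
  }

  void die(Agent& a, int detail) {
    occ[idx(a.row, a.col)] = 0;
    counts[a.kind]--;
    if (is_tumoral(a)) {
      n_mutated--;
      cum_tu_deaths++;
    }
    a.alive = false;
    event(EV_DEATH, a, detail);
  }

  int spawn(int kind, int r, int c, int mut, int div_left, int kills,
            int ev_type, int detail) {
    Agent a;
    a.id = next_id++;
    a.kind = kind;
    a.row = r;
    a.col = c;
    a.mut = mut;
    a.div_left = div_left;
    a.kills = kills;
    a.age = 0;
    a.emt = false;
    a.alive = true;
    agents.push_back(a);
    occ[idx(r, c)] = (int)agents.size();
    counts[kind]++;
    if (kind == K_TU || (kind == K_STEM && mut > 0)) {
      n_mutated++;
      check_tumoral_position(agents.back());
    }
    event(ev_type, agents.back(), detail);
    return (int)agents.size() - 1;
  }

  // milestone checks when a tumoral cell appears at / moves to a position
  void check_tumoral_position(const Agent& a) {
    if (model != MODEL_ACINUS) return;
    int i = idx(a.row, a.col);
    if (ms_first_basal < 0 && !basreg.empty() && basreg[i])
      ms_first_basal = step;
    if (ms_first_invasion < 0 && regcode[i] >= 4) ms_first_invasion = step;
  }

  void convert_kind(Agent& a, int to) {  // differentiation-style kind change
    int from = a.kind;
    counts[from]--;
    counts[to]++;
    a.kind = to;
    event(EV_DIFF, a, from);
  }

  // ---- neighborhood helpers -------------------------------------------

  // collect free positions (no agent, no passive layer) at Chebyshev
  // distance 1..range; region = optional mask the target must satisfy
  int free_neighbors(int r, int c, int range, const std::vector<uint8_t>* region,
                     int* out_r, int* out_c) {
    int n = 0;
    for (int dr = -range; dr <= range; dr++) {
      int rr = r + dr;
      if (rr < 0 || rr >= H) continue;
      for (int dc = -range; dc <= range; dc++) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int i = idx(rr, cc);
        if (occ[i] == 0 && pas[i] == P_EMPTY &&
            (region == 0 || (*region)[i])) {
          out_r[n] = rr;
          out_c[n] = cc;
          n++;
        }
      }
    }
    return n;
  }

  // collect adjacent (range 1) positions whose passive layer equals `layer`
  int passive_neighbors(int r, int c, int layer, int* out_r, int* out_c) {
    int n = 0;
    for (int dr = -1; dr <= 1; dr++) {
      int rr = r + dr;
      if (rr < 0 || rr >= H) continue;
      for (int dc = -1; dc <= 1; dc++) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        if (pas[idx(rr, cc)] == layer) {
          out_r[n] = rr;
          out_c[n] = cc;
          n++;
        }
      }
    }
    return n;
  }

  // collect adjacent agents of a given kind (alive); returns agent indices
  int kind_neighbors(int r, int c, int kind, int* out) {
    int n = 0;
    for (int dr = -1; dr <= 1; dr++) {
      int rr = r + dr;
      if (rr < 0 || rr >= H) continue;
      for (int dc = -1; dc <= 1; dc++) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int o = occ[idx(rr, cc)];
        if (o > 0 && agents[o - 1].kind == kind) out[n++] = o - 1;
      }
    }
    return n;
  }

  bool has_kind_neighbor(int r, int c, int kind) {
    int buf[8];
    return kind_neighbors(r, c, kind, buf) > 0;
  }

  // adjacent tumoral agents (tumor, or stem with mutations)
  int tumoral_neighbors(int r, int c, int* out) {
    int n = 0;
    for (int dr = -1; dr <= 1; dr++) {
      int rr = r + dr;
      if (rr < 0 || rr >= H) continue;
      for (int dc = -1; dc <= 1; dc++) {
        if (dr == 0 && dc == 0) continue;
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        int o = occ[idx(rr, cc)];
        if (o > 0 && is_tumoral(agents[o - 1])) out[n++] = o - 1;
      }
    }
    return n;
  }

  // any tumoral agent within Chebyshev distance `range` of (r, c)?
  bool tumoral_within(int r, int c, int range) {
    if (n_mutated == 0) return false;
    int r0 = std::max(0, r - range), r1 = std::min(H - 1, r + range);
    int c0 = std::max(0, c - range), c1 = std::min(W - 1, c + range);
    for (int rr = r0; rr <= r1; rr++)
      for (int cc = c0; cc <= c1; cc++) {
        int o = occ[idx(rr, cc)];
        if (o > 0 && is_tumoral(agents[o - 1])) return true;
      }
    return false;
  }

  // nearest tumoral agent within sensing radius (ties broken uniformly);
  // returns agent index or -1
  int nearest_tumoral(int r, int c, int range) {
    if (n_mutated == 0) return -1;
    int best = range + 1;
    std::vector<int> cand;
    int r0 = std::max(0, r - range), r1 = std::min(H - 1, r + range);
    int c0 = std::max(0, c - range), c1 = std::min(W - 1, c + range);
    for (int rr = r0; rr <= r1; rr++)
      for (int cc = c0; cc <= c1; cc++) {
        int o = occ[idx(rr, cc)];
        if (o > 0 && is_tumoral(agents[o - 1])) {
          int d = std::max(std::abs(rr - r), std::abs(cc - c));
          if (d < best) {
            best = d;
            cand.clear();
            cand.push_back(o - 1);
          } else if (d == best) {
            cand.push_back(o - 1);
          }
        }
      }
    if (cand.empty()) return -1;
    return cand[ri((int)cand.size())];
  }

  void move_agent(Agent& a, int r, int c) {
    occ[idx(a.row, a.col)] = 0;
    a.row = r;
    a.col = c;
    occ[idx(r, c)] = (int)(&a - &agents[0]) + 1;
    event(EV_MIG, a, 0);
    if (is_tumoral(a)) check_tumoral_position(a);
  }

  // ---- per-agent turns -------------------------------------------------

  // shared proliferation: mother decrements its remaining budget, daughter
  // inherits the decremented value (lineage division budget)
  void divide_into(Agent& a, int kind, int tr, int tc, int dmut, int ddiv) {
    if (a.div_left != DIV_INF) a.div_left--;
    spawn(kind, tr, tc, dmut, ddiv, 0, EV_BIRTH, a.id);
  }

  void turn_luminal(Agent& a) {
    if (a.div_left == 0) { die(a, D_EXHAUST); return; }
    if (bern(P.LCpdeath)) { die(a, D_SPONT); return; }
    if (bern(P.LCpprol)) {
      int nr[8], nc[8];
      int n = free_neighbors(a.row, a.col, 1, lumreg.empty() ? 0 : &lumreg,
                             nr, nc);
      if (n > 0) {
        int k = ri(n);
        int d = a.div_left == DIV_INF ? DIV_INF : a.div_left - 1;
        divide_into(a, K_LUM, nr[k], nc[k], 0, d);
      }
    }
    if (bern(P.TUpmut)) {  // luminal cell converts into a tumor cell
      convert_kind(a, K_TU);
      a.mut = 1;
      if (a.div_left != DIV_INF) a.div_left += P.TUaddedMax;
      n_mutated++;
      event(EV_MUT, a, a.mut);
      if (ms_first_mutation < 0) ms_first_mutation = step;
      check_tumoral_position(a);
    }
  }

  // stem cell in the healthy acinus epithelium: luminal behavior, no
  // exhaustion, daughters are luminal (or stem with prob SCrenew)
  void turn_stem_epithelial(Agent& a) {
    // stem cells are exempt from spontaneous death (self-renewing pool);
    // in the acinus they can still be killed by macrophages once mutated
    if (bern(P.LCpprol)) {
      int nr[8], nc[8];
      int n = free_neighbors(a.row, a.col, 1, lumreg.empty() ? 0 : &lumreg,
                             nr, nc);
      if (n > 0) {
        int k = ri(n);
        if (bern(P.SCrenew))
          divide_into(a, K_STEM, nr[k], nc[k], 0, DIV_INF);
        else
          divide_into(a, K_LUM, nr[k], nc[k], 0, P.TUpmax);
      }
    }
    if (P.stem_mutation && bern(P.TUpmut)) {
      a.mut = 1;  // kind stays stem; behaves as tumor from now on
      n_mutated++;
      event(EV_MUT, a, a.mut);
      if (ms_first_mutation < 0) ms_first_mutation = step;
      check_tumoral_position(a);
    }
  }

  // tumor cells, and stem cells behaving as tumor (minimal model, or
  // mutated stem in the acinus)
  void turn_tumoral(Agent& a) {
    bool is_stem = a.kind == K_STEM;
    if (!is_stem && a.div_left == 0) { die(a, D_EXHAUST); return; }
    if (bern(is_stem ? P.SCpdeath : P.TUpdeath)) { die(a, D_SPONT); return; }

    bool caf_adj = counts[K_CAF] > 0 && has_kind_neighbor(a.row, a.col, K_CAF);
    bool m2_adj = counts[K_M2] > 0 && has_kind_neighbor(a.row, a.col, K_M2);

    double p_eff = clamp01(P.TUpprol + a.mut * P.TUaddedProl +
                           (caf_adj ? P.CFprom : 0.0) +
                           (m2_adj ? P.M2TUadd : 0.0));
    if (bern(p_eff)) {
      int nr[8], nc[8];
      int n = free_neighbors(a.row, a.col, 1, 0, nr, nc);
      if (n > 0) {
        int k = ri(n);
        if (is_stem) {
          if (bern(P.SCrenew))
            divide_into(a, K_STEM, nr[k], nc[k], a.mut, DIV_INF);
          else
            divide_into(a, K_TU, nr[k], nc[k], a.mut,
                        P.TUpmax + a.mut * P.TUaddedMax);
        } else {
          divide_into(a, K_TU, nr[k], nc[k], a.mut, a.div_left - 1);
        }
      }
    }

    bool may_mutate = !is_stem || P.stem_mutation;
    if (may_mutate &&
        bern(clamp01(P.TUpmut * (1.0 + a.mut * P.TUmutEscalation)))) {
      bool was_tumoral = is_tumoral(a);
      a.mut++;
      if (!was_tumoral) n_mutated++;  // stem gaining its first mutation
      if (a.div_left != DIV_INF) a.div_left += P.TUaddedMax;
      event(EV_MUT, a, a.mut);
      if (ms_first_mutation < 0) ms_first_mutation = step;
      check_tumoral_position(a);
    }

    if (model == MODEL_ACINUS && a.mut >= P.TUthrshBM && bern(P.TUpkill)) {
      int nr[8], nc[8];
      int n = passive_neighbors(a.row, a.col, P_BM, nr, nc);
      if (n > 0) {
        int k = ri(n);
        pas[idx(nr[k], nc[k])] = P_EMPTY;
        bm_count--;
        event_at(EV_BREAK, a, nr[k], nc[k], P_BM);
        if (ms_bm_breakdown < 0) {
          ms_bm_breakdown = step;
          capture_invasion_covariates();
        }
      }
    }
    if (model == MODEL_ACINUS && a.mut >= P.TUthrshM && bern(P.TUpMdiff)) {
      int buf[8];
      int n = kind_neighbors(a.row, a.col, K_M1, buf);
      if (n > 0) polarize_m2(agents[buf[ri(n)]]);
    }
    if (model == MODEL_ACINUS && a.mut >= P.TUthrshMMP && bern(P.TUpMMP)) {
      int nr[8], nc[8];
      int n = passive_neighbors(a.row, a.col, P_ECM, nr, nc);
      if (n > 0) {
        int k = ri(n);
        pas[idx(nr[k], nc[k])] = P_EMPTY;
        event_at(EV_BREAK, a, nr[k], nc[k], P_ECM);
      }
    }

    if (!a.emt) {  // EMT is promoted by CAF or M2 proximity; irreversible
      if (caf_adj && bern(P.CFemt)) a.emt = true;
      if (!a.emt && m2_adj && bern(P.M2emt)) a.emt = true;
      if (a.emt) {
        event(EV_EMT, a, 0);
        if (ms_first_emt < 0) ms_first_emt = step;
      }
    }
    if (a.emt && bern(P.TUpmig)) {
      int nr[8], nc[8];
      int n = free_neighbors(a.row, a.col, 1, 0, nr, nc);
      if (n > 0) {
        int k = ri(n);
        move_agent(a, nr[k], nc[k]);
      }
    }
  }

  void turn_basal(Agent& a) {
    if (a.div_left == 0) { die(a, D_EXHAUST); return; }
    // must remain attached to the basement membrane to survive
    int nr[8], nc[8];
    if (passive_neighbors(a.row, a.col, P_BM, nr, nc) == 0) {
      die(a, D_DETACH);
      return;
    }
    if (bern(P.BCpdeath)) { die(a, D_SPONT); return; }
    if (bern(P.BCpprol)) {
      int n = free_neighbors(a.row, a.col, 1, basreg.empty() ? 0 : &basreg,
                             nr, nc);
      if (n > 0) {
        int k = ri(n);
        divide_into(a, K_BAS, nr[k], nc[k], 0,
                    a.div_left == DIV_INF ? DIV_INF : a.div_left - 1);
      }
    }
  }

  void turn_fibroblast(Agent& a) {
    if (model == MODEL_CULTURE) {  // in vitro fibroblasts proliferate freely
      if (a.div_left == 0) { die(a, D_EXHAUST); return; }
      if (bern(P.Fpdeath)) { die(a, D_SPONT); return; }
      if (bern(P.Fpprol)) {
        int nr[8], nc[8];
        int n = free_neighbors(a.row, a.col, 1, 0, nr, nc);
        if (n > 0) {
          int k = ri(n);
          divide_into(a, K_FIB, nr[k], nc[k], 0, a.div_left - 1);
        }
      }
      return;
    }
    // tissue fibroblasts are quiescent; tumor proximity can convert them
    if (tumoral_within(a.row, a.col, P.caf_induction_range) && bern(P.Fdiff)) {
      convert_kind(a, K_CAF);
      a.div_left = P.Fpmax;
      if (ms_first_caf < 0) ms_first_caf = step;
    }
  }

  void turn_caf(Agent& a) {
    if (a.div_left == 0) { die(a, D_EXHAUST); return; }
    if (bern(P.CFpdeath)) { die(a, D_SPONT); return; }
    if (bern(P.CFpprol)) {
      int nr[8], nc[8];
      int n = free_neighbors(a.row, a.col, 1, 0, nr, nc);
      if (n > 0) {
        int k = ri(n);
        divide_into(a, K_CAF, nr[k], nc[k], 0, a.div_left - 1);
      }
    }
    if (bern(P.CFmmp)) {  // break down one adjacent ECM position
      int nr[8], nc[8];
      int n = passive_neighbors(a.row, a.col, P_ECM, nr, nc);
      if (n > 0) {
        int k = ri(n);
        pas[idx(nr[k], nc[k])] = P_EMPTY;
        event_at(EV_BREAK, a, nr[k], nc[k], P_ECM);
      }
    }
    if (bern(P.CFmdiff)) {  // polarize one adjacent M1 toward M2
      int buf[8];
      int n = kind_neighbors(a.row, a.col, K_M1, buf);
      if (n > 0) polarize_m2(agents[buf[ri(n)]]);
    }
  }

  void polarize_m2(Agent& m) {
    convert_kind(m, K_M2);
    if (m.kills > P.M2kmax) m.kills = P.M2kmax;
    if (ms_first_m2 < 0) ms_first_m2 = step;
  }

  void turn_macrophage(Agent& a) {
    if (a.kills == 0) { die(a, D_EXHAUST); return; }
    if (bern(P.M1pdeath)) { die(a, D_SPONT); return; }
    double pk = a.kind == K_M1 ? P.M1pkill : P.M2pkill;
    if (bern(pk)) {
      int buf[8];
      int n = tumoral_neighbors(a.row, a.col, buf);
      if (n > 0) {
        Agent& victim = agents[buf[ri(n)]];
        event_at(EV_KILL, a, victim.row, victim.col, victim.id);
        die(victim, D_KILLED);
        a.kills--;
      }
    }
    if (bern(P.M1pmig)) {
      int range = P.macrophage_move_range;
      int target = nearest_tumoral(a.row, a.col, P.sensing_radius);
      int nr[24], nc[24];
      int n = free_neighbors(a.row, a.col, range, 0, nr, nc);
      if (target >= 0) {
        // chemotactic move: minimize Chebyshev distance to the sensed cell,
        // never move to a position farther than where we stand
        int tr = agents[target].row, tc = agents[target].col;
        int cur = std::max(std::abs(tr - a.row), std::abs(tc - a.col));
        int best = cur;
        int br[24], bc[24], nb = 0;
        for (int i = 0; i < n; i++) {
          int d = std::max(std::abs(tr - nr[i]), std::abs(tc - nc[i]));
          if (d < best) {
            best = d;
            nb = 0;
            br[nb] = nr[i];
            bc[nb] = nc[i];
            nb = 1;
          } else if (d == best && best < cur) {
            br[nb] = nr[i];
            bc[nb] = nc[i];
            nb++;
          }
        }
        if (nb > 0) {
          int k = ri(nb);
          move_agent(a, br[k], bc[k]);
        }
      } else if (n > 0) {
        int k = ri(n);
        move_agent(a, nr[k], nc[k]);
      }
    }
  }

  void capture_invasion_covariates() {
    inv_caf = counts[K_CAF];
    long mut_sum = 0;
    int mut_n = 0;
    for (size_t i = 0; i < agents.size(); i++) {
      const Agent& a = agents[i];
      if (a.alive && is_tumoral(a)) {
        mut_sum += a.mut;
        mut_n++;
      }
    }
    inv_mut_load = mut_n > 0 ? (double)mut_sum / mut_n : NA_REAL;
    inv_m2m1 = counts[K_M1] > 0 ? (double)counts[K_M2] / counts[K_M1]
                                : NA_REAL;
  }

  // ---- scheduler -------------------------------------------------------

  // snapshot the indices of alive agents of the given kinds, shuffled;
  // agents born during the round do not act until the next step
  void round_over(const std::vector<int>& kinds) {
    std::vector<int> sel;
    bool want[N_KINDS] = {false};
    for (size_t i = 0; i < kinds.size(); i++) want[kinds[i]] = true;
    for (size_t i = 0; i < agents.size(); i++)
      if (agents[i].alive && want[agents[i].kind]) sel.push_back((int)i);
    // each agent divides at most once per round: reserving now guarantees
    // no reallocation while Agent& references are held inside a turn
    agents.reserve(agents.size() + sel.size() + 4);
    // Fisher-Yates shuffle
    for (int i = (int)sel.size() - 1; i > 0; i--) {
      int j = ri(i + 1);
      std::swap(sel[i], sel[j]);
    }
    for (size_t i = 0; i < sel.size(); i++) {
      Agent& a = agents[sel[i]];
      if (!a.alive) continue;  // killed earlier in this round
      int kind = a.kind;       // dispatch on kind at turn start
      switch (kind) {
        case K_LUM:
          turn_luminal(a);
          break;
        case K_STEM:
          if (model == MODEL_ACINUS && a.mut == 0)
            turn_stem_epithelial(a);
          else
            turn_tumoral(a);
          break;
        case K_TU:
          turn_tumoral(a);
          break;
        case K_BAS:
          turn_basal(a);
          break;
        case K_FIB:
          turn_fibroblast(a);
          break;
        case K_CAF:
          turn_caf(a);
          break;
        case K_M1:
        case K_M2:
          turn_macrophage(a);
          break;
      }
      if (a.alive) a.age++;
    }
  }

  void macrophage_influx() {
    if (entries.empty()) return;
    if (!detection || !P.sticky_detection) {
      bool seen = false;
      if (n_mutated > 0) {
        for (size_t i = 0; i < agents.size() && !seen; i++) {
          const Agent& a = agents[i];
          if (a.alive && (a.kind == K_M1 || a.kind == K_M2) &&
              tumoral_within(a.row, a.col, P.sensing_radius))
            seen = true;
        }
      }
      if (P.sticky_detection)
        detection = detection || seen;
      else
        detection = seen;
    }
    double p_in = clamp01(P.M1influxProb + (detection ? P.M1influxadd : 0.0));
    if (bern(p_in)) {
      int fr[16], fc[16], n = 0;
      for (size_t i = 0; i < entries.size(); i++) {
        int j = idx(entries[i].first, entries[i].second);
        if (occ[j] == 0 && pas[j] == P_EMPTY && n < 16) {
          fr[n] = entries[i].first;
          fc[n] = entries[i].second;
          n++;
        }
      }
      if (n > 0) {
        int k = ri(n);
        spawn(K_M1, fr[k], fc[k], 0, DIV_INF, P.M1kmax, EV_INFLUX, 0);
      }
    }
  }

  void step_once() {
    step++;
    std::vector<int> r1, r2, r3;
    if (model == MODEL_MINIMAL) {
      r1.push_back(K_STEM);
      r1.push_back(K_TU);
      round_over(r1);
      return;
    }
    if (model == MODEL_CULTURE) {
      r1.push_back(K_STEM);
      r1.push_back(K_TU);
      round_over(r1);
      r3.push_back(K_FIB);
      r3.push_back(K_CAF);
      round_over(r3);
      std::vector<int> r4;
      r4.push_back(K_M1);
      r4.push_back(K_M2);
      round_over(r4);
      return;
    }
    // acinus: (1) luminal + stem + tumor, (2) basal, (3) fibroblast + CAF,
    // (4) macrophage influx then resident macrophages
    r1.push_back(K_LUM);
    r1.push_back(K_STEM);
    r1.push_back(K_TU);
    round_over(r1);
    r2.push_back(K_BAS);
    round_over(r2);
    r3.push_back(K_FIB);
    r3.push_back(K_CAF);
    round_over(r3);
    macrophage_influx();
    std::vector<int> r4;
    r4.push_back(K_M1);
    r4.push_back(K_M2);
    round_over(r4);
  }

  void record_row() {
    double stem_pct = NA_REAL;
    int denom = counts[K_STEM] + counts[K_TU];
    stem_pct = denom > 0 ? 100.0 * counts[K_STEM] / denom : 0.0;
    long mut_sum = 0;
    int mut_n = 0;
    if (n_mutated > 0) {
      for (size_t i = 0; i < agents.size(); i++) {
        const Agent& a = agents[i];
        if (a.alive && is_tumoral(a)) {
          mut_sum += a.mut;
          mut_n++;
        }
      }
    }
    double mmut = mut_n > 0 ? (double)mut_sum / mut_n : NA_REAL;
    double m2m1 = counts[K_M1] > 0 ? (double)counts[K_M2] / counts[K_M1]
                                   : NA_REAL;
    ts.push_back(step);
    ts.push_back(step / 2.0);  // days
    for (int k = 0; k < N_KINDS; k++) ts.push_back(counts[k]);
    ts.push_back(n_mutated);
    ts.push_back(stem_pct);
    ts.push_back(mmut);
    ts.push_back(m2m1);
    ts.push_back(bm_count);
    ts.push_back((double)cum_tu_deaths);
  }

  void run(int n_steps) {
    record_row();  // state on entry
    for (int s = 0; s < n_steps; s++) {
      step_once();
      bool last = (s == n_steps - 1);
      bool extinct = false;
      if (model != MODEL_ACINUS && extinction_step < 0 &&
          counts[K_STEM] + counts[K_TU] == 0) {
        extinction_step = step;
        extinct = (model == MODEL_MINIMAL);
      }
      if (step % record_every == 0 || last || extinct) record_row();
      if (extinct) break;  // minimal model: nothing left that can act
      if (s % 200 == 199) Rcpp::checkUserInterrupt();
    }
  }
};

static std::vector<uint8_t> mask_from(const RObject& o, int H, int W) {
  std::vector<uint8_t> m;
  if (o.isNULL()) return m;
  LogicalMatrix lm = as<LogicalMatrix>(o);
  m.resize((size_t)H * W, 0);
  for (int r = 0; r < H; r++)
    for (int c = 0; c < W; c++) m[r * W + c] = lm(r, c) == TRUE ? 1 : 0;
  return m;
}

// [[Rcpp::export]]
List cpp_simulate(List state, List params, int n_steps, int model,
                  int record_every, bool record_events) {
  Sim S;
  S.model = model;
  S.P = read_params(params);
  S.W = as<int>(state["width"]);
  S.H = as<int>(state["height"]);
  S.step = as<int>(state["step_index"]);
  S.record_every = record_every < 1 ? 1 : record_every;
  S.record_events = record_events;
  S.detection = as<bool>(state["detection"]);
  S.next_id = as<int>(state["next_id"]);
  S.extinction_step = -1;
  S.ms_first_mutation = S.ms_first_basal = S.ms_first_caf = S.ms_first_m2 =
      S.ms_bm_breakdown = S.ms_first_emt = S.ms_first_invasion = -1;
  S.inv_caf = S.inv_mut_load = S.inv_m2m1 = NA_REAL;

  IntegerMatrix pm = state["passive"];
  if (pm.nrow() != S.H || pm.ncol() != S.W)
    stop("passive matrix does not match grid dimensions");
  S.pas.resize((size_t)S.H * S.W);
  S.bm_count = 0;
  for (int r = 0; r < S.H; r++)
    for (int c = 0; c < S.W; c++) {
      S.pas[r * S.W + c] = pm(r, c);
      if (pm(r, c) == P_BM) S.bm_count++;
    }
  S.bm_initial = S.bm_count;

  S.lumreg = mask_from(state["luminal_region"], S.H, S.W);
  S.basreg = mask_from(state["basal_region"], S.H, S.W);
  RObject rc = state["region_code"];
  if (!rc.isNULL()) {
    IntegerMatrix rm = as<IntegerMatrix>(rc);
    S.regcode.resize((size_t)S.H * S.W);
    for (int r = 0; r < S.H; r++)
      for (int c = 0; c < S.W; c++) S.regcode[r * S.W + c] = rm(r, c);
  } else if (model == MODEL_ACINUS) {
    stop("acinus model requires a region_code matrix");
  }
  RObject en = state["entry"];
  if (!en.isNULL()) {
    IntegerMatrix em = as<IntegerMatrix>(en);
    for (int i = 0; i < em.nrow(); i++)
      S.entries.push_back(std::make_pair(em(i, 0), em(i, 1)));
  }

  DataFrame adf = as<DataFrame>(state["agents"]);
  IntegerVector aid = adf["id"], akind = adf["kind"], arow = adf["row"],
                acol = adf["col"], amut = adf["mutations"],
                adiv = adf["divisions_left"], akill = adf["kills_left"],
                aage = adf["age"];
  LogicalVector aemt = adf["emt"];
  int n0 = aid.size();
  S.occ.assign((size_t)S.H * S.W, 0);
  for (int k = 0; k < N_KINDS; k++) S.counts[k] = 0;
  S.n_mutated = 0;
  S.cum_tu_deaths = 0;
  S.agents.reserve(n0 + 1024);
  for (int i = 0; i < n0; i++) {
    Agent a;
    a.id = aid[i];
    a.kind = akind[i];
    a.row = arow[i];
    a.col = acol[i];
    a.mut = amut[i];
    a.div_left = adiv[i];
    a.kills = akill[i];
    a.age = aage[i];
    a.emt = aemt[i] == TRUE;
    a.alive = true;
    if (a.kind < 0 || a.kind >= N_KINDS) stop("unknown agent kind");
    if (a.row < 0 || a.row >= S.H || a.col < 0 || a.col >= S.W)
      stop("agent position outside the grid");
    int j = a.row * S.W + a.col;
    if (S.occ[j] != 0) stop("two agents share a grid position");
    if (S.pas[j] != P_EMPTY)
      stop("agent placed on a basement-membrane or ECM position");
    S.agents.push_back(a);
    S.occ[j] = (int)S.agents.size();
    S.counts[a.kind]++;
    if (a.kind == K_TU || (a.kind == K_STEM && a.mut > 0)) S.n_mutated++;
  }

  S.run(n_steps);

  // pack timeseries
  int nrow = (int)(S.ts.size() / Sim::TS_NCOL);
  NumericMatrix tsm(nrow, Sim::TS_NCOL);
  for (int i = 0; i < nrow; i++)
    for (int j = 0; j < Sim::TS_NCOL; j++)
      tsm(i, j) = S.ts[i * Sim::TS_NCOL + j];
  colnames(tsm) = CharacterVector::create(
      "step", "days", "n_luminal", "n_basal", "n_stem", "n_tumor",
      "n_fibroblast", "n_caf", "n_m1", "n_m2", "n_mutated", "stem_pct",
      "mean_mutations", "m2_m1_ratio", "bm_count", "cum_tumor_deaths");

  // pack surviving agents
  std::vector<int> alive_idx;
  for (size_t i = 0; i < S.agents.size(); i++)
    if (S.agents[i].alive) alive_idx.push_back((int)i);
  int na = (int)alive_idx.size();
  IntegerVector oid(na), okind(na), orow(na), ocol(na), omut(na), odiv(na),
      okill(na), oage(na);
  LogicalVector oemt(na);
  for (int i = 0; i < na; i++) {
    const Agent& a = S.agents[alive_idx[i]];
    oid[i] = a.id;
    okind[i] = a.kind;
    orow[i] = a.row;
    ocol[i] = a.col;
    omut[i] = a.mut;
    odiv[i] = a.div_left;
    okill[i] = a.kills;
    oage[i] = a.age;
    oemt[i] = a.emt;
  }
  DataFrame agents_out = DataFrame::create(
      _["id"] = oid, _["kind"] = okind, _["row"] = orow, _["col"] = ocol,
      _["mutations"] = omut, _["divisions_left"] = odiv,
      _["kills_left"] = okill, _["emt"] = oemt, _["age"] = oage);

  IntegerMatrix pas_out(S.H, S.W);
  for (int r = 0; r < S.H; r++)
    for (int c = 0; c < S.W; c++) pas_out(r, c) = S.pas[r * S.W + c];

  List events = R_NilValue;
  if (record_events) {
    events = DataFrame::create(
        _["step"] = wrap(S.ev_step), _["type"] = wrap(S.ev_type),
        _["kind"] = wrap(S.ev_kind), _["id"] = wrap(S.ev_id),
        _["row"] = wrap(S.ev_row), _["col"] = wrap(S.ev_col),
        _["detail"] = wrap(S.ev_detail));
  }

  IntegerVector ms = IntegerVector::create(
      _["first_mutation"] = S.ms_first_mutation,
      _["first_basal_occupancy"] = S.ms_first_basal,
      _["first_caf"] = S.ms_first_caf, _["first_m2"] = S.ms_first_m2,
      _["bm_breakdown"] = S.ms_bm_breakdown,
      _["first_emt"] = S.ms_first_emt,
      _["first_invasion"] = S.ms_first_invasion);
  for (int i = 0; i < ms.size(); i++)
    if (ms[i] < 0) ms[i] = NA_INTEGER;

  return List::create(
      _["timeseries"] = tsm, _["agents"] = agents_out,
      _["passive"] = pas_out, _["events"] = events, _["milestones"] = ms,
      _["detection"] = S.detection, _["next_id"] = S.next_id,
      _["step_index"] = S.step,
      _["extinction_step"] =
          S.extinction_step < 0 ? NA_INTEGER : S.extinction_step,
      _["bm_initial"] = S.bm_initial,
      _["invasion_covariates"] = NumericVector::create(
          _["n_caf"] = S.inv_caf, _["mean_mutations"] = S.inv_mut_load,
          _["m2_m1_ratio"] = S.inv_m2m1));
}

// Moore neighborhood of Chebyshev range 1..range, clipped at borders,
// row-major order; 0-based coordinates
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_neighborhood(int row, int col, int range, int height,
                               int width) {
  if (row < 0 || row >= height || col < 0 || col >= width)
    stop("position outside the grid");
  if (range < 1) stop("range must be >= 1");
  std::vector<int> rs, cs;
  for (int dr = -range; dr <= range; dr++) {
    int rr = row + dr;
    if (rr < 0 || rr >= height) continue;
    for (int dc = -range; dc <= range; dc++) {
      if (dr == 0 && dc == 0) continue;
      int cc = col + dc;
      if (cc < 0 || cc >= width) continue;
      rs.push_back(rr);
      cs.push_back(cc);
    }
  }
  IntegerMatrix out((int)rs.size(), 2);
  for (size_t i = 0; i < rs.size(); i++) {
    out(i, 0) = rs[i];
    out(i, 1) = cs[i];
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}
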