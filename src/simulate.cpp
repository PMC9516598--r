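#include <Rcpp.h>
using namespace Rcpp;

// State codes, matching HEALTH_STATES order in R/markov.R
enum State {
  SOUND = 0, E2 = 1, D1 = 2, D2D3 = 3, ARRESTED = 4, RESTORED = 5,
  CROWNED = 6, ROOT_FILLED = 7, RETREAT_NONSURG = 8, RETREAT_SURG = 9,
  EXTRACTED = 10
};

// Cost indices, matching COST_NAMES order in R/parameters.R
enum Cost {
  C_RADIOGRAPH = 0, C_VT_EXAM = 1, C_AI = 2, C_INFILTRATION = 3,
  C_RESTORATION = 4, C_REPAIR = 5, C_REPLACEMENT = 6, C_CROWN = 7,
  C_CROWN_REPL = 8, C_ROOT_CANAL = 9, C_RETREAT_NS = 10, C_RETREAT_S = 11,
  C_EXTRACTION = 12, C_IMPLANT = 13
};

// Transition indices, matching TRANSITION_NAMES order
enum Trans {
  T_SOUND_E2 = 0, T_E2_D1 = 1, T_D1_D2D3 = 2, T_ARREST_FAIL = 3,
  T_REST_FAIL = 4, T_CROWN_FAIL = 5, T_ENDO = 6, T_ROOTFILL_FAIL = 7,
  T_RETREAT_FAIL = 8, T_SURG_FAIL = 9
};

static inline double cap1(double p) { return p > 1.0 ? 1.0 : p; }

// Simulate one cohort of independent teeth over the horizon for one
// strategy under one point-valued parameter set. Per-cycle order matches
// the R reference (simulate_tooth): exam fees -> examine/treat ->
// natural progression -> treated-state failures. Uses R's RNG so that
// set.seed() in R governs reproducibility.
// [[Rcpp::export]]
List sim_cohort_cpp(int n_teeth, int horizon,
                    NumericVector init_prev,   // sound, E2, D1, D2D3
                    NumericVector trans,       // 10, TRANSITION_NAMES order
                    double mult,               // progression multiplier
                    int k_crown, double p_repair,
                    NumericVector rad_acc,     // sensE2, sensD1, sensD2D3, spec
                    NumericVector vt_acc,      // sensD2D3, spec
                    double fp_adv_share,
                    int vt_every, int rad_every,
                    NumericVector costs,       // 14, COST_NAMES order
                    bool use_ai, double ai_teeth_per_app,
                    double discount_rate) {
  NumericVector retention(n_teeth), total_cost(n_teeth);
  IntegerVector final_state(n_teeth);

  // per-cycle discount factors
  std::vector<double> disc(horizon);
  for (int t = 0; t < horizon; ++t)
    disc[t] = std::pow(1.0 + discount_rate, -t);

  double p_sound_e2 = cap1(trans[T_SOUND_E2] * mult);
  double p_e2_d1 = cap1(trans[T_E2_D1] * mult);
  double p_d1_d2d3 = cap1(trans[T_D1_D2D3] * mult);
  double ai_fee = use_ai ? costs[C_AI] / ai_teeth_per_app : 0.0;

  for (int i = 0; i < n_teeth; ++i) {
    // initial state draw
    double u = unif_rand();
    int state;
    if (u < init_prev[0]) state = SOUND;
    else if (u < init_prev[0] + init_prev[1]) state = E2;
    else if (u < init_prev[0] + init_prev[1] + init_prev[2]) state = D1;
    else state = D2D3;

    int rest_failures = 0;
    bool crown_replaced = false;
    double ret = 0.0, cost = 0.0;

    for (int t = 0; t < horizon; ++t) {
      if (state == EXTRACTED) break;
      ret += 1.0;  // cycle entered with the tooth in situ
      bool rad = (t % rad_every) == 0;
      bool vt = (t % vt_every) == 0;

      // examination fees
      if (vt) cost += costs[C_VT_EXAM] * disc[t];
      if (rad) {
        cost += costs[C_RADIOGRAPH] * disc[t];
        cost += ai_fee * disc[t];
      }

      // examine and treat
      if (vt || rad) {
        if (state == SOUND || state == ARRESTED) {
          double fp_rad = rad ? 1.0 - rad_acc[3] : 0.0;
          double fp_vt = vt ? 1.0 - vt_acc[1] : 0.0;
          double p_fp = 1.0 - (1.0 - fp_rad) * (1.0 - fp_vt);
          if (unif_rand() < p_fp) {
            if (unif_rand() < fp_adv_share) {
              state = RESTORED;           // sound tooth enters the cascade
              cost += costs[C_RESTORATION] * disc[t];
            } else {
              cost += costs[C_INFILTRATION] * disc[t];
            }
          }
        } else if (state == E2 || state == D1) {
          double p_det = rad ? rad_acc[state == E2 ? 0 : 1] : 0.0;
          if (unif_rand() < p_det) {
            state = ARRESTED;
            cost += costs[C_INFILTRATION] * disc[t];
          }
        } else if (state == D2D3) {
          double p_rad = rad ? rad_acc[2] : 0.0;
          double p_vt = vt ? vt_acc[0] : 0.0;
          double p_det = 1.0 - (1.0 - p_rad) * (1.0 - p_vt);
          if (unif_rand() < p_det) {
            state = RESTORED;
            cost += costs[C_RESTORATION] * disc[t];
          }
        }
      }

      // natural progression (untreated states, at most one step)
      switch (state) {
        case SOUND: if (unif_rand() < p_sound_e2) state = E2; break;
        case E2: if (unif_rand() < p_e2_d1) state = D1; break;
        case D1: if (unif_rand() < p_d1_d2d3) state = D2D3; break;
        case ARRESTED: if (unif_rand() < trans[T_ARREST_FAIL]) state = D1; break;
        default: break;
      }

      // treated-state failures and cascade progression
      if (state == RESTORED || state == CROWNED) {
        if (unif_rand() < trans[T_ENDO]) {
          state = ROOT_FILLED;
          cost += costs[C_ROOT_CANAL] * disc[t];
        } else if (state == RESTORED) {
          if (unif_rand() < trans[T_REST_FAIL]) {
            ++rest_failures;
            if (rest_failures >= k_crown) {
              state = CROWNED;
              cost += costs[C_CROWN] * disc[t];
            } else if (unif_rand() < p_repair) {
              cost += costs[C_REPAIR] * disc[t];
            } else {
              cost += costs[C_REPLACEMENT] * disc[t];
            }
          }
        } else {  // CROWNED
          if (unif_rand() < trans[T_CROWN_FAIL]) {
            if (!crown_replaced) {
              crown_replaced = true;
              cost += costs[C_CROWN_REPL] * disc[t];
            } else {
              state = ROOT_FILLED;
              cost += costs[C_ROOT_CANAL] * disc[t];
            }
          }
        }
      } else if (state == ROOT_FILLED) {
        if (unif_rand() < trans[T_ROOTFILL_FAIL]) {
          state = RETREAT_NONSURG;
          cost += costs[C_RETREAT_NS] * disc[t];
        }
      } else if (state == RETREAT_NONSURG) {
        if (unif_rand() < trans[T_RETREAT_FAIL]) {
          state = RETREAT_SURG;
          cost += costs[C_RETREAT_S] * disc[t];
        }
      } else if (state == RETREAT_SURG) {
        if (unif_rand() < trans[T_SURG_FAIL]) {
          state = EXTRACTED;
          cost += (costs[C_EXTRACTION] + costs[C_IMPLANT]) * disc[t];
        }
      }
    }
    retention[i] = ret;
    total_cost[i] = cost;
    final_state[i] = state;
  }

  return List::create(_["retention_years"] = retention,
                      _["discounted_cost"] = total_cost,
                      _["final_state"] = final_state);
}
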