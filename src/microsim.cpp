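// Monte Carlo life-course engine.
//
// One woman = one reproducible PCG32 stream keyed by (master seed, cohort,
// woman index), so the same woman carries identical latent randomness through
// every scenario arm (common random numbers). Other-cause death and benign
// hysterectomy months are pre-drawn by inverse CDF from their marginal
// monthly-probability processes; the monthly loop then resolves scheduled
// screening contacts and disease transitions. Within a cycle, symptomatic
// presentation of a preclinical cancer resolves first (before any scheduled
// contact, so it never coincides with an attended screen), then contacts,
// then the remaining competing events in the fixed order death >
// hysterectomy > disease transition — exactly the algebra of the
// deterministic cohort solver.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Pcg32 {
  uint64_t state = 0, inc = 1;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xs = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xs >> rot) | (xs << ((32u - rot) & 31u));
  }
  double u01() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

enum State { HEALTHY = 0, HPV = 1, PREC = 2, PRECL = 3, DIAG = 4, HYST = 5, DEAD = 6 };

// first month >= m0 at which the marginal process fires, conditional on not
// having fired before m0; returns n_months when it never fires
inline int draw_event_month(const double* cdf, int n_months, double u, int m0) {
  double prior = (m0 > 0) ? cdf[m0 - 1] : 0.0;
  double tail = 1.0 - prior;
  if (tail <= 0.0) return n_months;
  double target = prior + u * tail;
  const double* hit = std::lower_bound(cdf + m0, cdf + n_months, target);
  return (int)(hit - cdf);
}

struct Cascade {
  double cyto_sens_prec, cyto_sens_cancer, cyto_spec;
  double hpv_sens, hpv_spec, colpo_sens, colpo_comp, treat_comp;

  double cyto_pos(int state, bool occult) const {
    if (state == PREC) return occult ? 0.0 : cyto_sens_prec;
    if (state == PRECL) return occult ? 0.0 : cyto_sens_cancer;
    return 1.0 - cyto_spec;
  }
  double hpv_pos(int state) const {
    return (state == HEALTHY) ? 1.0 - hpv_spec : hpv_sens;
  }
};

struct EventLogs {
  bool on = false;
  std::vector<int> st_woman, st_month, st_state, st_gt, st_occ;
  std::vector<int> sc_woman, sc_month, sc_kind, sc_mod, sc_result, sc_call,
      sc_triage, sc_referred, sc_attended, sc_state, sc_occ, sc_detected,
      sc_treated;
  void state_change(int w, int m, int s, int g, bool occ) {
    if (!on) return;
    st_woman.push_back(w); st_month.push_back(m); st_state.push_back(s);
    st_gt.push_back(g); st_occ.push_back(occ ? 1 : 0);
  }
  void screen(int w, int m, int kind, int mod, int result, int call,
              int triage, int referred, int attended, int state, int occ,
              int detected, int treated) {
    if (!on) return;
    sc_woman.push_back(w); sc_month.push_back(m); sc_kind.push_back(kind);
    sc_mod.push_back(mod); sc_result.push_back(result); sc_call.push_back(call);
    sc_triage.push_back(triage); sc_referred.push_back(referred);
    sc_attended.push_back(attended); sc_state.push_back(state);
    sc_occ.push_back(occ); sc_detected.push_back(detected);
    sc_treated.push_back(treated);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(int n, int n_months,
                    NumericVector acq16, NumericVector acq_oth,
                    NumericVector death_cdf, NumericVector hyst_cdf,
                    double coverage, double ve,
                    double c16, double c_oth, double pi16, double pi_oth,
                    double rho16, double rho_oth, double tau, double sigma,
                    double occult_frac,
                    double cyto_sens_prec, double cyto_sens_cancer,
                    double cyto_spec, double hpv_sens, double hpv_spec,
                    double colpo_sens, double colpo_comp, double treat_comp,
                    IntegerVector screen_month, IntegerVector screen_modality,
                    int init_state, int init_month, int init_genotype,
                    bool init_occult,
                    double master_seed, double cohort_key, double woman_offset,
                    bool record_events) {
  const int ns = screen_month.size();
  const double* dcdf = REAL(death_cdf);
  const double* hcdf = REAL(hyst_cdf);
  const double* a16 = REAL(acq16);
  const double* aoth = REAL(acq_oth);
  Cascade cas{cyto_sens_prec, cyto_sens_cancer, cyto_spec,
              hpv_sens, hpv_spec, colpo_sens, colpo_comp, treat_comp};

  IntegerVector out_diag_mode(n), out_diag_month(n), out_diag_gt(n);
  IntegerVector out_death(n), out_hyst(n), out_vacc(n);
  EventLogs log;
  log.on = record_events;

  const uint64_t base =
      splitmix64((uint64_t)master_seed * 0x9E3779B97F4A7C15ULL ^
                 splitmix64((uint64_t)cohort_key + 0x243F6A8885A308D3ULL));

  const double c_g[2] = {c16, c_oth};
  const double pi_g[2] = {pi16, pi_oth};
  const double rho_g[2] = {rho16, rho_oth};

  for (int i = 0; i < n; ++i) {
    uint64_t wid = (uint64_t)(woman_offset + i);
    Pcg32 rng;
    rng.seed(splitmix64(base + wid * 0x9E3779B97F4A7C15ULL),
             splitmix64(base ^ (wid + 0x94D049BB133111EBULL)));

    bool vacc = rng.u01() < coverage;
    int m_death = draw_event_month(dcdf, n_months, rng.u01(), init_month);
    int m_hyst = draw_event_month(hcdf, n_months, rng.u01(), init_month);

    int state = init_state;
    int gt = init_genotype; // 0 none, 1 hpv16/18, 2 other hr
    bool occult = init_occult;
    int surv_due = -1;
    int diag_mode = 0, diag_month = -1, diag_gt = 0;
    int death_rec = -1, hyst_rec = -1;
    int sidx = 0;
    while (sidx < ns && screen_month[sidx] < init_month) ++sidx;
    log.state_change(i, init_month, state, gt, occult);

    for (int m = init_month; m < n_months; ++m) {
      // --- symptomatic presentation resolves first, before any contact ---
      if (state == PRECL && rng.u01() < sigma) {
        diag_mode = 2; diag_month = m; diag_gt = gt; state = DIAG;
        log.state_change(i, m, state, gt, occult);
        break;
      }

      // --- scheduled contacts ---
      if (surv_due == m) {
        // surveillance re-management of a previously detected, untreated lesion
        int attended = rng.u01() < cas.colpo_comp;
        int detected = 0, treated = 0;
        if (attended) {
          if (state == PREC) {
            detected = rng.u01() < cas.colpo_sens;
            if (detected) {
              treated = rng.u01() < cas.treat_comp;
              if (treated) {
                state = HEALTHY; gt = 0; occult = false; surv_due = -1;
                log.state_change(i, m, state, gt, occult);
              } else surv_due = m + 12;
            } else surv_due = m + 12;
          } else { // PRECL
            detected = rng.u01() < cas.colpo_sens;
            if (detected) {
              diag_mode = 1; diag_month = m; diag_gt = gt; state = DIAG;
              log.state_change(i, m, state, gt, occult);
            } else surv_due = m + 12;
          }
        } else surv_due = m + 12;
        log.screen(i, m, 1, -1, -1, -1, -1, 1, attended, state == DIAG ? PRECL : state,
                   occult ? 1 : 0, detected, treated);
        if (state == DIAG) break;
      }
      if (sidx < ns && screen_month[sidx] == m) {
        int mod = screen_modality[sidx];
        ++sidx;
        if (surv_due < 0) { // routine screens are suppressed while under surveillance
          int result = 0, call = 0, triage = -1, referred = 0;
          if (mod == 0) { // primary cytology, reflex HPV on ASCUS+
            result = rng.u01() < cas.cyto_pos(state, occult);
            if (result) referred = rng.u01() < cas.hpv_pos(state);
          } else { // primary HPV with partial genotyping
            result = rng.u01() < cas.hpv_pos(state);
            if (result) {
              call = (state == HEALTHY) ? 2 : gt;
              if (call == 1) referred = 1;
              else {
                triage = rng.u01() < cas.cyto_pos(state, occult);
                referred = triage;
              }
            }
          }
          int attended = 0, detected = 0, treated = 0;
          if (referred) {
            attended = rng.u01() < cas.colpo_comp;
            if (attended) {
              if (state == PREC) {
                detected = rng.u01() < cas.colpo_sens;
                if (detected) {
                  treated = rng.u01() < cas.treat_comp;
                  if (treated) {
                    state = HEALTHY; gt = 0; occult = false; surv_due = -1;
                    log.state_change(i, m, state, gt, occult);
                  } else surv_due = m + 12;
                }
              } else if (state == PRECL) {
                detected = rng.u01() < cas.colpo_sens;
                if (detected) {
                  diag_mode = 1; diag_month = m; diag_gt = gt; state = DIAG;
                  log.state_change(i, m, state, gt, occult);
                }
              }
            }
          }
          log.screen(i, m, 0, mod, result, call, triage, referred, attended,
                     state == DIAG ? PRECL : state, occult ? 1 : 0, detected,
                     treated);
          if (state == DIAG) break;
        }
      }

      // --- competing events: death > hysterectomy > disease transition ---
      if (m == m_death) { death_rec = m; state = DEAD; log.state_change(i, m, state, 0, false); break; }
      if (m == m_hyst) {
        if (state <= PREC) {
          hyst_rec = m; state = HYST; log.state_change(i, m, state, 0, false); break;
        }
        // hysterectomy blocked by prevalent invasive cancer: the benign-
        // hysterectomy process keeps running, so redraw its next firing
        m_hyst = draw_event_month(hcdf, n_months, rng.u01(), m + 1);
      }

      switch (state) {
        case HEALTHY: {
          double p16 = a16[m] * (vacc ? 1.0 - ve : 1.0);
          double ptot = p16 + aoth[m];
          if (ptot > 0.0) {
            double u = rng.u01();
            if (u < p16) { state = HPV; gt = 1; log.state_change(i, m, state, gt, occult); }
            else if (u < ptot) { state = HPV; gt = 2; log.state_change(i, m, state, gt, occult); }
          }
          break;
        }
        case HPV: {
          double u = rng.u01();
          double pp = pi_g[gt - 1];
          if (u < pp) {
            state = PREC;
            occult = rng.u01() < occult_frac;
            log.state_change(i, m, state, gt, occult);
          } else if (u < pp + c_g[gt - 1]) {
            state = HEALTHY; gt = 0; occult = false;
            log.state_change(i, m, state, gt, occult);
          }
          break;
        }
        case PREC: {
          double u = rng.u01();
          if (u < tau) {
            state = PRECL; // occult flag and any surveillance countdown carry over
            log.state_change(i, m, state, gt, occult);
          } else if (u < tau + rho_g[gt - 1]) {
            state = HPV; occult = false; surv_due = -1;
            log.state_change(i, m, state, gt, occult);
          }
          break;
        }
        case PRECL:
          break; // symptomatic presentation already resolved at cycle start
        default: break;
      }
      if (state == DIAG) break;
    }

    out_diag_mode[i] = diag_mode;
    out_diag_month[i] = diag_month;
    out_diag_gt[i] = diag_gt;
    out_death[i] = death_rec;
    out_hyst[i] = hyst_rec;
    out_vacc[i] = vacc ? 1 : 0;
  }

  List res = List::create(
      _["diag_mode"] = out_diag_mode, _["diag_month"] = out_diag_month,
      _["diag_genotype"] = out_diag_gt, _["death_month"] = out_death,
      _["hyst_month"] = out_hyst, _["vaccinated"] = out_vacc);
  if (record_events) {
    res["state_log"] = List::create(
        _["woman"] = log.st_woman, _["month"] = log.st_month,
        _["state"] = log.st_state, _["genotype"] = log.st_gt,
        _["occult"] = log.st_occ);
    res["screen_log"] = List::create(
        _["woman"] = log.sc_woman, _["month"] = log.sc_month,
        _["kind"] = log.sc_kind, _["modality"] = log.sc_mod,
        _["result"] = log.sc_result, _["genotype_call"] = log.sc_call,
        _["triage"] = log.sc_triage, _["referred"] = log.sc_referred,
        _["attended"] = log.sc_attended, _["state"] = log.sc_state,
        _["occult"] = log.sc_occ, _["detected"] = log.sc_detected,
        _["treated"] = log.sc_treated);
  }
  return res;
}
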