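#include <Rcpp.h>
using namespace Rcpp;

// Individual-level monthly-cycle engine.
//
// Band coding: 0 = gt500, 1 = c350_500, 2 = c200_349, 3 = lt200.
// Care coding: 1 = on first line, 2 = off ART (first-line eligible),
//              3 = on second line, 4 = off ART (second-line only).
// Events resolve sequentially each cycle: death -> LTFU/re-engagement ->
// line switch / second-line failure -> CD4 band drift. Accrual uses the
// post-transition state at the cycle midpoint (half-cycle correction is
// baked into the discount vector v). Draws come from R's RNG, consumed
// person by person, so results are reproducible under set.seed().
//
// Output columns: 0 cost_patient_disc, 1 cost_hs_disc, 2 dalys_disc,
// 3 cost_patient_undisc, 4 cost_hs_undisc, 5 dalys_undisc,
// 6 survival_years, 7 years_on_art, 8 final_band (1..4),
// 9 final_care (0 = dead, else care code).

// [[Rcpp::export]]
NumericMatrix cpp_simulate_persons(
    int T,
    NumericVector v,            // midpoint discount factor per cycle
    NumericVector tail_disc,    // discounted years-of-life-lost from cycle t
    NumericVector tail_undisc,
    NumericVector p_mort,       // length 4 by band
    double p_ltfu_forced, double p_ltfu_regular,
    double p_reengage,
    NumericVector p_switch,     // length 2: dtg, efv
    double p_fail_second,
    NumericVector p_up_on_art, NumericVector p_down_failing,
    NumericVector p_down_off,   // each length 4 by band
    NumericVector daly_on, NumericVector daly_off,
    NumericVector hs_cost_forced,   // length 4: (line-1)*2 + regimen
    NumericVector hs_cost_regular,
    double pat_cost_forced, double pat_cost_regular,
    IntegerVector init_band,    // 1..4
    IntegerVector init_care,    // 1 or 3
    IntegerVector regimen) {    // 1 dtg, 2 efv
  const int n = init_band.size();
  NumericMatrix out(n, 10);
  for (int i = 0; i < n; ++i) {
    int band = init_band[i] - 1;
    int care = init_care[i];
    const int reg = regimen[i] - 1;
    bool failing = false;
    int months_art = 0;
    double pat_d = 0, hs_d = 0, yld_d = 0, yll_d = 0;
    double pat_u = 0, hs_u = 0, yld_u = 0, yll_u = 0;
    double surv = T / 12.0;
    bool alive = true;
    for (int t = 1; t <= T; ++t) {
      if (unif_rand() < p_mort[band]) {
        alive = false;
        surv = (t - 0.5) / 12.0;           // lived half the death cycle
        yll_d += tail_disc[t - 1];         // life lost through the horizon
        yll_u += tail_undisc[t - 1];
        break;
      }
      bool on_art = (care == 1 || care == 3);
      bool forced = (months_art < 3 || band == 3);
      if (on_art) {
        const double pl = forced ? p_ltfu_forced : p_ltfu_regular;
        if (unif_rand() < pl) {
          care = (care == 1) ? 2 : 4;
          on_art = false;
        }
      } else if (unif_rand() < p_reengage) {
        care = (care == 2) ? 1 : 3;
        on_art = true;
      }
      if (care == 1) {
        if (unif_rand() < p_switch[reg]) care = 3;  // once-only line switch
      } else if (care == 3 && !failing) {
        if (unif_rand() < p_fail_second) failing = true;
      }
      if (on_art) {
        if (!failing) {
          if (band > 0 && unif_rand() < p_up_on_art[band]) --band;
        } else if (band < 3 && unif_rand() < p_down_failing[band]) {
          ++band;
        }
      } else if (band < 3 && unif_rand() < p_down_off[band]) {
        ++band;
      }
      // accrual on the post-transition state
      forced = (months_art < 3 || band == 3);
      const double w = on_art ? daly_on[band] : daly_off[band];
      yld_u += w / 12.0;
      yld_d += w / 12.0 * v[t - 1];
      if (on_art) {
        const int li = (care == 3) ? 1 : 0;
        const double ch = forced ? hs_cost_forced[li * 2 + reg]
                                 : hs_cost_regular[li * 2 + reg];
        const double cp = forced ? pat_cost_forced : pat_cost_regular;
        hs_u += ch; hs_d += ch * v[t - 1];
        pat_u += cp; pat_d += cp * v[t - 1];
        ++months_art;
      }
    }
    out(i, 0) = pat_d;
    out(i, 1) = hs_d;
    out(i, 2) = yld_d + yll_d;
    out(i, 3) = pat_u;
    out(i, 4) = hs_u;
    out(i, 5) = yld_u + yll_u;
    out(i, 6) = surv;
    out(i, 7) = months_art / 12.0;
    out(i, 8) = band + 1;
    out(i, 9) = alive ? care : 0;
  }
  return out;
}
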