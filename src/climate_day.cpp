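#include <Rcpp.h>
using namespace Rcpp;

// Saturation absolute humidity (g/m3), Magnus over ideal-gas vapour density.
static inline double sat_ah(double t) {
  double es = 611.2 * std::exp(17.62 * t / (t + 243.12));
  return es / (461.5 * (t + 273.15)) * 1000.0;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// One block of 5-min greenhouse climate slots with day-constant crop state.
// Semi-implicit update: controls and sources evaluated at the old state,
// exchange (ventilation/envelope/condensation) terms implicit, so CO2 and
// water ledgers close exactly by construction.
// [[Rcpp::export(name = ".climate_day_cpp")]]
List climate_day_cpp(NumericVector G, NumericVector par_out, NumericVector t_out,
                     NumericVector ah_out, NumericVector wind,
                     LogicalVector hps_on, LogicalVector led_on,
                     NumericVector heat_sp, NumericVector vent_temp,
                     NumericVector min_vent,
                     NumericVector screen_energy, NumericVector screen_blackout,
                     NumericVector co2_sp, NumericVector co2_cap,
                     NumericVector hd_sp,
                     NumericVector min_rail, NumericVector min_crop,
                     NumericVector hod,
                     double t_in0, double co2_0, double ah_0,
                     double lai, double rd_co2,
                     List pars, double dt) {
  const int n = G.size();
  const double tau    = pars["light_transmissivity"];
  const double hps_par = pars["hps_par_capacity"];
  const double led_par = pars["led_par_capacity"];
  const double led_fr  = pars["led_farred_capacity"];
  const double hps_eff = pars["hps_efficacy"];
  const double led_eff = pars["led_efficacy"];
  const double cap_rail = pars["heat_capacity_rail"];
  const double cap_crop = pars["heat_capacity_crop_pipe"];
  const double fog_cap  = pars["fog_capacity"];
  const double U0      = pars["envelope_conductance"];
  const double se_u    = pars["screen_energy_u_factor"];
  const double sb_u    = pars["screen_blackout_u_factor"];
  const double se_sh   = pars["screen_energy_shading"];
  const double sb_sh   = pars["screen_blackout_shading"];
  const double f_sens  = pars["solar_heat_fraction"];
  const double c_air   = pars["air_heat_capacity"];
  const double p_band  = pars["p_band"];
  const double kp_heat = pars["kp_heat"];
  const double h_rail  = pars["h_rail"];
  const double h_cpipe = pars["h_crop_pipe"];
  const double leak    = pars["leakage"];
  const double va      = pars["vent_area_ratio"];
  const double vf_base = pars["vent_flux_base"];
  const double vf_wind = pars["vent_flux_wind"];
  const double g_cond  = pars["cover_condensance"];
  const double co2_out = pars["co2_outside"];
  const double co2_pb  = pars["co2_p_band"];
  const double fog_pb  = pars["fog_p_band"];
  const double height  = pars["height"];
  const List cpars     = pars["crop"];
  const double k_ext   = cpars["k_ext"];
  const double alpha   = cpars["alpha"];
  const double amax    = cpars["amax_ref"];
  const double co2_km  = cpars["co2_km"];
  const double t_opt   = cpars["t_opt"];
  const double t_wid   = cpars["t_width"];
  const double e_par   = cpars["transp_par"];
  const double e_hd    = cpars["transp_hd"];

  const double co2_g_per_m3_ppm = 44.0 / 24.0 / 1000.0;
  const double mpp = co2_g_per_m3_ppm * height;  // g/m2 per ppm
  const double rho_cp = 1200.0;                  // J/m3/K
  const double flai = 1.0 - std::exp(-k_ext * lai);

  NumericVector temp_in(n), co2_in(n), ah_in(n), par_in(n), vent_opening(n),
    heat_power(n), lamp_elec(n), co2_dose(n), assim(n), transp(n),
    screen_pos(n);
  double T = t_in0, C = co2_0, AH = ah_0;
  double heat_J = 0, elec_peak_J = 0, elec_off_J = 0, co2_g = 0,
    transp_g = 0, assim_ch2o = 0, co2_upt_g = 0, co2_vent_g = 0, fog_g = 0;

  for (int i = 0; i < n; ++i) {
    const double se = screen_energy[i] / 100.0, sb = screen_blackout[i] / 100.0;
    const double scr_light = (1.0 - se_sh * se) * (1.0 - sb_sh * sb);
    const double p_sun = tau * scr_light * par_out[i];
    const double p_lamp = (hps_on[i] ? hps_par : 0.0) + (led_on[i] ? led_par : 0.0);
    const double p_in = p_sun + p_lamp;
    const double q_solar = f_sens * tau * scr_light * G[i];
    const double p_el = (hps_on[i] ? hps_par / hps_eff : 0.0) +
      (led_on[i] ? (led_par + led_fr) / led_eff : 0.0);

    // gross canopy photosynthesis, umol CO2/m2/s
    const double i_abs = p_in * flai;
    const double fc = C / (C + co2_km);
    const double dT_t = (T - t_opt) / t_wid;
    const double ft = std::exp(-dT_t * dT_t);
    const double am = amax * fc * ft * flai;
    const double A = (i_abs > 0 && am > 0) ? (alpha * i_abs * am) / (alpha * i_abs + am) : 0.0;

    // ventilation
    const double u = clampd(min_vent[i] + (100.0 - min_vent[i]) *
                            (T - vent_temp[i]) / p_band, min_vent[i], 100.0);
    const double phi = leak + (u / 100.0) * va * (vf_base + vf_wind * wind[i]);

    // heating: proportional toward the heating line, min-pipe power floors
    double floor_p = h_rail * std::max(0.0, min_rail[i] - T) +
      h_cpipe * std::max(0.0, min_crop[i] - T);
    floor_p = std::min(floor_p, cap_rail + cap_crop);
    const double q_heat = clampd(std::max(kp_heat * (heat_sp[i] - T), floor_p),
                                 0.0, cap_rail + cap_crop);

    // energy balance, exchange implicit
    const double u_env = U0 * (1.0 - (1.0 - se_u) * se) * (1.0 - (1.0 - sb_u) * sb);
    const double g_tot = u_env + rho_cp * phi;
    const double T_new = (T + dt / c_air * (q_solar + p_el + q_heat + g_tot * t_out[i])) /
      (1.0 + dt * g_tot / c_air);

    // CO2 balance (ppm), vent term implicit
    const double dose = ((hps_on[i] || G[i] > 5.0) ?
                         co2_cap[i] / 3600.0 * clampd((co2_sp[i] - C) / co2_pb, 0.0, 1.0) : 0.0);
    const double upt = A * 44e-6 - rd_co2;  // net crop uptake g CO2/m2/s
    const double kv = phi * co2_g_per_m3_ppm;  // g/m2/s per ppm
    const double C_new = (C + dt / mpp * (dose - upt + kv * co2_out)) /
      (1.0 + dt * kv / mpp);

    // humidity: transpiration + fog sources, vent implicit, condensation explicit
    const double hd = sat_ah(T) - AH;
    const double E = e_par * i_abs + e_hd * std::max(0.0, hd) * flai;
    const double fog = fog_cap / 3600.0 * clampd((hd - hd_sp[i]) / fog_pb, 0.0, 1.0);
    const double t_cover = T - 0.3 * (T - t_out[i]);
    const double cond = g_cond * std::max(0.0, AH - sat_ah(t_cover));
    const double AH_new = (AH + dt / height * (E + fog - cond + phi * ah_out[i])) /
      (1.0 + dt * phi / height);

    temp_in[i] = T_new; co2_in[i] = C_new; ah_in[i] = AH_new;
    par_in[i] = p_in; vent_opening[i] = u; heat_power[i] = q_heat;
    lamp_elec[i] = p_el; co2_dose[i] = dose * 3600.0; assim[i] = A;
    transp[i] = E; screen_pos[i] = screen_energy[i];

    heat_J += q_heat * dt;
    if (hod[i] >= 7.0 && hod[i] < 23.0) elec_peak_J += p_el * dt;
    else elec_off_J += p_el * dt;
    co2_g += dose * dt;
    co2_upt_g += upt * dt;
    co2_vent_g += kv * (C_new - co2_out) * dt;
    transp_g += E * dt;
    fog_g += fog * dt;
    assim_ch2o += A * 30e-6 * dt;  // g CH2O

    T = T_new; C = C_new; AH = AH_new;
  }

  return List::create(
    _["temp_in"] = temp_in, _["co2_in"] = co2_in, _["ah_in"] = ah_in,
    _["par_in"] = par_in, _["vent_opening"] = vent_opening,
    _["heat_power"] = heat_power, _["lamp_elec"] = lamp_elec,
    _["co2_dose"] = co2_dose, _["assim"] = assim, _["transp"] = transp,
    _["state"] = NumericVector::create(T, C, AH),
    _["heat_J"] = heat_J, _["elec_peak_J"] = elec_peak_J,
    _["elec_off_J"] = elec_off_J, _["co2_g"] = co2_g,
    _["co2_uptake_g"] = co2_upt_g, _["co2_vent_g"] = co2_vent_g,
    _["transp_g"] = transp_g, _["fog_g"] = fog_g,
    _["assim_ch2o_g"] = assim_ch2o);
}
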