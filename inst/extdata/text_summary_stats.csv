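stat,value
ratio_water_abs_g_mc_mean,0.85
ratio_water_abs_g_mc_sd,0.10
diff_abs_g_mc_ebt_mean_printed,0.07
diff_abs_g_mc_ebt_sd_printed,0.05
diff_abs_g_mc_ebt_max,0.12
diff_abs_g_mc_ebt_argmax_r_cm,4.8
diff_water_g_mc_ebt_mean,0.05
diff_water_g_mc_ebt_sd,0.05
f_ratio_max,1.26
f_ratio_max_r_cm,4.2
f_ratio_max_theta_deg,50
f_ratio_min,0.84
f_ratio_min_r_cm,3.6
f_ratio_min_theta_deg,20
azimuthal_max_ratio,1.06
azimuthal_max_phi_deg,150
type_b_quadrature_pct,12.02
type_a_quadrature_pct,0.04
total_uncertainty_printed_pct,12.06
lambda_abs_cgy_h_uA,1104.28
lambda_water_cgy_h_uA,1344.14
cf_at_1cm,1.23
cf_at_5cm,0.85
sk_gy_cm2_min,108.1
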