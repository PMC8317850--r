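quantity,value,tolerance,kind
accuracy_pct,63.9,0.05,deterministic
sensitivity_pct,56.0,0.05,deterministic
specificity_pct,74.7,0.05,deterministic
ppv_pct,75.3,0.05,deterministic
npv_pct,55.2,0.05,deterministic
prevalence_pct,58.0,0.05,deterministic
detection_rate_pct,32.5,0.05,deterministic
detection_prevalence_pct,43.1,0.05,deterministic
balanced_accuracy_pct,65.4,0.05,deterministic
youden_j_pct,30.7,0.05,deterministic
no_information_rate_pct,58.0,0.05,deterministic
kappa,0.2931,0.00005,deterministic
relative_treatment_time,1.94,0.005,deterministic
mishit_ratio_pct,32.9,0.05,deterministic
mishit_reduction_pct,67.1,0.05,deterministic
hits_per_minute_operator,45,0.5,deterministic
hits_per_minute_ai,23,0.5,deterministic
pooled_rate_pct,50.12,0.005,deterministic
chi2,927.4,1,deterministic
chi2_df,7,0,deterministic
skew_z,-0.005,0.001,deterministic
kurt_z,1.73,0.005,deterministic
rate_sd_pct,18.6,0.05,deterministic
median_p2_pct,53.4,0.5,stochastic
ci_low_p2_pct,51.6,0.5,stochastic
ci_high_p2_pct,55.1,0.5,stochastic
median_p4_pct,59.0,0.5,stochastic
ci_low_p4_pct,57.0,0.5,stochastic
ci_high_p4_pct,61.0,0.5,stochastic
median_p5_pct,63.4,0.5,stochastic
ci_low_p5_pct,61.6,0.5,stochastic
ci_high_p5_pct,65.2,0.5,stochastic
median_p6_pct,54.7,0.5,stochastic
ci_low_p6_pct,53.0,0.5,stochastic
ci_high_p6_pct,56.4,0.5,stochastic
median_p7_pct,47.9,0.5,stochastic
ci_low_p7_pct,46.2,0.5,stochastic
ci_high_p7_pct,49.5,0.5,stochastic
median_p8_pct,53.1,0.5,stochastic
ci_low_p8_pct,51.5,0.5,stochastic
ci_high_p8_pct,54.6,0.5,stochastic
median_p10_pct,21.3,0.5,stochastic
ci_low_p10_pct,20.0,0.5,stochastic
ci_high_p10_pct,22.7,0.5,stochastic
median_p11_pct,89.0,0.5,stochastic
ci_low_p11_pct,86.2,0.5,stochastic
ci_high_p11_pct,91.7,0.5,stochastic
cohort_rate_pct,55.2,1.5,stochastic
cohort_ci_low_pct,43.2,1.5,stochastic
cohort_ci_high_pct,67.3,1.5,stochastic
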