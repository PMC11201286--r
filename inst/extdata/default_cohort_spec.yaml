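# Default cohort simulation spec (mirrors the built-in cohort_spec()
# defaults). Component marginals emulate the reference cohort summary
# statistics; pairwise component Spearman targets default to a weak 0.3
# because within-cohort component pairs are not published.
#
# duration_noise_sd and rasrm_link$noise_sd are calibrated constants: with
# the default marginals they reproduce rank correlations of about 0.724
# (E-score vs duration) and 0.758 (E-score vs r-ASRM) at n = 5000.
n: 111
seed: 1
marginals:
  cyst:     {mean: 6.32, sd: 3.0, min: 0, max: 12}
  adhesion: {mean: 3.96, sd: 2.6, min: 0, max: 9}
  pain:     {mean: 6.07, sd: 2.5, min: 1, max: 10}
lesion_prevalence: {E: 0.522, R: 0.396, A: 0.243}
rare_prevalence: 0.045
myoma_prevalence: 0.162
target_spearman:
  - [1.0, 0.3, 0.3, 0.3]
  - [0.3, 1.0, 0.3, 0.3]
  - [0.3, 0.3, 1.0, 0.3]
  - [0.3, 0.3, 0.3, 1.0]
duration_model: {slope: 6.2995, intercept: 49.459}
duration_noise_sd: 41
duration_bounds: [51, 421]
bloodloss_model: {slope: 4.0, intercept: -15.5, noise_sd: 60}
bloodloss_bounds: [0, 500]
rasrm_link: {mean: 69.4, scale: 33, noise_sd: 24}
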