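# Published per-group texture-feature summary statistics (mean, SD) for the
# ARDS (n = 8) and cardiogenic pulmonary edema (CPE, n = 16) subject groups,
# in quantized-level units (Ng = 16). Used as the generative parameters of
# the Gaussian feature simulator.
groups:
  ARDS: {n_subjects: 8}
  CPE: {n_subjects: 16}
features:
  contrast:
    ARDS: {mean: 6.27, sd: 2.76}
    CPE: {mean: 10.72, sd: 2.26}
  cluster_shade:
    ARDS: {mean: 104.13, sd: 114.69}
    CPE: {mean: -56.22, sd: 45.58}
  entropy:
    ARDS: {mean: 4.00, sd: 0.21}
    CPE: {mean: 4.26, sd: 0.11}
  variance:
    ARDS: {mean: 23.11, sd: 6.24}
    CPE: {mean: 18.32, sd: 2.46}
  mean:
    ARDS: {mean: 5.79, sd: 1.26}
    CPE: {mean: 8.87, sd: 0.89}
  correlation:
    ARDS: {mean: 0.88, sd: 0.03}
    CPE: {mean: 0.74, sd: 0.06}
  energy:
    ARDS: {mean: 0.03, sd: 0.01}
    CPE: {mean: 0.02, sd: 0.01}
  homogeneity:
    ARDS: {mean: 0.65, sd: 0.04}
    CPE: {mean: 0.56, sd: 0.03}
  mean_sum:
    ARDS: {mean: 11.58, sd: 2.53}
    CPE: {mean: 17.73, sd: 1.77}
  entropy_sum:
    ARDS: {mean: 3.09, sd: 0.13}
    CPE: {mean: 3.06, sd: 0.07}
  variance_sum:
    ARDS: {mean: 125.30, sd: 45.16}
    CPE: {mean: 252.05, sd: 52.62}
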