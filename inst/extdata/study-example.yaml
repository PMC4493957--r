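# Example study configuration for `odemval study --config ...` or
# study_config_from_yaml(): a small run of two adapted schemes plus SRCV.
schemes: [Sln1_Sho1, Sln1_WT, srcv]
n_realizations: 10
master_seed: 1
noise_cv: 0.10
dense_dt: 1
srcv_redraw: true
# model:                # optional overrides of benchmark defaults
#   parameters:
#     k_gly_hog: 0.02
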