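# Synthetic stand-in for the pooled multi-study HEU cohort: 20 studies,
# covariate prevalences and effect sizes at the package's documented
# defaults, with missingness masks emulating incomplete source data.
# Consumed by as-is by run_pipeline() as the `simulate` block of a run
# config, or turned into a cohort_config via its arguments.
n_studies: 20
children_per_study: 960
theta: 0.25
baseline_breaks: [0.0, 91.0, 183.0, 365.0]
baseline_rates: [2.4e-04, 1.1e-04, 8.0e-05, 3.0e-05]
true_log_hr:
  region:
    Asia: -2.9957
  birth_weight_group:
    lt2500: 1.0647
    unknown: 0.8755
  ever_breastfed:
    "FALSE": 0.9163
  cd4_group:
    lt350: 0.3577
    unknown: 0.3988
  arv_category:
    mono_dual_pmtct: -0.2485
    art_pmtct: -0.4155
    art_life: -0.6931
  mother_dead:
    "1": 2.4069
prevalences:
  region:
    Africa: 0.77
    Asia: 0.23
  sex:
    male: 0.512
    female: 0.488
  birth_weight_group:
    ge2500: 0.866
    lt2500: 0.121
    unknown: 0.013
  ever_breastfed:
    "TRUE": 0.698
    "FALSE": 0.302
  arv_category:
    none: 0.228
    mono_dual_pmtct: 0.614
    art_pmtct: 0.117
    art_life: 0.041
  cd4_group:
    ge350: 0.579
    lt350: 0.365
    unknown: 0.056
maternal_death_rate: 2.2e-05
weaning_meanlog: 5.1985
weaning_sdlog: 0.8
admin_caps: [365.0, 550.0, 730.0]
admin_cap_probs: [0.3, 0.3, 0.4]
dropout_rate: 2.0e-04
followup_cap_days: 730
missing_weaning_prob: 0.077
unknown_bf_prob: 0.023
missing_arv_prob: 0.002
seed: 20170101
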