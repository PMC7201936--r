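# Annotated run configuration for the lifecourseMR pipeline.
# Unknown keys are rejected; every key below has the shown default.
# The resolved configuration is written beside the outputs of every run.

seed: 1                      # mandatory RNG seed for every stage
output_dir: lifecourseMR_run # all stage inputs/outputs live here

scenario:                    # causal diagram of the simulated world
  n_variants: 100            # biallelic variants in the panel
  maf_range: [0.1, 0.45]     # minor-allele frequencies, uniform
  ld_block_size: 1           # variants per LD block (1 = independent)
  ld_rho: 0.0                # latent equicorrelation within a block
  n_early_variants: 30       # variants acting on the early latent only
  n_adult_variants: 30       # ... on the adult latent only
  n_shared_variants: 0       # ... on both
  effect_size_sd_early: 0.15 # per-allele effect scale (latent SD units)
  effect_size_sd_adult: 0.15
  beta_early_to_adult: 0.6   # mediation path, early latent -> adult latent
  beta_early_direct: 0.0     # early -> outcome (0 = fully mediated)
  beta_adult_direct: 0.5     # adult -> outcome
  outcome_model: continuous  # or binary-logistic
  baseline_prevalence: 0.1   # binary outcomes only
  confounder_sd: 1.0         # shared confounder of both latents + outcome
  confounder_loading_early: 0.3
  confounder_loading_adult: 0.3
  confounder_loading_outcome: 0.3
  menarche_beta_early: -0.5  # early latent -> age at menarche (adult has none)
  category_proportions: [0.33333333333333331, 0.33333333333333331, 0.33333333333333337]
  palindromic_alleles: false # enable A/T and G/C pairs to exercise harmonization
  seed: 1                    # overridden by the top-level seed

misclassification:           # self-report error in the early category
  mode: none                 # none | nondifferential | differential-on-adult
  spill: 0.1                 # off-diagonal mass of the symmetric confusion
  adult_dependence_slope: 0.0 # log-odds shift per unit adult latent (differential)

samples:
  n_exposure: 20000          # exposure (discovery) sample size
  n_outcome: 20000           # outcome sample size (two-sample design)

scan:
  early_phenotype: early_reported   # 3-category reported early size
  adult_phenotype: adult_latent     # measured continuous adult size
  outcome_phenotype: outcome        # or menarche for the negative control
  early_covariates: [age, sex, month_of_birth]
  adult_covariates: [age, sex]
  outcome_covariates: [age, sex]

clump:
  p_threshold: 5.0e-8        # genome-wide significance for index variants
  r2_threshold: 0.001        # dosage r-squared ceiling between instruments

harmonize:
  palindrome_policy: frequency  # frequency | drop
  palindrome_window: [0.42, 0.58] # frequencies treated as unresolvable

mr:
  random_effects: false      # multiplicative random-effects se inflation

validate:
  n_validation: 5000         # independent sample for the score ROC analysis
  centile: 0.85              # overweight cut-point for dichotomisation

study:
  replicates: 20             # replicates per misclassification-grid cell
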