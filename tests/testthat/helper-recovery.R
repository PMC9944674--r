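# Shared noise-free parameter-recovery procedure: generate synthetic data
# from the shipped (truth) parameter set, perturb the fitted parameters,
# refit, return estimates alongside the truth.
recover_fit <- function(api, species, tissues, times_h, free,
                        strength_pct = 0.5, init_mult = 5, seed = 1) {
  drug <- fx_drug(api)
  truth <- vapply(free, function(p) get_drug_param(drug, p), numeric(1))
  st <- noise_free_study(api, species, tissues, times_h,
                         strength_pct = strength_pct,
                         study_id = paste(api, species, sep = "."))
  spec <- fit_spec(free, init = truth * init_mult, n_starts = 1,
                   seed = seed)
  fr <- fit_parameters(spec, st$data, drug, st$contexts)
  list(truth = truth, estimates = fr$estimates, result = fr)
}
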