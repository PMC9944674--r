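# Cached physiologies and drug records (loading is cheap but repeated a lot)
.fix <- new.env()

fx_phys <- function(species) {
  key <- paste0("phys_", species)
  if (is.null(.fix[[key]])) .fix[[key]] <- get_physiology(species)
  .fix[[key]]
}

fx_drug <- function(api) {
  if (is.null(.fix[[api]])) .fix[[api]] <- load_drug(api)
  .fix[[api]]
}

# Noise-free synthetic dataset + matching fit context for one study design
noise_free_study <- function(api, species, tissues, times_h,
                             strength_pct = 0.5, horizon_h = max(times_h),
                             study_id = "synth") {
  prot <- study_protocol(study_id, species, "single", 30, strength_pct,
                         tissues = tissues, times_h = times_h,
                         design = "destructive_rabbit", n_per_time = 1,
                         cv = 0, horizon_h = horizon_h)
  list(data = generate_study(prot, fx_drug(api), seed = 1),
       contexts = stats::setNames(list(protocol_context(prot)), study_id),
       protocol = prot)
}

# Single-drop regimen shared by many tests
fx_single_drop <- function(strength_pct = 0.5) {
  dose_regimen(0, 30, strength_pct)
}
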