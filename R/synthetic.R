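#' Define a synthetic study protocol
#'
#' Emulates the two study designs behind published ocular tissue PK:
#' destructive rabbit sampling (one cohort of animals per time point;
#' tissue concentrations reported as mean and SD of n animals) and
#' surgical human sampling (one specimen per subject taken at the time of
#' surgery; individual values).
#'
#' @param study_id Study code (e.g. `"Lev.NZ.synth1"`).
#' @param species Species id.
#' @param regimen_spec Schedule string for [expand_regimen()].
#' @param drop_volume_uL,strength_pct Drop volume and strength.
#' @param tissues Sampled tissues.
#' @param times_h Sampling times (h).
#' @param design `"destructive_rabbit"` or `"surgical_human"`.
#' @param n_per_time Animals per time point (destructive) or subjects per
#'   time (surgical).
#' @param cv Lognormal residual coefficient of variation (fraction, e.g.
#'   0.3); 0 gives noise-free data.
#' @param loq Assay limit of quantification (ug/mL).
#' @param horizon_h Simulation horizon; defaults past the last sample.
#' @return List of class `study_protocol`.
#' @export
study_protocol <- function(study_id, species, regimen_spec = "single",
                           drop_volume_uL = 30, strength_pct = 0.5,
                           tissues = "AH",
                           times_h = c(0.25, 0.5, 1, 2, 4, 8, 24),
                           design = c("destructive_rabbit",
                                      "surgical_human"),
                           n_per_time = 4, cv = 0.3, loq = 0.001,
                           horizon_h = NULL) {
  design <- match.arg(design)
  stopifnot(cv >= 0, n_per_time >= 1, all(times_h >= 0))
  if (is.null(horizon_h)) horizon_h <- max(times_h)
  stopifnot(all(times_h <= horizon_h))
  structure(list(study_id = study_id, species = species,
                 regimen_spec = regimen_spec,
                 drop_volume_uL = drop_volume_uL,
                 strength_pct = strength_pct, tissues = tissues,
                 times_h = times_h, design = design,
                 n_per_time = n_per_time, cv = cv, loq = loq,
                 horizon_h = horizon_h), class = "study_protocol")
}

#' Generate an observed-style dataset from a protocol
#'
#' The underlying truth is the model simulation; each sample is the true
#' concentration times a lognormal deviate with
#' `sdlog = sqrt(log(1 + cv^2))` (so the empirical CV of many samples
#' approaches the protocol's `cv`). Destructive records report the mean
#' and SD of `n_per_time` replicates; surgical records are individual.
#' Records below the LOQ are flagged BLQ. Identical seeds give identical
#' datasets.
#'
#' @param protocol `study_protocol`.
#' @param drug `drug_parameters`.
#' @param seed Integer seed for the residual error draws.
#' @param interstudy_k_drain_cv Optional lognormal CV of a per-study
#'   random multiplier on the drainage rate constant, emulating the
#'   several-fold between-study spread of observed Cmax; 0 (default)
#'   disables it.
#' @return `observed_dataset`.
#' @export
generate_study <- function(protocol, drug, seed = 1,
                           interstudy_k_drain_cv = 0) {
  stopifnot(inherits(protocol, "study_protocol"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  ph <- get_physiology(protocol$species)
  opts <- sim_options()
  if (interstudy_k_drain_cv > 0) {
    sdl <- sqrt(log(1 + interstudy_k_drain_cv^2))
    opts$tear_flow_multiplier <- stats::rlnorm(1, -sdl^2 / 2, sdl)
  }
  reg <- expand_regimen(protocol$regimen_spec, protocol$horizon_h,
                        drop_volume_uL = protocol$drop_volume_uL,
                        strength_pct = protocol$strength_pct)
  sim <- simulate_ocular(drug, ph$ocular, ph$systemic, reg,
                         t_grid = sort(unique(c(protocol$times_h,
                                                reg$events$time_h))),
                         options = opts)
  sdlog <- sqrt(log(1 + protocol$cv^2))
  rows <- list()
  for (tt in protocol$tissues) {
    truth <- tissue_conc(sim, tt)[match(round(protocol$times_h, 10),
                                        round(sim$time, 10))]
    for (i in seq_along(protocol$times_h)) {
      if (protocol$cv > 0) {
        draws <- truth[i] * stats::rlnorm(protocol$n_per_time, 0, sdlog)
      } else {
        draws <- rep(truth[i], protocol$n_per_time)
      }
      if (protocol$design == "destructive_rabbit") {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tt, time_h = protocol$times_h[i],
          conc_ug_per_mL = mean(draws),
          sd = if (protocol$n_per_time > 1) stats::sd(draws) else NA_real_,
          n = protocol$n_per_time)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tt, time_h = protocol$times_h[i],
          conc_ug_per_mL = draws, sd = NA_real_, n = 1L)
      }
    }
  }
  dat <- do.call(rbind, rows)
  observed_dataset(protocol$study_id, dat$tissue, dat$time_h,
                   dat$conc_ug_per_mL, sd = dat$sd, n = dat$n,
                   loq = protocol$loq)
}

#' Context matching a synthetic protocol
#'
#' Builds the [study_context()] that reproduces a protocol's simulation
#' settings, for use in fitting the data the protocol generated.
#'
#' @param protocol `study_protocol`.
#' @return `study_context` keyed list entry.
#' @export
protocol_context <- function(protocol) {
  ph <- get_physiology(protocol$species)
  reg <- expand_regimen(protocol$regimen_spec, protocol$horizon_h,
                        drop_volume_uL = protocol$drop_volume_uL,
                        strength_pct = protocol$strength_pct)
  study_context(reg, ph$ocular, ph$systemic)
}

#' Library of study-design templates
#'
#' Templates mirroring the preclinical and clinical designs the model is
#' exercised against: albino-rabbit single and multiple dose tissue PK,
#' pigmented-rabbit single dose (iris-ciliary body + aqueous humor),
#' and surgical human sampling (cataract: aqueous humor; keratoplasty:
#' cornea layers + aqueous humor; vitrectomy: aqueous + vitreous humor
#' after three drops fifteen minutes apart), plus healthy-subject
#' conjunctival biopsy.
#'
#' @return Named list of `study_protocol`s.
#' @export
protocol_library <- function() {
  list(
    nz_single_cornea_conj = study_protocol(
      "NZ.single.1", "NZ_rabbit", "single", 30, 0.5,
      tissues = c("cornea", "conjunctiva", "AH"),
      times_h = c(0.25, 0.5, 1, 2, 4, 8, 24),
      design = "destructive_rabbit", n_per_time = 4, cv = 0.3),
    nz_single_cornea_ah = study_protocol(
      "NZ.single.2", "NZ_rabbit", "single", 30, 0.5,
      tissues = c("cornea", "AH"),
      times_h = c(0.25, 0.5, 1, 2, 4, 8, 24),
      design = "destructive_rabbit", n_per_time = 4, cv = 0.3),
    nz_multi_tid = study_protocol(
      "NZ.multi.1", "NZ_rabbit", "TIDx3d", 30, 0.5,
      tissues = c("cornea", "AH"),
      times_h = c(48.25, 48.5, 49, 50, 52, 56, 72),
      design = "destructive_rabbit", n_per_time = 4, cv = 0.3,
      horizon_h = 72),
    db_single_icb_ah = study_protocol(
      "DB.single.1", "DB_rabbit", "single", 30, 0.5,
      tissues = c("ICB", "AH"),
      times_h = c(0.25, 0.5, 1, 2, 4, 8, 24, 48),
      design = "destructive_rabbit", n_per_time = 4, cv = 0.3,
      horizon_h = 48),
    db_multi_icb = study_protocol(
      "DB.multi.1", "DB_rabbit", "BIDx2d", 30, 0.5,
      tissues = c("ICB", "AH"),
      times_h = c(24.5, 25, 26, 28, 32, 48),
      design = "destructive_rabbit", n_per_time = 3, cv = 0.3,
      horizon_h = 48),
    human_cataract = study_protocol(
      "Hum.cataract.1", "human", "q1hx3", 30, 0.5,
      tissues = "AH", times_h = 3,
      design = "surgical_human", n_per_time = 12, cv = 0.5,
      horizon_h = 6),
    human_keratoplasty = study_protocol(
      "Hum.keratoplasty.1", "human", "QIDx3d", 30, 0.5,
      tissues = c("cornea_epi", "cornea_stroma", "AH"), times_h = 49,
      design = "surgical_human", n_per_time = 10, cv = 0.5,
      horizon_h = 72),
    human_vitrectomy = study_protocol(
      "Hum.vitrectomy.1", "human", "q15minx3", 30, 0.3,
      tissues = c("AH", "VH"), times_h = 1.5,
      design = "surgical_human", n_per_time = 10, cv = 0.5,
      horizon_h = 6),
    human_conj_biopsy = study_protocol(
      "Hum.conj.1", "human", "single", 30, 0.3,
      tissues = "conjunctiva", times_h = 0.25,
      design = "surgical_human", n_per_time = 12, cv = 0.953,
      horizon_h = 2)
  )
}

#' Write / read a study protocol config file
#'
#' @param protocol `study_protocol`.
#' @param path YAML path.
#' @return `read_protocol` returns a `study_protocol` identical to the one
#'   written.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "study_protocol"))
  yaml::write_yaml(unclass(protocol), path, precision = 15)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  raw <- yaml::read_yaml(path)
  study_protocol(raw$study_id, raw$species, raw$regimen_spec,
                 raw$drop_volume_uL, raw$strength_pct,
                 unlist(raw$tissues), unlist(raw$times_h), raw$design,
                 raw$n_per_time, raw$cv, raw$loq, raw$horizon_h)
}
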