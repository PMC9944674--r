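#' Non-compartmental exposure metrics
#'
#' Linear-trapezoid AUC to the last observation (ocular profiles are
#' reported to finite horizons, so no terminal-phase extrapolation is
#' applied); Cmax ties resolve to the earliest Tmax.
#'
#' @param time_h Time vector (h), at least two points, increasing.
#' @param conc Concentration vector (ug/mL), non-negative.
#' @return List with `cmax` (ug/mL), `tmax` (h), `auc` (ug.h/mL).
#' @export
nca <- function(time_h, conc) {
  stopifnot(length(time_h) == length(conc))
  if (length(time_h) < 2)
    stop("at least two time points are required for NCA")
  if (is.unsorted(time_h, strictly = TRUE)) stop("times must be increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  i <- which.max(conc)
  auc <- sum(diff(time_h) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  list(cmax = conc[i], tmax = time_h[i], auc = auc)
}

#' Differences between two drug parameter records
#'
#' Compares every numeric entry of two records and reports the paths that
#' differ; the empty result is the provenance guarantee that an
#' extrapolation changed physiology only.
#'
#' @param a,b `drug_parameters` records.
#' @return Character vector of differing parameter paths (empty if none).
#' @export
drug_param_diff <- function(a, b) {
  stopifnot(inherits(a, "drug_parameters"), inherits(b, "drug_parameters"))
  flat <- function(d) c(
    mwt = d$mwt, logp = d$logp, fu_plasma = d$fu_plasma,
    fu_melanin = d$fu_melanin,
    stats::setNames(d$rbp, paste0("rbp.", names(d$rbp))),
    stats::setNames(d$peff_cm_s, paste0("peff.", names(d$peff_cm_s))),
    stats::setNames(d$renal_fraction,
                    paste0("renal_fraction.", names(d$renal_fraction))),
    stats::setNames(d$clint_L_h, paste0("clint.", names(d$clint_L_h))),
    stats::setNames(d$perm_cm_s, paste0("perm.", names(d$perm_cm_s))),
    stats::setNames(d$sar_per_s, paste0("sar.", names(d$sar_per_s))))
  fa <- flat(a); fb <- flat(b)
  nm <- union(names(fa), names(fb))
  differs <- vapply(nm, function(k) {
    !isTRUE(all.equal(fa[[k]], fb[[k]], tolerance = 0))
  }, logical(1))
  nm[differs]
}

#' Simulate a dosing scenario and summarize exposure
#'
#' Runs [simulate_ocular()] for one species and regimen and attaches a
#' per-tissue NCA table. The drug record is used unchanged, and the
#' returned `drug_diff` (input record vs record stored in the simulation)
#' documents that no drug-specific parameter moved.
#'
#' @param drug `drug_parameters` record.
#' @param species Species id.
#' @param regimen `dose_regimen`.
#' @param t_grid Output grid (h); default 0-24 h past last dose.
#' @param options [sim_options()]; `tear_flow_multiplier` scales the
#'   drainage rate constant.
#' @param tissues Tissues for the NCA table (default: all ocular
#'   compartments plus the combined cornea).
#' @return Object of class `ocat_scenario`: `sim`, `nca` (data.frame
#'   tissue/cmax/tmax/auc), `descriptor`, `drug_diff`.
#' @export
run_scenario <- function(drug, species, regimen, t_grid = NULL,
                         options = sim_options(), tissues = NULL) {
  ph <- get_physiology(species)
  if (is.null(t_grid)) {
    last <- max(regimen$events$time_h)
    t_grid <- sort(unique(c(regimen$events$time_h,
                            last + c(seq(0.05, 1, by = 0.05),
                                     seq(1.25, 24, by = 0.25)))))
  }
  sim <- simulate_ocular(drug, ph$ocular, ph$systemic, regimen,
                         t_grid = t_grid, options = options)
  if (is.null(tissues)) tissues <- c(ocular_compartments(), "cornea")
  tab <- do.call(rbind, lapply(tissues, function(tt) {
    m <- nca(sim$time, tissue_conc(sim, tt))
    data.frame(tissue = tt, cmax = m$cmax, tmax = m$tmax, auc = m$auc)
  }))
  structure(list(
    sim = sim, nca = tab,
    descriptor = list(species = species, regimen = regimen$label,
                      tear_flow_multiplier = options$tear_flow_multiplier %||% 1),
    drug_diff = drug_param_diff(drug, sim$drug)
  ), class = "ocat_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extrapolate a rabbit-validated model to human
#'
#' The translation step: every drug-specific parameter keeps its
#' rabbit-fitted value and only the physiology is exchanged for the human
#' one. The returned scenario's `drug_diff` is empty by construction; a
#' mutated drug record raises an error.
#'
#' @param drug Rabbit-validated `drug_parameters` record.
#' @param clinical_regimen `dose_regimen` matching the clinical study.
#' @param t_grid,options,tissues Passed to [run_scenario()].
#' @return `ocat_scenario` for the human physiology.
#' @export
extrapolate_to_human <- function(drug, clinical_regimen, t_grid = NULL,
                                 options = sim_options(), tissues = NULL) {
  snapshot <- drug
  sc <- run_scenario(drug, "human", clinical_regimen, t_grid = t_grid,
                     options = options, tissues = tissues)
  if (length(drug_param_diff(snapshot, sc$sim$drug)) > 0)
    stop("drug parameters changed between rabbit and human runs")
  sc
}

#' Sensitivity of aqueous humor exposure to tear-flow reduction
#'
#' Re-runs a scenario with the nasolacrimal drainage rate constant scaled
#' by `1 - reduction` for each grid value. Less drainage leaves drug on
#' the eye surface longer, so aqueous humor exposure increases with the
#' reduction.
#'
#' @param drug,species,regimen,t_grid,options As in [run_scenario()].
#' @param reductions Fractional reductions of tear flow in `[0, 0.95]`.
#' @return data.frame with columns `reduction`, `ah_cmax`, `ah_auc`.
#' @export
tear_flow_sensitivity <- function(drug, species, regimen,
                                  reductions = c(0, 0.6, 0.8),
                                  t_grid = NULL, options = sim_options()) {
  stopifnot(all(reductions >= 0), all(reductions <= 0.95))
  rows <- lapply(reductions, function(r) {
    opt <- utils::modifyList(options, list(tear_flow_multiplier = 1 - r))
    sc <- run_scenario(drug, species, regimen, t_grid = t_grid,
                       options = opt, tissues = "AH")
    data.frame(reduction = r, ah_cmax = sc$nca$cmax, ah_auc = sc$nca$auc)
  })
  do.call(rbind, rows)
}

#' Interstudy variability report
#'
#' For tissues observed in at least two studies, reports the fold-range of
#' observed Cmax across studies and where the model prediction falls
#' within it.
#'
#' @param scenario `ocat_scenario` (prediction).
#' @param observed_sets List of `observed_dataset`s (same drug/tissues).
#' @return data.frame: `tissue`, `n_studies`, `obs_cmax_min`,
#'   `obs_cmax_max`, `fold_range`, `pred_cmax`, `within_range`.
#' @export
interstudy_variability_report <- function(scenario, observed_sets) {
  stopifnot(inherits(scenario, "ocat_scenario"))
  obs <- do.call(rbind, lapply(observed_sets, as.data.frame))
  rows <- lapply(unique(obs$tissue), function(tt) {
    per_study <- tapply(obs$conc_ug_per_mL[obs$tissue == tt],
                        obs$study_id[obs$tissue == tt], max)
    if (length(per_study) < 2) return(NULL)
    pred <- scenario$nca$cmax[scenario$nca$tissue == tt]
    if (length(pred) == 0) pred <- NA_real_
    data.frame(tissue = tt, n_studies = length(per_study),
               obs_cmax_min = min(per_study), obs_cmax_max = max(per_study),
               fold_range = max(per_study) / min(per_study),
               pred_cmax = pred,
               within_range = is.finite(pred) & pred >= min(per_study) &
                 pred <= max(per_study))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("need at least two studies on some tissue")
  out
}
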