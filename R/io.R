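#' Write a simulation result as tidy CSV
#'
#' One row per time point and compartment with columns `time_h`,
#' `compartment`, `amount_ug`, `conc_ug_per_mL` (concentration only for
#' ocular compartments; the pre-cornea concentration uses the
#' instantaneous fluid volume). Output is deterministic given identical
#' inputs and options.
#'
#' @param sim `ocat_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  stopifnot(inherits(sim, "ocat_sim"))
  comps <- colnames(sim$amounts)
  df <- do.call(rbind, lapply(comps, function(cc) {
    data.frame(time_h = sim$time, compartment = cc,
               amount_ug = sim$amounts[, cc],
               conc_ug_per_mL = if (cc %in% colnames(sim$conc))
                 sim$conc[, cc] else NA_real_)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write observed datasets in the standard CSV schema
#'
#' Columns: `study_id, tissue, time_h, conc_ug_per_mL, sd, n, loq`
#' (a `blq` column is recomputed from `loq` on read).
#'
#' @param dat `observed_dataset`.
#' @param path CSV path.
#' @return `read_observed_csv` returns an `observed_dataset`.
#' @export
write_observed_csv <- function(dat, path) {
  stopifnot(inherits(dat, "observed_dataset"))
  utils::write.csv(as.data.frame(dat)[, c("study_id", "tissue", "time_h",
                                          "conc_ug_per_mL", "sd", "n",
                                          "loq")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("study_id", "tissue", "time_h", "conc_ug_per_mL")
  if (!all(need %in% names(df)))
    stop("observed CSV must have columns: ", paste(need, collapse = ", "))
  observed_dataset(df$study_id, df$tissue, df$time_h, df$conc_ug_per_mL,
                   sd = if ("sd" %in% names(df)) df$sd else NA_real_,
                   n = if ("n" %in% names(df)) df$n else NA_integer_,
                   loq = if ("loq" %in% names(df)) df$loq else NA_real_)
}

#' Write a run manifest
#'
#' Records command, config digest, package version, seed and output file
#' digests so a run can be reproduced and verified.
#'
#' @param command Stage name.
#' @param config_path Config file used (digested with md5).
#' @param seed Seed used for stochastic steps (NA when none).
#' @param outputs Character vector of output file paths.
#' @param path Manifest JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, config_path, seed, outputs, path) {
  man <- list(
    command = command,
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    package_version = as.character(utils::packageVersion("ocupbpk")),
    seed = seed,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.cfg_regimen <- function(cfg) {
  if (!is.null(cfg$regimen_csv)) return(read_regimen_csv(cfg$regimen_csv))
  expand_regimen(cfg$regimen %||% "single",
                 horizon_h = cfg$horizon_h %||% 24,
                 drop_volume_uL = cfg$drop_volume_uL %||% 30,
                 strength_pct = cfg$strength_pct %||% 0.5)
}

.cfg_options <- function(cfg) {
  opt <- sim_options()
  if (!is.null(cfg$tear_flow_multiplier))
    opt$tear_flow_multiplier <- cfg$tear_flow_multiplier
  if (!is.null(cfg$rtol)) opt$rtol <- cfg$rtol
  if (!is.null(cfg$atol)) opt$atol <- cfg$atol
  opt
}

.read_config <- function(path, required) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse config ", path, ": ", conditionMessage(e)))
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config ", path, " is missing required keys: ",
         paste(missing, collapse = ", "))
  cfg
}

#' Run a simulation from a config file
#'
#' Config keys: `drug`, `species`, `regimen` (or `regimen_csv`),
#' `horizon_h`, `drop_volume_uL`, `strength_pct`, optional
#' `tear_flow_multiplier`, `rtol`, `atol`, `out_csv`, `manifest`.
#'
#' @param config_path YAML config path.
#' @return The `ocat_sim`, invisibly; writes the tidy CSV and a manifest.
#' @export
run_simulation_config <- function(config_path) {
  cfg <- .read_config(config_path, c("drug", "species"))
  drug <- load_drug(cfg$drug)
  ph <- get_physiology(cfg$species)
  reg <- .cfg_regimen(cfg)
  sim <- simulate_ocular(drug, ph$ocular, ph$systemic, reg,
                         options = .cfg_options(cfg))
  out <- cfg$out_csv %||% file.path(dirname(config_path), "simulation.csv")
  write_simulation_csv(sim, out)
  write_manifest("simulate", config_path, NA, out,
                 cfg$manifest %||% paste0(out, ".manifest.json"))
  invisible(sim)
}

#' Run a fitting stage from a config file
#'
#' Config keys: `drug`, `species`, `datasets` (list of observed CSV
#' paths), `regimen`/`horizon_h`/... (shared study design), `free`
#' (parameter paths, at most 4), `init` (initial values), optional
#' `lower`, `upper`, `n_starts`, `seed`, `out_json`.
#'
#' @param config_path YAML config path.
#' @return The `fit_result`, invisibly; writes a JSON report.
#' @export
run_fit_config <- function(config_path) {
  cfg <- .read_config(config_path, c("drug", "species", "datasets", "free",
                                     "init"))
  free <- unlist(cfg$free)
  if (length(free) > 4)
    stop("at most 4 free parameters are supported (got ", length(free), ")")
  for (f in unlist(cfg$datasets)) if (!file.exists(f))
    stop("dataset file not found: ", f)
  datasets <- lapply(unlist(cfg$datasets), read_observed_csv)
  drug <- load_drug(cfg$drug)
  ph <- get_physiology(cfg$species)
  reg <- .cfg_regimen(cfg)
  ctx <- study_context(reg, ph$ocular, ph$systemic, .cfg_options(cfg))
  ids <- unique(unlist(lapply(datasets, function(d) d$study_id)))
  contexts <- stats::setNames(rep(list(ctx), length(ids)), ids)
  init <- unlist(cfg$init)
  spec <- fit_spec(free, init,
                   lower = if (!is.null(cfg$lower)) unlist(cfg$lower)
                   else init / 100,
                   upper = if (!is.null(cfg$upper)) unlist(cfg$upper)
                   else init * 100,
                   n_starts = cfg$n_starts %||% 8, seed = cfg$seed %||% 1)
  fr <- fit_parameters(spec, datasets, drug, contexts)
  out <- cfg$out_json %||% file.path(dirname(config_path), "fit.json")
  jsonlite::write_json(list(
    estimates = as.list(fr$estimates), loss = fr$loss,
    convergence = fr$convergence, starts = fr$starts,
    collinear_pairs = fr$collinear_pairs
  ), out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest("fit", config_path, spec$seed, out,
                 paste0(out, ".manifest.json"))
  invisible(fr)
}

#' Run a human extrapolation from a config file
#'
#' Config keys: `drug`, `regimen`/`horizon_h`/..., optional
#' `tear_flow_reductions` (sensitivity grid), `observed` (CSV overlay),
#' `out_csv`, `out_nca_json`.
#'
#' @param config_path YAML config path.
#' @return The `ocat_scenario`, invisibly; writes outputs + manifest.
#' @export
run_extrapolation_config <- function(config_path) {
  cfg <- .read_config(config_path, c("drug"))
  drug <- load_drug(cfg$drug)
  fitted_any <- any(vapply(drug$provenance, function(s)
    identical(s, "fitted (this package)"), logical(1)))
  if (!fitted_any)
    warning("drug record carries no fit provenance; ",
            "proceeding with shipped parameter values")
  reg <- .cfg_regimen(cfg)
  sc <- extrapolate_to_human(drug, reg, options = .cfg_options(cfg))
  out <- cfg$out_csv %||% file.path(dirname(config_path), "scenario.csv")
  write_simulation_csv(sc$sim, out)
  outs <- out
  nca_path <- cfg$out_nca_json %||% paste0(out, ".nca.json")
  jsonlite::write_json(sc$nca, nca_path, digits = NA, pretty = TRUE)
  outs <- c(outs, nca_path)
  if (!is.null(cfg$tear_flow_reductions)) {
    tf <- tear_flow_sensitivity(drug, "human", reg,
                                reductions = unlist(cfg$tear_flow_reductions),
                                options = .cfg_options(cfg))
    tf_path <- paste0(out, ".tearflow.csv")
    utils::write.csv(tf, tf_path, row.names = FALSE)
    outs <- c(outs, tf_path)
  }
  if (!is.null(cfg$observed)) {
    obs <- lapply(unlist(cfg$observed), read_observed_csv)
    ov <- interstudy_variability_report(sc, obs)
    ov_path <- paste0(out, ".overlay.csv")
    utils::write.csv(ov, ov_path, row.names = FALSE)
    outs <- c(outs, ov_path)
  }
  write_manifest("extrapolate", config_path, NA, outs,
                 paste0(out, ".manifest.json"))
  invisible(sc)
}
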