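#' Set / get drug parameters by path
#'
#' Paths address the estimable entries of a drug record:
#' `"perm.<tissue>"` (ocular permeability, cm/s), `"sar.<route>"`
#' (systemic absorption rate, 1/s) and `"fu_melanin"`.
#'
#' @param drug `drug_parameters` record.
#' @param path Parameter path string.
#' @param value Replacement value (for `set_drug_param`).
#' @return Modified record / current value.
#' @export
set_drug_param <- function(drug, path, value) {
  stopifnot(inherits(drug, "drug_parameters"), is.finite(value))
  if (path == "fu_melanin") {
    drug$fu_melanin <- value
  } else if (grepl("^perm\\.", path)) {
    key <- sub("^perm\\.", "", path)
    if (!key %in% names(drug$perm_cm_s)) stop("unknown tissue in ", path)
    drug$perm_cm_s[[key]] <- value
  } else if (grepl("^sar\\.", path)) {
    key <- sub("^sar\\.", "", path)
    if (!key %in% names(drug$sar_per_s)) stop("unknown route in ", path)
    drug$sar_per_s[[key]] <- value
  } else {
    stop("unsupported parameter path '", path, "'")
  }
  drug
}

#' @rdname set_drug_param
#' @export
get_drug_param <- function(drug, path) {
  if (path == "fu_melanin") return(drug$fu_melanin)
  if (grepl("^perm\\.", path)) return(drug$perm_cm_s[[sub("^perm\\.", "", path)]])
  if (grepl("^sar\\.", path)) return(drug$sar_per_s[[sub("^sar\\.", "", path)]])
  stop("unsupported parameter path '", path, "'")
}

#' Construct an observed-tissue-concentration dataset
#'
#' The common currency of fitting and synthetic generation: sparse records
#' of tissue concentration vs time with optional dispersion and
#' below-limit-of-quantification (BLQ) flags.
#'
#' @param study_id Study code.
#' @param tissue Tissue ids (model compartments, or `"cornea"` for the
#'   combined cornea).
#' @param time_h Sampling times, h.
#' @param conc_ug_per_mL Concentrations, ug/mL.
#' @param sd,n Optional per-record standard deviation / replicate count.
#' @param loq Assay limit of quantification (ug/mL); records below it are
#'   flagged `blq`.
#' @return data.frame of class `observed_dataset`.
#' @export
observed_dataset <- function(study_id, tissue, time_h, conc_ug_per_mL,
                             sd = NA_real_, n = NA_integer_,
                             loq = NA_real_) {
  stopifnot(all(time_h >= 0), all(conc_ug_per_mL >= 0 | is.na(conc_ug_per_mL)))
  df <- data.frame(study_id = study_id, tissue = tissue, time_h = time_h,
                   conc_ug_per_mL = conc_ug_per_mL, sd = sd, n = n,
                   loq = loq)
  df$blq <- !is.na(df$loq) & df$conc_ug_per_mL < df$loq
  class(df) <- c("observed_dataset", "data.frame")
  df
}

#' Study context for fitting
#'
#' Binds a study id to the inputs needed to reproduce its simulation.
#'
#' @param regimen `dose_regimen`.
#' @param phys,sys_phys Species physiology records.
#' @param options Simulation options ([sim_options()]).
#' @return List of class `study_context`.
#' @export
study_context <- function(regimen, phys, sys_phys, options = sim_options()) {
  structure(list(regimen = regimen, phys = phys, sys_phys = sys_phys,
                 options = options), class = "study_context")
}

# Predictions for every record of a dataset stack, one simulation per study.
predict_dataset <- function(drug, datasets, contexts) {
  dat <- do.call(rbind, lapply(datasets, as.data.frame))
  pred <- numeric(nrow(dat))
  for (sid in unique(dat$study_id)) {
    ctx <- contexts[[sid]]
    if (is.null(ctx)) stop("no study context for study '", sid, "'")
    rows <- which(dat$study_id == sid)
    times <- sort(unique(dat$time_h[rows]))
    sim <- simulate_ocular(drug, ctx$phys, ctx$sys_phys, ctx$regimen,
                           t_grid = sort(unique(c(times,
                                                  ctx$regimen$events$time_h))),
                           options = ctx$options)
    for (tt in unique(dat$tissue[rows])) {
      series <- tissue_conc(sim, tt)
      sel <- rows[dat$tissue[rows] == tt]
      pred[sel] <- series[match(round(dat$time_h[sel], 10),
                                round(sim$time, 10))]
    }
  }
  pred
}

#' Log-scale least-squares objective
#'
#' Sum over records of `(log(pred + eps) - log(obs + eps))^2` with
#' `eps = LOQ/2` (tissue concentrations span several orders of magnitude
#' across compartments, so log residuals weight all tissues comparably).
#' BLQ records contribute one-sidedly: `max(0, log(pred) - log(LOQ))^2`.
#'
#' @param values Numeric vector of trial values for the free parameters.
#' @param free Character vector of parameter paths (see
#'   [set_drug_param()]).
#' @param drug Base `drug_parameters` record.
#' @param datasets List of `observed_dataset`s (or a single one).
#' @param contexts Named list of `study_context`s keyed by study id.
#' @return Scalar loss.
#' @export
fit_objective <- function(values, free, drug, datasets, contexts) {
  if (inherits(datasets, "observed_dataset")) datasets <- list(datasets)
  dat <- do.call(rbind, lapply(datasets, as.data.frame))
  if (nrow(dat) == 0) stop("empty dataset")
  for (i in seq_along(free)) drug <- set_drug_param(drug, free[i], values[i])
  pred <- predict_dataset(drug, datasets, contexts)
  eps <- ifelse(is.na(dat$loq), 0, dat$loq / 2)
  resid2 <- ifelse(
    dat$blq,
    pmax(0, log(pmax(pred, 1e-300)) - log(dat$loq))^2,
    (log(pred + eps + 1e-300) - log(dat$conc_ug_per_mL + eps + 1e-300))^2
  )
  sum(resid2)
}

#' Specification of a fit
#'
#' @param free Character vector of parameter paths, at most 4 (fitting
#'   philosophy: a minimal subset of drug-specific parameters).
#' @param init Named or positional initial values (natural scale).
#' @param lower,upper Bounds (natural scale); default spans 100-fold around
#'   the initial values in each direction.
#' @param n_starts Number of optimization starts (the first is `init`, the
#'   rest log-uniform in the bounds).
#' @param seed RNG seed for the extra starts.
#' @return List of class `fit_spec`.
#' @export
fit_spec <- function(free, init, lower = init / 100, upper = init * 100,
                     n_starts = 8, seed = 1) {
  stopifnot(length(free) >= 1, length(free) <= 4,
            length(init) == length(free), all(init > 0),
            all(lower > 0), all(upper > lower), all(init >= lower),
            all(init <= upper))
  structure(list(free = free, init = init, lower = lower, upper = upper,
                 n_starts = n_starts, seed = seed), class = "fit_spec")
}

#' Fit drug-specific parameters to observed tissue concentrations
#'
#' Multi-start local optimization of [fit_objective()] in log10-parameter
#' space (Brent for one free parameter, Nelder-Mead with a polish restart
#' otherwise). Deterministic given the spec's seed.
#'
#' @param spec `fit_spec`.
#' @param datasets List of `observed_dataset`s (or a single one).
#' @param drug Base `drug_parameters` record (free entries are replaced
#'   during optimization).
#' @param contexts Named list of `study_context`s keyed by study id.
#' @return List of class `fit_result`: `estimates` (named, natural scale),
#'   `loss`, `convergence` (TRUE when the best start converged), `starts`
#'   (per-start data.frame), `residuals` (log-scale, per record),
#'   `sensitivity_correlation` (matrix; pairs with |r| > 0.98 are reported
#'   in `collinear_pairs`), and the updated `drug` record with fit
#'   provenance tags.
#' @export
fit_parameters <- function(spec, datasets, drug, contexts) {
  stopifnot(inherits(spec, "fit_spec"))
  if (inherits(datasets, "observed_dataset")) datasets <- list(datasets)
  lo <- log10(spec$lower); hi <- log10(spec$upper)
  obj_log <- function(lp) {
    if (any(lp < lo - 1e-12) || any(lp > hi + 1e-12)) return(1e10)
    fit_objective(10^lp, spec$free, drug, datasets, contexts)
  }
  # seeded, RNG-state-preserving start generation
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  starts <- rbind(log10(spec$init),
                  if (spec$n_starts > 1)
                    matrix(stats::runif((spec$n_starts - 1) * length(lo),
                                        rep(lo, each = spec$n_starts - 1),
                                        rep(hi, each = spec$n_starts - 1)),
                           ncol = length(lo)))
  res <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    if (length(spec$free) == 1) {
      o <- stats::optim(starts[s, ], obj_log, method = "Brent",
                        lower = lo, upper = hi,
                        control = list(reltol = 1e-12))
    } else {
      o <- stats::optim(starts[s, ], obj_log, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 1000))
      o <- stats::optim(o$par, obj_log, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 1000))
    }
    res[[s]] <- o
  }
  losses <- vapply(res, function(o) o$value, numeric(1))
  best <- res[[which.min(losses)]]
  est <- stats::setNames(10^best$par, spec$free)
  drug_fit <- drug
  for (i in seq_along(spec$free)) {
    drug_fit <- set_drug_param(drug_fit, spec$free[i], est[[i]])
    drug_fit$provenance[[spec$free[i]]] <- "fitted (this package)"
  }
  dat <- do.call(rbind, lapply(datasets, as.data.frame))
  pred <- predict_dataset(drug_fit, datasets, contexts)
  eps <- ifelse(is.na(dat$loq), 0, dat$loq / 2)
  residuals <- log(pred + eps + 1e-300) -
    log(dat$conc_ug_per_mL + eps + 1e-300)
  sens <- .sensitivity_correlation(drug_fit, spec$free, datasets, contexts)
  collinear <- character(0)
  if (length(spec$free) > 1) {
    cm <- sens
    for (i in seq_len(ncol(cm) - 1)) for (j in (i + 1):ncol(cm)) {
      if (is.finite(cm[i, j]) && abs(cm[i, j]) > 0.98)
        collinear <- c(collinear,
                       paste(spec$free[i], spec$free[j], sep = " ~ "))
    }
  }
  structure(list(
    estimates = est, loss = best$value,
    convergence = best$convergence == 0,
    starts = data.frame(start = seq_along(losses), loss = losses,
                        converged = vapply(res, function(o)
                          o$convergence == 0, logical(1))),
    residuals = residuals,
    sensitivity_correlation = sens,
    collinear_pairs = collinear,
    drug = drug_fit
  ), class = "fit_result")
}

# correlation of per-record log-prediction sensitivities between free
# parameters (identifiability guard)
.sensitivity_correlation <- function(drug, free, datasets, contexts,
                                     rel_step = 0.05) {
  base <- log(pmax(predict_dataset(drug, datasets, contexts), 1e-300))
  jac <- vapply(free, function(p) {
    v <- get_drug_param(drug, p)
    d2 <- set_drug_param(drug, p, v * (1 + rel_step))
    (log(pmax(predict_dataset(d2, datasets, contexts), 1e-300)) - base) /
      log(1 + rel_step)
  }, numeric(length(base)))
  if (length(free) == 1) return(matrix(1, 1, 1,
                                       dimnames = list(free, free)))
  stats::cor(jac)
}

#' Single-parameter melanin-binding fit on pigmented-species data
#'
#' The staged workflow: permeabilities and absorption rates are frozen at
#' their albino-rabbit-validated values and only the melanin unbound
#' fraction is estimated, on log scale, from pigmented-tissue (typically
#' iris-ciliary body) data. The estimate applies to all melanin-containing
#' tissues (ICB, retina, choroid, sclera) through the shared pigmentation
#' flags.
#'
#' @param datasets_db `observed_dataset`(s) from a pigmented-species study.
#' @param drug `drug_parameters` with albino-validated values.
#' @param contexts Named `study_context` list (pigmented species).
#' @param init Initial fu_melanin (default: 10x the record's value).
#' @param lower,upper Bounds on fu_melanin.
#' @param seed RNG seed.
#' @return `fit_result` with an extra logical `flat_profile_warning`
#'   element: `TRUE` when the pigmented-tissue data span less than a
#'   two-fold concentration range (little information about binding).
#' @export
melanin_fit <- function(datasets_db, drug, contexts,
                        init = 10 * drug$fu_melanin,
                        lower = 1e-5, upper = 1, seed = 1) {
  spec <- fit_spec("fu_melanin", init = init, lower = lower, upper = upper,
                   n_starts = 1, seed = seed)
  fr <- fit_parameters(spec, datasets_db, drug, contexts)
  dat <- if (inherits(datasets_db, "observed_dataset"))
    as.data.frame(datasets_db) else
      do.call(rbind, lapply(datasets_db, as.data.frame))
  pig <- dat[dat$tissue %in% c("ICB", "retina", "choroid", "sclera") &
               !dat$blq, ]
  flat <- nrow(pig) > 0 &&
    max(pig$conc_ug_per_mL) < 2 * max(min(pig$conc_ug_per_mL), 1e-300)
  fr$flat_profile_warning <- flat
  fr
}
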