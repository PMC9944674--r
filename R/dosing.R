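#' Construct an eye-drop dosing regimen
#'
#' @param time_h Numeric vector of instillation times (h), strictly
#'   increasing.
#' @param drop_volume_uL Drop volume(s), uL (recycled).
#' @param strength_pct Solution strength(s), percent w/v (g/100 mL,
#'   recycled). The instilled amount per drop is
#'   `drop_volume_uL * strength_pct * 10` micrograms.
#' @param label Free-text description.
#' @return Object of class `dose_regimen`: data.frame of events plus label.
#' @export
dose_regimen <- function(time_h, drop_volume_uL = 30, strength_pct = 0.5,
                         label = "") {
  stopifnot(length(time_h) >= 1, all(is.finite(time_h)), all(time_h >= 0))
  if (is.unsorted(time_h, strictly = TRUE))
    stop("event times must be strictly increasing")
  ev <- data.frame(time_h = time_h,
                   drop_volume_uL = rep_len(drop_volume_uL, length(time_h)),
                   strength_pct = rep_len(strength_pct, length(time_h)))
  if (any(ev$drop_volume_uL < 0) || any(ev$strength_pct < 0))
    stop("drop volumes and strengths must be non-negative")
  ev$dose_ug <- ev$drop_volume_uL * ev$strength_pct * 10
  structure(list(events = ev, label = label), class = "dose_regimen")
}

#' Apply an instilled drop to the pre-cornea compartment
#'
#' Implements the overflow rule of the tear-film model: the instilled
#' fluid mixes instantaneously with the resident tear fluid, the volume is
#' capped at the species maximum pre-cornea volume, and any excess volume
#' is discarded at the mixed concentration (so discarded drug mass is
#' proportional to the discarded volume). Setting `mix = FALSE` discards
#' pure instilled fluid instead.
#'
#' @param precornea_volume_uL Resident fluid volume (uL), at least the
#'   physiological tear volume.
#' @param precornea_amount_ug Resident drug amount (ug).
#' @param drop_volume_uL,strength_pct Drop volume (uL) and strength (% w/v).
#' @param phys `ocular_physiology` record (for tear volume and cap).
#' @param mix Mix before overflow (default) or discard pure drop fluid.
#' @return List with `volume_uL`, `amount_ug`, `discarded_ug`. Mass is
#'   conserved exactly: retained + discarded = resident + instilled.
#' @examples
#' phys <- get_physiology("NZ_rabbit")$ocular
#' apply_drop(5, 0, 30, 0.5, phys)  # fills the 35 uL cap, 1500 ug retained
#' @export
apply_drop <- function(precornea_volume_uL, precornea_amount_ug,
                       drop_volume_uL, strength_pct, phys, mix = TRUE) {
  stopifnot(inherits(phys, "ocular_physiology"))
  v_max <- phys$precornea_max_volume_mL * 1000
  v_tear <- phys$tear_volume_mL * 1000
  if (precornea_volume_uL < v_tear - 1e-9)
    stop("precornea volume below physiological tear volume")
  dose_ug <- drop_volume_uL * strength_pct * 10
  v_tot <- precornea_volume_uL + drop_volume_uL
  a_tot <- precornea_amount_ug + dose_ug
  v_new <- min(v_tot, v_max)
  v_exc <- v_tot - v_new
  if (v_exc <= 0) {
    disc <- 0
  } else if (mix) {
    disc <- a_tot * v_exc / v_tot
  } else {
    # discard pure instilled fluid (capped at the drop volume)
    v_drop_out <- min(v_exc, drop_volume_uL)
    disc <- if (drop_volume_uL > 0) dose_ug * v_drop_out / drop_volume_uL else 0
    # any remainder comes out mixed
    v_rem <- v_exc - v_drop_out
    if (v_rem > 0) disc <- disc + (a_tot - disc) * v_rem / (v_tot - v_drop_out)
  }
  list(volume_uL = v_new, amount_ug = a_tot - disc, discarded_ug = disc)
}

#' Expand a schedule specification into a dosing regimen
#'
#' Grammar (case-insensitive):
#' \itemize{
#'   \item `"single"` — one drop at t = 0;
#'   \item `"q<N><min|h>x<M>"` — M drops spaced N minutes/hours, starting
#'     at t = 0 (e.g. `"q15minx3"` gives 0, 0.25, 0.5 h);
#'   \item `"<QD|BID|TID|QID>x<D>d"` — 1/2/3/4 drops per day for D days,
#'     spread evenly over a waking window starting at the beginning of
#'     each day (e.g. `"QIDx3d"` gives 12 events).
#' }
#' A multiplication sign is accepted in place of `x`.
#'
#' @param spec Schedule string.
#' @param horizon_h Simulation horizon (h); events beyond it are dropped
#'   (at least one event must remain).
#' @param drop_volume_uL,strength_pct Passed to [dose_regimen()].
#' @param waking_window_h Window over which daily doses are spread
#'   (default 16 h; clinical sources rarely report clock times).
#' @return A `dose_regimen`.
#' @export
expand_regimen <- function(spec, horizon_h, drop_volume_uL = 30,
                           strength_pct = 0.5, waking_window_h = 16) {
  stopifnot(is.character(spec), length(spec) == 1, horizon_h > 0)
  s <- tolower(gsub("×", "x", trimws(spec)))
  if (s == "single") {
    times <- 0
  } else if (grepl("^q([0-9.]+)(min|h)x([0-9]+)$", s)) {
    m <- regmatches(s, regexec("^q([0-9.]+)(min|h)x([0-9]+)$", s))[[1]]
    step <- as.numeric(m[2]) * if (m[3] == "min") 1 / 60 else 1
    n <- as.integer(m[4])
    times <- step * (seq_len(n) - 1)
  } else if (grepl("^(qd|bid|tid|qid)x([0-9]+)d$", s)) {
    m <- regmatches(s, regexec("^(qd|bid|tid|qid)x([0-9]+)d$", s))[[1]]
    per_day <- c(qd = 1, bid = 2, tid = 3, qid = 4)[[m[2]]]
    days <- as.integer(m[3])
    daily <- if (per_day == 1) 0 else
      seq(0, waking_window_h, length.out = per_day)
    times <- as.vector(outer(daily, 24 * (seq_len(days) - 1), `+`))
    times <- sort(times)
  } else {
    stop("cannot parse schedule spec '", spec,
         "': expected 'single', 'q<N><min|h>x<M>' or '<QD|BID|TID|QID>x<D>d'")
  }
  times <- times[times <= horizon_h]
  if (length(times) == 0) stop("no events fall within the horizon")
  dose_regimen(times, drop_volume_uL, strength_pct, label = spec)
}

#' Read a dosing regimen from CSV
#'
#' Expects columns `time_h`, `volume_uL`, `strength_pct`.
#'
#' @param path CSV file path.
#' @return A `dose_regimen`.
#' @export
read_regimen_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "volume_uL", "strength_pct")
  if (!all(need %in% names(df)))
    stop("regimen CSV must have columns: ", paste(need, collapse = ", "))
  dose_regimen(df$time_h, df$volume_uL, df$strength_pct,
               label = basename(path))
}
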