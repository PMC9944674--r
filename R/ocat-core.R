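#' Ocular compartment exchange topology
#'
#' The ten passive-exchange interfaces of the ocular model. Parameter sets
#' of this kind name one permeability per tissue, not per interface, so
#' interface permeabilities follow a uniform "inner tissue" rule: the
#' permeability named for a tissue governs exchange across that tissue's
#' outer-facing interface(s). The topology is kept in this one declarative
#' table so it can be revised without touching the solver.
#'
#' @return data.frame with columns `outer`, `inner` (compartment ids),
#'   `perm` (the drug permeability entry governing the interface) and
#'   `surface` (the exchange-surface key in the physiology file).
#' @export
ocular_topology <- function() {
  data.frame(
    outer = c("precornea", "precornea", "cornea_epi", "cornea_stroma",
              "AH", "ICB", "conjunctiva", "sclera", "choroid", "retina"),
    inner = c("cornea_epi", "conjunctiva", "cornea_stroma", "AH",
              "ICB", "VH", "sclera", "choroid", "retina", "VH"),
    perm = c("cornea_epi", "conjunctiva", "cornea_stroma", "AH",
             "ICB", "VH", "sclera", "choroid", "retina", "VH"),
    surface = c("precornea.cornea_epi", "precornea.conjunctiva",
                "cornea_epi.cornea_stroma", "cornea_stroma.AH",
                "AH.ICB", "ICB.VH", "conjunctiva.sclera", "sclera.choroid",
                "choroid.retina", "retina.VH"),
    stringsAsFactors = FALSE
  )
}

# Routes with a first-order systemic absorption rate constant.
sar_routes <- function() c("conjunctiva", "ICB", "choroid", "retina")

.species_group <- function(species_id) {
  if (species_id %in% c("NZ_rabbit", "DB_rabbit")) "rabbit" else "human"
}

#' Default simulation options
#'
#' @param rtol,atol Solver relative/absolute tolerances. The defaults are
#'   tight because the tear film drains fast (60 per hour) next to slow
#'   tissue kinetics.
#' @param couple_systemic Couple the ocular model to the whole-body model
#'   (drained drug enters the gut lumen, systemic absorption routes feed
#'   venous blood, unbound plasma drug back-partitions into vascularized
#'   ocular tissues). When `FALSE` those routes become terminal sinks.
#' @param tear_flow_multiplier Scales the nasolacrimal drainage rate
#'   constant (scenario analysis of reduced tear turnover).
#' @param fu_melanin_override Optional replacement for the drug's melanin
#'   unbound fraction.
#' @param mix_before_overflow Overflow rule for [apply_drop()].
#' @return Named list of options.
#' @export
sim_options <- function(rtol = 1e-8, atol = 1e-10, couple_systemic = TRUE,
                        tear_flow_multiplier = 1, fu_melanin_override = NULL,
                        mix_before_overflow = TRUE) {
  list(rtol = rtol, atol = atol, couple_systemic = couple_systemic,
       tear_flow_multiplier = tear_flow_multiplier,
       fu_melanin_override = fu_melanin_override,
       mix_before_overflow = mix_before_overflow)
}

#' Unbound concentration driving inter-compartment transfer
#'
#' In pigmented tissues (melanin-containing: iris-ciliary body, retina,
#' choroid, sclera, when the species' pigmentation flag is set) only the
#' melanin-unbound fraction of drug drives passive transfer; elsewhere the
#' total concentration does. Binding is linear (a single unbound fraction,
#' no capacity limit).
#'
#' @param compartment Compartment id (see [ocular_compartments()]).
#' @param total_conc Total tissue concentration (ug/mL).
#' @param drug `drug_parameters` record.
#' @param phys `ocular_physiology` record.
#' @return Unbound concentration (ug/mL).
#' @export
unbound_concentration <- function(compartment, total_conc, drug, phys) {
  stopifnot(compartment %in% ocular_compartments())
  pig <- compartment %in% names(phys$pigmented) &&
    isTRUE(phys$pigmented[[compartment]])
  if (pig) drug$fu_melanin * total_conc else total_conc
}

# Build the flattened parameter/closure environment for the coupled ODE.
.build_model <- function(drug, phys, sys_phys, options) {
  comps <- ocular_compartments()
  tissues9 <- setdiff(comps, "precornea")
  vols <- phys$compartment_volumes_mL[tissues9]
  topo <- ocular_topology()
  g <- drug$perm_cm_s[topo$perm] * 3600 *
    phys$exchange_surfaces_cm2[topo$surface]          # mL/h
  i_idx <- match(topo$outer, comps)
  j_idx <- match(topo$inner, comps)
  fu_mel <- if (!is.null(options$fu_melanin_override))
    options$fu_melanin_override else drug$fu_melanin
  fu_comp <- stats::setNames(rep(1, length(comps)), comps)
  for (tt in names(phys$pigmented))
    if (isTRUE(phys$pigmented[[tt]])) fu_comp[tt] <- fu_mel
  sar_h <- drug$sar_per_s[sar_routes()] * 3600        # 1/h
  grp <- .species_group(phys$species_id)
  rbp <- drug$rbp[[grp]]
  fu_p <- drug$fu_plasma
  st <- sys_phys$tissues
  kp <- calc_kp(drug, species = grp)$kp[st$tissue]
  kp[is.na(kp)] <- 1
  co <- sys_phys$cardiac_output_mL_h
  lung_i <- which(st$tissue == "lung")
  liver_i <- which(st$tissue == "liver")
  kidney_i <- which(st$tissue == "kidney")
  periph <- setdiff(seq_len(nrow(st)), lung_i)
  shunt <- co - sum(st$flow_mL_h[periph])
  ka <- drug$peff_cm_s[[grp]] * 2e4                   # 1/h; Peff 2e-4 -> 4/h
  kfec <- 0.25                                        # 1/h gut transit loss
  list(
    comps = comps, tissues9 = tissues9, vols = unname(vols),
    g = unname(g), i_idx = i_idx, j_idx = j_idx,
    fu_comp = unname(fu_comp),
    k_drain = phys$drainage_rate_per_h * options$tear_flow_multiplier,
    v_tear = phys$tear_volume_mL,
    v_max = phys$precornea_max_volume_mL,
    q_ah = phys$aqueous_turnover_mL_h,
    ah_i = match("AH", comps),
    sar_h = unname(sar_h),
    sar_i = match(sar_routes(), comps),
    sar_vol = unname(phys$compartment_volumes_mL[sar_routes()]),
    rbp = rbp, fu_p = fu_p,
    sys_names = st$tissue, sys_vol = st$volume_mL, sys_q = st$flow_mL_h,
    kp = unname(kp), co = co, shunt = shunt,
    lung_i = lung_i, liver_i = liver_i, kidney_i = kidney_i, periph = periph,
    v_ven = sys_phys$venous_volume_mL, v_art = sys_phys$arterial_volume_mL,
    renal_fr = drug$renal_fraction[[grp]],
    clint_mL_h = drug$clint_L_h[[grp]] * 1000,
    ka = ka, kfec = kfec,
    couple = isTRUE(options$couple_systemic)
  )
}

# state layout: [1] V_pc, [2:11] ocular amounts (ocular_compartments order),
# [12] gut lumen, [13] venous, [14] arterial, [15:(14+nT)] systemic tissues,
# then 5 ledgers: drained, absorbed_systemic, renal, hepatic, fecal.
.state_template <- function(m) {
  nT <- length(m$sys_names)
  n <- 14 + nT + 5
  nm <- c("V_pc", m$comps, "gut_lumen", "venous", "arterial", m$sys_names,
          "led_drained", "led_absorbed", "led_renal", "led_hepatic",
          "led_fecal")
  stats::setNames(numeric(n), nm)
}

.make_rhs <- function(m) {
  nT <- length(m$sys_names)
  oc_i <- 2:11
  gut_i <- 12L; ven_i <- 13L; art_i <- 14L
  sys_i <- 15L:(14L + nT)
  led_i <- (14L + nT) + 1:5
  force(m)
  function(t, y, parms) {
    V <- y[1]
    drain_q <- m$k_drain * (V - m$v_tear)           # mL/h
    c_pre <- if (V > 0) y[2] / V else 0
    drug_drain <- drain_q * c_pre
    conc9 <- y[3:11] / m$vols
    cu <- c(c_pre, conc9) * m$fu_comp
    dA <- numeric(10)
    fl <- m$g * (cu[m$i_idx] - cu[m$j_idx])
    for (k in seq_along(fl)) {
      dA[m$i_idx[k]] <- dA[m$i_idx[k]] - fl[k]
      dA[m$j_idx[k]] <- dA[m$j_idx[k]] + fl[k]
    }
    dA[1] <- dA[1] - drug_drain
    ah_out <- m$q_ah * conc9[m$ah_i - 1]
    dA[m$ah_i] <- dA[m$ah_i] - ah_out
    sar_out <- m$sar_h * y[m$sar_i + 1]             # amounts offset by V_pc
    dA[m$sar_i] <- dA[m$sar_i] - sar_out
    dy <- numeric(length(y))
    dy[1] <- -drain_q
    dled <- numeric(5)
    dled[1] <- drug_drain
    dled[2] <- sum(sar_out) + ah_out
    if (m$couple) {
      a_sys <- y[sys_i]
      c_sys <- a_sys / m$sys_vol
      cvb <- c_sys * m$rbp / m$kp
      c_ven <- y[ven_i] / m$v_ven
      c_art <- y[art_i] / m$v_art
      c_plasma <- c_ven / m$rbp
      reentry <- m$sar_h * m$sar_vol * m$fu_p * c_plasma
      dA[m$sar_i] <- dA[m$sar_i] + reentry
      dsys <- numeric(nT)
      dsys[m$lung_i] <- m$co * (c_ven - cvb[m$lung_i])
      dsys[m$periph] <- m$sys_q[m$periph] * (c_art - cvb[m$periph])
      renal <- m$renal_fr * m$sys_q[m$kidney_i] * c_art
      dsys[m$kidney_i] <- dsys[m$kidney_i] - renal
      hep <- m$clint_mL_h * m$fu_p * c_sys[m$liver_i] / m$kp[m$liver_i]
      abs_gut <- m$ka * y[gut_i]
      fec <- m$kfec * y[gut_i]
      dsys[m$liver_i] <- dsys[m$liver_i] + abs_gut - hep
      dy[gut_i] <- drug_drain - abs_gut - fec
      dy[ven_i] <- sum(m$sys_q[m$periph] * cvb[m$periph]) +
        m$shunt * c_art - m$co * c_ven + sum(sar_out) + ah_out - sum(reentry)
      dy[art_i] <- m$co * cvb[m$lung_i] - m$co * c_art
      dy[sys_i] <- dsys
      dled[3] <- renal
      dled[4] <- hep
      dled[5] <- fec
    }
    dy[oc_i] <- dA
    dy[led_i] <- dled
    list(dy)
  }
}

#' Simulate ocular (and coupled systemic) drug disposition
#'
#' Integrates the coupled tear-film / ocular-tissue / whole-body ODE system
#' for an eye-drop regimen. Tear-film dynamics follow
#' `dV/dt = -k_drain (V - V_tear)`; drug leaves the pre-cornea compartment
#' with the drained fluid at the current mixed concentration; passive
#' transfer between adjacent compartments is
#' `Perm * SA * (Cu_outer - Cu_inner)` with `Cu` the melanin-unbound
#' concentration in pigmented tissues; aqueous humor turnover carries drug
#' from the anterior chamber into venous blood; first-order systemic
#' absorption routes drain the vascularized tissues, and unbound plasma
#' drug re-enters those tissues symmetrically. Integration is restarted at
#' every instillation event, where the drop is applied with the
#' volume-cap/discard rule of [apply_drop()].
#'
#' @param drug `drug_parameters` record from [load_drug()] (possibly with
#'   modified entries).
#' @param phys `ocular_physiology` record.
#' @param sys_phys `systemic_physiology` record of the same species.
#' @param regimen `dose_regimen`.
#' @param t_grid Output time grid (h); must cover the regimen. Defaults to
#'   a log-spaced-ish grid over 24 h past the last dose.
#' @param options See [sim_options()].
#' @return Object of class `ocat_sim`: list with `time`, `amounts`
#'   (time x compartment matrix, ug; includes gut lumen and systemic
#'   tissues), `conc` (time x ocular compartment, ug/mL; pre-cornea uses
#'   the instantaneous fluid volume), `precornea_volume_uL`, `ledgers`
#'   (cumulative drained/absorbed/renal/hepatic/fecal plus the event-driven
#'   `discarded`), `dose_instilled_ug`, `dose_retained_ug`, and metadata.
#' @export
simulate_ocular <- function(drug, phys, sys_phys, regimen, t_grid = NULL,
                            options = sim_options()) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(phys, "ocular_physiology"),
            inherits(sys_phys, "systemic_physiology"),
            inherits(regimen, "dose_regimen"))
  if (phys$species_id != sys_phys$species_id)
    stop("ocular and systemic physiologies are for different species (",
         phys$species_id, " vs ", sys_phys$species_id, ")")
  options <- utils::modifyList(sim_options(), options)
  ev <- regimen$events
  if (is.null(t_grid))
    t_grid <- sort(unique(c(ev$time_h, max(ev$time_h) + c(
      0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 16, 24))))
  if (max(t_grid) < max(ev$time_h))
    stop("t_grid must cover the dosing regimen")
  t_grid <- sort(unique(c(0, t_grid)))
  m <- .build_model(drug, phys, sys_phys, options)
  rhs <- .make_rhs(m)
  y <- .state_template(m)
  y["V_pc"] <- phys$tear_volume_mL
  bounds <- sort(unique(c(0, ev$time_h, max(t_grid))))
  out_rows <- matrix(NA_real_, nrow = length(t_grid),
                     ncol = length(y), dimnames = list(NULL, names(y)))
  disc_series <- numeric(length(t_grid))
  disc_cum <- 0
  # record state at t=0 after any t=0 dose below
  for (b in seq_len(length(bounds))) {
    t0 <- bounds[b]
    ev_here <- which(abs(ev$time_h - t0) < 1e-12)
    if (length(ev_here) == 1) {
      upd <- apply_drop(y[["V_pc"]] * 1000, y[["precornea"]],
                        ev$drop_volume_uL[ev_here], ev$strength_pct[ev_here],
                        phys, mix = options$mix_before_overflow)
      y[["V_pc"]] <- upd$volume_uL / 1000
      y[["precornea"]] <- upd$amount_ug
      disc_cum <- disc_cum + upd$discarded_ug
    }
    if (b == length(bounds)) {
      sel <- which(abs(t_grid - t0) < 1e-12)
      if (length(sel)) {
        out_rows[sel, ] <- matrix(y, nrow = length(sel), ncol = length(y),
                                  byrow = TRUE)
        disc_series[sel] <- disc_cum
      }
      break
    }
    t1 <- bounds[b + 1]
    seg_t <- sort(unique(c(t0, t_grid[t_grid > t0 + 1e-12 &
                                        t_grid < t1 - 1e-12], t1)))
    sol <- deSolve::lsoda(y = unname(y), times = seg_t, func = rhs,
                          parms = NULL, rtol = options$rtol,
                          atol = options$atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed near t = ", utils::tail(sol[, 1], 1), " h")
    sel0 <- which(abs(t_grid - t0) < 1e-12)
    if (length(sel0)) {
      out_rows[sel0, ] <- matrix(y, nrow = length(sel0), ncol = length(y),
                                 byrow = TRUE)
      disc_series[sel0] <- disc_cum
    }
    for (ti in seq_along(seg_t)) {
      sel <- which(abs(t_grid - seg_t[ti]) < 1e-12 & t_grid > t0 + 1e-12)
      if (length(sel)) {
        out_rows[sel, ] <- matrix(sol[ti, -1], nrow = length(sel),
                                  ncol = length(y), byrow = TRUE)
        disc_series[sel] <- disc_cum
      }
    }
    y[] <- sol[nrow(sol), -1]
  }
  amounts <- out_rows[, c(ocular_compartments(), "gut_lumen", "venous",
                          "arterial", m$sys_names), drop = FALSE]
  neg_tol <- max(options$atol * 100, 1e-9 * max(amounts, 1e-30))
  if (min(amounts) < -neg_tol)
    stop("negative state beyond tolerance (min = ", min(amounts), " ug)")
  vols9 <- phys$compartment_volumes_mL[setdiff(ocular_compartments(),
                                               "precornea")]
  conc <- out_rows[, ocular_compartments(), drop = FALSE]
  conc[, "precornea"] <- conc[, "precornea"] / out_rows[, "V_pc"]
  for (tt in names(vols9)) conc[, tt] <- conc[, tt] / vols9[[tt]]
  ledgers <- cbind(out_rows[, c("led_drained", "led_absorbed", "led_renal",
                                "led_hepatic", "led_fecal"), drop = FALSE],
                   discarded = disc_series)
  colnames(ledgers) <- c("drained_to_gut", "absorbed_systemic", "renal",
                         "hepatic", "fecal_unabsorbed", "discarded")
  structure(list(
    time = t_grid,
    amounts = amounts,
    conc = conc,
    precornea_volume_uL = out_rows[, "V_pc"] * 1000,
    ledgers = ledgers,
    dose_instilled_ug = sum(ev$dose_ug),
    dose_retained_ug = sum(ev$dose_ug) - disc_cum,
    drug = drug, species = phys$species_id, regimen = regimen,
    options = options
  ), class = "ocat_sim")
}

#' Concentration series for a (possibly composite) tissue
#'
#' `"cornea"` is the amount-weighted whole cornea (epithelium + stroma),
#' matching how ocular tissue assays report whole-cornea concentrations;
#' other ids map directly to model compartments.
#'
#' @param sim `ocat_sim` result.
#' @param tissue Tissue id: a model compartment or `"cornea"`.
#' @return Numeric vector of concentrations (ug/mL) on `sim$time`.
#' @export
tissue_conc <- function(sim, tissue) {
  stopifnot(inherits(sim, "ocat_sim"))
  if (tissue == "cornea") {
    vols <- get_physiology(sim$species)$ocular$compartment_volumes_mL
    return((sim$amounts[, "cornea_epi"] + sim$amounts[, "cornea_stroma"]) /
             (vols[["cornea_epi"]] + vols[["cornea_stroma"]]))
  }
  if (!tissue %in% colnames(sim$conc))
    stop("unknown tissue '", tissue, "'")
  sim$conc[, tissue]
}

#' Maximum relative mass-balance error of a simulation
#'
#' At every grid point the drug in all compartments (ocular, gut lumen,
#' systemic) plus all terminal ledgers (renal, hepatic, fecal, discarded;
#' plus the drained/absorbed sinks when the systemic model is decoupled)
#' must equal the cumulative instilled dose. Returns the maximum absolute
#' deviation relative to the total retained dose; defined as 0 for a
#' zero-dose simulation.
#'
#' @param sim `ocat_sim` result.
#' @return Scalar maximum relative error.
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "ocat_sim"))
  if (sim$dose_instilled_ug <= 0) return(0)
  total <- rowSums(sim$amounts) + sim$ledgers[, "renal"] +
    sim$ledgers[, "hepatic"] + sim$ledgers[, "fecal_unabsorbed"] +
    sim$ledgers[, "discarded"]
  if (!isTRUE(sim$options$couple_systemic))
    total <- total + sim$ledgers[, "drained_to_gut"] +
      sim$ledgers[, "absorbed_systemic"]
  ev <- sim$regimen$events
  instilled <- vapply(sim$time, function(t)
    sum(ev$dose_ug[ev$time_h <= t + 1e-12]), numeric(1))
  max(abs(total - instilled)) / max(sim$dose_retained_ug, 1e-300)
}
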