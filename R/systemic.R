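#' Tissue-to-plasma partition coefficients (mechanistic)
#'
#' Computes perfusion-limited tissue/plasma partition coefficients from a
#' shipped tissue-composition table using a mechanistic
#' tissue-composition equation family: the uncharged microspecies
#' equilibrates across membranes, ionization is re-established at each
#' water space's pH (plasma/extracellular 7.4, intracellular 7.0) via
#' [ionization_fractions()], neutral lipid partitioning scales with the
#' octanol/water partition ratio and neutral phospholipid with
#' `0.3 P + 0.7`. For tissue `t`:
#' \deqn{Kpu_t = f_{ew} + f_{iw} X_{iw}/X_p +
#'   (P f_{nl} + (0.3 P + 0.7) f_{np})/X_p, \quad Kp_t = fu_p \, Kpu_t}
#' where `X = 1/(fraction uncharged)` at the local pH.
#'
#' @param drug `drug_parameters` record (needs `logp`, `pkas`, `fu_plasma`).
#' @param species `"rabbit"` or `"human"` (recorded in the result; the
#'   composition table is species-shared).
#' @param tissue_composition Optional data.frame with columns `tissue`,
#'   `f_ew`, `f_iw`, `f_nl`, `f_np`; defaults to the shipped table.
#' @param ph_plasma,ph_iw Plasma/extracellular and intracellular pH.
#' @param override Optional named numeric vector of user Kp values that
#'   replace calculated entries (recorded with method `"user-override"`).
#' @return List of class `kp_set`: `kp` (named vector), `method` (named
#'   character: `"calculated"` or `"user-override"`), `species`.
#' @export
calc_kp <- function(drug, species = "rabbit", tissue_composition = NULL,
                    ph_plasma = 7.4, ph_iw = 7.0, override = NULL) {
  for (f in c("logp", "fu_plasma")) {
    if (is.null(drug[[f]]) || !is.finite(drug[[f]]))
      stop("drug record is missing physicochemistry field '", f, "'")
  }
  if (is.null(drug$pkas) || nrow(drug$pkas) == 0)
    stop("drug record is missing physicochemistry field 'pkas'")
  if (is.null(tissue_composition)) {
    tissue_composition <- utils::read.csv(
      system.file("extdata", "tissue_composition.csv", package = "ocupbpk",
                  mustWork = TRUE))
  }
  p <- 10^drug$logp
  x_p <- 1 / fraction_uncharged(drug$pkas, ph_plasma)
  x_iw <- 1 / fraction_uncharged(drug$pkas, ph_iw)
  kpu <- with(tissue_composition,
              f_ew + f_iw * x_iw / x_p +
                (p * f_nl + (0.3 * p + 0.7) * f_np) / x_p)
  kp <- stats::setNames(drug$fu_plasma * kpu, tissue_composition$tissue)
  method <- stats::setNames(rep("calculated", length(kp)), names(kp))
  if (!is.null(override)) {
    stopifnot(!is.null(names(override)), all(override > 0))
    kp[names(override)] <- override
    method[names(override)] <- "user-override"
  }
  structure(list(kp = kp, method = method, species = species),
            class = "kp_set")
}

# Shared systemic RHS used by the standalone systemic simulator.
# Tissue rows named lung/liver/kidney get their special roles; each is
# optional (no lung => venous blood passes directly to arterial).
.make_sys_rhs <- function(sys_phys, drug, kps, species,
                          input_gut = NULL, input_venous = NULL) {
  st <- sys_phys$tissues
  nT <- nrow(st)
  kp <- kps$kp[st$tissue]
  if (anyNA(kp)) stop("kp_set is missing tissues: ",
                      paste(st$tissue[is.na(kp)], collapse = ", "))
  rbp <- drug$rbp[[species]]
  fu_p <- drug$fu_plasma
  co <- sys_phys$cardiac_output_mL_h
  lung_i <- which(st$tissue == "lung")
  liver_i <- which(st$tissue == "liver")
  kidney_i <- which(st$tissue == "kidney")
  periph <- setdiff(seq_len(nT), lung_i)
  shunt <- co - sum(st$flow_mL_h[periph])
  ka <- drug$peff_cm_s[[species]] * 2e4
  kfec <- 0.25
  renal_fr <- drug$renal_fraction[[species]]
  clint <- drug$clint_L_h[[species]] * 1000
  v_ven <- sys_phys$venous_volume_mL
  v_art <- sys_phys$arterial_volume_mL
  vol <- st$volume_mL; q <- st$flow_mL_h
  kpv <- unname(kp)
  # state: gut, ven, art, tissues..., led_renal, led_hepatic, led_fecal
  function(t, y, parms) {
    a_t <- y[3 + seq_len(nT)]
    c_t <- a_t / vol
    cvb <- c_t * rbp / kpv
    c_ven <- y[2] / v_ven
    c_art <- y[3] / v_art
    dt_t <- numeric(nT)
    if (length(lung_i)) {
      dt_t[lung_i] <- co * (c_ven - cvb[lung_i])
      art_in <- co * cvb[lung_i]
    } else {
      art_in <- co * c_ven
    }
    dt_t[periph] <- q[periph] * (c_art - cvb[periph])
    renal <- if (length(kidney_i)) renal_fr * q[kidney_i] * c_art else 0
    if (length(kidney_i)) dt_t[kidney_i] <- dt_t[kidney_i] - renal
    abs_gut <- ka * y[1]
    fec <- kfec * y[1]
    hep <- 0
    if (length(liver_i)) {
      hep <- clint * fu_p * c_t[liver_i] / kpv[liver_i]
      dt_t[liver_i] <- dt_t[liver_i] + abs_gut - hep
    }
    gut_in <- if (is.null(input_gut)) 0 else input_gut(t)
    ven_in <- if (is.null(input_venous)) 0 else input_venous(t)
    dgut <- gut_in - abs_gut - fec
    dven <- sum(q[periph] * cvb[periph]) + shunt * c_art -
      co * c_ven + ven_in +
      (if (length(liver_i)) 0 else abs_gut)  # no liver: gut drug to blood
    dart <- art_in - co * c_art
    list(c(dgut, dven, dart, dt_t, renal, hep, fec))
  }
}

#' Simulate the reduced whole-body PBPK model on its own
#'
#' All tissues are perfusion limited; renal elimination is a fixed
#' fraction of kidney blood flow applied to arterial blood, hepatic
#' elimination follows intrinsic clearance acting on unbound liver
#' concentration (venous-equilibration / well-stirred behaviour), and the
#' gut lumen absorbs first-order with `ka` mapped linearly from the
#' intestinal permeability (`ka [1/h] = 2e4 * Peff [cm/s]`, giving
#' near-complete absorption for Peff at or above 2e-4 cm/s against the
#' 0.25/h unabsorbed-loss rate).
#'
#' @param drug `drug_parameters` record.
#' @param sys_phys `systemic_physiology` record.
#' @param kps Optional `kp_set` (defaults to [calc_kp()]).
#' @param iv_bolus_ug Amount placed in venous blood at t = 0.
#' @param oral_ug Amount placed in the gut lumen at t = 0.
#' @param input_gut,input_venous Optional functions of time (h) returning
#'   exogenous input rates (ug/h) into gut lumen / venous blood, e.g. the
#'   ocular drainage and absorption time-courses.
#' @param t_grid Output times (h).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `systemic_sim`: `time`, `amounts` (gut lumen,
#'   venous, arterial, tissues), `plasma_conc` (venous plasma, ug/mL),
#'   `ledgers` (cumulative renal/hepatic/fecal), `dose_ug`.
#' @export
simulate_systemic <- function(drug, sys_phys, kps = NULL, iv_bolus_ug = 0,
                              oral_ug = 0, input_gut = NULL,
                              input_venous = NULL,
                              t_grid = seq(0, 24, by = 0.25),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(sys_phys, "systemic_physiology"))
  species <- .species_group(sys_phys$species_id)
  if (is.null(kps)) kps <- calc_kp(drug, species = species)
  rhs <- .make_sys_rhs(sys_phys, drug, kps, species, input_gut, input_venous)
  nT <- nrow(sys_phys$tissues)
  y0 <- c(oral_ug, iv_bolus_ug, 0, rep(0, nT), 0, 0, 0)
  sol <- deSolve::lsoda(y0, sort(unique(c(0, t_grid))), rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) stop("systemic ODE solver failed")
  amounts <- sol[, -1, drop = FALSE]
  colnames(amounts) <- c("gut_lumen", "venous", "arterial",
                         sys_phys$tissues$tissue,
                         "led_renal", "led_hepatic", "led_fecal")
  structure(list(
    time = sol[, 1],
    amounts = amounts[, seq_len(3 + nT), drop = FALSE],
    plasma_conc = amounts[, "venous"] / sys_phys$venous_volume_mL /
      drug$rbp[[species]],
    ledgers = amounts[, c("led_renal", "led_hepatic", "led_fecal"),
                      drop = FALSE],
    dose_ug = iv_bolus_ug + oral_ug
  ), class = "systemic_sim")
}

#' Fraction of eliminated drug excreted renally
#'
#' @param result `systemic_sim` from [simulate_systemic()].
#' @return Renal ledger divided by total eliminated at the simulation
#'   horizon. Errors when nothing has been eliminated.
#' @export
fraction_excreted_renal <- function(result) {
  stopifnot(inherits(result, "systemic_sim"))
  led <- result$ledgers[nrow(result$ledgers), ]
  total <- sum(led)
  if (total <= 0) stop("no drug eliminated; fraction is undefined")
  unname(led[["led_renal"]] / total)
}
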