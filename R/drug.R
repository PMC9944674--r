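#' Registered active pharmaceutical ingredients
#'
#' @return Character vector of API identifiers with a shipped parameter file.
#' @export
api_ids <- function() c("levofloxacin", "moxifloxacin", "gatifloxacin")

.drug_file <- function(api_id) {
  system.file("extdata", "drugs", paste0(api_id, ".yaml"),
              package = "ocupbpk", mustWork = TRUE)
}

.species_map <- function(x, field) {
  # a per-species field is either a single printed value (applies to both
  # species) or explicit rabbit/human entries
  if (is.list(x)) {
    if (!is.null(x$rabbit) || !is.null(x$human)) {
      rb <- if (!is.null(x$rabbit)) x$rabbit else x$human
      hu <- if (!is.null(x$human)) x$human else x$rabbit
      return(c(rabbit = rb, human = hu))
    }
    if (!is.null(x$value)) return(c(rabbit = x$value, human = x$value))
  }
  if (is.numeric(x)) return(c(rabbit = x, human = x))
  stop("cannot resolve per-species field '", field, "'")
}

#' Load a drug parameter record
#'
#' Reads the shipped parameter file for one API and normalizes every value
#' to base units: percents become fractions, scale prefixes are resolved,
#' permeabilities are cm/s, systemic absorption rates 1/s, intrinsic
#' clearance L/h. Species-specific entries are resolved into explicit
#' rabbit/human maps; where a single value is recorded it applies to both
#' species.
#'
#' @param api_id One of `api_ids()`.
#' @return A list of class `drug_parameters` with elements `api_id`, `mwt`,
#'   `logp`, `fu_plasma`, `fu_melanin`, `rbp` (named rabbit/human),
#'   `solubility` (`value` mg/mL at `ph`), `pkas` (data.frame `value`,
#'   `type`, sorted ascending), `peff_cm_s` (named rabbit/human, cm/s),
#'   `renal_fraction`, `clint_L_h` (named rabbit/human), `perm_cm_s`
#'   (named per-tissue vector), `sar_per_s` (named per-route vector), and a
#'   `provenance` map recording each parameter's source tag
#'   (literature / predicted / default / fitted).
#' @examples
#' lev <- load_drug("levofloxacin")
#' lev$perm_cm_s[["cornea_epi"]]  # 1.85e-7
#' @export
load_drug <- function(api_id) {
  if (!is.character(api_id) || length(api_id) != 1 || !api_id %in% api_ids()) {
    stop("unknown API '", paste(api_id, collapse = ","),
         "'; registered APIs are: ", paste(api_ids(), collapse = ", "))
  }
  raw <- yaml::read_yaml(.drug_file(api_id))
  pc <- raw$physicochemistry
  ac <- raw$absorption_clearance
  oc <- raw$ocular
  pkas <- data.frame(
    value = vapply(pc$pkas, function(p) p$value, numeric(1)),
    type = vapply(pc$pkas, function(p) p$type, character(1))
  )
  pkas <- pkas[order(pkas$value), , drop = FALSE]
  rownames(pkas) <- NULL
  perm <- vapply(oc$permeability_cm_s, function(p) p$value, numeric(1))
  sar <- vapply(oc$systemic_absorption_rate_per_s,
                function(p) p$value, numeric(1))
  prov <- c(
    list(mwt = pc$mwt_g_mol$source, logp = pc$logp_neutral$source,
         fu_plasma = pc$fu_plasma_pct$source,
         fu_melanin = pc$fu_melanin_pct$source, rbp = pc$rbp$source,
         solubility = pc$solubility_mg_mL$source,
         peff = ac[["peff_1e-4_cm_s"]]$source,
         renal_fraction = ac$renal_fraction$source,
         clint = ac$clint_L_h$source),
    stats::setNames(lapply(oc$permeability_cm_s, function(p) p$source),
                    paste0("perm.", names(perm))),
    stats::setNames(lapply(oc$systemic_absorption_rate_per_s,
                           function(p) p$source),
                    paste0("sar.", names(sar)))
  )
  structure(list(
    api_id = raw$api_id,
    mwt = pc$mwt_g_mol$value,
    logp = pc$logp_neutral$value,
    fu_plasma = pc$fu_plasma_pct$value / 100,
    fu_melanin = pc$fu_melanin_pct$value / 100,
    rbp = .species_map(pc$rbp, "rbp"),
    solubility = list(value = pc$solubility_mg_mL$value,
                      ph = pc$solubility_mg_mL$ph),
    pkas = pkas,
    peff_cm_s = .species_map(ac[["peff_1e-4_cm_s"]], "peff") * 1e-4,
    renal_fraction = .species_map(ac$renal_fraction, "renal_fraction"),
    clint_L_h = .species_map(ac$clint_L_h, "clint"),
    perm_cm_s = perm,
    sar_per_s = sar,
    provenance = prov
  ), class = "drug_parameters")
}

#' Ionization microstate fractions by independent-site Henderson-Hasselbalch
#'
#' Treats each macroscopic pKa as an independent protonation site. An acid
#' site is neutral when protonated and carries charge -1 when deprotonated;
#' a base site carries +1 when protonated and is neutral when deprotonated.
#' Microstate probabilities are products of per-site Henderson-Hasselbalch
#' fractions; this is the standard convention when only macroscopic pKas
#' are available.
#'
#' @param pkas Data frame with columns `value` (pKa) and `type`
#'   (`"acid"`/`"base"`), e.g. `load_drug(...)$pkas`, or a numeric vector
#'   with a `type` attribute-free single-site shortcut when `type` is given.
#' @param ph The pH (0 < pH < 14).
#' @param type Optional character vector of site types when `pkas` is a
#'   bare numeric vector.
#' @return A data.frame with one row per protonation microstate: logical
#'   columns `site<i>_protonated`, the microstate net `charge`, and its
#'   `fraction`. Fractions are non-negative and sum to 1. The row with all
#'   acid sites protonated and all base sites deprotonated is the fully
#'   uncharged microspecies used for lipid partitioning.
#' @examples
#' ionization_fractions(data.frame(value = 7.4, type = "base"), ph = 7.4)
#' @export
ionization_fractions <- function(pkas, ph, type = NULL) {
  if (is.numeric(pkas)) {
    pkas <- data.frame(value = pkas,
                       type = if (is.null(type)) "acid" else type)
  }
  stopifnot(nrow(pkas) >= 1, is.numeric(ph), length(ph) == 1)
  if (ph <= 0 || ph >= 14) stop("ph must be strictly between 0 and 14")
  k <- nrow(pkas)
  # per-site probability of being protonated
  p_prot <- 1 / (1 + 10^(ph - pkas$value))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(grid) <- paste0("site", seq_len(k), "_protonated")
  frac <- apply(grid, 1, function(g) {
    prod(ifelse(g, p_prot, 1 - p_prot))
  })
  charge <- apply(grid, 1, function(g) {
    sum(ifelse(pkas$type == "base", as.numeric(g), as.numeric(g) - 1))
  })
  out <- cbind(grid, charge = charge, fraction = frac)
  rownames(out) <- NULL
  out
}

#' Fraction of fully uncharged microspecies
#'
#' Convenience wrapper over [ionization_fractions()]: the probability that
#' every acid site is protonated and every base site deprotonated.
#'
#' @inheritParams ionization_fractions
#' @return Scalar fraction in (0, 1].
#' @export
fraction_uncharged <- function(pkas, ph) {
  fr <- ionization_fractions(pkas, ph)
  k <- nrow(pkas)
  sites <- as.matrix(fr[paste0("site", seq_len(k), "_protonated")])
  want <- pkas$type == "acid"  # acid protonated = neutral
  idx <- apply(sites, 1, function(g) all(g == want))
  sum(fr$fraction[idx])
}

#' Export the full drug parameter table for audit
#'
#' Writes one row per parameter and API with the normalized (base-unit)
#' value and its source tag.
#'
#' @param path Optional CSV output path; when `NULL` the table is returned
#'   only.
#' @return data.frame with columns `parameter`, `api`, `value`, `source`.
#' @export
export_drug_table <- function(path = NULL) {
  rows <- do.call(rbind, lapply(api_ids(), function(a) {
    d <- load_drug(a)
    flat <- c(
      mwt = d$mwt, logp = d$logp, fu_plasma = d$fu_plasma,
      fu_melanin = d$fu_melanin,
      rbp.rabbit = d$rbp[["rabbit"]], rbp.human = d$rbp[["human"]],
      solubility = d$solubility$value,
      stats::setNames(d$pkas$value, paste0("pka.", seq_len(nrow(d$pkas)))),
      peff.rabbit = d$peff_cm_s[["rabbit"]],
      peff.human = d$peff_cm_s[["human"]],
      renal_fraction.rabbit = d$renal_fraction[["rabbit"]],
      renal_fraction.human = d$renal_fraction[["human"]],
      clint.rabbit = d$clint_L_h[["rabbit"]],
      clint.human = d$clint_L_h[["human"]],
      stats::setNames(d$perm_cm_s, paste0("perm.", names(d$perm_cm_s))),
      stats::setNames(d$sar_per_s, paste0("sar.", names(d$sar_per_s)))
    )
    src <- vapply(names(flat), function(nm) {
      key <- sub("\\.(rabbit|human|[0-9]+)$", "", nm)
      s <- d$provenance[[key]]
      if (is.null(s)) s <- d$provenance[[nm]]
      if (is.null(s)) NA_character_ else s
    }, character(1))
    data.frame(parameter = names(flat), api = a, value = unname(flat),
               source = unname(src), row.names = NULL)
  }))
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
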