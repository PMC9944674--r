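# Internal unit conventions: amounts ug, volumes mL, time h, concentrations
# ug/mL. Interface units (uL, 1/min, cm/s, 1/s, L/h) are converted once at
# ingestion and never afterwards.

#' Ocular compartments of the topical absorption model
#'
#' Compartment identifiers used throughout the package, ordered from the
#' ocular surface inwards.
#'
#' @return Character vector of compartment ids.
#' @export
ocular_compartments <- function() {
  c("precornea", "cornea_epi", "cornea_stroma", "conjunctiva",
    "AH", "ICB", "sclera", "choroid", "retina", "VH")
}

#' Registered species
#'
#' @return Character vector of species identifiers with a shipped physiology.
#' @export
species_ids <- function() c("NZ_rabbit", "DB_rabbit", "human")

.phys_file <- function(species_id) {
  fname <- c(NZ_rabbit = "nz_rabbit.yaml", DB_rabbit = "db_rabbit.yaml",
             human = "human.yaml")[[species_id]]
  system.file("extdata", "physiology", fname, package = "ocupbpk",
              mustWork = TRUE)
}

.val <- function(x) if (is.list(x) && !is.null(x$value)) x$value else x

#' Load the physiology of a registered species
#'
#' Reads the provenance-annotated physiology file shipped with the package
#' and returns the ocular and systemic physiology records in internal units
#' (volumes mL, time h). Every numeric value in the shipped file carries a
#' `provenance` note; the raw annotated structure is kept in the
#' `provenance` element of each record.
#'
#' @param species_id One of `species_ids()`: `"NZ_rabbit"` (albino New
#'   Zealand White), `"DB_rabbit"` (pigmented Dutch Belted) or `"human"`.
#' @return A list with elements `ocular` (class `ocular_physiology`) and
#'   `systemic` (class `systemic_physiology`).
#' @examples
#' phys <- get_physiology("NZ_rabbit")
#' phys$ocular$tear_volume_mL * 1000  # 5 uL
#' @export
get_physiology <- function(species_id) {
  if (!is.character(species_id) || length(species_id) != 1 ||
      !species_id %in% species_ids()) {
    stop("unknown species '", paste(species_id, collapse = ","),
         "'; registered species are: ", paste(species_ids(), collapse = ", "))
  }
  raw <- yaml::read_yaml(.phys_file(species_id))
  oc <- raw$ocular
  vols <- vapply(oc$compartment_volumes_mL, .val, numeric(1))
  sas <- vapply(oc$exchange_surfaces_cm2, .val, numeric(1))
  pig <- vapply(oc$pigmented, isTRUE, logical(1))
  ocular <- structure(list(
    species_id = raw$species_id,
    tear_volume_mL = .val(oc$tear_volume_uL) / 1000,
    precornea_max_volume_mL = .val(oc$precornea_max_volume_uL) / 1000,
    drainage_rate_per_h = .val(oc$drainage_rate_constant_per_min) * 60,
    aqueous_turnover_mL_h = .val(oc$aqueous_turnover_uL_per_min) * 60 / 1000,
    compartment_volumes_mL = vols,
    exchange_surfaces_cm2 = sas,
    pigmented = pig,
    provenance = oc
  ), class = "ocular_physiology")
  sy <- raw$systemic
  tis <- sy$tissues
  tissues <- data.frame(
    tissue = names(tis),
    volume_mL = vapply(tis, function(t) t$volume_mL, numeric(1)),
    flow_mL_h = vapply(tis, function(t) t$flow_mL_per_min * 60, numeric(1)),
    row.names = NULL
  )
  systemic <- structure(list(
    species_id = raw$species_id,
    body_weight_kg = .val(sy$body_weight_kg),
    hematocrit = .val(sy$hematocrit),
    cardiac_output_mL_h = .val(sy$cardiac_output_mL_per_min) * 60,
    tissues = tissues,
    venous_volume_mL = .val(sy$blood$venous_volume_mL),
    arterial_volume_mL = .val(sy$blood$arterial_volume_mL),
    provenance = sy
  ), class = "systemic_physiology")
  list(ocular = ocular, systemic = systemic)
}

#' Validate a physiology record
#'
#' Checks the structural invariants of an ocular or systemic physiology
#' record and returns the violations found instead of raising an error, so
#' user-modified records can be audited before simulation.
#'
#' @param phys An `ocular_physiology` or `systemic_physiology` record.
#' @return Character vector of violations (empty when the record is valid);
#'   each entry names the offending field and the rule.
#' @export
validate_physiology <- function(phys) {
  v <- character(0)
  if (inherits(phys, "ocular_physiology")) {
    scal <- c(tear_volume_mL = phys$tear_volume_mL,
              precornea_max_volume_mL = phys$precornea_max_volume_mL,
              drainage_rate_per_h = phys$drainage_rate_per_h,
              aqueous_turnover_mL_h = phys$aqueous_turnover_mL_h)
    bad <- names(scal)[!is.finite(scal) | scal <= 0]
    v <- c(v, sprintf("%s: must be a positive finite number", bad))
    if (is.finite(phys$precornea_max_volume_mL) &&
        is.finite(phys$tear_volume_mL) &&
        phys$precornea_max_volume_mL <= phys$tear_volume_mL) {
      v <- c(v, "precornea_max_volume_mL: must exceed tear_volume_mL")
    }
    badv <- names(phys$compartment_volumes_mL)[
      !is.finite(phys$compartment_volumes_mL) | phys$compartment_volumes_mL <= 0]
    v <- c(v, sprintf("compartment_volumes_mL[%s]: must be > 0", badv))
    bads <- names(phys$exchange_surfaces_cm2)[
      !is.finite(phys$exchange_surfaces_cm2) | phys$exchange_surfaces_cm2 <= 0]
    v <- c(v, sprintf("exchange_surfaces_cm2[%s]: must be > 0", bads))
    missing <- setdiff(setdiff(ocular_compartments(), "precornea"),
                       names(phys$compartment_volumes_mL))
    v <- c(v, sprintf("compartment_volumes_mL[%s]: missing", missing))
  } else if (inherits(phys, "systemic_physiology")) {
    if (!is.finite(phys$cardiac_output_mL_h) || phys$cardiac_output_mL_h <= 0)
      v <- c(v, "cardiac_output_mL_h: must be a positive finite number")
    bad <- with(phys$tissues, tissue[!is.finite(volume_mL) | volume_mL <= 0])
    v <- c(v, sprintf("tissues[%s].volume_mL: must be > 0", bad))
    bad <- with(phys$tissues, tissue[!is.finite(flow_mL_h) | flow_mL_h <= 0])
    v <- c(v, sprintf("tissues[%s].flow_mL_h: must be > 0", bad))
    periph <- phys$tissues[phys$tissues$tissue != "lung", ]
    if (sum(periph$flow_mL_h) > phys$cardiac_output_mL_h * (1 + 1e-9))
      v <- c(v, "tissues: sum of non-lung flows exceeds cardiac output")
    if (!is.finite(phys$hematocrit) || phys$hematocrit <= 0 ||
        phys$hematocrit >= 1)
      v <- c(v, "hematocrit: must be in (0, 1)")
  } else {
    stop("phys must be an ocular_physiology or systemic_physiology record")
  }
  v
}

#' Write / read a physiology record to a portable file
#'
#' Serialization keeps the annotated (provenance-bearing) structure, so a
#' round trip through disk reproduces the record exactly.
#'
#' @param phys Record from [get_physiology()] (one of the two elements).
#' @param path Output YAML path.
#' @return `write_physiology` returns `path` invisibly; `read_physiology`
#'   returns the same class of record as [get_physiology()] produces.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, c("ocular_physiology", "systemic_physiology")))
  kind <- if (inherits(phys, "ocular_physiology")) "ocular" else "systemic"
  out <- list(species_id = phys$species_id)
  out[[kind]] <- phys$provenance
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- intersect(c("ocular", "systemic"), names(raw))
  if (length(kind) != 1) stop("file must contain one ocular or systemic block")
  tmp <- get_physiology_from_raw(raw, kind)
  tmp
}

# shared constructor for read_physiology; mirrors get_physiology internals
get_physiology_from_raw <- function(raw, kind) {
  if (kind == "ocular") {
    oc <- raw$ocular
    structure(list(
      species_id = raw$species_id,
      tear_volume_mL = .val(oc$tear_volume_uL) / 1000,
      precornea_max_volume_mL = .val(oc$precornea_max_volume_uL) / 1000,
      drainage_rate_per_h = .val(oc$drainage_rate_constant_per_min) * 60,
      aqueous_turnover_mL_h = .val(oc$aqueous_turnover_uL_per_min) * 60 / 1000,
      compartment_volumes_mL = vapply(oc$compartment_volumes_mL, .val,
                                      numeric(1)),
      exchange_surfaces_cm2 = vapply(oc$exchange_surfaces_cm2, .val,
                                     numeric(1)),
      pigmented = vapply(oc$pigmented, isTRUE, logical(1)),
      provenance = oc
    ), class = "ocular_physiology")
  } else {
    sy <- raw$systemic
    tis <- sy$tissues
    structure(list(
      species_id = raw$species_id,
      body_weight_kg = .val(sy$body_weight_kg),
      hematocrit = .val(sy$hematocrit),
      cardiac_output_mL_h = .val(sy$cardiac_output_mL_per_min) * 60,
      tissues = data.frame(
        tissue = names(tis),
        volume_mL = vapply(tis, function(t) t$volume_mL, numeric(1)),
        flow_mL_h = vapply(tis, function(t) t$flow_mL_per_min * 60, numeric(1)),
        row.names = NULL
      ),
      venous_volume_mL = .val(sy$blood$venous_volume_mL),
      arterial_volume_mL = .val(sy$blood$arterial_volume_mL),
      provenance = sy
    ), class = "systemic_physiology")
  }
}
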