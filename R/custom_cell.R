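# Custom-cell construction: the channel catalog, named roster presets, and the
# CustomCellSpec container (roster + per-channel scaling factors).

cust_channel_names <- c(
  "cic_na", "cic_kir", "cic_kca", "cic_to",
  "msc_to", "msc_to_ss", "msc_na", "msc_cal", "msc_kca", "msc_dr",
  "cf_kv", "cf_kir", "cf_nak",
  "cm_na", "cm_nal", "cm_to", "cm_cal", "cm_kr", "cm_ks", "cm_k1",
  "passive_leak"
)

cust_state_names <- c(
  "v", "m", "h", "j", "ml", "hl", "a", "i_f", "i_s",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca",
  "xrf", "xrs", "xs1", "xs2", "xk1",
  "cic_m", "cic_h", "cic_r", "cic_s",
  "msc_r", "msc_s", "msc_m", "msc_h", "msc_d", "msc_f", "msc_n",
  "cf_r", "cf_s"
)

catalog_cache <- function() {
  if (is.null(.cf_cache$catalog)) {
    .cf_cache$catalog <- jsonlite::read_json(param_file("support_cells.json"),
                                             simplifyVector = TRUE)
  }
  .cf_cache$catalog
}

#' Channel catalog for custom cells
#'
#' All channels available to a custom therapeutic cell, with their source cell
#' type, baseline conductance density, and units. Baselines are densities
#' referenced to the fixed 40 pF custom-cell capacitance; scaling factors in a
#' [custom_cell_spec()] multiply them.
#'
#' @return A data.frame with columns `name`, `source`, `baseline`, `unit`,
#'   `description`, `reconstructed`.
#' @export
channel_catalog <- function() {
  cat <- catalog_cache()
  ch <- cat$channels
  stopifnot(identical(ch$name, cust_channel_names))
  ch
}

#' Named channel roster presets
#'
#' The custom-cell channel rosters used by the in-package experiments:
#' `nonexcitable` (all hCIC + hMSC + CF channels), `all-channels` (those plus
#' the seven cardiomyocyte channels), the reduced cardiomyocyte-channel
#' rosters `ical-ik1`, `ik1-only`, `ical-only`, the purely `passive` cell, and
#' the engineered-therapeutic rosters `hmsc`, `hmsc-ik1`, `hcic`, `hcic-ik1`.
#'
#' @param name Preset name (see Details).
#' @return Character vector of channel names (see [channel_catalog()]).
#' @export
#' @examples
#' roster_preset("ik1-only")
roster_preset <- function(name) {
  nonexc <- cust_channel_names[1:13]
  cm <- cust_channel_names[14:20]
  msc <- grep("^msc_", cust_channel_names, value = TRUE)
  cic <- grep("^cic_", cust_channel_names, value = TRUE)
  presets <- list(
    "nonexcitable" = nonexc,
    "all-channels" = c(nonexc, cm),
    "ical-ik1"     = c("cm_cal", "cm_k1"),
    "ik1-only"     = "cm_k1",
    "ical-only"    = "cm_cal",
    "passive"      = "passive_leak",
    "hmsc"         = msc,
    "hmsc-ik1"     = c(msc, "cm_k1"),
    "hcic"         = cic,
    "hcic-ik1"     = c(cic, "cm_k1")
  )
  if (!name %in% names(presets))
    stop("unknown roster preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Custom therapeutic cell specification
#'
#' A custom cell is an isopotential 40 pF membrane carrying a roster of ion
#' channels, each scaled by a dimensionless factor >= 0, with intracellular
#' ion concentrations held constant throughout any simulation (the cell has no
#' calcium-handling machinery, SR, or ion accumulation). Gating variables of
#' roster channels are integrated; the total ionic current is the sum of the
#' scaled per-channel currents.
#'
#' @param roster Character vector of channel names (see [channel_catalog()])
#'   or a single preset name (see [roster_preset()]).
#' @param scaling Numeric vector of per-channel scaling factors, recycled or
#'   matched by name; defaults to 1 for every roster channel.
#' @param concentrations Fixed intracellular concentrations, named
#'   `c(nai=, ki=, cai=)` in mM.
#' @return Object of class `custom_cell_spec`.
#' @export
#' @examples
#' spec <- custom_cell_spec("ik1-only", scaling = c(cm_k1 = 3))
custom_cell_spec <- function(roster, scaling = NULL, concentrations = NULL) {
  if (length(roster) == 1 && !roster %in% cust_channel_names)
    roster <- roster_preset(roster)
  unknown <- setdiff(roster, cust_channel_names)
  if (length(unknown))
    stop("unknown channel identity: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(roster)) stop("duplicate channels in roster")
  sc <- setNames(rep(1, length(roster)), roster)
  if (!is.null(scaling)) {
    if (!is.null(names(scaling))) {
      bad <- setdiff(names(scaling), roster)
      if (length(bad)) stop("scaling names not in roster: ", paste(bad, collapse = ", "))
      sc[names(scaling)] <- scaling
    } else {
      if (length(scaling) != length(roster))
        stop("unnamed scaling must match roster length")
      sc[] <- scaling
    }
  }
  if (any(!is.finite(sc)) || any(sc < 0))
    stop("scaling factors must be finite and >= 0")
  cat <- catalog_cache()
  conc <- c(nai = 10, ki = 140, cai = 1e-4)
  conc[] <- unlist(cat$fixed_concentrations_mM)[names(conc)]
  if (!is.null(concentrations)) {
    stopifnot(all(names(concentrations) %in% names(conc)))
    conc[names(concentrations)] <- concentrations
    if (any(conc <= 0)) stop("concentrations must be positive")
  }
  structure(
    list(roster = roster, scaling = sc, capacitance_pf = 40,
         concentrations = conc),
    class = "custom_cell_spec")
}

# length-21 effective density vector (baseline * scaling; absent channels 0)
spec_densities <- function(spec) {
  stopifnot(inherits(spec, "custom_cell_spec"))
  cat <- channel_catalog()
  dens <- setNames(numeric(length(cust_channel_names)), cust_channel_names)
  base <- setNames(cat$baseline, cat$name)
  dens[spec$roster] <- base[spec$roster] * spec$scaling
  dens
}

#' @export
print.custom_cell_spec <- function(x, ...) {
  cat("<custom_cell_spec> ", length(x$roster), " channel(s), C = ",
      x$capacitance_pf, " pF\n", sep = "")
  for (ch in x$roster)
    cat("  ", format(ch, width = 12), " x", format(x$scaling[[ch]], digits = 4), "\n")
  cat("  fixed [Na]i/[K]i/[Ca]i (mM):",
      paste(format(x$concentrations, digits = 3), collapse = " / "), "\n")
  invisible(x)
}
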