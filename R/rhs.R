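# Right-hand-side entry points for the three cell models. These wrap the
# compiled single-evaluation routines (direct rate evaluation, no lookup
# table) and attach state/current names; they are the unit-testable surface
# for the model equations.

check_state <- function(state, expected_names, what) {
  if (length(state) != length(expected_names))
    stop(what, " state must have ", length(expected_names), " entries")
  if (is.null(names(state))) names(state) <- expected_names
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite ", what, " state entr", if (length(bad) > 1) "ies: " else "y: ",
         paste(expected_names[bad], collapse = ", "))
  state
}

#' Resting state of the cardiomyocyte model
#'
#' Published resting state of the endocardial model (voltage, gating
#' variables, intracellular/subspace/SR concentrations, CaMK trap state).
#' Operational steady state is defined by pacing, not by this vector: all
#' replication protocols pace 500 beats at 1 Hz from here.
#'
#' @return Named numeric vector of length 38.
#' @export
ord_initial_state <- function() {
  setNames(cm_default_state_cpp(), cm_state_names)
}

#' Cardiomyocyte right-hand side
#'
#' Time derivative of every state variable of the ventricular cardiomyocyte
#' model plus a labeled breakdown of each membrane current and SR flux.
#' `i_external` (stimulus plus gap-junction current per unit capacitance,
#' uA/uF) enters the voltage equation only (and the K+ balance, following the
#' source model's stimulus bookkeeping).
#'
#' @param state Named state vector (see [ord_initial_state()]).
#' @param params A [cm_parameters()] object.
#' @param i_external External current density, uA/uF (negative = inward).
#' @return List with `deriv` (d state / dt, per ms) and `currents`
#'   (uA/uF; SR fluxes in mM/ms).
#' @export
ord_rhs <- function(state, params = cm_parameters("healthy"), i_external = 0) {
  state <- check_state(state, cm_state_names, "cardiomyocyte")
  validate_cm_parameters(params)
  out <- cm_rhs_cpp(as.numeric(state), as.numeric(params$scale), i_external)
  list(deriv = setNames(out$deriv, cm_state_names),
       currents = setNames(out$currents, cm_current_names))
}

#' Resting state of the fibroblast model
#' @return Named numeric vector (voltage and the two Kv gates).
#' @export
fibroblast_initial_state <- function() {
  setNames(fib_default_state_cpp(), fib_state_names)
}

#' Fibroblast right-hand side
#'
#' The MacCannell active fibroblast: time- and voltage-dependent K+ current,
#' inward rectifying K+ current, Na+/K+ pump, and background Na+ leak, with a
#' 6.3 pF capacitance and fixed intracellular concentrations.
#'
#' @param state Named state vector (see [fibroblast_initial_state()]).
#' @param i_external_pa Whole-cell external (gap-junction) current, pA.
#' @param scale Multipliers on the four current magnitudes,
#'   `c(kv=, kir=, nak=, bna=)`.
#' @return List with `deriv` and `currents` (pA/pF).
#' @export
fibroblast_rhs <- function(state, i_external_pa = 0,
                           scale = c(kv = 1, kir = 1, nak = 1, bna = 1)) {
  state <- check_state(state, fib_state_names, "fibroblast")
  out <- fib_rhs_cpp(as.numeric(state), i_external_pa, as.numeric(scale))
  list(deriv = setNames(out$deriv, fib_state_names), currents = out$currents)
}

#' Initial state of a custom cell
#'
#' Gating variables start at their steady-state values for the starting
#' voltage. With `relax_ms > 0` the uncoupled cell is first relaxed toward its
#' own resting potential, which is the initialization used by [simulate()]
#' (the 500-beat washout makes the final beat insensitive to this choice).
#'
#' @param spec A [custom_cell_spec()].
#' @param v0 Starting voltage, mV.
#' @param relax_ms Uncoupled relaxation time, ms (0 to skip; 500 ms reaches
#'   the resting potential of any roster, and the paced washout removes the
#'   residual).
#' @return Named numeric vector of length 34.
#' @export
custom_initial_state <- function(spec, v0 = -60, relax_ms = 500) {
  stopifnot(inherits(spec, "custom_cell_spec"))
  if (relax_ms > 0) {
    s <- cust_relax_cpp(as.numeric(spec_densities(spec)),
                        as.numeric(spec$concentrations), v0, relax_ms, 0.05)
  } else {
    s <- cust_default_state_cpp(v0)
  }
  setNames(s, cust_state_names)
}

#' Custom-cell right-hand side
#'
#' Total ionic current is the sum over the roster of each channel's current
#' scaled by its factor. Intracellular concentrations are fixed by
#' construction (their derivatives are identically zero and they are not part
#' of the state); gating variables are integrated.
#'
#' @param state Named state vector (see [custom_initial_state()]).
#' @param spec A [custom_cell_spec()].
#' @param i_gap_pa Whole-cell gap-junction current entering the voltage
#'   equation, pA (positive leaves the cell).
#' @return List with `deriv` and `currents` (per-channel, pA/pF; channels
#'   absent from the roster report 0).
#' @export
custom_cell_rhs <- function(state, spec, i_gap_pa = 0) {
  state <- check_state(state, cust_state_names, "custom-cell")
  stopifnot(inherits(spec, "custom_cell_spec"))
  out <- cust_rhs_cpp(as.numeric(state), as.numeric(spec_densities(spec)),
                      as.numeric(spec$concentrations), i_gap_pa)
  list(deriv = setNames(out$deriv, cust_state_names),
       currents = setNames(out$currents, cust_channel_names))
}
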