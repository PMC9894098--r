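# Coupled heterocellular simulation: one cardiomyocyte, optionally a pool of
# identical fibroblasts (fibrotic HF), and n_custom identical custom cells,
# paced at the cardiomyocyte. All custom cells share one state vector (the
# lumped reading of the pair of coupling equations); so do the fibroblasts.

#' Coupling configuration
#'
#' Describes one heterocellular simulation: cardiomyocyte phenotype, the
#' fibroblast pool, the custom-cell count and gap conductance, and the pacing
#' protocol. Replication protocols use 1 Hz pacing for 500 beats; the reduced
#' `n_beats` used by fast tests is a documented desk-scale deviation.
#'
#' @param phenotype `"healthy"`, `"hf"` (non-fibrotic HF), or `"hf_fibrosis"`
#'   (HF cardiomyocyte coupled to 5 fibroblasts at 1 nS each).
#' @param n_fibroblasts Fibroblast count; defaults to 5 for `hf_fibrosis`,
#'   otherwise 0.
#' @param g_fib_ns Cardiomyocyte-fibroblast gap conductance per junction, nS.
#' @param n_custom Number of coupled custom cells (1-5; identical, lumped).
#' @param g_gap_ns Cardiomyocyte-custom gap conductance per junction, nS.
#' @param pacing_hz Pacing frequency (cycle length must be an integer ms).
#' @param n_beats Number of paced beats.
#' @param stim_amp,stim_dur Stimulus rectangle: amplitude (uA/uF, negative =
#'   depolarizing) and duration (ms), applied to the cardiomyocyte only.
#' @param dt_max Maximum integrator step, ms. The default 0.02 is the
#'   throughput setting; 0.005 is the fine correctness setting (the two agree
#'   on APD90 within 1 ms).
#' @param record_from_beat First beat recorded on the 1 ms output grid
#'   (default: final beat only).
#' @param record_currents Record the per-current traces of the cardiomyocyte.
#' @param init Optional warm start: list with any of `cm`, `fib`, `custom`
#'   state vectors (e.g. `final_state` of a previous run).
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(phenotype = c("healthy", "hf", "hf_fibrosis"),
                            n_fibroblasts = NULL, g_fib_ns = 1,
                            n_custom = 1L, g_gap_ns = 1,
                            pacing_hz = 1, n_beats = 500L,
                            stim_amp = -80, stim_dur = 0.5,
                            dt_max = 0.02, record_from_beat = NULL,
                            record_currents = FALSE, init = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(n_fibroblasts))
    n_fibroblasts <- if (phenotype == "hf_fibrosis") 5L else 0L
  cl <- 1000 / pacing_hz
  if (abs(cl - round(cl)) > 1e-9)
    stop("cycle length 1000/pacing_hz must be an integer number of ms")
  stopifnot(n_fibroblasts >= 0, g_fib_ns >= 0, g_gap_ns >= 0,
            n_custom >= 1, n_beats >= 1, dt_max > 0)
  if (is.null(record_from_beat)) record_from_beat <- n_beats
  structure(list(
    phenotype = phenotype, n_fibroblasts = as.integer(n_fibroblasts),
    g_fib_ns = g_fib_ns, n_custom = as.integer(n_custom), g_gap_ns = g_gap_ns,
    pacing_hz = pacing_hz, cl = round(cl), n_beats = as.integer(n_beats),
    stim_amp = stim_amp, stim_dur = stim_dur, dt_max = dt_max,
    record_from_beat = as.integer(record_from_beat),
    record_currents = record_currents, init = init
  ), class = "coupling_config")
}

cm_params_for <- function(phenotype) {
  cm_parameters(if (phenotype == "healthy") "healthy" else "hf")
}

#' Simulate heterocellular coupling
#'
#' Integrates the coupled system: the cardiomyocyte receives the stimulus and
#' the summed gap currents of `n_fibroblasts` fibroblasts (at `g_fib_ns` each)
#' and `n_custom` custom cells (at `g_gap_ns` each); each support cell sees
#' the equal-and-opposite current through its own junction. Gap current
#' through one junction is `G_gap * (V_cm - V_other)` in pA, converted to a
#' density by each cell's own capacitance. Custom cells couple only to the
#' cardiomyocyte, never to fibroblasts.
#'
#' @param config A [coupling_config()].
#' @param spec A [custom_cell_spec()], or NULL for no custom cells. A spec
#'   must be present exactly when custom cells are wanted.
#' @return Object of class `cellforge_trace`: 1 ms-grid series `time` (ms),
#'   `vm` (mV), `cai` (mM), plus `vm_custom`/`igap_custom_pa` and
#'   `vm_fib`/`igap_fib_pa` when those cells are present, an optional
#'   `currents` matrix, and `final_state` (list of end-of-run state vectors
#'   usable as `init` for a warm start).
#' @export
#' @examples
#' \donttest{
#' cfg <- coupling_config("healthy", n_beats = 5L)
#' tr <- simulate(cfg)
#' range(tr$vm)
#' }
simulate <- function(config, spec = NULL) {
  stopifnot(inherits(config, "coupling_config"))
  if (!is.null(spec)) stopifnot(inherits(spec, "custom_cell_spec"))
  params <- cm_params_for(config$phenotype)

  dens <- if (is.null(spec)) numeric(0) else as.numeric(spec_densities(spec))
  conc <- if (is.null(spec)) numeric(0) else as.numeric(spec$concentrations)

  init_cm <- init_fib <- init_cust <- numeric(0)
  if (!is.null(config$init)) {
    if (!is.null(config$init$cm)) init_cm <- as.numeric(config$init$cm)
    if (!is.null(config$init$fib)) init_fib <- as.numeric(config$init$fib)
    if (!is.null(config$init$custom)) init_cust <- as.numeric(config$init$custom)
  }
  if (!is.null(spec) && length(init_cust) == 0) {
    init_cust <- as.numeric(custom_initial_state(spec))
  }

  out <- sim_run_cpp(as.numeric(params$scale),
                     config$n_fibroblasts, config$g_fib_ns,
                     dens, config$g_gap_ns, config$n_custom, conc,
                     config$n_beats, config$cl,
                     config$stim_amp, config$stim_dur, config$dt_max,
                     config$record_from_beat, config$record_currents,
                     init_cm, init_fib, init_cust, -60)

  if (!all(is.finite(out$vm)) || !all(is.finite(out$cai))) {
    cond <- structure(
      class = c("cellforge_sim_error", "error", "condition"),
      list(message = "integration produced non-finite values (step-size collapse or blow-up)",
           call = sys.call(), config = config, spec = spec))
    stop(cond)
  }

  tr <- list(
    time = out$time, vm = out$vm, cai = out$cai,
    vm_custom = if (length(out$vm_custom)) out$vm_custom else NULL,
    vm_fib = if (length(out$vm_fib)) out$vm_fib else NULL,
    igap_custom_pa = if (length(out$igap_custom)) out$igap_custom else NULL,
    igap_fib_pa = if (length(out$igap_fib)) out$igap_fib else NULL,
    currents = if (config$record_currents) {
      m <- out$currents
      colnames(m) <- c(cm_current_names, "igap_custom_pa", "igap_fib_pa")
      m
    } else NULL,
    config = config, spec = spec,
    final_state = list(cm = setNames(out$final_cm, cm_state_names),
                       fib = setNames(out$final_fib, fib_state_names),
                       custom = setNames(out$final_cust, cust_state_names)),
    n_steps = out$n_steps
  )
  class(tr) <- "cellforge_trace"
  tr
}

#' @export
print.cellforge_trace <- function(x, ...) {
  cat("<cellforge_trace>", length(x$time), "samples,",
      x$config$n_beats, "beats at", x$config$pacing_hz, "Hz, phenotype",
      x$config$phenotype, "\n")
  cat("  Vm range:", paste(format(range(x$vm), digits = 4), collapse = " .. "),
      "mV; [Ca]i peak:", format(max(x$cai) * 1e3, digits = 4), "uM\n")
  invisible(x)
}

#' @export
as.data.frame.cellforge_trace <- function(x, ...) {
  df <- data.frame(time_ms = x$time, vm_mv = x$vm, cai_mm = x$cai)
  if (!is.null(x$vm_custom)) {
    df$vm_custom_mv <- x$vm_custom
    df$igap_custom_pa <- x$igap_custom_pa
  }
  if (!is.null(x$vm_fib)) {
    df$vm_fib_mv <- x$vm_fib
    df$igap_fib_pa <- x$igap_fib_pa
  }
  if (!is.null(x$currents)) df <- cbind(df, as.data.frame(x$currents))
  df
}

#' Extract the final-beat waveforms
#'
#' Returns the action potential (mV) and calcium transient (mM) over the
#' first 500 ms of the final beat, sampled on the 1 ms grid starting at the
#' final stimulus onset: exactly 501 samples.
#'
#' @param trace A `cellforge_trace` from [simulate()] whose recording covers
#'   the final beat.
#' @return Object of class `cellforge_beat`: list with `time_ms` (0..500),
#'   `ap`, `cat`.
#' @export
extract_final_beat <- function(trace) {
  stopifnot(inherits(trace, "cellforge_trace"))
  cfg <- trace$config
  t0 <- (cfg$n_beats - 1) * cfg$cl
  i0 <- match(TRUE, abs(trace$time - t0) < 1e-6)
  if (is.na(i0) || (i0 + 500) > length(trace$time))
    stop("trace does not cover the 500 ms window of the final beat")
  idx <- i0:(i0 + 500)
  structure(list(time_ms = trace$time[idx] - t0,
                 ap = trace$vm[idx], cat = trace$cai[idx]),
            class = "cellforge_beat")
}

beat_waveforms <- function(time_ms, ap, cat_) {
  stopifnot(length(time_ms) == length(ap), length(ap) == length(cat_))
  structure(list(time_ms = time_ms, ap = ap, cat = cat_),
            class = "cellforge_beat")
}

#' @export
print.cellforge_beat <- function(x, ...) {
  cat("<cellforge_beat> 0..", max(x$time_ms), " ms; AP ",
      paste(format(range(x$ap), digits = 4), collapse = " .. "), " mV; CaT peak ",
      format(max(x$cat) * 1e3, digits = 4), " uM\n", sep = "")
  invisible(x)
}

#' Write final-beat waveforms as CSV
#' @param beat A `cellforge_beat`.
#' @param path Output file.
#' @export
write_waveforms_csv <- function(beat, path) {
  stopifnot(inherits(beat, "cellforge_beat"))
  write.csv(data.frame(time_ms = beat$time_ms, vm_mv = beat$ap,
                       cai_mm = beat$cat),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a full trace as CSV
#' @param trace A `cellforge_trace`.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
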