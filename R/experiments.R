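# Named experiment presets, reference-waveform caching, the simulator-backed
# GA objective, and the budgeted minimum-RMSE search for the engineered
# hMSC/hCIC presets.

#' Reference waveforms for a cardiomyocyte phenotype
#'
#' Computes (and caches per session) the healthy and untreated final-beat
#' waveforms used by the normalized-RMSE objective, plus the untreated run's
#' final states for warm-starting candidate evaluations. Healthy is the
#' uncoupled healthy cardiomyocyte; untreated is the HF cardiomyocyte alone
#' (`"hf"`) or coupled to 5 fibroblasts at 1 nS (`"hf_fibrosis"`).
#'
#' @param phenotype `"hf"` or `"hf_fibrosis"`.
#' @param n_beats Pacing beats to reach operational steady state (500 for
#'   replication runs).
#' @param dt_max Integrator step ceiling, ms.
#' @param cache Reuse a cached result for identical settings.
#' @return List: `healthy`, `untreated` (`cellforge_beat`), `healthy_state` /
#'   `untreated_state` (warm-start states), `den_ap`/`den_cat` (denominator
#'   RMSEs), settings.
#' @export
reference_waveforms <- function(phenotype = c("hf_fibrosis", "hf"),
                                n_beats = 500L, dt_max = 0.02, cache = TRUE) {
  phenotype <- match.arg(phenotype)
  key <- paste("refs", phenotype, n_beats, dt_max, sep = "|")
  if (cache && !is.null(.cf_cache[[key]])) return(.cf_cache[[key]])
  healthy_tr <- simulate(coupling_config("healthy", n_beats = n_beats,
                                         dt_max = dt_max))
  untreated_tr <- simulate(coupling_config(phenotype, n_beats = n_beats,
                                           dt_max = dt_max))
  healthy <- extract_final_beat(healthy_tr)
  untreated <- extract_final_beat(untreated_tr)
  out <- list(phenotype = phenotype, n_beats = n_beats, dt_max = dt_max,
              healthy = healthy, untreated = untreated,
              healthy_state = healthy_tr$final_state,
              untreated_state = untreated_tr$final_state,
              den_ap = waveform_rmse(untreated$ap, healthy$ap),
              den_cat = waveform_rmse(untreated$cat, healthy$cat))
  if (cache) .cf_cache[[key]] <- out
  out
}

preset_names <- c(
  "nonexcitable-nonfibrotic", "nonexcitable-fibrotic",
  "allchannels-nonfibrotic", "allchannels-fibrotic",
  "ical-ik1", "ik1-only", "ical-only", "passive",
  "hmsc", "hmsc-ik1", "hcic", "hcic-ik1"
)

#' Experiment presets
#'
#' Named, config-driven reproductions of the in-package experiments. Each
#' preset fixes the cardiomyocyte phenotype, the custom-cell channel roster,
#' and which parameters the genetic algorithm searches. The `hmsc`/`hcic`
#' control presets carry their source cell's channels at fixed baseline
#' scaling and search only the gap-junction scale and cell count; their
#' `-ik1` variants additionally search the cardiomyocyte inward-rectifier
#' scaling.
#'
#' @param name One of `r paste(preset_names, collapse = ", ")`.
#' @return Object of class `experiment_preset`: list with `name`,
#'   `phenotype`, `roster`, `searchable` (channel names in the genome),
#'   `fixed_scaling`, and paper-scale `ga` defaults.
#' @export
experiment_preset <- function(name) {
  if (!name %in% preset_names)
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names, collapse = ", "))
  phen <- if (grepl("nonfibrotic$", name)) "hf" else "hf_fibrosis"
  roster_key <- switch(name,
    "nonexcitable-nonfibrotic" = , "nonexcitable-fibrotic" = "nonexcitable",
    "allchannels-nonfibrotic" = , "allchannels-fibrotic" = "all-channels",
    name)
  roster <- roster_preset(roster_key)
  searchable <- switch(name,
    "hmsc" = , "hcic" = character(0),
    "hmsc-ik1" = , "hcic-ik1" = "cm_k1",
    roster)
  fixed <- setdiff(roster, searchable)
  structure(list(
    name = name, phenotype = phen, roster = roster,
    searchable = searchable,
    fixed_scaling = setNames(rep(1, length(fixed)), fixed),
    ga = list(population = 2500L, generations = 5L),
    n_beats = 500L
  ), class = "experiment_preset")
}

#' Simulator-backed GA objective for a preset
#'
#' Returns the objective function scoring genomes by normalized AP/CaT RMSE
#' against the preset's cached references. Identical genomes share one
#' simulation result (memoized; evaluation order cannot affect results since
#' each genome is scored independently of the rest of its population). A
#' failed integration yields worst-case (infinite) RMSEs.
#'
#' @param preset An [experiment_preset()].
#' @param eval_beats Beats simulated per candidate, warm-starting the
#'   cardiomyocyte (and fibroblasts) from the untreated steady state. The
#'   replication protocol is 500 beats from rest; warm-started shorter runs
#'   are the documented desk-scale variant.
#' @param dt_max Integrator step ceiling, ms.
#' @param refs Optional precomputed [reference_waveforms()].
#' @return Function: genome matrix -> data.frame(rmse_ap, rmse_cat).
#' @export
make_objective <- function(preset, eval_beats = 500L, dt_max = 0.02,
                           refs = NULL) {
  stopifnot(inherits(preset, "experiment_preset"))
  if (is.null(refs))
    refs <- reference_waveforms(preset$phenotype, dt_max = dt_max)
  memo <- new.env(parent = emptyenv())
  force(eval_beats)
  function(pop) {
    n <- nrow(pop)
    rmse_ap <- rmse_cat <- numeric(n)
    for (i in seq_len(n)) {
      g <- pop[i, ]
      key <- paste(signif(g, 12), collapse = ",")
      hit <- memo[[key]]
      if (!is.null(hit)) {
        rmse_ap[i] <- hit[1]; rmse_cat[i] <- hit[2]
        next
      }
      res <- tryCatch(
        evaluate_genome(g, preset, refs, eval_beats, dt_max),
        cellforge_sim_error = function(e) c(Inf, Inf))
      rmse_ap[i] <- res[1]; rmse_cat[i] <- res[2]
      memo[[key]] <- res
    }
    data.frame(rmse_ap = rmse_ap, rmse_cat = rmse_cat)
  }
}

evaluate_genome <- function(genome, preset, refs, eval_beats, dt_max) {
  scaling <- c(preset$fixed_scaling, genome[preset$searchable])
  spec <- custom_cell_spec(preset$roster, scaling = scaling[preset$roster])
  cfg <- coupling_config(
    preset$phenotype,
    n_custom = as.integer(genome[["n_custom"]]),
    g_gap_ns = genome[["g_gap_scale"]] * 1.0,   # 1 nS baseline
    n_beats = as.integer(eval_beats), dt_max = dt_max,
    init = list(cm = refs$untreated_state$cm, fib = refs$untreated_state$fib))
  tr <- simulate(cfg, spec)
  beat <- extract_final_beat(tr)
  c(waveform_rmse(beat$ap, refs$healthy$ap) / refs$den_ap,
    waveform_rmse(beat$cat, refs$healthy$cat) / refs$den_cat)
}

#' Run a named experiment
#'
#' Runs the genetic algorithm for a preset and summarizes the final
#' generation's accepted set (median and IQR per genome parameter). Paper
#' scale is population 2500, 5 generations, 500 beats; all three are
#' overridable so desk-scale runs are first-class.
#'
#' @param preset An [experiment_preset()] or its name.
#' @param seed RNG seed.
#' @param population,generations,beats Overrides of the paper-scale defaults.
#' @param dt_max Integrator step ceiling, ms.
#' @param out_dir If non-NULL, write per-generation CSVs, the accepted
#'   summary, and a JSON manifest here.
#' @return List: `log` ([run_ga()] output), `accepted` (final-generation
#'   accepted rows), `summary` (median [IQR] per parameter over the accepted
#'   set), `preset`, `seed`.
#' @export
run_experiment <- function(preset, seed = 1L, population = NULL,
                           generations = NULL, beats = NULL,
                           dt_max = 0.02, out_dir = NULL) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  stopifnot(inherits(preset, "experiment_preset"))
  cfg <- ga_config(
    population = population %||% preset$ga$population,
    generations = generations %||% preset$ga$generations,
    seed = seed)
  refs <- reference_waveforms(preset$phenotype, dt_max = dt_max)
  obj <- make_objective(preset, eval_beats = beats %||% preset$n_beats,
                        dt_max = dt_max, refs = refs)
  log <- run_ga(cfg, preset$searchable, obj)
  final <- log$generations[[length(log$generations)]]
  accepted <- final[final$accepted, , drop = FALSE]
  pars <- genome_colnames(preset$searchable)
  summ <- if (nrow(accepted)) {
    do.call(rbind, lapply(pars, function(p) {
      q <- quantile(accepted[[p]], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(parameter = p, median = q[2], iqr_lo = q[1], iqr_hi = q[3])
    }))
  } else {
    data.frame(parameter = character(0), median = numeric(0),
               iqr_lo = numeric(0), iqr_hi = numeric(0))
  }
  bundle <- list(log = log, accepted = accepted, summary = summ,
                 preset = preset, seed = seed)
  if (!is.null(out_dir)) write_experiment(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_experiment <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in seq_along(bundle$log$generations)) {
    write.csv(bundle$log$generations[[g]],
              file.path(dir, sprintf("generation_%02d.csv", g - 1)),
              row.names = FALSE)
  }
  write.csv(bundle$summary, file.path(dir, "accepted_summary.csv"),
            row.names = FALSE)
  manifest <- list(
    preset = bundle$preset$name, phenotype = bundle$preset$phenotype,
    seed = bundle$seed, population = bundle$log$cfg$population,
    generations = bundle$log$cfg$generations,
    channels = as.list(bundle$log$channels),
    accepted_final = sum(bundle$log$generations[[length(bundle$log$generations)]]$accepted),
    package_version = as.character(utils::packageVersion("cellforge")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Minimum-RMSE search for the engineered hMSC/hCIC presets
#'
#' Seeded random search over the preset's searchable space (`n_custom`,
#' gap-junction scale, and the inward-rectifier scaling where the preset has
#' one) minimizing `rmse_ap + rmse_cat`. The minimum is taken pooled over all
#' evaluated points of the budgeted search.
#'
#' @param preset One of `hmsc`, `hmsc-ik1`, `hcic`, `hcic-ik1` (preset object
#'   or name).
#' @param budget Number of evaluations (>= 1).
#' @param seed RNG seed.
#' @param beats,dt_max Simulation settings per evaluation (see
#'   [make_objective()]).
#' @return List: `genome` (best), `rmse_ap`, `rmse_cat`, `total`, and the
#'   full `evaluated` table.
#' @export
min_rmse_search <- function(preset, budget = 200L, seed = 1L,
                            beats = 500L, dt_max = 0.02) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  stopifnot(inherits(preset, "experiment_preset"))
  if (!preset$name %in% c("hmsc", "hmsc-ik1", "hcic", "hcic-ik1"))
    stop("min_rmse_search applies to the engineered hMSC/hCIC presets")
  if (budget < 1) stop("budget must be >= 1")
  set.seed(seed)
  cfg <- ga_config(population = 2L, seed = seed)   # reuse ranges
  n <- as.integer(budget)
  ncont <- length(preset$searchable) + 1
  pop <- matrix(runif(n * ncont, cfg$scaling_range[1], cfg$scaling_range[2]),
                nrow = n)
  pop <- cbind(pop, sample(1:5, n, replace = TRUE))
  colnames(pop) <- genome_colnames(preset$searchable)
  obj <- make_objective(preset, eval_beats = beats, dt_max = dt_max)
  sc <- obj(pop)
  total <- sc$rmse_ap + sc$rmse_cat
  best <- which.min(total)
  list(genome = pop[best, ], rmse_ap = sc$rmse_ap[best],
       rmse_cat = sc$rmse_cat[best], total = total[best],
       evaluated = cbind(as.data.frame(pop), sc))
}
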