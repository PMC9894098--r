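# Cardiomyocyte parameter sets (healthy and HF-remodeled phenotypes).
#
# The compiled core stores the published baseline conductances; an R-level
# parameter set is a named vector of dimensionless multipliers applied on top.
# The HF phenotype is the healthy set times the remodeling factors shipped in
# inst/extdata/params/hf_remodeling.json.

cm_scale_names <- c(
  "g_na", "g_nal", "g_to", "p_ca", "g_kr", "g_ks", "g_k1", "g_ncx",
  "p_nak", "g_kb", "g_pca", "j_up", "j_leak", "j_rel", "tau_hl", "camk",
  "g_nab", "g_cab"
)

cm_state_names <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "h", "j", "ml", "hl", "hlp", "a", "i_f", "i_s", "ap", "i_fp", "i_sp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1", "jrelnp", "jrelp", "camkt"
)

cm_current_names <- c(
  "i_na", "i_nal", "i_to", "i_cal", "i_cana", "i_cak", "i_kr", "i_ks", "i_k1",
  "i_ncx", "i_nak", "i_nab", "i_cab", "i_pca", "i_kb", "j_rel", "j_up", "j_diff"
)

fib_state_names <- c("v", "r_kv", "s_kv")

param_file <- function(name) {
  path <- system.file("extdata", "params", name, package = "cellforge")
  if (!nzchar(path)) stop("parameter file not found: ", name)
  path
}

#' Cardiomyocyte parameter set
#'
#' Builds the multiplier set for the endocardial ventricular cardiomyocyte
#' model. `"healthy"` is the published baseline (all multipliers 1);
#' `"hf"` applies the heart-failure-with-reduced-ejection-fraction remodeling
#' factors via [apply_hf_remodeling()].
#'
#' @param phenotype `"healthy"` or `"hf"`.
#' @return An object of class `cm_parameters`: a list with `scale` (named
#'   multipliers on the baseline maximal conductances/permeabilities and
#'   fluxes), `capacitance_pf` (membrane capacitance, pF), and `phenotype`.
#' @export
#' @examples
#' p <- cm_parameters("healthy")
#' p$scale[["g_k1"]]
cm_parameters <- function(phenotype = c("healthy", "hf")) {
  phenotype <- match.arg(phenotype)
  scale <- setNames(rep(1, length(cm_scale_names)), cm_scale_names)
  obj <- structure(
    list(scale = scale, capacitance_pf = cm_capacitance_pf_cpp(),
         phenotype = "healthy"),
    class = "cm_parameters")
  if (phenotype == "hf") obj <- apply_hf_remodeling(obj)
  obj
}

#' Heart-failure remodeling factors
#'
#' The multiplicative remodeling applied to the healthy cardiomyocyte to model
#' HF with reduced ejection fraction, read from the versioned parameter file
#' `inst/extdata/params/hf_remodeling.json`.
#'
#' @return Named numeric vector of multipliers (a subset of the parameter
#'   names in a [cm_parameters()] scale vector).
#' @export
hf_remodeling_factors <- function() {
  f <- jsonlite::read_json(param_file("hf_remodeling.json"), simplifyVector = TRUE)
  unlist(f$factors)
}

#' Apply heart-failure remodeling to a healthy parameter set
#'
#' Multiplies the affected parameters by their remodeling factors and tags the
#' result as the `hf` phenotype. Unaffected parameters are returned untouched.
#' Applying remodeling to an already-remodeled set is an error (the factors
#' are not idempotent).
#'
#' @param params A `cm_parameters` object with phenotype `"healthy"`.
#' @return A `cm_parameters` object with phenotype `"hf"`.
#' @export
apply_hf_remodeling <- function(params) {
  stopifnot(inherits(params, "cm_parameters"))
  if (params$phenotype != "healthy")
    stop("HF remodeling can only be applied to a healthy parameter set ",
         "(got phenotype '", params$phenotype, "')")
  fac <- hf_remodeling_factors()
  bad <- setdiff(names(fac), names(params$scale))
  if (length(bad)) stop("unknown remodeling parameter(s): ", paste(bad, collapse = ", "))
  params$scale[names(fac)] <- params$scale[names(fac)] * fac
  params$phenotype <- "hf"
  params
}

validate_cm_parameters <- function(params) {
  stopifnot(inherits(params, "cm_parameters"))
  if (any(!is.finite(params$scale)) || any(params$scale < 0))
    stop("all parameter multipliers must be finite and >= 0")
  if (params$capacitance_pf <= 0) stop("capacitance must be positive")
  invisible(params)
}

#' @export
print.cm_parameters <- function(x, ...) {
  cat("<cm_parameters> phenotype:", x$phenotype,
      " capacitance:", format(x$capacitance_pf, digits = 4), "pF\n")
  mod <- x$scale[x$scale != 1]
  if (length(mod)) {
    cat("  non-unit multipliers:\n")
    for (n in names(mod)) cat("   ", n, "=", mod[[n]], "\n")
  } else cat("  all multipliers at baseline (1)\n")
  invisible(x)
}
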