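# Mapping from remodelable quantity names to parameter-vector entries.
# Ito scales both the slow and fast transient-outward conductances.
.remodel_targets <- list(
  INaL   = "GNaL",
  tau_hL = "tau_hL",
  Ito    = c("GtoSlow", "GtoFast"),
  IK1    = "GK1",
  INaK   = "IbarNaK",
  INab   = "GNaB",
  ICab   = "GCaB",
  INCX   = "IbarNCX",
  ISERCA = "VmaxSERCA",
  Ileak  = "leak_rate",
  EC50SR = "ec50SR",
  IKr    = "GKr",
  ICaL   = "pCa",
  Irel   = "ks_rel"
)

.hf_param_names <- c("INaL", "tau_hL", "Ito", "IK1", "INaK", "INab",
                     "ICab", "INCX", "ISERCA", "Ileak", "EC50SR")

#' Build a remodeling specification
#'
#' A remodeling specification is an ordered table of named parameter
#' transforms, each either a multiplicative `scale` (dimensionless factor)
#' or an `assign` (value in the parameter's own units), tagged with a
#' provenance label.  The empty specification is the identity; application
#' of disjoint transforms is order independent.
#'
#' @param parameter character vector of remodelable quantity names (INaL,
#'   tau_hL, Ito, IK1, INaK, INab, ICab, INCX, ISERCA, Ileak, EC50SR, IKr,
#'   ICaL, Irel).
#' @param transform `"scale"` or `"assign"`, recycled.
#' @param value factors (for scale) or assigned values, same length.
#' @param provenance label: `"basic_HF"`, `"variant"` or `"overlay"`.
#' @return object of class `hfcell_remodeling` (a data.frame).
#' @export
remodeling_spec <- function(parameter = character(), transform = "scale",
                            value = numeric(), provenance = "variant") {
  n <- length(parameter)
  spec <- data.frame(
    parameter = as.character(parameter),
    transform = rep_len(as.character(transform), n),
    value = as.numeric(value),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  validate_spec(spec)
  class(spec) <- c("hfcell_remodeling", "data.frame")
  spec
}

validate_spec <- function(spec) {
  bad <- setdiff(spec$parameter, names(.remodel_targets))
  if (length(bad)) stop("unknown remodelable parameter(s): ",
                        paste(unique(bad), collapse = ", "))
  if (!all(spec$transform %in% c("scale", "assign"))) {
    stop("transform must be 'scale' or 'assign'")
  }
  sc <- spec$transform == "scale"
  if (any(spec$value[sc] < 0)) stop("scale factors must be >= 0")
  dup <- spec$parameter[spec$transform == "assign"]
  if (anyDuplicated(dup)) {
    d <- dup[duplicated(dup)][1]
    src <- spec$provenance[spec$parameter == d & spec$transform == "assign"]
    stop("conflicting assignments to '", d, "' from: ",
         paste(src, collapse = " and "))
  }
  invisible(spec)
}

#' Basic heart-failure remodeling
#'
#' The chronic ion-channel and transporter remodeling of failing human
#' ventricular myocytes, expressed relative to the non-failing baseline:
#' late Na+ current density and its inactivation time constant doubled;
#' transient outward K+ current reduced to 40%; inward rectifier scaled by
#' 0.68; Na+/K+ pump reduced by 10%; background Na+ current removed;
#' background Ca2+ current scaled by 1.53; Na+/Ca2+ exchanger increased by
#' 75%; SERCA uptake halved; SR leak scaled five-fold; and the SR-luminal
#' half-activation of release lowered to 0.4 mM.
#'
#' The leak and background-Ca2+ factors are exposed because reported
#' values for these quantities vary; the defaults follow the single
#' consistent reading of the remodeling table (each "increase" entry read
#' as the new value in percent of baseline).
#'
#' @param leak_factor SR leak scale (default 5).
#' @param cab_factor background Ca2+ current scale (default 1.53).
#' @return `hfcell_remodeling` with provenance `"basic_HF"`.
#' @export
basic_hf_spec <- function(leak_factor = 5, cab_factor = 1.53) {
  remodeling_spec(
    parameter = c("INaL", "tau_hL", "Ito", "IK1", "INaK", "INab",
                  "ICab", "INCX", "ISERCA", "Ileak", "EC50SR"),
    transform = c(rep("scale", 5), "assign", rep("scale", 4), "assign"),
    value = c(2, 2, 0.4, 0.68, 0.9, 0, cab_factor, 1.75, 0.5,
              leak_factor, 0.4),
    provenance = "basic_HF"
  )
}

# Baseline (GPB) values of the remodelable quantities, for variant algebra.
.gpb_value <- function(parameter) {
  p <- default_parameters()
  unname(p[.remodel_targets[[parameter]][1]])
}

#' Sensitivity-analysis variant of a remodeling specification
#'
#' Replaces one remodeled parameter by its `no_change` value (the
#' non-failing baseline) or its `double_change` value, defined as doubling
#' the tabulated percent change relative to baseline: an up-regulation to
#' factor f becomes 2f, a down-regulation by d percent becomes 2d percent
#' (floored at zero).  An assignment is doubled through the equivalent
#' deviation from the baseline value, also floored at zero.  Examples:
#' I_NaK 0.9 -> 0.8, I_NaL x2 -> x4, EC50SR 0.4 mM -> 0.35 mM, I_Nab 0 ->
#' 0.
#'
#' @param base remodeling spec in which `parameter` is remodeled.
#' @param parameter name of the remodeled quantity to vary.
#' @param mode `"no_change"` or `"double_change"`.
#' @return modified `hfcell_remodeling` with provenance `"variant"`.
#' @export
sensitivity_variant <- function(base, parameter,
                                mode = c("no_change", "double_change")) {
  mode <- match.arg(mode)
  validate_spec(base)
  i <- which(base$parameter == parameter)
  if (!length(i)) stop("parameter '", parameter,
                       "' is not remodeled in the base specification")
  spec <- base
  if (mode == "no_change") {
    spec <- spec[-i, , drop = FALSE]
  } else {
    row <- spec[i, ]
    if (row$transform == "scale") {
      f <- row$value
      spec$value[i] <- if (f >= 1) 2 * f else max(0, 1 - 2 * (1 - f))
    } else {
      gpb <- .gpb_value(parameter)
      spec$value[i] <- max(0, gpb + 2 * (row$value - gpb))
    }
    spec$provenance[i] <- "variant"
  }
  class(spec) <- c("hfcell_remodeling", "data.frame")
  spec
}

#' Perturb a remodeling specification
#'
#' Scales the remodeled value of the selected parameters by `1 + fraction`
#' (e.g. `fraction = 0.15` is a +15% perturbation of the failing value;
#' I_SERCA 0.5 -> 0.575).  `parameters = "all"` perturbs every row.
#'
#' @param base remodeling spec.
#' @param parameters character vector of parameter names, or `"all"`.
#' @param fraction signed fraction in (-1, 1).
#' @return perturbed `hfcell_remodeling`.
#' @export
perturb_spec <- function(base, parameters, fraction) {
  validate_spec(base)
  if (abs(fraction) >= 1) stop("fraction must lie in (-1, 1)")
  if (identical(parameters, "all")) parameters <- unique(base$parameter)
  if (!length(parameters)) return(base)
  missing <- setdiff(parameters, base$parameter)
  if (length(missing)) stop("not remodeled in base: ",
                            paste(missing, collapse = ", "))
  spec <- base
  i <- spec$parameter %in% parameters
  spec$value[i] <- spec$value[i] * (1 + fraction)
  class(spec) <- c("hfcell_remodeling", "data.frame")
  spec
}

#' Arrhythmia overlays
#'
#' Appends the acute interventions used in the arrhythmia experiments on
#' top of a (possibly remodeled) specification: fractional block of the
#' rapid delayed rectifier (`ikr_block`, e.g. 0.5 for 50% inhibition),
#' fractional increase of the L-type Ca2+ current (`ical_increase`, e.g.
#' 0.3), multiplicative scaling of the late Na+ conductance relative to
#' the current spec (`inal_scale`, composed multiplicatively, so x2 on the
#' failing model is x4 versus baseline), and 50% blocks of SR release or
#' NCX (`irel_block`, `incx_block`, fractions).  Scale transforms compose;
#' assigning twice to one parameter is rejected.
#'
#' @param base remodeling spec (may be empty).
#' @param ikr_block,ical_increase,inal_scale,irel_block,incx_block numeric
#'   or `NULL`.
#' @return extended `hfcell_remodeling` with provenance `"overlay"`.
#' @export
overlay_spec <- function(base = remodeling_spec(), ikr_block = NULL,
                         ical_increase = NULL, inal_scale = NULL,
                         irel_block = NULL, incx_block = NULL) {
  validate_spec(base)
  add <- function(spec, parameter, value) {
    extra <- remodeling_spec(parameter, "scale", value, "overlay")
    out <- rbind(spec, extra)
    class(out) <- c("hfcell_remodeling", "data.frame")
    out
  }
  spec <- base
  if (!is.null(ikr_block)) spec <- add(spec, "IKr", 1 - ikr_block)
  if (!is.null(ical_increase)) spec <- add(spec, "ICaL", 1 + ical_increase)
  if (!is.null(inal_scale)) spec <- add(spec, "INaL", inal_scale)
  if (!is.null(irel_block)) spec <- add(spec, "Irel", 1 - irel_block)
  if (!is.null(incx_block)) spec <- add(spec, "INCX", 1 - incx_block)
  validate_spec(spec)
  spec
}

#' Apply a remodeling specification to model parameters
#'
#' Scale transforms multiply the current parameter value (so overlays
#' compose with earlier remodeling); assignments set it.  Applying the
#' empty spec is the identity.  A parameter vector remembers the
#' provenance labels already applied to it and rejects a second
#' application of the same label, preventing accidental double
#' application.
#'
#' @param params parameter vector from [default_parameters()].
#' @param spec `hfcell_remodeling`.
#' @return remodeled parameter vector (class and names preserved).
#' @export
apply_remodeling <- function(params, spec) {
  validate_parameters(params)
  validate_spec(spec)
  applied <- attr(params, "remodeling")
  labels <- unique(spec$provenance)
  clash <- intersect(labels, applied)
  if (length(clash)) {
    stop("remodeling with provenance '", clash[1],
         "' has already been applied to these parameters")
  }
  for (i in seq_len(nrow(spec))) {
    targets <- .remodel_targets[[spec$parameter[i]]]
    if (spec$transform[i] == "scale") {
      params[targets] <- params[targets] * spec$value[i]
    } else {
      params[targets] <- spec$value[i]
    }
  }
  validate_parameters(params)
  attr(params, "remodeling") <- c(applied, labels)
  class(params) <- c("hfcell_params", "numeric")
  params
}

#' Heart-failure model parameters
#'
#' Convenience wrapper: baseline parameters with [basic_hf_spec()]
#' applied.
#'
#' @param ... passed to [basic_hf_spec()].
#' @return remodeled parameter vector.
#' @export
hf_parameters <- function(...) {
  apply_remodeling(default_parameters(), basic_hf_spec(...))
}
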