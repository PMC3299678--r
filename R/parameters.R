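#' @useDynLib hfcell, .registration = TRUE
#' @importFrom stats approx setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# Parameter order is fixed and mirrored by src/gpb_model.c; do not reorder.
.param_names <- c(
  "GNa", "GNaL", "tau_hL", "hL_vhalf", "hL_k", "GNaB", "IbarNaK",
  "GtoSlow", "GtoFast", "GKr", "GKs", "GKp", "GK1", "GClCa", "GClB",
  "pCa", "pK", "pNa", "IbarNCX", "IbarSLCaP", "GCaB", "VmaxSERCA",
  "ks_rel", "leak_rate", "ec50SR", "Ko", "Nao", "Cao", "Cli", "Clo",
  "Mgi", "stim_amp", "vclamp", "naclamp"
)

.state_names <- c(
  "m", "h", "j", "xkr", "xks", "xtos", "ytos", "xtof", "ytof",
  "d", "f", "fcaBj", "fcaBsl", "RyRr", "RyRo", "RyRi",
  "NaBj", "NaBsl", "TnCL", "TnCHc", "TnCHm", "CaM", "Myoc", "Myom",
  "SRB", "SLLj", "SLLsl", "SLHj", "SLHsl", "Csqnb",
  "CaSR", "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai", "Vm", "hL"
)

.gate_states <- c("m", "h", "j", "xkr", "xks", "xtos", "ytos", "xtof",
                  "ytof", "d", "f", "fcaBj", "fcaBsl", "RyRr", "RyRo",
                  "RyRi", "hL")

.conc_states <- c("NaBj", "NaBsl", "TnCL", "TnCHc", "TnCHm", "CaM", "Myoc",
                  "Myom", "SRB", "SLLj", "SLLsl", "SLHj", "SLHsl", "Csqnb",
                  "CaSR", "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai")

.current_names <- c(
  "INa", "INaL", "INaK", "INab", "Ito", "IKr", "IKs", "IK1", "IKp",
  "ICaL", "ICaK", "ICaNa", "ICaLtot", "INCX", "IpCa", "ICab",
  "IClCa", "IClb", "Jrel", "Jserca", "Jleak", "Istim", "Iion"
)

#' Default model parameters
#'
#' Maximal conductances, transporter rates and fixed ionic conditions of the
#' endocardial human ventricular baseline model, extended with the late Na+
#' current parameters (`GNaL`, `tau_hL`, and the steady-state inactivation
#' sigmoid `hL_vhalf`/`hL_k`).  Units: conductances mS/uF, permeabilities
#' cm/s, pump/exchanger maxima A/F, SERCA maximum mM/ms, time constants ms,
#' concentrations mM, `stim_amp` A/F.
#'
#' The control late-Na+ conductance is 0.015 mS/uF with an inactivation time
#' constant of 233 ms (37 C), which under the voltage-clamp protocol of
#' [run_voltage_clamp()] yields a late-to-peak Na+ current ratio of roughly
#' 0.1%.
#'
#' @param ... named overrides of individual parameters.
#' @return Named numeric vector of class `hfcell_params`.
#' @examples
#' p <- default_parameters()
#' p["GNaL"]
#' p2 <- default_parameters(GNaL = 0)   # remove the late Na+ current
#' @export
default_parameters <- function(...) {
  p <- c(
    GNa       = 23,
    GNaL      = 0.015,
    tau_hL    = 233,
    hL_vhalf  = -91,
    hL_k      = 6.1,
    GNaB      = 0.597e-3,
    IbarNaK   = 1.8,
    GtoSlow   = 0.13 * 0.3 * 0.964,   # endocardial: mostly slow Ito
    GtoFast   = 0.13 * 0.3 * 0.036,
    GKr       = 0.035,
    GKs       = 0.0035,
    GKp       = 0.002,
    GK1       = 0.35,
    GClCa     = 0.5 * 0.109625,
    GClB      = 9e-3,
    pCa       = 0.5 * 5.4e-4,
    pK        = 0.5 * 2.7e-7,
    pNa       = 0.5 * 1.5e-8,
    IbarNCX   = 4.5,
    IbarSLCaP = 0.0673,
    GCaB      = 5.513e-4,
    VmaxSERCA = 5.3114e-3,
    ks_rel    = 25,
    leak_rate = 5.348e-6,
    ec50SR    = 0.45,
    Ko        = 5.4,
    Nao       = 140,
    Cao       = 1.8,
    Cli       = 15,
    Clo       = 150,
    Mgi       = 1,
    stim_amp  = 0,
    vclamp    = 0,
    naclamp   = 0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- unlist(dots)
  }
  validate_parameters(p)
  class(p) <- c("hfcell_params", "numeric")
  p
}

validate_parameters <- function(p) {
  if (!is.numeric(p) || length(p) != length(.param_names) ||
      !identical(names(p), .param_names)) {
    stop("parameter vector must carry the full named parameter set; ",
         "build it with default_parameters()")
  }
  if (any(!is.finite(p))) {
    stop("non-finite parameter value: ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  }
  cond <- c("GNa", "GNaL", "GNaB", "IbarNaK", "GtoSlow", "GtoFast", "GKr",
            "GKs", "GKp", "GK1", "GClCa", "GClB", "pCa", "pK", "pNa",
            "IbarNCX", "IbarSLCaP", "GCaB", "VmaxSERCA", "ks_rel",
            "leak_rate")
  if (any(p[cond] < 0)) {
    stop("negative conductance/rate: ",
         paste(cond[p[cond] < 0], collapse = ", "))
  }
  if (p["tau_hL"] <= 0) stop("tau_hL must be positive")
  if (p["ec50SR"] <= 0) stop("ec50SR must be positive")
  if (p["hL_k"] == 0) stop("hL_k (sigmoid slope) must be nonzero")
  invisible(p)
}

#' Default initial state
#'
#' Named state vector of the myocyte model.  `"control_1hz"` (the default)
#' and `"hf_1hz"` are 1-Hz steady-state snapshots of the control and basic
#' failing models (computed with this package itself and stored with the
#' sources); `"rest"` is the quiescent unstimulated resting state.
#' Starting pacing protocols from the matching snapshot shortens the
#' equilibration transient without changing the converged result.
#'
#' @param condition `"control_1hz"`, `"hf_1hz"` or `"rest"`.
#' @return Named numeric vector of length 40 (gates, buffers, compartmental
#'   Na+/Ca2+/K+ concentrations in mM, membrane potential mV).
#' @export
initial_state <- function(condition = c("control_1hz", "hf_1hz", "rest")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", paste0("state_", condition, ".csv"),
                      package = "hfcell")
  if (nzchar(path) && file.exists(path)) {
    return(read_state(path))
  }
  # fallback seed state (approximate diastole); used only during the very
  # first equilibration when no snapshot has been generated yet
  y <- c(
    m = 1.405627e-3, h = 9.867005e-1, j = 9.915620e-1,
    xkr = 8.641386e-3, xks = 5.412034e-3,
    xtos = 4.051574e-3, ytos = 9.945511e-1,
    xtof = 4.051574e-3, ytof = 9.945511e-1,
    d = 7.175662e-6, f = 1.000681e+0, fcaBj = 2.421991e-2,
    fcaBsl = 1.452605e-2,
    RyRr = 8.884332e-1, RyRo = 8.156628e-7, RyRi = 1.024274e-7,
    NaBj = 3.539892, NaBsl = 7.720854e-1,
    TnCL = 8.773191e-3, TnCHc = 1.078283e-1, TnCHm = 1.524002e-2,
    CaM = 2.911916e-4, Myoc = 1.298754e-3, Myom = 1.381982e-1,
    SRB = 2.143165e-3, SLLj = 9.566355e-3, SLLsl = 1.110363e-1,
    SLHj = 7.347888e-3, SLHsl = 7.297378e-2,
    Csqnb = 1.242988, CaSR = 0.5545201,
    Naj = 8.80329, Nasl = 8.80733, Nai = 8.80853, Ki = 120,
    Caj = 1.737475e-4, Casl = 1.031812e-4, Cai = 8.597401e-5,
    Vm = -8.09763e+1, hL = 0.99
  )
  y[.state_names]
}

validate_state <- function(y) {
  if (!is.numeric(y) || length(y) != length(.state_names) ||
      !identical(names(y), .state_names)) {
    stop("state vector must carry the full named state set; ",
         "see initial_state()")
  }
  if (any(!is.finite(y))) {
    stop("non-finite state entries: ",
         paste(names(y)[!is.finite(y)], collapse = ", "))
  }
  invisible(y)
}

#' Read / write a model state as a flat named-value table
#'
#' States are serialized as two-column CSV (`name,value`), round-tripping to
#' full double precision.
#'
#' @param path file path.
#' @param state named state vector as returned by [initial_state()].
#' @return `read_state()` returns the named state vector.
#' @export
read_state <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  y <- setNames(tab$value, tab$name)
  validate_state(y[.state_names])
  y[.state_names]
}

#' @rdname read_state
#' @export
write_state <- function(state, path) {
  validate_state(state)
  # 17 significant digits: round-trips doubles exactly
  con <- file(path, "w")
  writeLines("name,value", con)
  writeLines(sprintf("%s,%.17g", names(state), state), con)
  close(con)
  invisible(path)
}
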