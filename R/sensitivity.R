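#' Percent change of a characteristic
#'
#' \deqn{D_{c,p,x} = 100\,(C_{p,x} - C_{base}) / C_{base}}
#' the percentage by which a characteristic departs from its value in the
#' basic failing model when parameter p is set to variant x.
#'
#' @param c_px characteristic value under the variant.
#' @param c_base characteristic value in the base (failing) model.
#' @return percent change.
#' @export
percent_change <- function(c_px, c_base) {
  if (any(c_base == 0)) stop("base characteristic is zero: percent change undefined")
  100 * (c_px - c_base) / c_base
}

#' Two-point sensitivity index
#'
#' \deqn{S_{c,p} = (D_{c,p,2} - D_{c,p,1}) / \Delta_a}
#' where x = 1 is the no-change variant, x = 2 the double-change variant,
#' and `delta_a` the total interval over which the parameter multiplier
#' moves between the two variants, in units of its non-failing value.
#'
#' @param d_p1,d_p2 percent changes at the two variants.
#' @param delta_a parameter-change span (> 0).
#' @return sensitivity (percent per unit parameter change).
#' @export
sensitivity_index <- function(d_p1, d_p2, delta_a) {
  if (any(delta_a == 0)) stop("delta_a is zero: sensitivity undefined")
  (d_p2 - d_p1) / delta_a
}

.sens_characteristics <- c("APD90", "APD50", "triangulation",
                           "ca_systolic", "ca_diastolic", "tau_ca",
                           "casr_systolic", "casr_diastolic",
                           "nai", "t_ncxrp")

# multiplier (relative to the non-failing value) realised by a spec row
.variant_factor <- function(spec, parameter) {
  i <- which(spec$parameter == parameter)
  if (!length(i)) return(1)
  row <- spec[i[1], ]
  if (row$transform == "scale") row$value
  else row$value / .gpb_value(parameter)
}

#' Run the two-point sensitivity analysis of the failing model
#'
#' For every remodeled parameter, paces the failing model to steady state
#' with that parameter at its no-change (non-failing) and double-change
#' values (see [sensitivity_variant()]), extracts the biomarker set from
#' the final beat, and collects the percent changes versus the basic
#' failing model.
#'
#' @param base_spec remodeling spec to analyze (default [basic_hf_spec()]).
#' @param parameters parameter names to vary; default all rows of
#'   `base_spec`.
#' @param state starting state for every run.
#' @param frequency pacing frequency (Hz).
#' @param criterion steady-state criterion (reduced beat budgets give the
#'   same ordinal structure at a fraction of the cost).
#' @param stim,solver forwarded to [run_to_steady_state()].
#' @return data.frame with one row per (characteristic, parameter):
#'   columns `characteristic`, `parameter`, `D1`, `D2` (percent),
#'   `delta_a`, `S`; pass to [build_matrix()].
#' @export
run_sensitivity_analysis <- function(base_spec = basic_hf_spec(),
                                     parameters = unique(base_spec$parameter),
                                     state = initial_state("hf_1hz"),
                                     frequency = 1,
                                     criterion = steady_state_criterion(),
                                     stim = default_stimulus(),
                                     solver = list()) {
  run_one <- function(spec) {
    prm <- apply_remodeling(default_parameters(), spec)
    r <- run_to_steady_state(prm, frequency = frequency, state = state,
                             criterion = criterion, stim = stim,
                             solver = solver)
    unlist(r$biomarkers[1, .sens_characteristics])
  }
  c_base <- run_one(base_spec)
  rows <- list()
  for (pn in parameters) {
    v1 <- sensitivity_variant(base_spec, pn, "no_change")
    v2 <- sensitivity_variant(base_spec, pn, "double_change")
    c1 <- run_one(v1)
    c2 <- run_one(v2)
    delta_a <- abs(.variant_factor(v2, pn) - .variant_factor(v1, pn))
    d1 <- percent_change(c1, c_base)
    d2 <- percent_change(c2, c_base)
    rows[[pn]] <- data.frame(
      characteristic = .sens_characteristics, parameter = pn,
      D1 = unname(d1), D2 = unname(d2), delta_a = delta_a,
      S = unname(sensitivity_index(d1, d2, delta_a)),
      row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Assemble the normalized sensitivity matrix
#'
#' Normalizes each characteristic's sensitivities by the row maximum
#' absolute sensitivity, so every row has at least one cell of magnitude
#' 1; the sign encodes direct (+) versus inverse (-) dependence.  The row
#' maximum absolute sensitivity is also reported as a percent-change
#' figure (the larger of |D1|, |D2| for the dominant parameter).
#'
#' @param results long data.frame from [run_sensitivity_analysis()] (or
#'   any table with columns characteristic, parameter, D1, D2, S).
#' @return object of class `hfcell_sensitivity`: list with `long` (the
#'   input plus `normalized`), `matrix` (characteristics x parameters,
#'   normalized), `row_max_abs` (named; max |D| of the dominant
#'   parameter, percent).
#' @export
build_matrix <- function(results) {
  need <- c("characteristic", "parameter", "D1", "D2", "S")
  if (!all(need %in% names(results))) {
    stop("results must carry columns: ", paste(need, collapse = ", "))
  }
  chars <- unique(results$characteristic)
  pars <- unique(results$parameter)
  full <- expand.grid(characteristic = chars, parameter = pars,
                      stringsAsFactors = FALSE)
  key <- paste(results$characteristic, results$parameter)
  gap <- !(paste(full$characteristic, full$parameter) %in% key)
  if (any(gap)) {
    stop("missing sensitivity runs for: ",
         paste(paste(full$characteristic[gap], full$parameter[gap],
                     sep = "/"), collapse = ", "))
  }
  results$normalized <- NA_real_
  mat <- matrix(NA_real_, length(chars), length(pars),
                dimnames = list(chars, pars))
  row_max_abs <- setNames(numeric(length(chars)), chars)
  for (ch in chars) {
    i <- results$characteristic == ch
    smax <- max(abs(results$S[i]))
    norm <- if (smax == 0) results$S[i] else results$S[i] / smax
    results$normalized[i] <- norm
    mat[ch, results$parameter[i]] <- norm
    dom <- which(i)[which.max(abs(results$S[i]))]
    row_max_abs[ch] <- max(abs(results$D1[dom]), abs(results$D2[dom]))
  }
  structure(list(long = results, matrix = mat, row_max_abs = row_max_abs),
            class = "hfcell_sensitivity")
}

#' @export
print.hfcell_sensitivity <- function(x, ...) {
  cat("Normalized sensitivity matrix (rows: characteristics, ",
      "columns: parameters)\n", sep = "")
  print(round(x$matrix, 2))
  cat("\nRow maximum absolute change (%):\n")
  print(round(x$row_max_abs, 1))
  invisible(x)
}
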