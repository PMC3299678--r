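#' Consistency of the recorded current decomposition
#'
#' Checks, at every output time of a trace, that the recorded total
#' membrane current equals the sum of the recorded individual currents
#' and that the membrane-potential derivative implied by the states
#' equals `-(Iion - Istim)`.
#'
#' @param trace `hfcell_trace` with current columns.
#' @param params the parameter vector the trace was produced with.
#' @param stim stimulus amplitude during the trace window (A/F).
#' @return invisibly, the maximum absolute decomposition residual (A/F);
#'   components: `sum_residual` and `dvdt_residual`.
#' @export
check_current_consistency <- function(trace, params, stim = 0) {
  members <- c("INa", "INaL", "INab", "ICaLtot", "ICab", "IpCa", "INCX",
               "INaK", "Ito", "IKr", "IKs", "IK1", "IKp", "IClCa", "IClb")
  sum_res <- max(abs(rowSums(trace[, members]) - trace$Iion))
  rows <- unique(round(seq(1, nrow(trace), length.out = min(25, nrow(trace)))))
  dv_res <- 0
  for (i in rows) {
    y <- setNames(as.numeric(trace[i, .state_names]), .state_names)
    d <- compute_derivatives(y, params, stim = stim)
    dv_res <- max(dv_res,
                  abs(d$ydot[["Vm"]] -
                      (-(d$currents[["Iion"]] - d$currents[["Istim"]]))))
  }
  invisible(c(sum_residual = sum_res, dvdt_residual = dv_res))
}

#' Compare model derivatives against a reference table
#'
#' Evaluates the model right-hand side at externally supplied probe
#' states and compares every state derivative with reference values, for
#' validation against an independent encoding of the baseline model.  The
#' reference table is a CSV with one row per probe: columns `probe`,
#' `variable`, `state`, `deriv` (long format: each probe lists all state
#' variables with their values and expected derivatives).
#'
#' @param reference path to the reference CSV.
#' @param params parameter vector to evaluate with.
#' @param rtol relative tolerance.
#' @return data.frame per probe and variable with model and reference
#'   derivatives, relative error, and a `pass` flag.
#' @export
validate_derivatives <- function(reference, params = default_parameters(),
                                 rtol = 1e-6) {
  tab <- read.csv(reference, stringsAsFactors = FALSE)
  need <- c("probe", "variable", "state", "deriv")
  if (!all(need %in% names(tab))) {
    stop("reference table must carry columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (pr in unique(tab$probe)) {
    sub <- tab[tab$probe == pr, ]
    y <- setNames(sub$state, sub$variable)[.state_names]
    if (any(is.na(y))) stop("probe '", pr, "' does not list every state")
    d <- compute_derivatives(y, params)
    ref <- setNames(sub$deriv, sub$variable)[.state_names]
    scale <- pmax(abs(ref), 1e-12)
    rel <- abs(d$ydot - ref) / scale
    out[[as.character(pr)]] <- data.frame(
      probe = pr, variable = .state_names, model = unname(d$ydot),
      reference = unname(ref), rel_error = unname(rel),
      pass = unname(rel < rtol))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
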