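#' Synthetic fixtures with known biomarker values
#'
#' Builds small analytic traces and reduced models used by the unit tests
#' and examples, each with closed-form biomarker values:
#'
#' * `"triangle_ap"`: linear ramp from `v_peak` to `v_rest` over
#'   `duration` ms (APD at level L is exactly `L * duration`).
#' * `"plateau_ap"`: two-segment piecewise-linear action potential with a
#'   flat plateau, crossing times computable by hand.
#' * `"exp_ca"`: Ca2+ transient decaying exponentially at rate `rate` (1/ms)
#'   from amplitude `amplitude` above `baseline`; the 10%-residual decay
#'   time is `log(10)/rate`.
#' * `"ncx"`: current starting at `i_peak` and crossing zero at
#'   `t_cross` ms, linear.
#' * `"ead_ap"`: a repolarizing AP with one gaussian bump of `bump_mv` mV
#'   at `bump_t` ms.
#' * `"excitable2d"`: right-hand side and settings of a two-variable
#'   excitable (FitzHugh-Nagumo type) system for integrator exercises.
#'
#' @param kind fixture name.
#' @param ... fixture parameters with sensible defaults (see details).
#' @return for trace fixtures, a data.frame with `time` and the signal
#'   column (`v`, `ca`, or `incx`); for `"excitable2d"`, a list with
#'   `func`, `y0`, `parms`.
#' @export
generate_fixtures <- function(kind = c("triangle_ap", "plateau_ap",
                                       "exp_ca", "ncx", "ead_ap",
                                       "excitable2d"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  arg <- function(name, default) {
    if (name %in% names(args)) args[[name]] else default
  }
  dt <- arg("dt", 0.5)
  switch(kind,
    triangle_ap = {
      v_peak <- arg("v_peak", 40)
      v_rest <- arg("v_rest", -85)
      duration <- arg("duration", 300)
      tail_ms <- arg("tail_ms", 50)
      t <- seq(0, duration + tail_ms, by = dt)
      v <- ifelse(t <= 1, v_rest + (v_peak - v_rest) * t,        # 1-ms upstroke
            ifelse(t <= 1 + duration,
                   v_peak - (v_peak - v_rest) * (t - 1) / duration,
                   v_rest))
      data.frame(time = t, v = v)
    },
    plateau_ap = {
      v_peak <- arg("v_peak", 40)
      v_plateau <- arg("v_plateau", 0)
      v_rest <- arg("v_rest", -80)
      t_plateau <- arg("t_plateau", 200)
      t_repol <- arg("t_repol", 100)
      t <- seq(0, 1 + t_plateau + t_repol + 50, by = dt)
      v <- ifelse(t <= 1, v_rest + (v_peak - v_rest) * t,
            ifelse(t <= 1 + t_plateau,
                   v_peak + (v_plateau - v_peak) * (t - 1) / t_plateau,
            ifelse(t <= 1 + t_plateau + t_repol,
                   v_plateau + (v_rest - v_plateau) *
                     (t - 1 - t_plateau) / t_repol,
                   v_rest)))
      data.frame(time = t, v = v)
    },
    exp_ca = {
      rate <- arg("rate", 0.01)
      amplitude <- arg("amplitude", 4e-4)
      baseline <- arg("baseline", 1e-4)
      t_peak <- arg("t_peak", 30)
      t <- seq(0, arg("duration", 1000), by = dt)
      ca <- ifelse(t <= t_peak,
                   baseline + amplitude * t / t_peak,
                   baseline + amplitude * exp(-rate * (t - t_peak)))
      data.frame(time = t, ca = ca)
    },
    ncx = {
      i_peak <- arg("i_peak", 0.5)
      t_cross <- arg("t_cross", 120)
      t <- seq(0, arg("duration", 400), by = dt)
      data.frame(time = t, incx = i_peak * (1 - t / t_cross))
    },
    ead_ap = {
      base <- generate_fixtures("plateau_ap", t_plateau = arg("t_plateau", 500),
                                t_repol = arg("t_repol", 100), dt = dt)
      bump_mv <- arg("bump_mv", 10)
      bump_t <- arg("bump_t", 400)
      base$v <- base$v + bump_mv * exp(-((base$time - bump_t) / 15)^2)
      base
    },
    excitable2d = {
      eps <- arg("eps", 0.08)
      list(
        func = function(t, y, parms) {
          with(as.list(c(y, parms)), {
            dv <- v - v^3 / 3 - w + i_app
            dw <- eps * (v + 0.7 - 0.8 * w)
            list(c(dv, dw))
          })
        },
        y0 = c(v = -1.2, w = -0.6),
        parms = c(eps = eps, i_app = arg("i_app", 0.5))
      )
    })
}
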