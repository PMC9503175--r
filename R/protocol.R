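# Experiment-protocol arithmetic: image sampling schedules and pump-drive
# quantization. These small calculations parameterize runs and tests.

#' Define an image sampling plan
#'
#' @param start First capture time in seconds.
#' @param interval Capture interval in seconds (> 0).
#' @param duration Test duration in seconds (captures run while
#'   `t <= duration`, endpoint inclusive).
#' @param n_tests Number of repeated tests (>= 1).
#' @return A `sampling_plan` list.
#' @examples
#' sampling_plan(15, 15, 225, n_tests = 5)
#' @export
sampling_plan <- function(start = 15, interval = 15, duration = 225,
                          n_tests = 1) {
  if (interval <= 0) stop("interval must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  if (n_tests < 1) stop("n_tests must be >= 1")
  structure(list(start = start, interval = interval, duration = duration,
                 n_tests = as.integer(n_tests)),
            class = "sampling_plan")
}

#' Capture timestamps of one test
#'
#' Timestamps `start, start + interval, ...` while `<= duration`. The
#' default plan (first frame at 15 s, 15 s interval, 225 s duration)
#' yields 15 frames per test, the last at 225 s.
#'
#' @param plan A `sampling_plan`.
#' @return Numeric vector of capture times in seconds (possibly empty).
#' @export
sampling_schedule <- function(plan) {
  if (plan$start > plan$duration) return(numeric(0))
  seq(plan$start, plan$duration, by = plan$interval)
}

#' Total frames expected across all tests of a plan
#'
#' @param plan A `sampling_plan`.
#' @return `n_tests` times the per-test schedule length.
#' @examples
#' frames_expected(sampling_plan(15, 15, 225, n_tests = 5))  # 75
#' @export
frames_expected <- function(plan) {
  plan$n_tests * length(sampling_schedule(plan))
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> t = %g..%g s every %g s, %d test(s), %d frame(s)\n",
              x$start, x$duration, x$interval, x$n_tests, frames_expected(x)))
  invisible(x)
}

#' PWM voltage resolution of the pump drive
#'
#' The pump voltage is quantized by a PWM output with a fixed number of
#' duty-cycle levels. With the default convention the step is
#' `(v_max - v_min) / levels`; the alternative `(levels - 1)` divisor is
#' exposed because both conventions appear in controller documentation
#' (for a 0-9 V range with 256 levels they round to the same 0.035 V).
#'
#' @param v_min,v_max Voltage range in volts (`v_max > v_min`).
#' @param levels Number of PWM levels (>= 2, default 256 for an 8-bit
#'   timer).
#' @param divisor `"levels"` (default) or `"levels_minus_1"`.
#' @return List with `volts_per_step` (raw) and `volts_per_step_rounded`
#'   (3 decimals).
#' @examples
#' pwm_voltage_resolution(0, 9)$volts_per_step_rounded  # 0.035
#' @export
pwm_voltage_resolution <- function(v_min = 0, v_max = 9, levels = 256,
                                   divisor = c("levels", "levels_minus_1")) {
  divisor <- match.arg(divisor)
  if (v_max <= v_min) stop("v_max must exceed v_min")
  if (levels < 2) stop("levels must be >= 2")
  den <- if (divisor == "levels") levels else levels - 1
  raw <- (v_max - v_min) / den
  list(volts_per_step = raw, volts_per_step_rounded = round(raw, 3))
}
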