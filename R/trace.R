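# Reduction of raw instrument readouts: initial rates from kinetic traces,
# plateau fluorescence from ThT scans, and the normalizations built on them.

#' Construct an assay trace
#'
#' Bundles one well's kinetic readout (time, signal) with its assay
#' metadata. Time must be strictly increasing and the two sequences equal
#' length (>= 2).
#'
#' @param time Time points (s), strictly increasing.
#' @param signal Instrument signal (AU/AFU), same length as `time`.
#' @param assay_id Identifier of the well/trace.
#' @param substrate_conc,inhibitor_conc Concentrations (µM), `NA` if not
#'   applicable; negative values are rejected.
#' @param inhibitor_id Inhibitor label or `NA`.
#' @param replicate Replicate index.
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(time, signal, assay_id = "trace",
                        substrate_conc = NA_real_, inhibitor_id = NA_character_,
                        inhibitor_conc = NA_real_, replicate = 1L) {
  if (length(time) != length(signal) || length(time) < 2) {
    ik_abort("time and signal must be equal length >= 2",
             "inhibkin_input_error")
  }
  if (any(diff(time) <= 0)) {
    ik_abort("time must be strictly increasing", "inhibkin_input_error")
  }
  for (x in c(substrate_conc, inhibitor_conc)) {
    if (!is.na(x) && x < 0) {
      ik_abort("concentrations must be >= 0", "inhibkin_input_error")
    }
  }
  structure(
    list(assay_id = assay_id, time_s = as.numeric(time),
         signal = as.numeric(signal), substrate_conc = substrate_conc,
         inhibitor_id = inhibitor_id, inhibitor_conc = inhibitor_conc,
         replicate = replicate),
    class = "assay_trace"
  )
}

# Accept an assay_trace or a data.frame with time_s/signal (or time/signal).
as_trace_xy <- function(trace) {
  if (inherits(trace, "assay_trace")) {
    return(list(t = trace$time_s, y = trace$signal))
  }
  if (is.data.frame(trace)) {
    tcol <- intersect(c("time_s", "time"), names(trace))[1]
    ycol <- intersect(c("signal", "y"), names(trace))[1]
    if (is.na(tcol) || is.na(ycol)) {
      ik_abort("trace data.frame needs time_s and signal columns",
               "inhibkin_input_error")
    }
    t <- trace[[tcol]]
    if (any(diff(t) <= 0)) {
      ik_abort("time must be strictly increasing", "inhibkin_input_error")
    }
    return(list(t = as.numeric(t), y = as.numeric(trace[[ycol]])))
  }
  ik_abort("trace must be an assay_trace or data.frame", "inhibkin_input_error")
}

# Prefix/suffix linear-fit statistics from running sums. A zero-variance
# (perfectly flat) signal is defined to have r2 = 1 and slope 0 so that
# flat traces reduce cleanly instead of hitting 0/0.
window_fit <- function(t, y) {
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  flat_tol <- n * (1e-10 * (abs(mean(y)) + 1))^2
  if (syy <= flat_tol) {
    return(list(slope = 0, r2 = 1, se = 0, n = n))
  }
  slope <- sxy / sxx
  r2 <- (sxy * sxy) / (sxx * syy)
  r2 <- min(max(r2, 0), 1)
  sse <- max(syy - slope * sxy, 0)
  se <- if (n > 2) sqrt(sse / ((n - 2) * sxx)) else NA_real_
  list(slope = slope, r2 = r2, se = se, n = n)
}

#' Extract the initial rate from the linear portion of a kinetic trace
#'
#' Finds the longest prefix window (anchored at the first sample, optionally
#' capped at `max_window` seconds) whose ordinary least-squares fit achieves
#' `r2 >= r2_threshold`, and reports its slope as the initial rate v0
#' together with the coefficient of determination and the standard error of
#' the slope. Prefix anchoring reflects that the quantity of interest is the
#' *initial* linear portion of the kinetics.
#'
#' @param trace An [assay_trace()] or a data.frame with `time_s`, `signal`.
#' @param min_points Minimum window size in samples (default 5).
#' @param r2_threshold Linearity criterion in `(0, 1]` (default 0.99). A
#'   perfectly flat window counts as linear (`r2 = 1`, `v0 = 0`).
#' @param max_window Optional cap (s) on the window span; e.g. 1800 s for
#'   BACE-1-style assays whose kinetics are linear in the first 30 min.
#' @param fallback_min_window If no window reaches `r2_threshold`, accept
#'   the `min_points` window instead of erroring (default `FALSE`).
#'
#' @return An object of class `initial_rate`: list with `v0`, `window_start`,
#'   `window_end`, `r2`, `se`, `n_points`.
#' @section Errors: if no prefix window of at least `min_points` samples
#'   reaches `r2_threshold` (and `fallback_min_window` is `FALSE`), an error
#'   of class `inhibkin_degenerate_trace` is raised carrying the best
#'   achieved r-squared in its `best_r2` field.
#' @examples
#' tr <- simulate_progress_trace(0.5, 600, 61, curvature_onset = 600)
#' extract_initial_rate(tr)$v0
#' @export
extract_initial_rate <- function(trace, min_points = 5L, r2_threshold = 0.99,
                                 max_window = NULL,
                                 fallback_min_window = FALSE) {
  xy <- as_trace_xy(trace)
  t <- xy$t; y <- xy$y
  n <- length(t)
  if (r2_threshold <= 0 || r2_threshold > 1) {
    ik_abort("r2_threshold must be in (0, 1]", "inhibkin_input_error")
  }
  if (n < min_points) {
    ik_abort("trace has fewer samples than min_points", "inhibkin_input_error")
  }
  kmax <- n
  if (!is.null(max_window)) {
    kmax <- max(which(t - t[1] <= max_window))
  }
  if (kmax < min_points) {
    ik_abort("max_window admits fewer than min_points samples",
             "inhibkin_input_error")
  }

  best_r2 <- -Inf
  for (k in seq(kmax, min_points)) {
    f <- window_fit(t[1:k], y[1:k])
    if (f$r2 > best_r2) best_r2 <- f$r2
    if (f$r2 >= r2_threshold) {
      return(structure(
        list(v0 = f$slope, window_start = t[1], window_end = t[k],
             r2 = f$r2, se = f$se, n_points = k),
        class = "initial_rate"
      ))
    }
  }
  if (fallback_min_window) {
    f <- window_fit(t[1:min_points], y[1:min_points])
    out <- structure(
      list(v0 = f$slope, window_start = t[1], window_end = t[min_points],
           r2 = f$r2, se = f$se, n_points = as.integer(min_points)),
      class = "initial_rate"
    )
    attr(out, "accepted_min_window") <- TRUE
    return(out)
  }
  ik_abort(
    sprintf("no prefix window of >= %d points reaches r2 >= %g (best r2 = %.4f)",
            min_points, r2_threshold, best_r2),
    "inhibkin_degenerate_trace", best_r2 = best_r2
  )
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("<initial_rate> v0 = %.6g /s over [%g, %g] s (%d pts), r2 = %.4f, se = %.3g\n",
              x$v0, x$window_start, x$window_end, x$n_points, x$r2, x$se))
  invisible(x)
}

#' Average the plateau of a fluorescence scan
#'
#' Finds the longest suffix window spanning at least `min_span` seconds
#' whose fitted slope is not significantly different from zero (two-sided
#' normal test of slope/se at level `slope_alpha`) and returns the mean
#' signal over that window. If the whole scan qualifies, the whole scan is
#' used.
#'
#' @param scan An [assay_trace()] or data.frame with `time_s`, `signal`.
#' @param min_span Minimum plateau span in seconds (default 120, i.e. the
#'   plateau is averaged over at least 2 min of scan).
#' @param slope_alpha Significance level of the zero-slope test
#'   (default 0.05).
#'
#' @return An object of class `plateau_value`: list with `mean`, `sd`,
#'   `window_start`, `window_end`, `n_points`.
#' @section Errors: if no suffix window of at least `min_span` passes the
#'   zero-slope test, an error of class `inhibkin_no_plateau` is raised
#'   carrying the terminal slope in its `terminal_slope` field.
#' @examples
#' scan <- data.frame(time_s = 0:300, signal = 600)
#' plateau_mean(scan)$mean
#' @export
plateau_mean <- function(scan, min_span = 120, slope_alpha = 0.05) {
  xy <- as_trace_xy(scan)
  t <- xy$t; y <- xy$y
  n <- length(t)
  if (t[n] - t[1] < min_span) {
    ik_abort("scan shorter than the minimum plateau span",
             "inhibkin_input_error")
  }
  starts <- which(t[n] - t >= min_span)
  terminal <- NULL
  for (j in starts) {
    k <- n - j + 1
    if (k < 3) break
    f <- window_fit(t[j:n], y[j:n])
    terminal <- f
    pass <- if (f$se == 0 || is.na(f$se)) {
      f$slope == 0
    } else {
      2 * stats::pnorm(-abs(f$slope / f$se)) >= slope_alpha
    }
    if (pass) {
      w <- y[j:n]
      return(structure(
        list(mean = mean(w), sd = stats::sd(w),
             window_start = t[j], window_end = t[n], n_points = k),
        class = "plateau_value"
      ))
    }
  }
  ik_abort(
    sprintf("no suffix window of >= %g s has a slope consistent with zero (terminal slope %.3g)",
            min_span, terminal$slope),
    "inhibkin_no_plateau", terminal_slope = terminal$slope
  )
}

#' @export
print.plateau_value <- function(x, ...) {
  cat(sprintf("<plateau_value> mean = %.6g (sd %.3g) over [%g, %g] s (%d pts)\n",
              x$mean, x$sd, x$window_start, x$window_end, x$n_points))
  invisible(x)
}

#' Percent residual self-aggregation from ThT plateau values
#'
#' Background-subtracted plateau fluorescence of a sample expressed as a
#' percentage of the uninhibited control:
#' `100 * (sample - background) / (control - background)`, clamped below at
#' zero. Values above 100 (signal enhancement) are permitted but flagged via
#' the `"flagged"` attribute.
#'
#' @param sample,control,background [plateau_mean()] results or bare plateau
#'   means (AFU). `control` must exceed `background`.
#' @return Residual self-aggregation in percent, with attribute `flagged`
#'   set to `TRUE` when the value exceeds 100.
#' @examples
#' percent_residual(600, 1100, 100) # 50
#' @export
percent_residual <- function(sample, control, background) {
  s <- if (inherits(sample, "plateau_value")) sample$mean else sample
  c0 <- if (inherits(control, "plateau_value")) control$mean else control
  b <- if (inherits(background, "plateau_value")) background$mean else background
  if (c0 <= b) {
    ik_abort("control plateau must exceed background",
             "inhibkin_normalization_error")
  }
  val <- 100 * (s - b) / (c0 - b)
  out <- max(val, 0)
  attr(out, "flagged") <- val > 100
  out
}
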