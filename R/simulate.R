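# Synthetic assay data generators. Defaults mirror the study designs the
# package targets: Ellman-assay substrate range 80-500 uM, inhibitor doses
# 2.5-10 uM, triplicate determinations, ThT endpoint scans of 300 s with
# inhibitor doses 24-240 uM.

#' Model velocity under the general modifier equation
#'
#' Evaluates \eqn{v = V_{max} S / (K_m (1 + I/K_{ic}) + S (1 + I/K_{iu}))}
#' for a given truth; an absent site constant removes its term.
#'
#' @param truth An [inhibition_truth()].
#' @param S,I Substrate and inhibitor concentrations (µM), vectorised.
#' @return Numeric vector of noiseless rates.
#' @export
modifier_velocity <- function(truth, S, I) {
  stopifnot(inherits(truth, "inhibition_truth"))
  ac <- if (is.null(truth$Ki_c)) 1 else 1 + I / truth$Ki_c
  au <- if (is.null(truth$Ki_u)) 1 else 1 + I / truth$Ki_u
  truth$Vmax * S / (truth$Km * ac + S * au)
}

#' Simulate a velocity panel over a substrate x inhibitor grid
#'
#' Generates one reduced measurement (S, I, v0) per replicate per grid cell
#' from the general modifier equation, with multiplicative Gaussian noise of
#' coefficient of variation `truth$noise_cv`. The uninhibited column
#' (`I = 0`) is required so that downstream mechanism calls and dose-response
#' normalization have their reference.
#'
#' @param truth An [inhibition_truth()].
#' @param S_grid Substrate concentrations (µM), default the Ellman-assay
#'   range `c(80, 125, 200, 330, 500)`.
#' @param I_grid Inhibitor concentrations (µM) including 0, default
#'   `c(0, 2.5, 5, 10)`.
#' @param n_replicates Replicates per condition (default 3).
#'
#' @return A data.frame with columns `S_uM`, `I_uM`, `v0`, `replicate`.
#' @examples
#' tr <- inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_c = 10)
#' head(simulate_velocity_panel(tr))
#' @export
simulate_velocity_panel <- function(truth,
                                    S_grid = c(80, 125, 200, 330, 500),
                                    I_grid = c(0, 2.5, 5, 10),
                                    n_replicates = 3L) {
  stopifnot(inherits(truth, "inhibition_truth"))
  if (length(S_grid) == 0 || length(I_grid) == 0) {
    ik_abort("S_grid and I_grid must be non-empty", "inhibkin_input_error")
  }
  if (any(S_grid < 0) || any(I_grid < 0)) {
    ik_abort("concentrations must be >= 0", "inhibkin_input_error")
  }
  if (!any(I_grid == 0)) {
    ik_abort("I_grid must contain 0 (uninhibited reference)",
             "inhibkin_input_error")
  }
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      S_uM = S_grid, I_uM = I_grid)
  v <- modifier_velocity(truth, grid$S_uM, grid$I_uM)
  if (truth$noise_cv > 0) {
    v <- with_seed(truth$seed,
                   v * (1 + stats::rnorm(length(v), 0, truth$noise_cv)))
  }
  data.frame(S_uM = grid$S_uM, I_uM = grid$I_uM, v0 = v,
             replicate = grid$replicate)
}

#' Simulate a kinetic progress trace with an initial linear portion
#'
#' The noiseless trace is exactly linear with slope `v0_true` up to
#' `curvature_onset`, then decelerates along a saturating-exponential
#' approach to plateau with a continuous first derivative at the onset
#' (slope `v0_true` there, decaying with time constant one third of the
#' remaining duration). Additive Gaussian noise of standard deviation
#' `noise_sd` is applied pointwise.
#'
#' @param v0_true True initial rate (signal/s).
#' @param duration Trace length (s), > 0.
#' @param n_points Number of evenly spaced samples (>= 2).
#' @param curvature_onset Time (s) at which curvature begins; must lie in
#'   `(0, duration]`. Equal to `duration` means a perfectly linear trace.
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param seed Integer seed.
#' @param signal0 Signal at time zero (default 0).
#'
#' @return A data.frame with columns `time_s`, `signal`.
#' @examples
#' tr <- simulate_progress_trace(1, duration = 600, n_points = 61,
#'                               curvature_onset = 300)
#' @export
simulate_progress_trace <- function(v0_true, duration, n_points,
                                    curvature_onset = duration,
                                    noise_sd = 0, seed = 1L, signal0 = 0) {
  check_number(v0_true, "v0_true")
  check_number(duration, "duration", positive = TRUE)
  if (!is.numeric(n_points) || n_points < 2) {
    ik_abort("n_points must be >= 2", "inhibkin_input_error")
  }
  check_number(curvature_onset, "curvature_onset", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (curvature_onset > duration) {
    ik_abort("curvature_onset must be <= duration", "inhibkin_input_error")
  }
  t <- seq(0, duration, length.out = as.integer(n_points))
  y <- signal0 + v0_true * pmin(t, curvature_onset)
  post <- t > curvature_onset
  if (any(post)) {
    tau <- (duration - curvature_onset) / 3
    y[post] <- signal0 + v0_true * curvature_onset +
      v0_true * tau * (1 - exp(-(t[post] - curvature_onset) / tau))
  }
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  data.frame(time_s = t, signal = y)
}

#' Simulate a full panel of progress traces from an inhibition truth
#'
#' One trace per (substrate, inhibitor, replicate) condition: the well's
#' underlying rate is the modifier-equation velocity with the truth's
#' multiplicative rate noise, and the trace itself follows
#' [simulate_progress_trace()] with additive read noise. Output is in the
#' trace CSV schema consumed by [run_profiling()].
#'
#' @inheritParams simulate_velocity_panel
#' @param duration,n_points,curvature_onset,trace_noise_sd Trace shape and
#'   read-noise settings passed per well.
#' @param inhibitor_id Label recorded in the `inhibitor_id` column.
#' @return A data.frame with columns `assay_id`, `time_s`, `signal`,
#'   `substrate_uM`, `inhibitor_id`, `inhibitor_uM`, `replicate`.
#' @export
simulate_trace_panel <- function(truth,
                                 S_grid = c(80, 125, 200, 330, 500),
                                 I_grid = c(0, 2.5, 5, 10),
                                 n_replicates = 3L,
                                 duration = 600, n_points = 121L,
                                 curvature_onset = 300,
                                 trace_noise_sd = 0,
                                 inhibitor_id = "inhibitor") {
  panel <- simulate_velocity_panel(truth, S_grid, I_grid, n_replicates)
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    tr <- simulate_progress_trace(panel$v0[i], duration, n_points,
                                  curvature_onset, trace_noise_sd,
                                  seed = truth$seed + i)
    out[[i]] <- data.frame(
      assay_id = sprintf("S%g_I%g_r%d", panel$S_uM[i], panel$I_uM[i],
                         panel$replicate[i]),
      time_s = tr$time_s, signal = tr$signal,
      substrate_uM = panel$S_uM[i], inhibitor_id = inhibitor_id,
      inhibitor_uM = panel$I_uM[i], replicate = panel$replicate[i]
    )
  }
  do.call(rbind, out)
}

#' Simulate thioflavin-T endpoint scans
#'
#' For each inhibitor concentration the fibril fluorescence sits at the
#' logistic level of the [tht_truth()] law; each scan is that constant over
#' `scan_duration` seconds plus additive Gaussian noise, together with a
#' dye-only background scan. The `I = 0` scan is the uninhibited control.
#'
#' @param truth A [tht_truth()].
#' @param I_grid Inhibitor concentrations (µM) including 0; default the
#'   assay doses `c(0, 24, 120, 240)`.
#' @param scan_duration Scan length in seconds (default 300).
#' @param n_scan_points Samples per scan (default 301, i.e. 1 Hz).
#' @param n_replicates Replicate scans per concentration (default 3).
#'
#' @return A data.frame with columns `scan_id`, `time_s`, `signal`,
#'   `inhibitor_uM`, `role` (`"control"`, `"sample"` or `"background"`) and
#'   `replicate`.
#' @examples
#' th <- tht_truth(IC50 = 100)
#' scans <- simulate_tht_assay(th)
#' @export
simulate_tht_assay <- function(truth, I_grid = c(0, 24, 120, 240),
                               scan_duration = 300, n_scan_points = 301L,
                               n_replicates = 3L) {
  stopifnot(inherits(truth, "tht_truth"))
  if (length(I_grid) == 0 || any(I_grid < 0)) {
    ik_abort("I_grid must be non-empty with concentrations >= 0",
             "inhibkin_input_error")
  }
  if (!any(I_grid == 0)) {
    ik_abort("I_grid must contain 0 (uninhibited control)",
             "inhibkin_input_error")
  }
  check_number(scan_duration, "scan_duration", positive = TRUE)
  if (n_scan_points < 2) {
    ik_abort("n_scan_points must be >= 2", "inhibkin_input_error")
  }

  t <- seq(0, scan_duration, length.out = as.integer(n_scan_points))
  span <- truth$F_control - truth$F_background
  plateau <- function(I) {
    span / (1 + (I / truth$IC50)^truth$hill_slope) + truth$F_background
  }

  levels <- rbind(
    data.frame(inhibitor_uM = I_grid,
               role = ifelse(I_grid == 0, "control", "sample"),
               level = plateau(I_grid)),
    data.frame(inhibitor_uM = 0, role = "background",
               level = truth$F_background)
  )

  with_seed(truth$seed, {
    out <- vector("list", nrow(levels) * n_replicates)
    k <- 0L
    for (i in seq_len(nrow(levels))) {
      for (r in seq_len(n_replicates)) {
        k <- k + 1L
        sd <- truth$scan_noise_cv * levels$level[i]
        sig <- levels$level[i] +
          if (sd > 0) stats::rnorm(length(t), 0, sd) else 0
        out[[k]] <- data.frame(
          scan_id = sprintf("%s_I%g_r%d", levels$role[i],
                            levels$inhibitor_uM[i], r),
          time_s = t, signal = sig,
          inhibitor_uM = levels$inhibitor_uM[i],
          role = levels$role[i], replicate = r
        )
      }
    }
    do.call(rbind, out)
  })
}
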