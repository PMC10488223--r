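#' Ground truth for a simulated enzyme-inhibition experiment
#'
#' Describes the generative model behind a synthetic velocity panel: the
#' uninhibited Michaelis-Menten parameters, the inhibition mechanism, and the
#' site-specific inhibition constants of the general modifier equation
#' \deqn{v = \frac{V_{max} S}{K_m (1 + I/K_{ic}) + S (1 + I/K_{iu})}}
#' where \eqn{K_{ic}} is the competitive-site constant (binding to free
#' enzyme) and \eqn{K_{iu}} the uncompetitive-site constant (binding to the
#' enzyme-substrate complex). Pure mechanisms are special cases: competitive
#' has no \eqn{K_{iu}} term, uncompetitive no \eqn{K_{ic}} term,
#' noncompetitive has \eqn{K_{ic} = K_{iu}}, and mixed has both present but
#' unequal.
#'
#' @param mechanism One of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`.
#' @param Km,Vmax Uninhibited Michaelis constant (µM) and maximal rate
#'   (signal/s); both must be positive.
#' @param Ki_c,Ki_u Competitive-site / uncompetitive-site inhibition
#'   constants (µM). Which ones are required depends on `mechanism`; for
#'   `"noncompetitive"` supplying either one sets both.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise applied to simulated rates (0 = noiseless).
#' @param seed Integer seed; simulations from this truth are reproducible.
#'
#' @return An object of class `inhibition_truth`.
#' @seealso [simulate_velocity_panel()], [simulate_trace_panel()]
#' @examples
#' inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_c = 12)
#' inhibition_truth("mixed", Km = 100, Vmax = 10, Ki_c = 5, Ki_u = 20)
#' @export
inhibition_truth <- function(mechanism = c("competitive", "noncompetitive",
                                           "uncompetitive", "mixed"),
                             Km, Vmax, Ki_c = NULL, Ki_u = NULL,
                             noise_cv = 0, seed = 1L) {
  mechanism <- match.arg(mechanism)
  check_number(Km, "Km", positive = TRUE)
  check_number(Vmax, "Vmax", positive = TRUE)
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (!is.null(Ki_c)) check_number(Ki_c, "Ki_c", positive = TRUE)
  if (!is.null(Ki_u)) check_number(Ki_u, "Ki_u", positive = TRUE)

  if (mechanism == "competitive") {
    if (is.null(Ki_c) || !is.null(Ki_u)) {
      ik_abort("competitive inhibition requires Ki_c and forbids Ki_u",
               "inhibkin_config_error")
    }
  } else if (mechanism == "uncompetitive") {
    if (is.null(Ki_u) || !is.null(Ki_c)) {
      ik_abort("uncompetitive inhibition requires Ki_u and forbids Ki_c",
               "inhibkin_config_error")
    }
  } else if (mechanism == "noncompetitive") {
    if (is.null(Ki_c) && is.null(Ki_u)) {
      ik_abort("noncompetitive inhibition requires Ki_c = Ki_u (supply one)",
               "inhibkin_config_error")
    }
    if (!is.null(Ki_c) && !is.null(Ki_u) && Ki_c != Ki_u) {
      ik_abort("noncompetitive inhibition requires Ki_c = Ki_u",
               "inhibkin_config_error")
    }
    Ki_c <- Ki_u <- Ki_c %||% Ki_u
  } else { # mixed
    if (is.null(Ki_c) || is.null(Ki_u)) {
      ik_abort("mixed inhibition requires both Ki_c and Ki_u",
               "inhibkin_config_error")
    }
    if (Ki_c == Ki_u) {
      ik_abort("mixed inhibition requires Ki_c != Ki_u (equal constants are noncompetitive)",
               "inhibkin_config_error")
    }
  }

  structure(
    list(mechanism = mechanism, Km = Km, Vmax = Vmax,
         Ki_c = Ki_c, Ki_u = Ki_u, noise_cv = noise_cv,
         seed = as.integer(seed)),
    class = "inhibition_truth"
  )
}

#' @export
print.inhibition_truth <- function(x, ...) {
  cat(sprintf("<inhibition_truth> %s: Km = %g uM, Vmax = %g, Ki_c = %s, Ki_u = %s, cv = %g, seed = %d\n",
              x$mechanism, x$Km, x$Vmax,
              if (is.null(x$Ki_c)) "-" else format(x$Ki_c),
              if (is.null(x$Ki_u)) "-" else format(x$Ki_u),
              x$noise_cv, x$seed))
  invisible(x)
}

#' Ground truth for a simulated thioflavin-T self-aggregation assay
#'
#' The fibril signal above background follows a logistic inhibition law in
#' inhibitor concentration \eqn{I}:
#' \deqn{F(I) = \frac{F_{control} - F_{background}}{1 + (I/IC_{50})^h} + F_{background}.}
#' An endpoint scan at each concentration is this constant plus Gaussian
#' noise, plus one dye-only background scan.
#'
#' @param IC50 Concentration (µM) at which the background-subtracted plateau
#'   is half the control's; must be positive.
#' @param hill_slope Hill coefficient of the inhibition law (> 0, default 1).
#' @param F_control,F_background Plateau fluorescence (AFU) of the
#'   uninhibited aggregate and of the dye-only background;
#'   `F_control > F_background >= 0`.
#' @param scan_noise_cv Coefficient of variation of the additive scan noise
#'   (sd = `scan_noise_cv` times the scan's own plateau level).
#' @param seed Integer seed.
#'
#' @return An object of class `tht_truth`.
#' @seealso [simulate_tht_assay()]
#' @examples
#' tht_truth(IC50 = 100)
#' @export
tht_truth <- function(IC50, hill_slope = 1, F_control = 1100,
                      F_background = 100, scan_noise_cv = 0, seed = 1L) {
  check_number(IC50, "IC50", positive = TRUE)
  check_number(hill_slope, "hill_slope", positive = TRUE)
  check_number(F_control, "F_control")
  check_number(F_background, "F_background", nonneg = TRUE)
  check_number(scan_noise_cv, "scan_noise_cv", nonneg = TRUE)
  if (F_control <= F_background) {
    ik_abort("F_control must exceed F_background", "inhibkin_config_error")
  }
  structure(
    list(IC50 = IC50, hill_slope = hill_slope, F_control = F_control,
         F_background = F_background, scan_noise_cv = scan_noise_cv,
         seed = as.integer(seed)),
    class = "tht_truth"
  )
}

#' @export
print.tht_truth <- function(x, ...) {
  cat(sprintf("<tht_truth> IC50 = %g uM, hill = %g, F_control = %g, F_background = %g, cv = %g, seed = %d\n",
              x$IC50, x$hill_slope, x$F_control, x$F_background,
              x$scan_noise_cv, x$seed))
  invisible(x)
}

#' Write a truth sidecar next to a generated dataset
#'
#' Records the generative parameters and seed of a synthetic dataset as JSON
#' so that downstream recovery can be checked against ground truth.
#'
#' @param truth An [inhibition_truth()] or [tht_truth()] object.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  lst <- unclass(truth)
  lst$kind <- class(truth)[1]
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
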