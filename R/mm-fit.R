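# Michaelis-Menten parameter estimation: nonlinear least squares and the
# Lineweaver-Burk double-reciprocal linearization. Replicates enter as
# individual points (unweighted least squares on all determinations).

# Canonicalise a velocity table: S_uM/I_uM/v0 (S/I/v accepted), single I.
as_velocity_points <- function(points) {
  if (!is.data.frame(points)) {
    ik_abort("points must be a data.frame", "inhibkin_input_error")
  }
  nm <- names(points)
  scol <- intersect(c("S_uM", "S"), nm)[1]
  vcol <- intersect(c("v0", "v"), nm)[1]
  icol <- intersect(c("I_uM", "I"), nm)[1]
  if (is.na(scol) || is.na(vcol)) {
    ik_abort("points needs S_uM and v0 columns", "inhibkin_input_error")
  }
  d <- data.frame(S_uM = as.numeric(points[[scol]]),
                  v0 = as.numeric(points[[vcol]]),
                  I_uM = if (is.na(icol)) 0 else as.numeric(points[[icol]]))
  if (length(unique(d$I_uM)) > 1) {
    ik_abort("points must come from a single inhibitor concentration",
             "inhibkin_input_error")
  }
  d <- d[d$S_uM > 0, , drop = FALSE]
  if (length(unique(d$S_uM)) < 3) {
    ik_abort("need >= 3 distinct substrate concentrations > 0",
             "inhibkin_input_error")
  }
  if (any(d$v0 < 0)) {
    warning("negative rates present in velocity table", call. = FALSE)
  }
  d
}

mm_params <- function(Km, Vmax, se_Km, se_Vmax, r2, method, n, I) {
  structure(
    list(Km = Km, Vmax = Vmax, se_Km = se_Km, se_Vmax = se_Vmax,
         r2_or_gof = r2, method = method, n_points = n, I_uM = I),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit %s> Km = %.6g +/- %.3g uM, Vmax = %.6g +/- %.3g, gof = %.4f (n = %d, I = %g uM)\n",
              x$method, x$Km, x$se_Km, x$Vmax, x$se_Vmax, x$r2_or_gof,
              x$n_points, x$I_uM))
  invisible(x)
}

#' Fit the Michaelis-Menten equation by nonlinear least squares
#'
#' Unweighted Levenberg-Marquardt least squares of
#' \eqn{v = V_{max} S / (K_m + S)} on a single-inhibitor-concentration
#' velocity table. Initialization is parameter-free: `Vmax` starts at 1.2
#' times the largest observed rate and `Km` at the substrate concentration
#' whose rate is closest to half that; iteration stops at a relative step
#' below 1e-10 or 500 iterations. Standard errors come from the local
#' curvature of the objective at the solution.
#'
#' @param points data.frame with columns `S_uM` and `v0` (and optionally a
#'   constant `I_uM`); rows with `S_uM = 0` are excluded; at least three
#'   distinct substrate concentrations are required. Replicates are fitted
#'   as individual points.
#'
#' @return An object of class `mm_fit` with `Km`, `Vmax`, `se_Km`,
#'   `se_Vmax`, `r2_or_gof` (1 - SSres/SStot), `method = "nonlinear"`,
#'   `n_points`, `I_uM`.
#' @section Errors: non-convergence or estimates pinned at the positivity
#'   boundary (e.g. saturated panels where all rates coincide drive Km to 0)
#'   raise an error of class `inhibkin_fit_failure` carrying the last
#'   iterate in its `last_iterate` field and a `diagnostic` message.
#' @examples
#' tr <- inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_c = 10)
#' pts <- simulate_velocity_panel(tr, I_grid = 0)
#' fit_mm_nonlinear(pts)
#' @export
fit_mm_nonlinear <- function(points) {
  d <- as_velocity_points(points)
  vmax0 <- 1.2 * max(d$v0)
  km0 <- d$S_uM[which.min(abs(d$v0 - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v0 ~ Vmax * S_uM / (Km + S_uM), data = d,
      start = list(Vmax = vmax0, Km = km0),
      lower = c(Vmax = 0, Km = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-12,
                                           ftol = 1e-14)
    ),
    error = function(e) {
      ik_abort(paste0("nonlinear fit failed: ", conditionMessage(e)),
               "inhibkin_fit_failure",
               last_iterate = c(Vmax = vmax0, Km = km0),
               diagnostic = conditionMessage(e))
    }
  )
  co <- stats::coef(fit)
  if (co[["Km"]] <= 1e-8 * max(d$S_uM) || co[["Vmax"]] <= 0) {
    ik_abort("fit pinned at the positivity boundary (Km -> 0 or Vmax -> 0)",
             "inhibkin_fit_failure", last_iterate = co,
             diagnostic = "boundary-pinned")
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  ss_tot <- sum((d$v0 - mean(d$v0))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  mm_params(co[["Km"]], co[["Vmax"]], se[["Km"]], se[["Vmax"]],
            r2, "nonlinear", nrow(d), d$I_uM[1])
}

#' Fit the Michaelis-Menten parameters by Lineweaver-Burk linearization
#'
#' Ordinary least squares of `1/v0` on `1/S`; the fitted intercept and slope
#' give `Vmax = 1/intercept` and `Km = slope/intercept`. The r-squared of
#' the reciprocal fit is reported; standard errors are propagated from the
#' linear coefficients by the delta method.
#'
#' @inheritParams fit_mm_nonlinear
#' @return An object of class `mm_fit` with `method = "lineweaver_burk"`.
#' @section Errors: any `v0 <= 0` makes the reciprocal transform undefined
#'   and raises an error of class `inhibkin_transform_error` listing the
#'   offending rows; a non-positive intercept or slope (negative apparent
#'   Vmax or Km) raises `inhibkin_nonphysical_fit`.
#' @examples
#' pts <- data.frame(S_uM = c(80, 125, 200, 330, 500),
#'                   v0 = 10 * c(80, 125, 200, 330, 500) /
#'                        (100 + c(80, 125, 200, 330, 500)))
#' fit_mm_lineweaver_burk(pts)
#' @export
fit_mm_lineweaver_burk <- function(points) {
  d <- as_velocity_points(points)
  bad <- which(d$v0 <= 0)
  if (length(bad)) {
    ik_abort(sprintf("reciprocal transform undefined for non-positive rates (rows %s)",
                     paste(bad, collapse = ", ")),
             "inhibkin_transform_error", rows = bad)
  }
  fit <- stats::lm(I(1 / v0) ~ I(1 / S_uM), data = d)
  b <- stats::coef(fit)
  b0 <- b[[1]]; b1 <- b[[2]]
  if (b0 <= 0 || b1 <= 0) {
    ik_abort("Lineweaver-Burk fit non-physical (intercept or slope <= 0)",
             "inhibkin_nonphysical_fit", intercept = b0, slope = b1)
  }
  # suppressWarnings: summary.lm warns on numerically perfect (noiseless) fits
  V <- suppressWarnings(stats::vcov(fit))
  se_vmax <- sqrt(V[1, 1]) / b0^2
  g <- c(-b1 / b0^2, 1 / b0) # gradient of Km = b1/b0 in (b0, b1)
  se_km <- sqrt(drop(t(g) %*% V %*% g))
  yr <- 1 / d$v0
  ss_tot <- sum((yr - mean(yr))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(stats::resid(fit)^2) / ss_tot)) else 1
  mm_params(b1 / b0, 1 / b0, se_km, se_vmax, r2, "lineweaver_burk",
            nrow(d), d$I_uM[1])
}
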