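# IC50 estimation from semilogarithmic linear fits of residual activity
# (enzyme assays) or residual self-aggregation (ThT assays).

#' Residual enzymatic activity relative to the uninhibited control
#'
#' @param v_inhibited Rate in the presence of inhibitor.
#' @param v_control Uninhibited rate, > 0.
#' @return Residual activity in percent (`100 * v_inhibited / v_control`);
#'   values above 100 are permitted but flagged via the `"flagged"`
#'   attribute.
#' @examples
#' residual_activity(5, 10) # 50
#' @export
residual_activity <- function(v_inhibited, v_control) {
  if (!is.numeric(v_control) || any(v_control <= 0)) {
    ik_abort("v_control must be > 0", "inhibkin_normalization_error")
  }
  val <- 100 * v_inhibited / v_control
  attr(val, "flagged") <- any(val > 100)
  val
}

#' Estimate IC50 from a semilogarithmic linear fit
#'
#' Fits a straight line to dose-response points in one of two
#' semilogarithmic dialects and interpolates the concentration at 50%
#' residual:
#'
#' * `"residual_vs_log_conc"` — OLS of residual (%) on `log10(I)`;
#'   `IC50 = 10^((50 - intercept)/slope)`. The conventional semilog
#'   dose-response plot; default for enzyme assays.
#' * `"log_residual_vs_conc"` — OLS of `log10(residual %)` on `I`;
#'   `IC50 = (log10(50) - intercept)/slope`. The transform used for the
#'   ThT self-aggregation readout.
#'
#' Rows with `I = 0` (the normalization control) are excluded from the fit;
#' rows with non-positive residual are excluded (with a warning) where the
#' dialect takes a logarithm of the residual. A fitted IC50 outside the
#' tested concentration range is reported but `censored` is set to
#' `"above_range"`/`"below_range"` and the `IC50` field carries the nearest
#' tested bound, with the raw interpolate in `IC50_extrapolated`.
#'
#' @param curve_points data.frame with columns `I_uM` (or `I`) and
#'   `residual` (percent of the uninhibited control); at least two distinct
#'   positive concentrations.
#' @param dialect Which axis is log-transformed; see above.
#'
#' @return An object of class `dose_response_curve`: `points`, `dialect`,
#'   `slope`, `intercept`, `r2`, `IC50`, `IC50_extrapolated`, `censored`
#'   (`"none"`, `"above_range"` or `"below_range"`), `no_inhibition`.
#'   A slope of the wrong sign (residual increasing with dose) yields a
#'   no-inhibition result — `IC50 = NA`, `no_inhibition = TRUE` — not an
#'   error.
#' @examples
#' pts <- data.frame(I_uM = c(10, 100, 1000), residual = c(80, 50, 20))
#' fit_ic50(pts, "residual_vs_log_conc")$IC50 # 100
#' @export
fit_ic50 <- function(curve_points,
                     dialect = c("residual_vs_log_conc",
                                 "log_residual_vs_conc")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(curve_points)) {
    ik_abort("curve_points must be a data.frame", "inhibkin_input_error")
  }
  icol <- intersect(c("I_uM", "I"), names(curve_points))[1]
  rcol <- intersect(c("residual", "residual_pct"), names(curve_points))[1]
  if (is.na(icol) || is.na(rcol)) {
    ik_abort("curve_points needs I_uM and residual columns",
             "inhibkin_input_error")
  }
  d <- data.frame(I = as.numeric(curve_points[[icol]]),
                  residual = as.numeric(curve_points[[rcol]]))
  if (any(d$residual < 0)) {
    ik_abort("residuals must be >= 0", "inhibkin_input_error")
  }
  d <- d[d$I > 0, , drop = FALSE]
  if (dialect == "log_residual_vs_conc" && any(d$residual <= 0)) {
    warning("excluding rows with residual <= 0 from the log-residual fit",
            call. = FALSE)
    d <- d[d$residual > 0, , drop = FALSE]
  }
  if (length(unique(d$I)) < 2) {
    ik_abort("need >= 2 distinct positive inhibitor concentrations",
             "inhibkin_input_error")
  }

  if (dialect == "log_residual_vs_conc") {
    x <- d$I; y <- log10(d$residual)
  } else {
    x <- log10(d$I); y <- d$residual
  }
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  intercept <- b[[1]]; slope <- b[[2]]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(stats::resid(fit)^2) / ss_tot)) else 1

  out <- list(points = d, dialect = dialect, slope = slope,
              intercept = intercept, r2 = r2, IC50 = NA_real_,
              IC50_extrapolated = NA_real_, censored = "none",
              no_inhibition = FALSE)
  if (slope >= 0) {
    out$no_inhibition <- TRUE
    return(structure(out, class = "dose_response_curve"))
  }
  raw <- if (dialect == "log_residual_vs_conc") {
    (log10(50) - intercept) / slope
  } else {
    10^((50 - intercept) / slope)
  }
  out$IC50_extrapolated <- raw
  if (raw > max(d$I)) {
    out$censored <- "above_range"
    out$IC50 <- max(d$I)
  } else if (raw < min(d$I)) {
    out$censored <- "below_range"
    out$IC50 <- min(d$I)
  } else {
    out$IC50 <- raw
  }
  structure(out, class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  if (x$no_inhibition) {
    cat(sprintf("<dose_response_curve %s> no inhibition (slope %.3g >= 0)\n",
                x$dialect, x$slope))
  } else {
    cen <- if (x$censored == "none") ""
           else sprintf(" [%s; interpolate %.4g uM]", x$censored,
                        x$IC50_extrapolated)
    cat(sprintf("<dose_response_curve %s> IC50 = %.4g uM%s, r2 = %.4f (n = %d)\n",
                x$dialect, x$IC50, cen, x$r2, nrow(x$points)))
  }
  invisible(x)
}
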