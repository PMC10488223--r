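# Inhibition-mechanism classification from paired uninhibited/inhibited
# Michaelis-Menten fits, and per-concentration apparent inhibition constants
# computed from the shifts in Km and Vmax.

# Change screen for one parameter. A parameter counts as *changed* only when
# the relative shift exceeds rel_tol AND the shift is significant at `alpha`
# under a two-sample z-test on the fitted values; requiring both avoids
# chasing fit noise (large but insignificant shifts) and flagging precisely
# measured but negligible shifts.
param_change <- function(p0, se0, pI, seI, rel_tol, alpha) {
  d <- pI - p0
  rel <- d / p0
  sse <- sqrt(sum(c(se0, seI)^2, na.rm = TRUE))
  z <- if (is.finite(sse) && sse > 0) d / sse else if (d == 0) 0 else Inf * sign(d)
  p <- 2 * stats::pnorm(-abs(z))
  changed <- abs(rel) > rel_tol && p < alpha
  list(direction = if (!changed) "unchanged" else if (d > 0) "up" else "down",
       rel_change = rel, z = z, p = p)
}

#' Classify the inhibition mechanism from paired fits
#'
#' Compares Michaelis-Menten fits without (`mm0`) and with (`mmI`)
#' inhibitor and maps the pattern of parameter shifts to a mechanism label:
#'
#' | Km        | Vmax      | Km/Vmax ratio  | label          |
#' |-----------|-----------|----------------|----------------|
#' | unchanged | down      | (any)          | noncompetitive |
#' | up        | unchanged | (any)          | competitive    |
#' | down      | down      | preserved      | uncompetitive  |
#' | changed   | down      | not preserved  | mixed          |
#' | anything else (e.g. Vmax up)           || undetermined  |
#'
#' A parameter is *changed* only when its relative shift exceeds `rel_tol`
#' and is significant at `alpha` given the fits' standard errors; the ratio
#' is *preserved* when `|K'm/V'max - Km/Vmax| / (Km/Vmax) <= rel_tol`.
#' Single-parameter patterns take precedence over the mixed pattern.
#'
#' @param mm0,mmI [fit_mm_nonlinear()] / [fit_mm_lineweaver_burk()] results
#'   for the uninhibited and inhibited panels; must share the same method.
#' @param rel_tol Relative-change tolerance for "unchanged" (default 0.10).
#' @param alpha Significance level of the z-screen (default 0.05).
#'
#' @return An object of class `mechanism_call`: `label`, `km_change`,
#'   `vmax_change`, `ratio_constant`, and an `evidence` data.frame of
#'   per-parameter test statistics. `"undetermined"` is a value, not an
#'   error.
#' @examples
#' mm0 <- fit_mm_nonlinear(data.frame(S_uM = c(80, 125, 200, 330, 500),
#'   v0 = 10 * c(80, 125, 200, 330, 500) / (100 + c(80, 125, 200, 330, 500))))
#' mmI <- fit_mm_nonlinear(data.frame(S_uM = c(80, 125, 200, 330, 500),
#'   v0 = 5 * c(80, 125, 200, 330, 500) / (100 + c(80, 125, 200, 330, 500))))
#' classify_mechanism(mm0, mmI)$label # noncompetitive
#' @export
classify_mechanism <- function(mm0, mmI, rel_tol = 0.10, alpha = 0.05) {
  stopifnot(inherits(mm0, "mm_fit"), inherits(mmI, "mm_fit"))
  if (mm0$method != mmI$method) {
    ik_abort("mm0 and mmI must come from the same fitting method",
             "inhibkin_input_error")
  }
  km <- param_change(mm0$Km, mm0$se_Km, mmI$Km, mmI$se_Km, rel_tol, alpha)
  vm <- param_change(mm0$Vmax, mm0$se_Vmax, mmI$Vmax, mmI$se_Vmax,
                     rel_tol, alpha)
  ratio0 <- mm0$Km / mm0$Vmax
  ratioI <- mmI$Km / mmI$Vmax
  ratio_constant <- abs(ratioI - ratio0) / ratio0 <= rel_tol

  kc <- km$direction; vc <- vm$direction
  label <-
    if (kc == "unchanged" && vc == "down") "noncompetitive"
    else if (kc == "up" && vc == "unchanged") "competitive"
    else if (kc == "down" && vc == "down" && ratio_constant) "uncompetitive"
    else if (kc != "unchanged" && vc == "down" && !ratio_constant) "mixed"
    else "undetermined"

  structure(
    list(label = label, km_change = kc, vmax_change = vc,
         ratio_constant = ratio_constant,
         evidence = data.frame(
           parameter = c("Km", "Vmax"),
           baseline = c(mm0$Km, mm0$Vmax),
           inhibited = c(mmI$Km, mmI$Vmax),
           rel_change = c(km$rel_change, vm$rel_change),
           z = c(km$z, vm$z), p = c(km$p, vm$p)
         )),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (Km %s, Vmax %s, ratio %s)\n",
              x$label, x$km_change, x$vmax_change,
              if (x$ratio_constant) "preserved" else "changed"))
  invisible(x)
}

#' Apparent inhibition constant at one inhibitor concentration
#'
#' Computes the apparent inhibition constant K'i from the shift between an
#' uninhibited and an inhibited Michaelis-Menten fit, selecting the relation
#' by mechanism:
#'
#' * noncompetitive — `K'i = V'max * I / (Vmax - V'max)` (relation 1);
#' * competitive — `K'i = K'm * I / (K'm - Km)` (relation 2, as used in the
#'   source protocol; see Details);
#' * uncompetitive — `K'i = K'm * I / (Km - K'm)` (relation 3);
#' * mixed — the arithmetic mean of relation 1 with relation 2 (when K'm
#'   rose) or relation 3 (when K'm fell).
#'
#' @details The competitive relation carries K'm — not Km — in its
#' numerator. For exact competitive data, where `K'm = Km (1 + I/Ki)`, it
#' therefore returns `Ki + I` rather than `Ki`; this systematic property is
#' retained because the relation is applied exactly as the assay protocol
#' states it. `equation_mode = "classical"` substitutes Km in the numerator
#' (`K'i = Km * I / (K'm - Km)`), which recovers Ki exactly for competitive
#' truth, and is provided for comparison only — it is never the default.
#' The noncompetitive and uncompetitive relations are exact for their
#' mechanisms: relation 1 inverts `V'max = Vmax/(1 + I/Ki)` and relation 3
#' inverts `K'm = Km/(1 + I/Ki)`.
#'
#' @param mm0,mmI Paired `mm_fit` objects (without / with inhibitor).
#' @param I Inhibitor concentration (µM), > 0.
#' @param call A [classify_mechanism()] result or one of the mechanism
#'   labels; `"undetermined"` is not accepted.
#' @param equation_mode `"as_printed"` (default) or `"classical"`; affects
#'   only the competitive relation, see Details.
#'
#' @return List with `Ki` (µM) and `equations_used` (integer subset of
#'   1:3).
#' @section Errors: a non-positive denominator (a parameter shift
#'   inconsistent with the label) raises `inhibkin_ki_inconsistent` naming
#'   the offending relation.
#' @export
apparent_ki <- function(mm0, mmI, I, call,
                        equation_mode = c("as_printed", "classical")) {
  equation_mode <- match.arg(equation_mode)
  check_number(I, "I", positive = TRUE)
  label <- if (inherits(call, "mechanism_call")) call$label else call
  label <- match.arg(label, c("competitive", "noncompetitive",
                              "uncompetitive", "mixed"))
  Km <- mm0$Km; Vmax <- mm0$Vmax; Kmp <- mmI$Km; Vmaxp <- mmI$Vmax

  eq1 <- function() {
    if (Vmax - Vmaxp <= 0) {
      ik_abort("relation 1 requires Vmax' < Vmax", "inhibkin_ki_inconsistent",
               equation = 1L)
    }
    Vmaxp * I / (Vmax - Vmaxp)
  }
  eq2 <- function() {
    if (Kmp - Km <= 0) {
      ik_abort("relation 2 requires Km' > Km", "inhibkin_ki_inconsistent",
               equation = 2L)
    }
    num <- if (equation_mode == "classical") Km else Kmp
    num * I / (Kmp - Km)
  }
  eq3 <- function() {
    if (Km - Kmp <= 0) {
      ik_abort("relation 3 requires Km' < Km", "inhibkin_ki_inconsistent",
               equation = 3L)
    }
    Kmp * I / (Km - Kmp)
  }

  switch(label,
    noncompetitive = list(Ki = eq1(), equations_used = 1L),
    competitive = list(Ki = eq2(), equations_used = 2L),
    uncompetitive = list(Ki = eq3(), equations_used = 3L),
    mixed = {
      if (Kmp > Km) {
        list(Ki = mean(c(eq1(), eq2())), equations_used = c(1L, 2L))
      } else if (Kmp < Km) {
        list(Ki = mean(c(eq1(), eq3())), equations_used = c(1L, 3L))
      } else {
        ik_abort("mixed label with Km' = Km is inconsistent",
                 "inhibkin_ki_inconsistent", equation = NA_integer_)
      }
    }
  )
}

#' Pool per-concentration apparent Ki values
#'
#' The apparent inhibition constants obtained at the individual inhibitor
#' concentrations are averaged (arithmetic mean, sample standard deviation)
#' into a single apparent Ki per compound.
#'
#' @param per_conc data.frame with columns `I_uM` (or `I`) and `Ki`; at
#'   least one row, all Ki finite and positive.
#' @return An object of class `ki_estimate`: `per_conc`, `Ki_mean`,
#'   `Ki_sd` (`NA` for a single entry), `n`.
#' @examples
#' pooled_ki(data.frame(I_uM = c(2.5, 5), Ki = c(8, 12)))
#' @export
pooled_ki <- function(per_conc) {
  if (!is.data.frame(per_conc) || nrow(per_conc) == 0) {
    ik_abort("per_conc must be a non-empty data.frame", "inhibkin_input_error")
  }
  icol <- intersect(c("I_uM", "I"), names(per_conc))[1]
  if (is.na(icol) || !"Ki" %in% names(per_conc)) {
    ik_abort("per_conc needs I_uM and Ki columns", "inhibkin_input_error")
  }
  ki <- per_conc$Ki
  if (any(!is.finite(ki)) || any(ki <= 0)) {
    ik_abort("all Ki must be finite and positive", "inhibkin_input_error")
  }
  structure(
    list(per_conc = data.frame(I_uM = per_conc[[icol]], Ki = ki),
         Ki_mean = mean(ki),
         Ki_sd = if (length(ki) > 1) stats::sd(ki) else NA_real_,
         n = length(ki)),
    class = "ki_estimate"
  )
}

#' @export
print.ki_estimate <- function(x, ...) {
  cat(sprintf("<ki_estimate> Ki = %.6g +/- %s uM (n = %d)\n",
              x$Ki_mean,
              if (is.na(x$Ki_sd)) "NA" else sprintf("%.3g", x$Ki_sd), x$n))
  invisible(x)
}

# Consensus label across per-concentration calls: majority vote excluding
# "undetermined"; ties resolved in favour of the call at the highest
# inhibitor concentration (the most perturbed, hence most informative, dose).
consensus_label <- function(labels, I) {
  ok <- labels != "undetermined"
  if (!any(ok)) return("undetermined")
  labels <- labels[ok]; I <- I[ok]
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  by_I <- labels[order(-I)]
  by_I[by_I %in% top][1]
}

#' Full inhibition profile of one compound against one target
#'
#' Fits the uninhibited panel and each inhibited panel, classifies the
#' mechanism per inhibitor concentration against the uninhibited baseline,
#' forms a consensus label (majority vote across concentrations, ties going
#' to the highest concentration), and computes the per-concentration
#' apparent Ki under that consensus, pooled via [pooled_ki()].
#'
#' @param points Velocity table with columns `S_uM`, `I_uM`, `v0` covering
#'   `I = 0` plus at least one positive inhibitor concentration.
#' @param method `"nonlinear"` (default) or `"lineweaver_burk"`.
#' @param rel_tol,alpha Passed to [classify_mechanism()].
#' @param equation_mode Passed to [apparent_ki()].
#'
#' @return An object of class `inhibition_profile`: `label`, `calls` (one
#'   [classify_mechanism()] result per concentration), `ki` (a
#'   [pooled_ki()] result, or `NULL` when no concentration yields a valid
#'   Ki), `fits` (baseline plus per-concentration `mm_fit`s).
#' @examples
#' tr <- inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_c = 12)
#' prof <- profile_inhibition(simulate_velocity_panel(tr))
#' prof$label
#' prof$ki$Ki_mean
#' @export
profile_inhibition <- function(points, method = c("nonlinear", "lineweaver_burk"),
                               rel_tol = 0.10, alpha = 0.05,
                               equation_mode = c("as_printed", "classical")) {
  method <- match.arg(method)
  equation_mode <- match.arg(equation_mode)
  fit_fun <- switch(method, nonlinear = fit_mm_nonlinear,
                    lineweaver_burk = fit_mm_lineweaver_burk)
  icol <- intersect(c("I_uM", "I"), names(points))[1]
  if (is.na(icol)) {
    ik_abort("points needs an I_uM column", "inhibkin_input_error")
  }
  I_levels <- sort(unique(points[[icol]]))
  if (!0 %in% I_levels || length(I_levels) < 2) {
    ik_abort("points must cover I = 0 and at least one positive concentration",
             "inhibkin_input_error")
  }
  mm0 <- fit_fun(points[points[[icol]] == 0, , drop = FALSE])
  I_pos <- I_levels[I_levels > 0]
  fits <- list(`0` = mm0)
  calls <- list()
  for (I in I_pos) {
    mmI <- fit_fun(points[points[[icol]] == I, , drop = FALSE])
    fits[[as.character(I)]] <- mmI
    calls[[as.character(I)]] <- classify_mechanism(mm0, mmI, rel_tol, alpha)
  }
  labels <- vapply(calls, `[[`, "", "label")
  label <- consensus_label(labels, I_pos)

  ki <- NULL
  if (label != "undetermined") {
    rows <- lapply(I_pos, function(I) {
      est <- tryCatch(
        apparent_ki(mm0, fits[[as.character(I)]], I, label,
                    equation_mode = equation_mode),
        inhibkin_ki_inconsistent = function(e) NULL
      )
      if (is.null(est) || est$Ki <= 0) return(NULL)
      data.frame(I_uM = I, Ki = est$Ki,
                 equations_used = paste(est$equations_used, collapse = "+"))
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows) > 0) ki <- pooled_ki(rows)
  }

  structure(list(label = label, calls = calls, ki = ki, fits = fits,
                 method = method, equation_mode = equation_mode),
            class = "inhibition_profile")
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat(sprintf("<inhibition_profile> %s (%s fits)\n", x$label, x$method))
  if (!is.null(x$ki)) print(x$ki)
  invisible(x)
}
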