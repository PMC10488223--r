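# CSV interchange schemas and input validation. All interchange is plain
# delimited text in three declared schemas:
#   trace:    assay_id, time_s, signal, substrate_uM, inhibitor_id,
#             inhibitor_uM, replicate
#   velocity: S_uM, I_uM, v0, replicate
#   tht_scan: scan_id, time_s, signal, inhibitor_uM, role, replicate

ik_schemas <- list(
  trace = c("assay_id", "time_s", "signal", "substrate_uM", "inhibitor_id",
            "inhibitor_uM", "replicate"),
  velocity = c("S_uM", "I_uM", "v0", "replicate"),
  tht_scan = c("scan_id", "time_s", "signal", "inhibitor_uM", "role",
               "replicate")
)

#' Read / write interchange CSV tables
#'
#' Thin wrappers around [utils::read.csv()]/[utils::write.csv()] for the
#' three declared schemas (`trace`, `velocity`, `tht_scan`); see
#' [validate_inputs()] for the column contracts.
#'
#' @param path CSV file path.
#' @param x Data.frame in the corresponding schema.
#' @return The data.frame (readers) or `path`, invisibly (writers).
#' @name interchange_io
NULL

#' @rdname interchange_io
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) {
    ik_abort(sprintf("file not found: %s", path), "inhibkin_io_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname interchange_io
#' @export
write_assay_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Validate an input table against a declared schema
#'
#' Checks a CSV file (or in-memory data.frame) against one of the package's
#' interchange schemas and returns a character vector of violations; an
#' empty vector means the input is valid. Checks: required columns present;
#' numeric columns numeric; concentrations non-negative; for trace/scan
#' schemas, time strictly increasing within each trace id and metadata
#' constant within each id (a reused id with conflicting metadata is
#' reported as a duplicated id).
#'
#' @param x Path to a CSV file, or a data.frame.
#' @param schema One of `"trace"`, `"velocity"`, `"tht_scan"`.
#' @return Character vector of violation messages (empty when valid).
#' @examples
#' validate_inputs(data.frame(S_uM = 100, I_uM = 0, v0 = 5, replicate = 1),
#'                 "velocity")
#' @export
validate_inputs <- function(x, schema = c("trace", "velocity", "tht_scan")) {
  schema <- match.arg(schema)
  df <- if (is.data.frame(x)) x else read_assay_csv(x)
  required <- ik_schemas[[schema]]
  violations <- character()

  missing <- setdiff(required, names(df))
  if (length(missing)) {
    violations <- c(violations,
                    sprintf("missing column '%s'", missing))
    return(violations)
  }
  if (nrow(df) == 0) return(violations)

  num_cols <- switch(schema,
    trace = c("time_s", "signal", "substrate_uM", "inhibitor_uM"),
    velocity = c("S_uM", "I_uM", "v0"),
    tht_scan = c("time_s", "signal", "inhibitor_uM"))
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      violations <- c(violations, sprintf("column '%s' is not numeric", col))
    }
  }
  if (length(violations)) return(violations)

  conc_cols <- switch(schema,
    trace = c("substrate_uM", "inhibitor_uM"),
    velocity = c("S_uM", "I_uM"),
    tht_scan = "inhibitor_uM")
  for (col in conc_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      violations <- c(violations,
                      sprintf("negative concentrations in column '%s'", col))
    }
  }

  if (schema %in% c("trace", "tht_scan")) {
    idcol <- if (schema == "trace") "assay_id" else "scan_id"
    metacols <- setdiff(required, c(idcol, "time_s", "signal"))
    for (id in unique(df[[idcol]])) {
      g <- df[df[[idcol]] == id, , drop = FALSE]
      if (any(diff(g$time_s) <= 0)) {
        violations <- c(violations,
                        sprintf("non-monotone time in %s '%s'", idcol, id))
      }
      n_meta <- vapply(metacols,
                       function(cl) length(unique(g[[cl]])), integer(1))
      if (any(n_meta > 1)) {
        violations <- c(violations,
                        sprintf("duplicated %s '%s' (conflicting metadata)",
                                idcol, id))
      }
    }
  }
  if (schema == "tht_scan") {
    bad_role <- setdiff(unique(df$role), c("sample", "control", "background"))
    if (length(bad_role)) {
      violations <- c(violations,
                      sprintf("unknown role '%s'", bad_role))
    }
  }
  violations
}

#' Reduce a table of kinetic traces to a velocity table
#'
#' Applies [extract_initial_rate()] to every trace (grouped by `assay_id`)
#' in a trace-schema table and returns the reduced velocity table.
#'
#' @param traces Data.frame in the trace schema.
#' @param min_points,r2_threshold,max_window Passed to
#'   [extract_initial_rate()].
#' @param fallback_min_window Accept the minimum window for traces whose
#'   initial portion never reaches `r2_threshold` (default `TRUE`, so a
#'   profiling run degrades gracefully on noisy wells).
#' @return Data.frame in the velocity schema (`S_uM`, `I_uM`, `v0`,
#'   `replicate`) plus `assay_id`, `r2_window`, `window_end`.
#' @export
reduce_traces <- function(traces, min_points = 5L, r2_threshold = 0.99,
                          max_window = NULL, fallback_min_window = TRUE) {
  ids <- unique(traces$assay_id)
  rows <- lapply(ids, function(id) {
    g <- traces[traces$assay_id == id, , drop = FALSE]
    g <- g[order(g$time_s), , drop = FALSE]
    ir <- extract_initial_rate(g, min_points = min_points,
                               r2_threshold = r2_threshold,
                               max_window = max_window,
                               fallback_min_window = fallback_min_window)
    data.frame(assay_id = id, S_uM = g$substrate_uM[1],
               I_uM = g$inhibitor_uM[1], v0 = ir$v0,
               replicate = g$replicate[1], r2_window = ir$r2,
               window_end = ir$window_end)
  })
  do.call(rbind, rows)
}

#' Reduce thioflavin-T scans to a residual self-aggregation table
#'
#' Averages the plateau of each scan with [plateau_mean()], averages
#' replicate plateaus per concentration, and converts to percent residual
#' self-aggregation with [percent_residual()] using the `control` and
#' `background` scans.
#'
#' @param scans Data.frame in the `tht_scan` schema; must contain at least
#'   one `control` and one `background` scan.
#' @param min_span,slope_alpha Passed to [plateau_mean()].
#' @param fallback_terminal_window A zero-slope test at level `slope_alpha`
#'   falsely rejects a genuinely flat noisy scan about `slope_alpha` of the
#'   time; when `TRUE` (default) such scans are averaged over the trailing
#'   `min_span` window instead of failing the whole reduction, and the scan
#'   is marked in the `plateaus` attribute.
#' @return Data.frame with columns `I_uM`, `residual` (one row per positive
#'   inhibitor concentration), with attribute `plateaus` holding the
#'   per-scan plateau table (`scan_id`, `inhibitor_uM`, `role`, `plateau`,
#'   `fallback`).
#' @export
reduce_tht_scans <- function(scans, min_span = 120, slope_alpha = 0.05,
                             fallback_terminal_window = TRUE) {
  need <- c("control", "background")
  for (r in need) {
    if (!any(scans$role == r)) {
      ik_abort(sprintf("tht scans must include a '%s' scan", r),
               "inhibkin_input_error")
    }
  }
  ids <- unique(scans$scan_id)
  plat <- do.call(rbind, lapply(ids, function(id) {
    g <- scans[scans$scan_id == id, , drop = FALSE]
    fallback <- FALSE
    pv <- tryCatch(
      plateau_mean(g, min_span = min_span, slope_alpha = slope_alpha),
      inhibkin_no_plateau = function(e) {
        if (!fallback_terminal_window) stop(e)
        fallback <<- TRUE
        tail_win <- g[g$time_s >= max(g$time_s) - min_span, , drop = FALSE]
        list(mean = mean(tail_win$signal))
      }
    )
    data.frame(scan_id = id, inhibitor_uM = g$inhibitor_uM[1],
               role = g$role[1], plateau = pv$mean, fallback = fallback)
  }))
  bg <- mean(plat$plateau[plat$role == "background"])
  ctrl <- mean(plat$plateau[plat$role == "control"])
  I_pos <- sort(unique(plat$inhibitor_uM[plat$role == "sample"]))
  res <- vapply(I_pos, function(I) {
    s <- mean(plat$plateau[plat$role == "sample" & plat$inhibitor_uM == I])
    as.numeric(percent_residual(s, ctrl, bg))
  }, numeric(1))
  out <- data.frame(I_uM = I_pos, residual = res)
  attr(out, "plateaus") <- plat
  out
}
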