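#' Construct a 2-D sway trajectory
#'
#' A trajectory is the common substrate for both video-derived
#' centre-of-mass (COM) paths, in pixel units, and force-plate
#' centre-of-pressure (COP) paths, in millimetres.  The x axis is
#' mediolateral (image column / plate x), the y axis anteroposterior
#' (image row / plate y).
#'
#' @param x,y Numeric vectors of equal length (>= 2), the sample
#'   coordinates along each axis.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param units `"pixel"` or `"mm"`.
#' @return An object of class `sway_trajectory` with fields `x`, `y`,
#'   `rate_hz` and `units`.
#' @export
trajectory <- function(x, y, rate_hz, units = c("pixel", "mm")) {
  units <- match.arg(units)
  if (!is.numeric(x) || !is.numeric(y)) stop_param("x/y", "must be numeric")
  if (length(x) != length(y)) stop_param("x/y", "must have equal length")
  if (length(x) < 2L) stop("trajectory needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_param("x/y", "all samples must be finite")
  }
  check_scalar_num(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 rate_hz = rate_hz, units = units),
            class = "sway_trajectory")
}

#' @export
print.sway_trajectory <- function(x, ...) {
  cat(sprintf("<sway_trajectory> %d samples @ %g Hz [%s], duration %.3f s\n",
              length(x$x), x$rate_hz, x$units,
              (length(x$x) - 1) / x$rate_hz))
  invisible(x)
}

#' @export
length.sway_trajectory <- function(x) length(x$x)

#' Per-step displacement series of a trajectory
#'
#' Computes the signed axis increments `dx[i] = x[i+1] - x[i]`,
#' `dy[i] = y[i+1] - y[i]` and the Euclidean step length
#' `dr[i] = sqrt(dx[i]^2 + dy[i]^2)`, the increments underlying all
#' path-length and velocity metrics.
#'
#' @param traj A [trajectory()].
#' @return A list of class `step_series` with `dx`, `dy`, `dr` and the
#'   sampling interval `dt` (seconds).
#' @export
step_displacements <- function(traj) {
  stopifnot(inherits(traj, "sway_trajectory"))
  if (length(traj$x) < 2L) stop("need at least 2 samples", call. = FALSE)
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  structure(list(dx = dx, dy = dy, dr = sqrt(dx^2 + dy^2),
                 dt = 1 / traj$rate_hz),
            class = "step_series")
}

#' Nine-parameter sway summary of a trajectory
#'
#' For each axis a in \{x, y, r\} the instantaneous speed series is
#' `v_a[i] = |d_a[i]| * rate_hz`; the parameters are
#' `vmean_a = mean(v_a)` (average oscillation velocity, units/s),
#' `vstd_a = sd(v_a)` (velocity variability, n-1 denominator) and
#' `ctotal_a = sum(|d_a|)` (total path length, units).  The radial axis
#' uses the Euclidean step length.  By construction
#' `vmean_a * duration_s == ctotal_a`.
#'
#' @param traj A [trajectory()].
#' @return An object of class `sway_parameters`: a named list with the
#'   nine parameters plus `units` and `duration_s`.
#' @export
compute_sway_parameters <- function(traj) {
  steps <- step_displacements(traj)
  rate <- traj$rate_hz
  duration <- length(steps$dx) / rate
  axis <- function(d) {
    v <- abs(d) * rate
    c(vmean = mean(v), vstd = sd(v), ctotal = sum(abs(d)))
  }
  ax <- axis(steps$dx); ay <- axis(steps$dy); ar <- axis(steps$dr)
  structure(list(
    vmean_x = ax[["vmean"]], vmean_y = ay[["vmean"]], vmean_r = ar[["vmean"]],
    vstd_x = ax[["vstd"]], vstd_y = ay[["vstd"]], vstd_r = ar[["vstd"]],
    ctotal_x = ax[["ctotal"]], ctotal_y = ay[["ctotal"]], ctotal_r = ar[["ctotal"]],
    units = traj$units, duration_s = duration
  ), class = "sway_parameters")
}

#' @export
print.sway_parameters <- function(x, ...) {
  cat(sprintf("<sway_parameters> [%s], duration %.3f s\n", x$units, x$duration_s))
  m <- matrix(unlist(x[c("vmean_x", "vmean_y", "vmean_r",
                         "vstd_x", "vstd_y", "vstd_r",
                         "ctotal_x", "ctotal_y", "ctotal_r")]),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Vmean", "Vstd", "Ctotal"), c("x", "y", "r")))
  print(signif(m, 5))
  invisible(x)
}

#' Convert a pixel trajectory to millimetres
#'
#' Multiplies both coordinates by a calibration factor `mm_per_pixel`
#' (e.g. the known width of a calibration object divided by its span in
#' pixels).  All nine sway parameters are homogeneous of degree 1 in the
#' coordinates, so they scale by the same factor.  Correlation-based
#' validity analyses are unaffected by the choice of factor.
#'
#' @param traj A [trajectory()] in pixel units.
#' @param mm_per_pixel Positive scale factor (mm per pixel).
#' @return A [trajectory()] in mm units.
#' @export
scale_trajectory <- function(traj, mm_per_pixel) {
  stopifnot(inherits(traj, "sway_trajectory"))
  if (traj$units != "pixel") {
    stop_param("traj", "must be in pixel units to convert to mm")
  }
  check_scalar_num(mm_per_pixel, "mm_per_pixel", lower = 0, strict_lower = TRUE)
  trajectory(traj$x * mm_per_pixel, traj$y * mm_per_pixel,
             traj$rate_hz, units = "mm")
}

# Canonical parameter column order for a given source ("COM" or "COP"),
# used both for CSV headers and as the deterministic tie-break order in
# predictor selection.
sway_columns <- function(source = c("COM", "COP")) {
  source <- match.arg(source)
  paste0(rep(c("Vmean_", "Vstd_", "Ctotal_"), each = 3),
         source, c("x", "y", "r"))
}

#' One-row parameter table for a trial
#'
#' Lays the nine parameters out as a one-row data frame using the
#' standard column names (`Vmean_COMx` ... `Ctotal_COPr`), prefixed by
#' any identifying key columns supplied in `keys`.
#'
#' @param params A [compute_sway_parameters()] result.
#' @param source `"COM"` for image-derived, `"COP"` for force-plate
#'   parameters; selects the column-name infix.
#' @param keys Named list of identifying columns (e.g. `subject_id`,
#'   `group`, `condition`) prepended to the row.
#' @return A one-row `data.frame`.
#' @export
sway_parameters_row <- function(params, source = c("COM", "COP"), keys = list()) {
  source <- match.arg(source)
  stopifnot(inherits(params, "sway_parameters"))
  vals <- unlist(params[c("vmean_x", "vmean_y", "vmean_r",
                          "vstd_x", "vstd_y", "vstd_r",
                          "ctotal_x", "ctotal_y", "ctotal_r")])
  row <- as.data.frame(as.list(vals))
  names(row) <- sway_columns(source)
  if (length(keys)) row <- cbind(as.data.frame(keys, stringsAsFactors = FALSE), row)
  row
}

#' Write / read a trial parameter table as CSV
#'
#' @param table A data frame of one row per trial (see
#'   [sway_parameters_row()]).
#' @param path Output CSV path.
#' @export
write_parameters_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameters_csv
#' @export
read_parameters_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a trajectory as CSV
#'
#' Columns: `frame_index` (0-based), `time_s`, and the two coordinates
#' named after the units (`x_px`/`y_px` or `x_mm`/`y_mm`).
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sway_trajectory"))
  n <- length(traj$x)
  suffix <- if (traj$units == "pixel") "px" else "mm"
  df <- data.frame(frame_index = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / traj$rate_hz)
  df[[paste0("x_", suffix)]] <- traj$x
  df[[paste0("y_", suffix)]] <- traj$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
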