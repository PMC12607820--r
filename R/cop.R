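#' Raw force-plate centre-of-pressure recording
#'
#' Two-channel COP time series in millimetres, mediolateral (x) and
#' anteroposterior (y), typically digitised at 100 Hz.
#'
#' @param x_mm,y_mm Numeric sample vectors in mm, equal length >= 2.
#' @param rate_hz Sampling rate in Hz (default 100).
#' @param subject_id,condition Optional trial metadata.
#' @return An object of class `cop_recording`.
#' @export
cop_recording <- function(x_mm, y_mm, rate_hz = 100,
                          subject_id = NA_character_,
                          condition = NA_character_) {
  if (length(x_mm) != length(y_mm)) stop_param("x_mm/y_mm", "must have equal length")
  if (length(x_mm) < 2L) stop("COP recording needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(x_mm)) || !all(is.finite(y_mm))) {
    stop_param("x_mm/y_mm", "all samples must be finite")
  }
  check_scalar_num(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  structure(list(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                 rate_hz = rate_hz, subject_id = subject_id,
                 condition = condition, filtered = FALSE, filter = NULL),
            class = "cop_recording")
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf("<cop_recording> %d samples @ %g Hz, %s\n",
              length(x$x_mm), x$rate_hz,
              if (isTRUE(x$filtered)) "filtered" else "unfiltered"))
  invisible(x)
}

#' Low-pass filter specification
#'
#' Defaults follow standard stabilometric conditioning: a fourth-order
#' Butterworth with 10 Hz cutoff.  In `zero_phase` mode the filter is
#' applied forward and backward, giving zero lag and the squared
#' magnitude response (so the gain at the cutoff is 0.5, not 1/sqrt(2));
#' `causal` mode applies it once.
#'
#' @param order Filter order (>= 1, default 4).
#' @param cutoff_hz -3 dB frequency in Hz (default 10); must lie below
#'   the Nyquist frequency of the series it is applied to.
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 10,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  check_scalar_num(order, "order", lower = 1)
  if (order != round(order)) stop_param("order", "must be an integer")
  check_scalar_num(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz, mode = mode),
            class = "sway_filter_spec")
}

# Single-channel Butterworth low-pass.  Edge handling: the series is
# extended by odd reflection about each endpoint (length 3*(order+1)
# samples) and the filter state is initialised at steady state for the
# first padded sample, so the startup transient is suppressed and
# results are bit-reproducible.  Zero-phase mode runs the forward pass,
# reverses, runs again and reverses back.
butter_lowpass_1d <- function(x, order, cutoff_hz, rate_hz, mode) {
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq) {
    stop_param("cutoff_hz", sprintf("must be below the Nyquist frequency (%g Hz)", nyq))
  }
  n <- length(x)
  pad <- 3L * (order + 1L)
  if (n <= max(pad, 3L * order + 1L)) {
    stop(sprintf("series too short to filter: need more than %d samples, got %d",
                 pad, n), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  one_pass <- function(v) {
    # steady-state start: past inputs and outputs pinned at v[1]
    # (exact for DC because the low-pass has unit DC gain)
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], order),
                              init.y = rep(v[1], order)))
  }
  xp <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- one_pass(xp)
  if (mode == "zero_phase") {
    y <- rev(one_pass(rev(y)))
  }
  y[(pad + 1L):(pad + n)]
}

#' Butterworth low-pass filtering of a COP recording
#'
#' Filters each axis independently.  Output length equals input length;
#' the returned recording is flagged as filtered and carries the filter
#' specification in its metadata.
#'
#' @param rec A [cop_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [cop_recording()].
#' @export
butterworth_lowpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "cop_recording"), inherits(spec, "sway_filter_spec"))
  out <- rec
  out$x_mm <- butter_lowpass_1d(rec$x_mm, spec$order, spec$cutoff_hz,
                                rec$rate_hz, spec$mode)
  out$y_mm <- butter_lowpass_1d(rec$y_mm, spec$order, spec$cutoff_hz,
                                rec$rate_hz, spec$mode)
  out$filtered <- TRUE
  out$filter <- spec
  out
}

#' Convert a COP recording to a trajectory
#'
#' Emits a mm-space [trajectory()] ready for
#' [compute_sway_parameters()].  An unfiltered recording is converted
#' with a warning, not an error, so the effect of skipping conditioning
#' can be examined deliberately.
#'
#' @param rec A [cop_recording()].
#' @export
cop_to_trajectory <- function(rec) {
  stopifnot(inherits(rec, "cop_recording"))
  if (!isTRUE(rec$filtered)) {
    warning("COP recording has not been low-pass filtered; ",
            "sway parameters will include raw high-frequency noise",
            call. = FALSE)
  }
  trajectory(rec$x_mm, rec$y_mm, rec$rate_hz, units = "mm")
}

#' Read a COP recording from CSV
#'
#' Expected columns: `time_s` (or `sample_index`) plus `cop_x_mm` and
#' `cop_y_mm`, with a header row.  The sampling rate is inferred from
#' the median time step unless `rate_hz` is supplied; if both are
#' available and disagree by more than 1%, a warning is issued and the
#' declared rate wins.
#'
#' @param path CSV file path.
#' @param rate_hz Optional declared sampling rate in Hz.
#' @param subject_id,condition Optional metadata attached to the
#'   recording.
#' @return A [cop_recording()].
#' @export
load_cop <- function(path, rate_hz = NULL,
                     subject_id = NA_character_, condition = NA_character_) {
  if (!file.exists(path)) stop(sprintf("COP file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cop_x_mm", "cop_y_mm")) {
    if (!col %in% names(df)) {
      stop(sprintf("COP file %s: missing required column `%s`", path, col),
           call. = FALSE)
    }
  }
  if (nrow(df) < 2L) {
    stop(sprintf("COP file %s: need at least 2 rows, got %d", path, nrow(df)),
         call. = FALSE)
  }
  for (col in c("time_s", "cop_x_mm", "cop_y_mm")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("COP file %s: non-numeric value in column `%s` at row %d",
                     path, col, bad[1]), call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop(sprintf("COP file %s: missing value in column `%s` at row %d",
                   path, col, which(is.na(v))[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  inferred <- if ("time_s" %in% names(df)) {
    dt <- median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) {
      stop(sprintf("COP file %s: time_s column is not strictly increasing", path),
           call. = FALSE)
    }
    1 / dt
  } else NULL
  if (is.null(rate_hz)) {
    if (is.null(inferred)) {
      stop(sprintf("COP file %s has no time_s column; pass rate_hz explicitly", path),
           call. = FALSE)
    }
    rate_hz <- inferred
  } else if (!is.null(inferred) && abs(inferred - rate_hz) / rate_hz > 0.01) {
    warning(sprintf("declared rate %g Hz differs from inferred %g Hz by > 1%%; using declared",
                    rate_hz, inferred), call. = FALSE)
  }
  cop_recording(df$cop_x_mm, df$cop_y_mm, rate_hz,
                subject_id = subject_id, condition = condition)
}

#' Write a COP recording as CSV
#'
#' Inverse of [load_cop()]: columns `time_s`, `cop_x_mm`, `cop_y_mm`.
#'
#' @param rec A [cop_recording()].
#' @param path Output CSV path.
#' @export
write_cop_csv <- function(rec, path) {
  stopifnot(inherits(rec, "cop_recording"))
  n <- length(rec$x_mm)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$rate_hz,
                   cop_x_mm = rec$x_mm, cop_y_mm = rec$y_mm)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
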