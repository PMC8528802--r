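#' Acquisition schedule for a transient-state sequence
#'
#' An acquisition schedule holds the per-repetition flip angles and the fixed
#' timing (TI/TR/TE) of an inversion-prepared, gradient-spoiled transient-state
#' sequence. The flip-angle train is what drives the magnetization through the
#' transient state and encodes T1 and T2 in the temporal signal shape.
#'
#' @param flip_angles numeric vector of flip angles in degrees, one per
#'   repetition; each must lie in (0, 180].
#' @param tr_ms repetition time in ms.
#' @param te_ms echo time in ms; must satisfy 0 < te_ms < tr_ms.
#' @param ti_ms inversion time in ms (delay between the inversion pulse and the
#'   first excitation); must be >= 0.
#' @param inversion_flip_deg inversion pulse angle in degrees (default 180,
#'   i.e. ideal inversion).
#'
#' @return an object of class `qti_schedule`.
#' @export
qti_schedule <- function(flip_angles, tr_ms, te_ms, ti_ms,
                         inversion_flip_deg = 180) {
  flip_angles <- as.numeric(flip_angles)
  if (length(flip_angles) < 1L)
    stop("schedule needs at least one flip angle")
  bad <- which(!is.finite(flip_angles) | flip_angles <= 0 | flip_angles > 180)
  if (length(bad))
    stop("flip angle out of (0, 180] at repetition ", bad[1L])
  stopifnot(is.finite(tr_ms), is.finite(te_ms), is.finite(ti_ms),
            tr_ms > 0, te_ms > 0, te_ms < tr_ms, ti_ms >= 0)
  structure(
    list(flip_angles = flip_angles,
         tr_ms = as.numeric(tr_ms),
         te_ms = as.numeric(te_ms),
         ti_ms = as.numeric(ti_ms),
         inversion_flip_deg = as.numeric(inversion_flip_deg)),
    class = "qti_schedule")
}

#' Default 880-repetition ramped flip-angle schedule
#'
#' The default transient-state schedule: 880 repetitions whose flip angles form
#' a symmetric piecewise-linear ramp from 0.8 degrees up to 70 degrees (over
#' repetitions 1-440) and back down to 0.8 degrees (repetitions 441-880), with
#' TI = 18 ms, TR = 7.8 ms and TE = 1.8 ms. The triangular ramp is the simplest
#' shape consistent with the stated bounds and repetition count; alternative
#' waveforms can be supplied via [load_schedule()].
#'
#' @return a `qti_schedule` of length 880.
#' @export
default_schedule <- function() {
  n <- 880L
  half <- n %/% 2L
  up <- seq(0.8, 70, length.out = half)
  qti_schedule(flip_angles = c(up, rev(up)),
               tr_ms = 7.8, te_ms = 1.8, ti_ms = 18)
}

#' Read an acquisition schedule from a flip-angle CSV
#'
#' The file holds one flip angle (degrees) per row; the sequence timing is
#' supplied by the caller (or by a run configuration). A header row named
#' `flip_deg` is permitted and skipped.
#'
#' @param path path to the CSV file.
#' @inheritParams qti_schedule
#' @return a `qti_schedule`.
#' @export
load_schedule <- function(path, tr_ms = 7.8, te_ms = 1.8, ti_ms = 18,
                          inversion_flip_deg = 180) {
  if (!file.exists(path)) stop("schedule file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1L]), "flip_deg"))
    lines <- lines[-1L]
  if (!length(lines)) stop("schedule file is empty: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-numeric flip angle in ", path, " at row ", bad[1L],
         ": '", lines[bad[1L]], "'")
  bad <- which(vals <= 0 | vals > 180)
  if (length(bad))
    stop("flip angle out of (0, 180] in ", path, " at row ", bad[1L],
         ": ", vals[bad[1L]])
  qti_schedule(vals, tr_ms = tr_ms, te_ms = te_ms, ti_ms = ti_ms,
               inversion_flip_deg = inversion_flip_deg)
}

#' Write a schedule's flip angles to CSV
#'
#' Writes one flip angle per row with a `flip_deg` header, with enough digits
#' that a write/read round trip preserves the angles to well below 1e-9
#' degrees.
#'
#' @param schedule a `qti_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "qti_schedule"))
  writeLines(c("flip_deg", format(schedule$flip_angles, digits = 17,
                                  scientific = FALSE, trim = TRUE)),
             con = path)
  invisible(path)
}

#' @export
print.qti_schedule <- function(x, ...) {
  cat(sprintf(paste0("Transient-state acquisition schedule: %d repetitions, ",
                     "flip %.3g-%.3g deg\n  TI = %g ms, TR = %g ms, TE = %g ms, ",
                     "inversion %g deg\n"),
              length(x$flip_angles), min(x$flip_angles), max(x$flip_angles),
              x$ti_ms, x$tr_ms, x$te_ms, x$inversion_flip_deg))
  invisible(x)
}
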