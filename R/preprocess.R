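#' Construct an FHR signal
#'
#' A single-channel FHR time series with its sampling rate and a
#' provenance tally of what preprocessing has done to it: how many long
#' gaps were excised, how many samples were linearly interpolated
#' (dropouts and out-of-range outliers), how many were rebuilt with a
#' cubic spline (spikes), and how many edge samples were trimmed.
#'
#' @param samples numeric bpm vector.
#' @param fs sampling rate in Hz.
#' @param provenance named counts; missing entries default to 0.
#' @return an object of class `fhr_signal`.
#' @export
fhr_signal <- function(samples, fs = 4,
                       provenance = c(gaps_removed = 0,
                                      samples_interpolated_linear = 0,
                                      samples_interpolated_spline = 0,
                                      edge_samples_trimmed = 0)) {
  prov <- c(gaps_removed = 0, samples_interpolated_linear = 0,
            samples_interpolated_spline = 0, edge_samples_trimmed = 0)
  prov[names(provenance)] <- provenance
  structure(list(samples = as.numeric(samples), fs = fs, provenance = prov),
            class = "fhr_signal")
}

#' @export
print.fhr_signal <- function(x, ...) {
  cat(sprintf("<fhr_signal> %d samples @ %g Hz; provenance: %s\n",
              length(x$samples), x$fs,
              paste(names(x$provenance), x$provenance, sep = "=", collapse = " ")))
  invisible(x)
}

as_fhr_signal <- function(x, fs = 4) {
  if (inherits(x, "fhr_signal")) x
  else if (inherits(x, "ctg_record")) fhr_signal(x$fhr, x$fs)
  else fhr_signal(x, fs)
}

#' Locate runs of missing (zero-valued) samples
#'
#' Sensor dropouts appear as runs of exactly-zero FHR values. Returns the
#' maximal runs, sorted by start index (1-based).
#'
#' @param signal an `fhr_signal` or numeric vector.
#' @return data.frame with columns `start`, `length`.
#' @export
find_missing_runs <- function(signal) {
  x <- as_fhr_signal(signal)$samples
  if (length(x) == 0L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Delete long dropout gaps
#'
#' Zero-runs lasting strictly more than `max_gap_seconds` are excised and
#' the remainder of the series concatenated, so downstream analysis sees a
#' contiguous signal. The rule is strict: a run of exactly
#' `max_gap_seconds` (60 samples at 4 Hz for the default 15 s) is kept for
#' interpolation. Nonzero samples are never altered by this step.
#'
#' @param signal an `fhr_signal` or numeric vector.
#' @param max_gap_seconds longest dropout that is still interpolated.
#' @return `fhr_signal` with `gaps_removed` provenance incremented.
#' @export
remove_long_gaps <- function(signal, max_gap_seconds = 15) {
  sig <- as_fhr_signal(signal)
  x <- sig$samples
  if (all(x == 0)) stop("empty-signal error: signal is entirely missing")
  runs <- find_missing_runs(sig)
  long <- runs[runs$length > max_gap_seconds * sig$fs, , drop = FALSE]
  if (nrow(long)) {
    drop_idx <- unlist(mapply(function(s, l) s:(s + l - 1L),
                              long$start, long$length, SIMPLIFY = FALSE))
    x <- x[-drop_idx]
  }
  sig$samples <- x
  sig$provenance["gaps_removed"] <- sig$provenance["gaps_removed"] + nrow(long)
  sig
}

#' Trim missing edges
#'
#' Leading and trailing zero-runs are removed entirely, whatever their
#' length, so the retained signal starts and ends at a stable measurement.
#'
#' @param signal an `fhr_signal` or numeric vector.
#' @return trimmed `fhr_signal`.
#' @export
trim_edges <- function(signal) {
  sig <- as_fhr_signal(signal)
  x <- sig$samples
  nz <- which(x != 0)
  if (length(nz) == 0L) stop("empty-signal error: signal is entirely missing")
  trimmed <- length(x) - (nz[length(nz)] - nz[1] + 1L)
  sig$samples <- x[nz[1]:nz[length(nz)]]
  sig$provenance["edge_samples_trimmed"] <-
    sig$provenance["edge_samples_trimmed"] + trimmed
  sig
}

#' Linear interpolation between two anchor points
#'
#' Evaluates the linear polynomial through `(x0, y0)` and `(x1, y1)` at
#' `x`: `y = (y0 (x1 - x) + y1 (x - x0)) / (x1 - x0)`.
#'
#' @param x0,y0 left anchor.
#' @param x1,y1 right anchor.
#' @param x query position, strictly between the anchors.
#' @return interpolated value.
#' @export
linear_interpolate <- function(x0, y0, x1, y1, x) {
  if (any(x1 == x0)) stop("degenerate-anchor error: x0 == x1")
  (y0 * (x1 - x) + y1 * (x - x0)) / (x1 - x0)
}

#' Interpolate outliers and short dropouts
#'
#' FHR values below 50 bpm or above 200 bpm are not physiologic; together
#' with the remaining short zero-runs they are replaced by linear
#' interpolation between the nearest valid neighbors on each side. Valid
#' means nonzero and inside `[low, high]` (the bounds themselves are
#' valid). Assumes long gaps and missing edges have already been removed,
#' so every invalid sample has a valid anchor on both sides.
#'
#' @param signal an `fhr_signal` or numeric vector.
#' @param low,high physiologic bpm range.
#' @return `fhr_signal` with `samples_interpolated_linear` incremented.
#' @export
interpolate_outliers <- function(signal, low = 50, high = 200) {
  sig <- as_fhr_signal(signal)
  x <- sig$samples
  bad <- x == 0 | x < low | x > high
  if (any(bad)) {
    valid <- which(!bad)
    if (length(valid) < 2L && any(bad)) {
      stop("internal error: not enough valid anchors for interpolation")
    }
    if (bad[1] || bad[length(x)]) {
      stop("internal error: invalid samples at the signal edge; trim_edges first")
    }
    for (i in which(bad)) {
      left <- max(valid[valid < i])
      right <- min(valid[valid > i])
      x[i] <- linear_interpolate(left, x[left], right, x[right], i)
    }
  }
  sig$samples <- x
  sig$provenance["samples_interpolated_linear"] <-
    sig$provenance["samples_interpolated_linear"] + sum(bad)
  sig
}

#' Remove non-physiologic spikes by cubic-spline repair
#'
#' A jump of more than `max_delta` bpm (default 25) from the previous
#' stable beat marks the start of an unstable run; the run ends at the
#' first later sample back within `max_delta` of the last stable value.
#' The run is replaced by a natural cubic spline fitted through up to
#' `anchors_per_side` stable samples on each side, and the scan repeats
#' until no violation remains (at most `max_passes` passes). A run that
#' reaches the signal end is replaced by a least-squares linear extension
#' of the left anchors.
#'
#' @param signal an `fhr_signal` or numeric vector.
#' @param max_delta largest physiologic beat-to-beat change, bpm.
#' @param anchors_per_side stable samples used on each side of a run.
#' @param max_passes re-scan bound before giving up.
#' @param low,high clamp range for repaired values.
#' @return `fhr_signal` with `samples_interpolated_spline` incremented.
#' @export
remove_spikes <- function(signal, max_delta = 25, anchors_per_side = 4,
                          max_passes = 10, low = 50, high = 200) {
  sig <- as_fhr_signal(signal)
  x <- sig$samples
  n <- length(x)
  replaced <- 0L
  for (pass in seq_len(max_passes + 1L)) {
    viol <- which(abs(diff(x)) > max_delta) + 1L
    if (length(viol) == 0L) break
    if (pass > max_passes) {
      stop("convergence error: spike removal did not settle in ",
           max_passes, " passes")
    }
    i <- viol[1]
    stable <- i - 1L
    after <- which(abs(x[seq.int(i, n)] - x[stable]) <= max_delta)
    j <- if (length(after)) i + after[1] - 1L else NA_integer_
    if (is.na(j)) {
      # run reaches the signal end: linear extension from the left anchors
      anchors <- seq.int(max(1L, stable - anchors_per_side + 1L), stable)
      if (length(anchors) >= 2L) {
        fit <- stats::lm.fit(cbind(1, anchors), x[anchors])
        new_vals <- fit$coefficients[1] + fit$coefficients[2] * seq.int(i, n)
      } else {
        new_vals <- rep(x[stable], n - i + 1L)
      }
      x[i:n] <- pmin(pmax(new_vals, low), high)
      replaced <- replaced + (n - i + 1L)
    } else {
      left <- seq.int(max(1L, stable - anchors_per_side + 1L), stable)
      right <- seq.int(j, min(n, j + anchors_per_side - 1L))
      knots_x <- c(left, right)
      fit <- stats::spline(knots_x, x[knots_x], xout = seq.int(i, j - 1L),
                           method = "natural")
      x[i:(j - 1L)] <- pmin(pmax(fit$y, low), high)
      replaced <- replaced + (j - i)
    }
  }
  sig$samples <- x
  sig$provenance["samples_interpolated_spline"] <-
    sig$provenance["samples_interpolated_spline"] + replaced
  sig
}

#' Extract a labor-stage segment
#'
#' Stage 1 analysis uses the first 20 minutes of the cleaned signal (4800
#' samples at 4 Hz); stage 2 uses the last 15 minutes (3600 samples).
#' Signals shorter than the window are rejected, never padded.
#'
#' @param signal a cleaned `fhr_signal`.
#' @param stage `"stage1"` or `"stage2"`.
#' @param record_id identifier stored in the segment origin.
#' @return an object of class `fhr_segment` with fields `samples`, `fs`,
#'   `stage`, `origin = (record_id, start_index)`.
#' @export
segment_fhr <- function(signal, stage = c("stage1", "stage2"),
                        record_id = NA_character_) {
  stage <- match.arg(stage)
  sig <- as_fhr_signal(signal)
  n <- length(sig$samples)
  win <- segment_window(stage, sig$fs)
  if (n < win) {
    stop(sprintf("record rejected: %d samples < %s window of %d", n, stage, win))
  }
  start <- if (stage == "stage1") 1L else n - win + 1L
  new_segment(sig$samples[start:(start + win - 1L)], sig$fs, stage,
              record_id, start)
}

segment_window <- function(stage, fs) {
  minutes <- if (stage == "stage1") 20 else 15
  as.integer(round(minutes * 60 * fs))
}

new_segment <- function(samples, fs, stage, record_id, start_index) {
  structure(list(samples = as.numeric(samples), fs = fs, stage = stage,
                 origin = list(record_id = record_id,
                               start_index = as.integer(start_index))),
            class = "fhr_segment")
}

#' @export
print.fhr_segment <- function(x, ...) {
  cat(sprintf("<fhr_segment %s> %d samples @ %g Hz from %s@%d\n",
              x$stage, length(x$samples), x$fs,
              x$origin$record_id, x$origin$start_index))
  invisible(x)
}

#' Clean an FHR signal
#'
#' Runs the artifact-removal chain in its defined order: delete long
#' dropout gaps, trim missing edges, linearly interpolate outliers and
#' short dropouts, then repair >25 bpm spikes with cubic splines. The
#' output contains no zeros, lies within `[low, high]` bpm and has no
#' adjacent change above `max_delta` bpm; provenance counts record every
#' correction. The stage order matters and outputs are defined only for
#' this order.
#'
#' @param record a [ctg_record()], `fhr_signal`, or numeric vector.
#' @param max_gap_seconds,low,high,max_delta rule thresholds.
#' @return cleaned `fhr_signal`.
#' @export
preprocess_signal <- function(record, max_gap_seconds = 15, low = 50,
                              high = 200, max_delta = 25) {
  sig <- as_fhr_signal(record)
  sig <- remove_long_gaps(sig, max_gap_seconds)
  sig <- trim_edges(sig)
  sig <- interpolate_outliers(sig, low, high)
  remove_spikes(sig, max_delta, low = low, high = high)
}

#' Full preprocessing pipeline: record to labor-stage segment
#'
#' Extracts the FHR channel, cleans it with [preprocess_signal()] and cuts
#' the requested labor-stage window.
#'
#' @param record a [ctg_record()].
#' @param stage `"stage1"` or `"stage2"`.
#' @inheritParams preprocess_signal
#' @return an `fhr_segment`; the cleaned signal (with provenance) is
#'   attached as attribute `"signal"`.
#' @export
preprocess_pipeline <- function(record, stage = c("stage1", "stage2"),
                                max_gap_seconds = 15, low = 50, high = 200,
                                max_delta = 25) {
  stage <- match.arg(stage)
  rid <- if (inherits(record, "ctg_record")) record$record_id else NA_character_
  sig <- preprocess_signal(record, max_gap_seconds, low, high, max_delta)
  seg <- segment_fhr(sig, stage, record_id = rid)
  attr(seg, "signal") <- sig
  seg
}
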