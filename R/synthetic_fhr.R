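#' Synthetic FHR simulation configuration
#'
#' Parameters of the synthetic 4 Hz FHR generator used to exercise the
#' pipeline without clinical data. A normal trace is a ~140 bpm baseline
#' with band-limited short-term variability, occasional accelerations and
#' mild decelerations; the distressed signature lowers the baseline,
#' damps variability and adds deeper, more frequent decelerations — the
#' qualitative CTG correlates of fetal compromise. On top of the clean
#' physiology, sensor defects are injected at controlled rates: zero-run
#' dropouts (a 70/30 mixture of runs at most 15 s and longer ones, so both
#' the interpolation and the deletion path are exercised), non-physiologic
#' outliers outside 50-200 bpm, and isolated >25 bpm spikes.
#'
#' @param duration_s recording length in seconds (default 2100 = 35 min,
#'   enough for the stage-1 window plus two backward slices with headroom
#'   for long-gap deletion).
#' @param fs sampling rate, Hz.
#' @param baseline_bpm normal-class baseline level.
#' @param variability_bpm short-term variability amplitude (bpm, sd ~ half).
#' @param accel_per_10min,decel_per_10min expected event counts.
#' @param accel_height_bpm,decel_depth_bpm event magnitudes.
#' @param dropout_per_10min,outlier_per_10min,spike_per_10min expected
#'   defect counts per 10 minutes.
#' @param class_separation dimensionless knob scaling the normal vs
#'   distressed parameter gap; 0 makes the classes indistinguishable.
#' @param seed RNG seed.
#' @return an object of class `fhr_sim_config`.
#' @export
fhr_sim_config <- function(duration_s = 2100, fs = 4, baseline_bpm = 140,
                           variability_bpm = 8, accel_per_10min = 1.5,
                           decel_per_10min = 0.5, accel_height_bpm = 15,
                           decel_depth_bpm = 25, dropout_per_10min = 1,
                           outlier_per_10min = 1, spike_per_10min = 1,
                           class_separation = 1, seed = 1) {
  stopifnot(duration_s > 0, fs > 0, abs(duration_s * fs - round(duration_s * fs)) < 1e-9,
            variability_bpm >= 0, dropout_per_10min >= 0,
            outlier_per_10min >= 0, spike_per_10min >= 0)
  structure(as.list(environment()), class = "fhr_sim_config")
}

# parameter set actually drawn from, given the class label
class_params <- function(config, label) {
  s <- if (identical(as.character(label), "distressed")) config$class_separation else 0
  list(baseline = config$baseline_bpm - 20 * s,
       variability = config$variability_bpm * max(0.3, 1 - 0.45 * s),
       accel_rate = config$accel_per_10min * max(0, 1 - 0.5 * s),
       decel_rate = config$decel_per_10min + 1.5 * s,
       accel_height = config$accel_height_bpm,
       decel_depth = config$decel_depth_bpm + 10 * s)
}

# band-limited noise: white noise smoothed with a Gaussian kernel (sd in
# samples), circular convolution, rescaled to the requested sd
smooth_noise <- function(n, sd_samples, target_sd) {
  if (target_sd <= 0) return(numeric(n))
  half <- ceiling(3 * sd_samples)
  kern <- exp(-0.5 * ((-half):half / sd_samples)^2)
  kern <- kern / sum(kern)
  z <- stats::filter(rnorm(n), kern, sides = 2, circular = TRUE)
  z <- as.numeric(z)
  z / stats::sd(z) * target_sd
}

gauss_bump <- function(n, center, sd_samples, height) {
  t <- seq_len(n)
  height * exp(-0.5 * ((t - center) / sd_samples)^2)
}

#' Simulate one labeled CTG record with a defect ledger
#'
#' Generates the clean physiology for the class, injects defects at
#' well-separated positions (at least 40 samples apart and 200 samples
#' from either edge, so every defect is attributable), and returns both
#' the record and a ledger listing every injected defect. The ledger lets
#' tests assert that preprocessing finds and repairs exactly what was
#' injected. The synthesized pH is consistent with the label (<= 7.15 iff
#' distressed).
#'
#' @param config an [fhr_sim_config()].
#' @param label `"normal"` or `"distressed"`.
#' @param record_id identifier for the record.
#' @return list with `record` (a [ctg_record()]) and `ledger` (data.frame
#'   of `type` in {short_gap, long_gap, outlier, spike}, `start`,
#'   `length`).
#' @export
simulate_fhr_record <- function(config, label = c("normal", "distressed"),
                                record_id = NULL) {
  label <- match.arg(label)
  set.seed(config$seed)
  n <- as.integer(round(config$duration_s * config$fs))
  p <- class_params(config, label)

  # clean physiology: baseline + slow wander + variability + events
  x <- rep(p$baseline, n) +
    3 * sin(2 * pi * seq_len(n) / (600 * config$fs) + runif(1, 0, 2 * pi)) +
    smooth_noise(n, sd_samples = 1.5 * config$fs, target_sd = p$variability / 2)
  ten_min <- config$duration_s / 600
  n_acc <- rpois(1, p$accel_rate * ten_min)
  n_dec <- rpois(1, p$decel_rate * ten_min)
  for (c_ in if (n_acc) round(runif(n_acc, 1, n)) else integer(0)) {
    x <- x + gauss_bump(n, c_, 30 * config$fs, p$accel_height)
  }
  for (c_ in if (n_dec) round(runif(n_dec, 1, n)) else integer(0)) {
    x <- x - gauss_bump(n, c_, 40 * config$fs, p$decel_depth)
  }
  x <- pmin(pmax(x, 55), 195)

  # defect injection at non-overlapping, edge-clear positions
  margin <- 40L
  edge <- 200L
  occupied <- rep(FALSE, n)
  occupied[seq_len(min(edge, n))] <- TRUE
  occupied[seq.int(max(1L, n - edge + 1L), n)] <- TRUE
  place <- function(len) {
    for (attempt in 1:200) {
      s <- sample.int(n - len + 1L, 1)
      span <- seq.int(max(1L, s - margin), min(n, s + len - 1L + margin))
      if (!any(occupied[span])) {
        occupied[span] <<- TRUE
        return(s)
      }
    }
    NA_integer_
  }
  ledger <- list()
  note <- function(type, start, length) {
    ledger[[length(ledger) + 1L]] <<- data.frame(type = type, start = start,
                                                 length = length)
  }
  for (k in seq_len(rpois(1, config$dropout_per_10min * ten_min))) {
    long <- runif(1) > 0.7
    len <- if (long) sample(61:140, 1) else sample(8:60, 1)
    s <- place(len)
    if (is.na(s)) next
    x[s:(s + len - 1L)] <- 0
    note(if (long) "long_gap" else "short_gap", s, len)
  }
  for (k in seq_len(rpois(1, config$outlier_per_10min * ten_min))) {
    s <- place(1L)
    if (is.na(s)) next
    x[s] <- if (runif(1) < 0.5) runif(1, 205, 240) else runif(1, 15, 45)
    note("outlier", s, 1L)
  }
  for (k in seq_len(rpois(1, config$spike_per_10min * ten_min))) {
    s <- place(1L)
    if (is.na(s)) next
    jump <- runif(1, 35, 55)
    x[s] <- x[s] + if (x[s] > 125) -jump else jump
    note("spike", s, 1L)
  }

  # uterine activity: periodic contraction bumps, plumbing only
  uc <- pmax(0, 15 + 35 * sin(2 * pi * seq_len(n) / (300 * config$fs))^8 +
               smooth_noise(n, 2 * config$fs, 2))
  ph <- if (label == "distressed") runif(1, 6.90, 7.15) else runif(1, 7.20, 7.40)
  rec <- ctg_record(record_id %||% sprintf("sim_%s_%d", label, config$seed),
                    fhr = x, uc = uc, fs = config$fs, ph = ph)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(type = character(0), start = integer(0), length = integer(0))
  list(record = rec, ledger = ledger)
}

#' Simulate a labeled cohort
#'
#' Draws `n_normal` + `n_distressed` records; each record gets its own
#' seed derived from the config seed, so the cohort is reproducible and
#' records are independent. With `class_separation = 0` the two classes
#' are draws from the same distribution.
#'
#' @param n_normal,n_distressed record counts (at least one total).
#' @param config an [fhr_sim_config()]; its seed anchors the cohort.
#' @return list with `records` (list of [ctg_record()]), `labels`
#'   (data.frame from [label_database()]), `ledgers` (per-record defect
#'   ledgers, named by record id).
#' @export
simulate_cohort <- function(n_normal, n_distressed, config = fhr_sim_config()) {
  stopifnot(n_normal >= 0, n_distressed >= 0)
  if (n_normal + n_distressed == 0L) stop("empty cohort requested")
  labels_in <- c(rep("normal", n_normal), rep("distressed", n_distressed))
  records <- vector("list", length(labels_in))
  ledgers <- vector("list", length(labels_in))
  for (i in seq_along(labels_in)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    rid <- sprintf("sim_%s_%03d", labels_in[i], i)
    sim <- simulate_fhr_record(cfg_i, labels_in[i], record_id = rid)
    records[[i]] <- sim$record
    ledgers[[i]] <- sim$ledger
  }
  names(ledgers) <- vapply(records, `[[`, "", "record_id")
  list(records = records, labels = label_database(records), ledgers = ledgers)
}
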