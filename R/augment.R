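#' Window-slicing plan for minority oversampling
#'
#' The distressed class is oversampled by re-slicing each recording:
#' besides the base labor-stage window, the same-length window is taken
#' shifted backward (toward earlier time) by five minutes, twice. The
#' window length follows the stage: 20 min (1200 s) for stage 1, 15 min
#' (900 s) for stage 2.
#'
#' @param stage `"stage1"` or `"stage2"`.
#' @param shift_seconds backward shift per extra slice (default 300).
#' @param n_slices number of extra slices (default 2).
#' @return an object of class `slice_plan`.
#' @export
slice_plan <- function(stage = c("stage1", "stage2"), shift_seconds = 300,
                       n_slices = 2) {
  stage <- match.arg(stage)
  stopifnot(n_slices >= 0, shift_seconds > 0)
  structure(list(stage = stage,
                 window_seconds = if (stage == "stage1") 1200 else 900,
                 shift_seconds = shift_seconds,
                 n_slices = as.integer(n_slices)),
            class = "slice_plan")
}

#' Slice-augment a preprocessed FHR signal
#'
#' Returns `1 + n_slices` same-length segments. Because the stage-1 base
#' window starts at time zero, backward shifts are anchored the other way
#' round: the base window is taken at offset `n_slices * shift` and the
#' extra slices step backward toward offset 0 (offsets 2400, 1200, 0
#' samples under the defaults at 4 Hz). For stage 2 the base is the final
#' window of the recording and each slice moves its start five minutes
#' earlier. If the signal is too short for some slices, the feasible ones
#' are returned with a warning; samples are never fabricated.
#'
#' @param signal a cleaned `fhr_signal` (or numeric vector at 4 Hz).
#' @param stage `"stage1"` or `"stage2"`.
#' @param plan a [slice_plan()]; defaults to the stage's standard plan.
#' @param record_id identifier stored in each segment's origin.
#' @return list of `fhr_segment`s, base window first.
#' @export
slice_augment <- function(signal, stage = c("stage1", "stage2"), plan = NULL,
                          record_id = NA_character_) {
  stage <- match.arg(stage)
  sig <- as_fhr_signal(signal)
  plan <- plan %||% slice_plan(stage)
  stopifnot(plan$stage == stage)
  n <- length(sig$samples)
  win <- as.integer(round(plan$window_seconds * sig$fs))
  shift <- as.integer(round(plan$shift_seconds * sig$fs))
  if (n < win) stop(sprintf("record rejected: %d samples < window of %d", n, win))
  starts <- if (stage == "stage1") {
    1L + plan$n_slices * shift - (0:plan$n_slices) * shift
  } else {
    (n - win + 1L) - (0:plan$n_slices) * shift
  }
  feasible <- starts >= 1L & (starts + win - 1L) <= n
  if (!all(feasible)) {
    warning(sprintf("signal too short for %d of %d slices; returning %d",
                    sum(!feasible), length(starts), sum(feasible)))
    starts <- starts[feasible]
  }
  if (stage == "stage1") {
    # base window (offset 0) first, extra slices in increasing offset
    starts <- sort(starts)
  }
  lapply(starts, function(s) {
    new_segment(sig$samples[s:(s + win - 1L)], sig$fs, stage, record_id, s)
  })
}

#' Dataset size under minority slicing
#'
#' Pure count arithmetic: each majority (normal) record contributes one
#' segment per stage, each minority (distressed) record `1 + n_slices`.
#'
#' @param n_normal,n_distressed record counts.
#' @param n_slices extra slices per distressed record (default 2).
#' @param n_stages how many labor-stage experiments are pooled (1 or 2).
#' @return named vector `c(total =, normal =, distressed =)`.
#' @export
augmented_counts <- function(n_normal, n_distressed, n_slices = 2,
                             n_stages = 1) {
  normal <- n_normal * n_stages
  distressed <- n_distressed * (1 + n_slices) * n_stages
  c(total = normal + distressed, normal = normal, distressed = distressed)
}

#' Build a labeled scalogram-ready dataset
#'
#' Preprocesses every record, slices the distressed class according to the
#' plan (normal records contribute their single base segment) and returns
#' the labeled segment collection with per-class counts. Records that fail
#' preprocessing or are too short for the window are skipped with a
#' warning.
#'
#' @param records list of [ctg_record()]s.
#' @param labels data.frame from [label_database()] (or with columns
#'   `record_id`, `label`).
#' @param stage `"stage1"` or `"stage2"`.
#' @param augment_minority oversample the distressed class?
#' @param plan a [slice_plan()] for the minority class.
#' @return an object of class `ctg_dataset`: list with `items` (each item
#'   has `item_id`, `record_id`, `stage`, `offset`, `label`, `segment`),
#'   `counts`, `stage`.
#' @export
build_dataset <- function(records, labels, stage = c("stage1", "stage2"),
                          augment_minority = TRUE, plan = NULL) {
  stage <- match.arg(stage)
  plan <- plan %||% slice_plan(stage)
  lab <- setNames(as.character(labels$label), labels$record_id)
  items <- list()
  skipped <- 0L
  for (rec in records) {
    cls <- lab[[rec$record_id]]
    if (is.null(cls)) next
    segs <- tryCatch({
      sig <- preprocess_signal(rec)
      if (cls == "distressed" && augment_minority) {
        slice_augment(sig, stage, plan, record_id = rec$record_id)
      } else {
        list(segment_fhr(sig, stage, record_id = rec$record_id))
      }
    }, error = function(e) NULL)
    if (is.null(segs)) { skipped <- skipped + 1L; next }
    for (seg in segs) {
      items[[length(items) + 1L]] <- list(
        item_id = sprintf("%s_%s_off%d", rec$record_id, stage,
                          seg$origin$start_index - 1L),
        record_id = rec$record_id, stage = stage,
        offset = seg$origin$start_index - 1L,
        label = cls, segment = seg)
    }
  }
  if (skipped > 0L) warning(skipped, " record(s) skipped during preprocessing")
  lbls <- vapply(items, `[[`, "", "label")
  counts <- c(normal = sum(lbls == "normal"),
              distressed = sum(lbls == "distressed"))
  if (any(counts == 0)) {
    stop("degenerate-dataset error: a class has zero members (normal=",
         counts["normal"], ", distressed=", counts["distressed"], ")")
  }
  structure(list(items = items, counts = counts, stage = stage),
            class = "ctg_dataset")
}

#' @export
print.ctg_dataset <- function(x, ...) {
  cat(sprintf("<ctg_dataset %s> %d items (%d normal, %d distressed)\n",
              x$stage, length(x$items), x$counts["normal"],
              x$counts["distressed"]))
  invisible(x)
}

#' Dataset manifest
#'
#' @param dataset a `ctg_dataset`.
#' @return data.frame of (item_id, record_id, stage, offset, label).
#' @export
dataset_manifest <- function(dataset) {
  do.call(rbind, lapply(dataset$items, function(it) {
    data.frame(item_id = it$item_id, record_id = it$record_id,
               stage = it$stage, offset = it$offset, label = it$label,
               stringsAsFactors = FALSE)
  }))
}

#' Write a dataset manifest TSV
#'
#' @param dataset a `ctg_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_tsv <- function(dataset, path) {
  mf <- dataset_manifest(dataset)
  lines <- c(paste(names(mf), collapse = "\t"),
             do.call(sprintf, c(list("%s\t%s\t%s\t%d\t%s"), mf)))
  writeLines(lines, path)
  invisible(path)
}
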