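#' Construct a CTG record
#'
#' A CTG record pairs a fetal-heart-rate (FHR) channel in beats per minute
#' with a uterine-contraction (UC) channel, both sampled at the same rate
#' (4 Hz for intrapartum monitors). An FHR value of exactly 0 encodes a
#' missing sample (sensor dropout); no NaN encoding is used in raw input.
#'
#' @param record_id character identifier.
#' @param fhr numeric vector of bpm values, all >= 0 (0 = missing).
#' @param uc numeric vector of uterine activity (arbitrary units), or NULL.
#' @param fs sampling rate in Hz (> 0).
#' @param ph umbilical-artery pH (> 0), or NA when unknown.
#' @return an object of class `ctg_record`.
#' @export
ctg_record <- function(record_id, fhr, uc = NULL, fs = 4, ph = NA_real_) {
  fhr <- as.numeric(fhr)
  if (anyNA(fhr)) stop("fhr must not contain NA; missing samples are encoded as 0")
  if (any(fhr < 0)) stop("fhr values must be >= 0")
  if (!is.null(uc)) {
    uc <- as.numeric(uc)
    if (length(uc) != length(fhr)) {
      stop("fhr and uc must have equal length when both present")
    }
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(
    list(record_id = as.character(record_id), fhr = fhr, uc = uc,
         fs = fs, ph = as.numeric(ph)),
    class = "ctg_record"
  )
}

#' @export
print.ctg_record <- function(x, ...) {
  cat(sprintf("<ctg_record %s> %d samples @ %g Hz (%.1f min), pH %s\n",
              x$record_id, length(x$fhr), x$fs,
              length(x$fhr) / x$fs / 60,
              ifelse(is.na(x$ph), "unknown", format(x$ph))))
  invisible(x)
}

#' Read a CTG recording
#'
#' Reads either the package CSV dialect (header line `fhr,uc`, one sample
#' per row, sampling rate in an optional `<path>.meta` sidecar, default
#' 4 Hz) or a PhysioNet WFDB record (text `.hea` header plus format-16
#' binary `.dat`), as used by the CTU-UHB intrapartum database. For WFDB
#' input the FHR and UC channels are located by their header description
#' and the pH is taken from a `#pH <value>` header comment.
#'
#' @param path file path; for WFDB either the `.hea` file or the record
#'   name without extension.
#' @param format `"csv"` or `"physionet"`.
#' @param fs sampling rate used for csv input when no sidecar is present.
#' @return a [ctg_record()].
#' @export
read_ctg_record <- function(path, format = c("csv", "physionet"), fs = 4) {
  format <- match.arg(format)
  if (format == "csv") read_ctg_csv(path, fs = fs) else read_wfdb_record(path)
}

read_ctg_csv <- function(path, fs = 4) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"fhr" %in% names(df)) stop("csv parse error: missing required column 'fhr'")
  meta_path <- paste0(path, ".meta")
  record_id <- sub("\\.csv$", "", basename(path))
  ph <- NA_real_
  if (file.exists(meta_path)) {
    meta <- read_kv_file(meta_path)
    fs <- as.numeric(meta[["fs"]] %||% fs)
    record_id <- meta[["record_id"]] %||% record_id
    if (!is.null(meta[["ph"]])) ph <- as.numeric(meta[["ph"]])
  }
  uc <- if ("uc" %in% names(df)) df$uc else NULL
  ctg_record(record_id, df$fhr, uc, fs = fs, ph = ph)
}

#' Write a CTG record in the package CSV dialect
#'
#' Values are printed with 17 significant digits so a read-back reproduces
#' the doubles bit-exactly. Sampling rate, record id and pH go to a
#' `<path>.meta` sidecar.
#'
#' @param record a [ctg_record()].
#' @param path output csv path.
#' @return `path`, invisibly.
#' @export
write_ctg_csv <- function(record, path) {
  stopifnot(inherits(record, "ctg_record"))
  uc <- record$uc %||% rep(0, length(record$fhr))
  lines <- c("fhr,uc",
             sprintf("%.17g,%.17g", record$fhr, uc))
  writeLines(lines, path)
  meta <- c(sprintf("record_id: %s", record$record_id),
            sprintf("fs: %.17g", record$fs))
  if (!is.na(record$ph)) meta <- c(meta, sprintf("ph: %.17g", record$ph))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

read_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = ":")))
  names(out) <- vapply(kv, function(p) trimws(p[1]), "")
  out
}

# Minimal WFDB reader: text header plus format-16 (16-bit little-endian,
# interleaved) signal file. Covers the layout CTU-UHB records use; other
# sample formats are rejected explicitly.
read_wfdb_record <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  comments <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("wfdb parse error: header has no signal lines")
  rec <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (length(rec) < 3L) stop("wfdb parse error: malformed record line")
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4]) else NA_integer_
  sig_lines <- body[-1][seq_len(n_sig)]
  sig <- lapply(sig_lines, parse_wfdb_signal_line)
  files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(files) != 1L) stop("wfdb parse error: multi-file records unsupported")
  dat_path <- file.path(dirname(hea_path), files)
  if (!file.exists(dat_path)) stop("file not found: ", dat_path)
  fmts <- vapply(sig, `[[`, "", "format")
  if (!all(fmts == "16")) {
    stop("wfdb parse error: unsupported sample format '",
         paste(unique(fmts[fmts != "16"]), collapse = ","), "' (only 16)")
  }
  raw_n <- file.size(dat_path) / 2L
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2L,
                  signed = TRUE, endian = "little")
  if (is.na(n_samp)) n_samp <- floor(length(vals) / n_sig)
  m <- matrix(vals[seq_len(n_sig * n_samp)], nrow = n_sig)  # interleaved
  desc <- toupper(vapply(sig, `[[`, "", "description"))
  fhr_i <- which(desc == "FHR")[1]
  if (is.na(fhr_i)) stop("structural error: no FHR channel in ", hea_path)
  uc_i <- which(desc == "UC")[1]
  phys <- function(i) (m[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  ph <- NA_real_
  ph_line <- grep("^\\s*#\\s*pH\\b", comments, ignore.case = TRUE, value = TRUE)
  if (length(ph_line)) {
    ph <- as.numeric(sub("^\\s*#\\s*pH\\s+", "", ph_line[1], ignore.case = TRUE))
  }
  ctg_record(sub("\\.hea$", "", basename(hea_path)),
             fhr = phys(fhr_i),
             uc = if (!is.na(uc_i)) phys(uc_i) else NULL,
             fs = fs, ph = ph)
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(tok) < 2L) stop("wfdb parse error: malformed signal line: ", line)
  fmt <- sub("x.*$", "", tok[2])           # strip samples-per-frame suffix
  gain_spec <- if (length(tok) >= 3L) tok[3] else "200"
  gain <- as.numeric(sub("^([-0-9.eE]+).*", "\\1", gain_spec))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- 0
  if (grepl("\\(", gain_spec)) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
  }
  # description = free text after the numeric fields (last token for CTU-UHB)
  desc <- tok[length(tok)]
  list(file = tok[1], format = fmt, gain = gain, baseline = baseline,
       description = desc)
}

#' Label a record from umbilical-artery pH
#'
#' Fetal acidemia at birth is the objective ground truth used to label the
#' recordings: pH less than or equal to the threshold (default 7.15) is
#' distressed, anything above is normal.
#'
#' @param ph umbilical-artery pH, > 0.
#' @param threshold decision boundary, included in the distressed class.
#' @return `"distressed"` or `"normal"` (factor with those two levels).
#' @export
label_by_ph <- function(ph, threshold = 7.15) {
  if (length(ph) == 0L) stop("labeling error: no pH supplied")
  if (anyNA(ph) || any(ph <= 0)) {
    stop("labeling error: pH must be present and positive")
  }
  factor(ifelse(ph <= threshold, "distressed", "normal"),
         levels = c("normal", "distressed"))
}

#' Label a collection of CTG records
#'
#' Records without a usable pH are excluded with a warning rather than
#' guessed at.
#'
#' @param records list of [ctg_record()] objects.
#' @param threshold pH decision boundary passed to [label_by_ph()].
#' @return a data.frame with columns `record_id`, `ph`, `label`, carrying a
#'   `counts` attribute `c(normal =, distressed =)`.
#' @export
label_database <- function(records, threshold = 7.15) {
  if (length(records) == 0L) stop("labeling error: empty record collection")
  ph <- vapply(records, function(r) r$ph, numeric(1))
  ids <- vapply(records, function(r) r$record_id, character(1))
  usable <- !is.na(ph) & ph > 0
  if (!all(usable)) {
    warning(sum(!usable), " record(s) excluded: missing or non-positive pH (",
            paste(ids[!usable], collapse = ", "), ")")
  }
  if (!any(usable)) stop("labeling error: no record has a usable pH")
  labels <- data.frame(
    record_id = ids[usable],
    ph = ph[usable],
    label = label_by_ph(ph[usable], threshold),
    stringsAsFactors = FALSE
  )
  attr(labels, "counts") <- c(
    normal = sum(labels$label == "normal"),
    distressed = sum(labels$label == "distressed")
  )
  labels
}

#' Write labels as a two-column TSV
#'
#' @param labels data.frame from [label_database()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  writeLines(c("record_id\tlabel",
               sprintf("%s\t%s", labels$record_id, labels$label)), path)
  invisible(path)
}
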