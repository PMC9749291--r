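# shared fixtures, all generated in code

# clean bpm trace: gentle oscillation around a baseline, no defects
clean_trace <- function(n, baseline = 130, amp = 4, fs = 4) {
  baseline + amp * sin(2 * pi * seq_len(n) / (60 * fs))
}

# a cosine tone segment for ridge checks
tone_segment <- function(freq_hz, n = 4800, fs = 4, amplitude = 1) {
  amplitude * cos(2 * pi * freq_hz * (seq_len(n) - 1) / fs)
}

# cohort -> backbone features, the common end-to-end path
cohort_features <- function(n_normal, n_distressed, separation, seed,
                            stage = "stage1", duration_s = 2100) {
  cfg <- fhr_sim_config(duration_s = duration_s, class_separation = separation,
                        seed = seed)
  coh <- simulate_cohort(n_normal, n_distressed, cfg)
  ds <- suppressWarnings(build_dataset(coh$records, coh$labels, stage))
  dataset_features(ds)
}

# write a tiny two-channel WFDB format-16 record; returns the record path
write_wfdb_fixture <- function(dir, name = "rec01", fhr = c(120, 130, 0, 140),
                               uc = c(5, 10, 15, 20), gain = 4, ph = 7.10) {
  vals <- as.integer(rbind(round(fhr * gain), round(uc * gain)))
  writeBin(vals, file.path(dir, paste0(name, ".dat")), size = 2,
           endian = "little")
  writeLines(c(
    sprintf("%s 2 4 %d", name, length(fhr)),
    sprintf("%s.dat 16 %d(0)/bpm 16 0 %d 0 0 FHR", name, gain, round(fhr[1] * gain)),
    sprintf("%s.dat 16 %d(0)/nd 16 0 %d 0 0 UC", name, gain, round(uc[1] * gain)),
    sprintf("#pH %.2f", ph)
  ), file.path(dir, paste0(name, ".hea")))
  file.path(dir, name)
}
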