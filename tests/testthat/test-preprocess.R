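test_that("missing runs are located as maximal zero runs", {
  expect_equal(find_missing_runs(c(120, 0, 0, 0, 130)),
               data.frame(start = 2L, length = 3L))
  expect_equal(nrow(find_missing_runs(c(120, 130))), 0L)
  expect_equal(find_missing_runs(c(0, 0, 120, 0)),
               data.frame(start = c(1L, 4L), length = c(2L, 1L)))
})

test_that("long-gap deletion is strict at 15 s and only deletes", {
  base <- clean_trace(800)
  x61 <- c(base[1:300], rep(0, 61), base[301:800])
  out61 <- remove_long_gaps(fhr_signal(x61, fs = 4))
  expect_equal(length(out61$samples), 800L)
  expect_equal(out61$samples, base)
  expect_equal(unname(out61$provenance["gaps_removed"]), 1)

  x60 <- c(base[1:300], rep(0, 60), base[301:800])
  out60 <- remove_long_gaps(fhr_signal(x60, fs = 4))
  expect_equal(length(out60$samples), 860L)
  expect_equal(unname(out60$provenance["gaps_removed"]), 0)

  ident <- remove_long_gaps(fhr_signal(base, fs = 4))
  expect_equal(ident$samples, base)
  expect_error(remove_long_gaps(fhr_signal(rep(0, 10))), "empty-signal")
})

test_that("gap deletion never alters surviving nonzero values", {
  set.seed(21)
  for (rep_i in 1:20) {
    x <- clean_trace(500, baseline = runif(1, 110, 160))
    s <- sample(50:400, 1); len <- sample(c(10, 61, 100), 1)
    x[s:(s + len - 1)] <- 0
    out <- remove_long_gaps(fhr_signal(x, fs = 4))$samples
    expect_identical(out[out != 0], x[x != 0])
  }
})

test_that("edge trimming drops leading/trailing zero runs entirely", {
  expect_equal(trim_edges(c(0, 0, 140, 141, 0))$samples, c(140, 141))
  expect_equal(trim_edges(c(140, 141))$samples, c(140, 141))
  long <- c(rep(0, 100), clean_trace(50), rep(0, 3))
  out <- trim_edges(long)
  expect_equal(out$samples, clean_trace(50))
  expect_equal(unname(out$provenance["edge_samples_trimmed"]), 103)
  expect_error(trim_edges(rep(0, 5)), "empty-signal")
})

test_that("linear interpolation matches the two-point formula", {
  expect_equal(linear_interpolate(0, 100, 2, 120, 1), 110)
  expect_equal(linear_interpolate(0, 100, 4, 100, 3), 100)
  expect_equal(linear_interpolate(10, 80, 14, 120, 11), 90)
  expect_error(linear_interpolate(3, 10, 3, 20, 3), "degenerate-anchor")
  # oracle: stats::approx on random anchors
  set.seed(9)
  for (i in 1:50) {
    x0 <- runif(1, 0, 10); x1 <- x0 + runif(1, 0.5, 10)
    y0 <- runif(1, 50, 200); y1 <- runif(1, 50, 200)
    x <- runif(1, x0 + 1e-6, x1 - 1e-6)
    expect_equal(linear_interpolate(x0, y0, x1, y1, x),
                 approx(c(x0, x1), c(y0, y1), xout = x)$y, tolerance = 1e-12)
  }
})

test_that("outliers and short dropouts are linearly interpolated", {
  expect_equal(interpolate_outliers(c(120, 210, 124))$samples, c(120, 122, 124))
  expect_equal(interpolate_outliers(c(100, 0, 0, 130))$samples,
               c(100, 110, 120, 130))
  expect_equal(interpolate_outliers(c(60, 49, 61))$samples, c(60, 60.5, 61))
  # 50 and 200 are valid ("less than 50 ... greater than 200")
  expect_equal(interpolate_outliers(c(60, 50, 200, 61))$samples,
               c(60, 50, 200, 61))
  out <- interpolate_outliers(c(100, 0, 220, 0, 130))
  expect_equal(unname(out$provenance["samples_interpolated_linear"]), 3)
})

test_that("spike repair enforces the 25 bpm adjacent-delta bound", {
  base <- clean_trace(200, baseline = 130, amp = 2)
  spiky <- base; spiky[100] <- base[100] + 50
  out <- remove_spikes(fhr_signal(spiky, fs = 4))
  expect_lte(max(abs(diff(out$samples))), 25)
  expect_lte(abs(out$samples[100] - out$samples[99]), 25)
  expect_equal(unname(out$provenance["samples_interpolated_spline"]), 1)
  # untouched samples are preserved
  expect_equal(out$samples[-100], spiky[-100])
  # clean signal is identity
  clean_out <- remove_spikes(fhr_signal(base, fs = 4))
  expect_identical(clean_out$samples, base)
})

test_that("spike repair output always satisfies the delta bound (property)", {
  set.seed(31)
  for (rep_i in 1:25) {
    x <- clean_trace(400, baseline = runif(1, 100, 160), amp = runif(1, 2, 8))
    for (k in 1:sample(1:4, 1)) {
      pos <- sample(20:380, 1)
      x[pos] <- x[pos] + sample(c(-1, 1), 1) * runif(1, 30, 60)
    }
    x <- pmin(pmax(x, 51), 199)
    out <- remove_spikes(fhr_signal(x, fs = 4))$samples
    expect_lte(max(abs(diff(out))), 25)  # brute-force scan
    expect_true(all(out >= 50 & out <= 200))
  }
})

test_that("labor-stage segmentation takes the stated windows", {
  x <- clean_trace(21000)
  s1 <- segment_fhr(fhr_signal(x, fs = 4), "stage1")
  expect_equal(length(s1$samples), 4800L)
  expect_equal(s1$samples, x[1:4800])
  s2 <- segment_fhr(fhr_signal(x, fs = 4), "stage2")
  expect_equal(length(s2$samples), 3600L)
  expect_equal(s2$samples, x[(21000 - 3599):21000])
  expect_error(segment_fhr(fhr_signal(clean_trace(4000), fs = 4), "stage1"),
               "rejected")
})

test_that("the full pipeline composes the stages in order with provenance", {
  base <- clean_trace(7200, baseline = 135, amp = 5)
  x <- base
  x[1000:1080] <- 0                      # long gap: 81 samples
  x[c(2000, 3000, 4000)] <- c(220, 30, 240)  # 3 outliers
  x[5000] <- x[5000] + 45                # 1 spike
  rec <- ctg_record("fix", x, fs = 4, ph = 7.3)
  seg <- preprocess_pipeline(rec, "stage1")
  expect_s3_class(seg, "fhr_segment")
  expect_equal(length(seg$samples), 4800L)
  sig <- attr(seg, "signal")
  expect_equal(unname(sig$provenance),
               c(1, 3, 1, 0))
  y <- sig$samples
  expect_true(all(y != 0))
  expect_true(all(y >= 50 & y <= 200))
  expect_lte(max(abs(diff(y))), 25)
  # clean record: provenance all zero
  clean_seg <- preprocess_pipeline(ctg_record("c", base, fs = 4, ph = 7.3),
                                   "stage1")
  expect_equal(unname(attr(clean_seg, "signal")$provenance), c(0, 0, 0, 0))
  expect_error(preprocess_pipeline(ctg_record("z", rep(0, 100), fs = 4),
                                   "stage1"), "empty-signal")
})

test_that("the pipeline is idempotent on its own output", {
  cfg <- fhr_sim_config(seed = 77)
  sim <- simulate_fhr_record(cfg, "normal")
  seg <- preprocess_pipeline(sim$record, "stage1")
  again <- preprocess_signal(fhr_signal(seg$samples, fs = 4))
  expect_identical(again$samples, seg$samples)
  expect_equal(unname(again$provenance), c(0, 0, 0, 0))
})
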