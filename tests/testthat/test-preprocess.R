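test_that("the filter chain removes DC, crushes 50 Hz, and passes mid-band", {
  spec <- filter_spec()
  dc <- eareeg:::filter_signal_vector(rep(100, 1500), fs_default, spec)
  expect_lt(abs(mean(dc)), 0.1)
  s50 <- sinusoid(50, amplitude = 10)
  f50 <- eareeg:::filter_signal_vector(s50, fs_default, spec)
  expect_lt(sqrt(mean(f50^2)) / sqrt(mean(s50^2)), 0.01)
  s10 <- sinusoid(10, amplitude = 10)
  f10 <- eareeg:::filter_signal_vector(s10, fs_default, spec)
  expect_lt(abs(max(abs(f10)) / 10 - 1), 0.05)
  # length preserved, zero phase (peak positions unchanged in passband)
  expect_length(f10, length(s10))
  expect_equal(which.max(f10[100:1400]), which.max(s10[100:1400]), tolerance = 1)
  expect_error(eareeg:::filter_signal_vector(rnorm(10), fs_default, spec),
               "warm-up")
  expect_error(eareeg:::filter_signal_vector(rnorm(1000), 90, spec), "fs")
})

test_that("filtering is idempotent in the passband", {
  spec <- filter_spec()
  s10 <- sinusoid(10, amplitude = 5)
  once <- eareeg:::filter_signal_vector(s10, fs_default, spec)
  twice <- eareeg:::filter_signal_vector(once, fs_default, spec)
  expect_lt(abs(sqrt(mean(twice^2)) / sqrt(mean(once^2)) - 1), 0.05)
})

test_that("segmentation yields non-overlapping windows and drops remainders", {
  rec <- tibble::tibble(subject_id = "a", fs = fs_default,
                        signal = list(rnorm(120 * fs_default)))
  segs <- segment_recordings(rec)
  expect_equal(nrow(segs), 40)
  expect_true(all(vapply(segs$samples, length, 1L) == 3 * fs_default))
  rec2 <- tibble::tibble(subject_id = "a", fs = fs_default,
                         signal = list(rnorm(round(121.5 * fs_default))))
  expect_equal(nrow(segment_recordings(rec2)), 40)
  # reassembled segments reproduce the prefix of the recording
  expect_identical(unlist(segs$samples), rec$signal[[1]][1:(40 * 3 * fs_default)])
  # trial mode: one segment per recording row
  wl <- tibble::tibble(subject_id = "a", trial = 1:6, fs = fs_default,
                       signal = lapply(1:6, function(i) rnorm(1250)))
  expect_equal(nrow(segment_recordings(wl, mode = "trial")), 6)
  short <- tibble::tibble(subject_id = "a", fs = fs_default,
                          signal = list(rnorm(100)))
  expect_error(segment_recordings(short), "shorter")
})

test_that("QC assigns exactly one status with the documented precedence", {
  segs <- qc_segments(toy_qc_segments())
  expect_identical(as.character(segs$qc_status), segs$truth)
  # boundary convention: strict inequalities. A sample exactly at the +/-20
  # bound is retained; a range of exactly 80 escapes saturation but its
  # +/-40 samples still trip the amplitude rule.
  at_bounds <- tibble::tibble(
    subject_id = "b", fs = fs_default, segment = 1:2,
    samples = list(c(rep(-40, 750), rep(40, 750)),   # range exactly 80
                   c(rep(-10, 750), rep(20, 750))))  # max |x| exactly 20
  st <- qc_segments(at_bounds)$qc_status
  expect_identical(as.character(st), c("artifact", "pass"))
  # precedence: a saturated segment also exceeding +/-20 is saturated
  sat <- tibble::tibble(subject_id = "c", fs = fs_default, segment = 1,
                        samples = list(sinusoid(2, amplitude = 55)))
  expect_identical(as.character(qc_segments(sat)$qc_status), "saturated")
})

test_that("artifact-free synthetic segments pass QC at a high rate", {
  study <- generate_stress_study(4, seed = 6,
                                 artifact_rates = c(motion = 0, muscle = 0))
  segs <- qc_segments(segment_recordings(apply_filters(study)))
  expect_gte(mean(segs$qc_status == "pass"), 0.95)
})

test_that("class balancing downsamples to the minimum class without inventing rows", {
  tbl <- tibble::tibble(
    label = rep(c("meditation", "eyes_open", "cold_pressor"), c(429, 1258, 737)),
    id = seq_len(429 + 1258 + 737))
  bal <- balance_classes(tbl, seed = 2)
  expect_equal(unname(table(bal$label)), rep(429L, 3), ignore_attr = TRUE)
  expect_true(all(bal$id %in% tbl$id))
  expect_false(anyDuplicated(bal$id) > 0)
  # already balanced input is unchanged as a multiset
  even <- tibble::tibble(label = rep(c("a", "b"), each = 100), id = 1:200)
  expect_setequal(balance_classes(even, seed = 1)$id, even$id)
  expect_identical(balance_classes(tbl, seed = 7), balance_classes(tbl, seed = 7))
  expect_error(balance_classes(tibble::tibble(label = rep("a", 5)), seed = 1),
               "two classes")
})
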