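acq <- acquisition_params()
sets <- build_dynamic_sets(acq)

test_that("the default dynamic sets reproduce the eight printed durations", {
  expect_equal(nrow(sets), 8)
  expect_equal(sets$duration, c(40.5, 54, 67.5, 81, 94.5, 108, 121.5, 135))
  expect_equal(sets$label[c(1, 3, 8)], c("SD_40.5s", "SD_67.5s", "SD_135s"))
  expect_equal(sets$duration, sets$phase_count * acq$dt)
})

test_that("invalid phase counts are rejected", {
  expect_error(build_dynamic_sets(acq, c(9, 12, 31)), "exceeds")
  expect_error(build_dynamic_sets(acq, c(12, 9)), "ascending")
  expect_error(build_dynamic_sets(acq, c(1, 9)), "post-contrast")
})

test_that("truncation keeps the right samples with unchanged timestamps", {
  curve <- ramp_series(0.01, acq)
  full <- truncate_curve(curve, sets[sets$label == "SD_135s", ], acq)
  expect_equal(full$values, curve$values)     # identity at 30 phases
  short <- truncate_curve(curve, sets[sets$label == "SD_40.5s", ], acq)
  expect_length(short$times, 8)
  expect_equal(max(short$times), 36)          # (9 - 1) x 4.5 s
  mid <- truncate_curve(curve, sets[sets$label == "SD_67.5s", ], acq)
  expect_length(mid$times, 14)
  expect_equal(max(mid$times), 63)            # covers the 60 s window
})

test_that("maximum slope is exact on flat and linear curves", {
  tt <- post_times(acq)
  expect_equal(max_slope(concentration_series(tt, rep(0, length(tt)))), 0)
  # constant positive curve: the baseline-to-first segment dominates
  expect_equal(max_slope(concentration_series(tt, rep(0.9, length(tt)))),
               0.9 / 4.5)
  expect_equal(max_slope(ramp_series(0.013, acq)), 0.013)
})

test_that("maximum slope equals the brute-force segment scan on model curves", {
  g <- seq(0, 140, by = 0.1)
  aif <- list(times = g, values = population_aif(g))
  tt <- post_times(acq)
  curve <- concentration_series(
    tt, tofts_concentration(kinetic_spec(0.25, 0.3, 0.02, 5), aif, tt))
  a_t <- c(0, tt); a_c <- c(0, curve$values)
  brute <- -Inf
  for (i in seq_len(length(a_t) - 1))
    brute <- max(brute, (a_c[i + 1] - a_c[i]) / (a_t[i + 1] - a_t[i]))
  expect_equal(max_slope(curve), max(0, brute))
})

test_that("iAUC matches closed forms on ramps, with the truncation exception", {
  k <- 0.007
  full <- iauc(truncate_curve(ramp_series(k, acq),
                              sets[sets$label == "SD_135s", ], acq))
  expect_equal(full$iauc, 1800 * k)           # k * 60^2 / 2, trapezoid exact
  expect_false(full$truncated)
  expect_equal(full$iauc_window, 60)
  short <- iauc(truncate_curve(ramp_series(k, acq),
                               sets[sets$label == "SD_40.5s", ], acq))
  expect_equal(short$iauc, 648 * k)           # k * 36^2 / 2 at the 36 s end
  expect_true(short$truncated)
  expect_equal(short$iauc_window, 36)
  expect_equal(iauc(concentration_series(post_times(acq),
                                         rep(0, acq$n_post)))$iauc, 0)
})

test_that("the 60 s window endpoint is linearly interpolated between samples", {
  # sample times 58.5 s and 63 s straddle the 60 s window end; on a ramp
  # the interpolated endpoint keeps the trapezoid integral exact
  k <- 0.01
  mid <- iauc(truncate_curve(ramp_series(k, acq),
                             sets[sets$label == "SD_67.5s", ], acq))
  expect_equal(mid$iauc, 1800 * k)
  expect_false(mid$truncated)
})

test_that("per-lesion records have full cardinality and monotone structure", {
  study <- simulate_cohort(cohort_spec(n_benign = 6, n_malignant = 8,
                                       seed = 5), acq)
  rec <- compute_parameters(study, sets)
  expect_s3_class(rec, "kinetic_records")
  expect_equal(nrow(rec), 14 * 8)
  expect_true(all(rec$ms >= 0) && all(rec$iauc >= 0))
  expect_equal(rec$truncated, rec$iauc_window < 60)
  for (id in unique(rec$lesion_id)) {
    r <- rec[rec$lesion_id == id, ]
    r <- r[order(r$duration), ]
    # MS is a max over nested segment sets: non-decreasing in duration
    expect_true(all(diff(r$ms) >= -1e-12))
    # iAUC non-decreasing until the window is covered, constant after
    expect_true(all(diff(r$iauc) >= -1e-12))
    covered <- r$iauc_window >= 60
    expect_equal(diff(r$iauc[covered]), rep(0, sum(covered) - 1))
  }
})

test_that("the full default cohort yields 151 x 8 = 1208 records", {
  study <- simulate_cohort(cohort_spec(seed = 2), acq)
  rec <- compute_parameters(study, sets)
  expect_equal(nrow(rec), 1208)
})
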