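# A small synthetic electropherogram with three guanine peaks and a control,
# built directly (not via the generator) so these tests stand on their own.
fp_trace <- function(amps, centers = c(20, 60, 100, 140), sd = 2,
                     scan = seq(0, 160, by = 1), baseline = 0) {
  sig <- rep(baseline, length(scan))
  for (i in seq_along(centers)) {
    sig <- sig + amps[i] * exp(-(scan - centers[i])^2 / (2 * sd^2))
  }
  electropherogram(scan, sig)
}

fp_map <- data.frame(base_index = c(5, 10, 11, 20),
                     window_start = c(12, 52, 92, 132),
                     window_end = c(28, 68, 108, 148),
                     is_control = c(FALSE, FALSE, FALSE, TRUE))

test_that("integrate_peaks matches the analytic Gaussian area within 1%", {
  tr <- fp_trace(c(100, 0, 0, 50))
  tab <- integrate_peaks(tr, fp_map)
  expect_equal(tab$area[1], 100 * 2 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(tab$area[2], 0, tolerance = 1e-6)
})

test_that("integration is additive over split windows and zero on empty traces", {
  tr <- fp_trace(c(100, 80, 60, 50))
  whole <- integrate_peaks(tr, fp_map)
  halves <- fp_map[c(1, 1, 2:4), ]
  halves$window_start[1:2] <- c(12, 20); halves$window_end[1:2] <- c(20, 28)
  halves$base_index[1:2] <- c(5, 6)
  split_tab <- integrate_peaks(tr, halves)
  expect_equal(split_tab$area[1] + split_tab$area[2], whole$area[1],
               tolerance = 1e-9)
  zero <- integrate_peaks(electropherogram(0:160, rep(0, 161)), fp_map)
  expect_true(all(zero$area == 0))
})

test_that("overlapping or out-of-range windows are rejected", {
  bad <- fp_map; bad$window_end[1] <- 60
  expect_error(integrate_peaks(fp_trace(c(1, 1, 1, 1)), bad),
               class = "etsdyn_validation_error")
  far <- fp_map; far$window_end[4] <- 500
  expect_error(integrate_peaks(fp_trace(c(1, 1, 1, 1)), far),
               class = "etsdyn_validation_error")
})

test_that("control normalization sets the control to 1 and cancels scaling", {
  tr <- fp_trace(c(50, 25, 10, 50))
  tab <- normalize_to_control(integrate_peaks(tr, fp_map))
  expect_equal(tab$normalized_area[tab$is_control], 1)
  expect_equal(tab$normalized_area[1] / tab$normalized_area[2], 2, tolerance = 1e-6)
  # uniform 3x rescaling leaves normalized areas unchanged
  tr3 <- electropherogram(tr$scan, 3 * tr$signal)
  tab3 <- normalize_to_control(integrate_peaks(tr3, fp_map))
  expect_equal(tab3$normalized_area, tab$normalized_area, tolerance = 1e-12)
  # zero control area errors
  tr0 <- fp_trace(c(0, 0, 0, 0))
  expect_error(normalize_to_control(integrate_peaks(tr0, fp_map)),
               class = "etsdyn_validation_error")
})

test_that("protection reports the bound/unbound core ratio at 0.1 granularity", {
  unb <- normalize_to_control(integrate_peaks(fp_trace(c(0, 100, 100, 50)), fp_map))
  # core suppressed to 10%: ~90% protection
  bnd <- normalize_to_control(integrate_peaks(fp_trace(c(0, 10, 10, 50)), fp_map))
  rep90 <- protection(bnd, unb, core_indices = c(10, 11))
  expect_equal(rep90$protection_percent, 90, tolerance = 0.2)
  expect_equal(rep90$core_fraction_unbound, 4.0)
  # identical tables: 0%
  expect_equal(protection(unb, unb, c(10, 11))$protection_percent, 0)
  # hypersensitivity: bound > unbound gives negative protection
  hyp <- normalize_to_control(integrate_peaks(fp_trace(c(0, 150, 150, 50)), fp_map))
  expect_lt(protection(hyp, unb, c(10, 11))$protection_percent, 0)
})

test_that("flag_changes applies the strict >20% rule and excludes the control", {
  unb <- normalize_to_control(integrate_peaks(fp_trace(c(50, 100, 100, 50)), fp_map))
  # base 5: +30% (flagged); bases 10/11 +10% (not flagged)
  bnd <- normalize_to_control(integrate_peaks(fp_trace(c(65, 110, 110, 50)), fp_map))
  flags <- flag_changes(bnd, unb)
  expect_equal(flags$base_index, 5)
  expect_equal(nrow(flag_changes(unb, unb)), 0)
  # threshold 0 flags every changed peak
  expect_setequal(flag_changes(bnd, unb, threshold = 0)$base_index, c(5, 10, 11))
  # zero unbound, nonzero bound: infinite change marker
  unb0 <- unb; unb0$normalized_area[1] <- 0
  inf_flags <- flag_changes(bnd, unb0)
  expect_true(is.infinite(inf_flags$relative_change[inf_flags$base_index == 5]))
})

test_that("hypersensitivity_check uses a strict factor threshold", {
  unb <- normalize_to_control(integrate_peaks(fp_trace(c(50, 100, 100, 50)), fp_map))
  b3 <- normalize_to_control(integrate_peaks(fp_trace(c(50, 300, 100, 50)), fp_map))
  expect_true(hypersensitivity_check(b3, unb, window = c(10, 11))$site_specific)
  expect_false(hypersensitivity_check(unb, unb, window = c(10, 11))$site_specific)
  # ratio exactly at the factor is not flagged
  b2 <- normalize_to_control(integrate_peaks(fp_trace(c(50, 200, 100, 50)), fp_map))
  res <- hypersensitivity_check(b2, unb, window = c(10, 11), factor = 2)
  expect_equal(res$max_ratio, 2, tolerance = 1e-6)
  expect_false(res$site_specific)
  expect_error(hypersensitivity_check(b2, unb, window = numeric(0)),
               class = "etsdyn_validation_error")
})

test_that("baseline subtraction removes a common offset without moving areas", {
  tr <- fp_trace(c(100, 80, 60, 50))
  off <- electropherogram(tr$scan, tr$signal + 25)
  tab <- normalize_to_control(integrate_peaks(tr, fp_map))
  tab_off <- normalize_to_control(integrate_peaks(off, fp_map, baseline_window = 41))
  expect_equal(tab_off$normalized_area, tab$normalized_area, tolerance = 0.02)
})

test_that("end-to-end: known suppression factors are recovered within 2%", {
  window <- paste0("ATTGACGTCA", "AGCGGAAGTG", "CATGACGTCA")
  for (supp in c(0.1, 0.4, 0.75)) {
    un <- gen_electropherogram(window, 11, bound = FALSE)
    bn <- gen_electropherogram(window, 11, bound = TRUE, suppression = supp)
    tab_u <- normalize_to_control(integrate_peaks(un$trace, un$index_map))
    tab_b <- normalize_to_control(integrate_peaks(bn$trace, bn$index_map))
    rep_ <- protection(tab_b, tab_u, un$core_indices)
    expect_equal(rep_$core_fraction_bound_raw / rep_$core_fraction_unbound_raw,
                 supp, tolerance = 0.02)
  }
})

test_that("trace and index-map files round-trip", {
  window <- paste0("ATTGACGTCA", "AGCGGAAGTG", "CATGACGTCA")
  g <- gen_electropherogram(window, 11, bound = FALSE)
  td <- withr::local_tempdir()
  write_trace_csv(g$trace, file.path(td, "t.csv"))
  write_index_map(g$index_map, file.path(td, "m.tsv"))
  tr2 <- read_trace_csv(file.path(td, "t.csv"))
  im2 <- read_index_map(file.path(td, "m.tsv"))
  expect_equal(tr2$signal, g$trace$signal, tolerance = 1e-9)
  expect_equal(im2$is_control, g$index_map$is_control)
})
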