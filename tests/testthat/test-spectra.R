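# Preprocessing chain: each operator against its independent oracle, then
# the chain as a whole against generator truth.

test_that("TIC normalization scales to unit sum and is idempotent", {
  s <- mass_spectrum(1:10, rep(2, 10))
  expect_equal(tic_normalize(s)$intensity, rep(0.1, 10))
  r <- pepclass:::with_seed(3, mass_spectrum(1:200, runif(200, 0.1, 5)))
  n1 <- tic_normalize(r)
  expect_lt(abs(sum(n1$intensity) - 1), 1e-12)
  expect_equal(tic_normalize(n1)$intensity, n1$intensity)
  expect_identical(n1$mz, r$mz)
  expect_error(tic_normalize(mass_spectrum(1:5, rep(0, 5))), "all-zero")
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials and shrinks noise", {
  cfg <- processing_config()
  s <- mass_spectrum(1:50, rep(4, 50))
  expect_equal(smooth_spectrum(s, cfg)$intensity, rep(4, 50))
  ramp <- mass_spectrum(1:100, seq(0, 9.9, 0.1) + 1)
  sm <- smooth_spectrum(ramp, cfg)
  interior <- 5:96
  expect_lt(max(abs(sm$intensity[interior] - ramp$intensity[interior])), 1e-9)
  noise <- pepclass:::with_seed(4, mass_spectrum(1:5000, pmax(rnorm(5000, 10, 1), 0)))
  expect_lt(sd(smooth_spectrum(noise, cfg)$intensity), sd(noise$intensity))
  expect_error(smooth_spectrum(mass_spectrum(1:5, rep(1, 5)), cfg), "window longer")
})

test_that("top-hat baseline equals the brute-force opening and removes offsets", {
  cfg <- processing_config(mz_min = 0, mz_max = 100, baseline_width_fraction = 0.1)
  flat <- mass_spectrum(seq(0, 100, 0.5), rep(7, 201))
  expect_equal(remove_baseline(flat, cfg)$intensity, rep(0, 201))
  # Gaussian (FWHM ~2.4 << 10-unit element) on an offset: peak survives
  g <- gaussian_spectrum(50, 25, 1, mz = seq(0, 100, 0.1), offset = 3)
  out <- remove_baseline(g, cfg)
  truth <- 25 * dnorm(g$mz, 50, 1)
  expect_lt(max(abs(out$intensity - truth)), 0.01 * max(truth))
  # random signal: exact agreement with the sliding min/max oracle, and
  # anti-extensivity of the opening
  r <- pepclass:::with_seed(5, runif(400, 0, 10))
  sr <- mass_spectrum(seq_len(400), r)
  cfg2 <- processing_config(mz_min = 1, mz_max = 400, baseline_width_fraction = 0.1)
  width <- as.integer(round(0.1 * 399))  # matches remove_baseline's rounding
  if (width %% 2L == 0L) width <- width + 1L
  base <- remove_baseline(sr, cfg2, return_baseline = TRUE)
  expect_equal(base, opening_bruteforce(r, width))
  expect_true(all(base <= r))
})

test_that("noise estimator recovers iid Gaussian sigma and ignores offsets", {
  y <- pepclass:::with_seed(6, rnorm(1e5, 50, 1))
  s <- mass_spectrum(seq_along(y), pmax(y, 0))
  est <- estimate_noise(s)
  expect_gt(est, 0.97); expect_lt(est, 1.03)
  s2 <- mass_spectrum(seq_along(y), pmax(y, 0) + 20)
  expect_equal(estimate_noise(s2), est)
  expect_equal(estimate_noise(mass_spectrum(1:20, rep(3, 20))), 0)
  expect_error(estimate_noise(mass_spectrum(1:5, rep(1, 5))), "too short")
})

test_that("peak detection finds constructed peaks and respects the S/N threshold", {
  # peak_window_rel matched to the fixture's sigma = 4 Da peaks, which are
  # much wider than resolution-1000 TOF peaks at these masses
  cfg <- processing_config(mz_min = 0, mz_max = 4000, peak_window_rel = 0.005)
  centers <- c(1000, 2000, 3000)
  s <- gaussian_spectrum(centers, areas = c(500, 800, 600), sigma = 4,
                         mz = seq(0, 4000, 0.5), noise_sd = 1, seed = 7)
  # noise passed at its known generating value: zero-flooring of the trace
  # biases the successive-difference estimate on this synthetic fixture
  pk <- detect_peaks(s, cfg, noise = 1)
  expect_equal(nrow(pk), 3L)
  expect_lt(max(abs(pk$mz_centroid - centers)), 0.25)
  expect_true(all(pk$snr > 5))
  # peak at 2x noise with threshold 5: nothing detected
  weak <- gaussian_spectrum(2000, areas = 2 * 4 * sqrt(2 * pi), sigma = 4,
                            mz = seq(0, 4000, 0.5), noise_sd = 1, seed = 8)
  expect_equal(nrow(detect_peaks(weak, cfg, noise = 1)), 0L)
  # ... and the strong peaks are found uniquely even with the duplicate-prone
  # default window when the fixture matches TOF widths (sigma = mz/2354.8)
  s2 <- gaussian_spectrum(centers, areas = c(500, 800, 600),
                          sigma = 2000 / 2354.8, mz = seq(500, 3500, 0.25),
                          noise_sd = 0.5, seed = 7)
  expect_equal(nrow(detect_peaks(s2, processing_config(mz_min = 500, mz_max = 3500),
                                 noise = 0.5)), 3L)
  z <- mass_spectrum(seq(0, 4000, 0.5), rep(0, 8001))
  expect_equal(nrow(detect_peaks(z, cfg)), 0L)
})

test_that("peak count is monotone non-increasing in the S/N threshold", {
  s <- gaussian_spectrum(c(1000, 1500, 2000, 2500, 3000),
                         areas = c(30, 60, 120, 240, 480), sigma = 3,
                         mz = seq(800, 3500, 0.5), noise_sd = 0.5, seed = 9)
  counts <- vapply(c(1, 3, 5, 10, 30), function(thr)
    nrow(detect_peaks(s, processing_config(snr_threshold = thr), noise = 0.5)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-level integration matches the analytic Gaussian area and converges", {
  sig <- 2
  s <- gaussian_spectrum(1000, areas = 10 * sig * sqrt(2 * pi), sigma = sig,
                         mz = seq(980, 1020, 0.1))
  a <- integrate_peak_area(s, 1000 - 5 * sig, 1000 + 5 * sig)
  expect_equal(a, 50.13, tolerance = 0.01)
  # halving the step changes the trapezoid by < 0.1% (Richardson check)
  s2 <- gaussian_spectrum(1000, areas = 10 * sig * sqrt(2 * pi), sigma = sig,
                          mz = seq(980, 1020, 0.05))
  a2 <- integrate_peak_area(s2, 1000 - 5 * sig, 1000 + 5 * sig)
  expect_lt(abs(a2 - a) / a2, 0.001)
  z <- mass_spectrum(seq(980, 1020, 0.1), rep(0, 401))
  expect_equal(integrate_peak_area(z, 990, 1010), 0)
  expect_error(integrate_peak_area(s, 1010, 990), "inverted")
})

test_that("recalibration recovers a known uniform shift and leaves aligned spectra alone", {
  centers <- c(1200, 2500, 4000, 6000, 8000)
  mk <- function(shift, id) gaussian_spectrum(centers + shift, areas = rep(400, 5),
                                              sigma = 3, mz = seq(1000, 9000, 0.25),
                                              sample_id = id)
  spectra <- c(lapply(1:4, function(i) mk(0, paste0("ok", i))), list(mk(1.0, "shifted")))
  rcfg <- processing_config(mz_min = 1000, mz_max = 9000, peak_window_rel = 0.002)
  cal <- recalibrate_spectra(spectra, rcfg)
  # after recalibration every spectrum's centroids agree with the consensus:
  # the per-peak spread across spectra collapses from 1.0 Da to < 0.1 Da
  cents <- sapply(cal, function(s) {
    pk <- detect_peaks(smooth_spectrum(remove_baseline(s, rcfg), rcfg), rcfg)
    vapply(centers, function(cc) pk$mz_centroid[which.min(abs(pk$mz_centroid - cc))], 0)
  })
  expect_lt(max(apply(cents, 1, function(v) diff(range(v)))), 0.1)
  # already-aligned spectra are (near-)identity mapped
  cal0 <- recalibrate_spectra(spectra[1:4], processing_config(mz_min = 1000, mz_max = 9000))
  for (i in 1:4) expect_lt(max(abs(cal0[[i]]$mz - spectra[[i]]$mz)), 1e-3)
  # a single spectrum passes through untouched
  expect_identical(recalibrate_spectra(spectra[1]), spectra[1])
})

test_that("alignment merges within-tolerance centroids and separates distant ones", {
  cfg <- processing_config()
  mkpk <- function(mz, area) data.frame(mz_centroid = mz, height = 1, area = area,
                                        snr = 10, left_bound = mz - 1, right_bound = mz + 1)
  m1 <- build_peak_matrix(list(a = mkpk(3323.30, 5), b = mkpk(3323.40, 6)), cfg)
  expect_equal(ncol(m1$areas), 1L)
  expect_equal(unname(m1$areas[, 1]), c(5, 6))
  expect_equal(m1$reference_mz, 3323.35)
  m2 <- build_peak_matrix(list(a = mkpk(800, 5), b = mkpk(9000, 6)), cfg)
  expect_equal(ncol(m2$areas), 2L)
  expect_equal(unname(m2$areas), rbind(c(5, 0), c(0, 6)))
})

test_that("full chain recovers generated peaks and areas at low noise", {
  pm <- simulate_peak_table(5, 5, seed = 21)
  # noise well under 1% of the tallest peak height
  sp <- simulate_spectra(pm, noise_sd = 0.005, calibration_shift_sd = 0, seed = 21)
  mat <- process_spectra(sp, group = pm$group)
  panel <- default_peak_panel()
  hit <- vapply(pm$reference_mz, function(m) {
    j <- which.min(abs(mat$reference_mz - m))
    if (abs(mat$reference_mz[j] - m) < 0.002 * m) j else NA_integer_
  }, 1L)
  expect_gte(sum(!is.na(hit)), 40L)
  di <- which(panel$is_differential)
  expect_true(all(!is.na(hit[di])))
  # centroid error < 0.05% relative m/z; area correlation > 0.9 per peak
  expect_lt(max(abs(mat$reference_mz[hit[di]] - pm$reference_mz[di]) /
                  pm$reference_mz[di]), 5e-4)
  cors <- vapply(di, function(j) cor(pm$areas[, j], mat$areas[, hit[j]]), 0)
  expect_true(all(cors > 0.9))
})

test_that("peak-matrix CSV round trip preserves the dialect", {
  pm <- simulate_peak_table(3, 3, seed = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_matrix(pm, f)
  head1 <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", head1[1:3]),
               c("sample_id", "group", sprintf("%.2f", pm$reference_mz[1])))
  back <- read_peak_matrix(f)
  expect_equal(back$areas, pm$areas, tolerance = 1e-12)
  expect_identical(back$group, pm$group)
})
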