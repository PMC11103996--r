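#' Construct a mass spectrum
#'
#' A spectrum is one sample's (m/z, intensity) trace, the unit of data the
#' preprocessing chain operates on. m/z values must be strictly ascending.
#'
#' @param mz numeric vector of mass-to-charge values in Da, strictly ascending.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @param sample_id opaque sample identifier.
#' @return an object of class `mass_spectrum`.
#' @export
#' @examples
#' s <- mass_spectrum(seq(800, 810, 0.1), runif(101), "s1")
#' s
mass_spectrum <- function(mz, intensity, sample_id = "sample") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) < 2L) stop("a spectrum needs at least 2 points")
  if (any(diff(mz) <= 0)) stop("mz must be strictly ascending")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = mz, intensity = intensity, sample_id = as.character(sample_id)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s: %d points, m/z %.2f-%.2f, TIC %.4g\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Spectral processing parameters
#'
#' Bundles the tunable parameters of the preprocessing chain. Defaults follow
#' the published workflow where it states them (800-10,000 Da window,
#' signal-to-noise threshold 5, minimum baseline width 10% of the processed
#' range) and field-standard choices where it does not (Savitzky-Golay
#' window 9 / order 3; 2000 ppm alignment tolerance; a reference peak must be
#' present in at least 25% of samples).
#'
#' @param mz_min,mz_max processed m/z window, Da.
#' @param snr_threshold minimum peak height in units of the robust noise scale.
#' @param baseline_width_fraction top-hat structuring element span as a
#'   fraction of `mz_max - mz_min`.
#' @param smoothing_window odd Savitzky-Golay window length, points.
#' @param smoothing_polyorder Savitzky-Golay polynomial order.
#' @param alignment_tolerance relative m/z tolerance used for recalibration
#'   and cross-sample peak alignment (0.002 = 2000 ppm).
#' @param presence_fraction fraction of samples a cluster must appear in to
#'   become a reference peak.
#' @param peak_window_rel relative m/z half-window within which a detected
#'   apex must be the unique maximum (0.0005 = half a FWHM at resolving
#'   power 1000); suppresses noise-fragmented duplicate apexes.
#' @param min_halfwidth_points minimum number of grid points a peak's
#'   above-half-height region must span; rejects sub-resolution artifacts.
#' @param smooth_before_baseline apply smoothing before baseline subtraction
#'   (the published order is ambiguous; default is baseline first).
#' @param integrate_smoothed integrate areas on the processed (smoothed)
#'   trace (`TRUE`) or defer smoothing until after integration.
#' @return a list of class `processing_config`.
#' @export
processing_config <- function(mz_min = 800, mz_max = 10000,
                              snr_threshold = 5,
                              baseline_width_fraction = 0.10,
                              smoothing_window = 9L,
                              smoothing_polyorder = 3L,
                              alignment_tolerance = 0.002,
                              presence_fraction = 0.25,
                              peak_window_rel = 0.0005,
                              min_halfwidth_points = 3L,
                              smooth_before_baseline = FALSE,
                              integrate_smoothed = TRUE) {
  stopifnot(mz_min < mz_max, snr_threshold > 0,
            baseline_width_fraction > 0, baseline_width_fraction <= 1,
            smoothing_window %% 2 == 1,
            smoothing_window >= smoothing_polyorder + 2,
            alignment_tolerance > 0, presence_fraction > 0, presence_fraction <= 1,
            peak_window_rel > 0, min_halfwidth_points >= 1)
  structure(list(mz_min = mz_min, mz_max = mz_max, snr_threshold = snr_threshold,
                 baseline_width_fraction = baseline_width_fraction,
                 smoothing_window = as.integer(smoothing_window),
                 smoothing_polyorder = as.integer(smoothing_polyorder),
                 alignment_tolerance = alignment_tolerance,
                 presence_fraction = presence_fraction,
                 peak_window_rel = peak_window_rel,
                 min_halfwidth_points = as.integer(min_halfwidth_points),
                 smooth_before_baseline = smooth_before_baseline,
                 integrate_smoothed = integrate_smoothed),
            class = "processing_config")
}

#' Restrict a spectrum to the processed m/z window
#' @param s a `mass_spectrum`.
#' @param cfg a [processing_config()].
#' @return the trimmed spectrum.
#' @export
trim_spectrum <- function(s, cfg = processing_config()) {
  keep <- s$mz >= cfg$mz_min & s$mz <= cfg$mz_max
  if (sum(keep) < 2L) stop("fewer than 2 points inside the m/z window")
  mass_spectrum(s$mz[keep], s$intensity[keep], s$sample_id)
}

#' Total-ion-current normalization
#'
#' Divides every intensity by the spectrum's total ion current so the
#' intensities sum to one; m/z is unchanged.
#'
#' @param s a `mass_spectrum`.
#' @return the normalized spectrum.
#' @export
tic_normalize <- function(s) {
  tic <- sum(s$intensity)
  if (tic <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  mass_spectrum(s$mz, s$intensity / tic, s$sample_id)
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing, the standard low-distortion
#' smoother for TOF profiles (it preserves peak areas better than a moving
#' average). Output is floored at zero. Edges are smoothed against an
#' even-reflection pad so constants and interior polynomials pass through.
#'
#' @inheritParams trim_spectrum
#' @return the smoothed spectrum.
#' @export
smooth_spectrum <- function(s, cfg = processing_config()) {
  w <- cfg$smoothing_window
  if (w > length(s$mz)) stop("smoothing window longer than the spectrum")
  h <- (w - 1L) %/% 2L
  co <- sgolay_coef(w, cfg$smoothing_polyorder)
  y <- s$intensity
  ypad <- c(y[(h + 1L):2L], y, y[(length(y) - 1L):(length(y) - h)])
  sm <- stats::filter(ypad, co, sides = 2)
  sm <- as.numeric(sm)[(h + 1L):(h + length(y))]
  mass_spectrum(s$mz, pmax(sm, 0), s$sample_id)
}

#' Top-hat baseline subtraction
#'
#' Estimates the baseline as the morphological opening (erosion then
#' dilation, i.e. running minimum then running maximum) of the intensity
#' trace with a flat structuring element spanning
#' `baseline_width_fraction * (mz_max - mz_min)` Da, then subtracts it and
#' floors at zero. Features narrower than the element survive; the opening is
#' anti-extensive, so the baseline never exceeds the signal.
#'
#' The element width is converted to grid points using the median m/z
#' spacing, assuming near-uniform sampling.
#'
#' @inheritParams trim_spectrum
#' @param return_baseline return the baseline estimate instead of the
#'   subtracted spectrum.
#' @return the baseline-subtracted spectrum (or the baseline as a numeric
#'   vector if `return_baseline`).
#' @export
remove_baseline <- function(s, cfg = processing_config(), return_baseline = FALSE) {
  step <- stats::median(diff(s$mz))
  span_da <- cfg$baseline_width_fraction * (cfg$mz_max - cfg$mz_min)
  width <- max(3L, as.integer(round(span_da / step)))
  if (width %% 2L == 0L) width <- width + 1L
  if (width > length(s$mz)) stop("structuring element wider than the spectrum")
  eroded <- running_extreme(s$intensity, width, "min")
  baseline <- running_extreme(eroded, width, "max")
  if (return_baseline) return(baseline)
  mass_spectrum(s$mz, pmax(s$intensity - baseline, 0), s$sample_id)
}

#' Robust noise-scale estimate
#'
#' `1.4826 * median(|successive differences|) / sqrt(2)`: the MAD of the
#' first difference, back-scaled to the point-noise standard deviation. The
#' differencing removes baseline and broad peaks, so the estimate is driven
#' by point-to-point noise only.
#'
#' @param s a `mass_spectrum`, ideally baseline-subtracted.
#' @return noise standard deviation in intensity units.
#' @export
estimate_noise <- function(s) {
  if (length(s$intensity) < 16L) stop("spectrum too short for noise estimation")
  1.4826 * stats::median(abs(diff(s$intensity))) / sqrt(2)
}

#' Detect peaks above a signal-to-noise threshold
#'
#' Finds local intensity maxima at least `snr_threshold` times the robust
#' noise scale. For each peak the centroid is the intensity-weighted mean
#' m/z over the contiguous region above half the apex height; the bounds are
#' the nearest flanking local minima or zero crossings.
#'
#' @param s a smoothed, baseline-subtracted `mass_spectrum`.
#' @inheritParams trim_spectrum
#' @param noise noise scale to threshold against; defaults to
#'   [estimate_noise()] on `s`. Pass the pre-smoothing estimate when `s` has
#'   been smoothed — smoothing correlates neighboring points and deflates
#'   the successive-difference estimator.
#' @return a data frame with one row per peak: `mz_centroid`, `height`,
#'   `area`, `snr`, `left_bound`, `right_bound` (areas by zero-level
#'   trapezoidal integration between the bounds).
#' @export
detect_peaks <- function(s, cfg = processing_config(), noise = NULL) {
  y <- s$intensity
  n <- length(y)
  if (is.null(noise)) noise <- if (n >= 16L) estimate_noise(s) else 0
  thr <- if (noise > 0) cfg$snr_threshold * noise else .Machine$double.eps
  empty <- data.frame(mz_centroid = numeric(0), height = numeric(0),
                      area = numeric(0), snr = numeric(0),
                      left_bound = numeric(0), right_bound = numeric(0))
  # candidate apexes: 3-point maxima above threshold (left-strict so
  # flat-topped plateaus collapse to one apex)
  apex <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  apex <- apex[y[apex] >= thr]
  if (length(apex) == 0L) return(empty)
  # an apex must be the unique maximum within +- peak_window_rel * mz:
  # noise ripple on a real peak fragments it into several 3-point maxima
  w <- cfg$peak_window_rel * s$mz[apex]
  lo <- findInterval(s$mz[apex] - w, s$mz) + 1L
  hi <- findInterval(s$mz[apex] + w, s$mz)
  keep <- vapply(seq_along(apex), function(j) {
    win <- lo[j]:hi[j]
    m <- max(y[win])
    y[apex[j]] >= m && apex[j] == win[which.max(y[win])]
  }, TRUE)
  apex <- apex[keep]
  if (length(apex) == 0L) return(empty)
  # tolerated rise above the running valley minimum before a bound is called
  rise_tol <- function(h) max(3 * noise, 0.05 * h)
  out <- lapply(apex, function(i) {
    h <- y[i]
    tol <- rise_tol(h)
    max_ext <- 10 * cfg$peak_window_rel * s$mz[i]   # cap: +- 5 FWHM-equivalents
    # walk out tracking the running minimum; stop at zero, at a persistent
    # rise (the next peak's flank), or at the extent cap
    l <- i; lmin <- i
    while (l > 1L && y[l] > 0 && s$mz[i] - s$mz[l] < max_ext) {
      l <- l - 1L
      if (y[l] < y[lmin]) lmin <- l
      if (y[l] > y[lmin] + tol) break
    }
    r <- i; rmin <- i
    while (r < n && y[r] > 0 && s$mz[r] - s$mz[i] < max_ext) {
      r <- r + 1L
      if (y[r] < y[rmin]) rmin <- r
      if (y[r] > y[rmin] + tol) break
    }
    l <- lmin; r <- rmin
    # contiguous above-half-height region for the centroid
    hl <- i
    while (hl > l && y[hl - 1L] >= h / 2) hl <- hl - 1L
    hr <- i
    while (hr < r && y[hr + 1L] >= h / 2) hr <- hr + 1L
    if (hr - hl + 1L < cfg$min_halfwidth_points) return(NULL)
    seg <- hl:hr
    centroid <- sum(s$mz[seg] * y[seg]) / sum(y[seg])
    area <- trapezoid(s$mz[l:r], y[l:r])
    c(centroid, h, area, if (noise > 0) h / noise else Inf, s$mz[l], s$mz[r])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  data.frame(mz_centroid = out[, 1], height = out[, 2], area = out[, 3],
             snr = out[, 4], left_bound = out[, 5], right_bound = out[, 6])
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Zero-level peak area
#'
#' Trapezoidal integral of the baseline-subtracted trace between the peak
#' bounds, integrating down to the zero intensity level.
#'
#' @param s a baseline-subtracted `mass_spectrum`.
#' @param left_bound,right_bound integration bounds in Da.
#' @return the area in intensity x Da units.
#' @export
integrate_peak_area <- function(s, left_bound, right_bound) {
  if (left_bound >= right_bound) stop("inverted integration bounds")
  keep <- s$mz >= left_bound & s$mz <= right_bound
  trapezoid(s$mz[keep], s$intensity[keep])
}

# 1-D single-linkage clustering of sorted positions with a relative gap
# threshold: a new cluster starts wherever the gap to the previous position
# exceeds tol * position.
gap_cluster <- function(pos, tol) {
  o <- order(pos)
  p <- pos[o]
  brk <- c(FALSE, diff(p) > tol * p[-length(p)])
  cl <- cumsum(brk) + 1L
  cl[order(o)]
}

#' Recalibrate spectra on prominent common peaks
#'
#' Identifies prominent peaks — those appearing (within the alignment
#' tolerance) in at least 80% of spectra among each spectrum's 20 tallest
#' peaks — and, per spectrum, fits a linear m/z map `mz' = a*mz + b` by least
#' squares onto the consensus positions. Spectra matching fewer than 3
#' prominent peaks pass through unchanged.
#'
#' @param spectra a list of `mass_spectrum` objects.
#' @inheritParams trim_spectrum
#' @param min_presence fraction of spectra a candidate must appear in.
#' @param top_n number of tallest peaks considered per spectrum.
#' @return the list of recalibrated spectra.
#' @export
recalibrate_spectra <- function(spectra, cfg = processing_config(),
                                min_presence = 0.8, top_n = 20L) {
  if (length(spectra) < 2L) return(spectra)
  peaksets <- lapply(spectra, function(s) {
    b <- remove_baseline(s, cfg)
    p <- detect_peaks(smooth_spectrum(b, cfg), cfg, noise = estimate_noise(b))
    if (nrow(p) > top_n) p <- p[order(-p$height)[seq_len(top_n)], ]
    p
  })
  all_mz <- unlist(lapply(peaksets, `[[`, "mz_centroid"))
  if (length(all_mz) == 0L) return(spectra)
  src <- rep(seq_along(peaksets), vapply(peaksets, nrow, 1L))
  cl <- gap_cluster(all_mz, cfg$alignment_tolerance)
  presence <- tapply(src, cl, function(i) length(unique(i)))
  prominent <- names(presence)[presence >= min_presence * length(spectra)]
  if (length(prominent) == 0L) return(spectra)
  consensus <- tapply(all_mz, cl, mean)[prominent]
  Map(function(s, k) {
    own <- all_mz[src == k]
    owncl <- as.character(cl[src == k])
    hit <- owncl %in% prominent
    if (sum(hit) < 3L) return(s)
    x <- own[hit]
    y <- consensus[owncl[hit]]
    fit <- stats::lm.fit(cbind(1, x), y)$coefficients
    mass_spectrum(fit[1] + fit[2] * s$mz, s$intensity, s$sample_id)
  }, spectra, seq_along(spectra))
}
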