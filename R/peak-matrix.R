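#' Construct a peak matrix
#'
#' The samples x aligned-reference-peaks table of zero-level areas that all
#' downstream statistics operate on. Missing peaks are recorded as 0.
#'
#' @param areas numeric matrix, samples in rows, reference peaks in columns.
#' @param reference_mz strictly ascending reference m/z values, one per column.
#' @param sample_ids character vector, one per row.
#' @param group group labels: `"response"`, `"progression"` or `"unlabeled"`.
#' @return an object of class `peak_matrix`.
#' @export
peak_matrix <- function(areas, reference_mz, sample_ids = rownames(areas),
                        group = rep("unlabeled", nrow(areas))) {
  areas <- as.matrix(areas)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(areas)))
  group <- as.character(group)
  if (length(reference_mz) != ncol(areas)) stop("one reference m/z per column required")
  if (length(sample_ids) != nrow(areas)) stop("one sample_id per row required")
  if (length(group) != nrow(areas)) stop("one group label per row required")
  if (is.unsorted(reference_mz, strictly = TRUE)) stop("reference_mz must be strictly ascending")
  if (!all(group %in% c("response", "progression", "unlabeled")))
    stop("group labels must be 'response', 'progression' or 'unlabeled'")
  dimnames(areas) <- list(sample_ids, sprintf("%.2f", reference_mz))
  structure(list(areas = areas, reference_mz = as.numeric(reference_mz),
                 sample_ids = as.character(sample_ids), group = group),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  tab <- table(factor(x$group, levels = c("response", "progression", "unlabeled")))
  cat(sprintf("<peak_matrix> %d samples x %d reference peaks (m/z %.2f-%.2f)\n",
              nrow(x$areas), ncol(x$areas),
              min(x$reference_mz), max(x$reference_mz)))
  cat(sprintf("  groups: response %d, progression %d, unlabeled %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
as.data.frame.peak_matrix <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, group = x$group, x$areas,
             check.names = FALSE, row.names = NULL)
}

#' Align per-sample peak lists into a peak matrix
#'
#' Single-linkage clusters all detected centroids on a relative m/z gap
#' threshold; clusters present in at least `presence_fraction` of samples
#' become reference peaks (reference m/z = mean member centroid). Each
#' sample contributes the area of its member peak (the largest, if several
#' of its peaks fall in one cluster), else 0.
#'
#' @param peaklists list of per-sample peak data frames from [detect_peaks()].
#' @param cfg a [processing_config()].
#' @param sample_ids sample identifiers, one per peak list.
#' @param group optional group labels.
#' @return a [peak_matrix()].
#' @export
build_peak_matrix <- function(peaklists, cfg = processing_config(),
                              sample_ids = names(peaklists),
                              group = rep("unlabeled", length(peaklists))) {
  if (length(peaklists) < 1L) stop("at least one sample required")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(peaklists))
  npk <- vapply(peaklists, nrow, 1L)
  all_mz <- unlist(lapply(peaklists, `[[`, "mz_centroid"), use.names = FALSE)
  if (length(all_mz) == 0L) stop("no peaks detected in any sample")
  all_area <- unlist(lapply(peaklists, `[[`, "area"), use.names = FALSE)
  src <- rep(seq_along(peaklists), npk)
  cl <- gap_cluster(all_mz, cfg$alignment_tolerance)
  presence <- tapply(src, cl, function(i) length(unique(i)))
  keep <- names(presence)[presence >= cfg$presence_fraction * length(peaklists)]
  ref_mz <- sort(tapply(all_mz, cl, mean)[keep])
  areas <- matrix(0, length(peaklists), length(ref_mz))
  for (j in seq_along(ref_mz)) {
    kid <- names(ref_mz)[j]
    sel <- cl == as.integer(kid)
    # max area wins if one sample has several member peaks in a cluster
    a <- tapply(all_area[sel], src[sel], max)
    areas[as.integer(names(a)), j] <- a
  }
  peak_matrix(areas, as.numeric(ref_mz), sample_ids, group)
}

#' Run the full preprocessing chain on a set of spectra
#'
#' Fixed pipeline order: trim to the m/z window, TIC-normalize, recalibrate
#' on prominent common peaks, top-hat baseline subtraction, Savitzky-Golay
#' smoothing, S/N-thresholded peak detection with zero-level integration,
#' and cross-sample alignment into a [peak_matrix()].
#'
#' @param spectra list of `mass_spectrum` objects.
#' @param cfg a [processing_config()].
#' @param group optional per-spectrum group labels.
#' @return a [peak_matrix()].
#' @export
process_spectra <- function(spectra, cfg = processing_config(),
                            group = rep("unlabeled", length(spectra))) {
  spectra <- lapply(spectra, trim_spectrum, cfg = cfg)
  spectra <- lapply(spectra, tic_normalize)
  spectra <- recalibrate_spectra(spectra, cfg)
  spectra <- lapply(spectra, remove_baseline, cfg = cfg)
  # noise from the unsmoothed trace: smoothing correlates neighbors and
  # deflates the successive-difference estimator
  noise <- vapply(spectra, estimate_noise, 0)
  if (cfg$integrate_smoothed) spectra <- lapply(spectra, smooth_spectrum, cfg = cfg)
  peaklists <- Map(function(s, nz) detect_peaks(s, cfg, noise = nz), spectra, noise)
  build_peak_matrix(peaklists, cfg,
                    sample_ids = vapply(spectra, `[[`, "", "sample_id"),
                    group = group)
}

#' Write / read the peak-matrix CSV dialect
#'
#' First column `sample_id`, second `group`, remaining columns named by
#' reference m/z printed to 2 decimals.
#'
#' @param x a [peak_matrix()].
#' @param path file path.
#' @return `read_peak_matrix` returns a [peak_matrix()];
#'   `write_peak_matrix` returns `path` invisibly.
#' @export
write_peak_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "group") == names(df)[1:2]))
    stop("expected columns sample_id, group, then m/z-named areas")
  areas <- as.matrix(df[, -(1:2), drop = FALSE])
  peak_matrix(areas, as.numeric(colnames(areas)), df$sample_id, df$group)
}

#' Read a two-column whitespace text spectrum
#'
#' @param path file with two whitespace-separated columns: m/z, intensity.
#' @param sample_id identifier; defaults to the file name.
#' @return a [mass_spectrum()].
#' @export
read_spectrum_txt <- function(path, sample_id = basename(path)) {
  m <- utils::read.table(path, col.names = c("mz", "intensity"))
  mass_spectrum(m$mz, m$intensity, sample_id)
}

#' @rdname read_spectrum_txt
#' @param s a `mass_spectrum`.
#' @export
write_spectrum_txt <- function(s, path) {
  utils::write.table(data.frame(s$mz, s$intensity), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
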