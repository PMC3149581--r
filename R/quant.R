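# Chromatogram quantification: Gaussian smoothing, robust noise estimation,
# S/N-gated peak-region detection, two quantities per trace (total EIC sum
# and gated area over raw intensities) and a reliability heuristic.

#' Gaussian smoothing of an intensity trace
#'
#' Discrete convolution with a Gaussian kernel truncated at +/- 4 sigma and
#' renormalized to sum 1. At the trace edges the kernel is renormalized over
#' its in-bounds part, so a constant trace is a fixed point everywhere and
#' the total signal of an interior-supported peak is conserved.
#'
#' @param trace Numeric intensity vector (length >= 1).
#' @param sigma_scans Kernel standard deviation in scans (default 3).
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth <- function(trace, sigma_scans = 3) {
  stopifnot(is.numeric(trace), length(trace) >= 1L, sigma_scans > 0)
  h <- as.integer(ceiling(4 * sigma_scans))
  k <- stats::dnorm(-h:h, sd = sigma_scans)
  k <- k / sum(k)
  n <- length(trace)
  pad <- function(x) c(rep(0, h), x, rep(0, h))
  conv <- function(x) {
    y <- stats::filter(pad(x), k, method = "convolution", sides = 2)
    as.numeric(y)[(h + 1L):(h + n)]
  }
  num <- conv(trace)
  den <- conv(rep(1, n))  # in-bounds kernel mass per position
  num / den
}

#' Robust noise level of a smoothed trace
#'
#' `1.4826 * median(|x - median(x)|)` (the MAD scaled to estimate a Gaussian
#' standard deviation). When the MAD is zero — typical for traces that are
#' mostly exact zeros — the estimate falls back to the smallest positive
#' intensity at or below the trace median (a constant positive baseline thus
#' estimates its own level), and finally to 1.0 when no such baseline
#' variation exists, so the returned level is always positive.
#'
#' @param smoothed Numeric vector, length >= 4 (shorter traces carry too
#'   little information for a spread estimate).
#' @return Positive noise level in intensity counts.
#' @export
estimate_noise <- function(smoothed) {
  stopifnot(is.numeric(smoothed), length(smoothed) >= 4L)
  med <- stats::median(smoothed)
  noise <- 1.4826 * stats::median(abs(smoothed - med))
  if (noise > 0) return(noise)
  base <- smoothed[smoothed > 0 & smoothed <= med]
  if (length(base)) min(base) else 1.0
}

#' Detect S/N-gated peak regions
#'
#' Maximal runs of consecutive scans whose smoothed intensity exceeds
#' `sn_cutoff * noise`; runs shorter than `min_scans` are discarded.
#' Regions are disjoint and ordered by start scan.
#'
#' @param smoothed Smoothed intensity vector.
#' @param noise Positive noise level (see [estimate_noise()]).
#' @param sn_cutoff Signal-to-noise multiple for the gate (default 3).
#' @param min_scans Minimum region length in scans (default 3).
#' @return Data frame with columns `start` and `end` (1-based scan indices,
#'   inclusive); zero rows when nothing qualifies.
#' @export
detect_peak_regions <- function(smoothed, noise, sn_cutoff = 3,
                                min_scans = 3) {
  stopifnot(is.numeric(smoothed), noise > 0, sn_cutoff > 0, min_scans >= 1)
  above <- smoothed > sn_cutoff * noise
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_scans
  data.frame(start = starts[keep], end = ends[keep])
}

#' Quantify a chromatogram trace
#'
#' Two quantities from the *raw* trace: `eic_sum`, the sum of the total ion
#' chromatogram over all scans, and `sn_area`, the sum over scans inside the
#' detected peak regions only. Smoothing is used solely to select the
#' regions; areas are always summed from raw intensities so the two
#' quantities stay directly comparable.
#'
#' @param raw_trace Raw intensity vector.
#' @param regions Regions from [detect_peak_regions()], within trace bounds.
#' @return Named list with `eic_sum` and `sn_area`.
#' @export
quantify_trace <- function(raw_trace, regions) {
  stopifnot(is.numeric(raw_trace))
  if (nrow(regions)) {
    if (any(regions$start < 1L) || any(regions$end > length(raw_trace)))
      stop("regions outside trace bounds")
    sel <- unlist(mapply(seq, regions$start, regions$end, SIMPLIFY = FALSE))
    sn <- sum(raw_trace[sel])
  } else sn <- 0
  list(eic_sum = sum(raw_trace), sn_area = sn)
}

#' Flag unreliable chromatograms
#'
#' Automated stand-in for visual curation of extracted chromatograms. A
#' trace is unreliable when (a) it is *stretched*: the fraction of scans
#' above the S/N gate exceeds `stretch_fraction` of the run (the analyte
#' signal spans essentially the whole experiment), or (b) it has a *noisy
#' baseline*: no qualifying peak region was found yet more than 20 percent
#' of scans lie above one noise level.
#'
#' @param smoothed Smoothed intensity vector.
#' @param regions Regions from [detect_peak_regions()].
#' @param noise Positive noise level.
#' @param sn_cutoff S/N multiple used for region detection (default 3).
#' @param stretch_fraction Fraction of the run above the gate beyond which
#'   the trace counts as stretched (default 0.8).
#' @return Named list with `reliable` (logical) and `reason` (`""`,
#'   `"stretched"` or `"noisy_baseline"`).
#' @export
flag_unreliable <- function(smoothed, regions, noise, sn_cutoff = 3,
                            stretch_fraction = 0.8) {
  stopifnot(is.numeric(smoothed), noise > 0)
  frac_above_gate <- mean(smoothed > sn_cutoff * noise)
  if (frac_above_gate > stretch_fraction)
    return(list(reliable = FALSE, reason = "stretched"))
  if (nrow(regions) == 0L && mean(smoothed > noise) > 0.2)
    return(list(reliable = FALSE, reason = "noisy_baseline"))
  list(reliable = TRUE, reason = "")
}

#' Quantify one extracted chromatogram
#'
#' Convenience wrapper running the full per-trace chain: Gaussian smoothing,
#' noise estimation, region detection, quantification and reliability
#' flagging.
#'
#' @param chrom A `"chromatogram"` from [extract_chromatogram()].
#' @param sn_cutoff,gaussian_sigma_scans,min_region_scans,stretch_fraction
#'   Tuning parameters; see the underlying functions.
#' @return One-row data frame with columns `sample_id`, `mz_center`,
#'   `eic_sum`, `sn_area`, `n_peak_regions`, `reliable`, `reason`.
#' @export
quantify_chromatogram <- function(chrom, sn_cutoff = 3,
                                  gaussian_sigma_scans = 3,
                                  min_region_scans = 3,
                                  stretch_fraction = 0.8) {
  stopifnot(inherits(chrom, "chromatogram"))
  sm <- gaussian_smooth(chrom$intensity, gaussian_sigma_scans)
  noise <- estimate_noise(sm)
  regions <- detect_peak_regions(sm, noise, sn_cutoff, min_region_scans)
  q <- quantify_trace(chrom$intensity, regions)
  fl <- flag_unreliable(sm, regions, noise, sn_cutoff, stretch_fraction)
  data.frame(sample_id = chrom$sample_id, mz_center = chrom$mz_center,
             eic_sum = q$eic_sum, sn_area = q$sn_area,
             n_peak_regions = nrow(regions),
             reliable = fl$reliable, reason = fl$reason,
             stringsAsFactors = FALSE)
}
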