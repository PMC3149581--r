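# The single-step m/z picking + alignment core: collect the top intensity
# fraction of every sample, pool, group by ppm closeness, take group medians,
# and extract narrow ion chromatograms on each sample's own scan grid.
# No retention-time alignment is performed anywhere: with ppm-level mass
# accuracy, the m/z value itself is the cross-sample anchor.

#' Collect the highest-intensity data points of each sample
#'
#' For each run independently, retains the `ceiling(top_fraction * N)`
#' highest-intensity points of that run's `N` points; the per-sample
#' intensity threshold is the value of the point at that rank, and ties at
#' the threshold are all retained (so a run can contribute slightly more
#' points — deterministic and order-independent). The retained points of all
#' runs are pooled into one table, each tagged with its sample. Thresholding
#' per sample, not on the pooled data, means a globally dimmer sample still
#' contributes its own top fraction.
#'
#' @param runs A [centroid_run()] or list of them.
#' @param top_fraction Fraction in (0, 1] of each sample's points to keep
#'   (default 0.01: the top 1 percent, treating the remaining 99 percent of
#'   low-intensity points as background noise).
#' @return Data frame of pooled points with columns `sample_id`, `scan`,
#'   `rt`, `mz`, `intensity`.
#' @export
collect_data_points <- function(runs, top_fraction = 0.01) {
  if (inherits(runs, "centroid_run")) runs <- list(runs)
  if (!length(runs) || !all(vapply(runs, inherits, logical(1), "centroid_run")))
    stop("'runs' must be one or more centroid_run objects")
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  out <- lapply(runs, function(run) {
    p <- run$points
    if (nrow(p) == 0L)
      stop("run '", run$sample_id, "' contains no data points")
    k <- ceiling(top_fraction * nrow(p))
    thr <- sort(p$intensity, decreasing = TRUE)[k]
    keep <- p$intensity >= thr
    cbind(sample_id = run$sample_id, p[keep, , drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group pooled data points by m/z closeness
#'
#' Sorts all pooled m/z values ascending and starts a new group wherever the
#' gap to the previous value, `(mz[i] - mz[i-1]) / mz[i-1] * 1e6`, exceeds
#' `closeness_ppm`. This is single-linkage chaining: any run of
#' within-tolerance neighbor gaps merges into one group, so a group's total
#' span may exceed the tolerance and there is no limit on the number of
#' points per group. The groups partition the input.
#'
#' @param points Data frame with an `mz` column (e.g. from
#'   [collect_data_points()]) or a bare numeric vector of m/z values.
#' @param closeness_ppm Neighbor-gap tolerance in ppm (default 5).
#' @return An object of class `"mz_groups"`: list with `points` (the input,
#'   sorted by m/z, plus a `group` index column), `groups` (one row per
#'   group: `group`, `n_points`, `mz_lo`, `mz_hi`, `mz_median`) and
#'   `closeness_ppm`.
#' @export
group_by_mz <- function(points, closeness_ppm = 5) {
  if (is.numeric(points)) points <- data.frame(mz = points)
  if (!is.data.frame(points) || !"mz" %in% names(points))
    stop("'points' must be a data frame with an 'mz' column")
  if (nrow(points) == 0L) stop("cannot group an empty set of points")
  if (!is.numeric(closeness_ppm) || closeness_ppm <= 0)
    stop("closeness_ppm must be positive")
  pts <- points[order(points$mz), , drop = FALSE]
  mz <- pts$mz
  n <- length(mz)
  if (n > 1L) {
    gap_ppm <- diff(mz) / mz[-n] * 1e6
    grp <- cumsum(c(1L, as.integer(gap_ppm > closeness_ppm)))
  } else grp <- 1L
  pts$group <- grp
  rownames(pts) <- NULL
  # groups are contiguous runs in the sorted order; vectorized medians
  last <- cumsum(tabulate(grp))
  first <- c(1L, last[-length(last)] + 1L)
  len <- last - first + 1L
  mid <- first + (len - 1L) %/% 2L
  med <- ifelse(len %% 2L == 1L, mz[mid], (mz[mid] + mz[mid + 1L]) / 2)
  groups <- data.frame(group = seq_along(first), n_points = len,
                       mz_lo = mz[first], mz_hi = mz[last], mz_median = med)
  structure(list(points = pts, groups = groups,
                 closeness_ppm = closeness_ppm),
            class = "mz_groups")
}

#' @export
print.mz_groups <- function(x, ...) {
  cat(sprintf("<mz_groups> %d groups from %d points (closeness %g ppm)\n",
              nrow(x$groups), nrow(x$points), x$closeness_ppm))
  invisible(x)
}

#' Representative m/z of a group
#'
#' The representative of an m/z group is the median of its member m/z values
#' pooled across all samples; for an even member count, the arithmetic mean
#' of the two central values. Applied to an `"mz_groups"` object it returns
#' the vector of all group representatives.
#'
#' @param group Numeric vector of member m/z values, or an `"mz_groups"`
#'   object from [group_by_mz()].
#' @return Representative m/z value(s) in Thomson.
#' @export
representative_mz <- function(group) {
  if (inherits(group, "mz_groups")) return(group$groups$mz_median)
  if (!is.numeric(group) || length(group) == 0L)
    stop("group must be a non-empty numeric vector of m/z values")
  stats::median(group)
}

#' Extract an ion chromatogram
#'
#' For each scan of the run, sums the intensities of all centroid peaks whose
#' m/z lies in the inclusive window
#' `[mz_center * (1 - tol_ppm * 1e-6), mz_center * (1 + tol_ppm * 1e-6)]`.
#' Scans with no in-window peak contribute zero, so the trace always has one
#' value per scan of the sample's own grid; no retention-time alignment is
#' applied across samples.
#'
#' @param run A [centroid_run()].
#' @param mz_center Window center in Thomson.
#' @param tol_ppm Half-width of the window in ppm (default 5).
#' @return Object of class `"chromatogram"`: list with `sample_id`,
#'   `mz_center`, `tol_ppm`, `rt` (minutes) and `intensity` vectors.
#' @export
extract_chromatogram <- function(run, mz_center, tol_ppm = 5) {
  stopifnot(inherits(run, "centroid_run"), tol_ppm > 0, mz_center > 0)
  ord <- order(run$points$mz)
  .eic(run, mz_center, tol_ppm, ord)
}

# internal: EIC given a precomputed order(points$mz), reused by the pipeline
.eic <- function(run, mz_center, tol_ppm, ord) {
  lo <- mz_center * (1 - tol_ppm * 1e-6)
  hi <- mz_center * (1 + tol_ppm * 1e-6)
  mzs <- run$points$mz[ord]
  i0 <- findInterval(lo, mzs, left.open = TRUE) + 1L  # first mz >= lo
  i1 <- findInterval(hi, mzs)                         # last mz <= hi
  trace <- numeric(n_scans(run))
  if (i1 >= i0) {
    idx <- ord[i0:i1]
    agg <- rowsum(run$points$intensity[idx], run$points$scan[idx])
    trace[as.integer(rownames(agg))] <- agg[, 1L]
  }
  structure(list(sample_id = run$sample_id, mz_center = mz_center,
                 tol_ppm = tol_ppm, rt = run$rt, intensity = trace),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %s  m/z %.5f +/- %g ppm, %d scans, total %g\n",
    x$sample_id, x$mz_center, x$tol_ppm, length(x$rt), sum(x$intensity)))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::plot(x$rt, x$intensity, type = "l",
                 xlab = "retention time (min)", ylab = "intensity",
                 main = sprintf("m/z %.5f +/- %g ppm (%s)",
                                x$mz_center, x$tol_ppm, x$sample_id), ...)
  invisible(x)
}

#' Percent of total intensity variance in the top fraction of points
#'
#' Sorts intensities descending and returns
#' `100 * sum((x_top - mu)^2) / sum((x - mu)^2)` where `mu` is the mean of
#' *all* intensities and `x_top` are the `ceiling(fraction * N)` largest.
#' On LC-orbitrap data a very small top fraction typically carries nearly
#' all the variance, which justifies treating the rest as background noise.
#'
#' @param all_intensities Non-empty numeric vector of intensities.
#' @param fraction Fraction in (0, 1] of points counted as "top".
#' @return Percent of total variance (0-100). A constant vector has zero
#'   total variance; by convention 100 is returned with a warning.
#' @export
variance_explained <- function(all_intensities, fraction) {
  x <- all_intensities
  if (!is.numeric(x) || length(x) == 0L)
    stop("all_intensities must be a non-empty numeric vector")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  mu <- mean(x)
  tot <- sum((x - mu)^2)
  if (tot == 0) {
    warning("constant intensity vector: total variance is zero; returning 100")
    return(100)
  }
  k <- ceiling(fraction * length(x))
  xs <- sort(x, decreasing = TRUE)[seq_len(k)]
  100 * sum((xs - mu)^2) / tot
}

#' Group counts over a sweep of closeness tolerances
#'
#' Applies [group_by_mz()] at each tolerance and returns the number of
#' groups. Counts are monotonically non-increasing in the tolerance, since
#' single-linkage groups can only merge as the gap tolerance grows.
#'
#' @param points As in [group_by_mz()].
#' @param ppm_values Positive, ascending numeric vector of tolerances.
#' @return Integer vector of group counts, named by tolerance.
#' @export
sweep_closeness <- function(points, ppm_values) {
  if (!is.numeric(ppm_values) || !length(ppm_values) ||
      any(ppm_values <= 0) || is.unsorted(ppm_values))
    stop("ppm_values must be positive and ascending")
  counts <- vapply(ppm_values,
                   function(p) nrow(group_by_mz(points, p)$groups),
                   integer(1))
  names(counts) <- ppm_values
  counts
}
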