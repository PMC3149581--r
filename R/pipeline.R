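# End-to-end pipeline: collect -> group -> represent -> extract -> quantify
# -> (optionally) annotate, returning one classed result object.

#' Pipeline configuration
#'
#' Bundles every tunable parameter with its default. Defaults follow the
#' method's standard settings: the top 1 percent of each sample's points is
#' treated as signal, m/z grouping and chromatogram extraction both use a
#' 5 ppm tolerance, and quantification uses conventional chromatography
#' defaults (S/N gate 3 on a 3-scan-sigma Gaussian-smoothed trace, minimum
#' region length 3 scans, stretched-trace fraction 0.8, annotation at 5 ppm
#' for `[M+H]+`).
#'
#' @param top_fraction Fraction in (0, 1] of points collected per sample.
#' @param closeness_ppm Neighbor-gap grouping tolerance (ppm).
#' @param eic_tol_ppm Chromatogram window half-width (ppm).
#' @param sn_cutoff Signal-to-noise gate multiple.
#' @param gaussian_sigma_scans Smoothing kernel sigma (scans).
#' @param min_region_scans Minimum peak-region length (scans).
#' @param stretch_fraction Stretched-chromatogram fraction threshold.
#' @param adducts Adduct names used for annotation.
#' @param annotation_tol_ppm Annotation matching tolerance (ppm).
#' @return Named list of validated parameters, class `"amdorap_config"`.
#' @export
amdorap_config <- function(top_fraction = 0.01, closeness_ppm = 5,
                           eic_tol_ppm = 5, sn_cutoff = 3,
                           gaussian_sigma_scans = 3, min_region_scans = 3,
                           stretch_fraction = 0.8, adducts = "[M+H]+",
                           annotation_tol_ppm = 5) {
  cfg <- list(top_fraction = top_fraction, closeness_ppm = closeness_ppm,
              eic_tol_ppm = eic_tol_ppm, sn_cutoff = sn_cutoff,
              gaussian_sigma_scans = gaussian_sigma_scans,
              min_region_scans = min_region_scans,
              stretch_fraction = stretch_fraction, adducts = adducts,
              annotation_tol_ppm = annotation_tol_ppm)
  num <- cfg[setdiff(names(cfg), "adducts")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  logical(1))))
    stop("all numeric configuration values must be single positive numbers")
  if (cfg$top_fraction > 1) stop("top_fraction must be in (0, 1]")
  class(cfg) <- "amdorap_config"
  cfg
}

#' Run the full m/z detection pipeline
#'
#' Collects the top intensity fraction of each sample, pools and groups the
#' points by ppm closeness, takes each group's median m/z as representative,
#' extracts a narrow ion chromatogram per group from every sample on that
#' sample's own scan grid, quantifies each chromatogram (total EIC sum and
#' S/N-gated area) and classifies it (peak-region count, reliability).
#' Optionally annotates the representative m/z values against a compound
#' table.
#'
#' @param runs A [centroid_run()] or a list of them (sample ids must be
#'   unique).
#' @param config An [amdorap_config()].
#' @param compound_db Optional compound table (data frame with `name` and
#'   `formula`) for annotation.
#' @param keep_chromatograms Keep the extracted traces in the result (needed
#'   for plotting; default `TRUE`).
#' @return Object of class `"amdorap"`: list with `groups` (per-group m/z
#'   summary plus annotation), `quant` (long per-group, per-sample
#'   quantification), `chromatograms` (nested list, or `NULL`),
#'   `sample_ids`, `config`, `n_points_collected` and `call`. Use
#'   `as.data.frame()` for the wide feature table.
#' @examples
#' sc <- sim_scenario(sim_compound(200, 10, 0.5, 1e5), n_scans = 60,
#'                    run_minutes = 20, noise_points_per_scan = 40,
#'                    seed = 4, min_peak_intensity = 500)
#' res <- amdorap(simulate_run(sc)$run,
#'                config = amdorap_config(top_fraction = 0.02))
#' res
#' @export
amdorap <- function(runs, config = amdorap_config(), compound_db = NULL,
                    keep_chromatograms = TRUE) {
  cl <- match.call()
  if (inherits(runs, "centroid_run")) runs <- list(runs)
  stopifnot(inherits(config, "amdorap_config"))
  ids <- vapply(runs, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  pooled <- collect_data_points(runs, config$top_fraction)
  grp <- group_by_mz(pooled, config$closeness_ppm)
  groups <- grp$groups
  names(groups)[names(groups) == "mz_median"] <- "mz"

  quant <- vector("list", length(runs))
  chroms <- if (keep_chromatograms)
    stats::setNames(vector("list", length(runs)), ids)
  for (j in seq_along(runs)) {
    run <- runs[[j]]
    ord <- order(run$points$mz)
    rows <- vector("list", nrow(groups))
    traces <- if (keep_chromatograms) vector("list", nrow(groups))
    for (g in seq_len(nrow(groups))) {
      ch <- .eic(run, groups$mz[g], config$eic_tol_ppm, ord)
      q <- quantify_chromatogram(
        ch, sn_cutoff = config$sn_cutoff,
        gaussian_sigma_scans = config$gaussian_sigma_scans,
        min_region_scans = config$min_region_scans,
        stretch_fraction = config$stretch_fraction)
      rows[[g]] <- cbind(group = groups$group[g], q)
      if (keep_chromatograms) traces[[g]] <- ch
    }
    quant[[j]] <- do.call(rbind, rows)
    if (keep_chromatograms) chroms[[j]] <- traces
  }
  quant <- do.call(rbind, quant)
  rownames(quant) <- NULL

  groups$annotation <- ""
  if (!is.null(compound_db) && nrow(groups)) {
    ann <- annotate(groups$mz, compound_db, adducts = config$adducts,
                    tol_ppm = config$annotation_tol_ppm)
    if (nrow(ann)) {
      gi <- match(ann$query_mz, groups$mz)  # queries were exactly groups$mz
      lab <- tapply(sprintf("%s %s (%.2f ppm)", ann$name, ann$adduct,
                            ann$error_ppm),
                    gi, paste, collapse = "; ")
      groups$annotation[as.integer(names(lab))] <- unname(lab)
    }
  }

  structure(list(groups = groups, quant = quant,
                 chromatograms = if (keep_chromatograms) chroms,
                 sample_ids = ids, config = config,
                 n_points_collected = nrow(pooled), call = cl),
            class = "amdorap")
}

#' @export
print.amdorap <- function(x, ...) {
  cat("Single-step m/z detection result\n")
  cat(sprintf("  samples: %s\n", paste(x$sample_ids, collapse = ", ")))
  cat(sprintf("  %d points collected (top %g%% per sample)\n",
              x$n_points_collected, 100 * x$config$top_fraction))
  cat(sprintf("  %d m/z groups at %g ppm closeness\n",
              nrow(x$groups), x$config$closeness_ppm))
  n_ann <- sum(nzchar(x$groups$annotation))
  if (n_ann) cat(sprintf("  %d groups annotated\n", n_ann))
  invisible(x)
}

#' @export
summary.amdorap <- function(object, ...) {
  q <- object$quant
  per_sample <- do.call(rbind, lapply(object$sample_ids, function(s) {
    qs <- q[q$sample_id == s, ]
    data.frame(sample_id = s,
               n_chromatograms = nrow(qs),
               reliable = sum(qs$reliable),
               one_peak = sum(qs$n_peak_regions == 1L),
               two_peaks = sum(qs$n_peak_regions == 2L),
               more_peaks = sum(qs$n_peak_regions > 2L),
               no_peak = sum(qs$n_peak_regions == 0L))
  }))
  out <- list(n_groups = nrow(object$groups),
              mz_range = range(object$groups$mz),
              config = object$config, per_sample = per_sample)
  class(out) <- "summary.amdorap"
  out
}

#' @export
print.summary.amdorap <- function(x, ...) {
  cat(sprintf("%d m/z groups (%.5f - %.5f)\n",
              x$n_groups, x$mz_range[1], x$mz_range[2]))
  cat("\nPer-sample chromatogram classification:\n")
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}

#' Wide feature table of an analysis result
#'
#' One row per m/z group: representative m/z, pooled point count, per-sample
#' EIC sum, S/N-gated area and peak-region count, an overall reliability
#' flag (`TRUE` when the chromatogram is reliable in every sample) and the
#' annotation string.
#'
#' @param x An `"amdorap"` object.
#' @param ... Unused.
#' @return Data frame, deterministic column order (samples in input order).
#' @export
as.data.frame.amdorap <- function(x, ...) {
  out <- data.frame(group = x$groups$group, mz = x$groups$mz,
                    n_points = x$groups$n_points)
  for (s in x$sample_ids) {
    qs <- x$quant[x$quant$sample_id == s, ]
    i <- match(x$groups$group, qs$group)
    out[[paste0("eic_sum.", s)]] <- qs$eic_sum[i]
    out[[paste0("sn_area.", s)]] <- qs$sn_area[i]
    out[[paste0("n_peaks.", s)]] <- qs$n_peak_regions[i]
  }
  rel <- tapply(x$quant$reliable, x$quant$group, all)
  out$reliable <- as.logical(rel[as.character(x$groups$group)])
  out$annotation <- x$groups$annotation
  rownames(out) <- NULL
  out
}

#' Plot extracted chromatograms of a group
#'
#' Overlays the per-sample extracted ion chromatograms of one m/z group
#' (each on its own sample's scan grid, no retention-time alignment).
#'
#' @param x An `"amdorap"` object built with `keep_chromatograms = TRUE`.
#' @param group Group index to plot (default 1).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.amdorap <- function(x, group = 1, ...) {
  if (is.null(x$chromatograms))
    stop("result was built with keep_chromatograms = FALSE")
  chs <- lapply(x$chromatograms, `[[`, group)
  cols <- grDevices::hcl.colors(max(2L, length(chs)), "Dark 2")
  rts <- lapply(chs, `[[`, "rt")
  ints <- lapply(chs, `[[`, "intensity")
  graphics::plot(NA, xlim = range(unlist(rts)), ylim = c(0, max(unlist(ints))),
                 xlab = "retention time (min)", ylab = "intensity",
                 main = sprintf("group %d: m/z %.5f +/- %g ppm", group,
                                x$groups$mz[group], x$config$eic_tol_ppm), ...)
  for (j in seq_along(chs))
    graphics::lines(rts[[j]], ints[[j]], col = cols[j], lty = j)
  graphics::legend("topright", legend = x$sample_ids,
                   col = cols[seq_along(chs)], lty = seq_along(chs), bty = "n")
  invisible(x)
}

#' Run the pipeline on mzML files and write its outputs
#'
#' Reads centroid mzML runs, executes [amdorap()], and writes to `out_dir`:
#' `features.tsv` (the wide feature table via [write_feature_table()]),
#' `chromatograms.tsv` (long per-group, per-sample traces) and `run.log`
#' (the full effective configuration, input files and group count, so every
#' run is reproducible from its log). Output is byte-identical for
#' identical inputs and configuration.
#'
#' @param mzml_paths Character vector of mzML input paths (>= 1).
#' @param out_dir Output directory, created if missing.
#' @param config An [amdorap_config()].
#' @param compound_table Optional path to a compound table for annotation.
#' @return The `"amdorap"` object, invisibly.
#' @export
run_pipeline <- function(mzml_paths, out_dir, config = amdorap_config(),
                         compound_table = NULL) {
  if (!length(mzml_paths)) stop("at least one input mzML file is required")
  missing_in <- mzml_paths[!file.exists(mzml_paths)]
  if (length(missing_in))
    stop("input file does not exist: ", paste(missing_in, collapse = ", "))
  runs <- lapply(mzml_paths, read_centroid_run)
  db <- if (!is.null(compound_table)) load_compound_table(compound_table)
  res <- amdorap(runs, config = config, compound_db = db,
                 keep_chromatograms = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(as.data.frame(res), file.path(out_dir, "features.tsv"))
  ch_long <- do.call(rbind, lapply(res$sample_ids, function(s) {
    do.call(rbind, lapply(seq_len(nrow(res$groups)), function(g) {
      ch <- res$chromatograms[[s]][[g]]
      data.frame(group = g, sample_id = s, rt = ch$rt,
                 intensity = ch$intensity)
    }))
  }))
  utils::write.table(ch_long, file.path(out_dir, "chromatograms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(
    "# m/z detection pipeline run log",
    paste0("input: ", mzml_paths),
    if (!is.null(compound_table)) paste0("compound_table: ", compound_table),
    vapply(names(unclass(config)), function(k)
      paste0("config.", k, ": ",
             paste(config[[k]], collapse = ",")), character(1)),
    paste0("points_collected: ", res$n_points_collected),
    paste0("n_groups: ", nrow(res$groups)))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(res)
}
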