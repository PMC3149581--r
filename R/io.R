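# Reading centroid-mode mzML runs, compound tables in, feature tables out.
# All mzML access goes through Bioconductor's mzR (proteowizard backend).

#' Construct a centroid run
#'
#' A `centroid_run` holds one sample's MS1 centroid data: the retention-time
#' grid (one value per scan, minutes, strictly ascending) and a data frame of
#' data points `(scan, rt, mz, intensity)` with `scan` a 1-based index into
#' the grid. Points are stored sorted by scan, then m/z; intensities and m/z
#' must be positive.
#'
#' @param sample_id Text label for the sample.
#' @param rt Numeric vector of scan retention times in minutes, ascending.
#' @param points Data frame with columns `scan`, `mz`, `intensity` (an `rt`
#'   column, if present, is replaced by the grid value of each point's scan).
#' @return An object of class `"centroid_run"`.
#' @export
centroid_run <- function(sample_id, rt, points) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.numeric(rt), length(rt) >= 1L)
  if (is.unsorted(rt, strictly = TRUE))
    stop("scan retention times must be strictly ascending")
  need <- c("scan", "mz", "intensity")
  if (!all(need %in% names(points)))
    stop("points must have columns: ", paste(need, collapse = ", "))
  points <- as.data.frame(points)[, need]
  if (nrow(points)) {
    if (any(points$scan < 1L) || any(points$scan > length(rt)))
      stop("point scan index outside the scan grid")
    if (any(points$mz <= 0) || any(points$intensity <= 0))
      stop("all m/z and intensity values must be positive")
    points <- points[order(points$scan, points$mz), , drop = FALSE]
  }
  points$rt <- rt[points$scan]
  points <- points[, c("scan", "rt", "mz", "intensity")]
  rownames(points) <- NULL
  structure(list(sample_id = sample_id, rt = rt, points = points),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  cat("<centroid_run> sample:", x$sample_id, "\n")
  cat(sprintf("  %d MS1 scans, rt %.3f-%.3f min, %d data points\n",
              length(x$rt), min(x$rt), max(x$rt), nrow(x$points)))
  invisible(x)
}

#' Number of scans in a centroid run
#' @param run A `centroid_run`.
#' @return Integer scan count.
#' @export
n_scans <- function(run) length(run$rt)

#' Read a centroid-mode mzML run
#'
#' Reads an mzML file through `mzR`, keeps only MS1 scans (in acquisition
#' order, which must be ascending in retention time), sorts each scan's peaks
#' by m/z and drops non-positive intensities. Retention times are normalized
#' to minutes regardless of the unit stored in the file. Spectra flagged as
#' profile mode are a hard error: this pipeline requires centroided input,
#' and profile-to-centroid conversion is a vendor/converter responsibility.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @return A [centroid_run()].
#' @export
read_centroid_run <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot read mzML file '", path,
                                          "': ", conditionMessage(e)))
  on.exit(mzR::close(ms), add = TRUE)
  hd <- mzR::header(ms)
  if (nrow(hd) == 0L) stop("mzML file '", path, "' contains no spectra")
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) stop("mzML file '", path, "' contains no MS1 spectra")
  prof <- ms1[!is.na(hd$centroided[ms1]) & !hd$centroided[ms1]]
  if (length(prof))
    stop("profile-mode spectrum in '", path, "' (scan seqNum ", prof[1L],
         "); centroid data required")
  rt <- hd$retentionTime[ms1] / 60  # mzR reports seconds
  pk <- mzR::peaks(ms, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  pts <- do.call(rbind, lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    keep <- m[, 2L] > 0 & m[, 1L] > 0
    if (!any(keep)) return(NULL)
    m <- m[keep, , drop = FALSE]
    data.frame(scan = i, mz = m[, 1L], intensity = m[, 2L])
  }))
  if (is.null(pts))
    pts <- data.frame(scan = integer(), mz = numeric(), intensity = numeric())
  centroid_run(sample_id, rt, pts)
}

#' Load a compound table
#'
#' Reads a delimited text file with at least `name` and `formula` columns
#' (tab-separated by default, comma-separated for `.csv`). Every formula is
#' validated with [parse_formula()]; an unparseable formula is an error that
#' names the offending row.
#'
#' @param path Path to the table.
#' @return Data frame with columns `name` and `formula`.
#' @export
load_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table does not exist: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("name", "formula") %in% names(tab)))
    stop("compound table must have 'name' and 'formula' columns: ", path)
  for (i in seq_len(nrow(tab))) {
    tryCatch(parse_formula(tab$formula[i]), error = function(e)
      stop("row ", i, " ('", tab$name[i], "') of ", path, ": ",
           conditionMessage(e), call. = FALSE))
  }
  tab[, c("name", "formula")]
}

#' Write a feature table
#'
#' Writes one row per m/z group as tab-separated UTF-8 text with a single
#' header row. Representative m/z is printed with 5 decimal places and ppm
#' values with 2, matching the reporting precision used throughout.
#'
#' @param features Feature data frame, e.g. `as.data.frame()` of an
#'   [amdorap()] result: a numeric `mz` column plus per-sample
#'   quantification columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  out <- features
  if ("mz" %in% names(out)) out$mz <- sprintf("%.5f", out$mz)
  ppm_cols <- grep("ppm", names(out), value = TRUE)
  for (cl in ppm_cols)
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.2f", out[[cl]])
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a centroid run to mzML
#'
#' Serializes a [centroid_run()] as centroid-mode MS1 mzML through
#' `mzR::writeMSData()`, so that [read_centroid_run()] round-trips scan
#' count, retention times and all (m/z, intensity) pairs. Retention times
#' are stored in seconds per the mzML convention.
#'
#' @param run A `centroid_run` with at least one scan; every scan must carry
#'   at least one peak.
#' @param path Output file path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "centroid_run"))
  ns <- n_scans(run)
  if (ns < 1L || nrow(run$points) == 0L)
    stop("cannot write an empty run: mzML requires at least one spectrum ",
         "with peaks")
  counts <- tabulate(run$points$scan, nbins = ns)
  if (any(counts == 0L))
    stop("every scan must contain at least one peak to be serialized ",
         "(scan ", which(counts == 0L)[1L], " is empty)")
  idx <- split(seq_len(nrow(run$points)), run$points$scan)
  pk <- lapply(idx, function(i)
    cbind(mz = run$points$mz[i], intensity = run$points$intensity[i]))
  tic <- vapply(pk, function(m) sum(m[, 2L]), numeric(1))
  bpi <- vapply(pk, function(m) which.max(m[, 2L]), integer(1))
  hdr <- data.frame(
    seqNum = seq_len(ns), acquisitionNum = seq_len(ns),
    msLevel = 1L, polarity = 1L,
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = run$rt * 60,
    basePeakMZ = mapply(function(m, i) m[i, 1L], pk, bpi),
    basePeakIntensity = mapply(function(m, i) m[i, 2L], pk, bpi),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) min(m[, 1L]), numeric(1)),
    highMZ = vapply(pk, function(m) max(m[, 1L]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(ns)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(pk), file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
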