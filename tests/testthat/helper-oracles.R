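# Shared fixtures and independent oracles used across test files.

# Brute-force single-linkage clustering under the ppm-gap predicate:
# connect two values when their difference relative to the smaller one is
# within `ppm`, then take connected components. Independent of the sorted
# single-pass implementation in group_by_mz().
brute_force_groups <- function(mz, ppm) {
  o <- order(mz)
  m <- mz[o]
  n <- length(m)
  adj <- outer(m, m, function(a, b) abs(b - a) / pmin(a, b) * 1e6) <= ppm
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[1L]
        stack <- stack[-1L]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  # partition as a list of sorted member values, ordered by minimum
  parts <- split(m, comp)
  parts[order(vapply(parts, min, numeric(1)))]
}

# Random clustered m/z instance: a few tight ppm-scale clusters plus
# scattered singletons, the regime the grouping step faces.
random_mz_instance <- function(n_max = 200) {
  n <- sample(2:n_max, 1L)
  n_clust <- sample(1:8, 1L)
  centers <- runif(n_clust, 70, 1500)
  mz <- numeric(n)
  which_c <- sample(n_clust, n, replace = TRUE)
  jit <- rnorm(n, 0, runif(1, 0.5, 6))           # ppm-scale spread
  mz <- centers[which_c] * (1 + jit * 1e-6)
  scatter <- runif(n) < 0.3
  mz[scatter] <- runif(sum(scatter), 70, 1500)
  mz
}

# Minimal in-memory run: one scan per rt, peaks given as a data frame.
make_run <- function(sample_id, rt, scan, mz, intensity) {
  centroid_run(sample_id, rt,
               data.frame(scan = scan, mz = mz, intensity = intensity))
}

# Write an mzML file directly through mzR with full control over msLevel and
# the centroided flag, to exercise read_centroid_run()'s filtering and its
# profile-mode rejection (write_mzml() itself only emits centroid MS1).
write_raw_mzml <- function(path, peak_list, rt_seconds, ms_level,
                           centroided = TRUE) {
  n <- length(peak_list)
  ms_level <- rep_len(ms_level, n)
  centroided <- rep_len(centroided, n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(ms_level), polarity = 1L,
    peaksCount = vapply(peak_list, nrow, integer(1)),
    totIonCurrent = vapply(peak_list, function(m) sum(m[, 2L]), numeric(1)),
    retentionTime = rt_seconds,
    basePeakMZ = vapply(peak_list, function(m) m[which.max(m[, 2L]), 1L],
                        numeric(1)),
    basePeakIntensity = vapply(peak_list, function(m) max(m[, 2L]),
                               numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(peak_list, function(m) min(m[, 1L]), numeric(1)),
    highMZ = vapply(peak_list, function(m) max(m[, 1L]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = centroided, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(peak_list), file = path, header = hdr,
                   outformat = "mzml")
  path
}

# Small two-compound scenario used by several integration tests: narrow
# peaks, light noise floor, fast to simulate.
small_scenario <- function(seed = 11, compounds = NULL) {
  if (is.null(compounds))
    compounds <- list(
      sim_compound(150.05, 6, 0.4, 2e5),
      sim_compound(320.20, 14, 0.4, 3e5))
  sim_scenario(compounds, n_scans = 200, run_minutes = 20,
               noise_points_per_scan = 30, noise_intensity_scale = 20,
               min_peak_intensity = 1000, seed = seed)
}
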