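test_that("collection keeps the per-sample top fraction, ties included", {
  set.seed(101)
  ints <- sample(1:1000)                     # distinct intensities
  run <- make_run("a", rt = seq(0.1, 100, length.out = 1000),
                  scan = 1:1000, mz = runif(1000, 70, 1500),
                  intensity = ints)
  # identity case
  expect_identical(nrow(collect_data_points(run, 1.0)), 1000L)
  # top 1% of 1000 distinct values == the 10 largest, by full-sort oracle
  got <- collect_data_points(run, 0.01)
  expect_identical(sort(got$intensity), sort(sort(ints, decreasing = TRUE)[1:10]))
  # ties at the threshold are all retained
  run_tie <- make_run("a", rt = 1:4 / 10, scan = 1:4, mz = c(100, 200, 300, 400),
                      intensity = c(9, 5, 5, 1))
  expect_identical(sort(collect_data_points(run_tie, 0.5)$intensity),
                   c(5, 5, 9))
  expect_error(collect_data_points(run, 0), "\\(0, 1]")
  expect_error(collect_data_points(run, 1.2), "\\(0, 1]")
})

test_that("thresholding is per sample, not pooled, and scale-invariant", {
  set.seed(7)
  mk <- function(id, scale) make_run(id, rt = 1:200 / 10, scan = 1:200,
                                     mz = runif(200, 70, 1500),
                                     intensity = scale * sample(1:200))
  bright <- mk("bright", 100)
  dim_run <- mk("dim", 1)
  got <- collect_data_points(list(bright, dim_run), 0.01)
  expect_identical(unname(table(got$sample_id)["dim"]),
                   unname(table(got$sample_id)["bright"]))
  expect_identical(nrow(got), 4L)
  # scaling one sample's intensities does not change which of ITS points pass
  dim_scaled <- dim_run
  dim_scaled$points$intensity <- dim_run$points$intensity * 17.3
  a <- collect_data_points(list(bright, dim_run), 0.05)
  b <- collect_data_points(list(bright, dim_scaled), 0.05)
  expect_identical(a$mz[a$sample_id == "dim"], b$mz[b$sample_id == "dim"])
  expect_identical(a$mz[a$sample_id == "bright"],
                   b$mz[b$sample_id == "bright"])
})

test_that("ppm grouping follows the neighbor-gap rule with chaining", {
  # gaps 4.0 and 11.0 ppm at 5 ppm tolerance -> two groups
  g <- group_by_mz(c(100.0000, 100.0004, 100.0015), 5)
  expect_identical(nrow(g$groups), 2L)
  expect_identical(g$groups$n_points, c(2L, 1L))
  # chain of 4-ppm steps spanning 12 ppm total -> one group (no span limit)
  chain <- c(100.0000, 100.0004, 100.0008, 100.0012)
  g2 <- group_by_mz(chain, 5)
  expect_identical(nrow(g2$groups), 1L)
  expect_identical(g2$groups$n_points, 4L)
  # single point -> singleton group
  g3 <- group_by_mz(500.25, 5)
  expect_identical(nrow(g3$groups), 1L)
  expect_identical(g3$groups$mz_median, 500.25)
  expect_error(group_by_mz(numeric(0), 5), "empty")
  expect_error(group_by_mz(c(100, 101), 0), "positive")
})

test_that("grouping partitions the input and ignores input order", {
  set.seed(42)
  mz <- random_mz_instance(150)
  g <- group_by_mz(mz, 5)
  expect_identical(sum(g$groups$n_points), length(mz))
  expect_identical(sort(g$points$mz), sort(mz))
  perm <- sample(length(mz))
  g2 <- group_by_mz(mz[perm], 5)
  expect_equal(g$groups, g2$groups)
  # representative lies inside the member range
  expect_true(all(g$groups$mz_median >= g$groups$mz_lo &
                  g$groups$mz_median <= g$groups$mz_hi))
})

test_that("grouping matches the brute-force single-linkage oracle", {
  set.seed(12)
  for (rep in 1:50) {
    mz <- random_mz_instance(120)
    ppm <- runif(1, 1, 15)
    got <- group_by_mz(mz, ppm)
    members <- split(got$points$mz, got$points$group)
    oracle <- brute_force_groups(mz, ppm)
    expect_identical(length(members), length(oracle))
    expect_equal(unname(members), unname(oracle))
  }
})

test_that("representative m/z is the pooled median with even-count mean", {
  expect_identical(representative_mz(c(106.0495, 106.0496, 106.0497)),
                   106.0496)
  expect_identical(representative_mz(c(100.0000, 100.0002)), 100.0001)
  # label-free: the median only sees the pooled values
  pts <- data.frame(mz = c(100.0000, 100.0001, 100.0002),
                    sample_id = c("a", "b", "a"))
  g <- group_by_mz(pts, 5)
  pts2 <- pts
  pts2$sample_id <- rev(pts$sample_id)
  expect_identical(representative_mz(g),
                   representative_mz(group_by_mz(pts2, 5)))
})

test_that("chromatogram extraction sums in-window peaks per scan", {
  run <- make_run("a", rt = c(1, 2, 3),
                  scan = c(1L, 2L, 2L, 3L),
                  mz = c(200.0000, 199.9999, 200.0004, 300),
                  intensity = c(5, 3, 4, 9))
  # no peak in window -> all-zero full-length trace
  ch0 <- extract_chromatogram(run, 150, 5)
  expect_identical(ch0$intensity, c(0, 0, 0))
  # both scan-2 peaks fall in a 5 ppm window around 200.0001 and sum
  ch <- extract_chromatogram(run, 200.0001, 5)
  expect_equal(ch$intensity, c(5, 7, 0))
  # inclusive window ends: a peak exactly at the boundary is kept
  center <- 400
  edge <- center * (1 + 5e-6)
  run2 <- make_run("a", rt = 1, scan = 1L, mz = edge, intensity = 2)
  expect_equal(extract_chromatogram(run2, center, 5)$intensity, 2)
})

test_that("an injected compound's trace conserves its total ion count", {
  sim <- simulate_run(small_scenario(seed = 31, compounds = list(
    sim_compound(150.05, 6, 0.4, 2e5))), "a")
  # remove noise from the run so the window holds only the compound
  keep <- abs(sim$run$points$mz / 150.05 - 1) < 2e-5
  pure <- centroid_run("a", sim$run$rt, sim$run$points[keep, 1:4])
  ch <- extract_chromatogram(pure, 150.05, 20)
  expect_equal(sum(ch$intensity), sim$truth$total_ion_count, tolerance = 1e-12)
})

test_that("variance explained follows the global-mean definition", {
  expect_identical(variance_explained(c(3, 1, 4, 1, 5), 1.0), 100)
  # hand-computed: mu = 2.8, top contribution 51.84 of 64.8
  expect_equal(variance_explained(c(10, 1, 1, 1, 1), 0.2), 80.0)
  expect_warning(v <- variance_explained(rep(2, 10), 0.5), "constant")
  expect_identical(v, 100)
  expect_error(variance_explained(numeric(0), 0.5), "non-empty")
  expect_error(variance_explained(1:5, 0), "\\(0, 1]")
})

test_that("noise-dominated simulated data concentrates variance in the top 1%", {
  sim <- simulate_run(default_scenario(seed = 3), "a")
  expect_gt(variance_explained(sim$run$points$intensity, 0.01), 95)
})

test_that("closeness sweep counts are monotonically non-increasing", {
  counts <- sweep_closeness(c(100.0000, 100.0004, 100.0015), c(3, 5, 12))
  expect_identical(unname(counts), c(3L, 2L, 1L))
  expect_identical(unname(sweep_closeness(500.1, c(1, 5, 20))), c(1L, 1L, 1L))
  set.seed(9)
  for (rep in 1:10) {
    mz <- random_mz_instance(100)
    counts <- sweep_closeness(mz, 1:20)
    expect_true(all(diff(counts) <= 0L))
  }
  expect_error(sweep_closeness(c(100, 101), c(5, 3)), "ascending")
})
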