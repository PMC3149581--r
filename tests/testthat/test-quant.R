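test_that("gaussian smoothing is normalized, conservative and linear", {
  # constant trace is a fixed point (edge renormalization included)
  expect_equal(gaussian_smooth(rep(4.2, 50), 3), rep(4.2, 50),
               tolerance = 1e-12)
  # unit impulse spreads into a symmetric bell of total mass 1
  imp <- c(rep(0, 50), 1, rep(0, 50))
  sm <- gaussian_smooth(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm, rev(sm), tolerance = 1e-12)
  expect_identical(which.max(sm), 51L)
  # interior-supported signal conserves its sum
  x <- numeric(200)
  x[80:120] <- 1e4 * exp(-((80:120) - 100)^2 / (2 * 5^2))
  expect_equal(sum(gaussian_smooth(x, 3)), sum(x), tolerance = 1e-9)
  # linearity and positivity
  expect_equal(gaussian_smooth(3.7 * x, 2.5), 3.7 * gaussian_smooth(x, 2.5),
               tolerance = 1e-12)
  expect_true(all(gaussian_smooth(x, 2.5) >= 0))
  expect_identical(length(gaussian_smooth(1, 3)), 1L)
})

test_that("noise estimation uses scaled MAD with a positive fallback chain", {
  # all-zero trace: MAD 0, no positive baseline -> 1.0
  expect_identical(estimate_noise(rep(0, 9)), 1.0)
  # single spike on exact-zero baseline: zero-MAD path, no positive
  # baseline variation at or below the median -> 1.0
  expect_identical(estimate_noise(c(0, 0, 0, 0, 100, 0, 0, 0, 0)), 1.0)
  # constant positive baseline estimates its own level
  expect_identical(estimate_noise(rep(5, 8)), 5)
  # Gaussian white noise sigma = 5 on a flat baseline, n = 2000
  set.seed(55)
  est <- estimate_noise(100 + rnorm(2000, 0, 5))
  expect_lt(abs(est - 5) / 5, 0.1)
  expect_error(estimate_noise(c(1, 2)), ">= 4")
})

test_that("peak regions are maximal gated runs above the S/N cutoff", {
  expect_identical(nrow(detect_peak_regions(rep(0, 20), 1, 3)), 0L)
  # one well-separated peak -> one region containing the apex scan
  x <- numeric(200)
  x[90:110] <- 1000 * exp(-((90:110) - 100)^2 / (2 * 3^2))
  sm <- gaussian_smooth(x, 3)
  r <- detect_peak_regions(sm, 1, 3)
  expect_identical(nrow(r), 1L)
  expect_true(r$start <= 100 && r$end >= 100)
  # two well-separated peaks -> two disjoint ordered regions
  x2 <- x
  x2[30:50] <- 800 * exp(-((30:50) - 40)^2 / (2 * 3^2))
  r2 <- detect_peak_regions(gaussian_smooth(x2, 3), 1, 3)
  expect_identical(nrow(r2), 2L)
  expect_true(r2$end[1] < r2$start[2])
  # runs shorter than min_scans are discarded
  y <- numeric(30)
  y[10:11] <- 100
  expect_identical(nrow(detect_peak_regions(y, 1, 3, min_scans = 3)), 0L)
  expect_identical(nrow(detect_peak_regions(y, 1, 3, min_scans = 2)), 1L)
})

test_that("region detection is translation-equivariant in the interior", {
  base <- numeric(300)
  bump <- 500 * exp(-(-15:15)^2 / (2 * 4^2))
  x1 <- base; x1[85:115] <- bump
  x2 <- base; x2[135:165] <- bump
  r1 <- detect_peak_regions(gaussian_smooth(x1, 3), 1, 3)
  r2 <- detect_peak_regions(gaussian_smooth(x2, 3), 1, 3)
  expect_identical(r2$start, r1$start + 50L)
  expect_identical(r2$end, r1$end + 50L)
})

test_that("quantification sums raw intensities, gated and total", {
  expect_identical(quantify_trace(rep(0, 10), data.frame(start = integer(),
                                                         end = integer())),
                   list(eic_sum = 0, sn_area = 0))
  x <- c(1, 5, 9, 5, 1, 0, 0, 2)
  # regions covering every scan: gated area equals the total
  q <- quantify_trace(x, data.frame(start = 1L, end = 8L))
  expect_identical(q$sn_area, q$eic_sum)
  q2 <- quantify_trace(x, data.frame(start = 2L, end = 4L))
  expect_identical(q2$sn_area, 19)
  expect_identical(q2$eic_sum, sum(x))
  expect_error(quantify_trace(x, data.frame(start = 1L, end = 99L)), "bounds")
})

test_that("gated area never exceeds the total EIC sum", {
  set.seed(77)
  for (rep in 1:25) {
    x <- rexp(150, 1 / 50) + sample(0:1, 1) *
      c(numeric(60), 1e4 * exp(-(-14:15)^2 / 18), numeric(60))
    sm <- gaussian_smooth(x, 3)
    noise <- estimate_noise(sm)
    r <- detect_peak_regions(sm, noise, 3)
    q <- quantify_trace(x, r)
    expect_lte(q$sn_area, q$eic_sum)
    expect_gte(q$sn_area, 0)
    if (nrow(r) == 0L) expect_identical(q$sn_area, 0)
  }
})

test_that("reliability flags catch stretched and noisy-baseline traces", {
  # clean peak occupying ~5% of scans is reliable
  x <- numeric(400)
  x[190:210] <- 1e4 * exp(-((190:210) - 200)^2 / (2 * 4^2))
  sm <- gaussian_smooth(x, 3)
  noise <- estimate_noise(sm)
  r <- detect_peak_regions(sm, noise, 3)
  expect_identical(flag_unreliable(sm, r, noise),
                   list(reliable = TRUE, reason = ""))
  # above threshold for 90% of the run -> stretched
  y <- c(numeric(40), rep(1000, 360))
  fy <- flag_unreliable(y, data.frame(start = 41L, end = 400L), noise = 1)
  expect_false(fy$reliable)
  expect_identical(fy$reason, "stretched")
  # dense isolated spikes of random height: detection finds no qualifying
  # region, yet far more than 20% of scans sit above the noise level
  set.seed(13)
  z <- numeric(400)
  z[seq(1, 400, by = 3)] <- 50 + rexp(134, 1 / 200)
  nz <- estimate_noise(z)
  rz <- detect_peak_regions(z, nz, 3)
  expect_identical(nrow(rz), 0L)
  fz <- flag_unreliable(z, rz, noise = nz)
  expect_false(fz$reliable)
  expect_identical(fz$reason, "noisy_baseline")
})

test_that("the per-chromatogram wrapper composes the chain coherently", {
  run <- simulate_run(small_scenario(seed = 41), "q")$run
  ch <- extract_chromatogram(run, 150.05, 5)
  q <- quantify_chromatogram(ch)
  expect_identical(q$sample_id, "q")
  expect_identical(q$n_peak_regions, 1L)
  expect_true(q$reliable)
  expect_lte(q$sn_area, q$eic_sum)
  expect_gt(q$sn_area, 0)
})
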