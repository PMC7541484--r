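test_that("peak picking finds a single noiseless Gaussian at its apex", {
  mz <- seq(1000, 1010, by = 0.02)
  y <- 500 * exp(-0.5 * ((mz - 1005) / 0.05)^2)
  pk <- process_spectrum(maldi_spectrum(mz, y), deisotope = FALSE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, 1005, tolerance = 0.02)
})

test_that("relative-intensity threshold removes sub-0.5% peaks", {
  mz <- seq(1000, 1040, by = 0.02)
  peak <- function(c0, h) h * exp(-0.5 * ((mz - c0) / 0.05)^2)
  y <- peak(1005, 1000) + peak(1015, 20) + peak(1025, 6) + peak(1035, 3)
  pk <- process_spectrum(maldi_spectrum(mz, y), deisotope = FALSE)
  expect_equal(nrow(pk), 3L)  # 0.3% peak dropped
  expect_false(any(abs(pk$mz - 1035) < 1))
})

test_that("deisotoping collapses an isotope envelope to its monoisotopic peak", {
  reps <- gen_maldi_replicates(marker_p1105(), alpha_true = 1,
                               n_replicates = 1, noise_sd = 0)
  pk <- process_spectrum(reps[[1]], deisotope = TRUE)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, monoisotopic_mh(marker_p1105()), tolerance = 0.02)
})

test_that("replicate averaging is the pointwise mean and reduces variance", {
  mz <- seq(1000, 1010, by = 0.05)
  base <- 100 + 50 * exp(-0.5 * ((mz - 1005) / 0.1)^2)
  s1 <- maldi_spectrum(mz, base)
  expect_equal(average_replicates(list(s1, s1, s1))$intensity, base)
  s2 <- maldi_spectrum(mz, 2 * base); s3 <- maldi_spectrum(mz, 3 * base)
  expect_equal(average_replicates(list(s1, s2, s3))$intensity, 2 * base)
  reps <- gen_maldi_replicates(marker_p1105(), 0.5, n_replicates = 5,
                               noise_sd = 0.05, seed = 4)
  avg <- average_replicates(reps)
  truth <- gen_maldi_replicates(marker_p1105(), 0.5, n_replicates = 1,
                                noise_sd = 0)[[1]]$intensity
  err_avg <- mean((avg$intensity - truth)^2)
  err_rep <- mean(sapply(reps, function(r) mean((r$intensity - truth)^2)))
  expect_lt(err_avg, err_rep)
  expect_error(average_replicates(list(
    s1, maldi_spectrum(seq(2000, 2010, 0.05), base))), "incompatible")
})

test_that("marker matching assigns nearest peak within tolerance", {
  pk <- structure(data.frame(mz = c(1004.2, 1105.58, 1190.0),
                             intensity = c(10, 100, 50), snr = c(5, 50, 20)),
                  class = c("peak_list", "data.frame"))
  mm <- match_markers(pk, tol = 0.2)
  expect_true(mm$matched[mm$marker == "P1105"])
  expect_equal(mm$mz[mm$marker == "P1105"], 1105.58)
  # no peak in tolerance: reported absent
  mm2 <- match_markers(pk[pk$mz < 1100, ], tol = 0.2)
  expect_false(mm2$matched)
  # equidistant tie breaks to the lower m/z
  exp_mz <- zooms_markers()$expected_mz[1]
  tie <- structure(data.frame(mz = c(exp_mz - 0.1, exp_mz + 0.1),
                              intensity = c(5, 50), snr = c(5, 50)),
                   class = c("peak_list", "data.frame"))
  mm3 <- match_markers(tie, tol = 0.2)
  expect_equal(mm3$mz, exp_mz - 0.1)
})

test_that("alpha estimation is exact in the pure and mixed noiseless limits", {
  p <- marker_p1105()
  tt <- isotope_distribution(p, 6)$relative_intensities
  expect_equal(estimate_alpha(c(tt, 0), p)$alpha, 1.0, tolerance = 1e-9)
  expect_equal(estimate_alpha(c(0, tt), p)$alpha, 0.0, tolerance = 1e-9)
  reps <- gen_maldi_replicates(p, 0.6, n_replicates = 1, noise_sd = 0)
  est <- estimate_alpha(reps[[1]], p)
  expect_equal(est$alpha, 0.6, tolerance = 1e-6)
  expect_lt(est$residual, 1e-6)
  expect_error(estimate_alpha(rep(0, 7), p), "all-zero")
})

test_that("alpha estimation is scale invariant and monotone in truth", {
  p <- marker_p1105()
  reps <- gen_maldi_replicates(p, 0.35, n_replicates = 1, noise_sd = 0)
  sp <- reps[[1]]
  scaled <- maldi_spectrum(sp$mz, sp$intensity * 123.4)
  expect_equal(estimate_alpha(scaled, p)$alpha,
               estimate_alpha(sp, p)$alpha, tolerance = 1e-9)
  alphas <- seq(0, 1, by = 0.1)
  est <- sapply(alphas, function(a) {
    r <- gen_maldi_replicates(p, a, n_replicates = 1, noise_sd = 0)
    estimate_alpha(r[[1]], p)$alpha
  })
  expect_true(all(diff(est) > 0))
})

test_that("weighted averaging of replicates handles failures as n.d.", {
  w <- weighted_alpha(data.frame(alpha = c(0.5, 0.5, 0.5),
                                 weight = c(1, 7, 2)))
  expect_equal(w$alpha, 0.5)
  w2 <- weighted_alpha(data.frame(alpha = c(0, 1), weight = c(1, 3)))
  expect_equal(w2$alpha, 0.75)
  # one failed replicate is dropped; all failed propagates n.d.
  w3 <- weighted_alpha(data.frame(alpha = c(0.4, NA), weight = c(2, 5)))
  expect_equal(w3$alpha, 0.4)
  nd <- weighted_alpha(data.frame(alpha = c(NA_real_, NA_real_),
                                  weight = c(1, 1)))
  expect_true(nd$nd)
  expect_true(is.na(nd$alpha))
  expect_error(weighted_alpha(data.frame(alpha = 0.5, weight = -1)), ">= 0")
})

test_that("alpha orientation matches deamidation frequency (1 - alpha)", {
  p <- marker_p1105()
  deam_freq <- 0.25  # one quarter of molecules deamidated
  reps <- gen_maldi_replicates(p, 1 - deam_freq, n_replicates = 3,
                               noise_sd = 0)
  est <- sample_alpha(reps, p)
  expect_equal(1 - est$alpha, deam_freq, tolerance = 1e-6)
})
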