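# ADC quantification: b-pair selection, both methods, first-order
# statistics, mask erosion.

test_that("b-value pair selection follows the low/high rule", {
  p <- select_bvalue_pair(c(50, 400, 800))
  expect_equal(c(p$b1, p$b2), c(50, 800))
  p <- select_bvalue_pair(c(50, 750, 1500))
  expect_equal(c(p$b1, p$b2), c(50, 750))
  p <- select_bvalue_pair(c(50, 750, 800))       # 800 preferred over 750
  expect_equal(p$b2, 800)
  expect_equal(select_bvalue_pair(c(100, 860))$b2, 860)
  expect_error(select_bvalue_pair(c(50, 400)), "available: 50, 400")
  expect_error(select_bvalue_pair(800), "at least two")
})

test_that("mean-signal ADC inverts the mono-exponential closed form", {
  mk <- function(s1, s2) {
    vols <- array(0, c(2, 2, 1, 2))
    vols[, , , 1] <- s1; vols[, , , 2] <- s2
    dwi_study(vols, c(50, 800))
  }
  mask <- voi_mask(array(TRUE, c(2, 2, 1)))
  expect_equal(as.numeric(adc_from_mean_signal(mk(100, 100), mask)), 0)
  # frozen: 100 * exp(-0.75 * 1.5) = 32.4652... -> ADC = 1.5e-3
  a <- adc_from_mean_signal(mk(100, 100 * exp(-0.75 * 1.5)), mask)
  expect_equal(as.numeric(a), 1.5e-3, tolerance = 1e-12)
  expect_false(attr(a, "flagged_negative"))
  expect_warning(neg <- adc_from_mean_signal(mk(100, 120), mask),
                 "negative ADC")
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "flagged_negative"))
  expect_error(adc_from_mean_signal(mk(0, 10), mask), "nonpositive mean")
})

test_that("voxel-wise map recovers an arbitrary noise-free field", {
  set.seed(51)
  D <- array(runif(6 * 5 * 4, 0.3e-3, 2.5e-3), dim = c(6, 5, 4))
  st <- study_from_field(D)
  m <- adc_map(st)
  expect_lt(max(abs(m - D) / D), 1e-10)
  # homogeneous phantom: every VOI voxel equals the constant exactly
  ph <- make_skin_phantom(small_spec(noise_sigma = 0), seed = 1)
  mp <- adc_map(ph$study, mask = ph$voi)
  expect_equal(mp[ph$voi], rep(1.5e-3, sum(ph$voi)), tolerance = 1e-12)
  # a voxel with zero high-b signal is invalid, excluded and counted
  st2 <- study_from_field(D)
  st2$volumes[1, 1, 1, 2] <- 0
  full <- voi_mask(array(TRUE, dim(D)))
  m2 <- adc_map(st2, mask = full)
  expect_true(is.na(m2[1, 1, 1]))
  expect_equal(attr(m2, "n_invalid"), 1L)
  s <- first_order_stats(m2, full)
  expect_equal(s$n_voxels_excluded, 1L)
  expect_equal(s$n_voxels_used + s$n_voxels_excluded, sum(full))
})

test_that("first-order statistics follow direct arithmetic", {
  m <- array(NA_real_, c(2, 2, 1))
  m[1, 1, 1] <- 0.5e-3; m[2, 1, 1] <- 1.0e-3
  m[1, 2, 1] <- 1.5e-3; m[2, 2, 1] <- 2.0e-3
  s <- first_order_stats(m, array(TRUE, c(2, 2, 1)))
  expect_equal(s$mean, 1.25e-3)
  expect_equal(s$median, 1.25e-3)     # even count: midpoint average
  expect_equal(s$min, 0.5e-3)
  expect_equal(s$max, 2.0e-3)
  one <- array(TRUE, c(2, 2, 1)) & FALSE; one[2, 2, 1] <- TRUE
  s1 <- first_order_stats(m, one)
  expect_true(all(unlist(s1[c("mean", "median", "min", "max")]) == 2.0e-3))
  expect_error(first_order_stats(array(NA_real_, c(2, 2, 1)),
                                 array(TRUE, c(2, 2, 1))), "no valid voxels")
})

test_that("order-statistic invariants hold on noisy maps", {
  for (seed in 1:5) {
    ph <- make_skin_phantom(small_spec(noise_sigma = 10), seed = seed)
    r <- adc_quantify(ph$study, ph$voi)
    expect_lte(r$summary$min, r$summary$median)
    expect_lte(r$summary$median, r$summary$max)
    expect_lte(r$summary$min, r$summary$mean)
    expect_lte(r$summary$mean, r$summary$max)
    expect_equal(r$n_voxels_used + r$n_voxels_excluded, sum(ph$voi))
  }
})

test_that("methods agree on a homogeneous noise-free VOI, not under noise", {
  ph <- make_skin_phantom(small_spec(noise_sigma = 0), seed = 3)
  r <- adc_quantify(ph$study, ph$voi)
  expect_lt(abs(r$adc_of_mean_signal - r$summary$mean) / r$summary$mean,
            1e-10)
  expect_lt(abs(r$adc_of_mean_signal - 1.5e-3) / 1.5e-3, 1e-10)
})

test_that("low-SNR Rician floor biases the measured ADC downward", {
  # at high-b VOI SNR < 2 the noise floor inflates the high-b mean signal,
  # so the measured ADC underestimates the truth
  sp <- small_spec(true_adc_lesion = 1.5e-3)
  sp$noise_sigma <- sp$S0 * exp(-800 * 1.5e-3) / 1.5   # SNR target 1.5
  adcs <- vapply(1:60, function(s) {
    ph <- make_skin_phantom(sp, seed = s)
    as.numeric(suppressWarnings(adc_from_mean_signal(ph$study, ph$voi)))
  }, numeric(1))
  expect_lt(mean(adcs), 1.5e-3)
})

test_that("erosion matches the brute-force oracle", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  er <- erode_mask(cube, 1)
  expect_equal(sum(er), 27)                       # 5^3 cube -> 3^3 core
  expect_identical(which(as.logical(er)), which(erode_oracle(cube)))
  set.seed(61)
  blob <- array(runif(8 * 7 * 6) > 0.35, dim = c(8, 7, 6))
  expect_identical(which(as.logical(erode_mask(blob, 0))), which(blob))
  oracle <- erode_oracle(blob)
  if (any(oracle)) {
    expect_identical(which(as.logical(erode_mask(blob, 1))), which(oracle))
  }
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_error(erode_mask(one, 1), "empties the mask")
  expect_error(erode_mask(cube, -1), ">= 0")
})
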