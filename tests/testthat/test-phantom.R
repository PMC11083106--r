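# Phantom generator: signal model, noise model, determinism, cohort layout.

test_that("noise-free phantom follows the mono-exponential closed form", {
  sp <- small_spec(noise_sigma = 0, true_adc_lesion = 1.5e-3,
                   b_values = c(50, 800))
  ph <- make_skin_phantom(sp, seed = 1)
  s50 <- ph$study$volumes[, , , 1][ph$voi]
  s800 <- ph$study$volumes[, , , 2][ph$voi]
  # every lesion voxel: S(800)/S(50) = exp(-0.75 * 1.5)
  expect_equal(s800 / s50, rep(exp(-0.75 * 1.5), sum(ph$voi)),
               tolerance = 1e-12)
  # noise ROI is exactly zero without noise
  expect_true(all(ph$study$volumes[, , , 1][ph$noise_roi] == 0))
  expect_true(all(ph$study$volumes[, , , 2][ph$noise_roi] == 0))
})

test_that("signal model conservation and b-monotonicity hold across specs", {
  set.seed(21)
  for (rep in 1:5) {
    sp <- small_spec(noise_sigma = 0,
                     true_adc_background = runif(1, 1e-3, 2.5e-3),
                     true_adc_skin = runif(1, 0.4e-3, 2e-3),
                     true_adc_lesion = runif(1, 0.5e-3, 2.5e-3),
                     b_values = c(50, 400, 800))
    ph <- make_skin_phantom(sp, seed = rep)
    v <- ph$study$volumes
    body <- v[, , , 1] > 0
    # ln(S_b1/S_b2)/(b2-b1) recovers the generating D(x) at every body voxel
    D_hat <- log(v[, , , 1][body] / v[, , , 3][body]) / (800 - 50)
    spec_D <- c(sp$true_adc_background, sp$true_adc_skin, sp$true_adc_lesion)
    rel_err <- vapply(D_hat, function(dh) min(abs(dh - spec_D) / spec_D),
                      numeric(1))
    expect_lt(max(rel_err), 1e-10)
    # lesion voxels carry exactly the lesion diffusivity
    D_les <- log(v[, , , 1][ph$voi] / v[, , , 3][ph$voi]) / 750
    expect_equal(D_les, rep(sp$true_adc_lesion, sum(ph$voi)),
                 tolerance = 1e-12)
    # strictly decreasing in b wherever there is signal
    expect_true(all(v[, , , 2][body] < v[, , , 1][body]))
    expect_true(all(v[, , , 3][body] < v[, , , 2][body]))
  }
})

test_that("identical (spec, seed) gives identical phantoms; seeds differ", {
  sp <- small_spec(noise_sigma = 4)
  a <- make_skin_phantom(sp, seed = 99)
  b <- make_skin_phantom(sp, seed = 99)
  expect_identical(a$study$volumes, b$study$volumes)
  expect_identical(a$truth, b$truth)
  c <- make_skin_phantom(sp, seed = 100)
  expect_false(identical(a$study$volumes, c$study$volumes))
})

test_that("invalid geometry is rejected with explicit messages", {
  expect_error(small_spec(lesion_center = c(23, 13, 4)), "outside the grid")
  expect_error(small_spec(body_radius = 12), "noise ROI overlaps the body")
  expect_error(small_spec(b_values = c(800, 50)), "strictly increasing")
  expect_error(small_spec(true_adc_lesion = 0), "> 0")
  expect_error(small_spec(noise_sigma = -1), ">= 0")
})

test_that("Rician noise has the Rayleigh mean and high-SNR limit", {
  expect_identical(add_rician_noise(array(5, c(2, 2, 2)), 0), array(5, c(2, 2, 2)))
  expect_error(add_rician_noise(array(1, c(2, 2, 2)), -0.1), ">= 0")
  sigma <- 7
  bg <- add_rician_noise(array(0, c(100, 100, 100)), sigma, seed = 31)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
  s <- 50 * sigma
  hi <- add_rician_noise(array(s, c(40, 40, 40)), sigma, seed = 32)
  expect_equal(mean(hi), s, tolerance = 0.005)
  # determinism under seed
  expect_identical(add_rician_noise(array(1, c(3, 3, 3)), 2, seed = 8),
                   add_rician_noise(array(1, c(3, 3, 3)), 2, seed = 8))
})

test_that("group diffusivity sampling matches its truncated law", {
  d <- default_group_distributions()
  expect_equal(d$SIBC$mean_adc, 1.38)
  expect_equal(d$SIBC$sd_adc, 0.13 * sqrt(11))
  x <- sample_group_diffusivity(d$SIBC, 1e4, seed = 41)
  expect_equal(mean(x), 1.38, tolerance = 0.02)
  expect_true(all(x >= 0.73 & x <= 1.98))
  # distributional recovery: empirical moments approach the truncated law
  tn_mean <- function(mu, sig, lo, hi) {
    a <- (lo - mu) / sig; b <- (hi - mu) / sig
    mu + sig * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_equal(mean(x), tn_mean(1.38, 0.13 * sqrt(11), 0.73, 1.98),
               tolerance = 0.01)
  expect_identical(sample_group_diffusivity(d$BSI, 5, seed = 2),
                   sample_group_diffusivity(d$BSI, 5, seed = 2))
  expect_error(group_distribution("SIBC", 1.4, 0.4, c(1.4, 1.4), 5),
               "degenerate")
  expect_error(sample_group_diffusivity(d$SIBC, 0), ">= 1")
})

test_that("simulate_cohort reproduces the study's population layout", {
  co <- simulate_cohort(seed = 6, spec_base = small_spec())
  expect_equal(nrow(co$manifest), 88)
  tab <- table(co$truth$group)
  expect_equal(as.integer(tab[c("PD", "IBC", "BSI", "SIBC", "H")]),
               c(3, 5, 11, 11, 58))
  # healthy VOIs: single axial slice, 29 voxels
  h <- co$phantoms[[which(co$truth$group == "H")[1]]]
  expect_equal(sum(h$voi), 29)
  zs <- unique(which(h$voi, arr.ind = TRUE)[, 3])
  expect_length(zs, 1L)
  # pathology VOIs span >= 3 slices
  sib <- co$phantoms[[which(co$truth$group == "SIBC")[1]]]
  expect_gte(length(unique(which(sib$voi, arr.ind = TRUE)[, 3])), 3L)
  # ground truth stays inside each group's truncation range
  d <- default_group_distributions()
  for (g in names(d)) {
    v <- co$truth$true_voi_adc[co$truth$group == g]
    expect_true(all(v >= d[[g]]$truncation_range[1] &
                    v <= d[[g]]$truncation_range[2]))
  }
  # n = 0 drops a group silently; unknown labels are rejected
  co2 <- simulate_cohort(n = c(PD = 0, IBC = 1, BSI = 1, SIBC = 1, H = 1),
                         seed = 6, spec_base = small_spec())
  expect_false("PD" %in% co2$truth$group)
  expect_error(simulate_cohort(n = c(XX = 2), seed = 1), "unknown group")
})

test_that("snr_target calibration: measured SNR lands near the target", {
  # default geometry: its 64-voxel noise ROI keeps the sigma-estimate
  # spread well inside the +-20% band
  co <- simulate_cohort(n = c(SIBC = 20, BSI = 20), snr_target = 50,
                        seed = 17)
  snrs <- vapply(co$phantoms, function(ph)
    compute_snr(ph$study, ph$voi, ph$noise_roi)$high$snr, numeric(1))
  expect_gte(mean(snrs >= 40 & snrs <= 60), 0.95)
})
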