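test_that("SNR maps recover a known noise level from repeated STE", {
  p <- default_protocol()
  dims <- c(25, 20, 20)                 # 10^4 voxels
  nvox <- prod(dims)
  data <- array(0, c(dims, p$n_samples))
  e <- p$entries
  set.seed(31)
  # per-volume signal S = 1 with Gaussian noise sd S/10: true SNR = 10
  for (v in seq_len(p$n_samples))
    data[, , , v] <- 1 + rnorm(nvox, 0, 0.1)
  md <- array(1.0, dims)
  rep_ <- snr_map(data, p, md)
  snr_hi <- rep_$snr_maps[["2"]]
  expect_equal(median(snr_hi), 10, tolerance = 0.1)
  expect_equal(rep_$b_highest, 2)
  expect_gte(rep_$Q3, rep_$Q6)          # threshold nesting
  # scale invariance of SNR and Q statistics
  rep2 <- snr_map(data * 7, p, md)
  expect_equal(rep2$Q3, rep_$Q3)
  expect_equal(median(rep2$snr_maps[["2"]]), median(snr_hi), tolerance = 1e-9)
})

test_that("SNR edge cases: constant repeats, strong signal, thin masks", {
  p <- default_protocol()
  dims <- c(2, 2, 1)
  data <- array(1, c(dims, p$n_samples))
  md <- array(c(1, 1, 1, 2), dims)      # one voxel beyond the MD mask
  rep_ <- snr_map(data, p, md)
  # zero variance across repeats: flagged infinite, excluded from fractions
  expect_true(all(is.infinite(rep_$snr_maps[["2"]])))
  expect_true(is.na(rep_$Q3))
  expect_equal(sum(rep_$mask), 3)       # MD = 2 voxel excluded
  # all voxels far above threshold: Q3 = Q6 = 100%
  set.seed(5)
  data2 <- data + array(rnorm(length(data), 0, 0.01), dim(data))
  rep2 <- snr_map(data2, p, md)
  expect_equal(rep2$Q3, 1)
  expect_equal(rep2$Q6, 1)
  # a single STE repeat cannot give an SNR estimate
  p1 <- build_divide_protocol(5000, 115, b = c(0.1, 2), n_lte = c(2, 2),
                              n_ste = c(1, 1))
  d1 <- array(1, c(dims, p1$n_samples))
  expect_error(snr_map(d1, p1, md), ">= 2 STE repeats")
})

test_that("attenuation summary normalizes the b = 2 powder shells", {
  # monoexponential: both shapes attenuate identically, A = 100 e^-2 %
  pw <- powder_signal(b = c(0.1, 0.1, 2, 2), b_delta = c(1, 0, 1, 0),
                      S_mean = exp(-c(0.1, 0.1, 2, 2) * 1), n = c(6, 6, 16, 16))
  a <- attenuation_summary(pw, S0 = 1)
  expect_equal(a[["A_L"]], 100 * exp(-2), tolerance = 1e-12)
  expect_equal(a[["A_L"]], a[["A_S"]])
  # microscopic anisotropy lifts the LTE powder tail above STE
  p <- default_protocol()
  s <- dwi_signal(tissue_preset("wm_mimic"), p$btensors)
  pw2 <- powder_average(s, p)
  a2 <- attenuation_summary(pw2, S0 = 1)
  expect_gt(a2[["A_L"]], a2[["A_S"]])
  # S0 normalization: common scaling cancels
  pw3 <- powder_signal(pw2$b, pw2$b_delta, pw2$S_mean * 2, pw2$n)
  expect_equal(attenuation_summary(pw3, S0 = 2), a2)
  expect_error(attenuation_summary(pw, S0 = 1, b_ref = 3), "lacks")
})

test_that("repeatability statistics match the additive-noise oracle", {
  dims <- c(12, 12, 8)
  set.seed(17)
  base <- list(md = array(runif(prod(dims), 0.6, 1.2), dims),
               mki = array(runif(prod(dims), 0, 1), dims))
  mufa_m <- array(0.9, dims)
  md_m <- array(1.0, dims)
  # identical acquisitions: all differences exactly zero
  r0 <- repeatability(base, base, mufa_m, md_m)
  expect_equal(r0$stats$mean, c(0, 0))
  expect_equal(r0$stats$sd, c(0, 0))
  # one noisy copy against the clean maps: sd(Delta) ~ s
  s <- 0.05
  noisy <- lapply(base, function(m) m + array(rnorm(length(m), 0, s), dims))
  r1 <- repeatability(base, noisy, mufa_m, md_m)
  expect_equal(r1$stats$sd, c(s, s), tolerance = 0.05)
  expect_equal(r1$stats$mean, c(0, 0), tolerance = 3 * s / sqrt(prod(dims)))
  # independent noise on both: sd(Delta) ~ s sqrt(2)
  noisy2 <- lapply(base, function(m) m + array(rnorm(length(m), 0, s), dims))
  r2 <- repeatability(noisy, noisy2, mufa_m, md_m)
  expect_equal(r2$stats$sd, c(s * sqrt(2), s * sqrt(2)), tolerance = 0.05)
  # swapping acquisitions flips the bias sign, leaves the spread unchanged
  r12 <- repeatability(base, noisy, mufa_m, md_m)
  r21 <- repeatability(noisy, base, mufa_m, md_m)
  expect_equal(r21$stats$mean, -r12$stats$mean)
  expect_equal(r21$stats$sd, r12$stats$sd)
  # Bland-Altman lines are mean and +/- 2 SD
  ba <- r1$bland_altman$md
  expect_equal(unname(ba$lines["upper"] - ba$lines["mean"]),
               2 * r1$stats$sd[r1$stats$parameter == "md"])
  expect_equal(nrow(ba$points), sum(r1$mask))
})

test_that("the repeatability mask applies both tissue thresholds", {
  dims <- c(2, 2, 1)
  maps <- list(md = array(1, c(dims)))
  mufa_m <- array(c(0.9, 0.5, 0.9, 0.9), dims)   # one low-uFA voxel
  md_m <- array(c(1, 1, 2.0, 1), dims)           # one high-MD voxel
  r <- repeatability(maps, maps, mufa_m, md_m)
  expect_equal(sum(r$mask), 2)
  expect_false(r$mask[2, 1, 1])
  expect_false(r$mask[1, 2, 1])
  bad <- list(md = array(1, c(3, 2, 1)))
  expect_error(repeatability(maps, bad, mufa_m, md_m), "dimensions")
})
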