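test_that("cohort generation honors size, patch-count and label contracts", {
  cfg <- syntheticConfig(10, seed = 1)
  coh <- generateCohort(cfg)
  expect_s4_class(coh, "PairedCohort")
  expect_length(coh, 10)
  counts <- vapply(seq_len(10), function(i) nrow(patchFeatures(coh[[i]]@patches)),
                   integer(1))
  expect_true(all(counts >= cfg$patch_count_range[1] &
                    counts <= cfg$patch_count_range[2]))
  expect_identical(osLabels(coh), as.integer(osMonths(coh) > 12))
})

test_that("zero-noise cohorts are exact mixtures of the latent state", {
  coh <- tinyCohort(n = 5, seed = 3, imaging_noise_sd = 0, patch_noise_sd = 0)
  A <- coh@mixing$A; B <- coh@mixing$B; Z <- coh@mixing$Z
  for (i in 1:5) {
    z <- Z[i, ]
    expect_equal(coh[[i]]@imaging, as.numeric(A %*% z), tolerance = 1e-12)
    P <- patchFeatures(coh[[i]]@patches)
    expected <- as.numeric(B %*% c(z, pathproxy:::latentNonlinearity(z)))
    for (r in seq_len(nrow(P)))
      expect_equal(as.numeric(P[r, ]), expected, tolerance = 1e-12)
  }
})

test_that("generation is deterministic under seed and varies across seeds", {
  c1 <- tinyCohort(n = 6, seed = 11)
  c2 <- tinyCohort(n = 6, seed = 11)
  c3 <- tinyCohort(n = 6, seed = 12)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_false(isTRUE(all.equal(c1@mixing$Z, c3@mixing$Z)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(syntheticConfig(0), "n_patients")
  expect_error(syntheticConfig(5, patch_count_range = c(4, 2)),
               "patch_count_range")
  expect_error(syntheticConfig(5, imaging_noise_sd = -1), "nonnegative")
  expect_error(syntheticConfig(5, latent_dim = -2), "positive")
})

test_that("12-month label rate matches the logistic model expectation", {
  cfg <- syntheticConfig(2000, seed = 5)
  coh <- generateCohort(cfg)
  frac <- mean(osLabels(coh))
  # independent estimate of E[plogis(w . h(z))] by direct Monte Carlo
  set.seed(999)
  Zmc <- matrix(rnorm(2e5 * cfg$latent_dim), ncol = cfg$latent_dim)
  p_expect <- mean(plogis(pathproxy:::latentNonlinearity(Zmc) %*%
                            cfg$survival_weights))
  se <- sqrt(p_expect * (1 - p_expect) / 2000)
  expect_lt(abs(frac - p_expect), 3 * se)
})

test_that("imaging-pathology coupling decays with imaging noise", {
  sds <- c(0, 0.5, 1, 2, 4)
  mean_cos <- vapply(sds, function(s) {
    coh <- generateCohort(syntheticConfig(250, imaging_noise_sd = s,
                                          patch_noise_sd = 0, seed = 77))
    A <- coh@mixing$A; B <- coh@mixing$B
    Ainv <- solve(crossprod(A), t(A))             # latent reconstruction
    cs <- vapply(seq_len(250), function(i) {
      zi <- as.numeric(Ainv %*% coh[[i]]@imaging)
      zp <- coh@mixing$Z[i, ]                     # noise-free patch latent
      sum(zi * zp) / sqrt(sum(zi^2) * sum(zp^2))
    }, numeric(1))
    mean(cs)
  }, numeric(1))
  expect_true(all(diff(mean_cos) < 0))
})

test_that("Beer-Lambert patch rendering is exact and log-linear", {
  M <- stainMatrix(referenceStainModel())
  conc0 <- array(0, c(4, 4, 2))
  expect_equal(as.numeric(generateHEPatch(M, conc0, I0 = 200)),
               rep(200, 4 * 4 * 3))
  # single stain at concentration 1: intensity I0 * exp(-v) per channel
  conc1 <- conc0; conc1[, , 1] <- 1
  img <- generateHEPatch(M, conc1, I0 = 255)
  expect_equal(img[2, 2, ], 255 * exp(-M[, 1]), tolerance = 1e-12)
  # doubling concentrations doubles OD exactly
  conc2 <- conc1; conc2[, , 1] <- 2
  od1 <- -log(generateHEPatch(M, conc1, I0 = 255) / 255)
  od2 <- -log(generateHEPatch(M, conc2, I0 = 255) / 255)
  expect_equal(od2, 2 * od1, tolerance = 1e-9)
  expect_error(generateHEPatch(M, conc1 - 5, I0 = 255), "nonnegative")
})

test_that("bimodal image generator produces the stated mixture", {
  img <- generateBimodalImage(10, 200, noise_sd = 0, seed = 4)
  hist <- imageHistogram(img)
  expect_identical(sum(hist > 0), 2L)
  expect_true(all(which(hist > 0) - 1 %in% c(10, 200)))
  const <- generateBimodalImage(30, 90, fractions = c(1, 0), noise_sd = 0)
  expect_true(all(const == 30))
  expect_identical(generateBimodalImage(50, 180, noise_sd = 5, seed = 9),
                   generateBimodalImage(50, 180, noise_sd = 5, seed = 9))
  expect_error(generateBimodalImage(10, 200, fractions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(generateBimodalImage(200, 10), "mu0")
})

test_that("cohort serialization writes manifest and per-patient arrays", {
  dir <- withr::local_tempdir()
  coh <- tinyCohort(n = 4, seed = 2)
  man <- writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(nrow(man), 4L)
  expect_true(all(file.exists(file.path(dir,
    paste0(patientIds(coh), "_patches.csv")))))
  re <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(re$os_months, osMonths(coh), tolerance = 1e-9)
})
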