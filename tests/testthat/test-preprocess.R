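test_that("tiling follows the floor rule with 0-based grid origins", {
  img <- matrix(seq_len(512 * 512), 512, 512)
  tiles <- tileImage(img, 256)
  expect_length(tiles, 4)
  origins <- t(vapply(tiles, `[[`, numeric(2), "origin"))
  expect_equal(origins[order(origins[, 1], origins[, 2]), ],
               rbind(c(0, 0), c(0, 256), c(256, 0), c(256, 256)),
               ignore_attr = TRUE)
  expect_length(tileImage(matrix(0, 500, 500), 256), 1)
  one <- tileImage(matrix(1:9, 3, 3), 3)
  expect_identical(one[[1]]$pixels, matrix(1:9, 3, 3))
  expect_error(tileImage(matrix(0, 100, 300), 256), "smaller")
})

test_that("tiles reassembled at their origins reproduce the covered image", {
  set.seed(8)
  img <- matrix(runif(96 * 80), 96, 80)
  ps <- 32
  tiles <- tileImage(img, ps)
  rec <- matrix(NA_real_, 96, 64)
  for (t in tiles)
    rec[t$origin[1] + 1:ps, t$origin[2] + 1:ps] <- t$pixels
  expect_equal(rec, img[1:96, 1:64])
})

test_that("Otsu threshold maximizes between-class variance (oracle scan)", {
  # independent exhaustive oracle, written directly from the definition
  bruteOtsu <- function(h) {
    p <- h / sum(h); lev <- 0:255
    best <- -1; bt <- NA
    for (t in 0:254) {
      w0 <- sum(p[lev <= t]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(p[lev <= t] * lev[lev <= t]) / w0
      mu1 <- sum(p[lev > t] * lev[lev > t]) / w1
      v <- w0 * w1 * (mu0 - mu1)^2
      if (v > best + 1e-15) { best <- v; bt <- t }
    }
    bt
  }
  h <- numeric(256); h[c(11, 201)] <- 500      # equal masses at 10 and 200
  expect_identical(otsuThreshold(h), 10L)
  expect_identical(bruteOtsu(h), 10L)
  hconst <- numeric(256); hconst[40] <- 100
  expect_error(otsuThreshold(hconst), "degenerate")
  set.seed(21)
  for (i in 1:100) {
    h <- rpois(256, lambda = runif(1, 0.1, 3)) *
      rbinom(256, 1, runif(1, 0.2, 0.8))
    if (sum(h > 0) < 2) h[c(5, 250)] <- c(10, 10)
    expect_identical(otsuThreshold(h), as.integer(bruteOtsu(h)))
  }
})

test_that("Otsu separates the modes of a generated bimodal image", {
  img <- generateBimodalImage(50, 180, noise_sd = 5, seed = 31)
  t <- otsuThreshold(imageHistogram(img))
  expect_gt(t, 50)
  expect_lt(t, 180)
})

test_that("background filtering keeps tissue by luminance fraction", {
  dark <- list(pixels = matrix(10, 8, 8), origin = c(0, 0))
  white <- list(pixels = matrix(250, 8, 8), origin = c(0, 8))
  mixed <- list(pixels = matrix(c(rep(10, 26), rep(250, 38)), 8, 8),
                origin = c(8, 0))   # 26/64 ~ 40.6% tissue
  expect_length(filterBackground(list(white), 128), 0)
  expect_length(filterBackground(list(dark), 128), 1)
  expect_length(filterBackground(list(mixed), 128, 0.5), 0)
  expect_length(filterBackground(list(mixed), 128, 0.3), 1)
  expect_error(filterBackground(list(), 128), "empty")
  # keep-count monotone non-increasing in the tissue-fraction cutoff
  set.seed(12)
  patches <- tileImage(generateBimodalImage(40, 230, noise_sd = 20,
                                            shape = c(128, 128), seed = 3), 16)
  thr <- otsuThreshold(imageHistogram(generateBimodalImage(40, 230,
    noise_sd = 20, shape = c(128, 128), seed = 3)))
  kept <- vapply(seq(0, 1, by = 0.1), function(f)
    length(suppressWarnings(filterBackground(patches, thr, f))), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("stain vectors are recovered within 2 degrees from fixtures", {
  fx <- stainFixture()
  sm <- estimateStainModel(fx$patch)
  expect_s4_class(sm, "StainModel")
  expect_lt(vecAngle(stainMatrix(sm)[, 1], fx$M[, 1]), 2)
  expect_lt(vecAngle(stainMatrix(sm)[, 2], fx$M[, 2]), 2)
})

test_that("degenerate patches are rejected by stain estimation", {
  white <- array(255, c(16, 16, 3))
  expect_error(estimateStainModel(white), "too few")
  # single-stain: rank-1 OD cloud
  M <- stainMatrix(referenceStainModel())
  conc <- array(0, c(16, 16, 2))
  conc[, , 1] <- matrix(runif(256, 0.5, 1.5), 16, 16)
  single <- generateHEPatch(M, conc)
  expect_error(estimateStainModel(single), "single-stain")
})

test_that("two-column NNLS matches the generic NNLS solver", {
  skip_if_not_installed("pracma")
  set.seed(14)
  M <- stainMatrix(referenceStainModel())
  Y <- rbind(matrix(abs(rnorm(60)), 20, 3),
             matrix(rnorm(30), 10, 3))          # include infeasible rows
  C <- pathproxy:::nnls2(M, Y)
  for (i in seq_len(nrow(Y))) {
    ref <- pracma::lsqnonneg(M, Y[i, ])$x
    expect_equal(C[i, ], ref, tolerance = 1e-8)
  }
})

test_that("Macenko normalization round-trips and is idempotent", {
  fx <- stainFixture()
  ref <- referenceStainModel()
  src <- estimateStainModel(fx$patch)
  # scale concentrations consistently with the estimated source maxima
  ref_adj <- new("StainModel", stainMatrix = stainMatrix(ref),
                 maxConcentrations = src@maxConcentrations, I0 = 255)
  out <- macenkoNormalize(fx$patch, src, ref_adj)
  expect_lt(mean(abs(out - fx$patch)), 2)
  twice <- macenkoNormalize(out, estimateStainModel(out), ref_adj)
  expect_lt(mean(abs(twice - out)), 1)
  # uniform white patch is unchanged (zero concentrations)
  white <- array(255, c(8, 8, 3))
  expect_lt(max(abs(macenkoNormalize(white, ref, ref) - 255)), 1)
})

test_that("patches sharing concentrations converge after normalization", {
  fx <- stainFixture()
  set.seed(41)
  M2 <- fx$M + matrix(rnorm(6, sd = 0.08), 3, 2)
  M2 <- abs(M2); M2 <- sweep(M2, 2, sqrt(colSums(M2^2)), "/")
  p1 <- generateHEPatch(fx$M, fx$conc)
  p2 <- generateHEPatch(M2, fx$conc)
  ref <- referenceStainModel()
  n1 <- macenkoNormalize(p1, estimateStainModel(p1), ref)
  n2 <- macenkoNormalize(p2, estimateStainModel(p2), ref)
  expect_lt(mean(abs(n1 - n2)), 2)
})

test_that("tumor-centroid cropping shifts inward at boundaries", {
  vol <- array(rnorm(4 * 12 * 12 * 12), c(4, 12, 12, 12))
  full <- cropTumorVolume(vol, c(6, 6, 6), 12)
  expect_identical(full, vol)
  corner <- cropTumorVolume(vol, c(1, 1, 1), 6)
  expect_identical(dim(corner), c(4L, 6L, 6L, 6L))
  expect_identical(corner, vol[, 1:6, 1:6, 1:6, drop = FALSE])
  # bright cube at a known centroid is fully contained in the crop
  vol2 <- array(0, c(4, 16, 16, 16))
  vol2[, 7:10, 7:10, 7:10] <- 5
  crop <- cropTumorVolume(vol2, c(8, 8, 8), 8)
  expect_equal(sum(crop == 5), sum(vol2 == 5))
  expect_error(cropTumorVolume(vol, c(6, 6, 6), 20), "exceeds")
})

test_that("PNG round-trip preserves patch pixels to 8-bit precision", {
  skip_if_not_installed("png")
  fx <- stainFixture()
  path <- withr::local_tempfile(fileext = ".png")
  writeImagePNG(fx$patch, path)
  back <- png::readPNG(path) * 255
  expect_lt(max(abs(back - fx$patch)), 0.5 + 1e-9)
})
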