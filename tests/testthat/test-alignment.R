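test_that("projection head follows normalize-rectify-map arithmetic", {
  hd <- projectionHead(2L, 2L, 2L)
  hd$fc1$W <- diag(2); hd$fc1$b <- c(0, 0)
  hd$fc2$W <- matrix(c(1, -2, 3, 0.5), 2, 2); hd$fc2$b <- c(0.1, -0.1)
  x <- c(2, 1)
  # hand computation: h = x; LN: mean 1.5, var 0.25 -> xhat = (1, -1)/1.00002...
  inv <- 1 / sqrt(0.25 + 1e-5)
  xhat <- c(0.5, -0.5) * inv
  r <- pmax(xhat, 0)                     # rectifier kills the second unit
  expected <- as.numeric(r %*% hd$fc2$W) + hd$fc2$b
  expect_equal(project(x, hd), expected, tolerance = 1e-12)
  # zero second map gives zero output
  hd0 <- hd; hd0$fc2$W <- matrix(0, 2, 2); hd0$fc2$b <- c(0, 0)
  expect_equal(project(x, hd0), c(0, 0))
  # all-negative pre-activations are floored to zero by the rectifier
  hdn <- hd; hdn$ln$b <- c(-10, -10)
  expect_equal(project(x, hdn), hd$fc2$b)
  expect_error(project(c(1, 2, 3), hd), "match")
})

test_that("l2Normalize maps onto the unit sphere and preserves direction", {
  expect_equal(l2Normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_equal(l2Normalize(u), u)
  expect_equal(l2Normalize(c(-2, 0, 0)), c(-1, 0, 0))
  expect_error(l2Normalize(c(0, 0)), "zero")
  M <- matrix(rnorm(12), 3, 4)
  expect_equal(sqrt(rowSums(l2Normalize(M)^2)), rep(1, 3))
})

test_that("similarity matrix applies temperature-scaled cosines", {
  E <- diag(3)
  S <- similarityMatrix(E, E, tau = 1)
  expect_equal(S@values, diag(3))
  e <- l2Normalize(c(1, 2))
  expect_equal(similarityMatrix(rbind(e), rbind(e), tau = 0.07)@values[1, 1],
               1 / 0.07)
  expect_equal(similarityMatrix(rbind(e), rbind(-e), tau = 0.5)@values[1, 1],
               -2)
  expect_error(similarityMatrix(diag(3), diag(2)[, c(1, 2)], tau = 1))
})

test_that("symmetric InfoNCE satisfies its closed-form identities", {
  expect_equal(infonceSymmetric(matrix(5, 1, 1)), 0)
  for (N in c(2, 5, 15, 38))
    expect_equal(infonceSymmetric(matrix(0.7, N, N)), log(N),
                 tolerance = 1e-12)
  S <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_equal(infonceSymmetric(S), log(1 + exp(-2)), tolerance = 1e-12)
  expect_gte(infonceSymmetric(matrix(rnorm(25), 5, 5)), 0)
})

test_that("loss is invariant to modality-role transposition", {
  set.seed(17)
  for (i in 1:10) {
    S <- matrix(rnorm(36, sd = 3), 6, 6)
    expect_identical(infonceSymmetric(S), infonceSymmetric(t(S)))
  }
})

test_that("analytic InfoNCE gradient matches central finite differences", {
  set.seed(18)
  for (rep in 1:5) {
    S <- matrix(rnorm(16, sd = 2), 4, 4)
    G <- infonceGradient(S)
    h <- 1e-5
    for (i in 1:4) for (j in 1:4) {
      Sp <- S; Sm <- S
      Sp[i, j] <- Sp[i, j] + h
      Sm[i, j] <- Sm[i, j] - h
      fd <- (infonceSymmetric(Sp) - infonceSymmetric(Sm)) / (2 * h)
      expect_equal(G[i, j], fd, tolerance = 1e-5)
    }
  }
})

test_that("loss decreases with temperature for diagonal-dominant cosines", {
  set.seed(19)
  cosine <- matrix(runif(64, -0.3, 0.3), 8, 8)
  diag(cosine) <- runif(8, 0.7, 0.95)
  grid <- c(0.2, 0.1, 0.07, 0.05, 0.01)     # decreasing temperature
  losses <- vapply(grid, function(tau) infonceSymmetric(cosine / tau),
                   numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("stabilized softmax keeps extreme temperatures finite", {
  e <- l2Normalize(matrix(rnorm(10 * 4), 10, 4))
  f <- l2Normalize(matrix(rnorm(10 * 4), 10, 4))
  S <- similarityMatrix(e, f, tau = 0.01)
  expect_true(is.finite(infonceSymmetric(S)))
  expect_true(all(is.finite(infonceGradient(S))))
})

test_that("random heads are seed-deterministic and seed-sensitive", {
  h1 <- makeRandomHead(8L, 16L, 4L, seed = 3)
  h2 <- makeRandomHead(8L, 16L, 4L, seed = 3)
  h3 <- makeRandomHead(8L, 16L, 4L, seed = 4)
  expect_identical(h1, h2)
  expect_false(isTRUE(all.equal(h1$fc1$W, h3$fc1$W)))
})

test_that("random-projection embeddings retrieve at the 1/N chance level", {
  # held-out cohort embedded through random heads, many seeds, compared to
  # the analytic uniform-ranking level
  coh <- tinyCohort(n = 18, seed = 23)
  views <- pathproxy:::.cohortViews(coh)
  agg <- initAggregator(aggregatorConfig(8L), seed = 1)
  Z <- t(vapply(views$patches, function(ps)
    pathproxy:::aggForward(ps@features, ps@mask, agg)$out, numeric(8)))
  n_seeds <- 500
  r1 <- vapply(seq_len(n_seeds), function(s) {
    hi <- makeRandomHead(ncol(views$img), 16L, 8L, seed = 2 * s)
    hp <- makeRandomHead(8L, 16L, 8L, seed = 2 * s + 1)
    Ei <- l2Normalize(project(views$img, hi))
    Ep <- l2Normalize(project(Z, hp))
    mean(rankMatches(Ei %*% t(Ep)) == 1)
  }, numeric(1))
  p <- 1 / 18
  se <- sqrt(p * (1 - p) / (18 * n_seeds))
  expect_lt(abs(mean(r1) - p), 4 * se)
})

test_that("contrastive training descends and is seed-reproducible", {
  coh <- tinyCohort(n = 24, seed = 31, imaging_noise_sd = 0.2,
                    patch_noise_sd = 0.05)
  cfg <- trainConfig(epochs = 5L, batch_size = 8L, embed_dim = 8L,
                     hidden_img = 16L, hidden_path = 16L, seed = 2)
  m1 <- trainAlignment(coh, config = cfg)
  m2 <- trainAlignment(coh, config = cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
  expect_error(trainAlignment(coh[1], config = cfg), "at least 2")
})

test_that("temperature grid search returns a grid member with its scores", {
  coh <- tinyCohort(n = 16, seed = 37, imaging_noise_sd = 0.2)
  cfg <- trainConfig(epochs = 3L, batch_size = 8L, embed_dim = 8L,
                     hidden_img = 16L, hidden_path = 16L,
                     tau_grid = c(0.07, 0.2), seed = 5)
  m <- trainAlignment(coh, config = cfg)
  expect_true(m$tau %in% c(0.07, 0.2))
  expect_length(m$tau_scores, 2)
  expect_equal(unname(max(m$tau_scores)), m$best_val_recall1)
})

test_that("checkpoints rebuild the frozen model exactly", {
  coh <- tinyCohort(n = 12, seed = 61)
  cfg <- trainConfig(epochs = 2L, batch_size = 6L, embed_dim = 8L,
                     hidden_img = 16L, hidden_path = 16L, seed = 8)
  m <- trainAlignment(coh, config = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  saveAlignment(m, path)
  m2 <- loadAlignment(path)
  e1 <- embedCohort(m, coh)
  e2 <- embedCohort(m2, coh)
  expect_identical(e1, e2)
  expect_identical(m2$tau, m$tau)
})
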