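makeLibrary <- function(K, d, seed) {
  new("EmbeddingLibrary", ids = sprintf("P%03d", seq_len(K)),
      imgEmbeddings = randUnit(K, d, seed),
      pathEmbeddings = randUnit(K, d, seed + 1000))
}

test_that("library construction is frozen, ordered and unit-norm", {
  coh <- tinyCohort(n = 18, seed = 51)
  cfg <- trainConfig(epochs = 2L, batch_size = 9L, embed_dim = 8L,
                     hidden_img = 16L, hidden_path = 16L, seed = 3)
  m <- trainAlignment(coh, config = cfg)
  lib1 <- buildLibrary(m, coh)
  lib2 <- buildLibrary(m, coh)
  expect_length(lib1, 18)
  expect_identical(serialize(lib1, NULL), serialize(lib2, NULL))
  expect_identical(patientIds(lib1), sort(patientIds(coh)))
  expect_true(all(abs(sqrt(rowSums(imgEmbeddings(lib1)^2)) - 1) < 1e-6))
  expect_true(all(abs(sqrt(rowSums(pathEmbeddings(lib1)^2)) - 1) < 1e-6))
  expect_error(buildLibrary(m, coh[integer(0)]), "empty")
})

test_that("k=1 retrieval equals a brute-force scan on random libraries", {
  for (i in 1:100) {
    lib <- makeLibrary(K = sample(3:20, 1), d = 6, seed = i)
    q <- as.numeric(randUnit(1, 6, 5000 + i))
    res <- retrieveProxy(q, lib, k = 1)
    sims <- as.numeric(pathEmbeddings(lib) %*% q)
    expect_identical(res@neighborIds, patientIds(lib)[which.max(sims)])
    expect_equal(proxyEmbedding(res),
                 pathEmbeddings(lib)[which.max(sims), ])
  }
})

test_that("top-k retrieval follows the weighted-mean contract", {
  # 3 hand-written 2-d embeddings, hand-computed k=2 result
  e <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  lib <- new("EmbeddingLibrary", ids = c("a", "b", "c"),
             imgEmbeddings = e, pathEmbeddings = e)
  q <- l2Normalize(c(2, 1))
  res <- retrieveProxy(q, lib, k = 2)
  # sims: a = 2/sqrt5, b = 1/sqrt5, c = -2/sqrt5 -> neighbours a, b
  expect_identical(res@neighborIds, c("a", "b"))
  w <- c(2, 1) / sqrt(5); w <- w / sum(w)
  expect_equal(proxyEmbedding(res),
               l2Normalize(w[1] * e[1, ] + w[2] * e[2, ]))
  expect_equal(res@similarities, c(2, 1) / sqrt(5))
  expect_error(retrieveProxy(q, lib, k = 4), "k must")
})

test_that("equal similarities give the renormalized uniform mean at k=K", {
  base <- l2Normalize(c(1, 1, 0))
  perp1 <- l2Normalize(c(1, -1, 0)); perp2 <- c(0, 0, 1)
  # all path embeddings at equal cosine to the query
  E <- rbind(l2Normalize(base + perp2), l2Normalize(base - perp2),
             l2Normalize(base + perp1))
  lib <- new("EmbeddingLibrary", ids = c("a", "b", "c"),
             imgEmbeddings = E, pathEmbeddings = E)
  res <- retrieveProxy(base, lib, k = 3)
  expect_equal(res@similarities, rep(res@similarities[1], 3))
  expect_equal(proxyEmbedding(res), l2Normalize(colMeans(E)))
})

test_that("neighbour sets nest and proxies stay unit-norm for all k", {
  lib <- makeLibrary(12, 8, seed = 71)
  q <- as.numeric(randUnit(1, 8, 72))
  prev <- character(0)
  for (k in 1:12) {
    res <- retrieveProxy(q, lib, k = k)
    expect_equal(sqrt(sum(proxyEmbedding(res)^2)), 1, tolerance = 1e-9)
    expect_true(all(prev %in% res@neighborIds))
    expect_false(is.unsorted(rev(res@similarities)))
    prev <- res@neighborIds
  }
})

test_that("ties are broken by patient-id order", {
  e <- rbind(c(1, 0), c(1, 0), c(0, 1))
  lib <- new("EmbeddingLibrary", ids = c("a", "b", "c"),
             imgEmbeddings = e, pathEmbeddings = e)
  res <- retrieveProxy(c(1, 0), lib, k = 1)
  expect_identical(res@neighborIds, "a")
})

test_that("paired mode retrieves via imaging keys", {
  Ei <- diag(3)
  Ep <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  lib <- new("EmbeddingLibrary", ids = c("a", "b", "c"),
             imgEmbeddings = Ei, pathEmbeddings = Ep)
  res <- retrieveProxy(c(0, 1, 0), lib, k = 1, mode = "paired")
  expect_identical(res@neighborIds, "b")         # imaging match is b ...
  expect_equal(proxyEmbedding(res), Ep[2, ])     # ... and its paired path
})

test_that("self-match fraction equals Recall@1 from the metrics module", {
  lib <- makeLibrary(25, 6, seed = 91)
  Q <- imgEmbeddings(lib)
  self_match <- mean(vapply(seq_len(25), function(i)
    retrieveProxy(Q[i, ], lib, k = 1)@neighborIds == patientIds(lib)[i],
    logical(1)))
  ranks <- rankMatches(Q %*% t(pathEmbeddings(lib)))
  expect_equal(self_match, recallAtK(ranks, 1))
})
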