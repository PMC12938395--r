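# Shared fixtures, built in code at test time.

tinyCohort <- function(n = 12, seed = 1, ...) {
  generateCohort(syntheticConfig(n, imaging_dim = 24L, patch_dim = 8L,
                                 patch_count_range = c(3L, 6L),
                                 seed = seed, ...))
}

# A patch rendered from a known stain model, with near-pure regions of each
# stain so the angular extremes recover the generating vectors.
stainFixture <- function(I0 = 255) {
  M <- stainMatrix(referenceStainModel(I0))
  set.seed(99)
  H <- 24; W <- 24
  conc <- array(0, c(H, W, 2))
  u <- matrix(runif(H * W), H, W)                # mixing coordinate in [0,1]
  amp <- matrix(0.2 + 1.3 * runif(H * W), H, W)  # total stain amount
  conc[, , 1] <- amp * u
  conc[, , 2] <- amp * (1 - u)
  list(patch = generateHEPatch(M, conc, I0), M = M, conc = conc, I0 = I0)
}

# Angle in degrees between two vectors.
vecAngle <- function(a, b) {
  cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

# Deterministic random unit-row matrix.
randUnit <- function(n, d, seed) {
  set.seed(seed)
  l2Normalize(matrix(rnorm(n * d), n, d))
}
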