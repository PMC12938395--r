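#' Tile an image into non-overlapping square patches
#'
#' Partitions the image on a regular grid of `patch_size` x `patch_size`
#' patches; partial border tiles are dropped (floor rule). Origins are
#' 0-based (row, col) pixel coordinates in the source image, multiples of
#' `patch_size`.
#'
#' @param image grayscale matrix or H x W x 3 RGB array.
#' @param patch_size patch side length in pixels.
#' @return list of patches, each a list with elements `pixels` and `origin`.
#' @export
tileImage <- function(image, patch_size) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  stopIf(H < patch_size || W < patch_size,
         "image smaller than one patch in at least one axis")
  nr <- H %/% patch_size
  nc <- W %/% patch_size
  out <- vector("list", nr * nc)
  idx <- 1L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r0 <- (r - 1L) * patch_size
      c0 <- (cc - 1L) * patch_size
      rows <- (r0 + 1L):(r0 + patch_size)
      cols <- (c0 + 1L):(c0 + patch_size)
      px <- if (is.matrix(image)) image[rows, cols] else
        image[rows, cols, , drop = FALSE]
      out[[idx]] <- list(pixels = px, origin = c(row = r0, col = c0))
      idx <- idx + 1L
    }
  }
  out
}

#' Histogram of a gray image on the 256-level scale
#'
#' @param img numeric matrix; values clipped to `[0, 255]` and rounded.
#' @return integer vector of 256 counts for levels 0..255.
#' @export
imageHistogram <- function(img) {
  lev <- pmin(pmax(round(as.numeric(img)), 0), 255)
  tabulate(lev + 1L, nbins = 256L)
}

#' Otsu threshold from a 256-bin gray histogram
#'
#' Returns the gray level `t` maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2` of the split into levels `<= t` versus `> t`.
#' Ties are broken toward the lowest qualifying level.
#'
#' @param gray_histogram 256 nonnegative counts for levels 0..255.
#' @return the threshold level (0-based gray level, in 0..254).
#' @export
otsuThreshold <- function(gray_histogram) {
  stopifnot(length(gray_histogram) == 256, all(gray_histogram >= 0))
  stopIf(sum(gray_histogram > 0) < 2,
         "degenerate input: fewer than 2 occupied gray levels")
  p <- gray_histogram / sum(gray_histogram)
  lev <- 0:255
  w0 <- cumsum(p)                 # mass of class {levels <= t}, t = 0..255
  mu_c <- cumsum(p * lev)
  mu_T <- mu_c[256]
  t_idx <- 1:255                  # thresholds t = 0..254 (split must be real)
  w1 <- 1 - w0[t_idx]
  bcv <- rep(-Inf, 255)
  valid <- w0[t_idx] > 0 & w1 > 0
  mu0 <- mu_c[t_idx][valid] / w0[t_idx][valid]
  mu1 <- (mu_T - mu_c[t_idx][valid]) / w1[valid]
  bcv[valid] <- w0[t_idx][valid] * w1[valid] * (mu0 - mu1)^2
  which.max(bcv) - 1L             # which.max takes the first (lowest) maximum
}

#' Reject background-dominated patches
#'
#' A patch is kept iff the fraction of its pixels with luminance strictly
#' below `threshold` (tissue is darker than the glass background) is at
#' least `min_tissue_fraction`.
#'
#' @param patches list of patches as produced by [tileImage()].
#' @param threshold luminance threshold, typically from [otsuThreshold()]
#'   on the slide-level histogram.
#' @param min_tissue_fraction minimum tissue fraction to keep (default 0.5).
#' @return the kept subset of `patches`; each gains a `tissue_fraction`
#'   element.
#' @export
filterBackground <- function(patches, threshold, min_tissue_fraction = 0.5) {
  stopIf(length(patches) == 0, "empty patch list")
  fr <- vapply(patches, function(p) mean(luminance(p$pixels) < threshold),
               numeric(1))
  kept <- which(fr >= min_tissue_fraction)
  mapply(function(p, f) c(p, list(tissue_fraction = f)),
         patches[kept], fr[kept], SIMPLIFY = FALSE)
}

#' The fixed reference H&E stain model
#'
#' A conventional hematoxylin/eosin OD basis (columns unit-normalized)
#' serving as the shared normalization target across slides; override by
#' passing any [StainModel-class] to [macenkoNormalize()].
#'
#' @param I0 intensity ceiling.
#' @return A [StainModel-class].
#' @export
referenceStainModel <- function(I0 = 255) {
  M <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  new("StainModel", stainMatrix = M, maxConcentrations = c(1.5, 1.0),
      I0 = I0)
}

# Optical density of an RGB raster: -log((I + eps) / I0), pixels x 3.
.toOD <- function(patch, I0, eps = 1) {
  d <- dim(patch)
  stopifnot(length(d) == 3, d[3] == 3)
  px <- matrix(patch, d[1] * d[2], 3)
  -log(pmin((px + eps) / I0, 1))
}

# Exact nonnegative least squares for a 2-column design, vectorized over
# right-hand sides: tries the unconstrained 2x2 solve, falls back to the
# best single-column projection when a coefficient goes negative.
nnls2 <- function(M, Y) {
  G <- crossprod(M)                       # 2 x 2
  stopIf(abs(det(G)) < 1e-12, "singular stain matrix")
  Ginv <- solve(G)
  Cu <- Y %*% M %*% Ginv                  # n x 2 unconstrained solution
  c1 <- pmax(Y %*% M[, 1] / G[1, 1], 0)   # active-set candidates
  c2 <- pmax(Y %*% M[, 2] / G[2, 2], 0)
  bad <- Cu[, 1] < 0 | Cu[, 2] < 0
  if (any(bad)) {
    # residual^2 = |y|^2 - 2 c m.y + c^2 |m|^2; |y|^2 common, compare rest
    r1 <- -2 * c1[bad] * (Y[bad, , drop = FALSE] %*% M[, 1]) +
      c1[bad]^2 * G[1, 1]
    r2 <- -2 * c2[bad] * (Y[bad, , drop = FALSE] %*% M[, 2]) +
      c2[bad]^2 * G[2, 2]
    use1 <- r1 <= r2
    Cb <- cbind(ifelse(use1, c1[bad], 0), ifelse(use1, 0, c2[bad]))
    Cu[bad, ] <- Cb
  }
  dimnames(Cu) <- NULL
  Cu
}

#' Estimate an H&E stain model from a patch (Macenko)
#'
#' Converts the patch to optical density, discards near-transparent pixels
#' (all-channel OD at or below the floor `beta`), takes the top-2 singular
#' directions of the OD cloud, and sets the stain vectors to the extreme
#' directions at the `alpha` and `100 - alpha` angular percentiles within
#' that plane. Signs are fixed to nonnegative components and columns are
#' ordered hematoxylin-first (larger blue-channel OD weight). Robust maximum
#' concentrations are the 99th percentile of the per-stain nonnegative
#' least-squares concentrations.
#'
#' @param patch H x W x 3 RGB image on the `[0, I0]` scale.
#' @param I0 intensity ceiling (default 255).
#' @param beta OD floor below which pixels count as background (default
#'   0.15).
#' @param alpha angular percentile for the extreme directions (default 1).
#' @param min_pixels minimum number of above-floor pixels (default 50).
#' @return A [StainModel-class].
#' @export
estimateStainModel <- function(patch, I0 = 255, beta = 0.15, alpha = 1,
                               min_pixels = 50L) {
  od <- .toOD(patch, I0)
  keep <- !apply(od <= beta, 1, all)
  od <- od[keep, , drop = FALSE]
  stopIf(nrow(od) < min_pixels,
         "too few above-floor pixels for stain estimation")
  sv <- svd(od, nu = 0, nv = 2)
  stopIf(sv$d[2] < 1e-3 * sv$d[1],
         "rank-1 OD cloud: patch appears single-stain")
  V <- sv$v                              # 3 x 2 plane basis
  proj <- od %*% V
  # orient the basis so projections lie in a consistent half-plane
  if (sum(proj[, 1]) < 0) { V[, 1] <- -V[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  vecs <- V %*% rbind(cos(qs), sin(qs))  # 3 x 2 extreme directions
  for (j in 1:2) {
    if (sum(vecs[, j]) < 0) vecs[, j] <- -vecs[, j]
    vecs[, j] <- vecs[, j] / sqrt(sum(vecs[, j]^2))
  }
  if (any(vecs < -1e-6))
    vecs <- pmax(vecs, 0) / rep(sqrt(colSums(pmax(vecs, 0)^2)), each = 3)
  # hematoxylin carries the larger blue-channel OD weight
  if (vecs[3, 1] < vecs[3, 2]) vecs <- vecs[, 2:1]
  conc <- nnls2(vecs, od)
  maxc <- pmax(apply(conc, 2, quantile, probs = 0.99, names = FALSE), 1e-6)
  new("StainModel", stainMatrix = vecs, maxConcentrations = maxc, I0 = I0)
}

#' Macenko stain normalization of a patch
#'
#' Solves per-pixel stain concentrations against the source model by
#' nonnegative least squares, rescales each stain by the ratio of reference
#' to source robust maximum concentrations, and re-renders the pixel through
#' the reference stain matrix via the Beer-Lambert law. Output is clipped to
#' `[0, I0]`.
#'
#' @param patch H x W x 3 RGB image.
#' @param source [StainModel-class] of the patch's own slide.
#' @param reference target [StainModel-class] (default the shipped
#'   [referenceStainModel()]).
#' @return normalized H x W x 3 RGB image.
#' @export
macenkoNormalize <- function(patch, source, reference = referenceStainModel()) {
  stopifnot(is(source, "StainModel"), is(reference, "StainModel"))
  d <- dim(patch)
  od <- .toOD(patch, source@I0)
  conc <- nnls2(source@stainMatrix, od)
  conc <- sweep(conc, 2,
                reference@maxConcentrations / source@maxConcentrations, "*")
  od_new <- conc %*% t(reference@stainMatrix)
  img <- reference@I0 * exp(-od_new)
  array(pmin(pmax(img, 0), reference@I0), dim = d)
}

#' Crop a cube around the tumor centroid from a 4-channel volume
#'
#' Extracts an axis-aligned cube of side `size` centered at `centroid`
#' (1-based voxel coordinates in D, H, W order). When the cube would cross a
#' boundary, the window is shifted inward so the output is always fully
#' inside the volume — no padding. All 4 channels are cropped identically.
#'
#' @param volume array with dim (4, D, H, W).
#' @param centroid length-3 voxel coordinate of the solid-tumor centroid.
#' @param size cube side in voxels (e.g. 80 for full scale).
#' @return array with dim (4, size, size, size).
#' @export
cropTumorVolume <- function(volume, centroid, size) {
  d <- dim(volume)
  stopifnot(length(d) == 4, d[1] == 4, length(centroid) == 3)
  stopIf(any(size > d[2:4]), "crop size exceeds volume extent")
  starts <- integer(3)
  for (ax in 1:3) {
    s <- round(centroid[ax]) - size %/% 2
    starts[ax] <- min(max(s, 1L), d[ax + 1] - size + 1L)
  }
  volume[, starts[1]:(starts[1] + size - 1L),
         starts[2]:(starts[2] + size - 1L),
         starts[3]:(starts[3] + size - 1L), drop = FALSE]
}

#' Write a raster image to PNG
#'
#' Convenience writer for patch/slide fixtures; values on the `[0, 255]`
#' scale are rescaled to `[0, 1]`. Requires the png package.
#'
#' @param img grayscale matrix or H x W x 3 array on the 0--255 scale.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeImagePNG <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG output", call. = FALSE)
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
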