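# 3D convolution, kernel 3, padding 1, optional stride; x: (C_in, D, H, W),
# p$W: (C_out, C_in, 3, 3, 3), p$b: C_out. Implemented as 27 shift-and-
# multiply accumulations so BLAS does the channel mixing.
conv3dFwd <- function(x, p, stride = 1L) {
  d <- dim(x); Ci <- d[1]; D <- d[2]; H <- d[3]; Wd <- d[4]
  xp <- array(0, c(Ci, D + 2, H + 2, Wd + 2))
  xp[, 2:(D + 1), 2:(H + 1), 2:(Wd + 1)] <- x
  Co <- dim(p$W)[1]
  acc <- matrix(0, Co, D * H * Wd)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    sh <- xp[, (1 + dx):(D + dx), (1 + dy):(H + dy), (1 + dz):(Wd + dz),
             drop = FALSE]
    dim(sh) <- c(Ci, D * H * Wd)
    acc <- acc + matrix(p$W[, , dx + 1, dy + 1, dz + 1], Co, Ci) %*% sh
  }
  acc <- acc + p$b
  out <- array(acc, c(Co, D, H, Wd))
  if (stride > 1L)
    out <- out[, seq(1, D, by = stride), seq(1, H, by = stride),
               seq(1, Wd, by = stride), drop = FALSE]
  out
}

conv3dInit <- function(c_in, c_out) {
  fan_in <- c_in * 27
  list(W = array(rnorm(c_out * c_in * 27, sd = sqrt(2 / fan_in)),
                 c(c_out, c_in, 3, 3, 3)),
       b = numeric(c_out))
}

#' Construct the volumetric imaging encoder
#'
#' A small 3D residual convolutional network honoring the contract
#' "convolutional feature extractor followed by global average pooling over
#' spatial dimensions": stem conv, one residual block, strided downsampling
#' conv, a second residual block, then a per-voxel linear head whose
#' spatially averaged output is the imaging feature. Weights are drawn once
#' from a seeded He initialization and the encoder is used as a fixed,
#' deterministic feature extractor (evaluation mode).
#'
#' @param in_channels number of input channels (4 MRI sequences).
#' @param out_dim output feature dimension (default 512).
#' @param channels widths of the two stages (default c(8, 16)).
#' @param seed integer seed for the weight draw.
#' @return an encoder object of class `pathproxy_encoder`.
#' @export
imagingEncoder <- function(in_channels = 4L, out_dim = 512L,
                           channels = c(8L, 16L), seed = 1L) {
  withSeed(seed, {
    params <- list(
      stem = conv3dInit(in_channels, channels[1]),
      b1a = conv3dInit(channels[1], channels[1]),
      b1b = conv3dInit(channels[1], channels[1]),
      down = conv3dInit(channels[1], channels[2]),
      b2a = conv3dInit(channels[2], channels[2]),
      b2b = conv3dInit(channels[2], channels[2]),
      head = list(W = matrix(rnorm(channels[2] * out_dim,
                                   sd = sqrt(1 / channels[2])),
                             channels[2], out_dim),
                  b = numeric(out_dim))
    )
    structure(list(params = params,
                   config = list(in_channels = as.integer(in_channels),
                                 out_dim = as.integer(out_dim),
                                 channels = as.integer(channels),
                                 seed = as.integer(seed))),
              class = "pathproxy_encoder")
  })
}

#' Encode an imaging volume (or pass a precomputed feature through)
#'
#' Bypass mode: a plain numeric vector is returned unchanged, so externally
#' computed imaging features compose with downstream modules exactly as the
#' convolutional path does. A 4-channel voxel array is run through the
#' convolutional encoder and globally average-pooled.
#'
#' @param x numeric feature vector, or array with dim (4, D, H, W).
#' @param encoder an encoder from [imagingEncoder()]; required for volumes.
#' @return numeric feature vector of length `out_dim` (or the input in
#'   bypass mode).
#' @export
encodeImaging <- function(x, encoder = NULL) {
  if (is.numeric(x) && is.null(dim(x))) return(x)       # bypass
  d <- dim(x)
  stopIf(length(d) != 4, "imaging input must be a vector or 4-D array")
  stopifnot(inherits(encoder, "pathproxy_encoder"))
  stopIf(d[1] != encoder$config$in_channels,
         sprintf("expected %d input channels, got %d",
                 encoder$config$in_channels, d[1]))
  p <- encoder$params
  s1 <- pmax(conv3dFwd(x, p$stem), 0)
  r <- conv3dFwd(pmax(conv3dFwd(s1, p$b1a), 0), p$b1b)
  s2 <- pmax(s1 + r, 0)
  s3 <- pmax(conv3dFwd(s2, p$down, stride = 2L), 0)
  r2 <- conv3dFwd(pmax(conv3dFwd(s3, p$b2a), 0), p$b2b)
  s4 <- pmax(s3 + r2, 0)
  fm <- matrix(s4, dim(s4)[1], prod(dim(s4)[2:4]))       # channels x voxels
  pooled <- rowMeans(fm)                                 # GAP
  as.numeric(crossprod(p$head$W, pooled) + p$head$b)
}

#' Configuration of the multi-head attention patch aggregator
#'
#' @param feature_dim patch feature dimension C; must be divisible by
#'   `num_heads`.
#' @param num_heads number of attention heads (default 4).
#' @param depth number of transformer encoder layers (default 2).
#' @param mlp_ratio feed-forward expansion ratio (default 4.0).
#' @param dropout dropout rate applied within each layer during training
#'   (default 0.1); inactive in evaluation mode.
#' @return a validated configuration list.
#' @export
aggregatorConfig <- function(feature_dim, num_heads = 4L, depth = 2L,
                             mlp_ratio = 4.0, dropout = 0.1) {
  stopIf(feature_dim %% num_heads != 0,
         "feature_dim must be divisible by num_heads")
  stopIf(depth < 1, "depth must be >= 1")
  list(feature_dim = as.integer(feature_dim),
       num_heads = as.integer(num_heads), depth = as.integer(depth),
       mlp_ratio = mlp_ratio, dropout = dropout)
}

#' Initialize aggregator parameters
#'
#' A learnable CLS token plus `depth` post-norm transformer encoder layers.
#'
#' @param config from [aggregatorConfig()].
#' @param seed integer seed.
#' @return parameter list of class `pathproxy_aggregator`.
#' @export
initAggregator <- function(config, seed = 1L) {
  withSeed(seed, {
    params <- list(
      cls = list(t = rnorm(config$feature_dim, sd = 0.02)),
      layers = lapply(seq_len(config$depth), function(i)
        nnTransformerLayerInit(config$feature_dim, config$mlp_ratio))
    )
    structure(list(params = params, config = config),
              class = "pathproxy_aggregator")
  })
}

# Forward pass with caches kept for backpropagation.
aggForward <- function(features, mask, agg, training = FALSE) {
  cfg <- agg$config
  stopIf(!any(mask), "all patch rows are masked")
  stopifnot(ncol(features) == cfg$feature_dim)
  x <- rbind(agg$params$cls$t, features)
  m <- c(TRUE, mask)
  caches <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cc <- nnTransformerLayerFwd(x, m, agg$params$layers[[l]], cfg$num_heads,
                                cfg$dropout, training)
    caches[[l]] <- cc
    x <- cc$y
  }
  list(out = x[1, ], caches = caches, mask = m)
}

# Backward pass: dout is the gradient at the transformed CLS position.
aggBackward <- function(dout, fwd, agg) {
  cfg <- agg$config
  dy <- matrix(0, length(fwd$mask), cfg$feature_dim)
  dy[1, ] <- dout
  grads_layers <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    b <- nnTransformerLayerBwd(dy, fwd$caches[[l]], agg$params$layers[[l]],
                               cfg$num_heads)
    grads_layers[[l]] <- b$grad
    dy <- b$dx
  }
  list(grad = list(cls = list(t = dy[1, ]), layers = grads_layers),
       dPatches = dy[-1, , drop = FALSE])
}

#' Aggregate a variable-length patch set into a slide feature
#'
#' Prepends the learnable CLS token to the (masked) patch sequence, runs the
#' transformer encoder with the key padding mask suppressing all
#' contributions from padding rows, and returns the transformed CLS state.
#' Padded rows provably have zero influence on the output, and with no
#' positional encoding the aggregator is a set function: permuting the valid
#' rows leaves the output unchanged.
#'
#' @param patch_set a [PatchFeatureSet-class].
#' @param agg an aggregator from [initAggregator()].
#' @param training logical; enables dropout when `TRUE` (default `FALSE`,
#'   evaluation mode).
#' @return numeric slide feature of length `feature_dim`.
#' @export
aggregatePatches <- function(patch_set, agg, training = FALSE) {
  stopifnot(is(patch_set, "PatchFeatureSet"),
            inherits(agg, "pathproxy_aggregator"))
  aggForward(patch_set@features, patch_set@mask, agg, training)$out
}
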