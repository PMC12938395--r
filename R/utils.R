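# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed; kept below 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483629)
}

# Run expr with a local RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopIf <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# Luminance of a raster: grayscale matrix passes through, RGB uses Rec.601.
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
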