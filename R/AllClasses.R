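#' @import methods
#' @importFrom stats rnorm runif rbinom plogis rlogis sd quantile
#' @importFrom utils write.csv read.csv head
NULL

.isFiniteNumeric <- function(x) is.numeric(x) && all(is.finite(x))

#' PatchFeatureSet: a variable-length set of patch-level features
#'
#' Holds the N x C matrix of patch-level feature vectors extracted from one
#' whole-slide image, together with a logical validity mask distinguishing
#' real patches from padding rows. The mask is what makes batched,
#' padding-aware attention aggregation possible downstream.
#'
#' @slot features numeric matrix, one row per patch (valid or padding).
#' @slot mask logical vector, one entry per row; \code{TRUE} marks a valid
#'   patch. At least one entry must be \code{TRUE}.
#' @slot slideId single character identifier of the source slide.
#' @export
setClass("PatchFeatureSet",
  representation(features = "matrix", mask = "logical", slideId = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@features) != length(object@mask))
      msg <- c(msg, "mask length must equal the number of feature rows")
    if (!any(object@mask))
      msg <- c(msg, "at least one valid (unmasked) patch is required")
    if (!all(is.finite(object@features[object@mask, , drop = FALSE])))
      msg <- c(msg, "valid patch features must be finite")
    if (length(object@slideId) != 1L)
      msg <- c(msg, "slideId must be a single string")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a PatchFeatureSet
#'
#' @param features N x C numeric matrix of patch features.
#' @param mask logical validity mask (default: all rows valid).
#' @param slideId slide identifier.
#' @return A [PatchFeatureSet-class] object.
#' @export
PatchFeatureSet <- function(features, mask = rep(TRUE, nrow(features)),
                            slideId = "slide") {
  new("PatchFeatureSet", features = as.matrix(features), mask = as.logical(mask),
      slideId = as.character(slideId))
}

#' PairedSample: one patient's imaging view, patch set and survival record
#'
#' @slot patientId single character id.
#' @slot imaging either a numeric feature vector (feature-bypass mode) or a
#'   4-channel voxel array with dim (4, D, H, W).
#' @slot patches a [PatchFeatureSet-class].
#' @slot osMonths positive overall-survival time in months.
#' @slot osLabel binary 12-month survival label; 1 iff \code{osMonths > 12}.
#' @export
setClass("PairedSample",
  representation(patientId = "character", imaging = "ANY",
                 patches = "PatchFeatureSet", osMonths = "numeric",
                 osLabel = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@osMonths) != 1L || !is.finite(object@osMonths) ||
        object@osMonths <= 0)
      msg <- c(msg, "osMonths must be a single positive number")
    else if (object@osLabel != as.integer(object@osMonths > 12))
      msg <- c(msg, "osLabel inconsistent with the strict 12-month rule")
    if (!is.numeric(object@imaging))
      msg <- c(msg, "imaging must be numeric (vector or 4-channel array)")
    else if (is.array(object@imaging) && length(dim(object@imaging)) == 4 &&
             dim(object@imaging)[1] != 4)
      msg <- c(msg, "volumetric imaging must have 4 channels in dim 1")
    if (is.null(msg)) TRUE else msg
  }
)

#' PairedCohort: a list of paired samples with its generating metadata
#'
#' @slot samples list of [PairedSample-class] objects.
#' @slot mixing list with the latent-to-modality mixing matrices \code{A}
#'   (imaging) and \code{B} (pathology) plus the latent draws, kept for
#'   reproducibility and oracle checks.
#' @slot config the fully-resolved generator configuration list.
#' @export
setClass("PairedCohort",
  representation(samples = "list", mixing = "list", config = "list"),
  validity = function(object) {
    ok <- vapply(object@samples, is, logical(1), class2 = "PairedSample")
    if (!all(ok)) "all elements of samples must be PairedSample" else TRUE
  }
)

#' StainModel: Beer-Lambert stain basis for H&E normalization
#'
#' @slot stainMatrix 3 x 2 optical-density matrix; columns are unit-norm
#'   hematoxylin and eosin stain vectors (hematoxylin first).
#' @slot maxConcentrations length-2 positive reals, the per-stain robust
#'   (99th percentile) maximum concentrations.
#' @slot I0 transmitted-light intensity ceiling (default scale 255).
#' @export
setClass("StainModel",
  representation(stainMatrix = "matrix", maxConcentrations = "numeric",
                 I0 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@stainMatrix) == c(3L, 2L)))
      msg <- c(msg, "stainMatrix must be 3 x 2")
    else {
      nrm <- sqrt(colSums(object@stainMatrix^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "stainMatrix columns must have unit Euclidean norm")
    }
    if (length(object@maxConcentrations) != 2L ||
        any(object@maxConcentrations <= 0))
      msg <- c(msg, "maxConcentrations must be 2 positive reals")
    if (length(object@I0) != 1L || object@I0 <= 0)
      msg <- c(msg, "I0 must be a single positive number")
    if (is.null(msg)) TRUE else msg
  }
)

#' ScaledSimilarity: temperature-scaled cross-modal cosine similarities
#'
#' @slot values N x N matrix with entries cosine/tau.
#' @slot tau positive temperature.
#' @export
setClass("ScaledSimilarity",
  representation(values = "matrix", tau = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0)
      msg <- c(msg, "tau must be a single positive number")
    else if (any(abs(object@values) > 1 / object@tau + 1e-8))
      msg <- c(msg, "entries must lie within [-1/tau, 1/tau]")
    if (is.null(msg)) TRUE else msg
  }
)

#' EmbeddingLibrary: frozen paired unit embeddings for retrieval
#'
#' One record per library patient, pairing the imaging and pathology unit
#' embeddings produced by a single frozen forward pass. Row order is the
#' record order; pairing is index-exact.
#'
#' @slot ids character vector of unique patient ids, sorted.
#' @slot imgEmbeddings K x d matrix of unit-norm imaging embeddings.
#' @slot pathEmbeddings K x d matrix of unit-norm pathology embeddings.
#' @export
setClass("EmbeddingLibrary",
  representation(ids = "character", imgEmbeddings = "matrix",
                 pathEmbeddings = "matrix"),
  validity = function(object) {
    msg <- NULL
    K <- length(object@ids)
    if (anyDuplicated(object@ids)) msg <- c(msg, "patient ids must be unique")
    if (nrow(object@imgEmbeddings) != K || nrow(object@pathEmbeddings) != K)
      msg <- c(msg, "embedding matrices must have one row per id")
    if (ncol(object@imgEmbeddings) != ncol(object@pathEmbeddings))
      msg <- c(msg, "both modalities must share the embedding dimension")
    for (m in list(object@imgEmbeddings, object@pathEmbeddings)) {
      if (K > 0 && any(abs(sqrt(rowSums(m^2)) - 1) > 1e-6)) {
        msg <- c(msg, "all stored embeddings must have unit norm (1e-6)")
        break
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' RetrievalResult: proxy pathology embedding plus its provenance
#'
#' @slot proxy unit-norm proxy pathology embedding.
#' @slot neighborIds ids of the k retrieved library patients.
#' @slot similarities cosine similarities to the query, non-increasing.
#' @slot k number of neighbours used.
#' @export
setClass("RetrievalResult",
  representation(proxy = "numeric", neighborIds = "character",
                 similarities = "numeric", k = "integer"),
  validity = function(object) {
    msg <- NULL
    if (abs(sqrt(sum(object@proxy^2)) - 1) > 1e-6)
      msg <- c(msg, "proxy must have unit norm")
    if (length(object@neighborIds) != object@k ||
        length(object@similarities) != object@k)
      msg <- c(msg, "neighborIds and similarities must have length k")
    if (is.unsorted(rev(object@similarities)))
      msg <- c(msg, "similarities must be sorted non-increasing")
    if (any(abs(object@similarities) > 1 + 1e-8))
      msg <- c(msg, "similarities must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "PatchFeatureSet", function(object) {
  cat(sprintf("PatchFeatureSet '%s': %d patches (%d valid), C = %d\n",
              object@slideId, nrow(object@features), sum(object@mask),
              ncol(object@features)))
})

setMethod("show", "PairedCohort", function(object) {
  n <- length(object@samples)
  labs <- vapply(object@samples, function(s) s@osLabel, integer(1))
  cat(sprintf("PairedCohort: %d patients (%d with OS > 12 months)\n",
              n, sum(labs)))
  if (n > 0) {
    img <- object@samples[[1]]@imaging
    mode <- if (is.array(img) && length(dim(img)) == 4)
      sprintf("volume %s", paste(dim(img), collapse = "x")) else
      sprintf("feature vector (%d)", length(img))
    cat(sprintf("  imaging: %s; patch dim C = %d\n", mode,
                ncol(object@samples[[1]]@patches@features)))
  }
  invisible(object)
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel (Beer-Lambert, OD space)\n")
  m <- round(object@stainMatrix, 3)
  dimnames(m) <- list(c("R", "G", "B"), c("hematoxylin", "eosin"))
  print(m)
  cat(sprintf("  maxConcentrations: %.3f %.3f; I0 = %g\n",
              object@maxConcentrations[1], object@maxConcentrations[2],
              object@I0))
})

setMethod("show", "EmbeddingLibrary", function(object) {
  cat(sprintf("EmbeddingLibrary: K = %d paired records, d = %d\n",
              length(object@ids), ncol(object@imgEmbeddings)))
})

setMethod("show", "ScaledSimilarity", function(object) {
  cat(sprintf("ScaledSimilarity: %d x %d, tau = %g\n",
              nrow(object@values), ncol(object@values), object@tau))
})

setMethod("show", "RetrievalResult", function(object) {
  cat(sprintf("RetrievalResult: k = %d, top neighbour '%s' (cos = %.4f)\n",
              object@k, object@neighborIds[1], object@similarities[1]))
})
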