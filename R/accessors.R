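#' Accessors for pathproxy S4 containers
#'
#' Small, slot-hiding accessors in the usual Bioconductor style.
#'
#' @param x the object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchFeatures", function(x) standardGeneric("patchFeatures"))
#' @rdname accessors
#' @export
setMethod("patchFeatures", "PatchFeatureSet", function(x)
  x@features[x@mask, , drop = FALSE])

#' @rdname accessors
#' @export
setGeneric("patchMask", function(x) standardGeneric("patchMask"))
#' @rdname accessors
#' @export
setMethod("patchMask", "PatchFeatureSet", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setMethod("patientIds", "PairedCohort", function(x)
  vapply(x@samples, function(s) s@patientId, character(1)))
#' @rdname accessors
#' @export
setMethod("patientIds", "EmbeddingLibrary", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("osMonths", function(x) standardGeneric("osMonths"))
#' @rdname accessors
#' @export
setMethod("osMonths", "PairedCohort", function(x)
  vapply(x@samples, function(s) s@osMonths, numeric(1)))

#' @rdname accessors
#' @export
setGeneric("osLabels", function(x) standardGeneric("osLabels"))
#' @rdname accessors
#' @export
setMethod("osLabels", "PairedCohort", function(x)
  vapply(x@samples, function(s) s@osLabel, integer(1)))

#' @rdname accessors
#' @export
setGeneric("imgEmbeddings", function(x) standardGeneric("imgEmbeddings"))
#' @rdname accessors
#' @export
setMethod("imgEmbeddings", "EmbeddingLibrary", function(x) x@imgEmbeddings)

#' @rdname accessors
#' @export
setGeneric("pathEmbeddings", function(x) standardGeneric("pathEmbeddings"))
#' @rdname accessors
#' @export
setMethod("pathEmbeddings", "EmbeddingLibrary", function(x) x@pathEmbeddings)

#' @rdname accessors
#' @export
setGeneric("stainMatrix", function(x) standardGeneric("stainMatrix"))
#' @rdname accessors
#' @export
setMethod("stainMatrix", "StainModel", function(x) x@stainMatrix)

#' @rdname accessors
#' @export
setGeneric("proxyEmbedding", function(x) standardGeneric("proxyEmbedding"))
#' @rdname accessors
#' @export
setMethod("proxyEmbedding", "RetrievalResult", function(x) x@proxy)

#' Number of patients / records
#' @param x a PairedCohort or EmbeddingLibrary.
#' @export
setMethod("length", "PairedCohort", function(x) length(x@samples))
#' @rdname accessors
#' @export
setMethod("length", "EmbeddingLibrary", function(x) length(x@ids))

#' Extract samples from a cohort
#' @param x a PairedCohort.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PairedCohort", function(x, i, j, ..., drop = TRUE) {
  new("PairedCohort", samples = x@samples[i], mixing = x@mixing,
      config = x@config)
})

#' @rdname accessors
#' @param i sample index.
#' @export
setMethod("[[", "PairedCohort", function(x, i) x@samples[[i]])
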