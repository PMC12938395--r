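#' Build the frozen cross-modal embedding library
#'
#' Runs a single evaluation-mode forward pass of the trained (frozen)
#' alignment model over a paired cohort and stores the resulting unit
#' embeddings of both modalities with index-exact pairing, ordered by
#' patient id.
#'
#' @param model a `pathproxy_alignment` model.
#' @param cohort a paired [PairedCohort-class].
#' @param encoder optional imaging encoder for volumetric cohorts.
#' @return An [EmbeddingLibrary-class] with K records.
#' @export
buildLibrary <- function(model, cohort, encoder = NULL) {
  stopIf(length(cohort) == 0, "cannot build a library from an empty cohort")
  e <- embedCohort(model, cohort, encoder)
  ord <- order(e$ids)
  new("EmbeddingLibrary", ids = e$ids[ord],
      imgEmbeddings = e$img[ord, , drop = FALSE],
      pathEmbeddings = e$path[ord, , drop = FALSE])
}

#' Retrieve a proxy pathology embedding for an imaging-only query
#'
#' Default mode `"cross"` ranks library records by the cosine between the
#' query imaging embedding and the stored *pathology* embeddings (the
#' direct cross-modal reading of maximum-similarity matching). Mode
#' `"paired"` instead matches imaging-to-imaging and returns the paired
#' pathology embeddings. For `k = 1` the proxy is the top record's
#' pathology embedding exactly; for `k > 1` it is the similarity-weighted
#' mean of the k pathology embeddings (weights `max(sim, 0)` normalized to
#' sum 1, uniform fallback when all are nonpositive), re-normalized to unit
#' length. Ties are broken by patient-id order.
#'
#' @param query_img unit-norm imaging embedding of the query patient.
#' @param library an [EmbeddingLibrary-class].
#' @param k number of neighbours, `1 <= k <= K`.
#' @param mode `"cross"` (default) or `"paired"`.
#' @return A [RetrievalResult-class].
#' @export
retrieveProxy <- function(query_img, library, k = 1L,
                          mode = c("cross", "paired")) {
  mode <- match.arg(mode)
  K <- length(library@ids)
  stopIf(k < 1 || k > K, "k must satisfy 1 <= k <= K")
  keys <- if (mode == "cross") library@pathEmbeddings else
    library@imgEmbeddings
  sims <- as.numeric(keys %*% query_img)
  ord <- order(sims, decreasing = TRUE)    # stable: ties keep id order
  top <- ord[seq_len(k)]
  w <- pmax(sims[top], 0)
  if (sum(w) <= 0) w <- rep(1, k)
  w <- w / sum(w)
  proxy <- l2Normalize(as.numeric(
    crossprod(library@pathEmbeddings[top, , drop = FALSE], w)))
  new("RetrievalResult", proxy = proxy, neighborIds = library@ids[top],
      similarities = sims[top], k = as.integer(k))
}

#' Retrieve proxies for a matrix of query embeddings
#'
#' @param Q n x d matrix of unit-row query imaging embeddings.
#' @param library an [EmbeddingLibrary-class].
#' @param k,mode as in [retrieveProxy()].
#' @return list with `proxies` (n x d unit-row matrix) and `neighbors`
#'   (n x k id matrix).
#' @export
retrieveProxies <- function(Q, library, k = 1L, mode = "cross") {
  res <- apply(Q, 1, retrieveProxy, library = library, k = k, mode = mode,
               simplify = FALSE)
  list(proxies = do.call(rbind, lapply(res, function(r) r@proxy)),
       neighbors = do.call(rbind, lapply(res, function(r) r@neighborIds)))
}
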