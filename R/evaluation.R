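#' Rank of each true cross-modal match
#'
#' For each query row i, the 1-based rank of entry (i, i) when row i is
#' sorted in decreasing similarity. Ties are handled pessimistically: any
#' competitor with similarity equal to the true match ranks ahead of it, so
#' reported recall never benefits from ties.
#'
#' @param S square similarity matrix (unscaled cosines are fine, ranking is
#'   scale-invariant), or a [ScaledSimilarity-class].
#' @return integer vector of ranks in `[1, N]`.
#' @export
rankMatches <- function(S) {
  V <- if (is(S, "ScaledSimilarity")) S@values else as.matrix(S)
  stopIf(nrow(V) != ncol(V), "similarity matrix must be square")
  vapply(seq_len(nrow(V)), function(i) sum(V[i, ] >= V[i, i]), integer(1))
}

#' Recall at k
#'
#' @param ranks integer ranks from [rankMatches()].
#' @param k cutoff, `1 <= k <= N`.
#' @param N number of candidates (default `max(ranks)` is unsafe when all
#'   queries rank early, so pass it when known; defaults to
#'   `length(ranks)` for the square paired case).
#' @return fraction of queries with rank <= k.
#' @export
recallAtK <- function(ranks, k, N = length(ranks)) {
  stopIf(k < 1 || k > N, "k out of range")
  mean(ranks <= k)
}

#' Mean reciprocal rank
#'
#' @param ranks integer ranks from [rankMatches()].
#' @return mean of 1/rank, in (0, 1].
#' @export
meanReciprocalRank <- function(ranks) {
  stopIf(length(ranks) == 0, "empty rank table")
  mean(1 / ranks)
}

#' Monte-Carlo random-retrieval baseline
#'
#' Draws `n_sims` independent libraries of N random unit embeddings per
#' modality, ranks the diagonal matches, and averages Recall@k and MRR.
#' Analytically these converge to k/N and H_N/N (harmonic number over N)
#' under uniform rankings.
#'
#' @param N paired-cohort size.
#' @param k_values recall cutoffs to report.
#' @param n_sims number of random draws (each with a fresh seed).
#' @param d embedding dimension.
#' @param seed master seed.
#' @return list with `recall_at` (named numeric), `mrr`, and `N`.
#' @export
randomRetrievalBaseline <- function(N, k_values = c(1L, 5L), n_sims = 1000L,
                                    d = 64L, seed = 1L) {
  rec <- matrix(0, n_sims, length(k_values))
  mrr <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    ranks <- withSeed(deriveSeed(seed, s), {
      Ei <- l2Normalize(matrix(rnorm(N * d), N, d))
      Ep <- l2Normalize(matrix(rnorm(N * d), N, d))
      rankMatches(Ei %*% t(Ep))
    })
    rec[s, ] <- vapply(k_values, function(k) recallAtK(ranks, k), numeric(1))
    mrr[s] <- meanReciprocalRank(ranks)
  }
  list(recall_at = stats::setNames(colMeans(rec), paste0("k", k_values)),
       mrr = mean(mrr), N = N)
}

#' Binary classification metrics for 12-month survival prediction
#'
#' AUROC is computed via the rank statistic (midranks, so ties contribute
#' 1/2); accuracy, sensitivity, specificity and F1 use the stated score
#' threshold with `score >= threshold` predicting the positive class.
#'
#' @param labels binary 0/1 vector (1 = survived beyond 12 months).
#' @param scores predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return named list: accuracy, auroc, sensitivity, specificity, f1.
#'   AUROC is `NA` (with a warning) when only one class is present.
#' @export
classificationMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auroc <- if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(scores)                    # midranks handle ties as 1/2
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  }
  sens <- if (n1 > 0) tp / n1 else NA_real_
  spec <- if (n0 > 0) tn / n0 else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(accuracy = (tp + tn) / length(labels), auroc = auroc,
       sensitivity = sens, specificity = spec, f1 = f1)
}

#' Full retrieval report for a paired embedding set
#'
#' @param E_img,E_path N x d unit-row embedding matrices with row i of each
#'   matrix belonging to the same patient.
#' @param k_values recall cutoffs.
#' @return list with `recall_at`, `mrr`, `ranks`, `N`.
#' @export
retrievalReport <- function(E_img, E_path, k_values = c(1L, 5L)) {
  ranks <- rankMatches(E_img %*% t(E_path))
  list(recall_at = stats::setNames(
         vapply(k_values, function(k) recallAtK(ranks, k), numeric(1)),
         paste0("k", k_values)),
       mrr = meanReciprocalRank(ranks), ranks = ranks, N = length(ranks))
}
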