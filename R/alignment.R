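#' Initialize a two-layer projection head
#'
#' The shared-space projection `g(x) = W2 ReLU(LayerNorm(W1 x))`: a first
#' linear map to the hidden width, layer normalization, rectification, and a
#' second linear map to the embedding dimension.
#'
#' @param in_dim input feature dimension.
#' @param hidden_dim hidden width (convention: 256 for imaging, 512 for
#'   pathology).
#' @param out_dim shared embedding dimension d (default 256).
#' @return parameter list of class `pathproxy_head`.
#' @export
projectionHead <- function(in_dim, hidden_dim = 256L, out_dim = 256L) {
  structure(list(fc1 = nnLinearInit(in_dim, hidden_dim),
                 ln = nnLayerNormInit(hidden_dim),
                 fc2 = nnLinearInit(hidden_dim, out_dim),
                 dims = c(in_dim, hidden_dim, out_dim)),
            class = "pathproxy_head")
}

#' Seeded randomly initialized projection head (random-projection control)
#'
#' An untrained head with a seeded weight draw, used for the ablation in
#' which proxy pathology features pass through a random rather than a
#' learned projection.
#'
#' @param in_dim,hidden_dim,out_dim as in [projectionHead()].
#' @param seed integer seed.
#' @return parameter list of class `pathproxy_head`.
#' @export
makeRandomHead <- function(in_dim, hidden_dim = 256L, out_dim = 256L,
                           seed = 1L) {
  withSeed(seed, projectionHead(in_dim, hidden_dim, out_dim))
}

headForward <- function(x, head) {
  h <- nnLinearFwd(x, head$fc1)
  ln <- nnLayerNormFwd(h, head$ln)
  r <- pmax(ln$y, 0)
  y <- nnLinearFwd(r, head$fc2)
  list(y = y, h = h, ln = ln, r = r, x = x)
}

headBackward <- function(dy, cache, head) {
  b2 <- nnLinearBwd(dy, cache$r, head$fc2)
  dr <- b2$dx * (cache$ln$y > 0)
  bl <- nnLayerNormBwd(dr, cache$ln, head$ln)
  b1 <- nnLinearBwd(bl$dx, cache$x, head$fc1)
  list(grad = list(fc1 = b1$grad, ln = bl$grad, fc2 = b2$grad,
                   dims = head$dims * 0),
       dx = b1$dx)
}

#' Apply a projection head (evaluation mode)
#'
#' @param feature numeric vector or matrix of row features whose width
#'   matches the head's input dimension.
#' @param head a `pathproxy_head`.
#' @return projected features (same shape convention as the input); not yet
#'   L2-normalized.
#' @export
project <- function(feature, head) {
  stopifnot(inherits(head, "pathproxy_head"))
  x <- if (is.matrix(feature)) feature else matrix(feature, 1)
  stopIf(ncol(x) != head$dims[1],
         sprintf("feature length %d does not match head input %d",
                 ncol(x), head$dims[1]))
  y <- headForward(x, head)$y
  if (is.matrix(feature)) y else as.numeric(y)
}

#' L2-normalize a vector (or the rows of a matrix) onto the unit sphere
#'
#' @param x numeric vector, or matrix treated row-wise.
#' @param eps norms at or below this are an error (degenerate embedding).
#' @return unit-norm vector / matrix of unit-norm rows.
#' @export
l2Normalize <- function(x, eps = 1e-12) {
  if (is.matrix(x)) {
    n <- sqrt(rowSums(x^2))
    stopIf(any(n <= eps), "cannot normalize a (near-)zero vector")
    x / n
  } else {
    n <- sqrt(sum(x^2))
    stopIf(n <= eps, "cannot normalize a (near-)zero vector")
    x / n
  }
}

# backward through row-wise l2 normalization: v -> e = v/|v|
l2NormalizeBwd <- function(de, v) {
  n <- sqrt(rowSums(v^2))
  e <- v / n
  (de - e * rowSums(de * e)) / n
}

#' Temperature-scaled cross-modal similarity matrix
#'
#' `S[i, j] = (e_img[i] . e_path[j]) / tau` for unit embeddings, the
#' affinity structure underlying both the contrastive objective and
#' retrieval.
#'
#' @param E_img,E_path N x d matrices of unit-norm row embeddings.
#' @param tau positive temperature.
#' @return A [ScaledSimilarity-class].
#' @export
similarityMatrix <- function(E_img, E_path, tau = 0.07) {
  E_img <- if (is.matrix(E_img)) E_img else matrix(E_img, 1)
  E_path <- if (is.matrix(E_path)) E_path else matrix(E_path, 1)
  stopIf(nrow(E_img) != nrow(E_path), "modality batch sizes differ")
  stopIf(ncol(E_img) != ncol(E_path), "embedding dimensions differ")
  stopIf(tau <= 0, "tau must be positive")
  V <- (E_img %*% t(E_path)) / tau
  dimnames(V) <- NULL
  new("ScaledSimilarity", values = V, tau = tau)
}

.simValues <- function(S) {
  if (is(S, "ScaledSimilarity")) S@values else as.matrix(S)
}

#' Symmetric InfoNCE loss
#'
#' The average of the two directional contrastive losses: the row direction
#' scores each imaging anchor's softmax over all pathology candidates at the
#' diagonal (true pair), and the column direction swaps the query role.
#' Softmaxes are computed with max-subtraction stabilization so small
#' temperatures (1/tau up to 100) remain finite.
#'
#' @param S a [ScaledSimilarity-class] or a plain square matrix of scaled
#'   similarities.
#' @return nonnegative scalar loss; 0 when every diagonal softmax
#'   probability is 1 (and exactly 0 at N = 1).
#' @export
infonceSymmetric <- function(S) {
  V <- .simValues(S)
  stopIf(nrow(V) != ncol(V), "similarity matrix must be square")
  N <- nrow(V)
  logsumexp_rows <- function(M) {
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  l_row <- mean(logsumexp_rows(V) - diag(V))
  l_col <- mean(logsumexp_rows(t(V)) - diag(V))
  max(0.5 * (l_row + l_col), 0)
}

#' Analytic gradient of the symmetric InfoNCE loss
#'
#' @param S as in [infonceSymmetric()].
#' @return matrix dL/dS, equal to `((P_row - I) + (P_col - I)) / (2N)` with
#'   `P_row`/`P_col` the row- and column-wise softmaxes of S.
#' @export
infonceGradient <- function(S) {
  V <- .simValues(S)
  stopIf(nrow(V) != ncol(V), "similarity matrix must be square")
  N <- nrow(V)
  Pr <- nnSoftmaxRows(V)
  Pc <- t(nnSoftmaxRows(t(V)))
  ((Pr - diag(N)) + (Pc - diag(N))) / (2 * N)
}

#' Training configuration for contrastive alignment
#'
#' Defaults follow the reference protocol: Adam with cosine annealing from
#' 3e-3 to 1e-6, weight decay 1e-5 (applied to weight matrices only), batch
#' size 15, temperature 0.07 with grid {0.01, 0.05, 0.07, 0.1, 0.2}
#' available for selection on validation Recall@1.
#'
#' @param epochs number of epochs (reference protocol: 100).
#' @param batch_size contrastive batch size.
#' @param lr_init,lr_final cosine schedule endpoints.
#' @param weight_decay L2 coefficient on weight matrices.
#' @param tau temperature used when `tau_grid` is NULL.
#' @param tau_grid optional vector of temperatures to grid-search; the
#'   temperature with the best validation Recall@1 is selected.
#' @param embed_dim shared embedding dimension d.
#' @param hidden_img,hidden_path projection-head hidden widths.
#' @param val_fraction held-out fraction used for checkpoint/temperature
#'   selection when no explicit validation cohort is given.
#' @param seed master seed (fans out to initialization and data order).
#' @return a configuration list.
#' @export
trainConfig <- function(epochs = 100L, batch_size = 15L, lr_init = 3e-3,
                        lr_final = 1e-6, weight_decay = 1e-5, tau = 0.07,
                        tau_grid = NULL, embed_dim = 256L,
                        hidden_img = 256L, hidden_path = 512L,
                        val_fraction = 0.2, seed = 1L) {
  stopIf(epochs < 1, "epochs must be >= 1")
  stopIf(tau <= 0 || (!is.null(tau_grid) && any(tau_grid <= 0)),
         "temperatures must be positive")
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_init = lr_init, lr_final = lr_final, weight_decay = weight_decay,
       tau = tau, tau_grid = tau_grid, embed_dim = as.integer(embed_dim),
       hidden_img = as.integer(hidden_img),
       hidden_path = as.integer(hidden_path),
       val_fraction = val_fraction, seed = as.integer(seed))
}

# Extract per-sample imaging features (bypass or conv encoder) and patch
# sets from a cohort.
.cohortViews <- function(cohort, encoder = NULL) {
  feats <- lapply(cohort@samples, function(s) encodeImaging(s@imaging, encoder))
  list(img = do.call(rbind, feats),
       patches = lapply(cohort@samples, function(s) s@patches),
       ids = patientIds(cohort))
}

# Evaluation-mode embedding of prepared views under a parameter set.
.embedViews <- function(views, params, agg_template) {
  agg <- agg_template
  agg$params <- params$agg
  Z <- t(vapply(views$patches,
                function(ps) aggForward(ps@features, ps@mask, agg)$out,
                numeric(agg$config$feature_dim)))
  Ei <- l2Normalize(headForward(views$img, params$img_head)$y)
  Ep <- l2Normalize(headForward(Z, params$path_head)$y)
  list(img = Ei, path = Ep)
}

#' Embed a cohort with a trained alignment model (frozen, evaluation mode)
#'
#' @param model a `pathproxy_alignment` model from [trainAlignment()].
#' @param cohort a [PairedCohort-class].
#' @param encoder optional imaging encoder for volumetric cohorts.
#' @return list with N x d unit-row matrices `img` and `path` plus `ids`.
#' @export
embedCohort <- function(model, cohort, encoder = NULL) {
  stopifnot(inherits(model, "pathproxy_alignment"))
  views <- .cohortViews(cohort, encoder)
  e <- .embedViews(views, model$params, model$agg_template)
  c(e, list(ids = views$ids))
}

.valRecall1 <- function(params, views, agg_template) {
  e <- .embedViews(views, params, agg_template)
  ranks <- rankMatches(e$img %*% t(e$path))
  mean(ranks == 1)
}

.trainAlignmentOneTau <- function(tr_views, val_views, tau, config) {
  set.seed(deriveSeed(config$seed, 11L))
  C <- ncol(tr_views$patches[[1]]@features)
  agg_template <- initAggregator(aggregatorConfig(C),
                                 seed = deriveSeed(config$seed, 12L))
  params <- list(
    img_head = withSeed(deriveSeed(config$seed, 13L),
                        projectionHead(ncol(tr_views$img),
                                       config$hidden_img, config$embed_dim)),
    path_head = withSeed(deriveSeed(config$seed, 14L),
                         projectionHead(C, config$hidden_path,
                                        config$embed_dim)),
    agg = agg_template$params
  )
  opt <- adamInit(params)
  n <- nrow(tr_views$img)
  stopIf(n < 2, "contrastive training needs at least 2 paired samples")
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), val_recall1 = numeric(0))
  best <- list(recall = -Inf, params = params)
  agg_live <- agg_template
  for (epoch in seq_len(config$epochs)) {
    lr <- cosineLR(epoch, config$epochs, config$lr_init, config$lr_final)
    ord <- sample(n)
    losses <- c()
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      if (length(idx) < 2) next    # a singleton batch has no negatives
      Xi <- tr_views$img[idx, , drop = FALSE]
      agg_live$params <- params$agg
      fwd_aggs <- lapply(tr_views$patches[idx], function(ps)
        aggForward(ps@features, ps@mask, agg_live, training = TRUE))
      Z <- t(vapply(fwd_aggs, `[[`, numeric(C), "out"))
      fi <- headForward(Xi, params$img_head)
      fp <- headForward(Z, params$path_head)
      Ei <- l2Normalize(fi$y)
      Ep <- l2Normalize(fp$y)
      S <- (Ei %*% t(Ep)) / tau
      losses <- c(losses, infonceSymmetric(S))
      G <- infonceGradient(S)
      dEi <- (G %*% Ep) / tau
      dEp <- (t(G) %*% Ei) / tau
      bi <- headBackward(l2NormalizeBwd(dEi, fi$y), fi, params$img_head)
      bp <- headBackward(l2NormalizeBwd(dEp, fp$y), fp, params$path_head)
      dZ <- bp$dx
      agg_grad <- NULL
      for (s_i in seq_along(idx)) {
        g <- aggBackward(dZ[s_i, ], fwd_aggs[[s_i]], agg_live)$grad
        agg_grad <- if (is.null(agg_grad)) g else treeSum(agg_grad, g)
      }
      grads <- list(img_head = bi$grad, path_head = bp$grad, agg = agg_grad)
      st <- adamStep(params, grads, opt, lr, config$weight_decay)
      params <- st$params
      opt <- st$state
    }
    vr <- .valRecall1(params, val_views, agg_template)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(losses),
                                         val_recall1 = vr))
    if (vr > best$recall) best <- list(recall = vr, params = params)
  }
  list(params = best$params, final_params = params, history = history,
       best_val_recall1 = best$recall, agg_template = agg_template)
}

#' Train the cross-modal alignment model
#'
#' End-to-end optimization of the patch aggregator and both projection
#' heads under the symmetric InfoNCE objective, with Adam, a cosine-
#' annealed learning rate, weight decay on weight matrices, in-batch
#' negatives only, and checkpoint selection by best validation Recall@1.
#' When `config$tau_grid` is set, one full run per temperature is scored on
#' validation Recall@1 and the best temperature is returned.
#'
#' Imaging enters in feature-bypass mode when samples carry feature
#' vectors; volumetric samples are first encoded by the (fixed) `encoder`.
#'
#' @param cohort training [PairedCohort-class] (at least 2 samples).
#' @param val_cohort optional validation cohort; when NULL, a
#'   `val_fraction` split of `cohort` is held out.
#' @param config from [trainConfig()].
#' @param encoder optional [imagingEncoder()] for volumetric cohorts.
#' @return a `pathproxy_alignment` model: best-checkpoint parameters,
#'   selected temperature, loss/validation history, and the aggregator
#'   template.
#' @export
trainAlignment <- function(cohort, val_cohort = NULL, config = trainConfig(),
                           encoder = NULL) {
  stopifnot(is(cohort, "PairedCohort"))
  stopIf(length(cohort) < 2, "need at least 2 paired samples")
  if (is.null(val_cohort)) {
    n <- length(cohort)
    n_val <- max(2L, round(config$val_fraction * n))
    idx_val <- withSeed(deriveSeed(config$seed, 7L), sample(n, n_val))
    val_cohort <- cohort[idx_val]
    cohort <- cohort[setdiff(seq_len(n), idx_val)]
  }
  tr_views <- .cohortViews(cohort, encoder)
  val_views <- .cohortViews(val_cohort, encoder)
  taus <- if (is.null(config$tau_grid)) config$tau else config$tau_grid
  runs <- lapply(taus, function(tau)
    .trainAlignmentOneTau(tr_views, val_views, tau, config))
  scores <- vapply(runs, `[[`, numeric(1), "best_val_recall1")
  pick <- which.max(scores)
  run <- runs[[pick]]
  structure(list(params = run$params, tau = taus[pick],
                 history = run$history,
                 best_val_recall1 = run$best_val_recall1,
                 tau_scores = stats::setNames(scores, taus),
                 agg_template = run$agg_template, config = config),
            class = "pathproxy_alignment")
}

#' Save / load an alignment checkpoint
#'
#' One file bundles the aggregator and both projection heads, the selected
#' temperature, the training history and the full configuration, so a
#' frozen model can be rebuilt exactly.
#'
#' @param model a `pathproxy_alignment` model.
#' @param path checkpoint file path (RDS container).
#' @return `saveAlignment` returns `path` invisibly; `loadAlignment`
#'   returns the model.
#' @export
saveAlignment <- function(model, path) {
  stopifnot(inherits(model, "pathproxy_alignment"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveAlignment
#' @export
loadAlignment <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pathproxy_alignment"))
  model
}
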