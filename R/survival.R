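#' Binary 12-month overall-survival label
#'
#' Strictly-greater rule: label 1 iff `os_months > 12.0`; exactly 12 months
#' falls in the "not more than one year" class.
#'
#' @param os_months positive survival time(s) in months.
#' @return integer 0/1 vector.
#' @export
makeOsLabel <- function(os_months) {
  stopIf(any(os_months <= 0), "survival times must be positive")
  as.integer(os_months > 12)
}

#' Fuse an imaging feature with a proxy pathology embedding
#'
#' Deterministic channel-wise (flat vector) concatenation, imaging block
#' first, with the block boundary recorded so either block can be recovered
#' exactly.
#'
#' @param imaging_feature finite numeric imaging feature vector.
#' @param proxy unit-norm proxy pathology embedding.
#' @return list with `values`, `imaging_length`, `proxy_length`.
#' @export
fuseFeatures <- function(imaging_feature, proxy) {
  stopIf(length(imaging_feature) == 0 || length(proxy) == 0,
         "cannot fuse an empty input")
  stopIf(!all(is.finite(imaging_feature)) || !all(is.finite(proxy)),
         "inputs must be finite")
  list(values = c(as.numeric(imaging_feature), as.numeric(proxy)),
       imaging_length = length(imaging_feature),
       proxy_length = length(proxy))
}

#' Training configuration for the survival classifier
#'
#' Same optimizer and schedule as the alignment stage, with the batch size
#' raised to 20 for the classification setting. Checkpoint selection is by
#' best validation AUROC.
#'
#' @param epochs,batch_size,lr_init,lr_final,weight_decay,seed as in
#'   [trainConfig()].
#' @param hidden hidden width of the classification MLP.
#' @param val_fraction held-out fraction when no explicit validation set is
#'   given.
#' @return a configuration list.
#' @export
osTrainConfig <- function(epochs = 100L, batch_size = 20L, lr_init = 3e-3,
                          lr_final = 1e-6, weight_decay = 1e-5,
                          hidden = 32L, val_fraction = 0.25, seed = 1L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_init = lr_init, lr_final = lr_final, weight_decay = weight_decay,
       hidden = as.integer(hidden), val_fraction = val_fraction,
       seed = as.integer(seed))
}

.osForward <- function(X, params) {
  h <- nnLinearFwd(X, params$fc1)
  r <- pmax(h, 0)
  u <- as.numeric(nnLinearFwd(r, params$fc2))
  list(u = u, h = h, r = r, X = X)
}

#' Train the 12-month survival classification head
#'
#' A small feed-forward network (one rectified hidden layer, sigmoid
#' output) trained with cross-entropy, Adam, cosine-annealed learning rate
#' and weight decay. Supports any fused input mode (imaging-only,
#' imaging + trained proxy, imaging + random-projection proxy) since the
#' input is a plain feature matrix. The checkpoint with the best validation
#' AUROC is returned.
#'
#' @param features n x p feature matrix (rows standardized internally).
#' @param labels binary 0/1 vector; both classes must be present.
#' @param config from [osTrainConfig()].
#' @param val_features,val_labels optional explicit validation split; when
#'   omitted a `val_fraction` split of the data is held out.
#' @return a `pathproxy_osmodel`: parameters, feature standardization,
#'   training history and best validation AUROC.
#' @export
trainOsClassifier <- function(features, labels, config = osTrainConfig(),
                              val_features = NULL, val_labels = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopIf(length(unique(labels)) < 2,
         "training labels must contain both classes")
  if (is.null(val_features)) {
    n <- nrow(features)
    idx_val <- withSeed(deriveSeed(config$seed, 21L),
                        sample(n, max(2L, round(config$val_fraction * n))))
    val_features <- features[idx_val, , drop = FALSE]
    val_labels <- labels[idx_val]
    features <- features[-idx_val, , drop = FALSE]
    labels <- labels[-idx_val]
  }
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  sdv[sdv < 1e-8] <- 1
  Xtr <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  Xva <- sweep(sweep(as.matrix(val_features), 2, mu), 2, sdv, "/")
  set.seed(deriveSeed(config$seed, 22L))
  params <- list(fc1 = nnLinearInit(ncol(Xtr), config$hidden),
                 fc2 = nnLinearInit(config$hidden, 1L))
  opt <- adamInit(params)
  n <- nrow(Xtr)
  best <- list(auroc = -Inf, params = params)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), val_auroc = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    lr <- cosineLR(epoch, config$epochs, config$lr_init, config$lr_final)
    ord <- sample(n)
    losses <- c()
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
      X <- Xtr[idx, , drop = FALSE]
      y <- labels[idx]
      f <- .osForward(X, params)
      p <- plogis(f$u)
      eps <- 1e-12
      losses <- c(losses, -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
      du <- matrix((p - y) / length(idx), ncol = 1)
      b2 <- nnLinearBwd(du, f$r, params$fc2)
      dh <- b2$dx * (f$h > 0)
      b1 <- nnLinearBwd(dh, X, params$fc1)
      st <- adamStep(params, list(fc1 = b1$grad, fc2 = b2$grad), opt, lr,
                     config$weight_decay)
      params <- st$params
      opt <- st$state
    }
    val_scores <- plogis(.osForward(Xva, params)$u)
    va <- if (length(unique(val_labels)) < 2) NA_real_ else
      suppressWarnings(classificationMetrics(val_labels, val_scores)$auroc)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(losses), val_auroc = va))
    if (!is.na(va) && va > best$auroc)
      best <- list(auroc = va, params = params)
  }
  if (!is.finite(best$auroc)) best$params <- params
  structure(list(params = best$params, mu = mu, sd = sdv,
                 history = history, best_val_auroc = best$auroc,
                 config = config),
            class = "pathproxy_osmodel")
}

#' Predict 12-month survival probabilities
#'
#' @param model a `pathproxy_osmodel` from [trainOsClassifier()].
#' @param features n x p feature matrix (same layout as training).
#' @param ids optional patient ids for the output.
#' @return data.frame with `patient_id`, `score` (probability of surviving
#'   beyond 12 months) and `label` (score >= 0.5).
#' @export
predictOs <- function(model, features, ids = NULL) {
  stopifnot(inherits(model, "pathproxy_osmodel"))
  features <- as.matrix(features)
  stopIf(ncol(features) != length(model$mu),
         "feature length does not match the trained classifier")
  X <- sweep(sweep(features, 2, model$mu), 2, model$sd, "/")
  score <- plogis(.osForward(X, model$params)$u)
  data.frame(
    patient_id = if (is.null(ids)) sprintf("Q%04d", seq_len(nrow(X))) else ids,
    score = score, label = as.integer(score >= 0.5))
}
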