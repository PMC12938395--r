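#' Full run configuration for the end-to-end harness
#'
#' Nested sections mirror the stage configurations; every executed run
#' writes the fully-resolved configuration beside its outputs. Defaults are
#' the desk-scale study conditions: a 600-patient mediated synthetic
#' cohort, 400 of which form the paired alignment/library subset, the
#' remaining 200 the imaging-only survival subset (70/30 train/validation).
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_patients total synthetic cohort size.
#' @param n_pairs number of paired patients used for alignment and the
#'   embedding library; the rest are treated as imaging-only.
#' @param cohort named list of overrides for [syntheticConfig()].
#' @param align named list of overrides for [trainConfig()].
#' @param retrieval list with `k` (proxy neighbours for the main fusion),
#'   `k_ablation` (top-k ablation grid) and `mode`.
#' @param survival named list of overrides for [osTrainConfig()].
#' @param evaluation list with `k_values` for retrieval recall.
#' @return a `pathproxy_runcfg` list.
#' @export
runConfig <- function(seed = 1L, n_patients = 600L, n_pairs = 400L,
                      cohort = list(), align = list(),
                      retrieval = list(k = 1L,
                                       k_ablation = c(1L, 3L, 5L, 10L),
                                       mode = "cross"),
                      survival = list(),
                      evaluation = list(k_values = c(1L, 5L))) {
  stopIf(n_pairs >= n_patients, "n_pairs must be smaller than n_patients")
  align_defaults <- list(epochs = 50L, batch_size = 15L, embed_dim = 64L,
                         hidden_img = 64L, hidden_path = 128L)
  surv_defaults <- list(epochs = 60L, batch_size = 20L, hidden = 32L)
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    n_pairs = as.integer(n_pairs),
    cohort = cohort,
    align = utils::modifyList(align_defaults, align),
    retrieval = utils::modifyList(
      list(k = 1L, k_ablation = c(1L, 3L, 5L, 10L), mode = "cross"),
      retrieval),
    survival = utils::modifyList(surv_defaults, survival),
    evaluation = utils::modifyList(list(k_values = c(1L, 5L)), evaluation)
  ), class = "pathproxy_runcfg")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return a `pathproxy_runcfg`.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()          # empty file: all defaults
  do.call(runConfig, raw)
}

# Untrained alignment model with seeded random parameters: the
# random-projection control (and the random baseline for retrieval).
randomAlignmentModel <- function(img_dim, patch_dim, config, seed = 1L) {
  agg_template <- initAggregator(aggregatorConfig(patch_dim),
                                 seed = deriveSeed(seed, 31L))
  params <- list(
    img_head = makeRandomHead(img_dim, config$hidden_img, config$embed_dim,
                              seed = deriveSeed(seed, 32L)),
    path_head = makeRandomHead(patch_dim, config$hidden_path,
                               config$embed_dim,
                               seed = deriveSeed(seed, 33L)),
    agg = agg_template$params
  )
  structure(list(params = params, tau = config$tau,
                 history = NULL, best_val_recall1 = NA_real_,
                 agg_template = agg_template, config = config),
            class = "pathproxy_alignment")
}

# Project imaging features into the shared space (evaluation mode).
queryEmbed <- function(model, img_features) {
  X <- if (is.matrix(img_features)) img_features else matrix(img_features, 1)
  l2Normalize(headForward(X, model$params$img_head)$y)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a `pathproxy_runcfg` (or a [syntheticConfig()]).
#' @param out_dir output directory.
#' @return invisibly, the manifest data.frame.
#' @export
cmdSimulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "pathproxy_syncfg")) config else
    do.call(syntheticConfig,
            utils::modifyList(list(n_patients = config$n_patients,
                                   seed = config$seed), config$cohort))
  cohort <- generateCohort(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(writeCohort(cohort, out_dir))
}

.fuseMatrix <- function(img, proxies) {
  t(vapply(seq_len(nrow(img)), function(i)
    fuseFeatures(img[i, ], proxies[i, ])$values,
    numeric(ncol(img) + ncol(proxies))))
}

#' Run the full pipeline: simulate, align, retrieve, classify, evaluate
#'
#' Stages: (1) generate the mediated synthetic cohort; (2) train the
#' contrastive alignment on the paired subset; (3) build the frozen
#' embedding library; (4) retrieve proxy pathology embeddings for the
#' imaging-only survival subset; (5) train the 12-month survival classifier
#' in three input modes (imaging-only, imaging + trained proxy, imaging +
#' random-projection proxy) plus the top-k fusion ablation; (6) write
#' metric reports, the retrieval report, histories and the resolved
#' configuration. Every artifact is reproducible from (config, seed).
#'
#' @param config a `pathproxy_runcfg` from [runConfig()].
#' @param out_dir optional output directory; when NULL nothing is written.
#' @return list with `survival_metrics` (one row per input mode),
#'   `ablation` (one row per k), `retrieval` (alignment-validation
#'   retrieval report), `align_model`, and `library`.
#' @export
runPipeline <- function(config = runConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "pathproxy_runcfg"))
  log_lines <- c(sprintf("master seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  syn <- stage("simulate", {
    cfg <- do.call(syntheticConfig,
                   utils::modifyList(list(n_patients = config$n_patients,
                                          seed = deriveSeed(config$seed, 1L)),
                                     config$cohort))
    generateCohort(cfg)
  })
  idx_pairs <- seq_len(config$n_pairs)
  paired <- syn[idx_pairs]
  surv <- syn[setdiff(seq_len(config$n_patients), idx_pairs)]

  align_cfg <- do.call(trainConfig,
                       utils::modifyList(list(seed = deriveSeed(config$seed,
                                                                2L)),
                                         config$align))
  model <- stage("train-align", trainAlignment(paired, config = align_cfg))
  log_lines <- c(log_lines,
                 sprintf("selected tau: %g", model$tau),
                 sprintf("best val Recall@1: %.4f", model$best_val_recall1))

  lib <- stage("build-library", buildLibrary(model, paired))
  log_lines <- c(log_lines, sprintf("library size K: %d", length(lib)))

  rnd_model <- randomAlignmentModel(ncol(.cohortViews(paired)$img),
                                    ncol(paired[[1]]@patches@features),
                                    align_cfg,
                                    seed = deriveSeed(config$seed, 3L))
  rnd_lib <- stage("build-library-random", buildLibrary(rnd_model, paired))

  surv_views <- .cohortViews(surv)
  Q <- queryEmbed(model, surv_views$img)
  Qrnd <- queryEmbed(rnd_model, surv_views$img)
  ks <- sort(unique(c(config$retrieval$k, config$retrieval$k_ablation)))
  proxies <- stage("retrieve", lapply(stats::setNames(ks, paste0("k", ks)),
    function(k) retrieveProxies(Q, lib, k, config$retrieval$mode)$proxies))
  rnd_proxies <- stage("retrieve-random",
    retrieveProxies(Qrnd, rnd_lib, config$retrieval$k,
                    config$retrieval$mode)$proxies)

  labels <- osLabels(surv)
  n_surv <- length(surv)
  n_tr <- round(0.7 * n_surv)
  idx_tr <- withSeed(deriveSeed(config$seed, 4L), sample(n_surv, n_tr))
  idx_va <- setdiff(seq_len(n_surv), idx_tr)
  surv_cfg <- do.call(osTrainConfig,
                      utils::modifyList(list(seed = deriveSeed(config$seed,
                                                               5L)),
                                        config$survival))
  fitMode <- function(X) {
    m <- trainOsClassifier(X[idx_tr, , drop = FALSE], labels[idx_tr],
                           surv_cfg,
                           val_features = X[idx_va, , drop = FALSE],
                           val_labels = labels[idx_va])
    sc <- predictOs(m, X[idx_va, , drop = FALSE],
                    ids = surv_views$ids[idx_va])
    c(list(mode_model = m, predictions = sc),
      classificationMetrics(labels[idx_va], sc$score))
  }
  kmain <- paste0("k", config$retrieval$k)
  runs <- stage("train-os", list(
    imaging = fitMode(surv_views$img),
    trained_proxy = fitMode(.fuseMatrix(surv_views$img, proxies[[kmain]])),
    random_proxy = fitMode(.fuseMatrix(surv_views$img, rnd_proxies))
  ))
  ablation_runs <- stage("train-os-ablation",
    lapply(proxies[paste0("k", config$retrieval$k_ablation)],
           function(P) fitMode(.fuseMatrix(surv_views$img, P))))

  metric_cols <- c("accuracy", "auroc", "sensitivity", "specificity", "f1")
  survival_metrics <- data.frame(
    mode = names(runs),
    do.call(rbind, lapply(runs, function(r)
      as.data.frame(r[metric_cols]))),
    row.names = NULL)
  ablation <- data.frame(
    k = config$retrieval$k_ablation,
    do.call(rbind, lapply(ablation_runs, function(r)
      as.data.frame(r[metric_cols]))),
    row.names = NULL)

  e_val <- embedCohort(model, paired)
  retrieval_rep <- retrievalReport(e_val$img, e_val$path,
                                   config$evaluation$k_values)

  out <- list(survival_metrics = survival_metrics, ablation = ablation,
              retrieval = retrieval_rep, align_model = model,
              library = lib, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    write.csv(survival_metrics, file.path(out_dir, "survival_metrics.csv"),
              row.names = FALSE)
    write.csv(ablation, file.path(out_dir, "topk_ablation.csv"),
              row.names = FALSE)
    write.csv(model$history, file.path(out_dir, "align_history.csv"),
              row.names = FALSE)
    write.csv(data.frame(patient_id = lib@ids),
              file.path(out_dir, "library_ids.csv"), row.names = FALSE)
    write.csv(as.data.frame(lib@imgEmbeddings),
              file.path(out_dir, "library_img.csv"), row.names = FALSE)
    write.csv(as.data.frame(lib@pathEmbeddings),
              file.path(out_dir, "library_path.csv"), row.names = FALSE)
    jsonlite::write_json(list(recall_at = as.list(retrieval_rep$recall_at),
                              mrr = retrieval_rep$mrr,
                              N = retrieval_rep$N),
                         file.path(out_dir, "retrieval_report.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(runs))
      write.csv(runs[[nm]]$predictions,
                file.path(out_dir, sprintf("predictions_%s.csv", nm)),
                row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}
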