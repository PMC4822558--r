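#' Pipeline configuration
#'
#' Bundles every tunable of the extraction workflow: the instance
#' construction thresholds, the feature-family toggles, the hypernym-filter
#' toggles for training and post-processing, the classifier hyperparameters
#' and the annotation backend.  The ablation structure (LEX / DEP / HF /
#' post-processing) is runnable on any corpus by flipping these switches.
#'
#' @param k,n,stoplist See [cid_thresholds()].
#' @param features A [cid_feature_config()].
#' @param hypernym_filter Apply [filter_training_negatives()] during
#'   training.
#' @param postprocess Apply [postprocess_predictions()] to document-level
#'   output.
#' @param penalty,threshold Classifier hyperparameters (see
#'   [cid_train_model()]).
#' @param backend Annotation backend (default [stub_annotator()]).
#' @return Object of class `cid_config`.
#' @export
cid_config <- function(k = 10L, n = 3L, stoplist = "D064420",
                       features = cid_feature_config(),
                       hypernym_filter = TRUE, postprocess = TRUE,
                       penalty = 1.0, threshold = 0.5,
                       backend = stub_annotator()) {
  structure(list(
    thresholds = cid_thresholds(k = k, n = n, stoplist = stoplist),
    features = features,
    hypernym_filter = hypernym_filter,
    postprocess = postprocess,
    penalty = penalty,
    threshold = threshold,
    backend = backend
  ), class = "cid_config")
}

featurize_corpus <- function(corpus, annotations, instances, fconfig) {
  feats <- vector("list", nrow(instances))
  for (d in unique(instances$doc_id)) {
    rows <- which(instances$doc_id == d)
    feats[rows] <- extract_features(corpus[[d]], annotations[[d]],
                                    instances[rows, , drop = FALSE], fconfig)
  }
  feats
}

train_level <- function(features, labels, level, config) {
  if (length(unique(labels)) < 2L) {
    prob <- if (length(labels) && all(labels)) 1 else 0
    message("single-class training data at ", level,
            " level; using constant-probability fallback")
    return(cid_constant_model(prob, level = level,
                              threshold = config$threshold))
  }
  cid_train_model(features, labels, level = level, penalty = config$penalty,
                  threshold = config$threshold)
}

#' Train the two-level extraction system
#'
#' Runs construct -> distant-label -> hypernym-filter -> featurize -> train
#' for the intra- and inter-sentence levels and returns both models together
#' with a training report of the instance counts before and after each
#' filter.
#'
#' @param corpus Training `cid_corpus` with gold relations.
#' @param vocab A [mesh_vocabulary()].
#' @param config A [cid_config()].
#' @return Object of class `cid_pipeline`: `intra` and `inter` models,
#'   `config`, and `report`.
#' @export
cid_train <- function(corpus, vocab, config = cid_config()) {
  built <- build_instances(corpus, config$thresholds, config$backend,
                           label = TRUE)
  instances <- built$instances
  n_before <- table(factor(instances$level, levels = c("intra", "inter")))
  if (config$hypernym_filter) {
    instances <- filter_training_negatives(instances, vocab)
  }
  n_after <- table(factor(instances$level, levels = c("intra", "inter")))
  feats <- featurize_corpus(corpus, built$annotations, instances,
                            config$features)
  models <- list()
  for (lv in c("intra", "inter")) {
    sel <- instances$level == lv
    models[[lv]] <- train_level(feats[sel], instances$label[sel], lv, config)
  }
  structure(list(
    intra = models$intra,
    inter = models$inter,
    config = config,
    report = list(
      instances_before_filter = as.list(n_before),
      instances_after_filter = as.list(n_after),
      negatives_removed = sum(n_before) - sum(n_after),
      positives = as.list(table(factor(instances$level,
                                       levels = c("intra", "inter"))[instances$label]))
    )
  ), class = "cid_pipeline")
}

#' @export
#' @method print cid_pipeline
print.cid_pipeline <- function(x, ...) {
  cat("<cid_pipeline>\n  intra: ")
  print(x$intra)
  cat("  inter: ")
  print(x$inter)
  invisible(x)
}

#' Apply the trained system to a corpus
#'
#' Runs construct -> featurize -> classify -> merge -> post-process and, when
#' the input corpus carries gold relations, appends document-level and
#' (approximate, distant-label) mention-level evaluation.
#'
#' @param pipeline A trained `cid_pipeline`.
#' @param corpus Test `cid_corpus`.
#' @param vocab A [mesh_vocabulary()].
#' @return List with `predictions` (document-level positive triples with
#'   scores), `instances` (instance table with `prob`/`positive` columns),
#'   `evaluation` (document-level report or `NULL`), and `mention_scores`.
#' @export
cid_predict <- function(pipeline, corpus, vocab) {
  config <- pipeline$config
  built <- build_instances(corpus, config$thresholds, config$backend,
                           label = TRUE)
  instances <- built$instances
  feats <- featurize_corpus(corpus, built$annotations, instances,
                            config$features)
  instances$prob <- rep(NA_real_, nrow(instances))
  instances$positive <- rep(NA, nrow(instances))
  for (lv in c("intra", "inter")) {
    sel <- instances$level == lv
    if (!any(sel)) next
    pred <- cid_predict_model(pipeline[[lv]], feats[sel])
    instances$prob[sel] <- pred$prob
    instances$positive[sel] <- pred$positive
  }
  predictions <- merge_to_document(instances)
  if (config$postprocess) {
    predictions <- postprocess_predictions(predictions, vocab)
  }
  gold <- gold_relations(corpus)
  evaluation <- NULL
  mention_scores <- NULL
  if (nrow(gold)) {
    evaluation <- evaluation_report(predictions, gold)
    mention_scores <- mention_level_scores(
      instances, data.frame(positive = instances$positive))
  }
  list(predictions = predictions, instances = instances,
       evaluation = evaluation, mention_scores = mention_scores)
}

#' Write predictions as PubTator relation lines
#'
#' Attaches the predicted document-level relations to the corpus documents
#' and serializes them in the PubTator dialect.
#'
#' @param corpus The `cid_corpus` that was classified.
#' @param predictions Prediction triples from [cid_predict()].
#' @param file Optional output path.
#' @return PubTator lines (invisibly when `file` is given).
#' @export
write_predictions_pubtator <- function(corpus, predictions, file = NULL) {
  docs <- lapply(corpus, function(doc) {
    p <- predictions[predictions$doc_id == doc$doc_id, , drop = FALSE]
    doc$relations <- data.frame(chemical_id = p$chemical_id,
                                disease_id = p$disease_id,
                                stringsAsFactors = FALSE)
    doc
  })
  write_pubtator(as_corpus(docs), file = file)
}
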