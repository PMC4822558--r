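#' Train a maximum-entropy relation classifier
#'
#' A binary maximum-entropy model over sparse indicator features, realized
#' as L2-penalized (ridge) logistic regression fit with `glmnet`.  The
#' penalty strength defaults to 1.0 on the summed-log-likelihood scale
#' (i.e. `lambda = 1/n` in glmnet's per-observation parameterization), which
#' keeps weights finite on separable data while staying close to the
#' maximum-likelihood fit.  Training is deterministic: no resampling or
#' random initialization is involved.
#'
#' @param features List of character vectors, one per instance.
#' @param labels Logical vector of distant-supervision labels.
#' @param level Level tag stored with the model (`"intra"` or `"inter"`).
#' @param penalty L2 penalty strength on the total-log-likelihood scale.
#' @param threshold Posterior threshold for the positive decision.
#' @return Object of class `cid_maxent`: feature dictionary, intercept and
#'   weight vector, and the training configuration.
#' @export
cid_train_model <- function(features, labels, level = "intra",
                            penalty = 1.0, threshold = 0.5) {
  stopifnot(length(features) == length(labels), !anyNA(labels))
  if (length(unique(labels)) < 2L) {
    stop("training requires at least one instance of each class; ",
         "use a constant threshold fallback for single-class levels")
  }
  dictionary <- sort(unique(unlist(features)))
  n <- length(labels)
  ij <- do.call(rbind, lapply(seq_along(features), function(i) {
    j <- match(unique(features[[i]]), dictionary)
    if (!length(j)) return(NULL)
    cbind(i = i, j = j)
  }))
  x <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = 1,
                            dims = c(n, length(dictionary)))
  y <- labels
  # glmnet needs two observations per class; replicating the data while
  # keeping the penalty on the original total-likelihood scale leaves the
  # optimum unchanged
  if (min(table(y)) < 2L) {
    x <- rbind(x, x)
    y <- c(y, y)
  }
  lambda <- penalty / n
  # decreasing path ending at the target penalty (glmnet's recommended way
  # to obtain a single-penalty fit)
  path <- lambda * c(100, 10, 1)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 0, lambda = path,
                   standardize = FALSE, thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      # tiny-sample advisory; the caller chose the sample size
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- as.numeric(fit$beta[, length(path)])
  structure(list(
    level = level,
    dictionary = dictionary,
    intercept = fit$a0[[length(path)]],
    weights = setNames(beta, dictionary),
    penalty = penalty,
    threshold = threshold,
    n_train = n
  ), class = "cid_maxent")
}

#' @export
#' @method print cid_maxent
print.cid_maxent <- function(x, ...) {
  cat(sprintf("<cid_maxent %s: %d features, %d training instances>\n",
              x$level, length(x$dictionary), x$n_train))
  invisible(x)
}

#' Constant-probability fallback model
#'
#' Used by the pipeline when one level's training data contains a single
#' class: every instance receives the same posterior.
#'
#' @param prob Positive-class probability to emit.
#' @param level Level tag.
#' @param threshold Decision threshold.
#' @return Object of class `cid_constant`.
#' @export
cid_constant_model <- function(prob, level = "inter", threshold = 0.5) {
  structure(list(level = level, prob = prob, threshold = threshold),
            class = "cid_constant")
}

#' @export
#' @method print cid_constant
print.cid_constant <- function(x, ...) {
  cat(sprintf("<cid_constant %s: fixed positive probability %.3f>\n",
              x$level, x$prob))
  invisible(x)
}

#' Classify featurized instances
#'
#' @param model A `cid_maxent` (or `cid_constant`) model.
#' @param features List of character vectors.  Feature strings unseen in
#'   training are ignored.
#' @return Data frame with columns `prob` (positive-class posterior) and
#'   `positive` (`prob >= threshold`).
#' @export
cid_predict_model <- function(model, features) {
  if (inherits(model, "cid_constant")) {
    prob <- rep(model$prob, length(features))
  } else {
    prob <- vapply(features, function(fs) {
      known <- intersect(fs, model$dictionary)
      plogis(model$intercept + sum(model$weights[known]))
    }, numeric(1))
  }
  data.frame(prob = prob, positive = prob >= model$threshold)
}

#' Serialize a model to a flat text file
#'
#' @param model A `cid_maxent`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cid_model <- function(model, file) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("cidrex-maxent-v1",
               paste0("level\t", model$level),
               paste0("penalty\t", format(model$penalty, digits = 17)),
               paste0("threshold\t", format(model$threshold, digits = 17)),
               paste0("n_train\t", model$n_train),
               paste0("intercept\t", format(model$intercept, digits = 17))),
             con)
  writeLines(paste0(model$dictionary, "\t",
                    format(unname(model$weights), digits = 17, trim = TRUE)),
             con)
  invisible(file)
}

#' Read a serialized model
#'
#' @param file Path written by [write_cid_model()].
#' @return A `cid_maxent`.
#' @export
read_cid_model <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  stopifnot(lines[1] == "cidrex-maxent-v1")
  header <- strsplit(lines[2:6], "\t", fixed = TRUE)
  hv <- setNames(vapply(header, `[`, "", 2), vapply(header, `[`, "", 1))
  body <- strsplit(lines[-(1:6)], "\t", fixed = TRUE)
  dictionary <- vapply(body, `[`, "", 1)
  weights <- as.numeric(vapply(body, `[`, "", 2))
  structure(list(
    level = hv[["level"]],
    dictionary = dictionary,
    intercept = as.numeric(hv[["intercept"]]),
    weights = setNames(weights, dictionary),
    penalty = as.numeric(hv[["penalty"]]),
    threshold = as.numeric(hv[["threshold"]]),
    n_train = as.integer(hv[["n_train"]])
  ), class = "cid_maxent")
}

#' Merge mention-level decisions to document-level relations
#'
#' An entity pair is a document-level relation if and only if at least one
#' of its mention-level instances (either level) is classified positive;
#' the pair score is the maximum instance posterior.
#'
#' @param instance_predictions Data frame with columns `doc_id`,
#'   `chemical_id`, `disease_id`, `prob`, `positive` (instances of all
#'   levels, already classified).
#' @return Data frame of positive document-level pairs: `doc_id`,
#'   `chemical_id`, `disease_id`, `score`.
#' @export
merge_to_document <- function(instance_predictions) {
  p <- instance_predictions
  if (!nrow(p)) {
    return(data.frame(doc_id = character(), chemical_id = character(),
                      disease_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(p$doc_id, p$chemical_id, p$disease_id, sep = "\r")
  agg_pos <- tapply(p$positive, key, any)
  agg_score <- tapply(p$prob, key, max)
  parts <- strsplit(names(agg_pos), "\r", fixed = TRUE)
  out <- data.frame(
    doc_id = vapply(parts, `[`, "", 1),
    chemical_id = vapply(parts, `[`, "", 2),
    disease_id = vapply(parts, `[`, "", 3),
    score = as.numeric(agg_score),
    positive = as.logical(agg_pos),
    stringsAsFactors = FALSE)
  out <- out[out$positive, c("doc_id", "chemical_id", "disease_id", "score")]
  out <- out[order(out$doc_id, out$chemical_id, out$disease_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
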