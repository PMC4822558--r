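#' MeSH vocabulary: concept id to tree numbers
#'
#' A MeSH concept carries one or more hierarchical tree numbers
#' (dot-separated codes such as `"C14.280.067"`); the tree numbers encode
#' the hypernym/hyponym structure of the vocabulary.
#'
#' @param ids Character vector of concept identifiers (repeated for concepts
#'   with several tree numbers).
#' @param trees Character vector of tree numbers, parallel to `ids`.
#' @return Object of class `mesh_vocabulary`: a named list mapping each
#'   concept id to its set of tree numbers.
#' @export
mesh_vocabulary <- function(ids, trees) {
  stopifnot(length(ids) == length(trees))
  ok <- grepl("^[A-Z0-9.]+$", trees)
  if (!all(ok)) {
    stop("invalid tree number(s): ", paste(trees[!ok], collapse = ", "))
  }
  structure(split(trees, factor(ids, levels = unique(ids))),
            class = "mesh_vocabulary")
}

#' Read a MeSH tree-number table
#'
#' Two-column tab-separated file: concept id, tree number; one row per tree
#' number.
#'
#' @param file Path to the TSV file.
#' @return A [mesh_vocabulary()].
#' @export
read_mesh_table <- function(file) {
  tab <- read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "tree"), colClasses = "character")
  mesh_vocabulary(tab$id, tab$tree)
}

#' Is concept `a` a hypernym (more general ancestor) of concept `b`?
#'
#' True if and only if some tree number of `a` is a proper dot-boundary
#' prefix of some tree number of `b` (standard MeSH tree semantics).
#' Concepts absent from the vocabulary are never hypernyms of anything.
#'
#' @param a,b Concept identifiers.
#' @param vocab A [mesh_vocabulary()].
#' @return Logical scalar.  Irreflexive (`is_hypernym(x, x)` is `FALSE`) and
#'   transitive over tree chains.
#' @export
is_hypernym <- function(a, b, vocab) {
  if (identical(a, b)) return(FALSE)
  ta <- vocab[[a]]
  tb <- vocab[[b]]
  if (is.null(ta) || is.null(tb)) return(FALSE)
  for (x in ta) {
    if (any(startsWith(tb, paste0(x, ".")))) return(TRUE)
  }
  FALSE
}

#' Hypernym filtering of training negatives
#'
#' Within each document, removes a negative instance `(c, d)` when the
#' document also has a positive instance `(c, d')` with `d` a hypernym of
#' `d'`, or a positive instance `(c', d)` with `c` a hypernym of `c'`: a
#' negative whose entity is merely a more general ancestor of an entity
#' already participating in a positive relation with the same partner would
#' otherwise teach the classifier that a typical positive pattern is
#' negative.  Positives are never removed, and removed negatives are not
#' re-labeled positive.
#'
#' @param instances Labeled instance data frame.
#' @param vocab A [mesh_vocabulary()].
#' @param chemical_side Also filter on the chemical side (the disease-side
#'   rule mirrored); on by default.
#' @return Subset of `instances`.  Idempotent.
#' @export
filter_training_negatives <- function(instances, vocab, chemical_side = TRUE) {
  if (!nrow(instances)) return(instances)
  stopifnot(!anyNA(instances$label))
  drop <- rep(FALSE, nrow(instances))
  for (d in unique(instances$doc_id)) {
    in_doc <- instances$doc_id == d
    pos <- instances[in_doc & instances$label, , drop = FALSE]
    if (!nrow(pos)) next
    for (i in which(in_doc & !instances$label)) {
      ci <- instances$chemical_id[i]
      di <- instances$disease_id[i]
      same_chem <- pos[pos$chemical_id == ci, , drop = FALSE]
      if (any(vapply(same_chem$disease_id, function(dd)
        is_hypernym(di, dd, vocab), logical(1)))) {
        drop[i] <- TRUE
        next
      }
      if (chemical_side) {
        same_dis <- pos[pos$disease_id == di, , drop = FALSE]
        if (any(vapply(same_dis$chemical_id, function(cc)
          is_hypernym(ci, cc, vocab), logical(1)))) {
          drop[i] <- TRUE
        }
      }
    }
  }
  out <- instances[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypernym post-processing of document-level predictions
#'
#' Resolves hypernym redundancy among the predicted relations of a
#' document: a predicted pair `(c, d)` is removed when a co-predicted
#' `(c, d')` exists with `d` a hypernym of `d'`, or a co-predicted
#' `(c', d)` with `c` a hypernym of `c'` — the same rule as the training
#' filter, applied to test-time output.
#'
#' @param predictions Data frame with columns `doc_id`, `chemical_id`,
#'   `disease_id` (and optionally `score`).
#' @param vocab A [mesh_vocabulary()].
#' @param chemical_side Also filter on the chemical side.
#' @return Subset of `predictions`.  Idempotent.
#' @export
postprocess_predictions <- function(predictions, vocab, chemical_side = TRUE) {
  if (!nrow(predictions)) return(predictions)
  drop <- rep(FALSE, nrow(predictions))
  for (d in unique(predictions$doc_id)) {
    idx <- which(predictions$doc_id == d)
    for (i in idx) {
      ci <- predictions$chemical_id[i]
      di <- predictions$disease_id[i]
      for (j in setdiff(idx, i)) {
        if (predictions$chemical_id[j] == ci &&
            is_hypernym(di, predictions$disease_id[j], vocab)) {
          drop[i] <- TRUE
          break
        }
        if (chemical_side && predictions$disease_id[j] == di &&
            is_hypernym(ci, predictions$chemical_id[j], vocab)) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  out <- predictions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
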