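#' Heuristic thresholds for instance construction
#'
#' @param k Intra-sentence token-distance bound; a mention pair is kept only
#'   when its token distance is strictly less than `k` (default 10).
#' @param n Inter-sentence sentence-distance bound; strictly less than `n`
#'   (default 3).
#' @param stoplist Concept identifiers excluded from instance construction
#'   because they denote general, non-disease-specific relations; defaults to
#'   `"D064420"` ("Drug-Related Side Effects and Adverse Reactions").
#' @return Object of class `cid_thresholds`.
#' @export
cid_thresholds <- function(k = 10L, n = 3L, stoplist = "D064420") {
  stopifnot(k >= 1L, n >= 1L)
  structure(list(k = as.integer(k), n = as.integer(n), stoplist = stoplist),
            class = "cid_thresholds")
}

#' Token distance between two mentions in one sentence
#'
#' Defined as the difference between the sentence-level token index of the
#' later mention's first token and the index of the earlier mention's last
#' token; symmetric in argument order.  Two immediately adjacent mentions
#' have distance 1.
#'
#' @param ann A `cid_annotation`.
#' @param i,j Row indices into the annotated document's mention table.
#' @return Non-negative integer.
#' @export
token_distance <- function(ann, i, j) {
  mt <- ann$mention_tokens
  if (mt$sentence[i] != mt$sentence[j]) {
    stop("token_distance: mentions lie in different sentences")
  }
  if (mt$first[i] > mt$first[j]) {
    tmp <- i; i <- j; j <- tmp
  }
  mt$first[j] - mt$last[i]
}

# Is mention k of the annotated document inside parentheses?  True when an
# unbalanced '(' precedes it within its sentence.
in_parentheses <- function(ann, k) {
  mt <- ann$mention_tokens
  s <- mt$sentence[k]
  srow <- ann$sentences[ann$sentences$index == s, ]
  mstart <- ann$tokens$start[ann$tokens$sentence == s &
                               ann$tokens$index == mt$first[k]]
  before <- substring(ann$text, srow$start + 1L, mstart)
  open <- lengths(regmatches(before, gregexpr("(", before, fixed = TRUE)))
  close <- lengths(regmatches(before, gregexpr(")", before, fixed = TRUE)))
  open > close
}

empty_instances <- function() {
  data.frame(doc_id = character(), level = character(),
             chem_mention = integer(), dis_mention = integer(),
             chemical_id = character(), disease_id = character(),
             chem_sentence = integer(), dis_sentence = integer(),
             distance = integer(), label = logical(),
             stringsAsFactors = FALSE)
}

# expand a document's mentions into one row per (mention, concept id),
# dropping the unknown marker and, optionally, stoplisted ids
expanded_mentions <- function(doc, stoplist = character()) {
  m <- doc$mentions
  rows <- lapply(seq_len(nrow(m)), function(k) {
    ids <- setdiff(split_ids(m$ids[k]), stoplist)
    if (!length(ids)) return(NULL)
    data.frame(mention = k, type = m$type[k], start = m$start[k], id = ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mention = integer(), type = character(),
                      start = integer(), id = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Build intra-sentence relation instances
#'
#' For every sentence, candidate pairs of a chemical and a disease mention
#' are formed (one candidate per concept-identifier combination for
#' composite ids).  Mentions inside parentheses are ignored.  For each
#' (chemical entity, disease entity) within a sentence only the mention pair
#' with the smallest token distance is kept (ties broken by earliest
#' chemical, then earliest disease offset).  Pairs at token distance >= `k`
#' and pairs involving a stoplisted concept are dropped.
#'
#' @param doc A `cid_document`.
#' @param ann Its `cid_annotation`.
#' @param thresholds A [cid_thresholds()].
#' @return Instance data frame (one row per instance; `level = "intra"`,
#'   `distance` in tokens, `label` unset).
#' @export
build_intra_instances <- function(doc, ann, thresholds = cid_thresholds()) {
  em <- expanded_mentions(doc, thresholds$stoplist)
  if (!nrow(em)) return(empty_instances())
  mt <- ann$mention_tokens
  paren <- vapply(seq_len(nrow(doc$mentions)), function(k) in_parentheses(ann, k),
                  logical(1))
  em <- em[!paren[em$mention], , drop = FALSE]
  chems <- em[em$type == "Chemical", , drop = FALSE]
  dis <- em[em$type == "Disease", , drop = FALSE]
  if (!nrow(chems) || !nrow(dis)) return(empty_instances())

  cand <- list()
  for (ci in seq_len(nrow(chems))) {
    for (di in seq_len(nrow(dis))) {
      cm <- chems$mention[ci]; dm <- dis$mention[di]
      if (mt$sentence[cm] != mt$sentence[dm]) next
      if (cm == dm) next
      cand[[length(cand) + 1L]] <- data.frame(
        doc_id = doc$doc_id, level = "intra",
        chem_mention = cm, dis_mention = dm,
        chemical_id = chems$id[ci], disease_id = dis$id[di],
        chem_sentence = mt$sentence[cm], dis_sentence = mt$sentence[dm],
        distance = token_distance(ann, cm, dm),
        chem_start = chems$start[ci], dis_start = dis$start[di],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_instances())
  cand <- do.call(rbind, cand)
  # nearest pair per (entity pair, sentence); deterministic tie-break
  cand <- cand[order(cand$distance, cand$chem_start, cand$dis_start), ,
               drop = FALSE]
  key <- paste(cand$chemical_id, cand$disease_id, cand$chem_sentence)
  cand <- cand[!duplicated(key), , drop = FALSE]
  cand <- cand[cand$distance < thresholds$k, , drop = FALSE]
  cand$chem_start <- NULL
  cand$dis_start <- NULL
  cand$label <- rep(NA, nrow(cand))
  cand <- cand[order(cand$chem_sentence, cand$chem_mention, cand$dis_mention), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Build inter-sentence relation instances
#'
#' Entity pairs are considered at the inter-sentence level only when at
#' least one member entity appears in no intra-sentence instance of the
#' document.  Among a pair's cross-sentence mention combinations the one
#' with the smallest sentence distance (absolute difference of sentence
#' indices) is kept; pairs at sentence distance >= `n` are dropped.
#'
#' @inheritParams build_intra_instances
#' @param intra Intra-sentence instances already built for this document.
#' @return Instance data frame (`level = "inter"`, `distance` in sentences).
#' @export
build_inter_instances <- function(doc, ann, intra,
                                  thresholds = cid_thresholds()) {
  em <- expanded_mentions(doc, thresholds$stoplist)
  if (!nrow(em)) return(empty_instances())
  mt <- ann$mention_tokens
  involved <- unique(c(intra$chemical_id, intra$disease_id))
  chems <- em[em$type == "Chemical", , drop = FALSE]
  dis <- em[em$type == "Disease", , drop = FALSE]
  if (!nrow(chems) || !nrow(dis)) return(empty_instances())

  cand <- list()
  for (ci in seq_len(nrow(chems))) {
    for (di in seq_len(nrow(dis))) {
      cm <- chems$mention[ci]; dm <- dis$mention[di]
      sdist <- abs(mt$sentence[cm] - mt$sentence[dm])
      if (sdist < 1L) next
      if (chems$id[ci] %in% involved && dis$id[di] %in% involved) next
      cand[[length(cand) + 1L]] <- data.frame(
        doc_id = doc$doc_id, level = "inter",
        chem_mention = cm, dis_mention = dm,
        chemical_id = chems$id[ci], disease_id = dis$id[di],
        chem_sentence = mt$sentence[cm], dis_sentence = mt$sentence[dm],
        distance = sdist,
        chem_start = chems$start[ci], dis_start = dis$start[di],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_instances())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$distance, cand$chem_start, cand$dis_start), ,
               drop = FALSE]
  key <- paste(cand$chemical_id, cand$disease_id)
  cand <- cand[!duplicated(key), , drop = FALSE]
  cand <- cand[cand$distance < thresholds$n, , drop = FALSE]
  cand$chem_start <- NULL
  cand$dis_start <- NULL
  cand$label <- rep(NA, nrow(cand))
  cand <- cand[order(cand$chem_sentence, cand$chem_mention, cand$dis_mention), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Assign distant-supervision labels
#'
#' A mention-pair instance is labeled positive if and only if the
#' document-level gold annotation contains a CID relation between its two
#' entity identifiers; otherwise negative.  This transfers document-level
#' supervision to mention level, accepting label noise.
#'
#' @param instances Instance data frame (any mix of documents and levels).
#' @param gold Data frame with columns `doc_id`, `chemical_id`, `disease_id`
#'   (e.g. from [gold_relations()]).
#' @return `instances` with the `label` column filled (logical).
#' @export
assign_distant_labels <- function(instances, gold) {
  key <- paste(instances$doc_id, instances$chemical_id, instances$disease_id)
  gkey <- paste(gold$doc_id, gold$chemical_id, gold$disease_id)
  instances$label <- key %in% gkey
  instances
}

#' Gold relation triples of a corpus
#'
#' @param corpus A `cid_corpus`.
#' @return Data frame with columns `doc_id`, `chemical_id`, `disease_id`.
#' @export
gold_relations <- function(corpus) {
  rows <- lapply(corpus, function(doc) {
    r <- doc$relations
    if (!nrow(r)) return(NULL)
    data.frame(doc_id = doc$doc_id, chemical_id = r$chemical_id,
               disease_id = r$disease_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), chemical_id = character(),
                      disease_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build all instances of a corpus
#'
#' Convenience wrapper: annotates every document, builds intra- then
#' inter-sentence instances, and (when gold relations are present) assigns
#' distant-supervision labels.
#'
#' @param corpus A `cid_corpus`.
#' @param thresholds A [cid_thresholds()].
#' @param backend Annotation backend.
#' @param label Whether to assign distant labels from the corpus gold
#'   relations.
#' @return List with `instances` (one data frame) and `annotations` (named
#'   list of `cid_annotation` keyed by doc id).
#' @export
build_instances <- function(corpus, thresholds = cid_thresholds(),
                            backend = stub_annotator(), label = TRUE) {
  anns <- lapply(corpus, annotate_document, backend = backend)
  parts <- lapply(corpus, function(doc) {
    ann <- anns[[doc$doc_id]]
    intra <- build_intra_instances(doc, ann, thresholds)
    inter <- build_inter_instances(doc, ann, intra, thresholds)
    rbind(intra, inter)
  })
  instances <- do.call(rbind, parts)
  if (is.null(instances)) instances <- empty_instances()
  rownames(instances) <- NULL
  if (label) instances <- assign_distant_labels(instances, gold_relations(corpus))
  list(instances = instances, annotations = anns)
}
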