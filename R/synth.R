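#' Synthetic corpus configuration
#'
#' Parameters of the seedable generator of PubTator-style corpora with
#' planted CID relations, used for testing and calibration.  Defaults give
#' multi-sentence abstracts with a realistic relation density (about a third
#' of co-occurring entity pairs related), lexical trigger patterns
#' separating positives from negatives, and occasional hypernym structure.
#'
#' @param n_docs Number of documents.
#' @param sentences_min,sentences_max Range of filler sentences per abstract
#'   (entity-bearing sentences are added on top).
#' @param chemicals_min,chemicals_max Range of chemical entities per
#'   document.
#' @param diseases_min,diseases_max Range of disease entities per document.
#' @param relation_rate Probability that a (chemical, disease) entity pair
#'   of a document is a planted gold relation.
#' @param cooccur_rate Probability that a non-related pair still co-occurs
#'   in one sentence (producing a negative intra-sentence instance).
#' @param trigger_lexicon Verbs expressing a planted relation; each positive
#'   pair co-occurs at least once with a trigger between its mentions.
#' @param hypernym_pair_rate Probability that a document with a planted
#'   relation additionally mentions a more general ancestor of the related
#'   disease next to the chemical, exercising the hypernym filters.
#' @param noise_rate Probability that a non-related co-occurring pair uses a
#'   trigger pattern anyway (label noise; 0 gives a separable corpus).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 100L, sentences_min = 1L, sentences_max = 3L,
                         chemicals_min = 1L, chemicals_max = 2L,
                         diseases_min = 1L, diseases_max = 3L,
                         relation_rate = 0.3, cooccur_rate = 0.7,
                         trigger_lexicon = c("induced", "caused", "produced"),
                         hypernym_pair_rate = 0.2, noise_rate = 0,
                         seed = 1L) {
  stopifnot(n_docs >= 1L, chemicals_min >= 1L, diseases_min >= 1L,
            chemicals_max >= chemicals_min, diseases_max >= diseases_min,
            relation_rate >= 0, relation_rate <= 1,
            cooccur_rate >= 0, cooccur_rate <= 1,
            hypernym_pair_rate >= 0, hypernym_pair_rate <= 1,
            noise_rate >= 0, noise_rate <= 1, length(trigger_lexicon) >= 1L)
  structure(as.list(environment()), class = "synth_config")
}

.syllables <- c("bar", "cor", "dal", "fen", "gli", "lan", "mer", "nor",
                "pra", "quin", "ral", "sor", "tam", "vel", "xan", "zol")

synth_concepts <- function() {
  syl <- .syllables
  n_chem <- 24L
  n_dis <- 32L
  chem <- data.frame(
    id = sprintf("D6%05d", seq_len(n_chem)),
    surface = paste0(syl[(seq_len(n_chem) - 1L) %% 16L + 1L],
                     syl[(seq_len(n_chem) - 1L) %/% 16L + 3L], "ine"),
    tree = sprintf("D02.%03d", 100L + seq_len(n_chem)),
    stringsAsFactors = FALSE)
  grp <- (seq_len(n_dis) - 1L) %% 8L + 1L
  dis <- data.frame(
    id = sprintf("D0%05d", seq_len(n_dis)),
    surface = paste0(syl[(seq_len(n_dis) - 1L) %% 16L + 1L],
                     syl[(seq_len(n_dis) - 1L) %/% 16L + 5L], "itis"),
    tree = sprintf("C%02d.%03d.%03d", 10L + grp, 200L + grp, 500L + seq_len(n_dis)),
    stringsAsFactors = FALSE)
  parent <- data.frame(
    id = sprintf("D9%05d", seq_len(n_dis)),
    surface = paste0(syl[(seq_len(n_dis) - 1L) %% 16L + 1L],
                     syl[(seq_len(n_dis) - 1L) %/% 16L + 5L], "opathy"),
    tree = sprintf("C%02d.%03d", 10L + grp, 200L + grp),
    stringsAsFactors = FALSE)
  list(chemicals = chem, diseases = dis, parents = parent)
}

.filler_words <- c("clinical", "course", "was", "reviewed", "during",
                   "routine", "follow", "up", "visits", "laboratory",
                   "values", "remained", "stable", "over", "the", "study",
                   "period")

# one sentence = a character vector of words; mentions annotated as
# (word index range, type, id, surface)
synth_sentence <- function(words, mentions = NULL) {
  list(words = words, mentions = mentions)
}

mention_at <- function(word_from, word_to, type, id, surface) {
  data.frame(word_from = word_from, word_to = word_to, type = type, id = id,
             surface = surface, stringsAsFactors = FALSE)
}

positive_sentence <- function(chem, dis, trigger) {
  # trigger verb strictly between the mentions, token distance well under 10
  dwords <- strsplit(dis$surface, " ", fixed = TRUE)[[1]]
  words <- c("Treatment", "with", chem$surface, "frequently", trigger,
             dwords, "in", "patients", ".")
  synth_sentence(words, rbind(
    mention_at(3L, 3L, "Chemical", chem$id, chem$surface),
    mention_at(6L, 5L + length(dwords), "Disease", dis$id, dis$surface)))
}

negative_sentence <- function(chem, dis) {
  dwords <- strsplit(dis$surface, " ", fixed = TRUE)[[1]]
  words <- c("Patients", "receiving", chem$surface, "were", "monitored",
             "for", dwords, "at", "baseline", ".")
  synth_sentence(words, rbind(
    mention_at(3L, 3L, "Chemical", chem$id, chem$surface),
    mention_at(7L, 6L + length(dwords), "Disease", dis$id, dis$surface)))
}

hypernym_sentence <- function(chem, parent) {
  words <- c("Overall", "management", "with", chem$surface, "and", "general",
             parent$surface, "outcomes", "were", "recorded", ".")
  synth_sentence(words, rbind(
    mention_at(4L, 4L, "Chemical", chem$id, chem$surface),
    mention_at(7L, 7L, "Disease", parent$id, parent$surface)))
}

standalone_sentence <- function(concept, type) {
  words <- if (type == "Chemical") {
    c("Therapy", "with", concept$surface, "continued", "unchanged", ".")
  } else {
    c("Signs", "of", concept$surface, "were", "recorded", "separately", ".")
  }
  k <- if (type == "Chemical") 3L else 3L
  synth_sentence(words, mention_at(k, k, type, concept$id, concept$surface))
}

filler_sentence <- function() {
  n <- sample(5:9, 1L)
  words <- c(sample(.filler_words, n, replace = TRUE), ".")
  words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
  synth_sentence(words)
}

assemble_document <- function(doc_id, title_words, sentences, gold) {
  title <- paste(title_words, collapse = " ")
  mention_rows <- list()
  abs_parts <- character(length(sentences))
  offset <- nchar(title) + 1L    # abstract offsets continue after title + space
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    w <- s$words
    starts <- offset + c(0L, cumsum(nchar(w) + 1L))[seq_along(w)]
    if (!is.null(s$mentions)) {
      for (k in seq_len(nrow(s$mentions))) {
        mrow <- s$mentions[k, ]
        mstart <- starts[mrow$word_from]
        mend <- starts[mrow$word_to] + nchar(w[mrow$word_to])
        mention_rows[[length(mention_rows) + 1L]] <- data.frame(
          start = mstart, end = mend, text = mrow$surface, type = mrow$type,
          ids = mrow$id, stringsAsFactors = FALSE)
      }
    }
    abs_parts[si] <- paste(w, collapse = " ")
    offset <- offset + sum(nchar(w)) + length(w)   # + joining/trailing spaces
  }
  abstract <- paste(abs_parts, collapse = " ")
  mentions <- if (length(mention_rows)) do.call(rbind, mention_rows)
  else empty_mentions()
  cid_document(doc_id, title, abstract, mentions, gold)
}

#' Generate a synthetic corpus with planted relations
#'
#' Produces a corpus of PubTator-style documents in which every planted
#' (gold) chemical-disease pair co-occurs at least once with a trigger verb
#' between the mentions at a token distance well under the intra-sentence
#' bound, non-related pairs co-occur with neutral wording (or, with
#' probability `noise_rate`, with a spurious trigger), and some documents
#' carry a hypernym ancestor of a related disease alongside the chemical.
#' Identical seeds give byte-identical corpora.
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (a `cid_corpus`), `vocab` (a
#'   [mesh_vocabulary()] covering all concepts including the hypernym
#'   ancestors), and `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  pools <- synth_concepts()
  withr::with_seed(config$seed, {
    docs <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      n_c <- sample(config$chemicals_min:config$chemicals_max, 1L)
      n_d <- sample(config$diseases_min:config$diseases_max, 1L)
      chems <- pools$chemicals[sample(nrow(pools$chemicals), n_c), ,
                               drop = FALSE]
      dis <- pools$diseases[sample(nrow(pools$diseases), n_d), , drop = FALSE]
      sentences <- list()
      gold <- empty_relations()
      mentioned <- character()
      for (ci in seq_len(n_c)) {
        for (di in seq_len(n_d)) {
          if (stats::runif(1) < config$relation_rate) {
            trig <- sample(config$trigger_lexicon, 1L)
            sentences[[length(sentences) + 1L]] <-
              positive_sentence(chems[ci, ], dis[di, ], trig)
            gold <- rbind(gold, data.frame(chemical_id = chems$id[ci],
                                           disease_id = dis$id[di],
                                           stringsAsFactors = FALSE))
            mentioned <- c(mentioned, chems$id[ci], dis$id[di])
            if (stats::runif(1) < config$hypernym_pair_rate) {
              parent <- pools$parents[match(dis$id[di], pools$diseases$id), ]
              sentences[[length(sentences) + 1L]] <-
                hypernym_sentence(chems[ci, ], parent)
            }
          } else if (stats::runif(1) < config$cooccur_rate) {
            sentences[[length(sentences) + 1L]] <-
              if (stats::runif(1) < config$noise_rate) {
                positive_sentence(chems[ci, ], dis[di, ],
                                  sample(config$trigger_lexicon, 1L))
              } else {
                negative_sentence(chems[ci, ], dis[di, ])
              }
            mentioned <- c(mentioned, chems$id[ci], dis$id[di])
          }
        }
      }
      for (ci in seq_len(n_c)) {
        if (!(chems$id[ci] %in% mentioned)) {
          sentences[[length(sentences) + 1L]] <-
            standalone_sentence(chems[ci, ], "Chemical")
        }
      }
      for (di in seq_len(n_d)) {
        if (!(dis$id[di] %in% mentioned)) {
          sentences[[length(sentences) + 1L]] <-
            standalone_sentence(dis[di, ], "Disease")
        }
      }
      n_fill <- sample(config$sentences_min:config$sentences_max, 1L)
      for (i in seq_len(n_fill)) {
        sentences[[length(sentences) + 1L]] <- filler_sentence()
      }
      sentences <- sentences[sample(length(sentences))]
      docs[[d]] <- assemble_document(
        sprintf("9%06d", d),
        c("Observational", "report", sprintf("%d", d), "."),
        sentences, unique(gold))
    }
    all_concepts <- rbind(pools$chemicals, pools$diseases, pools$parents)
    list(corpus = as_corpus(docs),
         vocab = mesh_vocabulary(all_concepts$id, all_concepts$tree),
         config = config)
  })
}
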