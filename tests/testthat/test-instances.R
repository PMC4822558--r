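# Instance construction on the two worked-example documents plus generated
# corpora: heuristic filters, distances, labels, and monotonicity.

test_that("token distances in the observation sentence are 3 and 5", {
  doc <- example_documents()[["10328196"]]
  ann <- annotate_document(doc)
  m <- doc$mentions
  siro_b1 <- which(m$text == "sirolimus")[2]   # first sirolimus of sentence (b)
  siro_b2 <- which(m$text == "sirolimus")[3]
  cls_b <- which(m$text == "capillary leak syndrome")[2]
  psor_b <- which(m$text == "psoriasis")[2]
  expect_equal(token_distance(ann, siro_b1, cls_b), 3L)
  expect_equal(token_distance(ann, cls_b, siro_b1), 3L)  # symmetric
  expect_equal(token_distance(ann, siro_b2, psor_b), 5L)
  expect_error(token_distance(ann, siro_b1, which(m$text == "inflammatory")),
               "different sentences")
})

test_that("adjacent mentions have token distance 1", {
  title <- "Aspirin headache link."
  doc <- cid_document("21", title, "",
                      data.frame(start = c(0L, 8L), end = c(7L, 16L),
                                 text = c("Aspirin", "headache"),
                                 type = c("Chemical", "Disease"),
                                 ids = c("D001241", "D006261"),
                                 stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  expect_equal(token_distance(ann, 1L, 2L), 1L)
})

test_that("intra construction reproduces the worked example", {
  doc <- example_documents()[["10328196"]]
  ann <- annotate_document(doc)
  intra <- build_intra_instances(doc, ann)
  pairs <- unique(paste(intra$chemical_id, intra$disease_id))
  expect_setequal(pairs, c("D020123 D019559", "D020123 D011565"))
  # sentence (b) contributes the printed nearest pairs at distances 3 and 5
  b <- intra[intra$chem_sentence == 2L, ]
  expect_setequal(b$distance, c(3L, 5L))
  # the psoriasis--sirolimus combination of sentence (a) sits exactly at the
  # bound (distance 10) and is discarded as overlong
  expect_false(any(intra$chem_sentence == 1L & intra$disease_id == "D011565"))
})

test_that("distance bounds are strict: a pair at distance k is excluded", {
  doc <- example_documents()[["10328196"]]
  ann <- annotate_document(doc)
  at10 <- build_intra_instances(doc, ann, cid_thresholds(k = 10))
  at11 <- build_intra_instances(doc, ann, cid_thresholds(k = 11))
  expect_false(any(at10$distance >= 10L))
  expect_true(any(at11$distance == 10L))     # the sentence-(a) psoriasis pair
})

test_that("parenthesized mentions are ignored at the intra level", {
  title <- "A study."
  abstract <- "Severe rash appeared under treatment ( aspirin ) in all cases."
  text <- paste(title, abstract)
  loc <- function(what) regexpr(what, text, fixed = TRUE) - 1L
  doc <- cid_document("22", title, abstract, data.frame(
    start = c(loc("rash"), loc("aspirin")),
    end = c(loc("rash") + 4L, loc("aspirin") + 7L),
    text = c("rash", "aspirin"), type = c("Disease", "Chemical"),
    ids = c("D012871", "D001241"), stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  expect_equal(nrow(build_intra_instances(doc, ann)), 0L)
})

test_that("inter construction pairs only entities uninvolved at intra level", {
  docs <- example_documents()
  doc <- docs[["10328196"]]
  ann <- annotate_document(doc)
  intra <- build_intra_instances(doc, ann)
  inter <- build_inter_instances(doc, ann, intra)
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$chemical_id, "D020123")
  expect_equal(inter$disease_id, "D007249")    # the "inflammatory" entity
  expect_equal(inter$distance, 1L)
  # psoriasis and capillary-leak pairs are omitted: both members have
  # intra-sentence co-occurrence
  expect_false("D011565" %in% inter$disease_id)
  expect_false("D019559" %in% inter$disease_id)
})

test_that("a document whose every entity is intra-involved yields no inter instances", {
  doc <- example_documents()[["1728915"]]
  ann <- annotate_document(doc)
  intra <- build_intra_instances(doc, ann)
  expect_equal(nrow(build_inter_instances(doc, ann, intra)), 0L)
})

test_that("sentence-distance bound is strict and instances are disjoint across levels", {
  gen <- generate_corpus(synth_config(n_docs = 30, seed = 11,
                                      cooccur_rate = 0.3))
  built <- build_instances(gen$corpus)
  inst <- built$instances
  expect_true(all(inst$distance[inst$level == "intra"] < 10L))
  expect_true(all(inst$distance[inst$level == "inter"] >= 1L &
                    inst$distance[inst$level == "inter"] < 3L))
  key <- paste(inst$doc_id, inst$chemical_id, inst$disease_id)
  expect_equal(anyDuplicated(key[inst$level == "inter"]), 0L)
  # at most one intra instance per (entity pair, sentence)
  ikey <- paste(key, inst$chem_sentence)[inst$level == "intra"]
  expect_equal(anyDuplicated(ikey), 0L)
  # no pair appears at both levels
  expect_length(intersect(key[inst$level == "intra"], key[inst$level == "inter"]), 0L)
})

test_that("shrinking k or n never increases the instance count", {
  gen <- generate_corpus(synth_config(n_docs = 20, seed = 12))
  counts <- function(k, n) {
    nrow(build_instances(gen$corpus, cid_thresholds(k = k, n = n))$instances)
  }
  base <- counts(10, 3)
  for (k in c(8, 5, 2)) expect_lte(counts(k, 3), base)
  for (n in c(2, 1)) expect_lte(counts(10, n), base)
})

test_that("distant labels follow the document-level gold relations", {
  docs <- example_documents()
  built <- build_instances(docs)
  inst <- built$instances
  d1 <- inst[inst$doc_id == "10328196", ]
  expect_true(d1$label[d1$disease_id == "D019559"][1])      # sirolimus-CLS
  expect_false(any(d1$label[d1$disease_id == "D011565"]))   # psoriasis
  d2 <- inst[inst$doc_id == "1728915", ]
  expect_equal(sum(d2$label), 2L)
  # a document with an empty gold set labels everything negative
  nogold <- docs[["10328196"]]
  nogold$relations <- nogold$relations[0, ]
  built2 <- build_instances(make_corpus(list(nogold)))
  expect_false(any(built2$instances$label))
})

test_that("stoplisted general concepts never form instances", {
  title <- "A case."
  abstract <- "Aspirin caused severe adverse reactions today."
  text <- paste(title, abstract)
  loc <- function(what) regexpr(what, text, fixed = TRUE) - 1L
  doc <- cid_document("23", title, abstract, data.frame(
    start = c(loc("Aspirin"), loc("adverse reactions")),
    end = c(loc("Aspirin") + 7L, loc("adverse reactions") + 17L),
    text = c("Aspirin", "adverse reactions"),
    type = c("Chemical", "Disease"), ids = c("D001241", "D064420"),
    stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  expect_equal(nrow(build_intra_instances(doc, ann)), 0L)
  keep <- build_intra_instances(doc, ann, cid_thresholds(stoplist = character()))
  expect_equal(nrow(keep), 1L)
})

test_that("composite identifier fields spawn one candidate per identifier", {
  title <- "A case."
  abstract <- "Aspirin caused rash quickly."
  text <- paste(title, abstract)
  loc <- function(what) regexpr(what, text, fixed = TRUE) - 1L
  doc <- cid_document("24", title, abstract, data.frame(
    start = c(loc("Aspirin"), loc("rash")),
    end = c(loc("Aspirin") + 7L, loc("rash") + 4L),
    text = c("Aspirin", "rash"), type = c("Chemical", "Disease"),
    ids = c("D001241", "D012871|D003875"), stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  intra <- build_intra_instances(doc, ann)
  expect_setequal(intra$disease_id, c("D012871", "D003875"))
  # the unknown marker produces nothing
  doc$mentions$ids[2] <- "-1"
  expect_equal(nrow(build_intra_instances(doc, annotate_document(doc))), 0L)
})
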