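test_that("the block tokenizer splits letter/digit runs and single punctuation", {
  expect_equal(cid_tokenize("Lidocaine-induced")$text,
               c("Lidocaine", "-", "induced"))
  expect_equal(cid_tokenize("2.3-fold")$text, c("2", ".", "3", "-", "fold"))
  expect_equal(nrow(cid_tokenize("")), 0L)
  expect_equal(nrow(cid_tokenize("   ")), 0L)
})

test_that("token offsets slice the input and no token mixes classes", {
  texts <- c("Carbamazepine-induced cardiac dysfunction.",
             "A 2.3-fold increase (to 48%) was seen!",
             "x")
  for (txt in texts) {
    toks <- cid_tokenize(txt)
    expect_equal(substring(txt, toks$start + 1L, toks$end), toks$text)
    expect_false(any(grepl("[[:alnum:]]", toks$text) &
                       grepl("[^[:alnum:]]", toks$text)))
  }
})

test_that("tokenization is idempotent on re-joined token text", {
  txt <- "Sirolimus-induced capillary leak syndrome (21%)."
  once <- cid_tokenize(txt)$text
  again <- cid_tokenize(paste(once, collapse = " "))$text
  expect_equal(again, once)
})

test_that("mention masking uses the Doc_pmid_start_end_Type convention", {
  doc <- example_documents()[["10328196"]]
  masked <- mask_mentions(doc)
  siro1 <- doc$mentions[doc$mentions$text == "sirolimus", ][1, ]
  expect_true(grepl(sprintf("Doc_10328196_%d_%d_Chemical", siro1$start, siro1$end),
                    masked$text, fixed = TRUE))
  expect_true(grepl("Doc_10328196_[0-9]+_[0-9]+_Disease", masked$text))
  # every placeholder stands where its mention stood
  for (k in seq_len(nrow(masked$map))) {
    expect_equal(substring(masked$text, masked$map$masked_start[k] + 1L,
                           masked$map$masked_end[k]),
                 masked$map$token[k])
  }
  expect_equal(unmask_mentions(masked$text, masked$map), doc_text(doc))
})

test_that("masking a document without mentions is the identity", {
  doc <- cid_document("5", "No entities here.", "Plain text only.")
  masked <- mask_mentions(doc)
  expect_equal(masked$text, doc_text(doc))
  expect_equal(nrow(masked$map), 0L)
})

test_that("overlapping mentions are masked once, keeping the longer span", {
  title <- "Capillary leak syndrome occurred."
  mentions <- data.frame(
    start = c(0L, 0L), end = c(23L, 14L),
    text = c("Capillary leak syndrome", "Capillary leak"),
    type = "Disease", ids = c("D019559", "D019559"),
    stringsAsFactors = FALSE)
  doc <- cid_document("6", title, "", mentions)
  masked <- suppressMessages(mask_mentions(doc))
  expect_equal(sum(grepl("Doc_6_", strsplit(masked$text, " ")[[1]], fixed = TRUE)), 1L)
  expect_true(grepl("Doc_6_0_23_Disease", masked$text, fixed = TRUE))
})

test_that("the stub annotator is deterministic and sentence-aligns mentions", {
  doc <- example_documents()[["1728915"]]
  a1 <- annotate_document(doc)
  a2 <- annotate_document(doc)
  expect_identical(a1$tokens, a2$tokens)
  expect_identical(a1$sentences, a2$sentences)
  expect_equal(a1$tokens$text[a1$tokens$sentence == 0],
               c("Carbamazepine", "-", "induced", "cardiac", "dysfunction", "."))
  # each mention wholly inside one sentence
  mt <- a1$mention_tokens
  expect_false(anyNA(mt$sentence))
  expect_true(all(mt$first <= mt$last))
})

test_that("sentence spans tile the text without overlap and carry block labels", {
  doc <- example_documents()[["10328196"]]
  ann <- annotate_document(doc)
  s <- ann$sentences
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  expect_equal(s$block_label[1], "TITLE")
  expect_true("OBSERVATIONS" %in% s$block_label)
  # the block opened by a header is inherited by the following sentence
  obs <- which(s$block_label == "OBSERVATIONS")
  expect_equal(obs, c(3L, 4L))
})

test_that("a sentence boundary splitting a mention is repaired", {
  title <- "A report."
  abstract <- "We studied St. John extract in detail. It was safe."
  text <- paste(title, abstract)
  p <- regexpr("St. John extract", text, fixed = TRUE)
  doc <- cid_document("8", title, abstract,
                      data.frame(start = p - 1L, end = p + 15L,
                                 text = "St. John extract", type = "Chemical",
                                 ids = "D000001", stringsAsFactors = FALSE))
  expect_message(ann <- annotate_document(doc), "repairing sentence boundary")
  mt <- ann$mention_tokens
  expect_length(unique(ann$tokens$sentence[ann$tokens$start >= p - 1L &
                                             ann$tokens$end <= p + 15L]), 1L)
})

test_that("pre-parsed annotations load from the interchange TSV", {
  doc <- cid_document("12", "Aspirin helps.", "")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("doc_id\tsentence\tindex\ttext\tstart\tend\tpos\tlemma\thead\tlabel",
               "12\t0\t0\tAspirin\t0\t7\tNN\taspirin\t1\tnsubj",
               "12\t0\t1\thelps\t8\t13\tVBZ\thelp\t-1\troot",
               "12\t0\t2\t.\t13\t14\t.\t.\t1\tpunct"), tsv)
  ann <- read_annotation_tsv(tsv, doc)
  expect_equal(ann$tokens$lemma, c("aspirin", "help", "."))
  expect_length(ann$graphs, 1L)
  expect_equal(ann$graphs[[1]]$root, 1L)
  expect_equal(sort(ann$graphs[[1]]$edges$dependent), c(0L, 2L))
})

test_that("dependency graph construction rejects non-trees", {
  edges_two_heads <- data.frame(head = c(1L, 2L), dependent = c(0L, 0L),
                                label = "dep")
  expect_error(dependency_graph(1L, edges_two_heads, 3L), "exactly one head")
  expect_error(dependency_graph(0L,
                                data.frame(head = 2L, dependent = 1L, label = "dep"),
                                3L), "")
})
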