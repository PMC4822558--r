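# Feature extraction: template semantics on the worked examples plus
# mutual-exclusion and registry properties.

title_instance <- function() {
  doc <- example_documents()[["1728915"]]
  ann <- annotate_document(doc)
  intra <- build_intra_instances(doc, ann)
  list(doc = doc, ann = ann,
       inst = intra[intra$disease_id == "D006331", ][1, ])
}

test_that("in-between templates fire as printed for the title instance", {
  tc <- title_instance()
  fs <- extract_intra_lex(tc$doc, tc$ann, tc$inst)
  # two tokens between the mentions: "-" and "induced"
  expect_true("I:WBF=-" %in% fs)
  expect_true("I:WBL=induced" %in% fs)
  # "induced" is the only verb in between
  expect_true("I:WVFL" %in% fs)
  expect_true("I:WVTFL=induced" %in% fs)
  expect_true("I:WVLFL=induce" %in% fs)
  # instance occurs in the title
  expect_true("I:WINT" %in% fs)
  # mention templates
  expect_true("I:CMTXT=Carbamazepine" %in% fs)
  expect_true("I:DMTXT=cardiac dysfunction" %in% fs)
  expect_setequal(fs[startsWith(fs, "I:DBOW")],
                  c("I:DBOW=cardiac", "I:DBOW=dysfunction"))
  # sentence-boundary sentinels before the first mention
  expect_true("I:BM1F=<S>" %in% fs)
  expect_true("I:BM1L=<S>" %in% fs)
})

test_that("adjacent mentions emit WBNULL and nothing else from the WB family", {
  doc <- cid_document("21", "Aspirin headache link.", "",
                      data.frame(start = c(0L, 8L), end = c(7L, 16L),
                                 text = c("Aspirin", "headache"),
                                 type = c("Chemical", "Disease"),
                                 ids = c("D001241", "D006261"),
                                 stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  inst <- build_intra_instances(doc, ann)[1, ]
  fs <- extract_intra_lex(doc, ann, inst)
  expect_true("I:WBNULL" %in% fs)
  expect_true("I:WVNULL" %in% fs)
  expect_false(any(grepl("^I:WB[FL]", fs)))
  expect_false(any(grepl("^I:WV[FTL]", fs)))
})

test_that("WB/WV families are mutually exclusive by between-token count", {
  gen <- generate_corpus(synth_config(n_docs = 15, seed = 21, noise_rate = 0.3))
  built <- build_instances(gen$corpus)
  inst <- built$instances
  for (d in unique(inst$doc_id)) {
    rows <- inst[inst$doc_id == d & inst$level == "intra", , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      fs <- extract_intra_lex(gen$corpus[[d]], built$annotations[[d]], rows[i, ])
      if ("I:WBNULL" %in% fs) {
        expect_false(any(grepl("^I:WB(F|L|TFL|LFL|TPOS)", fs)))
      }
      if ("I:WBFL" %in% fs) {
        expect_true(any(startsWith(fs, "I:WBTFL=")))
        expect_false(any(startsWith(fs, "I:WBF=")))
      }
      if ("I:WVNULL" %in% fs) {
        expect_false(any(grepl("^I:WV(F|L|O|TFL|LFL)", fs)))
      }
      check_feature_registry(fs)
    }
  }
})

test_that("feature extraction is a pure function of instance and annotation", {
  docs <- example_documents()
  built <- build_instances(docs)
  d <- "10328196"
  inst <- built$instances[built$instances$doc_id == d, ]
  f1 <- extract_features(docs[[d]], built$annotations[[d]], inst)
  f2 <- extract_features(docs[[d]], built$annotations[[d]], inst)
  expect_identical(f1, f2)
  expect_true(all(lengths(f1) > 0L))
  check_feature_registry(f1)
})

test_that("dependency templates follow the fixture graph", {
  tc <- title_instance()
  # linear tree: induced is the root; Carbamazepine and dysfunction hang off
  # it, cardiac modifies dysfunction, punctuation attaches to the root
  g <- dependency_graph(
    root = 2L,
    edges = data.frame(head = c(2L, 2L, 2L, 4L, 2L),
                       dependent = c(0L, 1L, 4L, 3L, 5L),
                       label = c("nsubj", "punct", "dobj", "amod", "punct")),
    n_tokens = 6L)
  fs <- extract_intra_dep(tc$doc, tc$ann, tc$inst, graph = g)
  expect_false("I:WCDD" %in% fs)      # heads connect through "induced"
  expect_false("I:WRCD" %in% fs)      # chemical head is not the root
  expect_false("I:WRDD" %in% fs)
  expect_true("I:DPC2D=nsubj-dobj" %in% fs)
  expect_true("I:DPNS=CHEMICAL-induced-DISEASE" %in% fs)
  expect_true("I:VBLS=induce" %in% fs)
  expect_true("I:DPR2C=nsubj" %in% fs)
  check_feature_registry(fs)
})

test_that("direct edges and a root-mention degenerate path set the flags", {
  tc <- title_instance()
  # chemical head IS the root; disease head hangs directly off it
  g <- dependency_graph(
    root = 0L,
    edges = data.frame(head = c(0L, 0L, 0L, 4L, 0L),
                       dependent = c(1L, 2L, 4L, 3L, 5L),
                       label = c("punct", "acl", "nmod", "amod", "punct")),
    n_tokens = 6L)
  fs <- extract_intra_dep(tc$doc, tc$ann, tc$inst, graph = g)
  expect_true("I:WCDD" %in% fs)
  expect_true("I:WRCD" %in% fs)       # chemical head = root, empty root path
  expect_true("I:DPR2C=" %in% fs)
  expect_false("I:WRDD" %in% fs)
  expect_true("I:DPC2D=nmod" %in% fs)
})

test_that("long dependency paths collapse to the LONG sentinel", {
  title <- paste(c("Aaa", letters[1:9], "bbb", "."), collapse = " ")
  bpos <- regexpr("bbb", title, fixed = TRUE) - 1L
  doc <- cid_document("31", title, "",
                      data.frame(start = c(0L, bpos), end = c(3L, bpos + 3L),
                                 text = c("Aaa", "bbb"),
                                 type = c("Chemical", "Disease"),
                                 ids = c("D1", "D2"), stringsAsFactors = FALSE))
  ann <- annotate_document(doc)
  inst <- build_intra_instances(doc, ann, cid_thresholds(k = 50))[1, ]
  # a chain graph: 0 <- 1 <- 2 ... <- 10, root at the disease end
  n <- nrow(ann$tokens)
  g <- dependency_graph(
    root = n - 1L,
    edges = data.frame(head = seq_len(n - 1L), dependent = seq_len(n - 1L) - 1L,
                       label = "dep"),
    n_tokens = n)
  fs <- extract_intra_dep(doc, ann, inst, graph = g)
  expect_true("I:DPC2D=LONG" %in% fs)
})

test_that("inter-sentence templates encode distance, frequency and blocks", {
  docs <- example_documents()
  built <- build_instances(docs)
  d <- "10328196"
  inter <- built$instances[built$instances$doc_id == d &
                             built$instances$level == "inter", ][1, ]
  fs <- extract_inter_lex(docs[[d]], built$annotations[[d]], inter)
  expect_true("X:SDIST=1" %in% fs)
  expect_true("X:SDIST=bucket:1" %in% fs)
  expect_true("X:CFRQ=3" %in% fs)     # three sirolimus mentions
  expect_true("X:DFRQ=1" %in% fs)     # one "inflammatory" mention
  expect_true("X:WCO" %in% fs)        # sirolimus is the only chemical entity
  expect_false("X:WDO" %in% fs)       # three disease entities
  expect_true("X:SMBLOCK" %in% fs)    # sentences (b) and (c) share the block
  check_feature_registry(fs)
})

test_that("namespaces separate intra and inter feature spaces", {
  gen <- generate_corpus(synth_config(n_docs = 10, seed = 5))
  built <- build_instances(gen$corpus)
  inst <- built$instances
  feats <- lapply(seq_len(nrow(inst)), function(i) {
    d <- inst$doc_id[i]
    extract_features(gen$corpus[[d]], built$annotations[[d]],
                     inst[i, , drop = FALSE])[[1]]
  })
  intra_fs <- unlist(feats[inst$level == "intra"])
  inter_fs <- unlist(feats[inst$level == "inter"])
  expect_true(all(startsWith(intra_fs, "I:")))
  expect_true(all(startsWith(inter_fs, "X:")))
})

test_that("unknown templates are rejected by the registry check", {
  expect_error(check_feature_registry("I:BOGUS=1"), "unknown feature template")
  expect_error(check_feature_registry("X:DPC2D=a"), "unknown feature template")
  expect_silent(check_feature_registry(list(c("I:WINT", "X:SMBLOCK"))))
})
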