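# Shared fixtures built in code.

subset_corpus <- function(corpus, sel) {
  structure(corpus[sel], class = "cid_corpus")
}

# A tiny hand-made document: one chemical, two diseases, one gold relation.
# "Aspirin caused headache . Dizziness was unrelated ."
tiny_document <- function(doc_id = "1001") {
  title <- "A tiny report."
  abstract <- "Aspirin caused headache in two patients. Dizziness was unrelated."
  text <- paste(title, abstract)
  loc <- function(what) {
    p <- regexpr(what, text, fixed = TRUE)
    data.frame(start = p - 1L, end = p - 1L + attr(p, "match.length"),
               text = what, stringsAsFactors = FALSE)
  }
  mentions <- rbind(
    cbind(loc("Aspirin"), type = "Chemical", ids = "D001241"),
    cbind(loc("headache"), type = "Disease", ids = "D006261"),
    cbind(loc("Dizziness"), type = "Disease", ids = "D004244"))
  cid_document(doc_id, title, abstract, mentions,
               data.frame(chemical_id = "D001241", disease_id = "D006261",
                          stringsAsFactors = FALSE))
}

# Vocabulary with a three-level chain A > B > C plus a disjoint concept.
chain_vocab <- function() {
  mesh_vocabulary(
    ids = c("A", "B", "C", "Z"),
    trees = c("C14.100", "C14.100.200", "C14.100.200.300", "C10.900"))
}

make_corpus <- function(docs) {
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  structure(docs, class = "cid_corpus")
}
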