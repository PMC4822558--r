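# Worked-example documents: two PubMed records often used to illustrate the
# mention-pair construction and hypernym-filtering rules.  The texts are
# reconstructions (title + the illustrative sentences), so character offsets
# are internal to this fixture, not the offsets of the full original
# abstracts.

# 0-based [start, end) span of the n-th occurrence of `what` in `text`
locate_nth <- function(text, what, n = 1L) {
  m <- gregexpr(what, text, fixed = TRUE)[[1]]
  if (m[1] == -1L || length(m) < n) {
    stop("fixture error: occurrence ", n, " of '", what, "' not found")
  }
  c(start = m[n] - 1L, end = m[n] - 1L + attr(m, "match.length")[n])
}

fixture_mention <- function(text, what, n, type, id) {
  sp <- locate_nth(text, what, n)
  data.frame(start = sp[["start"]], end = sp[["end"]], text = what,
             type = type, ids = id, stringsAsFactors = FALSE)
}

#' Worked-example documents
#'
#' Reconstructions of two PubMed records used throughout the package's
#' documentation and tests: PMID 10328196 (sirolimus / capillary leak
#' syndrome / psoriasis / inflammatory) illustrating intra- and
#' inter-sentence instance construction, and PMID 1728915 (carbamazepine /
#' cardiac dysfunction / bradycardia / atrioventricular block) illustrating
#' hypernym filtering.  Gold relations: sirolimus-capillary leak syndrome
#' for the former; carbamazepine with each of the two specific cardiac
#' diseases (not with their more general ancestor) for the latter.
#'
#' @return A `cid_corpus` of the two documents.
#' @export
example_documents <- function() {
  title1 <- "Case observations."
  abs1 <- paste(
    "After 2 individuals with psoriasis developed a capillary leak syndrome",
    "following treatment with oral sirolimus, lesional skin cells and",
    "activated peripheral blood cells were analyzed for induction of",
    "apoptosis. OBSERVATIONS: A keratome skin specimen from 1 patient with",
    "sirolimus-induced capillary leak syndrome had a 2.3-fold increase in",
    "percentage of apoptotic cells (to 48%) compared with an unaffected",
    "sirolimus-treated patient with psoriasis (21%). Because patients with",
    "severe psoriasis may develop capillary leak from various systemic",
    "therapies, clinical monitoring is advisable for patients with",
    "inflammatory diseases who are treated with immune modulators.")
  text1 <- paste(title1, abs1)
  m1 <- rbind(
    fixture_mention(text1, "psoriasis", 1, "Disease", "D011565"),
    fixture_mention(text1, "capillary leak syndrome", 1, "Disease", "D019559"),
    fixture_mention(text1, "sirolimus", 1, "Chemical", "D020123"),
    fixture_mention(text1, "sirolimus", 2, "Chemical", "D020123"),
    fixture_mention(text1, "capillary leak syndrome", 2, "Disease", "D019559"),
    fixture_mention(text1, "sirolimus", 3, "Chemical", "D020123"),
    fixture_mention(text1, "psoriasis", 2, "Disease", "D011565"),
    fixture_mention(text1, "psoriasis", 3, "Disease", "D011565"),
    fixture_mention(text1, "capillary leak", 3, "Disease", "D019559"),
    fixture_mention(text1, "inflammatory", 1, "Disease", "D007249"))
  doc1 <- cid_document("10328196", title1, abs1, m1,
                       data.frame(chemical_id = "D020123",
                                  disease_id = "D019559",
                                  stringsAsFactors = FALSE))

  title2 <- "Carbamazepine-induced cardiac dysfunction."
  abs2 <- paste(
    "A patient with sinus bradycardia and atrioventricular block, induced",
    "by carbamazepine, prompted an extensive literature review of all",
    "previously reported cases.")
  text2 <- paste(title2, abs2)
  m2 <- rbind(
    fixture_mention(text2, "Carbamazepine", 1, "Chemical", "D002220"),
    fixture_mention(text2, "cardiac dysfunction", 1, "Disease", "D006331"),
    fixture_mention(text2, "bradycardia", 1, "Disease", "D001919"),
    fixture_mention(text2, "atrioventricular block", 1, "Disease", "D054537"),
    fixture_mention(text2, "carbamazepine", 1, "Chemical", "D002220"))
  doc2 <- cid_document("1728915", title2, abs2, m2,
                       data.frame(chemical_id = c("D002220", "D002220"),
                                  disease_id = c("D001919", "D054537"),
                                  stringsAsFactors = FALSE))
  as_corpus(list(doc1, doc2))
}

#' Fixture MeSH vocabulary for the worked examples
#'
#' A small synthetic tree-number table covering the concepts of
#' [example_documents()].  The tree numbers are fixture values, not the real
#' MeSH trees; they encode only the hierarchy the examples need (cardiac
#' dysfunction an ancestor of both bradycardia and atrioventricular block).
#'
#' @return A [mesh_vocabulary()].
#' @export
example_mesh <- function() {
  read_mesh_table(system.file("extdata", "mesh_fixture_synthetic.tsv",
                              package = "cidrex", mustWork = TRUE))
}
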