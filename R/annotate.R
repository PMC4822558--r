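#' Block tokenizer
#'
#' Splits text into tokens that are either a maximal contiguous block of
#' letters and/or digits or exactly one punctuation character.  Whitespace is
#' skipped.  So `"Lidocaine-induced"` becomes the three tokens `"Lidocaine"`,
#' `"-"`, `"induced"`, and `"2.3-fold"` becomes five tokens.
#'
#' @param text A single string.
#' @return Data frame with columns `text`, `start`, `end` (0-based,
#'   end-exclusive character offsets into `text`).
#' @export
cid_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, end), start = start, end = end,
             stringsAsFactors = FALSE)
}

# --- stub tagging resources ------------------------------------------------
# A small closed lexicon is enough to make the deterministic test annotator
# useful: verbhood only needs to be right for the trigger-like verbs the
# pipeline's features key on.

.verb_stems <- c(
  "be", "have", "do", "induce", "cause", "produce", "develop", "treat",
  "associate", "relate", "follow", "report", "analyze", "observe", "monitor",
  "increase", "decrease", "administer", "precipitate", "prompt", "receive",
  "present", "consider", "compare", "affect", "result", "show", "suggest",
  "lead", "occur", "measure", "review", "give", "link", "evaluate", "study",
  "confirm", "reveal", "remain", "improve", "worsen", "trigger", "elicit",
  "exhibit", "require", "undergo", "assess", "record", "note", "find")

.irregular_verbs <- c(
  is = "be", are = "be", was = "be", were = "be", been = "be", being = "be",
  am = "be", has = "have", had = "have", did = "do", done = "do",
  gave = "give", given = "give", led = "lead", found = "find",
  shown = "show", underwent = "undergo")

.closed_class <- c(
  a = "DT", an = "DT", the = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", any = "DT", each = "DT", all = "DT",
  of = "IN", "in" = "IN", with = "IN", without = "IN", "for" = "IN",
  from = "IN", by = "IN", to = "IN", after = "IN", before = "IN",
  during = "IN", on = "IN", at = "IN", into = "IN", via = "IN",
  because = "IN", since = "IN", "while" = "IN", as = "IN",
  and = "CC", or = "CC", but = "CC",
  not = "RB", also = "RB", only = "RB", most = "RBS",
  who = "WP", which = "WDT", when = "WRB",
  he = "PRP", she = "PRP", it = "PRP", they = "PRP", we = "PRP",
  may = "MD", can = "MD", should = "MD", would = "MD", must = "MD")

# Resolve a possibly inflected form to a verb stem, or NA if not a known verb.
verb_stem <- function(w) {
  if (w %in% names(.irregular_verbs)) return(unname(.irregular_verbs[w]))
  if (w %in% .verb_stems) return(w)
  strip <- function(suf, add = "") {
    if (endsWith(w, suf)) {
      s <- substr(w, 1L, nchar(w) - nchar(suf))
      cand <- c(paste0(s, add), s)
      hit <- cand[cand %in% .verb_stems]
      if (length(hit)) return(hit[1])
    }
    NULL
  }
  for (st in list(strip("ed", "e"), strip("d"), strip("ing", "e"),
                  strip("ing"), strip("es"), strip("s"))) {
    if (!is.null(st)) return(st)
  }
  NA_character_
}

tag_token <- function(w) {
  lw <- tolower(w)
  if (grepl("^[^[:alnum:]]$", w)) {
    return(list(pos = w, lemma = w))
  }
  if (grepl("^[0-9]+$", w)) {
    return(list(pos = "CD", lemma = w))
  }
  if (lw %in% names(.closed_class)) {
    return(list(pos = unname(.closed_class[lw]), lemma = lw))
  }
  vs <- verb_stem(lw)
  if (!is.na(vs)) {
    pos <- if (lw == vs) "VB"
    else if (endsWith(lw, "ing")) "VBG"
    else if (endsWith(lw, "ed") || lw %in% names(.irregular_verbs)) "VBN"
    else if (endsWith(lw, "s")) "VBZ"
    else "VBN"
    return(list(pos = pos, lemma = vs))
  }
  if (endsWith(lw, "s") && nchar(lw) > 3L) {
    return(list(pos = "NNS", lemma = sub("s$", "", lw)))
  }
  list(pos = "NN", lemma = lw)
}

# Sentence boundaries of a text region [from, to) (0-based offsets):
# a [.?!] followed by whitespace and an uppercase letter, digit or '('
# closes a sentence.  Returns a data.frame(start, end) of sentence spans
# with leading whitespace trimmed.
split_region <- function(text, from, to) {
  if (to <= from) {
    return(data.frame(start = integer(), end = integer()))
  }
  region <- substring(text, from + 1L, to)
  m <- gregexpr("[.?!](?=\\s+[A-Z0-9(])", region, perl = TRUE)[[1]]
  ends <- if (m[1] == -1L) integer() else as.integer(m)  # 1-based in region
  bounds <- c(0L, ends, nchar(region))                   # region offsets
  spans <- data.frame(start = head(bounds, -1L), end = tail(bounds, -1L))
  spans <- spans[spans$end > spans$start, , drop = FALSE]
  # trim leading whitespace
  for (i in seq_len(nrow(spans))) {
    while (spans$start[i] < spans$end[i] &&
           grepl("^\\s", substring(region, spans$start[i] + 1L, spans$start[i] + 1L))) {
      spans$start[i] <- spans$start[i] + 1L
    }
  }
  spans$start <- spans$start + from
  spans$end <- spans$end + from
  rownames(spans) <- NULL
  spans
}

#' Deterministic stub annotator
#'
#' A self-contained annotation backend satisfying the annotator contract:
#' block tokenization, rule-based sentence splitting (a `.?!` followed by
#' whitespace and a capital or digit closes a sentence; the title/abstract
#' boundary always does), POS tags from a small closed lexicon plus suffix
#' rules, and lemmas from an exception table plus suffix stripping.  With
#' `dependencies = TRUE` it also emits a deterministic "verb-star" dependency
#' tree per sentence: the first verb (or, failing that, the first token) is
#' the root and every other token attaches to it directly.
#'
#' The stub exists so that the entire pipeline, including its tests, runs
#' without any external parser; pre-parsed corpora can instead be loaded
#' through [read_annotation_tsv()].
#'
#' @param dependencies Whether to emit dependency graphs.
#' @return An object of class `cid_annotator` with fields `name`,
#'   `capabilities` and function `annotate(text, title_end)`.
#' @export
stub_annotator <- function(dependencies = FALSE) {
  structure(list(
    name = "stub",
    capabilities = c(sentences = TRUE, pos = TRUE, lemma = TRUE,
                     dependencies = dependencies),
    annotate = function(text, title_end = nchar(text)) {
      tokens <- cid_tokenize(text)
      tags <- lapply(tokens$text, tag_token)
      tokens$pos <- vapply(tags, `[[`, "", "pos")
      tokens$lemma <- vapply(tags, `[[`, "", "lemma")
      sentences <- rbind(split_region(text, 0L, title_end),
                         split_region(text, title_end, nchar(text)))
      n_title <- sum(sentences$start < title_end)
      list(tokens = tokens, sentences = sentences, n_title = n_title,
           dependencies = dependencies)
    }
  ), class = "cid_annotator")
}

verb_star_graph <- function(toks) {
  n <- nrow(toks)
  if (n == 0L) return(NULL)
  verbs <- which(startsWith(toks$pos, "VB"))
  root <- if (length(verbs)) verbs[1] - 1L else 0L     # 0-based token index
  others <- setdiff(seq_len(n) - 1L, root)
  edges <- if (length(others)) {
    data.frame(head = root, dependent = others, label = "dep",
               stringsAsFactors = FALSE)
  } else {
    data.frame(head = integer(), dependent = integer(), label = character(),
               stringsAsFactors = FALSE)
  }
  dependency_graph(root = root, edges = edges, n_tokens = n)
}

#' Construct a dependency graph
#'
#' @param root 0-based index of the root token.
#' @param edges Data frame with columns `head`, `dependent` (0-based token
#'   indices) and `label`.
#' @param n_tokens Number of tokens in the sentence.
#' @return Object of class `cid_depgraph`.  Validates that every non-root
#'   node has exactly one head and that the graph is a connected tree.
#' @export
dependency_graph <- function(root, edges, n_tokens) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  non_root <- setdiff(seq_len(n_tokens) - 1L, root)
  heads_of <- table(factor(edges$dependent, levels = non_root))
  if (length(non_root) && any(heads_of != 1L)) {
    stop("dependency graph: every non-root node must have exactly one head")
  }
  if (root %in% edges$dependent) {
    stop("dependency graph: root must not have a head")
  }
  # connected + acyclic follows from n-1 unique-head edges reaching the root;
  # verify reachability to reject cycles detached from the root
  parent <- setNames(edges$head, edges$dependent)
  for (v in non_root) {
    seen <- character()
    u <- as.character(v)
    while (u %in% names(parent)) {
      if (u %in% seen) stop("dependency graph: cycle detected")
      seen <- c(seen, u)
      u <- as.character(parent[[u]])
    }
    if (as.integer(u) != root) stop("dependency graph: disconnected node ", v)
  }
  structure(list(root = root, edges = edges, n_tokens = n_tokens),
            class = "cid_depgraph")
}

#' Annotate a document
#'
#' Runs an annotation backend over the document text and aligns the result
#' with the document's entity mentions: each mention is mapped to a
#' contiguous token span inside exactly one sentence.  A sentence boundary
#' that would split a mention is repaired by merging the adjacent sentences
#' (with a message).  Sentences get a `block_label`: title sentences are
#' block `"TITLE"`; an abstract sentence opening with a run of two or more
#' capital letters followed by `":"` (e.g. `"OBSERVATIONS:"`) opens a block
#' named by that header; other sentences inherit the previous block.
#'
#' @param doc A `cid_document`.
#' @param backend A `cid_annotator` (default [stub_annotator()]).
#' @return Object of class `cid_annotation`: list with `doc_id`, `text`,
#'   `sentences` (index, start, end, block_label), `tokens` (sentence, index,
#'   text, start, end, pos, lemma), `mention_tokens` (per-mention sentence,
#'   first/last 0-based token index within the sentence, head token), and
#'   `graphs` (list of `cid_depgraph` per sentence, or `NULL`).
#' @export
annotate_document <- function(doc, backend = stub_annotator()) {
  text <- doc_text(doc)
  title_end <- nchar(doc$title)
  ann <- backend$annotate(text, title_end)
  tokens <- ann$tokens
  sent <- ann$sentences
  m <- doc$mentions

  sentence_of <- function(pos) {
    # sentence whose span contains character offset pos
    i <- which(sent$start <= pos & pos < sent$end)
    if (!length(i)) i <- max(which(sent$start <= pos))
    i[1]
  }
  # repair boundaries splitting a mention
  repeat {
    merged <- FALSE
    for (k in seq_len(nrow(m))) {
      s1 <- sentence_of(m$start[k])
      s2 <- sentence_of(m$end[k] - 1L)
      if (s1 != s2) {
        message("repairing sentence boundary inside mention '", m$text[k],
                "' of document ", doc$doc_id)
        sent$end[s1] <- sent$end[s2]
        sent <- sent[-seq(s1 + 1L, s2), , drop = FALSE]
        rownames(sent) <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sent$index <- seq_len(nrow(sent)) - 1L

  # block labels
  labels <- character(nrow(sent))
  prev <- "ABSTRACT"
  for (i in seq_len(nrow(sent))) {
    if (sent$start[i] < title_end) {
      labels[i] <- "TITLE"
      next
    }
    stext <- substring(text, sent$start[i] + 1L, sent$end[i])
    hm <- regmatches(stext, regexpr("^[A-Z]{2,}(?=:)", stext, perl = TRUE))
    if (length(hm)) prev <- hm
    labels[i] <- prev
  }
  sent$block_label <- labels

  # token -> sentence assignment and per-sentence indices
  tok_sent <- vapply(tokens$start, sentence_of, 0L)
  tokens$sentence <- sent$index[tok_sent]
  tokens <- tokens[order(tokens$start), , drop = FALSE]
  tokens$index <- stats::ave(seq_len(nrow(tokens)), tokens$sentence,
                             FUN = seq_along) - 1L
  rownames(tokens) <- NULL

  graphs <- NULL
  if (isTRUE(ann$dependencies)) {
    graphs <- lapply(sent$index, function(s) {
      verb_star_graph(tokens[tokens$sentence == s, , drop = FALSE])
    })
  }

  annotation <- structure(list(
    doc_id = doc$doc_id, text = text, title_end = title_end,
    sentences = sent[, c("index", "start", "end", "block_label")],
    tokens = tokens[, c("sentence", "index", "text", "start", "end",
                        "pos", "lemma")],
    graphs = graphs
  ), class = "cid_annotation")
  annotation$mention_tokens <- align_mentions(doc, annotation)
  annotation
}

align_mentions <- function(doc, ann) {
  m <- doc$mentions
  out <- data.frame(mention = seq_len(nrow(m)),
                    sentence = rep(NA_integer_, nrow(m)),
                    first = rep(NA_integer_, nrow(m)),
                    last = rep(NA_integer_, nrow(m)),
                    head = rep(NA_integer_, nrow(m)))
  toks <- ann$tokens
  for (k in seq_len(nrow(m))) {
    hit <- which(toks$start < m$end[k] & toks$end > m$start[k])
    if (!length(hit)) {
      stop("mention '", m$text[k], "' of document ", doc$doc_id,
           " aligns to no token")
    }
    s <- unique(toks$sentence[hit])
    if (length(s) != 1L) {
      stop("mention '", m$text[k], "' spans sentences after repair")
    }
    idx <- toks$index[hit]
    out$sentence[k] <- s
    out$first[k] <- min(idx)
    out$last[k] <- max(idx)
    out$head[k] <- mention_head_token(ann, s, min(idx), max(idx))
  }
  out
}

# Syntactic head of a mention token span: the token whose dependency head
# lies outside the span; fallback: the rightmost token of the span.
mention_head_token <- function(ann, sentence, first, last) {
  if (!is.null(ann$graphs)) {
    g <- ann$graphs[[sentence + 1L]]
    if (!is.null(g)) {
      span <- first:last
      for (t in rev(span)) {
        if (t == g$root) return(t)
        h <- g$edges$head[g$edges$dependent == t]
        if (length(h) && !(h %in% span)) return(t)
      }
    }
  }
  last
}

#' Read pre-computed annotations from TSV
#'
#' Loads a line-oriented annotation interchange file so that corpora parsed
#' with an external tool chain can be used without any parser installed.
#' Columns: `doc_id`, `sentence`, `index`, `text`, `start`, `end`, `pos`,
#' `lemma`, `head`, `label` (dependency head token index, `-1` for the root;
#' empty `head` means no dependency layer).
#'
#' @param file Path to the TSV file.
#' @param doc The `cid_document` the annotation belongs to.
#' @return A `cid_annotation` for `doc`.
#' @export
read_annotation_tsv <- function(file, doc) {
  tab <- read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(doc_id = "character"))
  tab <- tab[tab$doc_id == doc$doc_id, , drop = FALSE]
  if (!nrow(tab)) stop("no annotation rows for document ", doc$doc_id)
  text <- doc_text(doc)
  sent_ids <- sort(unique(tab$sentence))
  sentences <- data.frame(
    index = sent_ids,
    start = vapply(sent_ids, function(s) min(tab$start[tab$sentence == s]), 0L),
    end = vapply(sent_ids, function(s) max(tab$end[tab$sentence == s]), 0L))
  has_dep <- "head" %in% names(tab) && !all(is.na(tab$head))
  backend <- structure(list(
    name = "tsv",
    capabilities = c(sentences = TRUE, pos = TRUE, lemma = TRUE,
                     dependencies = has_dep),
    annotate = function(text, title_end) {
      list(tokens = tab[, c("text", "start", "end", "pos", "lemma")],
           sentences = sentences[, c("start", "end")],
           dependencies = FALSE)
    }), class = "cid_annotator")
  ann <- annotate_document(doc, backend)
  if (has_dep) {
    ann$graphs <- lapply(ann$sentences$index, function(s) {
      rows <- tab[tab$sentence == s, , drop = FALSE]
      rows <- rows[order(rows$index), , drop = FALSE]
      root <- rows$index[is.na(rows$head) | rows$head < 0L][1]
      dep_rows <- rows[!is.na(rows$head) & rows$head >= 0L, , drop = FALSE]
      dependency_graph(root = root,
                       edges = data.frame(head = dep_rows$head,
                                          dependent = dep_rows$index,
                                          label = dep_rows$label,
                                          stringsAsFactors = FALSE),
                       n_tokens = nrow(rows))
    })
  }
  ann
}

#' Mask entity mentions for parsing
#'
#' Replaces every mention span by the single token
#' `Doc_{pmid}_{start}_{end}_{Type}` so that an external parser cannot split
#' a multi-word mention.  Overlapping mentions are resolved by keeping the
#' longer span (with a message).
#'
#' @param doc A `cid_document`.
#' @return List with `text` (masked text) and `map`, a data frame mapping
#'   each masked placeholder back to the original character span
#'   (`orig_start`, `orig_end`, `masked_start`, `masked_end`, `token`,
#'   `text`, `mention` = row index into `doc$mentions`, `NA` for mentions
#'   dropped by overlap resolution).
#' @export
mask_mentions <- function(doc) {
  m <- doc$mentions
  m$row <- seq_len(nrow(m))
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq(i + 1L, nrow(m))) {
        if (!keep[i] || !keep[j]) next
        if (m$start[j] < m$end[i] && m$start[i] < m$end[j]) {
          drop <- if ((m$end[i] - m$start[i]) >= (m$end[j] - m$start[j])) j else i
          message("overlapping mentions in document ", doc$doc_id,
                  ": dropping shorter span '", m$text[drop], "'")
          keep[drop] <- FALSE
        }
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  text <- doc_text(doc)
  map <- data.frame(mention = m$row, orig_start = m$start, orig_end = m$end,
                    text = m$text,
                    token = sprintf("Doc_%s_%d_%d_%s", doc$doc_id, m$start,
                                    m$end, m$type),
                    masked_start = rep(NA_integer_, nrow(m)),
                    masked_end = rep(NA_integer_, nrow(m)),
                    stringsAsFactors = FALSE)
  shift <- 0L
  for (k in seq_len(nrow(map))) {
    ms <- map$orig_start[k] + shift
    me <- map$orig_end[k] + shift
    text <- paste0(substr(text, 1L, ms), map$token[k], substring(text, me + 1L))
    map$masked_start[k] <- ms
    map$masked_end[k] <- ms + nchar(map$token[k])
    shift <- shift + nchar(map$token[k]) - (map$orig_end[k] - map$orig_start[k])
  }
  list(text = text, map = map)
}

#' Undo mention masking
#'
#' @param masked_text Text produced by [mask_mentions()].
#' @param map The `map` component returned by [mask_mentions()].
#' @return The original document text.
#' @export
unmask_mentions <- function(masked_text, map) {
  for (k in rev(seq_len(nrow(map)))) {
    masked_text <- paste0(substr(masked_text, 1L, map$masked_start[k]),
                          map$text[k],
                          substring(masked_text, map$masked_end[k] + 1L))
  }
  masked_text
}
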