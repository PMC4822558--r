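#' Feature template registries
#'
#' The three template families used by the relation classifiers: lexical
#' templates for intra-sentence instances, dependency templates for
#' intra-sentence instances, and lexical templates for inter-sentence
#' instances (dependency features are unavailable across sentences).
#'
#' @format Character vectors of template names.
#' @name feature_registry
NULL

#' @rdname feature_registry
#' @export
INTRA_LEX_TEMPLATES <- c(
  "CMTXT", "CBOW", "CPOS", "DMTXT", "DBOW", "DPOS",
  "WVNULL", "WVFL", "WVTFL", "WVLFL", "WVF", "WVFLM", "WVL", "WVLLM",
  "WVO", "WVOLM",
  "WBF", "WBFLM", "WBFPOS", "WBL", "WBLLM", "WBLPOS", "WBNULL", "WBFL",
  "WBTFL", "WBLFL", "WBTPOS",
  "BM1F", "BM1FL", "BM1L", "BM1LL", "AM2F", "AM2FL", "AM2L", "AM2LL",
  "WINT")

#' @rdname feature_registry
#' @export
INTRA_DEP_TEMPLATES <- c(
  "DPR2C", "DPR2D", "DPC2D", "DPC2DR", "DPNS", "VBLS",
  "WCDD", "WRCD", "WRDD")

#' @rdname feature_registry
#' @export
INTER_LEX_TEMPLATES <- c(
  "CBOW", "CPOS", "DBOW", "DPOS", "SDIST", "CFRQ", "DFRQ",
  "WCO", "WDO", "SMBLOCK")

#' Feature configuration
#'
#' @param intra_lex,intra_dep,inter_lex Template-family toggles.  Dependency
#'   features exist only at the intra-sentence level.
#' @return Object of class `cid_feature_config`.
#' @export
cid_feature_config <- function(intra_lex = TRUE, intra_dep = FALSE,
                               inter_lex = TRUE) {
  structure(list(intra_lex = intra_lex, intra_dep = intra_dep,
                 inter_lex = inter_lex), class = "cid_feature_config")
}

sentence_tokens <- function(ann, s) {
  t <- ann$tokens[ann$tokens$sentence == s, , drop = FALSE]
  t[order(t$index), , drop = FALSE]
}

is_verb <- function(pos) startsWith(pos, "VB")

# feature string helpers; intra features carry the "I:" namespace and inter
# features "X:" so the two models never share weights accidentally
feat <- function(ns, template, value = NULL) {
  if (is.null(value) || !length(value)) return(paste0(ns, template))
  paste0(ns, template, "=", value)
}

mention_bow <- function(toks, first, last) {
  unique(tolower(toks$text[toks$index >= first & toks$index <= last]))
}

#' Lexical features of an intra-sentence instance
#'
#' Emits the 36 intra-sentence lexical templates: the mention templates
#' (text, bag-of-words and head POS of each mention), the verb-in-between
#' templates keyed on the number of verbs strictly between the mentions, the
#' word-in-between templates keyed on the number of tokens strictly between,
#' the two-token context windows before the first and after the second
#' mention (in text order, with `<S>`/`</S>` sentinels at sentence edges),
#' and the `WINT` flag when the instance occurs in the title.
#'
#' @param doc A `cid_document`.
#' @param ann Its annotation.
#' @param inst One-row instance data frame (level `"intra"`).
#' @return Character vector of feature strings (namespace `"I:"`).
#' @export
extract_intra_lex <- function(doc, ann, inst) {
  if (!all(c("pos", "lemma") %in% names(ann$tokens)) ||
      anyNA(ann$tokens$pos)) {
    stop("intra-sentence lexical features need a backend with pos/lemma capability")
  }
  mt <- ann$mention_tokens
  cm <- inst$chem_mention
  dm <- inst$dis_mention
  s <- mt$sentence[cm]
  toks <- sentence_tokens(ann, s)
  fs <- character()

  ctext <- doc$mentions$text[cm]
  dtext <- doc$mentions$text[dm]
  fs <- c(fs,
          feat("I:", "CMTXT", ctext),
          feat("I:", "CBOW", mention_bow(toks, mt$first[cm], mt$last[cm])),
          feat("I:", "CPOS", toks$pos[toks$index == mt$head[cm]]),
          feat("I:", "DMTXT", dtext),
          feat("I:", "DBOW", mention_bow(toks, mt$first[dm], mt$last[dm])),
          feat("I:", "DPOS", toks$pos[toks$index == mt$head[dm]]))

  # first/second mention in text order
  if (mt$first[cm] <= mt$first[dm]) {
    m1 <- cm; m2 <- dm
  } else {
    m1 <- dm; m2 <- cm
  }
  between_idx <- seq_len(0)
  if (mt$first[m2] - mt$last[m1] > 1L) {
    between_idx <- (mt$last[m1] + 1L):(mt$first[m2] - 1L)
  }
  bt <- toks[toks$index %in% between_idx, , drop = FALSE]

  nb <- nrow(bt)
  if (nb == 0L) {
    fs <- c(fs, feat("I:", "WBNULL"))
  } else if (nb == 1L) {
    fs <- c(fs, feat("I:", "WBFL"),
            feat("I:", "WBTFL", bt$text),
            feat("I:", "WBLFL", bt$lemma),
            feat("I:", "WBTPOS", bt$pos))
  } else {
    fs <- c(fs,
            feat("I:", "WBF", bt$text[1]), feat("I:", "WBFLM", bt$lemma[1]),
            feat("I:", "WBFPOS", bt$pos[1]),
            feat("I:", "WBL", bt$text[nb]), feat("I:", "WBLLM", bt$lemma[nb]),
            feat("I:", "WBLPOS", bt$pos[nb]))
  }

  vb <- bt[is_verb(bt$pos), , drop = FALSE]
  nv <- nrow(vb)
  if (nv == 0L) {
    fs <- c(fs, feat("I:", "WVNULL"))
  } else if (nv == 1L) {
    fs <- c(fs, feat("I:", "WVFL"),
            feat("I:", "WVTFL", vb$text),
            feat("I:", "WVLFL", vb$lemma))
  } else {
    fs <- c(fs,
            feat("I:", "WVF", vb$text[1]), feat("I:", "WVFLM", vb$lemma[1]),
            feat("I:", "WVL", vb$text[nv]), feat("I:", "WVLLM", vb$lemma[nv]))
    if (nv > 2L) {
      mid <- seq(2L, nv - 1L)
      fs <- c(fs, feat("I:", "WVO", vb$text[mid]),
              feat("I:", "WVOLM", vb$lemma[mid]))
    }
  }

  ctx <- function(idx, template_t, template_l) {
    row <- toks[toks$index == idx, , drop = FALSE]
    if (nrow(row)) {
      c(feat("I:", template_t, row$text), feat("I:", template_l, row$lemma))
    } else {
      sentinel <- if (idx < 0L) "<S>" else "</S>"
      c(feat("I:", template_t, sentinel), feat("I:", template_l, sentinel))
    }
  }
  fs <- c(fs,
          ctx(mt$first[m1] - 1L, "BM1F", "BM1FL"),
          ctx(mt$first[m1] - 2L, "BM1L", "BM1LL"),
          ctx(mt$last[m2] + 1L, "AM2F", "AM2FL"),
          ctx(mt$last[m2] + 2L, "AM2L", "AM2LL"))

  block <- ann$sentences$block_label[ann$sentences$index == s]
  if (identical(block, "TITLE")) fs <- c(fs, feat("I:", "WINT"))
  unique(fs)
}

path_between <- function(graph, from, to) {
  # undirected shortest path over the dependency tree; returns list of
  # vertex sequence (0-based token indices) and the edge rows traversed
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$head),
               to = as.character(graph$edges$dependent)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(graph$n_tokens) - 1L)))
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(from), to = as.character(to), output = "vpath"))
  v <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  if (length(v) < 1L || (length(v) == 1L && from != to)) return(NULL)
  v
}

path_edges <- function(graph, vseq) {
  # for consecutive vertices, find edge row and direction (+1 head->dep)
  if (length(vseq) < 2L) {
    return(data.frame(label = character(), dir = integer()))
  }
  out <- data.frame(label = character(length(vseq) - 1L),
                    dir = integer(length(vseq) - 1L))
  for (i in seq_len(length(vseq) - 1L)) {
    a <- vseq[i]; b <- vseq[i + 1L]
    hit <- which(graph$edges$head == a & graph$edges$dependent == b)
    if (length(hit)) {
      out$label[i] <- graph$edges$label[hit[1]]
      out$dir[i] <- 1L
    } else {
      hit <- which(graph$edges$head == b & graph$edges$dependent == a)
      out$label[i] <- graph$edges$label[hit[1]]
      out$dir[i] <- -1L
    }
  }
  out
}

# longest dependency path rendered verbatim; beyond this a LONG sentinel
# bounds feature-space growth
.dep_path_cap <- 8L

render_path <- function(pe, directed = FALSE) {
  if (!nrow(pe)) return("")
  if (nrow(pe) > .dep_path_cap) return("LONG")
  lab <- if (directed) {
    paste0(ifelse(pe$dir > 0L, ">", "<"), pe$label)
  } else {
    pe$label
  }
  paste(lab, collapse = "-")
}

#' Dependency features of an intra-sentence instance
#'
#' Emits the 9 dependency templates from the sentence's dependency graph:
#' label paths from the root to each mention's head token (`DPR2C`,
#' `DPR2D`), the undirected shortest label path between the two mention
#' heads plain and with direction tags (`DPC2D`, `DPC2DR`), the token-node
#' sequence on that path with the mention endpoints generalized to
#' `CHEMICAL`/`DISEASE` (`DPNS`), the lemmas of verbs on the path (`VBLS`),
#' and the connectivity flags: `WCDD` when the two mention heads share a
#' direct edge, and `WRCD`/`WRDD` when a mention head is itself the sentence
#' root (directly attached to the virtual root, with an empty root path).
#'
#' @param doc A `cid_document`.
#' @param ann Its annotation (must carry dependency graphs, or pass `graph`).
#' @param inst One-row instance data frame (level `"intra"`).
#' @param graph Optionally a `cid_depgraph` overriding the annotation's
#'   graph for the instance's sentence.
#' @return Character vector of feature strings (namespace `"I:"`), empty
#'   when no graph is available.
#' @export
extract_intra_dep <- function(doc, ann, inst, graph = NULL) {
  mt <- ann$mention_tokens
  cm <- inst$chem_mention
  dm <- inst$dis_mention
  s <- mt$sentence[cm]
  if (is.null(graph)) {
    if (is.null(ann$graphs)) return(character())
    graph <- ann$graphs[[s + 1L]]
  }
  if (is.null(graph)) return(character())
  toks <- sentence_tokens(ann, s)
  ch <- mt$head[cm]
  dh <- mt$head[dm]
  fs <- character()

  direct <- function(a, b) {
    any(graph$edges$head == a & graph$edges$dependent == b) ||
      any(graph$edges$head == b & graph$edges$dependent == a)
  }
  if (direct(ch, dh)) fs <- c(fs, feat("I:", "WCDD"))
  if (ch == graph$root) fs <- c(fs, feat("I:", "WRCD"))
  if (dh == graph$root) fs <- c(fs, feat("I:", "WRDD"))

  emit_path <- function(template, from, to, directed = FALSE) {
    v <- path_between(graph, from, to)
    if (is.null(v)) return(NULL)
    feat("I:", template, render_path(path_edges(graph, v), directed))
  }
  fs <- c(fs,
          emit_path("DPR2C", graph$root, ch),
          emit_path("DPR2D", graph$root, dh))
  v <- path_between(graph, ch, dh)
  if (!is.null(v)) {
    pe <- path_edges(graph, v)
    fs <- c(fs,
            feat("I:", "DPC2D", render_path(pe)),
            feat("I:", "DPC2DR", render_path(pe, directed = TRUE)))
    node_txt <- vapply(v, function(t) toks$text[toks$index == t], "")
    node_txt[1] <- if (ch == v[1]) "CHEMICAL" else "DISEASE"
    node_txt[length(v)] <- if (dh == v[length(v)]) "DISEASE" else "CHEMICAL"
    fs <- c(fs, feat("I:", "DPNS", paste(node_txt, collapse = "-")))
    on_path <- toks[toks$index %in% v, , drop = FALSE]
    verbs <- on_path$lemma[is_verb(on_path$pos)]
    if (length(verbs)) {
      fs <- c(fs, feat("I:", "VBLS", paste(verbs, collapse = "-")))
    }
  }
  unique(fs)
}

#' Lexical features of an inter-sentence instance
#'
#' Emits the 10 inter-sentence lexical templates: mention bag-of-words and
#' head POS for both mentions, the sentence distance `SDIST` (raw and
#' bucketed into 1 / 2 / 3+), the document frequencies of the two entities
#' (`CFRQ`, `DFRQ`, capped at "5+"), flags for the entity being the only
#' chemical/disease entity in the document (`WCO`, `WDO`), and `SMBLOCK`
#' when both sentences belong to the same text block.
#'
#' @inheritParams extract_intra_lex
#' @return Character vector of feature strings (namespace `"X:"`).
#' @export
extract_inter_lex <- function(doc, ann, inst) {
  if (!all(c("pos", "lemma") %in% names(ann$tokens))) {
    stop("inter-sentence lexical features need a backend with pos/lemma capability")
  }
  mt <- ann$mention_tokens
  cm <- inst$chem_mention
  dm <- inst$dis_mention
  cs <- mt$sentence[cm]
  ds <- mt$sentence[dm]
  ctoks <- sentence_tokens(ann, cs)
  dtoks <- sentence_tokens(ann, ds)
  fs <- c(
    feat("X:", "CBOW", mention_bow(ctoks, mt$first[cm], mt$last[cm])),
    feat("X:", "CPOS", ctoks$pos[ctoks$index == mt$head[cm]]),
    feat("X:", "DBOW", mention_bow(dtoks, mt$first[dm], mt$last[dm])),
    feat("X:", "DPOS", dtoks$pos[dtoks$index == mt$head[dm]]))

  sdist <- abs(cs - ds)
  bucket <- if (sdist >= 3L) "3+" else as.character(sdist)
  fs <- c(fs, feat("X:", "SDIST", sdist),
          feat("X:", "SDIST", paste0("bucket:", bucket)))

  ids_of <- function(k) split_ids(doc$mentions$ids[k])
  all_ids <- lapply(seq_len(nrow(doc$mentions)), ids_of)
  freq_of <- function(id) {
    sum(vapply(all_ids, function(x) id %in% x, logical(1)))
  }
  cap5 <- function(x) if (x >= 5L) "5+" else as.character(x)
  fs <- c(fs, feat("X:", "CFRQ", cap5(freq_of(inst$chemical_id))),
          feat("X:", "DFRQ", cap5(freq_of(inst$disease_id))))

  ids_by_type <- function(type) {
    unique(unlist(all_ids[doc$mentions$type == type]))
  }
  if (length(ids_by_type("Chemical")) == 1L) fs <- c(fs, feat("X:", "WCO"))
  if (length(ids_by_type("Disease")) == 1L) fs <- c(fs, feat("X:", "WDO"))

  blocks <- ann$sentences$block_label
  if (blocks[ann$sentences$index == cs] == blocks[ann$sentences$index == ds]) {
    fs <- c(fs, feat("X:", "SMBLOCK"))
  }
  unique(fs)
}

#' Featurize instances
#'
#' Applies the enabled template families to every instance.  Feature
#' extraction is a pure function of the instance and the annotation.
#'
#' @param doc A `cid_document`.
#' @param ann Its annotation.
#' @param instances Instance data frame for this document.
#' @param config A [cid_feature_config()].
#' @return List of character vectors, one per instance row.
#' @export
extract_features <- function(doc, ann, instances,
                             config = cid_feature_config()) {
  lapply(seq_len(nrow(instances)), function(i) {
    inst <- instances[i, , drop = FALSE]
    fs <- character()
    if (inst$level == "intra") {
      if (config$intra_lex) fs <- c(fs, extract_intra_lex(doc, ann, inst))
      if (config$intra_dep) fs <- c(fs, extract_intra_dep(doc, ann, inst))
    } else {
      if (config$inter_lex) fs <- c(fs, extract_inter_lex(doc, ann, inst))
    }
    fs
  })
}

#' Check feature strings against the template registry
#'
#' @param features Character vector of feature strings (or a list of them).
#' @return `TRUE` invisibly; errors when a string's template name is not in
#'   the registry of its level.
#' @export
check_feature_registry <- function(features) {
  for (f in unlist(features)) {
    ns <- substr(f, 1L, 2L)
    name <- sub("=.*$", "", substring(f, 3L))
    ok <- if (ns == "I:") {
      name %in% c(INTRA_LEX_TEMPLATES, INTRA_DEP_TEMPLATES)
    } else if (ns == "X:") {
      name %in% INTER_LEX_TEMPLATES
    } else {
      FALSE
    }
    if (!ok) stop("unknown feature template in string: ", f)
  }
  invisible(TRUE)
}
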