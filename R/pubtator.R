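#' Create a document
#'
#' Constructs a `cid_document`, the container for one PubMed record: a PMID,
#' a title, an optional abstract, chemical/disease entity mentions and
#' document-level CID relations.  Offsets are 0-based, end-exclusive and are
#' resolved against the concatenation `title + " " + abstract`.
#'
#' @param doc_id PMID (non-empty string).
#' @param title Title text.
#' @param abstract Abstract text (may be empty).
#' @param mentions Data frame with columns `start`, `end`, `text`, `type`
#'   (`"Chemical"` or `"Disease"`), `ids` (identifiers, `|`-separated when
#'   composite; `"-1"` marks an unresolved concept).
#' @param relations Data frame with columns `chemical_id`, `disease_id`.
#' @return An object of class `cid_document`.
#' @export
cid_document <- function(doc_id, title, abstract = "",
                         mentions = empty_mentions(),
                         relations = empty_relations()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  doc <- structure(list(
    doc_id = doc_id,
    title = title,
    abstract = abstract,
    mentions = normalize_mentions(mentions),
    relations = relations
  ), class = "cid_document")
  validate_document(doc)
  doc
}

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), text = character(),
             type = character(), ids = character(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(chemical_id = character(), disease_id = character(),
             stringsAsFactors = FALSE)
}

normalize_mentions <- function(m) {
  if (nrow(m)) {
    m <- m[order(m$start, m$end), , drop = FALSE]
    rownames(m) <- NULL
    m$start <- as.integer(m$start)
    m$end <- as.integer(m$end)
  }
  m
}

#' Document text used for offset resolution
#'
#' Title and abstract joined by a single separator space (the PubTator
#' convention: abstract offsets continue after the title plus one space).
#'
#' @param doc A `cid_document`.
#' @return A single string.
#' @export
doc_text <- function(doc) {
  if (nzchar(doc$abstract)) paste(doc$title, doc$abstract) else doc$title
}

validate_document <- function(doc) {
  txt <- doc_text(doc)
  m <- doc$mentions
  if (!nrow(m)) return(invisible(doc))
  if (any(m$end <= m$start)) {
    stop("mention with end <= start in document ", doc$doc_id)
  }
  span <- substring(txt, m$start + 1L, m$end)
  bad <- which(span != m$text)
  if (length(bad)) {
    stop(sprintf(
      "offset validation failed in document %s: mention '%s' at [%d,%d) resolves to '%s'",
      doc$doc_id, m$text[bad[1]], m$start[bad[1]], m$end[bad[1]], span[bad[1]]))
  }
  invisible(doc)
}

#' @export
#' @method print cid_document
print.cid_document <- function(x, ...) {
  cat(sprintf("<cid_document %s: %d mentions, %d relations>\n",
              x$doc_id, nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' @export
#' @method print cid_corpus
print.cid_corpus <- function(x, ...) {
  cat(sprintf("<cid_corpus: %d documents, %d mentions, %d gold relations>\n",
              length(x), sum(vapply(x, function(d) nrow(d$mentions), 0L)),
              sum(vapply(x, function(d) nrow(d$relations), 0L))))
  invisible(x)
}

as_corpus <- function(docs) {
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  structure(docs, class = "cid_corpus")
}

#' Parse PubTator-formatted text
#'
#' Reads the line-oriented PubTator dialect: per document a `PMID|t|TITLE`
#' line, an optional `PMID|a|ABSTRACT` line, then tab-separated annotation
#' lines (6 fields for a mention, 4 fields for a CID relation), with a blank
#' line between documents.
#'
#' @param lines Character vector of input lines.
#' @return A `cid_corpus` (list of [cid_document()]s).
#' @seealso [read_pubtator()], [write_pubtator()]
#' @export
parse_pubtator <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  blank <- !nzchar(lines)
  block_id <- cumsum(c(TRUE, blank[-length(blank)]))
  keep <- !blank
  docs <- list()
  for (b in split(seq_along(lines)[keep], block_id[keep])) {
    docs[[length(docs) + 1L]] <- parse_pubtator_block(lines[b], b)
  }
  as_corpus(docs)
}

parse_pubtator_block <- function(blk, lineno) {
  t_i <- grep("\\|t\\|", blk, fixed = FALSE)
  if (length(t_i) != 1L) {
    stop("PubTator block near line ", lineno[1], " must contain exactly one |t| line")
  }
  a_i <- grep("\\|a\\|", blk)
  if (length(a_i) > 1L) {
    stop("PubTator block near line ", lineno[1], " has multiple |a| lines")
  }
  split_text_line <- function(line, sep) {
    p <- regexpr(sep, line, fixed = TRUE)
    c(substr(line, 1L, p - 1L), substring(line, p + 3L))
  }
  t_parts <- split_text_line(blk[t_i], "|t|")
  doc_id <- t_parts[1]
  title <- t_parts[2]
  abstract <- ""
  if (length(a_i)) {
    a_parts <- split_text_line(blk[a_i], "|a|")
    if (a_parts[1] != doc_id) {
      stop("PubTator |a| line ", lineno[a_i], ": PMID differs from |t| line")
    }
    abstract <- a_parts[2]
  }
  ann_idx <- setdiff(seq_along(blk), c(t_i, a_i))
  mentions <- empty_mentions()
  relations <- empty_relations()
  for (i in ann_idx) {
    f <- strsplit(blk[i], "\t", fixed = TRUE)[[1]]
    ln <- lineno[i]
    if (length(f) == 6L) {
      if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3])) {
        stop("line ", ln, ": non-numeric mention offsets")
      }
      mentions <- rbind(mentions, data.frame(
        start = as.integer(f[2]), end = as.integer(f[3]), text = f[4],
        type = f[5], ids = f[6], stringsAsFactors = FALSE))
    } else if (length(f) == 4L) {
      if (f[2] != "CID") {
        stop("line ", ln, ": unsupported relation type '", f[2], "'")
      }
      relations <- rbind(relations, data.frame(
        chemical_id = f[3], disease_id = f[4], stringsAsFactors = FALSE))
    } else {
      stop("line ", ln, ": malformed annotation line (", length(f), " fields)")
    }
  }
  cid_document(doc_id, title, abstract, mentions, relations)
}

#' Read a PubTator file
#'
#' @param file Path to a PubTator-formatted text file (UTF-8).
#' @return A `cid_corpus`.
#' @export
read_pubtator <- function(file) {
  parse_pubtator(readLines(file, encoding = "UTF-8", warn = FALSE))
}

#' Serialize documents to PubTator lines
#'
#' Emits the same dialect [parse_pubtator()] accepts; `parse(write(x))`
#' reproduces `x` field for field.  Mentions are written sorted by start
#' offset (ties by end offset).
#'
#' @param docs A `cid_corpus`, or a single `cid_document`.
#' @param file Optional path; when given, lines are also written there.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_pubtator <- function(docs, file = NULL) {
  if (inherits(docs, "cid_document")) docs <- as_corpus(list(docs))
  out <- character()
  for (doc in docs) {
    validate_document(doc)
    m <- normalize_mentions(doc$mentions)
    lines <- sprintf("%s|t|%s", doc$doc_id, doc$title)
    if (nzchar(doc$abstract)) {
      lines <- c(lines, sprintf("%s|a|%s", doc$doc_id, doc$abstract))
    }
    if (nrow(m)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                                doc$doc_id, m$start, m$end, m$text, m$type, m$ids))
    }
    r <- doc$relations
    if (nrow(r)) {
      lines <- c(lines, sprintf("%s\tCID\t%s\t%s", doc$doc_id,
                                r$chemical_id, r$disease_id))
    }
    out <- c(out, lines, "")
  }
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# Split a composite identifier field into its identifiers, dropping the
# unknown marker "-1".
split_ids <- function(ids) {
  setdiff(strsplit(ids, "|", fixed = TRUE)[[1]], "-1")
}
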