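## Corpus domain model: tokenized, entity-annotated sentences.
##
## A sentence holds a 0-based, contiguous token sequence (surface form, POS
## tag, incoming dependency label per token) and a set of typed entity
## mentions with half-open token spans [start, end) and knowledge-base
## normalized identifiers. Mention spans may not overlap; corpora violating
## this are rejected rather than silently resolved.

#' Construct a sentence record
#'
#' @param doc_id,sent_id Document and sentence identifiers; the pair must be
#'   unique within a corpus.
#' @param tokens data.frame with columns `surface`, `pos`, `dep`, one row per
#'   token in order (token index = row number - 1).
#' @param mentions data.frame with columns `mention_id`, `entity_type`
#'   (`"PROTEIN"` or `"LOCATION"`), `start`, `end` (half-open 0-based token
#'   interval) and `kb_id` (normalized entity identifier). May have zero rows.
#' @param gold_pairs Optional data.frame with columns `start1`, `start2`
#'   recording span starts of mention pairs that truly express the relation
#'   (used by the synthetic generator; real corpora leave it NULL).
#' @return A list of class `ds_sentence`.
#' @export
sentence <- function(doc_id, sent_id, tokens, mentions, gold_pairs = NULL) {
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  s <- structure(
    list(doc_id = as.character(doc_id), sent_id = as.character(sent_id),
         tokens = tokens, mentions = mentions, gold_pairs = gold_pairs),
    class = "ds_sentence"
  )
  validate_sentence(s)
  s
}

validate_sentence <- function(s) {
  tk <- s$tokens
  if (!all(c("surface", "pos", "dep") %in% names(tk))) {
    stop("sentence ", s$sent_id, ": tokens need surface/pos/dep columns")
  }
  n <- nrow(tk)
  if (n == 0L) stop("sentence ", s$sent_id, ": empty token sequence")
  m <- s$mentions
  if (nrow(m)) {
    if (!all(c("mention_id", "entity_type", "start", "end", "kb_id") %in% names(m))) {
      stop("sentence ", s$sent_id, ": mentions need mention_id/entity_type/start/end/kb_id")
    }
    if (any(m$start < 0L) || any(m$end > n) || any(m$start >= m$end)) {
      stop("sentence ", s$sent_id, ": mention span outside [0, ", n, ") or empty")
    }
    if (!all(m$entity_type %in% c("PROTEIN", "LOCATION"))) {
      stop("sentence ", s$sent_id, ": unknown entity type")
    }
    if (anyDuplicated(m$mention_id)) {
      stop("sentence ", s$sent_id, ": duplicate mention_id")
    }
    o <- order(m$start)
    st <- m$start[o]; en <- m$end[o]
    if (nrow(m) > 1L && any(st[-1L] < en[-nrow(m)])) {
      stop("sentence ", s$sent_id, ": overlapping mention spans")
    }
  }
  invisible(s)
}

#' @export
print.ds_sentence <- function(x, ...) {
  cat(sprintf("<sentence %s/%s: %d tokens, %d mentions>\n",
              x$doc_id, x$sent_id, nrow(x$tokens), nrow(x$mentions)))
  cat(" ", paste(x$tokens$surface, collapse = " "), "\n")
  invisible(x)
}

## A corpus is a list of ds_sentence with POS/dependency tag inventories
## attached; (doc_id, sent_id) pairs are unique.
as_corpus <- function(sentences) {
  keys <- vapply(sentences, function(s) paste0(s$doc_id, "\r", s$sent_id), "")
  if (anyDuplicated(keys)) stop("duplicate (doc_id, sent_id) in corpus")
  pos <- sort(unique(unlist(lapply(sentences, function(s) s$tokens$pos))))
  dep <- sort(unique(unlist(lapply(sentences, function(s) s$tokens$dep))))
  structure(sentences, class = "ds_corpus", pos_tags = pos, dep_labels = dep)
}

#' @export
print.ds_corpus <- function(x, ...) {
  nm <- sum(vapply(x, function(s) nrow(s$mentions), 0L))
  cat(sprintf("<corpus: %d sentences, %d mentions, %d docs>\n",
              length(x), nm, length(unique(vapply(x, `[[`, "", "doc_id")))))
  invisible(x)
}

#' @export
`[.ds_corpus` <- function(x, i) {
  as_corpus(unclass(x)[i])
}

#' Read a corpus from JSONL
#'
#' One sentence per line, as a JSON object
#' `{"doc_id":..., "sent_id":..., "tokens":[{"surface","pos","dep"},...],
#'   "mentions":[{"mention_id","entity_type","start","end","kb_id"},...]}`.
#' Records violating the sentence invariants (spans outside the token range,
#' overlapping mentions, duplicate sentence ids) are rejected with an error
#' naming the offending line or sentence.
#'
#' @param path Path to a JSONL file.
#' @return A `ds_corpus` (list of sentences with tag inventories attached).
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sentences <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
      error = function(e) stop("line ", i, ": malformed JSON: ", conditionMessage(e))
    )
    if (is.null(rec$doc_id) || is.null(rec$sent_id) || is.null(rec$tokens)) {
      stop("line ", i, ": record needs doc_id, sent_id, tokens")
    }
    mentions <- rec$mentions
    if (is.null(mentions) || length(mentions) == 0L) {
      mentions <- empty_mentions()
    }
    gp <- rec$gold_pairs
    if (!is.null(gp) && length(gp) == 0L) {
      gp <- data.frame(start1 = integer(), start2 = integer())
    }
    sentences[[i]] <- tryCatch(
      sentence(rec$doc_id, rec$sent_id, rec$tokens, mentions, gold_pairs = gp),
      error = function(e) stop("line ", i, ": ", conditionMessage(e))
    )
  }
  as_corpus(sentences)
}

#' Write a corpus as JSONL
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` reproduces
#' every field of `x`.
#'
#' @param corpus A `ds_corpus` or list of `ds_sentence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in corpus) {
    rec <- list(doc_id = s$doc_id, sent_id = s$sent_id,
                tokens = s$tokens, mentions = s$mentions)
    if (!is.null(s$gold_pairs)) rec$gold_pairs <- s$gold_pairs
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

empty_mentions <- function() {
  data.frame(mention_id = character(), entity_type = character(),
             start = integer(), end = integer(), kb_id = character(),
             stringsAsFactors = FALSE)
}

#' Read a PubTator-style document as sentences
#'
#' Adapter for the PubTator annotation format: a block of
#' `pmid|t|title` / `pmid|a|abstract` lines followed by tab-separated mention
#' lines `pmid<TAB>start<TAB>end<TAB>text<TAB>type<TAB>kb_id` with character
#' offsets into title + " " + abstract. The text is whitespace-tokenized and
#' each mention's character span must align exactly with token boundaries,
#' otherwise the document is rejected (this reader does not attempt
#' retokenization). POS and dependency tags are not carried by PubTator and
#' are filled with the placeholder tags `"X"` and `"dep"`. Each document
#' becomes a single sentence record (sentence segmentation is assumed to have
#' happened upstream).
#'
#' @param path PubTator file path.
#' @param type_map Named character vector mapping PubTator mention types to
#'   `"PROTEIN"`/`"LOCATION"` (default maps `Gene` and `Protein` to PROTEIN).
#' @return A `ds_corpus`.
#' @export
read_pubtator <- function(path, type_map = c(Gene = "PROTEIN", Protein = "PROTEIN",
                                             Location = "LOCATION")) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()   # pmid -> list(text parts, mention rows)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^[^\t|]+\\|[ta]\\|", ln)) {
      parts <- strsplit(ln, "|", fixed = TRUE)[[1]]
      pmid <- parts[1]
      txt <- paste(parts[-(1:2)], collapse = "|")
      if (is.null(docs[[pmid]])) docs[[pmid]] <- list(text = character(), men = list())
      docs[[pmid]]$text <- c(docs[[pmid]]$text, txt)
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 6L) stop("malformed PubTator mention line: ", ln)
      pmid <- f[1]
      if (is.null(docs[[pmid]])) stop("mention line before text for document ", pmid)
      docs[[pmid]]$men[[length(docs[[pmid]]$men) + 1L]] <- f
    }
  }
  sentences <- list()
  for (pmid in names(docs)) {
    text <- paste(docs[[pmid]]$text, collapse = " ")
    surf <- strsplit(text, " +")[[1]]
    surf <- surf[nzchar(surf)]
    # character offset of each token start in the original text
    starts <- integer(length(surf)); pos <- 0L; k <- 1L
    chars <- strsplit(text, "")[[1]]
    i <- 1L
    while (i <= length(chars) && k <= length(surf)) {
      if (chars[i] != " ") {
        starts[k] <- i - 1L
        i <- i + nchar(surf[k]); k <- k + 1L
      } else i <- i + 1L
    }
    ends <- starts + nchar(surf)
    men <- docs[[pmid]]$men
    rows <- lapply(seq_along(men), function(j) {
      f <- men[[j]]
      cs <- as.integer(f[2]); ce <- as.integer(f[3])
      t0 <- match(cs, starts); t1 <- match(ce, ends)
      if (is.na(t0) || is.na(t1)) {
        stop("document ", pmid, ": mention [", cs, ",", ce,
             ") does not align with token boundaries")
      }
      etype <- type_map[[f[5]]]
      if (is.null(etype)) stop("document ", pmid, ": unmapped mention type ", f[5])
      data.frame(mention_id = paste0("m", j), entity_type = etype,
                 start = t0 - 1L, end = t1, kb_id = f[6],
                 stringsAsFactors = FALSE)
    })
    mentions <- if (length(rows)) do.call(rbind, rows) else empty_mentions()
    tokens <- data.frame(surface = surf, pos = "X", dep = "dep",
                         stringsAsFactors = FALSE)
    sentences[[length(sentences) + 1L]] <- sentence(pmid, "s0", tokens, mentions)
  }
  as_corpus(sentences)
}
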