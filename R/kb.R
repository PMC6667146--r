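## Relation knowledge base: a set of normalized entity-identifier pairs.
## Undirected KBs canonicalize each pair to lexicographic order on insert so
## membership testing is symmetric; self-pairs are always dropped.

#' Construct a relation knowledge base
#'
#' @param pairs Two-column character matrix or data.frame of entity-ID pairs.
#' @param directed Logical; if FALSE (e.g. protein-protein interaction) the
#'   pair (A,B) also certifies (B,A).
#' @param type_signature Character vector of length 2 giving the entity types
#'   of the two slots, e.g. `c("PROTEIN", "PROTEIN")`.
#' @return Object of class `relation_kb` with fields `pairs` (canonical keys),
#'   `directed`, `type_signature`, and `n_self_dropped`.
#' @export
relation_kb <- function(pairs, directed = FALSE,
                        type_signature = c("PROTEIN", "PROTEIN")) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("KB pairs must have two columns")
  a <- as.character(pairs[, 1]); b <- as.character(pairs[, 2])
  self <- a == b
  n_self <- sum(self)
  if (n_self) {
    warning(n_self, " self-pair(s) dropped from KB")
    a <- a[!self]; b <- b[!self]
  }
  keys <- unique(kb_key(a, b, directed))
  structure(
    list(pairs = keys, directed = directed,
         type_signature = as.character(type_signature),
         n_self_dropped = n_self),
    class = "relation_kb"
  )
}

kb_key <- function(a, b, directed) {
  if (!length(a)) return(character())  # paste0 would recycle to length 1
  if (directed) paste0(a, "\r", b)
  else paste0(pmin(a, b), "\r", pmax(a, b))
}

#' Test membership of an entity-ID pair in a KB
#'
#' @param kb A `relation_kb`.
#' @param a,b Entity identifiers (vectorized).
#' @return Logical vector; symmetric in (a, b) iff the KB is undirected.
#' @export
kb_contains <- function(kb, a, b) {
  kb_key(as.character(a), as.character(b), kb$directed) %in% kb$pairs
}

#' Number of pairs stored in a KB
#' @param kb A `relation_kb`.
#' @return Integer count of (canonicalized) pairs.
#' @export
kb_size <- function(kb) length(kb$pairs)

#' @export
print.relation_kb <- function(x, ...) {
  cat(sprintf("<relation KB: %d %s pairs (%s-%s)%s>\n",
              kb_size(x), if (x$directed) "directed" else "undirected",
              x$type_signature[1], x$type_signature[2],
              if (x$n_self_dropped) sprintf(", %d self-pairs dropped", x$n_self_dropped) else ""))
  invisible(x)
}

#' Read a relation KB from a two-column TSV
#'
#' Each line is `kb_id1<TAB>kb_id2`. Undirected KBs collapse both orders of a
#' pair into one canonical entry; duplicate lines are collapsed; self-pairs
#' are dropped with a warning (the drop count is kept in `n_self_dropped`).
#'
#' @param path TSV file path.
#' @inheritParams relation_kb
#' @return A `relation_kb`.
#' @export
read_kb <- function(path, directed = FALSE,
                    type_signature = c("PROTEIN", "PROTEIN")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("line ", bad[1], ": expected 2 tab-separated columns")
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  relation_kb(m, directed = directed, type_signature = type_signature)
}

#' Write a relation KB as a two-column TSV
#' @param kb A `relation_kb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  ab <- do.call(rbind, strsplit(kb$pairs, "\r", fixed = TRUE))
  writeLines(paste(ab[, 1], ab[, 2], sep = "\t"), path)
  invisible(path)
}
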