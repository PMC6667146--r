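## Word-embedding table in word2vec text format, with a deterministic
## out-of-vocabulary policy: an OOV word receives a pseudo-random vector with
## components ~ uniform(-0.05, 0.05) keyed by (word, seed), so repeated
## lookups and repeated runs agree exactly.

#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per word, with rownames giving the
#'   vocabulary.
#' @param oov_seed Integer seed keying the deterministic OOV vectors.
#' @return Object of class `embedding_table` with fields `vectors`,
#'   `dimension`, `oov_seed`.
#' @export
embedding_table <- function(vectors, oov_seed = 1L) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) stop("embedding matrix needs word rownames")
  structure(
    list(vectors = vectors, dimension = ncol(vectors),
         oov_seed = as.integer(oov_seed)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embeddings: %d words x %d dims, OOV seed %d>\n",
              nrow(x$vectors), x$dimension, x$oov_seed))
  invisible(x)
}

#' Look up word vectors
#'
#' In-vocabulary words return their stored vector; out-of-vocabulary words
#' return the deterministic keyed vector with components in (-0.05, 0.05).
#'
#' @param emb An `embedding_table`.
#' @param words Character vector of surface forms.
#' @return Numeric matrix with `length(words)` rows.
#' @export
emb_lookup <- function(emb, words) {
  idx <- match(words, rownames(emb$vectors))
  out <- matrix(0, nrow = length(words), ncol = emb$dimension)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- emb$vectors[idx[hit], , drop = FALSE]
  for (i in which(!hit)) {
    out[i, ] <- keyed_uniform(words[i], emb$oov_seed, emb$dimension, 0.05)
  }
  out
}

#' Read embeddings in word2vec text format
#'
#' Expects a header line `V D` followed by `V` lines `word v1 ... vD`.
#'
#' @param path File path.
#' @param expected_dim Required vector dimension (default 200); a mismatch is
#'   a configuration error.
#' @param oov_seed Seed for the deterministic OOV policy.
#' @return An `embedding_table`.
#' @export
read_embeddings <- function(path, expected_dim = 200L, oov_seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), " +")[[1]]
  if (length(hdr) != 2L) stop("embeddings header must be 'V D'")
  v <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (d != expected_dim) {
    stop("embedding dimension ", d, " does not match configured dimension ",
         expected_dim)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != v) stop("header declares ", v, " words, found ", length(body))
  parts <- strsplit(trimws(body), " +")
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": expected ", d, " values, found ",
         lengths(parts)[bad[1]] - 1L)
  }
  words <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(d))
  vecs <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  rownames(vecs) <- words
  embedding_table(vecs, oov_seed = oov_seed)
}

#' Write embeddings in word2vec text format
#' @param emb An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(nrow(emb$vectors), emb$dimension), con)
  apply_rows <- apply(emb$vectors, 1L, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = " "))
  writeLines(paste(rownames(emb$vectors), apply_rows), con)
  invisible(path)
}
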