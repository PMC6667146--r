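## Multi-channel token featurization.
##
## Every token of an instance is represented by the concatenation of its
## word embedding (200-d by default), a learned POS-tag embedding (10-d), a
## learned incoming-dependency embedding (10-d), learned embeddings of the
## signed token distances to entity 1 and entity 2 (5-d each, distances
## clipped to +/-50), and a 4-d one-hot entity-role vector over
## {ENTITY1, ENTITY2, ENTITY, O} -- 234 dimensions at the defaults.
## Sentences longer than `max_len` (100) are pruned from the right, shorter
## ones padded with all-zero rows; the two entity span ends split the
## sentence into the three contiguous segments used by piecewise pooling.

ROLE_LEVELS <- c("ENTITY1", "ENTITY2", "ENTITY", "O")

#' Signed token distance to a mention
#'
#' Zero for tokens inside the span; for tokens outside, the token count to
#' the nearest span boundary, negative on the left of the mention and
#' positive on the right (adjacent tokens are at distance -1/+1). Distances
#' are clipped to `[-clip, clip]`.
#'
#' @param token_index Integer vector of 0-based token positions.
#' @param mention Mention (list with `start`, `end`).
#' @param clip Clipping bound (default 50).
#' @return Integer vector of signed distances.
#' @export
relative_distance <- function(token_index, mention, clip = 50L) {
  d <- integer(length(token_index))
  left <- token_index < mention$start
  right <- token_index >= mention$end
  d[left] <- token_index[left] - mention$start
  d[right] <- token_index[right] - mention$end + 1L
  pmax(pmin(d, clip), -clip)
}

#' Assign entity-role labels to every token
#'
#' Tokens in the e1 span get ENTITY1, in the e2 span ENTITY2, in any other
#' mention span ENTITY, and all remaining tokens O.
#'
#' @param sent A `ds_sentence`.
#' @param e1,e2 The two target mentions.
#' @return Character vector of roles, one per token.
#' @export
assign_roles <- function(sent, e1, e2) {
  n <- nrow(sent$tokens)
  idx <- seq_len(n) - 1L
  roles <- rep("O", n)
  m <- sent$mentions
  for (i in seq_len(nrow(m))) {
    roles[idx >= m$start[i] & idx < m$end[i]] <- "ENTITY"
  }
  roles[idx >= e1$start & idx < e1$end] <- "ENTITY1"
  roles[idx >= e2$start & idx < e2$end] <- "ENTITY2"
  roles
}

#' Initialize learned categorical-channel embedding tables
#'
#' POS-tag, dependency-label and distance embeddings are learnable model
#' parameters, initialized uniform(-0.1, 0.1) from the seed. Each table gets
#' an `<UNK>` row for tags unseen at training time.
#'
#' @param cfg A [ds_config()].
#' @param pos_tags,dep_labels Tag inventories (character vectors).
#' @param seed Integer seed.
#' @return List of matrices `pos`, `dep`, `d1`, `d2` with rownames.
#' @export
init_categorical_tables <- function(cfg, pos_tags, dep_labels, seed = 1L) {
  with_seed(mix_seed(seed, "cat-tables"), {
    mk <- function(rows, d) {
      m <- matrix(stats::runif(length(rows) * d, -0.1, 0.1),
                  nrow = length(rows), ncol = d)
      rownames(m) <- rows
      m
    }
    dist_rows <- as.character(seq(-cfg$dist_clip, cfg$dist_clip))
    list(pos = mk(c(pos_tags, "<UNK>"), cfg$pos_dim),
         dep = mk(c(dep_labels, "<UNK>"), cfg$dep_dim),
         d1 = mk(dist_rows, cfg$dist_dim),
         d2 = mk(dist_rows, cfg$dist_dim))
  })
}

#' Piecewise segment boundaries of an instance
#'
#' The two entity span ends divide `[0, true_length)` into three contiguous,
#' non-overlapping, ordered intervals: part 1 ends with the first entity,
#' part 2 ends with the second, part 3 is the remainder. Empty intervals are
#' permitted.
#'
#' @param inst A `ds_instance`.
#' @param true_length Unpadded token count of the (possibly pruned) sentence.
#' @return 3x2 integer matrix of half-open `[start, end)` intervals.
#' @export
segment_bounds <- function(inst, true_length) {
  b1 <- min(inst$e1$end, inst$e2$end)
  b2 <- max(inst$e1$end, inst$e2$end)
  b1 <- min(b1, true_length); b2 <- min(b2, true_length)
  matrix(c(0L, b1, b1, b2, b2, true_length), nrow = 3L, byrow = TRUE,
         dimnames = list(c("part1", "part2", "part3"), c("start", "end")))
}

## Index-level feature representation: everything needed to compose the
## dense matrix under the *current* categorical tables. Word vectors are
## fixed (pre-trained) and stored densely; categorical channels are stored
## as row indices so gradients can flow back into the tables.
instance_features <- function(inst, emb, tables, cfg) {
  sent <- inst$sentence
  n <- nrow(sent$tokens)
  if (max(inst$e1$end, inst$e2$end) > cfg$max_len) {
    stop(structure(
      class = c("dsre_prune_error", "error", "condition"),
      list(message = paste0("instance ", sent$doc_id, "/", sent$sent_id,
                            ": mention beyond max_len ", cfg$max_len),
           call = NULL)))
  }
  tl <- min(n, cfg$max_len)
  idx <- seq_len(tl) - 1L
  tk <- sent$tokens[seq_len(tl), , drop = FALSE]
  ridx <- function(tab, keys) {
    i <- match(keys, rownames(tab))
    i[is.na(i)] <- nrow(tab)  # <UNK> row
    i
  }
  d1 <- relative_distance(idx, inst$e1, cfg$dist_clip)
  d2 <- relative_distance(idx, inst$e2, cfg$dist_clip)
  roles <- assign_roles(sent, inst$e1, inst$e2)[seq_len(tl)]
  role_mat <- matrix(0, nrow = tl, ncol = 4L)
  role_mat[cbind(seq_len(tl), match(roles, ROLE_LEVELS))] <- 1
  list(
    tl = tl,
    W = emb_lookup(emb, tk$surface),
    pos_ids = ridx(tables$pos, tk$pos),
    dep_ids = ridx(tables$dep, tk$dep),
    d1_ids = ridx(tables$d1, as.character(d1)),
    d2_ids = ridx(tables$d2, as.character(d2)),
    role = role_mat,
    segments = segment_bounds(inst, tl),
    label = inst$label,
    gold = inst$gold
  )
}

## Compose the dense (tl x D) input matrix from an index representation and
## the current categorical tables. Shared by featurization and training.
compose_matrix <- function(feat, tables) {
  cbind(feat$W,
        tables$pos[feat$pos_ids, , drop = FALSE],
        tables$dep[feat$dep_ids, , drop = FALSE],
        tables$d1[feat$d1_ids, , drop = FALSE],
        tables$d2[feat$d2_ids, , drop = FALSE],
        feat$role)
}

#' Encode an instance as a padded token-feature matrix
#'
#' Builds the `max_len` x D matrix (D = 234 at the defaults) whose row t is
#' the multi-channel feature vector of token t; rows at and beyond the true
#' sentence length are all zero. Instances whose mentions lie beyond
#' `max_len` after pruning are rejected with an error of class
#' `dsre_prune_error` (callers count rejections; see [encode_instances()]).
#'
#' @param inst A `ds_instance`.
#' @param emb An `embedding_table` whose dimension equals `cfg$word_dim`.
#' @param tables Categorical tables from [init_categorical_tables()].
#' @param cfg A [ds_config()].
#' @return Object of class `instance_encoding`: list with `matrix`
#'   (`max_len` x D), `true_length`, `segments` (3x2), `label`.
#' @export
encode_instance <- function(inst, emb, tables, cfg = ds_config()) {
  if (emb$dimension != cfg$word_dim) {
    stop("embedding dimension ", emb$dimension, " != configured word_dim ",
         cfg$word_dim)
  }
  feat <- instance_features(inst, emb, tables, cfg)
  D <- feature_dim(cfg)
  mat <- matrix(0, nrow = cfg$max_len, ncol = D)
  mat[seq_len(feat$tl), ] <- compose_matrix(feat, tables)
  structure(
    list(matrix = mat, true_length = feat$tl, segments = feat$segments,
         label = feat$label),
    class = "instance_encoding"
  )
}

#' Encode a collection of instances
#'
#' REMOVED instances are skipped; instances rejected because a mention falls
#' beyond `max_len` are counted, not silently dropped.
#'
#' @inheritParams encode_instance
#' @param instances A `ds_instances` collection.
#' @return List with `encodings` (list of `instance_encoding`) and
#'   `n_rejected`.
#' @export
encode_instances <- function(instances, emb, tables, cfg = ds_config()) {
  enc <- list(); rejected <- 0L
  for (inst in active_instances(instances)) {
    e <- tryCatch(encode_instance(inst, emb, tables, cfg),
                  dsre_prune_error = function(cond) NULL)
    if (is.null(e)) rejected <- rejected + 1L else enc[[length(enc) + 1L]] <- e
  }
  list(encodings = enc, n_rejected = rejected)
}
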