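## Distant supervision: label every in-sentence mention pair by knowledge-base
## membership. A pair found in the KB yields a positive instance, a pair not
## found yields a negative one; pairs whose two mentions normalize to the same
## entity identifier are excluded (REMOVED) rather than labeled.

#' Enumerate candidate mention pairs in a sentence
#'
#' For a symmetric type signature (e.g. PROTEIN-PROTEIN) every unordered pair
#' of distinct mention spans of that type is a candidate, including pairs of
#' mentions sharing a kb_id at different positions; slot 1 is the mention
#' whose span starts first. For an asymmetric signature every
#' (type-1 mention, type-2 mention) cross pair is a candidate. A mention is
#' never paired with itself.
#'
#' @param sent A `ds_sentence`.
#' @param signature Character vector of length 2 of entity types.
#' @return A `ds_instances` collection of unlabeled candidates (possibly
#'   empty).
#' @export
enumerate_candidates <- function(sent, signature = c("PROTEIN", "PROTEIN")) {
  m <- sent$mentions
  out <- list()
  # gold is NA when the corpus carries no gold annotation at all; a present
  # but empty gold_pairs set means "no pair in this sentence is positive"
  gold_of <- function(e1, e2) {
    gp <- sent$gold_pairs
    if (is.null(gp)) return(NA)
    if (!nrow(gp)) return(FALSE)
    any((gp$start1 == e1$start & gp$start2 == e2$start) |
        (gp$start1 == e2$start & gp$start2 == e1$start))
  }
  if (signature[1] == signature[2]) {
    idx <- which(m$entity_type == signature[1])
    idx <- idx[order(m$start[idx])]
    n <- length(idx)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        e1 <- mention_row(m, idx[i]); e2 <- mention_row(m, idx[j])
        out[[length(out) + 1L]] <- new_instance(sent, e1, e2, gold = gold_of(e1, e2))
      }
    }
  } else {
    i1 <- which(m$entity_type == signature[1])
    i2 <- which(m$entity_type == signature[2])
    for (i in i1) for (j in i2) {
      e1 <- mention_row(m, i); e2 <- mention_row(m, j)
      out[[length(out) + 1L]] <- new_instance(sent, e1, e2, gold = gold_of(e1, e2))
    }
  }
  as_instances(out)
}

#' Label one candidate instance against a knowledge base
#'
#' The label is POS if the pair of kb_ids is in the KB (respecting the KB's
#' directedness), NEG otherwise; candidates whose two mentions share the same
#' kb_id are labeled REMOVED. The provenance trail gains the tag `DS`.
#'
#' @param candidate A `ds_instance` with mentions carrying kb_ids.
#' @param kb A `relation_kb`.
#' @return The labeled `ds_instance`.
#' @export
label_candidate <- function(candidate, kb) {
  id1 <- candidate$e1$kb_id; id2 <- candidate$e2$kb_id
  if (is.na(id1) || is.na(id2) || !nzchar(id1) || !nzchar(id2)) {
    stop("candidate mention lacks a kb_id")
  }
  candidate$label <- if (id1 == id2) "REMOVED"
                     else if (kb_contains(kb, id1, id2)) "POS"
                     else "NEG"
  candidate$provenance <- c(candidate$provenance, "DS")
  candidate
}

#' Distantly label a whole corpus
#'
#' Enumerates candidates in every sentence and labels each against the KB.
#' Deterministic: identical inputs give identical instance sets. The label
#' counts recorded in the `"stats"` attribute sum to the candidate count.
#'
#' @param corpus A `ds_corpus` (or list of sentences).
#' @param kb A `relation_kb`; its `type_signature` drives candidate
#'   enumeration.
#' @return A labeled `ds_instances` collection with a `"stats"` attribute
#'   (list `pos`/`neg`/`removed`).
#' @export
label_corpus <- function(corpus, kb) {
  out <- list()
  for (sent in corpus) {
    cands <- enumerate_candidates(sent, kb$type_signature)
    for (cand in cands) {
      out[[length(out) + 1L]] <- label_candidate(cand, kb)
    }
  }
  out <- as_instances(out)
  attr(out, "stats") <- instance_stats(out)
  out
}
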