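## Noise-reduction heuristics for distantly supervised instances.
##
## Closest Pair (CP) and Trigger Word (TW) act on positives, High-confidence
## Pattern (HP) on negatives, and the top-k entity-frequency filter on both.
## No heuristic ever flips POS <-> NEG: the only transition is to REMOVED,
## and every removal appends its step tag to the instance's provenance.

#' Rule-based lemmatizer
#'
#' Suffix stripper (ions/ion/ing/ed/s) over a small irregular-form table,
#' sufficient to conflate relation trigger variants such as "binds"/
#' "binding"/"bind" or "interacts"/"interaction"/"interact" at corpus scale.
#'
#' @param words Character vector of surface forms (case-insensitive).
#' @return Character vector of lemmas.
#' @export
lemmatize <- function(words) {
  w <- tolower(words)
  irregular <- c(was = "be", were = "be", is = "be", are = "be", been = "be",
                 being = "be", has = "have", had = "have", bound = "bind",
                 binding = "bind")
  hit <- match(w, names(irregular))
  out <- w
  out[!is.na(hit)] <- irregular[hit[!is.na(hit)]]
  todo <- is.na(hit)
  for (suf in c("ions", "ion", "ing", "ed", "s")) {
    n <- nchar(out)
    m <- todo & endsWith(out, suf) & (n - nchar(suf)) >= 3L
    out[m] <- substr(out[m], 1L, n[m] - nchar(suf))
    todo <- todo & !m
  }
  out
}

## Left/right mention of an instance by span position.
lr_mentions <- function(inst) {
  if (inst$e1$start <= inst$e2$start) list(left = inst$e1, right = inst$e2)
  else list(left = inst$e2, right = inst$e1)
}

## Token indices of the trigger search region: the inter-entity span plus
## `window` tokens on each side, excluding tokens inside either mention span.
trigger_region <- function(inst, window) {
  lr <- lr_mentions(inst)
  n <- nrow(inst$sentence$tokens)
  lo <- max(0L, lr$left$end - window)
  hi <- min(n - 1L, lr$right$start - 1L + window)
  if (lo > hi) return(integer())
  idx <- lo:hi
  in_span <- (idx >= inst$e1$start & idx < inst$e1$end) |
             (idx >= inst$e2$start & idx < inst$e2$end)
  idx[!in_span]
}

is_trigger_pos <- function(tags) grepl("^(V|N|J)", tags)

## Candidate trigger lemmas of one instance (unique per instance).
instance_trigger_lemmas <- function(inst, window) {
  idx <- trigger_region(inst, window)
  if (!length(idx)) return(character())
  tk <- inst$sentence$tokens[idx + 1L, , drop = FALSE]
  keep <- is_trigger_pos(tk$pos)
  unique(lemmatize(tk$surface[keep]))
}

#' Closest-pair heuristic
#'
#' Within each sentence, when the same entity-ID pair is DS-positive at more
#' than one mention-pair position (one entity mentioned several times), only
#' the instance whose mentions are closest in the text keeps its positive
#' label; the others are removed from the dataset, never relabeled negative.
#' Distance is the token count between the inner boundaries of the two
#' spans; ties keep the instance whose left mention starts first. Negative
#' instances are untouched.
#'
#' @param instances Labeled `ds_instances`.
#' @return Filtered `ds_instances` (same order).
#' @export
closest_pair_filter <- function(instances) {
  labels <- instance_labels(instances)
  pos_idx <- which(labels == "POS")
  if (!length(pos_idx)) return(instances)
  keys <- vapply(pos_idx, function(i) {
    inst <- instances[[i]]
    ids <- sort(c(inst$e1$kb_id, inst$e2$kb_id))
    paste(inst$sentence$doc_id, inst$sentence$sent_id, ids[1], ids[2], sep = "\r")
  }, "")
  out <- unclass(instances)
  for (grp in split(pos_idx, keys)) {
    if (length(grp) < 2L) next
    gaps <- vapply(grp, function(i) instance_gap(instances[[i]]), 0L)
    lefts <- vapply(grp, function(i) min(instances[[i]]$e1$start,
                                         instances[[i]]$e2$start), 0L)
    rights <- vapply(grp, function(i) max(instances[[i]]$e1$start,
                                          instances[[i]]$e2$start), 0L)
    keep <- grp[order(gaps, lefts, rights)][1L]
    for (i in setdiff(grp, keep)) {
      out[[i]]$label <- "REMOVED"
      out[[i]]$provenance <- c(out[[i]]$provenance, "CP")
    }
  }
  as_instances(out)
}

#' Mine relation trigger words
#'
#' Candidate triggers are lemmas of verbal, nominal or adjectival tokens
#' (POS tag starting V/N/J) occurring in the trigger search region (the
#' inter-entity span plus `window` tokens on each side). Each lemma is scored
#' by the smoothed log-ratio of instance-level occurrence counts,
#' `log((c_pos + 1) / (c_neg + 1))`, and the `top_k` positively scored
#' lemmas (ties broken lexicographically) form the lexicon: a lemma at most
#' as frequent in negatives as in positives carries no evidence of the
#' relation and is never admitted.
#'
#' @param pos_instances,neg_instances Non-empty positive / negative instance
#'   collections.
#' @param window Tokens searched beyond the inter-entity span on each side.
#' @param top_k Lexicon size.
#' @return Object of class `trigger_lexicon`: list with `entries` (named
#'   score vector, sorted), `window`, `top_k`.
#' @export
mine_triggers <- function(pos_instances, neg_instances, window = 2L, top_k = 20L) {
  if (!length(pos_instances)) stop("trigger mining needs positive instances")
  if (!length(neg_instances)) stop("trigger mining needs negative instances")
  count_lemmas <- function(insts) {
    lem <- unlist(lapply(insts, instance_trigger_lemmas, window = window))
    if (!length(lem)) return(integer())
    table(lem)
  }
  cp <- count_lemmas(pos_instances)
  cn <- count_lemmas(neg_instances)
  lemmas <- sort(unique(c(names(cp), names(cn))))
  if (!length(lemmas)) stop("no candidate trigger lemmas found")
  npos <- ifelse(lemmas %in% names(cp), as.integer(cp[lemmas]), 0L)
  nneg <- ifelse(lemmas %in% names(cn), as.integer(cn[lemmas]), 0L)
  score <- log((npos + 1) / (nneg + 1))
  eligible <- which(score > 0)
  if (!length(eligible)) stop("no positively scored trigger candidates")
  o <- eligible[order(-score[eligible], lemmas[eligible])]
  sel <- o[seq_len(min(top_k, length(o)))]
  entries <- stats::setNames(score[sel], lemmas[sel])
  structure(list(entries = entries, window = as.integer(window),
                 top_k = as.integer(top_k)),
            class = "trigger_lexicon")
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat(sprintf("<trigger lexicon: %d lemmas (window %d)>\n",
              length(x$entries), x$window))
  print(utils::head(round(x$entries, 3), 10))
  invisible(x)
}

#' Trigger-word heuristic
#'
#' A positive instance keeps its label only if some token in its trigger
#' search region has a lemma in the lexicon; otherwise it is removed.
#' Negatives are untouched. The filter is idempotent.
#'
#' @param instances Labeled `ds_instances`.
#' @param lexicon A `trigger_lexicon` from [mine_triggers()].
#' @return Filtered `ds_instances`.
#' @export
trigger_filter <- function(instances, lexicon) {
  out <- unclass(instances)
  vocab <- names(lexicon$entries)
  for (i in seq_along(out)) {
    if (out[[i]]$label != "POS") next
    lemmas <- instance_trigger_lemmas(out[[i]], lexicon$window)
    if (!any(lemmas %in% vocab)) {
      out[[i]]$label <- "REMOVED"
      out[[i]]$provenance <- c(out[[i]]$provenance, "TW")
    }
  }
  as_instances(out)
}

#' Extract the inter-entity lexical template of an instance
#'
#' Lowercased surface tokens from the start of the left mention to the end of
#' the right mention, with the two target spans collapsed to the placeholders
#' ENTITY1/ENTITY2 (by instance slot), other same-type mention spans to
#' ENTITY, plus up to `tail` tokens after the right mention. Returns NA when
#' more than `max_len` tokens separate the two spans.
#'
#' @param inst A `ds_instance`.
#' @param max_len Maximum inter-entity token count.
#' @param tail Tokens appended after the right mention.
#' @return A single template string, or `NA_character_`.
#' @export
extract_pattern <- function(inst, max_len = 10L, tail = 1L) {
  lr <- lr_mentions(inst)
  gap <- lr$right$start - lr$left$end
  if (gap > max_len) return(NA_character_)
  sent <- inst$sentence
  n <- nrow(sent$tokens)
  hi <- min(n - 1L, lr$right$end - 1L + tail)
  idx <- lr$left$start:hi
  ph1 <- if (identical(lr$left, inst$e1)) "ENTITY1" else "ENTITY2"
  ph2 <- if (identical(lr$left, inst$e1)) "ENTITY2" else "ENTITY1"
  types <- c(inst$e1$entity_type, inst$e2$entity_type)
  m <- sent$mentions
  pieces <- character(); i <- 1L
  while (i <= length(idx)) {
    t <- idx[i]
    if (t >= lr$left$start && t < lr$left$end) {
      pieces <- c(pieces, ph1); i <- i + (lr$left$end - t)
    } else if (t >= lr$right$start && t < lr$right$end) {
      pieces <- c(pieces, ph2); i <- i + (lr$right$end - t)
    } else {
      k <- which(m$start <= t & t < m$end & m$entity_type %in% types)
      if (length(k)) {
        pieces <- c(pieces, "ENTITY"); i <- i + (m$end[k[1]] - t)
      } else {
        pieces <- c(pieces, tolower(sent$tokens$surface[t + 1L])); i <- i + 1L
      }
    }
  }
  paste(pieces, collapse = " ")
}

#' Mine high-confidence patterns from positive instances
#'
#' Counts inter-entity templates over the positive set and keeps those with
#' support at least `min_support`.
#'
#' @param pos_instances Positive `ds_instances`.
#' @param min_support Minimum positive support.
#' @inheritParams extract_pattern
#' @return Object of class `pattern_set`: list with `patterns` (named support
#'   counts), `min_support`, `max_len`, `tail`.
#' @export
mine_patterns <- function(pos_instances, min_support = 10L, max_len = 10L,
                          tail = 1L) {
  tmpl <- vapply(pos_instances, extract_pattern, "",
                 max_len = max_len, tail = tail)
  tmpl <- tmpl[!is.na(tmpl)]
  support <- if (length(tmpl)) table(tmpl) else integer()
  keep <- support[support >= min_support]
  patterns <- stats::setNames(as.integer(keep), names(keep))
  structure(list(patterns = patterns, min_support = as.integer(min_support),
                 max_len = as.integer(max_len), tail = as.integer(tail)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern set: %d patterns (support >= %d)>\n",
              length(x$patterns), x$min_support))
  if (length(x$patterns)) print(utils::head(sort(x$patterns, decreasing = TRUE), 5))
  invisible(x)
}

#' High-confidence pattern heuristic
#'
#' A negative instance whose inter-entity template matches a mined
#' high-confidence pattern is removed from the dataset (knowledge-base
#' incompleteness makes it likely mislabeled); it is never relabeled
#' positive. Positives are untouched.
#'
#' @param instances Labeled `ds_instances`.
#' @param patterns A `pattern_set` from [mine_patterns()].
#' @return Filtered `ds_instances`.
#' @export
pattern_filter <- function(instances, patterns) {
  out <- unclass(instances)
  vocab <- names(patterns$patterns)
  if (length(vocab)) {
    for (i in seq_along(out)) {
      if (out[[i]]$label != "NEG") next
      tmpl <- extract_pattern(out[[i]], patterns$max_len, patterns$tail)
      if (!is.na(tmpl) && tmpl %in% vocab) {
        out[[i]]$label <- "REMOVED"
        out[[i]]$provenance <- c(out[[i]]$provenance, "HP")
      }
    }
  }
  as_instances(out)
}

#' Top-k entity-frequency filter
#'
#' Ranks the kb_ids occurring in one instance slot by their frequency over
#' the active (POS and NEG) instances and removes every instance whose slot
#' entity falls outside the top `k`; entities tied with the rank-k frequency
#' are all kept. Used to restrict protein-localization data to the most
#' frequent location names.
#'
#' @param instances Labeled `ds_instances`.
#' @param k Number of entities kept.
#' @param side Which slot to rank, `"e2"` (default) or `"e1"`.
#' @return Filtered `ds_instances`.
#' @export
top_entity_filter <- function(instances, k = 20L, side = c("e2", "e1")) {
  side <- match.arg(side)
  labels <- instance_labels(instances)
  act <- which(labels %in% c("POS", "NEG"))
  if (!length(act)) return(instances)
  ids <- vapply(act, function(i) instances[[i]][[side]]$kb_id, "")
  freq <- sort(table(ids), decreasing = TRUE)
  if (length(freq) > k) {
    cutoff <- as.integer(freq[k])
    kept_ids <- names(freq)[as.integer(freq) >= cutoff]
  } else kept_ids <- names(freq)
  out <- unclass(instances)
  for (j in seq_along(act)) {
    i <- act[j]
    if (!(ids[j] %in% kept_ids)) {
      out[[i]]$label <- "REMOVED"
      out[[i]]$provenance <- c(out[[i]]$provenance, "TOPK")
    }
  }
  as_instances(out)
}

#' Apply a noise-reduction pipeline
#'
#' Runs the named heuristics in the given order, mining the trigger lexicon
#' and pattern set from the instance collection as it stands when the
#' corresponding step executes. Recognized steps: `"cp"`, `"tw"`, `"hp"`,
#' `"topk"`.
#'
#' @param instances Labeled `ds_instances`.
#' @param steps Character vector of step names, applied in order (may be
#'   empty, in which case the instances pass through unchanged).
#' @param cfg A [ds_config()] supplying heuristic parameters
#'   (`trigger_window`, `trigger_top_k`, `pattern_min_support`,
#'   `pattern_max_len`, `pattern_tail`).
#' @param topk_k,topk_side Parameters of the `"topk"` step.
#' @return List with `instances` (filtered collection) and `stats`, a
#'   data.frame of pos/neg/removed counts after each step (first row =
#'   input).
#' @export
apply_pipeline <- function(instances, steps = character(), cfg = ds_config(),
                           topk_k = 20L, topk_side = "e2") {
  stats_rows <- list()
  snap <- function(step) {
    s <- instance_stats(instances)
    data.frame(step = step, pos = s$pos, neg = s$neg, removed = s$removed,
               stringsAsFactors = FALSE)
  }
  stats_rows[[1L]] <- snap("input")
  for (step in steps) {
    instances <- switch(
      tolower(step),
      cp = closest_pair_filter(instances),
      tw = {
        labels <- instance_labels(instances)
        lex <- mine_triggers(instances[labels == "POS"],
                             instances[labels == "NEG"],
                             window = cfg$trigger_window,
                             top_k = cfg$trigger_top_k)
        trigger_filter(instances, lex)
      },
      hp = {
        labels <- instance_labels(instances)
        pats <- mine_patterns(instances[labels == "POS"],
                              min_support = cfg$pattern_min_support,
                              max_len = cfg$pattern_max_len,
                              tail = cfg$pattern_tail)
        pattern_filter(instances, pats)
      },
      topk = top_entity_filter(instances, k = topk_k, side = topk_side),
      stop("unknown pipeline step: ", step)
    )
    stats_rows[[length(stats_rows) + 1L]] <- snap(tolower(step))
  }
  list(instances = instances, stats = do.call(rbind, stats_rows))
}
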