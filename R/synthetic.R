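## Synthetic corpus generator with controlled distant-supervision noise.
##
## Emulates the noise phenomena that motivate the heuristics, on a small
## closed grammar: co-occurrence-without-relation false positives (a
## KB-related pair mentioned in a sentence that does not express the
## relation), KB-incompleteness false negatives (relation-expressing
## sentences whose pair is withheld from the observed KB), multi-mention
## sentences (one entity repeated farther away, so closest-pair keeping is
## gold-correct), trigger-bearing positives and recurring lexical patterns.
## Gold labels are recorded independently of any KB. Tokens carry synthetic
## POS/dependency tags from a closed 12-tag / 10-label inventory.

SYN_TRIGGERS <- c("binds", "activates", "inhibits", "phosphorylates",
                  "regulates", "stabilizes", "recruits", "cleaves",
                  "acetylates", "ubiquitinates")

## Distractor vocabulary of the non-relational templates. The lexical slots
## vary independently so that no single non-relational inter-entity template
## recurs often enough among co-occurrence false positives to reach the
## default high-confidence-pattern support threshold.
SYN_NOUNS1 <- c("expression", "function", "abundance", "localization",
                "stability", "activity")
SYN_CONNS <- c("and", "or", "versus", "plus")
SYN_POSTS <- c("was", "were", "has", "had", "remains")
SYN_POSTS_POS <- c("VBD", "VBD", "VBZ", "VBD", "VBZ")
SYN_VERBS <- c("measured", "observed", "examined", "detected", "compared")
SYN_NOUNS2 <- c("cells", "lysates", "tissues", "extracts")

#' Configuration of the synthetic-data generator
#'
#' Defaults define the package's standard benchmark: 2000 distantly
#' supervised sentences (10x the manually annotated set), a 120-entity world
#' with 150 truly related pairs, 20% of true pairs withheld from the
#' observed KB (incompleteness false negatives), 30% of KB-pair sentences
#' that merely co-occur without expressing the relation (false positives),
#' 20% of relation sentences repeating one entity at a farther position, and
#' a 10-verb relation trigger inventory.
#'
#' @param ... Named overrides: `n_entities`, `n_kb_pairs`,
#'   `kb_incompleteness_rate`, `cooccurrence_fp_rate`, `multi_mention_rate`,
#'   `related_rate` (fraction of sentences about truly related pairs),
#'   `n_sentences` (DS corpus size), `ds_factor` (DS/MA size ratio),
#'   `sentences_per_doc`, `word_dim`, `trigger_inventory`, `seed`.
#' @return Named list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_entities = 120L,
    n_kb_pairs = 150L,
    kb_incompleteness_rate = 0.2,
    cooccurrence_fp_rate = 0.3,
    multi_mention_rate = 0.2,
    related_rate = 0.5,
    n_sentences = 2000L,
    ds_factor = 10L,
    sentences_per_doc = 5L,
    word_dim = 25L,
    trigger_inventory = SYN_TRIGGERS,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown generator_config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  rates <- c(cfg$kb_incompleteness_rate, cfg$cooccurrence_fp_rate,
             cfg$multi_mention_rate, cfg$related_rate)
  stopifnot(all(rates >= 0 & rates <= 1), length(cfg$trigger_inventory) >= 1,
            cfg$n_entities >= 4, cfg$n_sentences >= 1)
  structure(cfg, class = "generator_config")
}

#' Generate the entity world and knowledge bases
#'
#' The observed KB is the true KB minus a seeded draw of
#' `round(kb_incompleteness_rate * |true KB|)` pairs, emulating database
#' incompleteness.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `true_kb`, `observed_kb` (both `relation_kb`) and
#'   `entities` (character vector of kb ids).
#' @export
generate_world <- function(config = generator_config(), seed = config$seed) {
  entities <- sprintf("PROT%03d", seq_len(config$n_entities))
  with_seed(mix_seed(seed, "world"), {
    npair_max <- choose(config$n_entities, 2)
    npair <- min(config$n_kb_pairs, npair_max)
    # sample distinct unordered pairs by index
    picked <- sample.int(npair_max, npair)
    all_pairs <- utils::combn(config$n_entities, 2)
    tp <- all_pairs[, picked, drop = FALSE]
    true_pairs <- cbind(entities[tp[1, ]], entities[tp[2, ]])
    n_drop <- round(config$kb_incompleteness_rate * npair)
    drop_idx <- if (n_drop > 0) sample.int(npair, n_drop) else integer()
    obs_pairs <- true_pairs[setdiff(seq_len(npair), drop_idx), , drop = FALSE]
    list(
      true_kb = relation_kb(true_pairs, directed = FALSE),
      observed_kb = if (nrow(obs_pairs)) relation_kb(obs_pairs, directed = FALSE)
                    else relation_kb(matrix(character(), ncol = 2), directed = FALSE),
      entities = entities
    )
  })
}

## token helper: build the token data.frame from parallel vectors
syn_tokens <- function(surface, pos, dep) {
  data.frame(surface = surface, pos = pos, dep = dep, stringsAsFactors = FALSE)
}

## One synthetic sentence about entity pair (a, b). Returns the sentence
## tokens/mentions plus the gold-positive span pair (or NULL).
syn_sentence <- function(a, b, relational, multi_mention, trigger, style) {
  if (relational) {
    if (style == 1L) {
      # "<A> <trigger-3sg> <B> directly ."
      surf <- c(a, trigger, b, "directly", ".")
      pos <- c("NNP", "VBZ", "NNP", "RB", ".")
      dep <- c("nsubj", "root", "dobj", "advmod", "punct")
      spans <- list(c(0L, 1L), c(2L, 3L))
    } else {
      # "<A> and <B> <trigger-base> in cells ."
      base <- sub("s$", "", trigger)
      surf <- c(a, "and", b, base, "in", "cells", ".")
      pos <- c("NNP", "CC", "NNP", "VBP", "IN", "NNS", ".")
      dep <- c("nsubj", "cc", "conj", "root", "prep", "pobj", "punct")
      spans <- list(c(0L, 1L), c(2L, 3L))
    }
    if (multi_mention) {
      # repeat the second entity farther away; the far pairing is gold-NEG
      extra_surf <- c("in", "the", "presence", "of", b)
      extra_pos <- c("IN", "DT", "NN", "IN", "NNP")
      extra_dep <- c("prep", "det", "pobj", "prep", "pobj")
      k <- length(surf)
      surf <- c(surf[-k], extra_surf, ".")
      pos <- c(pos[-k], extra_pos, ".")
      dep <- c(dep[-k], extra_dep, "punct")
      spans[[3L]] <- c(length(surf) - 2L, length(surf) - 1L)
    }
    gold <- c(spans[[1]][1], spans[[2]][1])
  } else {
    gold <- NULL
    n1 <- sample(SYN_NOUNS1, 1L)
    v <- sample(SYN_VERBS, 1L)
    n2 <- sample(SYN_NOUNS2, 1L)
    if (style == 1L) {
      # "the <n1> of <A> <conn> <B> <post> <v> in <n2> ."
      ci <- sample.int(length(SYN_CONNS), 1L)
      pi <- sample.int(length(SYN_POSTS), 1L)
      surf <- c("the", n1, "of", a, SYN_CONNS[ci], b, SYN_POSTS[pi], v,
                "in", n2, ".")
      pos <- c("DT", "NN", "IN", "NNP", "CC", "NNP", SYN_POSTS_POS[pi],
               "VBN", "IN", "NNS", ".")
      dep <- c("det", "nsubj", "prep", "pobj", "cc", "conj", "aux", "root",
               "prep", "pobj", "punct")
      spans <- list(c(3L, 4L), c(5L, 6L))
    } else {
      # "<A> was <v> in <n2> expressing <B> ."
      surf <- c(a, "was", v, "in", n2, "expressing", b, ".")
      pos <- c("NNP", "VBD", "VBN", "IN", "NNS", "VBG", "NNP", ".")
      dep <- c("nsubj", "aux", "root", "prep", "pobj", "amod", "dobj", "punct")
      spans <- list(c(0L, 1L), c(6L, 7L))
    }
  }
  ents <- c(a, b, if (length(spans) == 3L) b)
  mentions <- data.frame(
    mention_id = paste0("m", seq_along(spans)),
    entity_type = "PROTEIN",
    start = vapply(spans, `[`, 0L, 1L),
    end = vapply(spans, `[`, 0L, 2L),
    kb_id = ents,
    stringsAsFactors = FALSE
  )
  list(tokens = syn_tokens(surf, pos, dep), mentions = mentions, gold = gold)
}

#' Generate a synthetic entity-annotated corpus
#'
#' Each sentence is instantiated from a closed template grammar about one
#' entity pair. Sentences about a truly related pair express the relation
#' with a planted trigger verb with probability
#' `1 - cooccurrence_fp_rate`, otherwise they merely co-occur; sentences
#' about unrelated pairs never express it. Gold relation labels are recorded
#' per mention pair in each sentence's `gold_pairs` field, independently of
#' any KB. With probability `multi_mention_rate` a relation sentence repeats
#' its second entity at a farther position (the far pairing is gold
#' negative).
#'
#' @param config A [generator_config()].
#' @param world From [generate_world()].
#' @param n_sentences Number of sentences (default `config$n_sentences`).
#' @param doc_prefix Document-id prefix.
#' @param seed Seed.
#' @return A `ds_corpus`.
#' @export
generate_corpus <- function(config = generator_config(),
                            world = generate_world(config),
                            n_sentences = config$n_sentences,
                            doc_prefix = "doc", seed = config$seed) {
  true_pairs <- do.call(rbind, strsplit(world$true_kb$pairs, "\r", fixed = TRUE))
  ents <- world$entities
  with_seed(mix_seed(seed, paste0("corpus-", doc_prefix)), {
    sentences <- vector("list", n_sentences)
    for (i in seq_len(n_sentences)) {
      related <- stats::runif(1) < config$related_rate
      if (related) {
        p <- true_pairs[sample.int(nrow(true_pairs), 1L), ]
      } else {
        repeat {
          p <- sample(ents, 2L)
          if (!kb_contains(world$true_kb, p[1], p[2])) break
        }
      }
      relational <- related && stats::runif(1) >= config$cooccurrence_fp_rate
      multi <- relational && stats::runif(1) < config$multi_mention_rate
      trig <- sample(config$trigger_inventory, 1L)
      style <- sample.int(2L, 1L)
      sp <- syn_sentence(p[1], p[2], relational, multi, trig, style)
      doc <- paste0(doc_prefix, sprintf("%04d", (i - 1L) %/% config$sentences_per_doc))
      gp <- if (!is.null(sp$gold)) {
        data.frame(start1 = sp$gold[1], start2 = sp$gold[2])
      } else data.frame(start1 = integer(), start2 = integer())
      sentences[[i]] <- sentence(doc, sprintf("s%05d", i), sp$tokens,
                                 sp$mentions, gold_pairs = gp)
    }
    as_corpus(sentences)
  })
}

#' Label candidate instances with their gold relation labels
#'
#' Simulates manual annotation: every candidate mention pair gets POS when
#' recorded in the sentence's `gold_pairs`, NEG otherwise; same-entity pairs
#' are REMOVED. Provenance tag is `GOLD`.
#'
#' @param corpus A `ds_corpus` with `gold_pairs` fields.
#' @return A `ds_instances` collection.
#' @export
gold_label_corpus <- function(corpus) {
  out <- list()
  for (sent in corpus) {
    for (cand in enumerate_candidates(sent)) {
      cand$label <- if (cand$e1$kb_id == cand$e2$kb_id) "REMOVED"
                    else if (isTRUE(cand$gold)) "POS" else "NEG"
      cand$provenance <- "GOLD"
      out[[length(out) + 1L]] <- cand
    }
  }
  as_instances(out)
}

#' Generate the full synthetic benchmark
#'
#' A DS corpus (to be labeled through the observed, incomplete KB), a
#' smaller gold-labeled MA corpus (one `ds_factor`-th the DS size, split
#' into documents for cross-validation or held-out splits), and a seeded
#' embedding table over the closed vocabulary.
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `ds_corpus`, `ma_corpus`, `ma_instances` (gold-labeled),
#'   `true_kb`, `observed_kb`, `embeddings`, `config`.
#' @export
generate_benchmark <- function(config = generator_config(), seed = config$seed) {
  world <- generate_world(config, seed)
  n_ma <- max(1L, as.integer(config$n_sentences / config$ds_factor))
  ds_corpus <- generate_corpus(config, world, config$n_sentences,
                               doc_prefix = "dsdoc", seed = seed)
  ma_corpus <- generate_corpus(config, world, n_ma,
                               doc_prefix = "madoc", seed = mix_seed(seed, "ma"))
  vocab <- sort(unique(c(
    unlist(lapply(ds_corpus, function(s) s$tokens$surface)),
    unlist(lapply(ma_corpus, function(s) s$tokens$surface)),
    world$entities, config$trigger_inventory,
    sub("s$", "", config$trigger_inventory)
  )))
  vecs <- with_seed(mix_seed(seed, "embeddings"), {
    m <- matrix(stats::runif(length(vocab) * config$word_dim, -0.5, 0.5),
                nrow = length(vocab))
    rownames(m) <- vocab
    m
  })
  list(
    ds_corpus = ds_corpus,
    ma_corpus = ma_corpus,
    ma_instances = gold_label_corpus(ma_corpus),
    true_kb = world$true_kb,
    observed_kb = world$observed_kb,
    embeddings = embedding_table(vecs, oov_seed = mix_seed(seed, "oov")),
    config = config
  )
}
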