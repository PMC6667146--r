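test_that("lemmatizer conflates inflected trigger variants", {
  expect_equal(lemmatize(c("binds", "binding", "bound", "bind")),
               rep("bind", 4))
  expect_equal(lemmatize(c("interacts", "interaction", "interactions")),
               rep("interact", 3))
  expect_equal(lemmatize(c("was", "is", "are")), rep("be", 3))
  # short words are not stripped into stumps
  expect_equal(lemmatize("as"), "as")
})

test_that("closest pair keeps only the nearest mention pair per entity pair", {
  kb <- relation_kb(rbind(c("bICP0", "IRF7")))
  insts <- label_corpus(list(bicp0_sentence()), kb)
  out <- closest_pair_filter(insts)
  labs <- vapply(out, `[[`, "", "label")
  kept <- out[labs == "POS"]
  expect_length(kept, 1L)
  # the survivor pairs bICP0 with the *first* IRF7 mention
  expect_equal(kept[[1]]$e2$start, 5L)
  cp_removed <- Filter(function(x) "CP" %in% x$provenance, out)
  expect_length(cp_removed, 1L)
  expect_equal(cp_removed[[1]]$label, "REMOVED")
  # groups of size one are untouched
  kb2 <- relation_kb(rbind(c("RFX5", "HDAC2")))
  one <- label_corpus(list(rfx5_sentence()), kb2)
  expect_identical(instance_stats(closest_pair_filter(one)),
                   instance_stats(one))
})

test_that("closest pair changes only the positive count on a synthetic corpus", {
  b <- tiny_benchmark(200, seed = 31)
  before <- instance_stats(b$ds_instances)
  after <- instance_stats(closest_pair_filter(b$ds_instances))
  expect_equal(after$neg, before$neg)
  expect_lte(after$pos, before$pos)
})

test_that("trigger mining ranks relation verbs first and rejects neutral lemmas", {
  pos_s <- lapply(1:3, function(i) make_sentence(
    "dp", paste0("s", i), c(paste0("A", i), "binds", paste0("B", i), "assay"),
    list(list(start = 0L, end = 1L, kb_id = paste0("A", i)),
         list(start = 2L, end = 3L, kb_id = paste0("B", i))),
    pos = c("NNP", "VBZ", "NNP", "NN")))
  neg_s <- lapply(1:3, function(i) make_sentence(
    "dn", paste0("s", i), c(paste0("C", i), "near", paste0("D", i), "assay"),
    list(list(start = 0L, end = 1L, kb_id = paste0("C", i)),
         list(start = 2L, end = 3L, kb_id = paste0("D", i))),
    pos = c("NNP", "IN", "NNP", "NN")))
  mk <- function(ss, lab) {
    as_inst <- lapply(ss, function(s) {
      x <- enumerate_candidates(s)[[1]]; x$label <- lab; x$provenance <- "DS"; x
    })
    dsre:::as_instances(as_inst)
  }
  lex <- mine_triggers(mk(pos_s, "POS"), mk(neg_s, "NEG"),
                       window = 2L, top_k = 20L)
  expect_equal(names(lex$entries)[1], "bind")
  expect_equal(unname(lex$entries["bind"]), log(4 / 1))
  # "assay" occurs equally in both sets -> score 0 -> never admitted
  expect_false("assay" %in% names(lex$entries))
  expect_error(mine_triggers(mk(list(), "POS"), mk(neg_s, "NEG")), "positive")
})

test_that("trigger filter keeps trigger-bearing positives and is idempotent", {
  # "Rpa43 directly bind Spt5": trigger inside the inter-entity region
  rpa <- make_sentence("d", "s",
                       c("Rpa43", "directly", "bind", "Spt5"),
                       list(list(start = 0L, end = 1L, kb_id = "Rpa43"),
                            list(start = 3L, end = 4L, kb_id = "Spt5")),
                       pos = c("NNP", "RB", "VBP", "NNP"))
  no_trig <- make_sentence("d", "s2", c("Foo", "and", "Bar", "here"),
                           list(list(start = 0L, end = 1L, kb_id = "Foo"),
                                list(start = 2L, end = 3L, kb_id = "Bar")),
                           pos = c("NNP", "CC", "NNP", "RB"))
  kb <- relation_kb(rbind(c("Rpa43", "Spt5"), c("Foo", "Bar")))
  insts <- label_corpus(list(rpa, no_trig), kb)
  lex <- structure(list(entries = c(bind = 1), window = 2L, top_k = 20L),
                   class = "trigger_lexicon")
  out <- trigger_filter(insts, lex)
  labs <- vapply(out, `[[`, "", "label")
  expect_equal(labs, c("POS", "REMOVED"))
  expect_identical(trigger_filter(out, lex), out)
})

test_that("trigger filter is idempotent on random synthetic corpora", {
  for (seed in c(3, 17)) {
    b <- tiny_benchmark(150, seed = seed)
    insts <- closest_pair_filter(b$ds_instances)
    labs <- vapply(insts, `[[`, "", "label")
    lex <- mine_triggers(insts[labs == "POS"], insts[labs == "NEG"])
    once <- trigger_filter(insts, lex)
    expect_identical(trigger_filter(once, lex), once)
    # negatives untouched
    expect_equal(instance_stats(once)$neg, instance_stats(insts)$neg)
  }
})

test_that("pattern extraction builds typed inter-entity templates", {
  kb <- relation_kb(rbind(c("AtGRIP", "AtARL1")))
  inst <- labeled_instance(atgrip_sentence(), kb)
  expect_equal(extract_pattern(inst), "ENTITY1 and ENTITY2 interact")
  # adjacent entities, tail reaches the next token
  adj <- make_sentence("d", "s", c("A", "B"),
                       list(list(start = 0L, end = 1L, kb_id = "A"),
                            list(start = 1L, end = 2L, kb_id = "B")))
  expect_equal(extract_pattern(labeled_instance(adj, relation_kb(rbind(c("A", "B"))))),
               "ENTITY1 ENTITY2")
  # a third same-type mention inside the span becomes ENTITY
  rfx <- labeled_instance(rfx5_sentence(), relation_kb(rbind(c("RFX5", "mSin3B"))), 2L)
  expect_equal(
    extract_pattern(rfx, max_len = 20L),
    paste("ENTITY1 specifically interacts with ENTITY ( hdac2 ) and the",
          "mammalian transcriptional repressor ( ENTITY2 )"))
  # inter-entity span longer than max_len -> no template
  far <- make_sentence("d", "s", c("A", rep("x", 40), "B"),
                       list(list(start = 0L, end = 1L, kb_id = "A"),
                            list(start = 41L, end = 42L, kb_id = "B")))
  expect_true(is.na(extract_pattern(labeled_instance(far, relation_kb(rbind(c("A", "B")))),
                                    max_len = 10L)))
})

test_that("pattern mining respects the support threshold exactly", {
  mk_inst <- function(n, a = "A", b = "B") {
    lapply(seq_len(n), function(i) {
      s <- make_sentence("d", paste0(a, b, i), c(a, "and", b, "interact", "."),
                         list(list(start = 0L, end = 1L, kb_id = paste0(a, i)),
                              list(start = 2L, end = 3L, kb_id = paste0(b, i))))
      x <- enumerate_candidates(s)[[1]]; x$label <- "POS"; x
    })
  }
  pos12 <- dsre:::as_instances(mk_inst(12))
  ps <- mine_patterns(pos12, min_support = 10L)
  expect_equal(ps$patterns[["ENTITY1 and ENTITY2 interact"]], 12L)
  ps9 <- mine_patterns(pos12[1:9], min_support = 10L)
  expect_length(ps9$patterns, 0L)
  expect_length(mine_patterns(dsre:::as_instances(list()))$patterns, 0L)
})

test_that("pattern filter removes matching negatives only", {
  kb <- relation_kb(rbind(c("X", "Y")))   # AtGRIP pair absent -> NEG
  neg <- labeled_instance(atgrip_sentence(), kb)
  expect_equal(neg$label, "NEG")
  long <- make_sentence("d", "s", c("A", rep("x", 20), "B"),
                        list(list(start = 0L, end = 1L, kb_id = "A"),
                             list(start = 21L, end = 22L, kb_id = "B")))
  neg2 <- labeled_instance(long, kb)
  ps <- structure(list(patterns = c("ENTITY1 and ENTITY2 interact" = 12L),
                       min_support = 10L, max_len = 10L, tail = 1L),
                  class = "pattern_set")
  out <- pattern_filter(dsre:::as_instances(list(neg, neg2)), ps)
  expect_equal(vapply(out, `[[`, "", "label"), c("REMOVED", "NEG"))
  expect_true("HP" %in% out[[1]]$provenance)
  # positives are never touched, |POS| preserved on a synthetic corpus
  b <- tiny_benchmark(150, seed = 41)
  labs <- vapply(b$ds_instances, `[[`, "", "label")
  pats <- mine_patterns(b$ds_instances[labs == "POS"], min_support = 5L)
  filt <- pattern_filter(b$ds_instances, pats)
  expect_equal(instance_stats(filt)$pos, instance_stats(b$ds_instances)$pos)
})

test_that("top-k entity filter ranks by frequency and keeps rank ties", {
  mk <- function(loc, n) lapply(seq_len(n), function(i) {
    s <- make_sentence("d", paste0(loc, i), c(paste0("P", loc, i), "in", loc),
                       list(list(start = 0L, end = 1L, kb_id = paste0("P", loc, i)),
                            list(start = 2L, end = 3L, kb_id = loc,
                                 type = "LOCATION")))
    x <- enumerate_candidates(s, c("PROTEIN", "LOCATION"))[[1]]
    x$label <- if (i %% 2) "POS" else "NEG"; x
  })
  insts <- dsre:::as_instances(c(mk("nucleus", 10), mk("cytosol", 5), mk("golgi", 1)))
  out <- top_entity_filter(insts, k = 2L, side = "e2")
  labs <- vapply(out, `[[`, "", "label")
  locs <- vapply(out, function(x) x$e2$kb_id, "")
  expect_true(all(labs[locs == "golgi"] == "REMOVED"))
  expect_true(all(labs[locs != "golgi"] != "REMOVED"))
  # k >= number of entities: nothing changes
  expect_identical(top_entity_filter(insts, k = 3L), insts)
  # tie at rank k: both tied entities survive
  tie <- dsre:::as_instances(c(mk("nucleus", 5), mk("cytosol", 5), mk("golgi", 1)))
  out_tie <- top_entity_filter(tie, k = 1L)
  locs_tie <- vapply(out_tie, function(x) x$e2$kb_id, "")
  labs_tie <- vapply(out_tie, `[[`, "", "label")
  expect_true(all(labs_tie[locs_tie %in% c("nucleus", "cytosol")] != "REMOVED"))
})

test_that("pipelines compose in order and only shrink the expected columns", {
  b <- tiny_benchmark(250, seed = 53)
  cfg <- ds_config(pattern_min_support = 5L)
  res <- apply_pipeline(b$ds_instances, c("cp", "hp"), cfg)
  # equals sequential manual application
  manual <- closest_pair_filter(b$ds_instances)
  labs <- vapply(manual, `[[`, "", "label")
  pats <- mine_patterns(manual[labs == "POS"], min_support = 5L)
  manual <- pattern_filter(manual, pats)
  expect_identical(res$instances, manual)
  # per-step stats: CP shrinks positives only, HP negatives only
  st <- res$stats
  expect_equal(st$neg[st$step == "cp"], st$neg[st$step == "input"])
  expect_lte(st$pos[st$step == "cp"], st$pos[st$step == "input"])
  expect_equal(st$pos[st$step == "hp"], st$pos[st$step == "cp"])
  expect_lte(st$neg[st$step == "hp"], st$neg[st$step == "cp"])
  # empty pipeline is the identity
  expect_identical(apply_pipeline(b$ds_instances, character())$instances,
                   b$ds_instances)
  # no POS<->NEG flips anywhere
  before <- vapply(b$ds_instances, `[[`, "", "label")
  after <- vapply(res$instances, `[[`, "", "label")
  changed <- before != after
  expect_true(all(after[changed] == "REMOVED"))
})
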