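# Hand-built sentences exercising the classic PPI phenomena: an entity
# mentioned twice (closest-pair), a trigger verb between entities, a
# recurring "X and Y interact" pattern, and a third entity in the sentence.

make_sentence <- function(doc_id, sent_id, surfaces, mentions,
                          pos = NULL, dep = NULL, gold_pairs = NULL) {
  n <- length(surfaces)
  tokens <- data.frame(
    surface = surfaces,
    pos = if (is.null(pos)) rep("NN", n) else pos,
    dep = if (is.null(dep)) rep("dep", n) else dep,
    stringsAsFactors = FALSE
  )
  men <- do.call(rbind, lapply(seq_along(mentions), function(i) {
    m <- mentions[[i]]
    data.frame(mention_id = paste0("m", i),
               entity_type = if (is.null(m$type)) "PROTEIN" else m$type,
               start = m$start, end = m$end, kb_id = m$kb_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(men)) men <- dsre:::empty_mentions()
  sentence(doc_id, sent_id, tokens, men, gold_pairs = gold_pairs)
}

# "The interaction between bICP0 and IRF7 correlates with reduced
#  trans-activation of the IFN-beta promoter by IRF7" -- IRF7 twice.
bicp0_sentence <- function() {
  make_sentence(
    "d-bicp0", "s1",
    c("The", "interaction", "between", "bICP0", "and", "IRF7", "correlates",
      "with", "reduced", "trans-activation", "of", "the", "IFN-beta",
      "promoter", "by", "IRF7"),
    mentions = list(list(start = 3L, end = 4L, kb_id = "bICP0"),
                    list(start = 5L, end = 6L, kb_id = "IRF7"),
                    list(start = 15L, end = 16L, kb_id = "IRF7")),
    pos = c("DT", "NN", "IN", "NNP", "CC", "NNP", "VBZ", "IN", "VBN", "NN",
            "IN", "DT", "NNP", "NN", "IN", "NNP")
  )
}

# "Among these ligands , MCP-3 had the remarkable property of binding CCR5
#  with high affinity without eliciting a functional response"
mcp3_sentence <- function() {
  make_sentence(
    "d-mcp3", "s1",
    c("Among", "these", "ligands", ",", "MCP-3", "had", "the", "remarkable",
      "property", "of", "binding", "CCR5", "with", "high", "affinity",
      "without", "eliciting", "a", "functional", "response"),
    mentions = list(list(start = 4L, end = 5L, kb_id = "MCP3"),
                    list(start = 11L, end = 12L, kb_id = "CCR5")),
    pos = c("IN", "DT", "NNS", ",", "NNP", "VBD", "DT", "JJ", "NN", "IN",
            "VBG", "NNP", "IN", "JJ", "NN", "IN", "VBG", "DT", "JJ", "NN")
  )
}

# "RFX5 specifically interacts with histone deacetylase 2 ( HDAC2 ) and the
#  mammalian transcriptional repressor ( mSin3B )" -- multi-token mention
# plus a third protein.
rfx5_sentence <- function() {
  make_sentence(
    "d-rfx5", "s1",
    c("RFX5", "specifically", "interacts", "with", "histone", "deacetylase",
      "2", "(", "HDAC2", ")", "and", "the", "mammalian", "transcriptional",
      "repressor", "(", "mSin3B", ")"),
    mentions = list(list(start = 0L, end = 1L, kb_id = "RFX5"),
                    list(start = 4L, end = 7L, kb_id = "HDAC2"),
                    list(start = 16L, end = 17L, kb_id = "mSin3B")),
    pos = c("NNP", "RB", "VBZ", "IN", "NN", "NN", "CD", "(", "NNP", ")",
            "CC", "DT", "JJ", "JJ", "NN", "(", "NNP", ")")
  )
}

# "This indicates that AtGRIP and AtARL1 interact directly ."
atgrip_sentence <- function() {
  make_sentence(
    "d-atgrip", "s1",
    c("This", "indicates", "that", "AtGRIP", "and", "AtARL1", "interact",
      "directly", "."),
    mentions = list(list(start = 3L, end = 4L, kb_id = "AtGRIP"),
                    list(start = 5L, end = 6L, kb_id = "AtARL1")),
    pos = c("DT", "VBZ", "IN", "NNP", "CC", "NNP", "VBP", "RB", ".")
  )
}

# instance for a specific mention pair of a sentence, labeled against a KB
labeled_instance <- function(sent, kb, which = 1L) {
  cands <- enumerate_candidates(sent, kb$type_signature)
  label_candidate(cands[[which]], kb)
}

# small deterministic embedding table over a vocabulary
toy_embeddings <- function(vocab, dim = 25L, seed = 42L) {
  v <- dsre:::with_seed(seed, matrix(stats::runif(length(vocab) * dim, -0.5, 0.5),
                                     nrow = length(vocab)))
  rownames(v) <- vocab
  embedding_table(v, oov_seed = seed)
}

# reduced configuration used for model unit tests (small and fast)
tiny_cfg <- function(...) {
  ds_config(word_dim = 25L, filters = 6L, hidden = 4L, max_len = 30L,
            batch_size = 16L, ...)
}

# small labeled synthetic world for training tests
tiny_benchmark <- function(n_sentences = 120L, seed = 7L, ...) {
  cfg <- generator_config(n_sentences = n_sentences, seed = seed, ...)
  bench <- generate_benchmark(cfg)
  bench$ds_instances <- label_corpus(bench$ds_corpus, bench$observed_kb)
  bench
}
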