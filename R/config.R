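#' Default configuration for featurization, models and training
#'
#' Central configuration object shared by the featurization, model and
#' training layers. Defaults follow the reference parameterization of the
#' pipeline: token feature channels of 200 (word) + 10 (POS) + 10 (dependency)
#' + 5 + 5 (signed distances to the two entities) + 4 (entity-role one-hot)
#' = 234 dimensions per token; sentences padded or pruned to 100 tokens;
#' 400 convolution filters of window 3 for the PCNN and a 400-unit hidden
#' state per direction for the BiLSTM; batch size 128; Adam at learning rate
#' 0.001 with exponential decay (rate 0.95 every 1000 steps) for the PCNN and
#' a constant rate for the BiLSTM; dropout 0.5 on the convolution/recurrent
#' features and 0.2 on the dense layer; 30 training epochs on distantly
#' supervised and mixed data, 200 (PCNN) or 100 (BiLSTM) on manually
#' annotated data and during fine-tuning.
#'
#' @param ... Named overrides of any default listed above, e.g.
#'   `ds_config(filters = 50, word_dim = 25)`.
#' @return A named list of class `ds_config`.
#' @export
#' @examples
#' cfg <- ds_config(filters = 50)
#' cfg$filters
ds_config <- function(...) {
  cfg <- list(
    # featurization
    word_dim = 200L,
    pos_dim = 10L,
    dep_dim = 10L,
    dist_dim = 5L,
    dist_clip = 50L,
    max_len = 100L,
    # models
    filters = 400L,
    window = 3L,
    hidden = 400L,
    bilstm_readout = "final",   # or "max" (max over time)
    conv_activation = "tanh",
    # training
    batch_size = 128L,
    lr = 0.001,
    decay_rate = 0.95,
    decay_steps = 1000L,
    dropout_feature = 0.5,
    dropout_dense = 0.2,
    epochs_ds = 30L,
    epochs_ma_pcnn = 200L,
    epochs_ma_bilstm = 100L,
    transfer_embeddings = TRUE, # categorical-channel tables travel with feature weights
    # noise-reduction heuristics
    trigger_window = 2L,
    trigger_top_k = 20L,
    pattern_min_support = 10L,
    pattern_max_len = 10L,
    pattern_tail = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown ds_config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(
    cfg$word_dim > 0, cfg$max_len > 0, cfg$filters > 0, cfg$hidden > 0,
    cfg$window >= 1, cfg$batch_size > 0, cfg$lr > 0,
    cfg$dropout_feature >= 0, cfg$dropout_feature < 1,
    cfg$dropout_dense >= 0, cfg$dropout_dense < 1
  )
  structure(cfg, class = "ds_config")
}

## Per-token feature width implied by a config (234 at defaults).
feature_dim <- function(cfg) {
  as.integer(cfg$word_dim + cfg$pos_dim + cfg$dep_dim + 2L * cfg$dist_dim + 4L)
}

#' @export
print.ds_config <- function(x, ...) {
  cat("dsre configuration\n")
  cat(sprintf("  token features : %d (word %d + pos %d + dep %d + 2x dist %d + role 4)\n",
              feature_dim(x), x$word_dim, x$pos_dim, x$dep_dim, x$dist_dim))
  cat(sprintf("  max sentence   : %d tokens\n", x$max_len))
  cat(sprintf("  PCNN           : %d filters, window %d\n", x$filters, x$window))
  cat(sprintf("  BiLSTM         : %d hidden/direction, readout %s\n", x$hidden, x$bilstm_readout))
  cat(sprintf("  training       : batch %d, lr %g, dropout %.1f/%.1f\n",
              x$batch_size, x$lr, x$dropout_feature, x$dropout_dense))
  invisible(x)
}
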