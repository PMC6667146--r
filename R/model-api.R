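## User-facing model object: a thin classed wrapper around the training
## loop, in the style of classic R model fits.

#' Fit a relation-extraction classifier
#'
#' Trains a PCNN or BiLSTM on labeled instances and returns a classed model
#' object supporting `print()`, `summary()`, `coef()` and `predict()`.
#'
#' @inheritParams train
#' @return An object of class `dsre_model`: list with `params`
#'   (`model_params`), `loss_history`, `n_rejected`, `emb`, `kind`,
#'   `n_train`.
#' @export
#' @examples
#' bench <- generate_benchmark(generator_config(n_sentences = 60, seed = 7))
#' insts <- label_corpus(bench$ds_corpus, bench$observed_kb)
#' cfg <- ds_config(word_dim = 25, filters = 8, max_len = 30)
#' fit <- train_model(insts, bench$embeddings, kind = "PCNN", cfg = cfg,
#'                    epochs = 1, seed = 1)
#' head(predict(fit, bench$ma_instances))
train_model <- function(instances, emb, kind = c("PCNN", "BILSTM"),
                        cfg = ds_config(), epochs = cfg$epochs_ds, seed = 1L,
                        init = NULL) {
  kind <- match.arg(kind)
  fit <- train(kind, instances, emb, cfg, epochs = epochs, seed = seed,
               init = init)
  structure(
    list(params = fit$params, loss_history = fit$loss_history,
         n_rejected = fit$n_rejected, emb = emb, kind = kind,
         n_train = length(active_instances(instances))),
    class = "dsre_model"
  )
}

#' @export
print.dsre_model <- function(x, ...) {
  cat(sprintf("dsre %s model: %d training instances, %d batches, final loss %.4f\n",
              x$kind, x$n_train, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.dsre_model <- function(object, ...) {
  cfg <- object$params$config
  cat(sprintf("dsre %s model\n", object$kind))
  cat(sprintf("  training instances : %d (%d rejected by pruning)\n",
              object$n_train, object$n_rejected))
  cat(sprintf("  feature width      : %d per token\n", feature_dim(cfg)))
  if (object$kind == "PCNN") {
    cat(sprintf("  filters            : %d (window %d), pooled width %d\n",
                cfg$filters, cfg$window, 3L * cfg$filters))
  } else {
    cat(sprintf("  hidden units       : %d per direction\n", cfg$hidden))
  }
  cat(sprintf("  loss               : %.4f -> %.4f over %d batches\n",
              object$loss_history[1], utils::tail(object$loss_history, 1),
              length(object$loss_history)))
  invisible(object)
}

#' @export
coef.dsre_model <- function(object, ...) {
  get_flat(object$params)
}

#' Predict relation labels with a fitted model
#'
#' @param object A `dsre_model`.
#' @param newdata A `ds_instances` collection.
#' @param ... Unused.
#' @return data.frame with `prob_positive` and `predicted` per instance (see
#'   [predict_instances()]).
#' @export
predict.dsre_model <- function(object, newdata, ...) {
  predict_instances(object$params, newdata, object$emb)
}
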