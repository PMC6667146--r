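## Training and evaluation.
##
## Mini-batch Adam training of PCNN/BiLSTM classifiers over index-level
## feature representations (word vectors fixed, categorical-channel tables
## learned), binary cross-entropy loss on the 2-class softmax. The PCNN
## learning rate decays exponentially (rate `decay_rate` every `decay_steps`
## batches); the BiLSTM uses a constant rate. REMOVED instances never enter
## training or evaluation.

## ---- flat parameter views -------------------------------------------------

get_flat <- function(params) {
  tb <- params$feature$tables
  common <- list(Wo = params$classifier$Wo, bo = params$classifier$bo,
                 pos = tb$pos, dep = tb$dep, d1 = tb$d1, d2 = tb$d2)
  if (params$kind == "PCNN") {
    c(list(Wc = params$feature$Wc, bc = params$feature$bc), common)
  } else {
    c(list(fWx = params$feature$fwd$Wx, fWh = params$feature$fwd$Wh,
           fb = params$feature$fwd$b,
           bWx = params$feature$bwd$Wx, bWh = params$feature$bwd$Wh,
           bb = params$feature$bwd$b), common)
  }
}

set_flat <- function(params, flat) {
  params$classifier$Wo <- flat$Wo
  params$classifier$bo <- flat$bo
  params$feature$tables$pos[] <- flat$pos
  params$feature$tables$dep[] <- flat$dep
  params$feature$tables$d1[] <- flat$d1
  params$feature$tables$d2[] <- flat$d2
  if (params$kind == "PCNN") {
    params$feature$Wc <- flat$Wc
    params$feature$bc <- flat$bc
  } else {
    params$feature$fwd$Wx <- flat$fWx; params$feature$fwd$Wh <- flat$fWh
    params$feature$fwd$b <- flat$fb
    params$feature$bwd$Wx <- flat$bWx; params$feature$bwd$Wh <- flat$bWh
    params$feature$bwd$b <- flat$bb
  }
  params
}

zero_like <- function(flat) lapply(flat, function(x) x * 0)

## Gradient of one instance, as a flat list (table gradients full-size).
instance_grad <- function(params, feat, y, training = TRUE) {
  cfg <- params$config
  tb <- params$feature$tables
  X <- compose_matrix(feat, tb)
  tl <- feat$tl
  if (params$kind == "PCNN") {
    masks <- list(
      feat = if (training) dropout_mask(tl * cfg$filters, cfg$dropout_feature,
                                        dim = c(tl, cfg$filters)) else NULL,
      dense = if (training) dropout_mask(3L * cfg$filters, cfg$dropout_dense)
              else NULL
    )
    h <- pcnn_head(X, feat$segments, params, masks$feat, masks$dense)
    g <- pcnn_backward(h, X, params, y)
    flat <- list(Wc = g$Wc, bc = g$bc, Wo = g$Wo, bo = g$bo)
  } else {
    H <- cfg$hidden
    masks <- list(
      feat = if (training && cfg$dropout_feature > 0) list(
        fwd = dropout_mask(tl * H, cfg$dropout_feature, dim = c(tl, H)),
        bwd = dropout_mask(tl * H, cfg$dropout_feature, dim = c(tl, H))
      ) else NULL,
      dense = if (training) dropout_mask(2L * H, cfg$dropout_dense) else NULL
    )
    h <- bilstm_head(X, params, masks$feat, masks$dense)
    g <- bilstm_backward(h, X, params, y)
    flat <- list(fWx = g$fwd$Wx, fWh = g$fwd$Wh, fb = g$fwd$b,
                 bWx = g$bwd$Wx, bWh = g$bwd$Wh, bb = g$bwd$b,
                 Wo = g$Wo, bo = g$bo)
  }
  # scatter dX columns back into the categorical tables
  dw <- cfg$word_dim
  col0 <- dw
  scatter <- function(tab, ids, cols) {
    gz <- tab * 0
    rs <- rowsum(g$dX[, cols, drop = FALSE], group = ids)
    gz[as.integer(rownames(rs)), ] <- rs
    gz
  }
  flat$pos <- scatter(tb$pos, feat$pos_ids, (col0 + 1L):(col0 + cfg$pos_dim))
  col0 <- col0 + cfg$pos_dim
  flat$dep <- scatter(tb$dep, feat$dep_ids, (col0 + 1L):(col0 + cfg$dep_dim))
  col0 <- col0 + cfg$dep_dim
  flat$d1 <- scatter(tb$d1, feat$d1_ids, (col0 + 1L):(col0 + cfg$dist_dim))
  col0 <- col0 + cfg$dist_dim
  flat$d2 <- scatter(tb$d2, feat$d2_ids, (col0 + 1L):(col0 + cfg$dist_dim))
  list(grad = flat, loss = -log(max(h$probs[y], 1e-12)))
}

## ---- training -------------------------------------------------------------

derive_inventories <- function(instances) {
  pos <- sort(unique(unlist(lapply(instances, function(i) i$sentence$tokens$pos))))
  dep <- sort(unique(unlist(lapply(instances, function(i) i$sentence$tokens$dep))))
  list(pos_tags = pos, dep_labels = dep)
}

#' Train a PCNN or BiLSTM classifier
#'
#' Mini-batch Adam training for `epochs` epochs from `init` (or a fresh
#' seeded initialization). REMOVED instances are excluded; instances whose
#' mentions fall beyond `max_len` are counted and skipped. One loss value is
#' recorded per mini-batch.
#'
#' @param kind `"PCNN"` or `"BILSTM"`.
#' @param instances Labeled `ds_instances` with both POS and NEG present.
#' @param emb An `embedding_table` matching `cfg$word_dim`.
#' @param cfg A [ds_config()].
#' @param epochs Training epochs (default: `cfg$epochs_ds`).
#' @param seed Seed driving initialization, shuffling and dropout.
#' @param init Optional starting `model_params` (e.g. from
#'   [transfer_params()]).
#' @return List with `params` (trained `model_params`), `loss_history`
#'   (numeric, one entry per batch) and `n_rejected`.
#' @export
train <- function(kind = c("PCNN", "BILSTM"), instances, emb,
                  cfg = ds_config(), epochs = cfg$epochs_ds, seed = 1L,
                  init = NULL) {
  kind <- match.arg(kind)
  act <- active_instances(instances)
  if (!length(act)) stop("no trainable instances")
  labels <- instance_labels(act)
  if (length(unique(labels)) < 2L) {
    stop("training requires both POS and NEG instances")
  }
  if (is.null(init)) {
    inv <- derive_inventories(act)
    params <- init_params(kind, cfg, inv$pos_tags, inv$dep_labels, seed)
  } else {
    check_transfer_compat(init, kind)
    params <- init
    cfg <- params$config
  }
  # index-level features, computed once (word vectors fixed; table row ids
  # stay valid because inventories do not change during training)
  feats <- list(); ys <- integer(); rejected <- 0L
  for (inst in act) {
    f <- tryCatch(instance_features(inst, emb, params$feature$tables, cfg),
                  dsre_prune_error = function(cond) NULL)
    if (is.null(f)) { rejected <- rejected + 1L; next }
    feats[[length(feats) + 1L]] <- f
    ys <- c(ys, if (inst$label == "POS") 1L else 2L)
  }
  n <- length(feats)
  if (!n) stop("all instances rejected by max_len pruning")
  flat <- get_flat(params)
  m <- zero_like(flat); v <- zero_like(flat)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  losses <- numeric()
  with_seed(mix_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      bstarts <- seq(1L, n, by = cfg$batch_size)
      for (bs in bstarts) {
        batch <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
        gacc <- zero_like(flat)
        bloss <- 0
        params <- set_flat(params, flat)
        for (i in batch) {
          r <- instance_grad(params, feats[[i]], ys[i])
          for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] + r$grad[[nm]]
          bloss <- bloss + r$loss
        }
        nb <- length(batch)
        step <- step + 1L
        lr <- if (kind == "PCNN") {
          cfg$lr * cfg$decay_rate^((step - 1L) %/% cfg$decay_steps)
        } else cfg$lr
        for (nm in names(flat)) {
          g <- gacc[[nm]] / nb
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g * g
          mhat <- m[[nm]] / (1 - beta1^step)
          vhat <- v[[nm]] / (1 - beta2^step)
          flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        losses <- c(losses, bloss / nb)
      }
    }
  })
  params <- set_flat(params, flat)
  list(params = params, loss_history = losses, n_rejected = rejected)
}

## Evaluation-mode predictions for a feature list under given params.
predict_feats <- function(params, feats) {
  fwd <- if (params$kind == "PCNN") {
    function(X, f) pcnn_head(X, f$segments, params)$probs
  } else {
    function(X, f) bilstm_head(X, params)$probs
  }
  t(vapply(feats, function(f) {
    X <- compose_matrix(f, params$feature$tables)
    fwd(X, f)
  }, numeric(2)))
}

#' Predict labels for instances
#'
#' Deterministic evaluation-mode forward passes; ties at probability 0.5
#' predict negative.
#'
#' @param params Trained `model_params`.
#' @param instances `ds_instances` (REMOVED instances are skipped).
#' @param emb The `embedding_table` used in training.
#' @return data.frame with `doc_id`, `sent_id`, `label` (instance label),
#'   `prob_positive`, `predicted`.
#' @export
predict_instances <- function(params, instances, emb) {
  act <- active_instances(instances)
  cfg <- params$config
  feats <- list(); keep <- logical(length(act))
  for (i in seq_along(act)) {
    f <- tryCatch(instance_features(act[[i]], emb, params$feature$tables, cfg),
                  dsre_prune_error = function(cond) NULL)
    if (!is.null(f)) { feats[[length(feats) + 1L]] <- f; keep[i] <- TRUE }
  }
  act <- act[keep]
  if (!length(act)) {
    return(data.frame(doc_id = character(), sent_id = character(),
                      label = character(), prob_positive = numeric(),
                      predicted = character(), stringsAsFactors = FALSE))
  }
  probs <- predict_feats(params, feats)
  data.frame(
    doc_id = vapply(act, function(i) i$sentence$doc_id, ""),
    sent_id = vapply(act, function(i) i$sentence$sent_id, ""),
    label = instance_labels(act),
    prob_positive = probs[, 1],
    predicted = ifelse(probs[, 1] > probs[, 2], "POS", "NEG"),
    stringsAsFactors = FALSE
  )
}

## ---- evaluation -----------------------------------------------------------

new_eval_report <- function(tp, fp, fn, tn, folds = NULL) {
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 folds = folds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("P=%.1f R=%.1f F1=%.1f  (tp=%d fp=%d fn=%d tn=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Evaluate a model on labeled instances
#'
#' Confusion counts over POS/NEG instances only; precision, recall and F1
#' reported as percentages (0 when a denominator is 0).
#'
#' @inheritParams predict_instances
#' @return An `eval_report` with fields `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate <- function(params, instances, emb) {
  pred <- predict_instances(params, instances, emb)
  confusion_report(pred$label, pred$predicted)
}

confusion_report <- function(label, predicted) {
  new_eval_report(
    tp = sum(label == "POS" & predicted == "POS"),
    fp = sum(label == "NEG" & predicted == "POS"),
    fn = sum(label == "POS" & predicted == "NEG"),
    tn = sum(label == "NEG" & predicted == "NEG")
  )
}

## ---- cross-validation and regimes ----------------------------------------

instance_docs <- function(instances) {
  vapply(instances, function(i) i$sentence$doc_id, "")
}

## Seeded partition of document ids into k folds.
make_folds <- function(docs, k, seed) {
  u <- sort(unique(docs))
  if (length(u) < k) stop("fewer documents (", length(u), ") than folds (", k, ")")
  ord <- with_seed(mix_seed(seed, "folds"), sample(u))
  split(ord, rep_len(seq_len(k), length(ord)))
}

#' k-fold cross-validation grouped by document
#'
#' Documents (not instances) are partitioned into k folds by a seeded
#' shuffle, so no document's instances ever straddle train and test within a
#' fold. Confusion counts are pooled (micro-aggregated) across folds. When
#' `pretrain` is given, each fold fine-tunes from that same checkpoint via
#' [transfer_params()] instead of a fresh initialization.
#'
#' @inheritParams train
#' @param k Number of folds (default 10).
#' @param grouping `"document"` (default) or `"instance"`.
#' @param pretrain Optional pretrained `model_params`.
#' @param tl_mode Transfer mode used with `pretrain`.
#' @return An `eval_report` with a `folds` field (per-fold data.frame).
#' @export
cross_validate <- function(kind, instances, emb, cfg = ds_config(), k = 10L,
                           grouping = c("document", "instance"),
                           epochs = cfg$epochs_ds, seed = 1L,
                           pretrain = NULL, tl_mode = "ALL") {
  grouping <- match.arg(grouping)
  act <- active_instances(instances)
  groups <- if (grouping == "document") instance_docs(act)
            else as.character(seq_along(act))
  folds <- make_folds(groups, k, seed)
  tp <- fp <- fn <- tn <- 0L
  fold_rows <- list()
  for (fi in seq_along(folds)) {
    test_docs <- folds[[fi]]
    in_test <- groups %in% test_docs
    init <- if (!is.null(pretrain)) {
      transfer_params(pretrain, mode = tl_mode, seed = mix_seed(seed, paste0("fold", fi)))
    } else NULL
    fit <- train(kind, act[!in_test], emb, cfg, epochs = epochs,
                 seed = mix_seed(seed, paste0("fold-train", fi)), init = init)
    rep_f <- evaluate(fit$params, act[in_test], emb)
    tp <- tp + rep_f$tp; fp <- fp + rep_f$fp
    fn <- fn + rep_f$fn; tn <- tn + rep_f$tn
    fold_rows[[fi]] <- data.frame(fold = fi, tp = rep_f$tp, fp = rep_f$fp,
                                  fn = rep_f$fn, tn = rep_f$tn,
                                  f1 = rep_f$f1)
  }
  new_eval_report(tp, fp, fn, tn, folds = do.call(rbind, fold_rows))
}

## Split MA instances into train/test portions of an evaluation spec.
split_eval <- function(ma_instances, eval_spec, seed) {
  act <- active_instances(ma_instances)
  docs <- instance_docs(act)
  if (identical(eval_spec$type, "split")) {
    if (!is.null(eval_spec$test_docs)) {
      test_docs <- eval_spec$test_docs
    } else {
      frac <- if (is.null(eval_spec$test_fraction)) 0.3 else eval_spec$test_fraction
      u <- sort(unique(docs))
      ord <- with_seed(mix_seed(seed, "eval-split"), sample(u))
      test_docs <- ord[seq_len(max(1L, round(frac * length(u))))]
    }
    list(train = act[!(docs %in% test_docs)], test = act[docs %in% test_docs])
  } else stop("eval spec must be type 'split' here")
}

#' Run a training regime
#'
#' The four data-combination regimes:
#' \describe{
#'   \item{DS_ONLY}{train on the DS instances, evaluate on the MA evaluation
#'     portion.}
#'   \item{MA_ONLY}{train and evaluate on MA data only.}
#'   \item{MIX}{train on the multiset union of DS and MA-train instances
#'     (DS-epoch budget).}
#'   \item{TL}{pretrain on DS (DS-epoch budget), transfer with `tl_mode`,
#'     fine-tune on MA-train (MA-epoch budget).}
#' }
#' `eval_spec` is either `list(type = "cv", k = 10)` (document-grouped
#' cross-validation over the MA set; DS_ONLY then evaluates on all MA
#' instances) or `list(type = "split", test_fraction = 0.3)` /
#' `list(type = "split", test_docs = c(...))` (fixed held-out document
#' split).
#'
#' @inheritParams train
#' @param regime One of `"DS_ONLY"`, `"MA_ONLY"`, `"MIX"`, `"TL"`.
#' @param ds_instances,ma_instances Labeled instance collections.
#' @param eval_spec Evaluation specification (see Details).
#' @param tl_mode `"ALL"` or `"FEATURES_ONLY"` (TL regime).
#' @param epochs_ds,epochs_ma Epoch budgets for the DS/mixed and MA/fine-tune
#'   phases.
#' @return An `eval_report`.
#' @export
run_regime <- function(regime = c("DS_ONLY", "MA_ONLY", "MIX", "TL"),
                       kind = c("PCNN", "BILSTM"),
                       ds_instances, ma_instances, eval_spec, emb,
                       cfg = ds_config(), tl_mode = "ALL", seed = 1L,
                       epochs_ds = cfg$epochs_ds,
                       epochs_ma = if (match.arg(kind) == "PCNN")
                         cfg$epochs_ma_pcnn else cfg$epochs_ma_bilstm) {
  regime <- match.arg(regime)
  kind <- match.arg(kind)
  if (regime == "TL" && !length(active_instances(ds_instances))) {
    warning("TL with empty DS data reduces to MA_ONLY")
    regime <- "MA_ONLY"
  }
  if (identical(eval_spec$type, "cv")) {
    k <- if (is.null(eval_spec$k)) 10L else eval_spec$k
    return(switch(
      regime,
      DS_ONLY = {
        fit <- train(kind, ds_instances, emb, cfg, epochs = epochs_ds, seed = seed)
        evaluate(fit$params, ma_instances, emb)
      },
      MA_ONLY = cross_validate(kind, ma_instances, emb, cfg, k = k,
                               epochs = epochs_ma, seed = seed),
      MIX = stop("MIX regime requires a split eval_spec (union train set)"),
      TL = {
        pre <- train(kind, ds_instances, emb, cfg, epochs = epochs_ds, seed = seed)
        cross_validate(kind, ma_instances, emb, cfg, k = k, epochs = epochs_ma,
                       seed = seed, pretrain = pre$params, tl_mode = tl_mode)
      }
    ))
  }
  sp <- split_eval(ma_instances, eval_spec, seed)
  switch(
    regime,
    DS_ONLY = {
      fit <- train(kind, ds_instances, emb, cfg, epochs = epochs_ds, seed = seed)
      evaluate(fit$params, sp$test, emb)
    },
    MA_ONLY = {
      fit <- train(kind, sp$train, emb, cfg, epochs = epochs_ma, seed = seed)
      evaluate(fit$params, sp$test, emb)
    },
    MIX = {
      mix <- as_instances(c(unclass(active_instances(ds_instances)),
                            unclass(sp$train)))
      fit <- train(kind, mix, emb, cfg, epochs = epochs_ds, seed = seed)
      evaluate(fit$params, sp$test, emb)
    },
    TL = {
      pre <- train(kind, ds_instances, emb, cfg, epochs = epochs_ds, seed = seed)
      init <- transfer_params(pre$params, mode = tl_mode,
                              seed = mix_seed(seed, "tl-clf"))
      fit <- train(kind, sp$train, emb, cfg, epochs = epochs_ma, seed = seed,
                   init = init)
      evaluate(fit$params, sp$test, emb)
    }
  )
}

#' Learning curve over the size of the manually annotated set
#'
#' For each fraction, the MA training documents are subsampled by a seeded
#' draw (nested across fractions: the 25% documents are a subset of the 50%
#' documents, and so on, for variance reduction); the held-out test portion
#' is untouched. Reports MA-only and transfer-learning performance at each
#' fraction, plus a DS-only reference.
#'
#' @inheritParams run_regime
#' @param fractions Fractions of MA training documents to use.
#' @return data.frame with columns `fraction`, `regime`, `precision`,
#'   `recall`, `f1`.
#' @export
learning_curve <- function(kind = c("PCNN", "BILSTM"), ds_instances,
                           ma_instances, eval_spec, emb, cfg = ds_config(),
                           fractions = c(0.25, 0.5, 0.75, 1.0),
                           tl_mode = "ALL", seed = 1L,
                           epochs_ds = cfg$epochs_ds,
                           epochs_ma = if (match.arg(kind) == "PCNN")
                             cfg$epochs_ma_pcnn else cfg$epochs_ma_bilstm) {
  kind <- match.arg(kind)
  sp <- split_eval(ma_instances, eval_spec, seed)
  train_docs <- sort(unique(instance_docs(sp$train)))
  ord <- with_seed(mix_seed(seed, "curve"), sample(train_docs))
  pre <- train(kind, ds_instances, emb, cfg, epochs = epochs_ds, seed = seed)
  ds_report <- evaluate(pre$params, sp$test, emb)
  rows <- list(data.frame(fraction = NA_real_, regime = "DS_ONLY",
                          precision = ds_report$precision,
                          recall = ds_report$recall, f1 = ds_report$f1))
  for (fr in sort(fractions)) {
    ndoc <- max(1L, ceiling(fr * length(ord)))
    sub_docs <- ord[seq_len(ndoc)]
    sub <- sp$train[instance_docs(sp$train) %in% sub_docs]
    fit_ma <- train(kind, sub, emb, cfg, epochs = epochs_ma, seed = seed)
    rep_ma <- evaluate(fit_ma$params, sp$test, emb)
    init <- transfer_params(pre$params, mode = tl_mode,
                            seed = mix_seed(seed, "tl-clf"))
    fit_tl <- train(kind, sub, emb, cfg, epochs = epochs_ma, seed = seed,
                    init = init)
    rep_tl <- evaluate(fit_tl$params, sp$test, emb)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = rep(fr, 2), regime = c("MA_ONLY", "TL"),
      precision = c(rep_ma$precision, rep_tl$precision),
      recall = c(rep_ma$recall, rep_tl$recall),
      f1 = c(rep_ma$f1, rep_tl$f1))
  }
  do.call(rbind, rows)
}
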