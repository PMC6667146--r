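test_that("loss history length follows the batch arithmetic", {
  b <- tiny_benchmark(30, seed = 3)
  cfg <- tiny_cfg(batch_size = 128L)
  act <- dsre:::active_instances(b$ds_instances)
  n <- length(act)
  fit <- train("PCNN", b$ds_instances, b$embeddings, cfg, epochs = 1L, seed = 1L)
  expect_length(fit$loss_history, ceiling(n / 128))
  fit3 <- train("PCNN", b$ds_instances, b$embeddings, cfg, epochs = 3L, seed = 1L)
  expect_length(fit3$loss_history, 3L * ceiling(n / 128))
})

test_that("training errors on single-class data and learns separable data", {
  b <- tiny_benchmark(120, seed = 9)
  labs <- vapply(b$ds_instances, `[[`, "", "label")
  only_pos <- b$ds_instances[labs == "POS"]
  expect_error(train("PCNN", only_pos, b$embeddings, tiny_cfg()),
               "both POS and NEG")
  # noise-free world: DS labels are gold, templates are separable
  clean <- tiny_benchmark(120, seed = 9, cooccurrence_fp_rate = 0,
                          kb_incompleteness_rate = 0)
  cfg <- tiny_cfg(filters = 16L)
  fit <- train("PCNN", clean$ds_instances, clean$embeddings, cfg,
               epochs = 20L, seed = 4L)
  nb <- length(fit$loss_history) / 20L
  early <- mean(fit$loss_history[seq_len(nb)])
  late <- mean(fit$loss_history[(length(fit$loss_history) - nb + 1):length(fit$loss_history)])
  expect_lt(late, early)
})

test_that("training is reproducible and honors a transferred start", {
  b <- tiny_benchmark(40, seed = 5)
  cfg <- tiny_cfg()
  f1 <- train("PCNN", b$ds_instances, b$embeddings, cfg, epochs = 2L, seed = 7L)
  f2 <- train("PCNN", b$ds_instances, b$embeddings, cfg, epochs = 2L, seed = 7L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_history, f2$loss_history)
  # init = transfer(ALL): parameters at step 0 equal the source, so a
  # 0-epoch "fine-tune" is the source itself
  src <- f1$params
  init <- transfer_params(src, "ALL", seed = 1L)
  fit0 <- train("PCNN", b$ds_instances, b$embeddings, cfg, epochs = 0L,
                seed = 1L, init = init)
  expect_equal(fit0$params$feature, src$feature)
  expect_equal(fit0$params$classifier, src$classifier)
})

test_that("evaluation reports follow the closed-form P/R/F1 definitions", {
  r <- dsre:::new_eval_report(tp = 1L, fp = 1L, fn = 1L, tn = 0L)
  expect_equal(r$precision, 50)
  expect_equal(r$recall, 50)
  expect_equal(r$f1, 50)
  # degenerate denominators are defined as 0
  r0 <- dsre:::new_eval_report(tp = 0L, fp = 0L, fn = 0L, tn = 5L)
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
  # perfect predictions
  rp <- dsre:::confusion_report(c("POS", "NEG"), c("POS", "NEG"))
  expect_equal(c(rp$precision, rp$recall, rp$f1), c(100, 100, 100))
  # random predictions: counts match an independent tabulation
  set.seed(77)
  lab <- sample(c("POS", "NEG"), 200, replace = TRUE)
  prd <- sample(c("POS", "NEG"), 200, replace = TRUE)
  r2 <- dsre:::confusion_report(lab, prd)
  tab <- table(lab, prd)
  expect_equal(r2$tp, unname(tab["POS", "POS"]))
  expect_equal(r2$fp, unname(tab["NEG", "POS"]))
  expect_equal(r2$fn, unname(tab["POS", "NEG"]))
  expect_equal(r2$tn, unname(tab["NEG", "NEG"]))
  expect_equal(r2$tp + r2$fp + r2$fn + r2$tn, 200L)
})

test_that("document-grouped cross-validation partitions without leakage", {
  b <- tiny_benchmark(60, seed = 23)   # 12 documents
  cfg <- tiny_cfg(filters = 4L)
  folds <- dsre:::make_folds(dsre:::instance_docs(
    dsre:::active_instances(b$ds_instances)), k = 4L, seed = 2L)
  expect_length(unlist(folds), 12L)
  expect_false(anyDuplicated(unlist(folds)) > 0)
  # fewer documents than folds errors
  expect_error(dsre:::make_folds(c("a", "b"), k = 3L, seed = 1L), "fewer documents")
  rep_cv <- cross_validate("PCNN", b$ds_instances, b$embeddings, cfg,
                           k = 4L, epochs = 1L, seed = 2L)
  act <- dsre:::active_instances(b$ds_instances)
  expect_equal(rep_cv$tp + rep_cv$fp + rep_cv$fn + rep_cv$tn, length(act))
  expect_equal(nrow(rep_cv$folds), 4L)
})

test_that("regimes compose the training sets they promise", {
  b <- tiny_benchmark(80, seed = 37)
  cfg <- tiny_cfg(filters = 4L)
  spec <- list(type = "split", test_fraction = 0.3)
  # TL with empty DS degrades to MA-only with a warning
  empty <- dsre:::as_instances(list())
  expect_warning(
    r <- run_regime("TL", "PCNN", empty, b$ma_instances, spec, b$embeddings,
                    cfg, seed = 1L, epochs_ds = 1L, epochs_ma = 1L),
    "reduces to MA_ONLY")
  expect_s3_class(r, "eval_report")
  # MIX trains on |DS| + |MA_train| instances: check via batch arithmetic
  sp <- dsre:::split_eval(b$ma_instances, spec, seed = 1L)
  n_mix <- length(dsre:::active_instances(b$ds_instances)) + length(sp$train)
  cfg1 <- tiny_cfg(filters = 4L, batch_size = 1000L)
  mix_fit <- train("PCNN", dsre:::as_instances(
    c(unclass(dsre:::active_instances(b$ds_instances)), unclass(sp$train))),
    b$embeddings, cfg1, epochs = 1L, seed = 1L)
  expect_length(mix_fit$loss_history, ceiling(n_mix / 1000))
  r_mix <- run_regime("MIX", "PCNN", b$ds_instances, b$ma_instances, spec,
                      b$embeddings, cfg1, seed = 1L, epochs_ds = 1L)
  expect_s3_class(r_mix, "eval_report")
})

test_that("learning-curve subsampling is nested and hits full size at 1.0", {
  b <- tiny_benchmark(80, seed = 41)
  spec <- list(type = "split", test_fraction = 0.3)
  sp <- dsre:::split_eval(b$ma_instances, spec, seed = 3L)
  train_docs <- sort(unique(dsre:::instance_docs(sp$train)))
  ord <- dsre:::with_seed(dsre:::mix_seed(3L, "curve"), sample(train_docs))
  d25 <- ord[seq_len(ceiling(0.25 * length(ord)))]
  d50 <- ord[seq_len(ceiling(0.50 * length(ord)))]
  expect_true(all(d25 %in% d50))
  cfg <- tiny_cfg(filters = 4L)
  lc <- learning_curve("PCNN", b$ds_instances, b$ma_instances, spec,
                       b$embeddings, cfg, fractions = c(0.5, 1.0),
                       seed = 3L, epochs_ds = 1L, epochs_ma = 2L)
  expect_setequal(lc$regime, c("DS_ONLY", "MA_ONLY", "TL"))
  # fraction 1.0 rows reproduce the plain regimes at the same seed
  r_ma <- run_regime("MA_ONLY", "PCNN", b$ds_instances, b$ma_instances, spec,
                     b$embeddings, cfg, seed = 3L, epochs_ma = 2L)
  expect_equal(lc$f1[lc$regime == "MA_ONLY" & lc$fraction == 1.0], r_ma$f1)
  r_tl <- run_regime("TL", "PCNN", b$ds_instances, b$ma_instances, spec,
                     b$embeddings, cfg, tl_mode = "ALL", seed = 3L,
                     epochs_ds = 1L, epochs_ma = 2L)
  expect_equal(lc$f1[lc$regime == "TL" & lc$fraction == 1.0], r_tl$f1)
})

test_that("the fitted-model object exposes the usual S3 surface", {
  b <- tiny_benchmark(40, seed = 55)
  cfg <- tiny_cfg(filters = 4L)
  fit <- train_model(b$ds_instances, b$embeddings, "PCNN", cfg,
                     epochs = 1L, seed = 1L)
  expect_s3_class(fit, "dsre_model")
  expect_output(print(fit), "PCNN")
  expect_output(summary(fit), "filters")
  expect_true(all(c("Wc", "Wo", "pos") %in% names(coef(fit))))
  pred <- predict(fit, b$ma_instances)
  expect_true(all(pred$predicted %in% c("POS", "NEG")))
  expect_true(all(pred$prob_positive >= 0 & pred$prob_positive <= 1))
})
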