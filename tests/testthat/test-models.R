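seg3 <- function(a, b, c, d) {
  matrix(c(a, b, b, c, c, d), nrow = 3, byrow = TRUE)
}

test_that("piecewise max pooling takes per-segment maxima", {
  fm <- matrix(c(1, 5, 2, 7, 3), ncol = 1)
  expect_equal(piecewise_max_pool(fm, seg3(0L, 3L, 4L, 5L)), c(5, 7, 3))
  # empty first/last segments contribute zeros
  expect_equal(piecewise_max_pool(fm, seg3(0L, 0L, 5L, 5L)), c(0, 7, 0))
  # degenerates to whole-sequence pooling when part 1 covers everything
  fm2 <- matrix(rnorm(40), ncol = 4)
  whole <- piecewise_max_pool(fm2, seg3(0L, 10L, 10L, 10L))
  expect_equal(whole[1:4], apply(fm2, 2, max))
  expect_equal(whole[5:12], rep(0, 8))
  expect_error(piecewise_max_pool(fm, seg3(0L, 3L, 4L, 9L)), "segment")
})

test_that("piecewise pooling matches a brute-force oracle on random maps", {
  set.seed(123)
  for (i in 1:100) {
    T_ <- sample(3:40, 1); F_ <- sample(1:8, 1)
    fm <- matrix(rnorm(T_ * F_), T_, F_)
    cuts <- sort(sample(0:T_, 2, replace = TRUE))
    seg <- seg3(0L, cuts[1], cuts[2], T_)
    # independent oracle: nested loops over segments and filters
    want <- numeric(3 * F_)
    for (s in 1:3) for (f in seq_len(F_)) {
      rows <- seq.int(seg[s, 1] + 1L, length.out = seg[s, 2] - seg[s, 1])
      want[(s - 1) * F_ + f] <- if (length(rows)) max(fm[rows, f]) else 0
    }
    expect_identical(piecewise_max_pool(fm, seg), want)
  }
})

make_encoded <- function(seed = 2L, n = 40L) {
  b <- tiny_benchmark(n, seed = seed)
  cfg <- tiny_cfg()
  inv <- dsre:::derive_inventories(b$ds_instances)
  params_p <- init_params("PCNN", cfg, inv$pos_tags, inv$dep_labels, seed = 5L)
  params_b <- init_params("BILSTM", cfg, inv$pos_tags, inv$dep_labels, seed = 5L)
  enc <- encode_instances(b$ds_instances, b$embeddings,
                          params_p$feature$tables, cfg)$encodings
  list(bench = b, cfg = cfg, inv = inv, params_p = params_p,
       params_b = params_b, enc = enc)
}

test_that("PCNN forward: normalized softmax, determinism, pooled width", {
  w <- make_encoded()
  for (e in w$enc[1:8]) {
    p1 <- pcnn_forward(e, w$params_p)
    p2 <- pcnn_forward(e, w$params_p)
    expect_identical(p1, p2)
    expect_equal(sum(p1$probs), 1, tolerance = 1e-9)
    expect_true(all(p1$probs >= 0))
    expect_equal(p1$label, if (p1$probs[1] > 0.5) "POS" else "NEG")
  }
  # pooled layer width is 3 x filter count
  e <- w$enc[[1]]
  X <- e$matrix[seq_len(e$true_length), ]
  h <- dsre:::pcnn_head(X, e$segments, w$params_p)
  expect_length(h$p, 3L * w$cfg$filters)
  expect_equal(nrow(w$params_p$classifier$Wo), 3L * w$cfg$filters)
  # all-zero instances give identical bias-driven outputs
  z1 <- e; z1$matrix[] <- 0
  z2 <- w$enc[[2]]; z2$matrix[] <- 0
  expect_equal(pcnn_forward(z1, w$params_p)$probs,
               pcnn_forward(z2, w$params_p)$probs)
})

test_that("PCNN output ignores the content of padding rows", {
  w <- make_encoded()
  e <- w$enc[[1]]
  tampered <- e
  tampered$matrix[(e$true_length + 1):nrow(e$matrix), ] <- 99
  expect_equal(pcnn_forward(e, w$params_p), pcnn_forward(tampered, w$params_p))
})

test_that("BiLSTM forward: padding invariance, single-token case, determinism", {
  w <- make_encoded()
  e <- w$enc[[1]]
  p1 <- bilstm_forward(e, w$params_b)
  expect_identical(p1, bilstm_forward(e, w$params_b))
  expect_equal(sum(p1$probs), 1, tolerance = 1e-9)
  # padded vs unpadded encodings agree
  unpadded <- e
  unpadded$matrix <- e$matrix[seq_len(e$true_length), , drop = FALSE]
  expect_equal(p1, bilstm_forward(unpadded, w$params_b))
  # single-token sentence: both directions read the same row
  one <- e
  one$true_length <- 1L
  one$segments <- matrix(c(0L, 1L, 1L, 1L, 1L, 1L), nrow = 3, byrow = TRUE)
  pone <- bilstm_forward(one, w$params_b)
  expect_equal(sum(pone$probs), 1, tolerance = 1e-9)
})

test_that("initialization is seed-reproducible with config-consistent shapes", {
  cfg <- tiny_cfg()
  a <- init_params("PCNN", cfg, c("NN", "VB"), c("root"), seed = 9L)
  b <- init_params("PCNN", cfg, c("NN", "VB"), c("root"), seed = 9L)
  expect_identical(a, b)
  c_ <- init_params("PCNN", cfg, c("NN", "VB"), c("root"), seed = 10L)
  expect_false(identical(a$feature$Wc, c_$feature$Wc))
  D <- dsre:::feature_dim(cfg)
  expect_equal(dim(a$feature$Wc), c(cfg$window * D, cfg$filters))
  expect_equal(dim(a$classifier$Wo), c(3L * cfg$filters, 2L))
  # default-scale shape audit: 400 filters of width 3 x 234
  full <- init_params("PCNN", ds_config(), "NN", "root", seed = 1L)
  expect_equal(dim(full$feature$Wc), c(3L * 234L, 400L))
  r <- init_params("BILSTM", cfg, c("NN"), c("root"), seed = 9L)
  expect_equal(dim(r$feature$fwd$Wx), c(D, 4L * cfg$hidden))
  expect_equal(dim(r$classifier$Wo), c(2L * cfg$hidden, 2L))
})

test_that("transfer copies exactly what its mode promises", {
  cfg <- tiny_cfg()
  src <- init_params("PCNN", cfg, c("NN", "VB"), c("root"), seed = 1L)
  all_t <- transfer_params(src, "ALL", seed = 99L)
  expect_equal(all_t$feature, src$feature)
  expect_equal(all_t$classifier, src$classifier)
  feat_t <- transfer_params(src, "FEATURES_ONLY", seed = 99L)
  expect_equal(feat_t$feature, src$feature)
  expect_false(identical(feat_t$classifier$Wo, src$classifier$Wo))
  # categorical tables can be excluded from the transfer
  no_emb <- transfer_params(src, "FEATURES_ONLY", seed = 99L,
                            transfer_embeddings = FALSE)
  expect_identical(no_emb$feature$Wc, src$feature$Wc)
  expect_false(identical(no_emb$feature$tables$pos, src$feature$tables$pos))
  # kind mismatch is an error
  rsrc <- init_params("BILSTM", cfg, c("NN"), c("root"), seed = 1L)
  expect_error(dsre:::check_transfer_compat(rsrc, "PCNN"), "transfer")
})

test_that("analytic gradients match finite differences for both models", {
  w <- make_encoded(seed = 6L, n = 12L)
  cfg <- ds_config(word_dim = 25L, filters = 3L, hidden = 2L, max_len = 30L,
                   dropout_feature = 0, dropout_dense = 0)
  inv <- w$inv
  inst <- dsre:::active_instances(w$bench$ds_instances)[[1]]
  for (kind in c("PCNN", "BILSTM")) {
    params <- init_params(kind, cfg, inv$pos_tags, inv$dep_labels, seed = 2L)
    feat <- dsre:::instance_features(inst, w$bench$embeddings,
                                     params$feature$tables, cfg)
    g <- dsre:::instance_grad(params, feat, 1L, training = FALSE)
    flat <- dsre:::get_flat(params)
    loss_at <- function(fl) {
      p2 <- dsre:::set_flat(params, fl)
      f2 <- dsre:::instance_features(inst, w$bench$embeddings,
                                     p2$feature$tables, cfg)
      X <- dsre:::compose_matrix(f2, p2$feature$tables)
      h <- if (kind == "PCNN") dsre:::pcnn_head(X, f2$segments, p2)
           else dsre:::bilstm_head(X, p2)
      -log(h$probs[1L])
    }
    set.seed(31)
    for (nm in names(flat)) {
      for (i in sample(seq_along(flat[[nm]]), min(3L, length(flat[[nm]])))) {
        up <- flat; up[[nm]][i] <- up[[nm]][i] + 1e-5
        dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - 1e-5
        num <- (loss_at(up) - loss_at(dn)) / 2e-5
        expect_equal(g$grad[[nm]][i], num, tolerance = 1e-3)
      }
    }
  }
})
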