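## Piecewise-max-pooling CNN (PCNN).
##
## One convolution layer (window 3, same padding, tanh) slides over the
## token-feature matrix; max pooling then operates separately on the three
## sentence segments delimited by the two entity mentions, and the three
## pooled vectors are concatenated (3 x filters wide, 1200 at the defaults)
## before the dense softmax classifier. Pooling and convolution are
## restricted to the true (unpadded) sentence length, so padding rows never
## influence the output.

#' Piecewise max pooling
#'
#' For each filter and each of the three segments, the maximum activation
#' over the segment's rows; an empty segment contributes 0 for every filter.
#' Outputs are concatenated in segment order.
#'
#' @param feature_map T x F numeric matrix.
#' @param segments 3x2 integer matrix of half-open row intervals (0-based),
#'   each within `[0, T)`.
#' @return Numeric vector of length `3 * F`.
#' @export
piecewise_max_pool <- function(feature_map, segments) {
  T_ <- nrow(feature_map); F_ <- ncol(feature_map)
  if (any(segments < 0L) || any(segments > T_)) {
    stop("segment bounds outside [0, ", T_, "]")
  }
  out <- numeric(3L * F_)
  for (s in 1:3) {
    a <- segments[s, 1]; b <- segments[s, 2]
    if (b > a) {
      seg <- feature_map[(a + 1L):b, , drop = FALSE]
      out[((s - 1L) * F_ + 1L):(s * F_)] <- apply(seg, 2L, max)
    }
  }
  out
}

## Convolution input: each row t is the concatenation of the `window` rows
## of X centred at t (zero rows beyond the sentence).
conv_windows <- function(X, window) {
  tl <- nrow(X); D <- ncol(X)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nrow = tl, ncol = window * D)
  for (w in seq_len(window)) {
    off <- w - 1L - half
    src <- seq_len(tl) + off
    ok <- src >= 1L & src <= tl
    out[ok, ((w - 1L) * D + 1L):(w * D)] <- X[src[ok], , drop = FALSE]
  }
  out
}

## Forward pass over a composed (tl x D) matrix. Returns prediction plus the
## cache needed for backprop. Dropout masks (inverted scaling) are drawn by
## the caller so that training batches control their own RNG stream.
pcnn_head <- function(X, segments, params, drop_feat = NULL, drop_dense = NULL) {
  cfg <- params$config
  Xw <- conv_windows(X, cfg$window)
  Z <- sweep(Xw %*% params$feature$Wc, 2L, params$feature$bc, "+")
  C0 <- if (cfg$conv_activation == "tanh") tanh(Z) else pmax(Z, 0)
  C <- if (is.null(drop_feat)) C0 else C0 * drop_feat
  F_ <- cfg$filters
  pooled <- numeric(3L * F_)
  argmax <- matrix(NA_integer_, nrow = 3L, ncol = F_)
  for (s in 1:3) {
    a <- segments[s, 1]; b <- segments[s, 2]
    if (b > a) {
      rows <- (a + 1L):b
      seg <- C[rows, , drop = FALSE]
      am <- max.col(t(seg), ties.method = "first")
      argmax[s, ] <- rows[am]
      pooled[((s - 1L) * F_ + 1L):(s * F_)] <- seg[cbind(am, seq_len(F_))]
    }
  }
  p <- if (is.null(drop_dense)) pooled else pooled * drop_dense
  logits <- drop(p %*% params$classifier$Wo) + params$classifier$bo
  probs <- softmax(logits)
  list(probs = probs, Xw = Xw, C0 = C0, argmax = argmax, p = p,
       drop_feat = drop_feat, drop_dense = drop_dense)
}

## Backward pass; y is 1 (positive) or 2 (negative). Returns gradients for
## every learnable weight plus dX (tl x D) for the embedding tables.
pcnn_backward <- function(cache, X, params, y) {
  cfg <- params$config
  F_ <- cfg$filters
  dlogits <- cache$probs
  dlogits[y] <- dlogits[y] - 1
  dWo <- outer(cache$p, dlogits)
  dbo <- dlogits
  dp <- drop(params$classifier$Wo %*% dlogits)
  if (!is.null(cache$drop_dense)) dp <- dp * cache$drop_dense
  dC <- matrix(0, nrow = nrow(X), ncol = F_)
  for (s in 1:3) {
    rows <- cache$argmax[s, ]
    if (!is.na(rows[1L])) {
      dC[cbind(rows, seq_len(F_))] <- dC[cbind(rows, seq_len(F_))] +
        dp[((s - 1L) * F_ + 1L):(s * F_)]
    }
  }
  if (!is.null(cache$drop_feat)) dC <- dC * cache$drop_feat
  dZ <- if (cfg$conv_activation == "tanh") dC * (1 - cache$C0^2)
        else dC * (cache$C0 > 0)
  dWc <- crossprod(cache$Xw, dZ)
  dbc <- colSums(dZ)
  dXw <- dZ %*% t(params$feature$Wc)
  # fold window gradient back onto token rows
  tl <- nrow(X); D <- ncol(X)
  half <- (cfg$window - 1L) %/% 2L
  dX <- matrix(0, nrow = tl, ncol = D)
  for (w in seq_len(cfg$window)) {
    off <- w - 1L - half
    src <- seq_len(tl) + off
    ok <- src >= 1L & src <= tl
    dX[src[ok], ] <- dX[src[ok], , drop = FALSE] +
      dXw[ok, ((w - 1L) * D + 1L):(w * D), drop = FALSE]
  }
  list(Wc = dWc, bc = dbc, Wo = dWo, bo = dbo, dX = dX)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' PCNN forward pass on an encoded instance
#'
#' Evaluation mode is deterministic; with `training = TRUE`, dropout masks
#' (rate `dropout_feature` post-convolution, `dropout_dense` on the pooled
#' vector) are drawn from `seed`.
#'
#' @param encoding An `instance_encoding` from [encode_instance()].
#' @param params `model_params` of kind PCNN.
#' @param training Logical; enables dropout.
#' @param seed Seed for the dropout masks (training mode only).
#' @return A prediction: list with `probs` (named vector over
#'   positive/negative, summing to 1) and `label` (`"POS"`/`"NEG"`, ties
#'   predict negative).
#' @export
pcnn_forward <- function(encoding, params, training = FALSE, seed = 1L) {
  stopifnot(inherits(params, "model_params"), params$kind == "PCNN")
  cfg <- params$config
  if (ncol(encoding$matrix) != feature_dim(cfg)) {
    stop("encoding width ", ncol(encoding$matrix), " != configured ",
         feature_dim(cfg))
  }
  tl <- encoding$true_length
  X <- encoding$matrix[seq_len(tl), , drop = FALSE]
  masks <- if (training) {
    with_seed(mix_seed(seed, "pcnn-dropout"), list(
      feat = dropout_mask(tl * cfg$filters, cfg$dropout_feature,
                          dim = c(tl, cfg$filters)),
      dense = dropout_mask(3L * cfg$filters, cfg$dropout_dense)
    ))
  } else list(feat = NULL, dense = NULL)
  h <- pcnn_head(X, encoding$segments, params,
                 drop_feat = masks$feat, drop_dense = masks$dense)
  as_prediction(h$probs)
}

dropout_mask <- function(n, rate, dim = NULL) {
  if (rate <= 0) return(NULL)
  m <- (stats::runif(n) >= rate) / (1 - rate)
  if (!is.null(dim)) m <- array(m, dim = dim)
  m
}

as_prediction <- function(probs) {
  names(probs) <- c("positive", "negative")
  # strict inequality: a tie at 0.5 predicts negative
  list(probs = probs, label = if (probs[1] > probs[2]) "POS" else "NEG")
}
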