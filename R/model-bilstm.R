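## Bidirectional LSTM classifier.
##
## Forward and backward recurrences run over the unpadded token rows; the
## readout concatenates the final hidden state of each direction (800-d at
## the defaults) -- or, as a configuration alternative, the elementwise max
## over time -- and feeds the dense softmax classifier. Gate slice order
## within the 4H pre-activation is (input, forget, output, cell).

sigmoid <- function(x) 1 / (1 + exp(-x))

## One direction. X is tl x D in the direction's own time order.
lstm_direction <- function(X, cell, H) {
  tl <- nrow(X)
  hs <- matrix(0, tl, H); cs <- matrix(0, tl, H)
  gates <- vector("list", tl)
  h <- numeric(H); cprev <- numeric(H)
  for (t in seq_len(tl)) {
    z <- drop(X[t, ] %*% cell$Wx) + drop(h %*% cell$Wh) + cell$b
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    o <- sigmoid(z[(2 * H + 1):(3 * H)]); g <- tanh(z[(3 * H + 1):(4 * H)])
    cnew <- f * cprev + i * g
    h <- o * tanh(cnew)
    hs[t, ] <- h; cs[t, ] <- cnew
    gates[[t]] <- list(i = i, f = f, o = o, g = g, cprev = cprev)
    cprev <- cnew
  }
  list(hs = hs, cs = cs, gates = gates)
}

## BPTT for one direction. dh_out is tl x H gradient injected at each step's
## hidden state (from the readout path). Returns weight grads and dX.
lstm_direction_backward <- function(X, cell, H, fw, dh_out) {
  tl <- nrow(X)
  dWx <- matrix(0, nrow(cell$Wx), ncol(cell$Wx))
  dWh <- matrix(0, nrow(cell$Wh), ncol(cell$Wh))
  db <- numeric(4 * H)
  dX <- matrix(0, tl, ncol(X))
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(tl))) {
    g <- fw$gates[[t]]
    tc <- tanh(fw$cs[t, ])
    dh <- dh_out[t, ] + dh_next
    do_ <- dh * tc
    dct <- dh * g$o * (1 - tc^2) + dc_next
    di <- dct * g$g; df <- dct * g$cprev; dg <- dct * g$i
    dz <- c(di * g$i * (1 - g$i),
            df * g$f * (1 - g$f),
            do_ * g$o * (1 - g$o),
            dg * (1 - g$g^2))
    dWx <- dWx + outer(X[t, ], dz)
    hprev <- if (t > 1L) fw$hs[t - 1L, ] else numeric(H)
    dWh <- dWh + outer(hprev, dz)
    db <- db + dz
    dX[t, ] <- drop(cell$Wx %*% dz)
    dh_next <- drop(cell$Wh %*% dz)
    dc_next <- dct * g$f
  }
  list(Wx = dWx, Wh = dWh, b = db, dX = dX)
}

## Forward pass over a composed (tl x D) matrix; returns prediction + cache.
bilstm_head <- function(X, params, drop_feat = NULL, drop_dense = NULL) {
  cfg <- params$config
  H <- cfg$hidden
  tl <- nrow(X)
  Xrev <- X[rev(seq_len(tl)), , drop = FALSE]
  fw <- lstm_direction(X, params$feature$fwd, H)
  bw <- lstm_direction(Xrev, params$feature$bwd, H)
  hf <- fw$hs; hb <- bw$hs
  if (!is.null(drop_feat)) {
    hf <- hf * drop_feat$fwd
    hb <- hb * drop_feat$bwd
  }
  if (cfg$bilstm_readout == "final") {
    r <- c(hf[tl, ], hb[tl, ])
    am <- NULL
  } else {
    amf <- max.col(t(hf), ties.method = "first")
    amb <- max.col(t(hb), ties.method = "first")
    r <- c(hf[cbind(amf, seq_len(H))], hb[cbind(amb, seq_len(H))])
    am <- list(fwd = amf, bwd = amb)
  }
  rd <- if (is.null(drop_dense)) r else r * drop_dense
  logits <- drop(rd %*% params$classifier$Wo) + params$classifier$bo
  probs <- softmax(logits)
  list(probs = probs, fw = fw, bw = bw, r = r, rd = rd, argmax = am,
       drop_feat = drop_feat, drop_dense = drop_dense)
}

bilstm_backward <- function(cache, X, params, y) {
  cfg <- params$config
  H <- cfg$hidden
  tl <- nrow(X)
  dlogits <- cache$probs
  dlogits[y] <- dlogits[y] - 1
  dWo <- outer(cache$rd, dlogits)
  dbo <- dlogits
  dr <- drop(params$classifier$Wo %*% dlogits)
  if (!is.null(cache$drop_dense)) dr <- dr * cache$drop_dense
  dhf <- matrix(0, tl, H); dhb <- matrix(0, tl, H)
  if (cfg$bilstm_readout == "final") {
    dhf[tl, ] <- dr[1:H]
    dhb[tl, ] <- dr[(H + 1):(2 * H)]
  } else {
    dhf[cbind(cache$argmax$fwd, seq_len(H))] <- dr[1:H]
    dhb[cbind(cache$argmax$bwd, seq_len(H))] <- dr[(H + 1):(2 * H)]
  }
  if (!is.null(cache$drop_feat)) {
    dhf <- dhf * cache$drop_feat$fwd
    dhb <- dhb * cache$drop_feat$bwd
  }
  Xrev <- X[rev(seq_len(tl)), , drop = FALSE]
  gf <- lstm_direction_backward(X, params$feature$fwd, H, cache$fw, dhf)
  gb <- lstm_direction_backward(Xrev, params$feature$bwd, H, cache$bw, dhb)
  dX <- gf$dX + gb$dX[rev(seq_len(tl)), , drop = FALSE]
  list(fwd = gf[c("Wx", "Wh", "b")], bwd = gb[c("Wx", "Wh", "b")],
       Wo = dWo, bo = dbo, dX = dX)
}

#' BiLSTM forward pass on an encoded instance
#'
#' Recurrences run only over the unpadded rows, so padding never influences
#' the output. Evaluation mode is deterministic; training mode draws dropout
#' masks (rate `dropout_feature` on the recurrent outputs at readout,
#' `dropout_dense` on the dense input) from `seed`.
#'
#' @inheritParams pcnn_forward
#' @param params `model_params` of kind BILSTM.
#' @return A prediction (list with `probs` and `label`), as for
#'   [pcnn_forward()].
#' @export
bilstm_forward <- function(encoding, params, training = FALSE, seed = 1L) {
  stopifnot(inherits(params, "model_params"), params$kind == "BILSTM")
  cfg <- params$config
  tl <- encoding$true_length
  X <- encoding$matrix[seq_len(tl), , drop = FALSE]
  masks <- if (training) {
    with_seed(mix_seed(seed, "bilstm-dropout"), list(
      feat = list(
        fwd = dropout_mask(tl * cfg$hidden, cfg$dropout_feature,
                           dim = c(tl, cfg$hidden)),
        bwd = dropout_mask(tl * cfg$hidden, cfg$dropout_feature,
                           dim = c(tl, cfg$hidden))
      ),
      dense = dropout_mask(2L * cfg$hidden, cfg$dropout_dense)
    ))
  } else list(feat = NULL, dense = NULL)
  if (training && (is.null(masks$feat$fwd) || is.null(masks$feat$bwd))) {
    masks$feat <- NULL
  }
  h <- bilstm_head(X, params, drop_feat = masks$feat, drop_dense = masks$dense)
  as_prediction(h$probs)
}
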