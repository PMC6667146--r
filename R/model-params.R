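## Model parameter containers.
##
## Every learnable weight of a model belongs to exactly one of two groups:
## "feature" weights (convolution filters or recurrent cell weights, plus the
## learned categorical-channel embedding tables) and "classifier" weights
## (the dense layer feeding the softmax). The partition is what makes
## partial transfer expressible: transfer of feature weights only, or of all
## weights.

glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nrow = nin, ncol = nout)
}

#' Initialize model parameters
#'
#' Reproducible initialization from a seed: convolution/dense weights are
#' Glorot-uniform, LSTM forget-gate biases start at 1, categorical embedding
#' tables uniform(-0.1, 0.1). The configuration is snapshotted inside the
#' returned object.
#'
#' @param kind `"PCNN"` or `"BILSTM"`.
#' @param cfg A [ds_config()].
#' @param pos_tags,dep_labels Tag inventories of the training corpus (sizing
#'   the learned categorical tables).
#' @param seed Integer seed.
#' @return Object of class `model_params` with fields `kind`, `feature`,
#'   `classifier`, `config`, `seed`.
#' @export
init_params <- function(kind = c("PCNN", "BILSTM"), cfg = ds_config(),
                        pos_tags, dep_labels, seed = 1L) {
  kind <- match.arg(kind)
  D <- feature_dim(cfg)
  tables <- init_categorical_tables(cfg, pos_tags, dep_labels, seed)
  with_seed(mix_seed(seed, paste0("init-", kind)), {
    if (kind == "PCNN") {
      feature <- list(
        Wc = glorot(cfg$window * D, cfg$filters),
        bc = numeric(cfg$filters),
        tables = tables
      )
      classifier <- list(
        Wo = glorot(3L * cfg$filters, 2L),
        bo = numeric(2L)
      )
    } else {
      H <- cfg$hidden
      cell <- function() {
        b <- numeric(4L * H)
        b[(H + 1L):(2L * H)] <- 1  # forget gate bias
        list(Wx = glorot(D, 4L * H), Wh = glorot(H, 4L * H), b = b)
      }
      feature <- list(fwd = cell(), bwd = cell(), tables = tables)
      classifier <- list(Wo = glorot(2L * H, 2L), bo = numeric(2L))
    }
    structure(list(kind = kind, feature = feature, classifier = classifier,
                   config = cfg, seed = as.integer(seed)),
              class = "model_params")
  })
}

#' @export
print.model_params <- function(x, ...) {
  nw <- function(g) sum(vapply(rapply(g, identity, how = "list",
                                      classes = c("matrix", "numeric", "integer")),
                               length, 0))
  cat(sprintf("<%s parameters: %d feature + %d classifier weights, seed %d>\n",
              x$kind, nw(x$feature), nw(x$classifier), x$seed))
  invisible(x)
}

#' Transfer parameters from a pretrained model
#'
#' `mode = "ALL"` copies every weight, so the target equals the source
#' exactly at fine-tuning step 0. `mode = "FEATURES_ONLY"` copies the
#' feature weights (convolution filters / recurrent cells and, by default,
#' the categorical-channel tables) and re-initializes the classifier weights
#' from `seed`. Nothing is frozen: all weights remain trainable during
#' fine-tuning.
#'
#' @param source A pretrained `model_params`.
#' @param mode `"ALL"` or `"FEATURES_ONLY"`.
#' @param seed Seed for the re-initialized classifier weights.
#' @param transfer_embeddings If FALSE, the categorical tables are
#'   re-initialized instead of copied under `FEATURES_ONLY`.
#' @return A `model_params` of the same kind.
#' @export
transfer_params <- function(source, mode = c("ALL", "FEATURES_ONLY"), seed = 1L,
                            transfer_embeddings = source$config$transfer_embeddings) {
  mode <- match.arg(mode)
  if (!inherits(source, "model_params")) stop("source must be model_params")
  if (mode == "ALL") {
    out <- source
    out$seed <- as.integer(seed)
    return(out)
  }
  fresh <- init_params(source$kind, source$config,
                       pos_tags = head_rownames(source$feature$tables$pos),
                       dep_labels = head_rownames(source$feature$tables$dep),
                       seed = seed)
  out <- source
  out$classifier <- fresh$classifier
  if (!transfer_embeddings) out$feature$tables <- fresh$feature$tables
  out$seed <- as.integer(seed)
  out
}

## rownames minus the trailing <UNK> row
head_rownames <- function(m) {
  rn <- rownames(m)
  rn[-length(rn)]
}

## Check that a source model can initialize a target configuration.
check_transfer_compat <- function(source, kind) {
  if (source$kind != kind) {
    stop("cannot transfer ", source$kind, " weights into a ", kind, " model")
  }
  invisible(TRUE)
}
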