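# Base-pair-matrix predictors: n x n input encoding and convolutional
# residual models (variants 0, 1 and 3; variant 3 adds a 2-D BLSTM block),
# with a sigmoid score per matrix entry.

#' Encode a sequence as an n x n x 8 pair-input tensor
#'
#' Entry `(i, j)` carries the concatenated one-hot encodings of residues `i`
#' (channels 1-4) and `j` (channels 5-8), so the tensor is symmetric under
#' `(i, j) <-> (j, i)` with the two channel blocks swapped.
#'
#' @param seq an RNA sequence.
#' @return array `(n, n, 8)`.
#' @export
encode_pair_input <- function(seq) {
  x <- encode_pair_batch(rna_sequence(seq))
  array(x, dim(x)[2:4])
}

# batch version: (N, n, n, 8) for equal-length sequences
encode_pair_batch <- function(seqs) {
  oh <- onehot_batch(seqs) # (N, n, 4)
  N <- dim(oh)[1L]; n <- dim(oh)[2L]
  x <- array(0, c(N, n, n, 8L))
  for (c in 1:4) {
    ri <- array(rep(oh[, , c], times = n), c(N, n, n)) # residue i along rows
    x[, , , c] <- ri
    x[, , , c + 4L] <- aperm(ri, c(1L, 3L, 2L))        # residue j along cols
  }
  x
}

#' Specification of a base-pair-matrix model
#'
#' Variants follow the three reference model sizes: variant 0 and 1 are
#' purely convolutional residual networks differing in depth; variant 3 (and
#' only variant 3) additionally contains a 2-D bidirectional LSTM block.
#' Widths and depths are configuration-exposed; faithfulness to the reference
#' architecture is claimed at the block-structure level only.
#'
#' @param variant 0, 1 or 3.
#' @param channels convolutional width.
#' @param blocks residual block count (defaults: 2 for variant 0, 4 for
#'   variant 1, 2 for variant 3).
#' @param lstm_hidden hidden units of the variant-3 recurrent block.
#' @export
matrix_model_spec <- function(variant = c(0L, 1L, 3L), channels = 12L,
                              blocks = NULL, lstm_hidden = 6L) {
  variant <- as.integer(variant)[1L]
  if (!variant %in% c(0L, 1L, 3L)) stop("unknown variant ", variant)
  if (is.null(blocks)) blocks <- switch(as.character(variant), "0" = 2L,
                                        "1" = 4L, "3" = 2L)
  structure(list(variant = variant, channels = as.integer(channels),
                 blocks = as.integer(blocks),
                 lstm_hidden = as.integer(lstm_hidden)),
            class = "matrix_model_spec")
}

#' Build a trainable base-pair-matrix model
#'
#' The model maps a pair-input tensor of any side length `n` to an `n x n`
#' score matrix in `[0, 1]` (size-agnostic: all layers are convolutional or
#' recurrent along rows/columns).
#'
#' @param spec a [matrix_model_spec()].
#' @param seed integer seed for weight initialization.
#' @export
build_matrix_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "matrix_model_spec")) stop("need a matrix_model_spec")
  with_seed(seed, {
    ch <- spec$channels
    layers <- list(nn_conv2d(8L, ch, 3L, act = "relu"))
    for (k in seq_len(spec$blocks)) layers <- c(layers, list(nn_res2d(ch)))
    if (spec$variant == 3L) {
      layers <- c(layers, list(nn_bilstm2d(ch, spec$lstm_hidden),
                               nn_conv2d(4L * spec$lstm_hidden, ch, 1L,
                                         act = "relu")))
    }
    layers <- c(layers, list(nn_conv2d(ch, 1L, 1L)))
    new_nn_model(layers, spec)
  })
}

matrix_targets <- function(bundle) lapply(bundle$structures, structure_matrix)

#' Train a base-pair-matrix model
#'
#' Per-entry binary cross-entropy against the binary symmetric ground-truth
#' matrices; sequences are bucketed by length so every minibatch is
#' length-homogeneous. Model selection by maximum validation MCC (per-entry,
#' upper triangle, binarized at 0.5). A fitted model (or checkpoint) can be
#' passed to continue training (e.g. after pre-training on random sequences).
#'
#' @param model a handle from [build_matrix_model()], a spec, or a
#'   `matrix_fit` to continue from.
#' @param train,val [dataset_bundle()]s.
#' @param protocol a [training_protocol()].
#' @param quiet suppress progress output.
#' @return object of class `matrix_fit`: `model`, `trace`, `selected_epoch`.
#' @export
train_matrix_model <- function(model, train, val,
                               protocol = training_protocol(), quiet = TRUE) {
  if (inherits(model, "matrix_model_spec"))
    model <- build_matrix_model(model, seed = protocol$seed)
  if (inherits(model, "matrix_fit")) model <- model$model
  if (!length(train$sequences) || !length(val$sequences)) stop("empty bundle")
  y_tr <- matrix_targets(train)
  y_va <- matrix_targets(val)
  if (is.null(model$adam)) adam_init(model)
  trace <- NULL
  best <- list(mcc = -Inf, params = get_params(model), epoch = 0L)
  with_seed(protocol$seed, {
    for (epoch in seq_len(protocol$max_epochs)) {
      tr_loss <- 0; nb <- 0L
      for (bidx in make_batches(train$sequences, protocol$batch_size)) {
        sub <- train$sequences[bidx]
        n <- nchar(sub[1L])
        x <- encode_pair_batch(sub)
        y <- array(0, c(length(bidx), n, n))
        for (k in seq_along(bidx)) y[k, , ] <- y_tr[[bidx[k]]]
        r <- forward_model(model, x, train = TRUE)
        l <- bce_logits(as.vector(r$out), as.vector(y), pos_weight = NA)
        grads <- backward_model(model, array(l$dz, c(length(bidx), n, n, 1L)),
                                r$caches)
        adam_step(model, grads, lr = protocol$lr)
        tr_loss <- tr_loss + l$loss; nb <- nb + 1L
      }
      m <- matrix_val_metrics(model, val$sequences, y_va, protocol$batch_size)
      trace <- rbind(trace, cbind(epoch = epoch, train_loss = tr_loss / nb, m))
      if (!quiet) message(sprintf("epoch %d: train loss %.4f val mcc %.3f",
                                  epoch, tr_loss / nb, m$mcc))
      if (m$mcc > best$mcc)
        best <- list(mcc = m$mcc, params = get_params(model), epoch = epoch)
    }
  })
  set_params(model, best$params)
  structure(list(model = model, trace = as.data.frame(trace),
                 selected_epoch = best$epoch, protocol = protocol),
            class = "matrix_fit")
}

# per-entry (upper triangle) metrics over a validation set
matrix_val_metrics <- function(model, seqs, targets, batch_size = 16L) {
  probs <- numeric(0L); ys <- numeric(0L)
  for (idx in length_buckets(seqs)) {
    for (bidx in split(idx, ceiling(seq_along(idx) / batch_size))) {
      sub <- seqs[bidx]
      n <- nchar(sub[1L])
      r <- forward_model(model, encode_pair_batch(sub))
      p <- array(sigm(r$out), c(length(bidx), n, n))
      ut <- upper.tri(matrix(0, n, n))
      for (k in seq_along(bidx)) {
        probs <- c(probs, p[k, , ][ut])
        ys <- c(ys, targets[[bidx[k]]][ut])
      }
    }
  }
  binary_metrics(probs, ys)
}

#' Predict a raw base-pair score matrix
#'
#' Raw per-entry scores in `[0, 1]`, before any postprocessing; pass the
#' result to [matrix_to_structure()] or [count_predicted_pairs()].
#'
#' @param fit a `matrix_fit` (or bare model handle).
#' @param seq one RNA sequence.
#' @return `n x n` numeric matrix.
#' @export
predict_matrix <- function(fit, seq) {
  model <- if (inherits(fit, "matrix_fit")) fit$model else fit
  seq <- rna_sequence(seq)
  n <- nchar(seq)
  r <- forward_model(model, encode_pair_batch(seq))
  matrix(sigm(r$out), n, n)
}

# batched prediction returning a list of matrices
predict_matrix_many <- function(fit, seqs, batch_size = 16L) {
  model <- if (inherits(fit, "matrix_fit")) fit$model else fit
  out <- vector("list", length(seqs))
  for (idx in length_buckets(seqs)) {
    for (bidx in split(idx, ceiling(seq_along(idx) / batch_size))) {
      sub <- seqs[bidx]
      n <- nchar(sub[1L])
      r <- forward_model(model, encode_pair_batch(sub))
      p <- array(sigm(r$out), c(length(bidx), n, n))
      for (k in seq_along(bidx)) out[[bidx[k]]] <- matrix(p[k, , ], n, n)
    }
  }
  out
}

#' Save and load model checkpoints
#'
#' Checkpoints embed the model specification, the parameters and (when saved
#' from a fit) the training protocol and metric trace, so training can be
#' resumed or audited later. The file is a standard R serialization.
#'
#' @param fit a `matrix_fit`, `pairedness_fit`, or bare model handle.
#' @param path destination file.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, c("matrix_fit", "pairedness_fit"))) fit$model else fit
  obj <- list(spec = model$spec, params = get_params(model),
              trace = if (inherits(fit, c("matrix_fit", "pairedness_fit")))
                fit$trace,
              protocol = if (inherits(fit, c("matrix_fit", "pairedness_fit")))
                fit$protocol,
              package_version = as.character(utils::packageVersion("synfold")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- if (inherits(obj$spec, "matrix_model_spec"))
    build_matrix_model(obj$spec) else build_pairedness_model(obj$spec)
  set_params(model, obj$params)
  attr(model, "trace") <- obj$trace
  model
}
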