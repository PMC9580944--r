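# Paired/unpaired sequence labelers: sliding-window feed-forward and 1-D
# convolutional models over one-hot windows with an explicit padding channel,
# and a window-less bidirectional LSTM.

#' Specification of a paired/unpaired predictor
#'
#' @param family `"FFN"`, `"CNN"` (both sliding-window) or `"BLSTM"`.
#' @param window odd window size for FFN/CNN (grid values 15, 35, 71).
#' @param layers,hidden BLSTM depth (1 or 3) and units per direction (40/80).
#' @param ffn_hidden hidden layer sizes of the FFN head.
#' @param cnn_filters,cnn_width,cnn_dense 1-D convolution hyperparameters.
#' @export
pairedness_model_spec <- function(family = c("FFN", "CNN", "BLSTM"),
                                  window = 15L, layers = 1L, hidden = 40L,
                                  ffn_hidden = c(64L, 32L), cnn_filters = 32L,
                                  cnn_width = 5L, cnn_dense = 32L) {
  family <- match.arg(family)
  if (family != "BLSTM" && window %% 2L == 0L) stop("window size must be odd")
  structure(list(family = family, window = as.integer(window),
                 layers = as.integer(layers), hidden = as.integer(hidden),
                 ffn_hidden = as.integer(ffn_hidden),
                 cnn_filters = as.integer(cnn_filters),
                 cnn_width = as.integer(cnn_width),
                 cnn_dense = as.integer(cnn_dense)),
            class = "pairedness_model_spec")
}

#' Build a trainable paired/unpaired model
#'
#' @param spec a [pairedness_model_spec()].
#' @param seed integer seed for weight initialization.
#' @return model handle (environment of class `synfold_nn`); see
#'   [n_parameters()].
#' @export
build_pairedness_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "pairedness_model_spec")) stop("need a pairedness_model_spec")
  with_seed(seed, {
    layers <- switch(spec$family,
      FFN = {
        sizes <- c(spec$window * 5L, spec$ffn_hidden)
        c(lapply(seq_len(length(sizes) - 1L), function(k)
            nn_dense(sizes[k], sizes[k + 1L], "relu")),
          list(nn_dense(sizes[length(sizes)], 1L)))
      },
      CNN = list(
        nn_conv1d(5L, spec$cnn_filters, spec$cnn_width),
        nn_maxpool1d(),
        nn_dense(spec$cnn_filters, spec$cnn_dense, "relu"),
        nn_dense(spec$cnn_dense, 1L)),
      BLSTM = {
        ls <- list(nn_lstm_bi(4L, spec$hidden))
        if (spec$layers > 1L)
          for (k in 2:spec$layers)
            ls[[k]] <- nn_lstm_bi(2L * spec$hidden, spec$hidden)
        c(ls, list(nn_dense(2L * spec$hidden, 1L)))
      })
    new_nn_model(layers, spec)
  })
}

#' Training protocol
#'
#' Models are trained for up to `max_epochs` epochs and the epoch with the
#' maximum validation MCC is selected.
#'
#' @param max_epochs default 100 (reference protocol); scale down for desk runs.
#' @param lr Adam learning rate.
#' @param batch_size sequences per minibatch.
#' @param seed integer seed.
#' @export
training_protocol <- function(max_epochs = 100L, lr = 1e-3, batch_size = 32L,
                              seed = 1L) {
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_protocol")
}

# one-hot encode equal-length sequences: (N, L, 4)
onehot_batch <- function(seqs) {
  L <- nchar(seqs[1L])
  N <- length(seqs)
  codes <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE),
                        c("A", "C", "G", "U")), N, L, byrow = TRUE)
  x <- array(0, c(N, L, 4L))
  x[cbind(rep(seq_len(N), L), rep(seq_len(L), each = N),
          as.vector(codes))] <- 1
  x
}

#' Encode sliding windows around every position
#'
#' One window per sequence position, padded symmetrically at the ends with an
#' explicit fifth padding channel.
#'
#' @param seq an RNA sequence.
#' @param w odd window size.
#' @return array `(L, w, 5)`; channel order A, C, G, U, pad.
#' @export
encode_windows <- function(seq, w) {
  if (w %% 2L == 0L) stop("window size must be odd")
  window_tensor(rna_sequence(seq), w) # N = 1, so rows index positions
}

# windows for a batch of equal-length sequences: (N*L, w, 5), rows ordered
# sequence-fastest then position (matching column-major flattening of (N, L))
window_tensor <- function(seqs, w) {
  N <- length(seqs)
  L <- nchar(seqs[1L])
  p <- (w - 1L) %/% 2L
  xp <- array(0, c(N, L + 2L * p, 5L))
  if (p > 0L) {
    xp[, c(seq_len(p), L + p + seq_len(p)), 5L] <- 1
  }
  xp[, p + seq_len(L), 1:4] <- onehot_batch(seqs)
  out <- array(0, c(N * L, w, 5L))
  for (o in seq_len(w))
    out[, o, ] <- matrix(xp[, o:(o + L - 1L), , drop = FALSE], N * L, 5L)
  out
}

paired_labels <- function(bundle) {
  lapply(bundle$structures, function(pt) as.numeric(!is.na(pt$partner)))
}

# group indices of a bundle by sequence length
length_buckets <- function(seqs) split(seq_along(seqs), nchar(seqs))

predict_pairedness_batch <- function(model, seqs) {
  spec <- model$spec
  out <- vector("list", length(seqs))
  for (idx in length_buckets(seqs)) {
    sub <- seqs[idx]
    L <- nchar(sub[1L])
    z <- if (spec$family == "BLSTM") {
      r <- forward_model(model, onehot_batch(sub))
      matrix(r$out, length(sub) * L)
    } else {
      wt <- window_tensor(sub, spec$window)
      x <- if (spec$family == "FFN") matrix(wt, dim(wt)[1L]) else wt
      forward_model(model, x)$out
    }
    pm <- matrix(sigm(as.vector(z)), length(sub), L)
    for (k in seq_along(idx)) out[[idx[k]]] <- pm[k, ]
  }
  out
}

#' Train a paired/unpaired predictor
#'
#' Labels are derived from the ground-truth pair tables (paired = 1). Returns
#' the model at the epoch with maximum validation MCC together with the full
#' per-epoch metric trace (accuracy, F1, loss, MCC).
#'
#' @param model a model handle from [build_pairedness_model()] (or a spec).
#' @param train,val [dataset_bundle()]s.
#' @param protocol a [training_protocol()].
#' @param quiet suppress progress output.
#' @return object of class `pairedness_fit`: fields `model`, `trace`,
#'   `selected_epoch`.
#' @export
train_pairedness <- function(model, train, val, protocol = training_protocol(),
                             quiet = TRUE) {
  if (inherits(model, "pairedness_model_spec"))
    model <- build_pairedness_model(model, seed = protocol$seed)
  if (!length(train$sequences) || !length(val$sequences)) stop("empty bundle")
  spec <- model$spec
  y_tr <- paired_labels(train)
  y_va <- paired_labels(val)
  adam_init(model)
  trace <- NULL
  best <- list(mcc = -Inf, params = get_params(model), epoch = 0L)
  with_seed(protocol$seed, {
    for (epoch in seq_len(protocol$max_epochs)) {
      for (bidx in make_batches(train$sequences, protocol$batch_size)) {
        sub <- train$sequences[bidx]
        L <- nchar(sub[1L])
        y <- as.numeric(do.call(rbind, y_tr[bidx])) # (N, L) column-major
        if (spec$family == "BLSTM") {
          r <- forward_model(model, onehot_batch(sub), train = TRUE)
          l <- bce_logits(as.vector(r$out), y)
          grads <- backward_model(model, matrix(l$dz, ncol = 1L), r$caches)
        } else {
          wt <- window_tensor(sub, spec$window)
          x <- if (spec$family == "FFN") matrix(wt, dim(wt)[1L]) else wt
          r <- forward_model(model, x, train = TRUE)
          l <- bce_logits(as.vector(r$out), y)
          grads <- backward_model(model, matrix(l$dz, ncol = 1L), r$caches)
        }
        adam_step(model, grads, lr = protocol$lr)
      }
      m <- pairedness_metrics(model, val$sequences, y_va)
      trace <- rbind(trace, cbind(epoch = epoch, m))
      if (!quiet) message(sprintf("epoch %d: val mcc %.3f", epoch, m$mcc))
      if (m$mcc > best$mcc)
        best <- list(mcc = m$mcc, params = get_params(model), epoch = epoch)
    }
  })
  set_params(model, best$params)
  structure(list(model = model, trace = as.data.frame(trace),
                 selected_epoch = best$epoch, protocol = protocol),
            class = "pairedness_fit")
}

make_batches <- function(seqs, batch_size) {
  # shuffle within length buckets so every batch is length-homogeneous
  out <- list()
  for (idx in length_buckets(seqs)) {
    idx <- idx[sample.int(length(idx))]
    k <- ceiling(length(idx) / batch_size)
    out <- c(out, split(idx, rep(seq_len(k), each = batch_size)[seq_along(idx)]))
  }
  out[sample.int(length(out))]
}

pairedness_metrics <- function(model, seqs, labels) {
  probs <- predict_pairedness_batch(model, seqs)
  p <- unlist(probs); y <- unlist(labels)
  binary_metrics(p, y)
}

#' Predict per-position pairedness probabilities
#'
#' @param fit a `pairedness_fit` (or bare model handle).
#' @param seqs character vector of sequences.
#' @return list of numeric vectors of probabilities, one per sequence.
#' @export
predict_pairedness <- function(fit, seqs) {
  model <- if (inherits(fit, "pairedness_fit")) fit$model else fit
  predict_pairedness_batch(model, rna_sequence(seqs))
}
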