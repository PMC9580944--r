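# Experiment grids: structural-statistics comparison, pair-count scaling
# analysis, cross-distribution training grid, bias experiment and the
# pseudoknot/multi-pair census of raw network output.

#' Structural statistics of oracle vs model structures
#'
#' Folds fresh random test sets (default 2000 sequences each of lengths 70
#' and 100) with the oracle and, when a fitted matrix model is given, derives
#' model structures via [matrix_to_structure()]; returns a
#' [aggregate_stats()] report per source and length.
#'
#' @param oracle a [folding_oracle()].
#' @param model optional `matrix_fit`; `NULL` reproduces the oracle-only rows.
#' @param lengths sequence lengths (default `c(70, 100)`).
#' @param per_length test sequences per length (reference scale: 2000).
#' @param seed integer seed.
#' @return nested list `result[[source]][[as.character(length)]]` of
#'   `structure_stats` (`source` in `"oracle"`, `"model"`).
#' @export
structure_stats_experiment <- function(oracle = folding_oracle(), model = NULL,
                              lengths = c(70L, 100L), per_length = 2000L,
                              seed = 1L) {
  out <- list(oracle = list(), model = list())
  for (L in lengths) {
    seqs <- sample_sequences(per_length, length_distribution("fixed", L),
                             seed = seed + L)
    bundle <- fold_dataset(seqs, oracle, "test")
    out$oracle[[as.character(L)]] <- aggregate_stats(seqs, bundle$structures)
    if (!is.null(model)) {
      pts <- lapply(predict_matrix_many(model, seqs), matrix_to_structure)
      out$model[[as.character(L)]] <- aggregate_stats(seqs, pts)
    }
  }
  out
}

#' Least-squares scaling fits of pair counts vs sequence length
#'
#' Fits both a line and a quadratic to mean pair counts per length and tests
#' the quadratic term by a nested-model F-test.
#'
#' @param lengths numeric vector of sequence lengths (>= 3 distinct values).
#' @param mean_counts mean pair count per length.
#' @param alpha significance level for the quadratic term (default 0.01).
#' @return object of class `scaling_fit`: coefficients of both fits, residual
#'   sums of squares, F statistic and p-value, `quadratic_significant`.
#' @export
scaling_fit <- function(lengths, mean_counts, alpha = 0.01) {
  if (length(unique(lengths)) < 3L)
    stop("need at least 3 length bins for the quadratic fit")
  df <- data.frame(n = lengths, y = mean_counts)
  lin <- stats::lm(y ~ n, df)
  quad <- stats::lm(y ~ n + I(n^2), df)
  ft <- stats::anova(lin, quad)
  pval <- ft$`Pr(>F)`[2L]
  structure(list(
    linear = stats::coef(lin), quadratic = stats::coef(quad),
    rss_linear = sum(stats::residuals(lin)^2),
    rss_quadratic = sum(stats::residuals(quad)^2),
    f_statistic = ft$F[2L], p_value = pval,
    quadratic_significant = is.finite(pval) && pval < alpha,
    slope = unname(stats::coef(lin)["n"]),
    quad_coefficient = unname(stats::coef(quad)["I(n^2)"]),
    lengths = lengths, mean_counts = mean_counts), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("scaling_fit over", length(x$lengths), "length bins\n")
  cat(sprintf("  linear:    %.4f + %.4f n (rss %.3g)\n",
              x$linear[1], x$linear[2], x$rss_linear))
  cat(sprintf("  quadratic: n^2 coefficient %.3g (F = %.2f, p = %.3g)%s\n",
              x$quad_coefficient, x$f_statistic, x$p_value,
              if (x$quadratic_significant) " *" else ""))
  invisible(x)
}

#' Pair-count scaling of a model vs ground truth over a length series
#'
#' For every length bin, the mean [count_predicted_pairs()] of the raw model
#' output (no postprocessing) and of the binary ground-truth matrices; both
#' are fit by [scaling_fit()].
#'
#' @param model fitted `matrix_fit` (or `NULL` for ground truth only).
#' @param series named list of bundles from [length_series_sets()].
#' @param threshold count threshold (default 0.5).
#' @param alpha significance level.
#' @return list with `model` and `ground_truth` `scaling_fit`s (model `NULL`
#'   when no model given).
#' @export
scaling_analysis <- function(model, series, threshold = 0.5, alpha = 0.01) {
  if (length(series) < 3L) stop("need at least 3 length bins")
  lengths <- as.numeric(names(series))
  gt_means <- vapply(series, function(b)
    mean(vapply(b$structures, function(pt) nrow(pairs_of(pt)), 0L)), 0)
  out <- list(ground_truth = scaling_fit(lengths, gt_means, alpha),
              model = NULL)
  if (!is.null(model)) {
    mod_means <- vapply(series, function(b) {
      ms <- predict_matrix_many(model, b$sequences)
      mean(vapply(ms, count_predicted_pairs, 0, threshold = threshold))
    }, 0)
    out$model <- scaling_fit(lengths, mod_means, alpha)
  }
  out
}

#' Cross-distribution training grid
#'
#' Trains one matrix model per preset length distribution and evaluates every
#' model on every validation set (16 cells) plus on its own training set.
#'
#' @param presets preset names (default D1-D4).
#' @param spec a [matrix_model_spec()].
#' @param protocol a [training_protocol()].
#' @param oracle a [folding_oracle()].
#' @param n_train,n_val bundle sizes (reference scale 30000/5000).
#' @param seed integer seed.
#' @return object of class `grid_result`: `mcc` 4x4 matrix (rows = training
#'   preset, columns = validation preset), `self` per-model training-set MCC,
#'   `diagonal_dominance` = mean(diagonal) - mean(off-diagonal).
#' @export
cross_grid_experiment <- function(presets = c("D1", "D2", "D3", "D4"),
                                  spec = matrix_model_spec(0L),
                                  protocol = training_protocol(),
                                  oracle = folding_oracle(),
                                  n_train = 30000L, n_val = 5000L, seed = 1L) {
  sets <- lapply(seq_along(presets), function(k)
    preset_distribution_sets(presets[k], seed = seed + 101L * k, oracle,
                             n_train = n_train, n_val = n_val))
  names(sets) <- presets
  m <- matrix(NA_real_, length(presets), length(presets),
              dimnames = list(train = presets, val = presets))
  self <- stats::setNames(numeric(length(presets)), presets)
  for (a in seq_along(presets)) {
    proto <- protocol; proto$seed <- protocol$seed + a
    fit <- train_matrix_model(spec, sets[[a]]$train, sets[[a]]$validation,
                              proto)
    for (b in seq_along(presets)) {
      va <- sets[[b]]$validation
      preds <- predict_matrix_many(fit, va$sequences)
      m[a, b] <- evaluate_predictions(preds, va$structures, "per-entry")$mcc
    }
    trp <- predict_matrix_many(fit, sets[[a]]$train$sequences)
    self[a] <- evaluate_predictions(trp, sets[[a]]$train$structures,
                                    "per-entry")$mcc
  }
  structure(list(mcc = m, self = self,
                 diagonal_dominance = mean(diag(m)) -
                   mean(m[row(m) != col(m)])),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("cross-distribution MCC grid (rows = training set):\n")
  print(round(x$mcc, 3))
  cat("self (training-set) MCC:", paste(round(x$self, 3), collapse = " "), "\n")
  cat("diagonal dominance:", round(x$diagonal_dominance, 4), "\n")
  invisible(x)
}

#' Structure-bias experiment
#'
#' Pre-trains a matrix model briefly on random sequences, then trains it on a
#' structure-biased bundle (from [replicate_bias_dataset()]); evaluates MCC
#' on (a) a held-out inverse-folded test set sharing the structure bias and
#' (b) its dinucleotide-shuffled, refolded control, both at the pre-trained
#' checkpoint and after bias training.
#'
#' @param bias list with `train` and `validation` bundles (the validation
#'   bundle doubles as the held-out inverse-folded test set).
#' @param spec a [matrix_model_spec()].
#' @param pretrain_protocol protocol for the random pre-training phase
#'   (reference: 3 epochs on random length-119/120 sequences).
#' @param protocol protocol for bias training.
#' @param oracle a [folding_oracle()].
#' @param n_pretrain random pre-training sequences.
#' @param pretrain_lengths lengths of the random pre-training sequences.
#' @param seed integer seed.
#' @return list with per-phase MCCs (`pretrained_inverse`,
#'   `pretrained_shuffled`, `trained_inverse`, `trained_shuffled`) and `gap`
#'   = trained inverse - shuffled.
#' @export
bias_experiment <- function(bias, spec = matrix_model_spec(0L),
                            pretrain_protocol = training_protocol(max_epochs = 3L),
                            protocol = training_protocol(),
                            oracle = folding_oracle(),
                            n_pretrain = 200L,
                            pretrain_lengths = c(119L, 120L), seed = 1L) {
  # shuffled control: dinucleotide-shuffle the test sequences, refold
  test <- bias$validation
  shuf_seqs <- vapply(seq_along(test$sequences), function(k)
    dinucleotide_shuffle(test$sequences[k], seed = seed + 7L * k), "")
  shuf_seqs <- make_unique_seqs(shuf_seqs)
  shuffled <- fold_dataset(shuf_seqs, oracle, "test")

  # pre-training on random sequences
  pre_dist <- length_distribution("empirical", min(pretrain_lengths),
                                  max(pretrain_lengths),
                                  lengths = pretrain_lengths)
  pre_seqs <- sample_sequences(n_pretrain, pre_dist, seed = seed + 13L)
  pre_val <- sample_sequences(max(20L, n_pretrain %/% 10L), pre_dist,
                              seed = seed + 14L)
  pre_tr <- fold_dataset(pre_seqs, oracle, "train")
  pre_va <- fold_dataset(pre_val, oracle, "validation")
  pp <- pretrain_protocol; pp$seed <- seed
  fit0 <- train_matrix_model(spec, pre_tr, pre_va, pp)

  eval_on <- function(fit, bundle)
    evaluate_predictions(predict_matrix_many(fit, bundle$sequences),
                         bundle$structures, "per-entry")$mcc
  pre_inv <- eval_on(fit0, test)
  pre_shuf <- eval_on(fit0, shuffled)

  bp <- protocol; bp$seed <- seed + 1L
  fit1 <- train_matrix_model(fit0, bias$train, bias$validation, bp)
  tr_inv <- eval_on(fit1, test)
  tr_shuf <- eval_on(fit1, shuffled)

  list(pretrained_inverse = pre_inv, pretrained_shuffled = pre_shuf,
       trained_inverse = tr_inv, trained_shuffled = tr_shuf,
       gap = tr_inv - tr_shuf,
       pretrained_gap = pre_inv - pre_shuf)
}

make_unique_seqs <- function(seqs) {
  # drop duplicates arising from shuffling near-degenerate sequences
  seqs[!duplicated(seqs)]
}

#' Census of pseudoknots and multi-pairings in raw model output
#'
#' Binarizes raw predicted matrices at `threshold` (no postprocessing),
#' extracts the upper-triangle pair list of every structure and runs
#' [crossing_multipair_census()]. Ground-truth matrices yield an all-zero
#' census.
#'
#' @param model fitted `matrix_fit`.
#' @param oracle a [folding_oracle()] used to generate the evaluation set.
#' @param length sequence length (reference: 100).
#' @param count number of sequences (reference: 2000).
#' @param threshold binarization threshold.
#' @param seed integer seed.
#' @export
pseudoknot_census_experiment <- function(model, oracle = folding_oracle(),
                                         length = 100L, count = 2000L,
                                         threshold = 0.5, seed = 1L) {
  seqs <- sample_sequences(count, length_distribution("fixed", length),
                           seed = seed)
  ms <- predict_matrix_many(model, seqs)
  raws <- lapply(ms, function(m) {
    idx <- which(m > threshold & upper.tri(m), arr.ind = TRUE)
    raw_pair_assignment(idx, nrow(m))
  })
  crossing_multipair_census(raws)
}
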