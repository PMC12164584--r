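#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param patience Early-stopping patience on validation loss; 0 disables.
#' @param weight_decay Decoupled L2 weight decay coefficient.
#' @param dropout Dropout rate on the squeezed position vector during
#'   training (inverted dropout; inference is unaffected).
#' @param conv_init `"seeded"` initializes half of the first conv layer's
#'   filters as detectors for label-enriched k-mers found in the training
#'   data (see [seed_conv_filters()]); `"random"` keeps Glorot init.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 16L,
                         learning_rate = 1e-3, optimizer = "adam",
                         seed = 1L, patience = 0L, weight_decay = 0,
                         dropout = 0, conv_init = c("seeded", "random")) {
  optimizer <- match.arg(optimizer, "adam")
  conv_init <- match.arg(conv_init)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, patience >= 0,
            weight_decay >= 0, dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), patience = as.integer(patience),
                 weight_decay = weight_decay, dropout = dropout,
                 conv_init = conv_init),
            class = "train_config")
}

#' Seed first-layer conv filters with label-enriched k-mers
#'
#' Gradient descent discovers position-invariant motif detectors slowly on
#' small datasets, because the gradient reaching a first-layer filter changes
#' sign with the motif's position. A standard remedy is to initialize part of
#' the filter bank as detectors for sequence patterns that are already
#' over-represented in positive examples. For each target, k-mers (k = kernel
#' size) are counted in the central bin region of positive vs negative
#' training windows; the most enriched k-mers are turned into matched filters
#' in embedding space (`W[k, , f]` proportional to the embedding row of the
#' k-mer's k-th base). Only the training split is consulted.
#'
#' @param params Parameter list from [init_params()].
#' @param config The `model_config`.
#' @param codes Integer code matrix of training windows.
#' @param labels Binary label matrix of the same rows.
#' @param frac Fraction of first-layer filters to seed (default 0.5).
#' @param kmers_per_target Enriched k-mers considered per target.
#' @return The parameter list with part of `conv1_W` replaced.
#' @export
seed_conv_filters <- function(params, config, codes, labels, frac = 0.5,
                              kmers_per_target = 8L) {
  K <- config$kernel_size
  L <- config$window_len
  bin_len <- min(200L, L)
  lo <- (L - bin_len) %/% 2L + 1L
  hi <- lo + bin_len - 1L
  base_chr <- c("N", "A", "C", "G", "T")
  central <- apply(codes[, lo:hi, drop = FALSE], 1, function(r) {
    paste(base_chr[r + 1L], collapse = "")
  })
  kmer_counts <- function(strs) {
    if (length(strs) == 0) return(table(character()))
    km <- unlist(lapply(strs, function(s) {
      n <- nchar(s)
      if (n < K) return(character())
      substring(s, seq_len(n - K + 1L), seq_len(n - K + 1L) + K - 1L)
    }))
    table(km)
  }
  picked <- character()
  for (j in seq_len(ncol(labels))) {
    pos <- kmer_counts(central[labels[, j] == 1])
    neg <- kmer_counts(central[labels[, j] == 0])
    if (length(pos) == 0) next
    all_k <- names(pos)
    p <- as.numeric(pos[all_k])
    q <- as.numeric(neg[all_k])
    q[is.na(q)] <- 0
    score <- (p + 1) / (sum(p) + 1) / ((q + 1) / (sum(q) + 1))
    ord <- order(score, decreasing = TRUE)
    picked <- c(picked, all_k[utils::head(ord, kmers_per_target)])
  }
  picked <- unique(picked[!grepl("N", picked)])
  n_seed <- min(length(picked), max(1L, floor(config$conv_filters[1] * frac)))
  if (n_seed == 0) return(params)
  E <- params$embed
  D <- config$embed_dim
  for (f in seq_len(n_seed)) {
    kmer <- strsplit(picked[f], "")[[1]]
    cds <- match(kmer, base_chr) - 1L
    Wf <- matrix(0, K * D, 1)
    for (k in seq_len(K)) {
      e <- E[cds[k] + 1L, ]
      # matched filter: unit response per matching base, so a full match
      # scores K and chance partial matches about K/4
      Wf[((k - 1L) * D + 1L):(k * D), 1] <- e / sum(e^2)
    }
    params$conv1_W[, f] <- Wf
    # negative bias suppresses partial-match background, keeping seeded
    # channels sparse and their signal well above optimizer drift
    params$conv1_b[1, f] <- -0.4 * K
  }
  params
}

#' Extract and encode model windows for a set of bins
#'
#' @param genome A `genome_index`.
#' @param matrix A `label_matrix`.
#' @param idx Integer bin indices (rows of `matrix$bins`).
#' @param config A `model_config` (supplies window/bin geometry).
#' @return Integer code matrix, `length(idx)` x `window_len`.
#' @export
windows_for_bins <- function(genome, matrix, idx, config) {
  bins <- matrix$bins[idx, , drop = FALSE]
  bin_len <- unique(bins$end - bins$start)
  if (length(bin_len) == 0) bin_len <- 200L
  stopifnot(length(bin_len) == 1)
  flank <- config$window_len - bin_len
  out <- base::matrix(0L, nrow = nrow(bins), ncol = config$window_len)
  for (i in seq_len(nrow(bins))) {
    w <- extract_window(genome, bins$chrom[i], bins$start[i],
                        bin_len = bin_len, flank_total = flank)
    out[i, ] <- encode_sequence(w)$codes
  }
  out
}

#' Train the network on a binned multi-label dataset
#'
#' Minimizes mean per-label binary cross-entropy with Adam, logging training
#' loss, validation loss and validation mean AUROC per epoch. Fully
#' reproducible given `config$seed`.
#'
#' @param config A `train_config`.
#' @param model_config A `model_config`; `n_targets` must equal the number
#'   of targets in `matrix`.
#' @param split A `dataset_split`.
#' @param matrix A `label_matrix`.
#' @param genome A `genome_index`.
#' @return A `trained_model`: list with `params`, `model_config`, `log`
#'   (data.frame epoch/train_loss/val_loss/val_mean_auroc), `targets`.
#' @export
train_model <- function(config, model_config, split, matrix, genome) {
  stopifnot(inherits(config, "train_config"),
            inherits(model_config, "model_config"))
  if (length(split$train) == 0) stop("empty training set")
  if (model_config$n_targets != nrow(matrix$targets)) {
    stop("model n_targets (", model_config$n_targets,
         ") != targets in matrix (", nrow(matrix$targets), ")")
  }
  tr_codes <- windows_for_bins(genome, matrix, split$train, model_config)
  tr_y <- matrix$values[split$train, , drop = FALSE]
  if (length(split$validation) > 0) {
    va_codes <- windows_for_bins(genome, matrix, split$validation,
                                 model_config)
    va_y <- matrix$values[split$validation, , drop = FALSE]
  } else {
    va_codes <- base::matrix(0L, 0, model_config$window_len)
    va_y <- base::matrix(0, 0, model_config$n_targets)
  }
  params <- init_params(model_config, seed = config$seed)
  if (identical(config$conv_init, "seeded")) {
    params <- seed_conv_filters(params, model_config, tr_codes, tr_y)
  }
  fit <- cpp_train(tr_codes, tr_y * 1.0, va_codes, va_y * 1.0, params,
                   unclass(model_config), config$epochs, config$batch_size,
                   config$learning_rate, config$seed, config$patience,
                   config$weight_decay %||% 0, config$dropout %||% 0)
  n_ep <- length(fit$train_loss)
  val_auc <- rep(NA_real_, n_ep)
  if (length(split$validation) > 0) {
    for (e in seq_len(n_ep)) {
      aucs <- vapply(seq_len(ncol(va_y)), function(j) {
        auroc(fit$val_probs[[e]][, j], va_y[, j])
      }, numeric(1))
      val_auc[e] <- mean(aucs, na.rm = TRUE)
    }
  }
  structure(list(params = fit$params, model_config = model_config,
                 targets = matrix$targets,
                 log = data.frame(epoch = seq_len(n_ep),
                                  train_loss = fit$train_loss,
                                  val_loss = fit$val_loss,
                                  val_mean_auroc = val_auc)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  n <- nrow(x$log)
  cat("trained_model:", x$model_config$n_targets, "targets,", n, "epochs;",
      "final train loss", signif(x$log$train_loss[n], 4))
  if (!is.na(x$log$val_mean_auroc[n])) {
    cat(", final validation mean AUROC", signif(x$log$val_mean_auroc[n], 4))
  }
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return AUROC in \[0, 1\], or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (PR-AUC)
#'
#' Step-wise average precision over distinct score thresholds:
#' `sum_i (R_i - R_{i-1}) P_i`. A constant-score predictor has a single
#' threshold at recall 1 and precision equal to prevalence, so its average
#' precision equals the positive-class prevalence exactly.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return Average precision in \[0, 1\]; 0 if there are no positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0) return(0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # threshold boundaries: last index of each distinct score
  bound <- which(c(s[-length(s)] != s[-1], TRUE))
  tp <- cumsum(y)[bound]
  n_pred <- bound
  prec <- tp / n_pred
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Baseline PR-AUC of a no-skill classifier
#'
#' Equal to the positive-class prevalence `N+ / (N+ + N-)`.
#'
#' @param labels Binary labels.
#' @return Fraction in \[0, 1\].
#' @export
baseline_prauc <- function(labels) {
  stopifnot(length(labels) >= 1)
  mean(as.integer(labels))
}

#' Per-target evaluation report from scores
#'
#' @param scores Matrix of prediction scores, bins x targets.
#' @param labels Binary label matrix of the same shape.
#' @param targets data.frame with `target_id`, `assay_class`.
#' @return An `eval_report` data.frame with columns target_id, assay_class,
#'   auroc, prauc, baseline; attribute `class_means` holds per-assay-class
#'   means over defined targets.
#' @export
eval_from_scores <- function(scores, labels, targets) {
  stopifnot(ncol(scores) == nrow(targets), all(dim(scores) == dim(labels)))
  rep <- data.frame(
    target_id = targets$target_id,
    assay_class = targets$assay_class,
    auroc = vapply(seq_len(ncol(scores)),
                   function(j) auroc(scores[, j], labels[, j]), numeric(1)),
    prauc = vapply(seq_len(ncol(scores)), function(j) {
      if (sum(labels[, j] == 1) == 0 || sum(labels[, j] == 0) == 0) {
        NA_real_
      } else {
        average_precision(scores[, j], labels[, j])
      }
    }, numeric(1)),
    baseline = colMeans(labels),
    stringsAsFactors = FALSE
  )
  if (all(is.na(rep$auroc))) {
    stop("no target has both classes present in the evaluated bin set")
  }
  defined <- !is.na(rep$auroc)
  cm <- stats::aggregate(rep[defined, c("auroc", "prauc", "baseline")],
                         by = list(assay_class = rep$assay_class[defined]),
                         FUN = mean)
  attr(rep, "class_means") <- cm
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Evaluate a trained model on a bin set
#'
#' Computes per-target AUROC (rank-based), PR-AUC (average precision) and
#' baseline PR-AUC (prevalence) over the given bins; targets with a single
#' class in the bin set are reported as `NA` and excluded from class means.
#'
#' @param model A `trained_model` (or list with `params`, `model_config`).
#' @param matrix A `label_matrix`.
#' @param genome A `genome_index`.
#' @param bins Integer bin indices to evaluate on.
#' @return An `eval_report`; see [eval_from_scores()].
#' @export
evaluate_model <- function(model, matrix, genome, bins) {
  codes <- windows_for_bins(genome, matrix, bins, model$model_config)
  scores <- predict_labels(codes, model$params, model$model_config)
  eval_from_scores(scores, matrix$values[bins, , drop = FALSE],
                   matrix$targets)
}

#' Write an evaluation report as TSV
#' @param report An `eval_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
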