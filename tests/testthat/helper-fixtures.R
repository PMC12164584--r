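# Shared fixtures: tiny genomes built in code, plus a memoized run of the
# desk-scale planted-motif experiment (reused across test files).

make_genome <- function(...) {
  genome_index(c(...))
}

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force per-base overlap of an interval set with a bin
brute_overlap <- function(intervals, bin_start, bin_end) {
  covered <- logical(bin_end - bin_start)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(intervals$start[i], bin_start)
    hi <- min(intervals$end[i], bin_end)
    if (lo < hi) covered[(lo - bin_start + 1):(hi - bin_start)] <- TRUE
  }
  sum(covered)
}

# naive triple-loop layer oracles (independent of the C++ path)
oracle_conv1d <- function(X, W, b, relu = TRUE) {
  K <- dim(W)[1]; D <- dim(W)[2]; F <- dim(W)[3]
  L <- nrow(X) - K + 1
  Y <- matrix(0, L, F)
  for (t in seq_len(L)) {
    for (f in seq_len(F)) {
      acc <- b[f]
      for (k in seq_len(K)) {
        for (d in seq_len(D)) acc <- acc + W[k, d, f] * X[t + k - 1, d]
      }
      Y[t, f] <- if (relu) max(0, acc) else acc
    }
  }
  Y
}

oracle_max_pool <- function(Y, p, s, ceil_mode = TRUE) {
  n <- nrow(Y)
  m <- if (ceil_mode) ceiling(n / s) else (n - p) %/% s + 1
  Z <- matrix(0, m, ncol(Y))
  for (t in seq_len(m)) {
    a <- (t - 1) * s + 1
    b <- min(a + p - 1, n)
    for (f in seq_len(ncol(Y))) Z[t, f] <- max(Y[a:b, f])
  }
  Z
}

oracle_attention_single_head <- function(X, Wq, bq, Wk, bk, Wv, bv) {
  Q <- sweep(X %*% Wq, 2, bq, "+")
  K <- sweep(X %*% Wk, 2, bk, "+")
  V <- sweep(X %*% Wv, 2, bv, "+")
  dk <- ncol(X)
  S <- Q %*% t(K) / sqrt(dk)
  A <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  if (nrow(S) == 1) A <- matrix(A, 1)  # apply() drops dims
  A %*% V
}

# memoized desk-scale experiment runs, keyed by training seed
.experiment_cache <- new.env(parent = emptyenv())
get_experiment <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.experiment_cache[[key]])) {
    .experiment_cache[[key]] <- run_synthetic_experiment(train_seed = seed)
  }
  .experiment_cache[[key]]
}

# a tiny trained-model stand-in with random parameters (no training)
tiny_random_model <- function(n_targets = 2, seed = 5) {
  cfg <- model_config(n_targets = n_targets, window_len = 60, embed_dim = 8,
                      kernel_size = 5, conv_filters = c(6L, 4L),
                      pool_size = 2, pool_stride = 2, attn_heads = 2,
                      attn_layers = 1)
  structure(list(params = init_params(cfg, seed = seed), model_config = cfg,
                 targets = data.frame(
                   target_id = paste0("t", seq_len(n_targets)),
                   assay_class = rep("tf_binding", n_targets))),
            class = "trained_model")
}
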