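#' Model architecture configuration
#'
#' Collects every architecture hyperparameter of the sequence-to-labels
#' network. Defaults follow the reference architecture: 2000-bp windows,
#' 128-dim embeddings, kernel size 10, two conv blocks with 64 then 32
#' filters, non-overlapping max-pooling of size/stride 3, and multi-head
#' self-attention over the pooled feature map with channel width equal to the
#' last conv filter count.
#'
#' @param n_targets Number of output labels (required).
#' @param window_len Input window length in bp.
#' @param embed_dim Embedding dimension (must be even for the sinusoidal
#'   positional encoding).
#' @param kernel_size Convolution kernel width in positions.
#' @param conv_filters Integer vector of length 2: filters of the two conv
#'   blocks.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param attn_heads Number of attention heads; must divide
#'   `conv_filters[2]`.
#' @param attn_layers Number of stacked attention layers.
#' @param head_hidden_units Optional hidden dense layer size between the
#'   squeezed position vector and the output layer; 0 disables it.
#' @param ceil_pool If `TRUE` (default) pooled length is
#'   `ceiling(n / stride)` and a trailing partial window maxes over the
#'   remaining elements; if `FALSE`, the usual `floor((n - pool)/stride) + 1`
#'   valid-window count is used.
#' @param attn_residual Add residual (skip) connections around each attention
#'   layer. Off by default.
#' @return A `model_config` list.
#' @export
model_config <- function(n_targets,
                         window_len = 2000L,
                         embed_dim = 128L,
                         kernel_size = 10L,
                         conv_filters = c(64L, 32L),
                         pool_size = 3L,
                         pool_stride = 3L,
                         attn_heads = 8L,
                         attn_layers = 2L,
                         head_hidden_units = 0L,
                         ceil_pool = TRUE,
                         attn_residual = FALSE) {
  stopifnot(length(conv_filters) == 2, all(conv_filters > 0),
            n_targets >= 1, window_len > kernel_size, embed_dim > 0,
            pool_size > 0, pool_stride > 0, attn_heads > 0, attn_layers >= 0)
  if (embed_dim %% 2 != 0) stop("embed_dim must be even")
  if (conv_filters[2] %% attn_heads != 0) {
    stop("attention channel width (", conv_filters[2],
         ") must be divisible by attn_heads (", attn_heads, ")")
  }
  cfg <- list(window_len = as.integer(window_len),
              embed_dim = as.integer(embed_dim),
              kernel_size = as.integer(kernel_size),
              conv_filters = as.integer(conv_filters),
              pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              conv_stride = 1L,
              attn_heads = as.integer(attn_heads),
              attn_layers = as.integer(attn_layers),
              attn_dim = as.integer(conv_filters[2]),
              n_targets = as.integer(n_targets),
              head_hidden_units = as.integer(head_hidden_units),
              ceil_pool = isTRUE(ceil_pool),
              attn_residual = isTRUE(attn_residual))
  class(cfg) <- "model_config"
  cfg
}

pooled_length <- function(n, pool, stride, ceil_pool = TRUE) {
  if (ceil_pool) ceiling(n / stride) else (n - pool) %/% stride + 1L
}

#' Per-layer position counts of the network
#'
#' Bookkeeping of the sequence-length axis through the pipeline:
#' window -> conv1 (`L - k + 1`) -> pool (`ceiling(n/s)`) -> conv2 -> pool.
#'
#' @param config A `model_config`.
#' @return Named integer vector with elements `window`, `conv1`, `pool1`,
#'   `conv2`, `pool2`.
#' @export
layer_lengths <- function(config) {
  l1 <- config$window_len - config$kernel_size + 1L
  p1 <- pooled_length(l1, config$pool_size, config$pool_stride,
                      config$ceil_pool)
  l2 <- p1 - config$kernel_size + 1L
  p2 <- pooled_length(l2, config$pool_size, config$pool_stride,
                      config$ceil_pool)
  c(window = config$window_len, conv1 = as.integer(l1), pool1 = as.integer(p1),
    conv2 = as.integer(l2), pool2 = as.integer(p2))
}

#' Sinusoidal positional encoding matrix
#'
#' `PE(p, 2i) = sin(p / 10000^(2i/dim))`, `PE(p, 2i+1) = cos(p /
#' 10000^(2i/dim))` for positions `p = 0..seqlen-1`. Consecutive sin/cos
#' columns at any position lie on the unit circle.
#'
#' @param seqlen Number of positions.
#' @param dim Encoding dimension (even).
#' @return `seqlen` x `dim` matrix.
#' @export
positional_encoding <- function(seqlen, dim) {
  stopifnot(seqlen >= 1, dim >= 2, dim %% 2 == 0)
  cpp_positional_encoding(as.integer(seqlen), as.integer(dim))
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, uniform(-0.05, 0.05) embeddings;
#' fully determined by `seed`.
#'
#' @param config A `model_config`.
#' @param seed Integer RNG seed.
#' @return Named list of parameter matrices (conv weights stored flattened as
#'   `kernel*channels x filters` with row index `k*channels + d`).
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(seed)
  D <- config$embed_dim
  K <- config$kernel_size
  f <- config$conv_filters
  C <- config$attn_dim
  P2 <- layer_lengths(config)[["pool2"]]
  # Base embeddings start mutually orthogonal (bases are categorical; no
  # similarity is assumed a priori) and scaled to the positional-encoding
  # amplitude so nucleotide identity is not drowned by the positional term.
  # N sits at the origin: an unknown base carries no sequence signal.
  Q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
  embed0 <- rbind(0, t(Q[, 1:4]) * sqrt(D / 2))
  params <- list(
    embed = embed0,
    conv1_W = glorot(K * D, f[1]),
    conv1_b = matrix(0, 1, f[1]),
    conv2_W = glorot(K * f[1], f[2]),
    conv2_b = matrix(0, 1, f[2])
  )
  for (l in seq_len(config$attn_layers)) {
    params[[paste0("attn", l, "_Wq")]] <- glorot(C, C)
    params[[paste0("attn", l, "_bq")]] <- matrix(0, 1, C)
    params[[paste0("attn", l, "_Wk")]] <- glorot(C, C)
    params[[paste0("attn", l, "_bk")]] <- matrix(0, 1, C)
    params[[paste0("attn", l, "_Wv")]] <- glorot(C, C)
    params[[paste0("attn", l, "_bv")]] <- matrix(0, 1, C)
  }
  params$head_W <- glorot(C, 1)
  params$head_b <- matrix(0, 1, 1)
  if (config$head_hidden_units > 0) {
    H <- config$head_hidden_units
    params$hid_W <- glorot(P2, H)
    params$hid_b <- matrix(0, 1, H)
    params$out_W <- glorot(H, config$n_targets)
  } else {
    params$out_W <- glorot(P2, config$n_targets)
  }
  params$out_b <- matrix(0, 1, config$n_targets)
  params
}

flatten_conv_weights <- function(W) {
  if (is.matrix(W)) return(W)
  stopifnot(length(dim(W)) == 3)
  d <- dim(W)  # kernel x channels x filters
  matrix(aperm(W, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Valid 1D convolution with ReLU
#'
#' `Y[t, f] = ReLU(sum_{k, d} W[k, d, f] X[t + k, d] + b[f])`, stride 1, no
#' padding: output has `nrow(X) - kernel_size + 1` positions.
#'
#' @param X Input matrix, positions x channels.
#' @param W Weights: 3D array `kernel x channels x filters`, or the
#'   equivalent flattened `kernel*channels x filters` matrix.
#' @param b Bias vector of length `filters`.
#' @param kernel_size Kernel width.
#' @param relu Apply ReLU (default TRUE).
#' @return Matrix `(positions - kernel_size + 1) x filters`.
#' @export
conv1d <- function(X, W, b, kernel_size, relu = TRUE) {
  Wf <- flatten_conv_weights(W)
  cpp_conv1d(X, Wf, as.numeric(b), as.integer(kernel_size), relu)
}

#' 1D max pooling along the position axis
#'
#' Output length is `ceiling(n / stride)` when `ceil_mode` (a trailing
#' partial window takes the max over the remaining elements), else the
#' valid-window count `floor((n - pool_size)/stride) + 1`.
#'
#' @param Y Input matrix, positions x channels.
#' @param pool_size Window size.
#' @param stride Step between windows.
#' @param ceil_mode Use ceiling-length pooling (default TRUE).
#' @return Pooled matrix.
#' @export
max_pool1d <- function(Y, pool_size = 3L, stride = 3L, ceil_mode = TRUE) {
  cpp_max_pool1d(Y, as.integer(pool_size), as.integer(stride), ceil_mode)
}

#' Multi-head scaled dot-product self-attention
#'
#' Q, K, V are affine projections of `X`; each is split into `heads` blocks
#' along the channel axis, per-head attention is
#' `softmax(Q K' / sqrt(d_k)) V` with `d_k = channels / heads`, and head
#' outputs are concatenated.
#'
#' @param X Input matrix, positions x channels.
#' @param Wq,Wk,Wv Square projection matrices (channels x channels).
#' @param bq,bk,bv Bias vectors of length channels.
#' @param heads Number of heads (must divide the channel count).
#' @param residual Add `X` to the output (default FALSE).
#' @return Matrix of the same shape as `X`.
#' @export
multi_head_attention <- function(X, Wq, bq, Wk, bk, Wv, bv, heads,
                                 residual = FALSE) {
  if (ncol(X) %% heads != 0) stop("channels not divisible by heads")
  cpp_multi_head_attention(X, Wq, as.numeric(bq), Wk, as.numeric(bk),
                           Wv, as.numeric(bv), as.integer(heads), residual)
}

as_code_matrix <- function(x, window_len) {
  if (inherits(x, "encoded_sequence")) {
    m <- matrix(x$codes, nrow = 1)
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(e) {
      if (inherits(e, "encoded_sequence")) e$codes else as.integer(e)
    }))
  } else if (is.matrix(x)) {
    m <- x
  } else {
    m <- matrix(as.integer(x), nrow = 1)
  }
  storage.mode(m) <- "integer"
  if (ncol(m) != window_len) {
    stop("sequence length ", ncol(m), " != window_len ", window_len)
  }
  if (any(m < 0L | m > 4L)) stop("nucleotide codes must lie in {0,..,4}")
  m
}

#' Forward pass: predicted label probabilities
#'
#' Runs the full pipeline (embedding + masked positional encoding, two
#' conv/pool blocks, attention stack, position-wise dense + squeeze, output
#' dense + sigmoid). Deterministic given fixed parameters.
#'
#' @param x An `encoded_sequence`, a list of them, or an integer code matrix
#'   (sequences x positions).
#' @param params Parameter list from [init_params()] or [train_model()].
#' @param config The `model_config` used to create the parameters.
#' @return Matrix `n_sequences x n_targets` of probabilities in (0, 1).
#' @export
predict_labels <- function(x, params, config) {
  m <- as_code_matrix(x, config$window_len)
  p <- cpp_forward(m, params, unclass(config))
  colnames(p) <- names(params$out_b) # usually NULL; targets tracked elsewhere
  p
}

#' Save model parameters and config as plain text
#'
#' Writes `config.json` plus one whitespace-delimited text file per parameter
#' matrix into `dir`.
#'
#' @param params Parameter list.
#' @param config A `model_config`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(params, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(params)) {
    utils::write.table(format(params[[nm]], digits = 17, scientific = TRUE,
                              trim = TRUE),
                       file.path(dir, paste0("param_", nm, ".txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a model saved by [save_model()]
#' @param dir Checkpoint directory.
#' @return List with `params` and `config`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- model_config(
    n_targets = cfg$n_targets, window_len = cfg$window_len,
    embed_dim = cfg$embed_dim, kernel_size = cfg$kernel_size,
    conv_filters = cfg$conv_filters, pool_size = cfg$pool_size,
    pool_stride = cfg$pool_stride, attn_heads = cfg$attn_heads,
    attn_layers = cfg$attn_layers, head_hidden_units = cfg$head_hidden_units,
    ceil_pool = cfg$ceil_pool, attn_residual = cfg$attn_residual)
  files <- list.files(dir, pattern = "^param_.*\\.txt$")
  params <- list()
  for (f in files) {
    nm <- sub("^param_(.*)\\.txt$", "\\1", f)
    params[[nm]] <- as.matrix(utils::read.table(file.path(dir, f),
                                                header = FALSE))
  }
  # restore canonical parameter order
  ord <- names(init_params(config, seed = 1L))
  stopifnot(setequal(ord, names(params)))
  params <- params[ord]
  params <- lapply(params, function(m) {
    dimnames(m) <- NULL
    m
  })
  list(params = params, config = config)
}
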