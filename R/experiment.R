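# Desk-scale planted-motif experiment: one self-contained run of the whole
# pipeline (simulate -> bin/label -> train -> evaluate -> mutagenize) sized
# for a single CPU. Shared by the test suite and the acceptance script.

#' Compact model configuration for desk-scale experiments
#'
#' Same architecture as the default configuration, scaled down for small
#' synthetic datasets: 400-bp windows (the 200-bp bin with 100-bp flanks),
#' 16-dim embeddings, 32/16 conv filters, one 4-head attention layer with
#' residual connections. The full-scale defaults (2000-bp windows, 128-dim,
#' 64/32 filters) are in [model_config()].
#'
#' @param n_targets Number of output labels.
#' @return A `model_config`.
#' @export
compact_model_config <- function(n_targets) {
  model_config(n_targets = n_targets, window_len = 400L, embed_dim = 16L,
               conv_filters = c(32L, 16L), attn_heads = 4L, attn_layers = 1L,
               attn_residual = TRUE)
}

#' Compact training configuration for desk-scale experiments
#'
#' Eight epochs of Adam at learning rate 1e-3, batch size 16, with light
#' weight decay, dropout on the squeezed position vector, and k-mer-seeded
#' first-layer filters (see [seed_conv_filters()]).
#'
#' @param seed RNG seed.
#' @param epochs Number of epochs (default 8).
#' @return A `train_config`.
#' @export
compact_train_config <- function(seed = 1L, epochs = 8L) {
  train_config(epochs = epochs, batch_size = 16L, learning_rate = 1e-3,
               seed = seed, weight_decay = 1e-4, dropout = 0.2,
               conv_init = "seeded")
}

#' Run the planted-motif recovery experiment
#'
#' Simulates the default synthetic universe (genome with planted motifs,
#' derived narrowPeak tracks, effect-labelled variants), builds the full-grid
#' 200-bp binned dataset, trains the compact model with one chromosome held
#' out for validation and one for testing, evaluates on the held-out test
#' chromosome, and scores every simulated variant by in-silico mutagenesis.
#'
#' @param train_seed Seed for initialization/shuffling of the training run.
#' @param spec A `synthetic_spec` (default: package defaults).
#' @param dir Directory for the intermediate fixture files (default: a
#'   fresh temporary directory).
#' @param epochs Training epochs (default 8).
#' @return List with `fit` (trained model), `report` (test-set
#'   `eval_report`), `test_mean_auroc`, `sad` (per-variant `sad_result`),
#'   `sad_by_label` (data.frame id, label, max_sad), `matrix`, `split`,
#'   `fixture`.
#' @export
run_synthetic_experiment <- function(train_seed = 1L,
                                     spec = synthetic_spec(),
                                     dir = tempfile("synthfix"),
                                     epochs = 8L) {
  fx <- simulate_fixture(spec, dir)
  tracks <- read_track_manifest(fx$manifest)
  mat <- label_bins(fx$genome, tracks, keep_all_bins = TRUE)
  split <- split_by_chromosome(mat, val_chroms = "chrS2",
                               test_chroms = "chrS3")
  mcfg <- compact_model_config(n_targets = nrow(mat$targets))
  tcfg <- compact_train_config(seed = train_seed, epochs = epochs)
  fit <- train_model(tcfg, mcfg, split, mat, fx$genome)
  report <- evaluate_model(fit, mat, fx$genome, split$test)
  sad <- sad_scores(fit, fx$genome, fx$variants)
  ok <- sad[is.na(sad$error), , drop = FALSE]
  max_sad <- stats::aggregate(list(max_sad = ok$sad), by = list(id = ok$id),
                              FUN = max)
  sad_by_label <- merge(max_sad, fx$labels, by = "id")
  list(fit = fit, report = report,
       test_mean_auroc = mean(report$auroc, na.rm = TRUE),
       sad = sad, sad_by_label = sad_by_label, matrix = mat, split = split,
       fixture = fx)
}
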