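#' Build a negative (non-regulatory) variant pool by exclusion filtering
#'
#' Starting from a candidate variant set (in production, a random draw from
#' a population panel such as 1000 Genomes), removes (i) variants whose rsID
#' appears in any exclusion list (e.g. GWAS-associated or eQTL variants) and
#' (ii) variants falling inside any exclusion interval set (e.g. exonic
#' regions, candidate cis-regulatory elements). Counts removed per filter
#' are reported via `message()`.
#'
#' @param candidates A `variant_table`.
#' @param exclude_ids Named list of character vectors of rsIDs to exclude.
#' @param exclude_intervals Named list of interval data.frames (chrom,
#'   start, end; 0-based half-open) to exclude.
#' @return A `variant_table` (the pool); errors if empty after filtering.
#' @export
build_negative_pool <- function(candidates, exclude_ids = list(),
                                exclude_intervals = list()) {
  stopifnot(nrow(candidates) > 0)
  keep <- rep(TRUE, nrow(candidates))
  for (nm in names(exclude_ids)) {
    hit <- candidates$id %in% exclude_ids[[nm]]
    message("exclusion list '", nm, "': removed ", sum(hit & keep))
    keep <- keep & !hit
  }
  pos0 <- candidates$pos - 1L
  for (nm in names(exclude_intervals)) {
    iv <- exclude_intervals[[nm]]
    hit <- rep(FALSE, nrow(candidates))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (candidates$chrom == iv$chrom[i] & pos0 >= iv$start[i] &
                      pos0 < iv$end[i])
    }
    message("exclusion intervals '", nm, "': removed ", sum(hit & keep))
    keep <- keep & !hit
  }
  pool <- candidates[keep, , drop = FALSE]
  if (nrow(pool) == 0) stop("negative pool is empty after filtering")
  pool
}

#' Empirical E-value of one variant's SAD scores against a negative pool
#'
#' For each of `n_resamples` seeded resamples (without replacement, size
#' `resample_size`) of the negative pool, the per-target E-value is the
#' fraction of sampled negatives whose SAD for that target is strictly
#' greater than the positive variant's SAD; the mean over resamples is
#' returned. Resample `r` uses seed `seed + r - 1` for auditability.
#'
#' @param positive_sad Named numeric vector: the variant's SAD per target.
#' @param pool_sad Numeric matrix of negative-pool SAD scores, variants x
#'   targets (columns matching `positive_sad`).
#' @param resample_size Negatives drawn per resample; by convention equal to
#'   the size of the positive variant set. Defaults to the full pool.
#' @param n_resamples Number of resamples (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector of mean E-values per target, with attribute
#'   `resolution` = `1 / resample_size` (the smallest attainable nonzero E).
#' @export
evalue <- function(positive_sad, pool_sad, resample_size = nrow(pool_sad),
                   n_resamples = 10L, seed = 1L) {
  stopifnot(length(positive_sad) == ncol(pool_sad))
  n_pool <- nrow(pool_sad)
  if (resample_size > n_pool) {
    stop("resample_size (", resample_size, ") exceeds pool size (",
         n_pool, ")")
  }
  stopifnot(resample_size >= 1, n_resamples >= 1)
  acc <- numeric(length(positive_sad))
  for (r in seq_len(n_resamples)) {
    set.seed(as.integer(seed) + r - 1L)
    idx <- sample.int(n_pool, resample_size, replace = FALSE)
    exceed <- colSums(pool_sad[idx, , drop = FALSE] >
                        matrix(positive_sad, nrow = resample_size,
                               ncol = length(positive_sad), byrow = TRUE))
    acc <- acc + exceed / resample_size
  }
  e <- acc / n_resamples
  names(e) <- colnames(pool_sad)
  attr(e, "resolution") <- 1 / resample_size
  e
}

#' Mean E-values for a set of positive variants
#'
#' Applies [evalue()] to each positive variant; negative resamples are
#' redrawn per variant under one master seed (variant `v` uses seeds
#' `seed + (v-1)*n_resamples`, ..., `+ n_resamples - 1`).
#'
#' @param positive_sad Matrix of positive-variant SAD scores, variants x
#'   targets (rownames = variant ids).
#' @param pool_sad Matrix of negative-pool SAD scores, variants x targets.
#' @param resample_size Negatives per resample; defaults to
#'   `nrow(positive_sad)` (same number of positive and negative variants),
#'   capped at the pool size.
#' @param n_resamples Number of resamples (default 10).
#' @param seed Master seed.
#' @param threshold Significance threshold on the mean E-value (default
#'   1e-5, inclusive).
#' @return An `evalue_report` data.frame: id, target_id, mean_evalue,
#'   significant; attributes `resample_size`, `n_resamples`, `seed`,
#'   `threshold`, `resolution`.
#' @export
evalue_report <- function(positive_sad, pool_sad,
                          resample_size = NULL, n_resamples = 10L,
                          seed = 1L, threshold = 1e-5) {
  stopifnot(ncol(positive_sad) == ncol(pool_sad))
  if (is.null(resample_size)) {
    resample_size <- min(nrow(positive_sad), nrow(pool_sad))
  }
  ids <- rownames(positive_sad)
  if (is.null(ids)) ids <- paste0("variant_", seq_len(nrow(positive_sad)))
  rows <- vector("list", nrow(positive_sad))
  for (v in seq_len(nrow(positive_sad))) {
    e <- evalue(positive_sad[v, ], pool_sad, resample_size, n_resamples,
                seed = as.integer(seed) + (v - 1L) * as.integer(n_resamples))
    rows[[v]] <- data.frame(id = ids[v], target_id = colnames(pool_sad),
                            mean_evalue = as.numeric(e),
                            stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  rep$significant <- rep$mean_evalue <= threshold
  attr(rep, "resample_size") <- resample_size
  attr(rep, "n_resamples") <- n_resamples
  attr(rep, "seed") <- seed
  attr(rep, "threshold") <- threshold
  attr(rep, "resolution") <- 1 / resample_size
  class(rep) <- c("evalue_report", class(rep))
  rep
}

#' Significance calls from an E-value report
#'
#' A (variant, target) pair is significant if its mean E-value is at or
#' below the threshold (inclusive); a variant is significant if at least
#' one of its targets is.
#'
#' @param report An `evalue_report` (or data.frame with id, target_id,
#'   mean_evalue).
#' @param threshold Inclusive threshold (default 1e-5).
#' @return List with `flags` (the report with a recomputed `significant`
#'   column) and `by_variant` (data.frame id, n_significant_labels,
#'   significant, sorted by descending label count).
#' @export
call_significant <- function(report, threshold = 1e-5) {
  report$significant <- report$mean_evalue <= threshold
  agg <- stats::aggregate(list(n_significant_labels = report$significant),
                          by = list(id = report$id), FUN = sum)
  agg$significant <- agg$n_significant_labels >= 1
  agg <- agg[order(-agg$n_significant_labels, agg$id), , drop = FALSE]
  rownames(agg) <- NULL
  list(flags = report, by_variant = agg)
}

#' Read one-per-line rsID exclusion lists
#' @param path Text file with one identifier per line.
#' @return Character vector.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Write an E-value report (and per-variant summary) as TSV
#' @param report An `evalue_report`.
#' @param path Output TSV for per-(variant, target) rows.
#' @param summary_path Optional output TSV for the per-variant summary.
#' @return `path`, invisibly.
#' @export
write_evalue_tsv <- function(report, path, summary_path = NULL) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    cs <- call_significant(report, attr(report, "threshold") %||% 1e-5)
    utils::write.table(cs$by_variant, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
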