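ASSAY_CLASSES <- c("chromatin_accessibility", "histone_modification",
                   "tf_binding")

#' Parse a narrowPeak (BED6+4) track
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used for labelling; the remaining narrowPeak columns are accepted and
#' ignored, and plain 3-column BED is accepted too.
#'
#' @param path Path to a narrowPeak/BED file.
#' @param target_id Label identifier, conventionally "sample | assay".
#' @param assay_class One of `"chromatin_accessibility"`,
#'   `"histone_modification"`, `"tf_binding"`.
#' @return A `label_track`: list with `target_id`, `assay_class` and an
#'   `intervals` data.frame (chrom, start, end) sorted within chromosome.
#' @export
parse_narrowpeak <- function(path, target_id, assay_class) {
  assay_class <- match.arg(assay_class, ASSAY_CLASSES)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    iv <- data.frame(chrom = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
    return(label_track(target_id, assay_class, iv))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) stop("narrowPeak line with fewer than 3 columns in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinates in ", path)
  }
  if (any(start >= end)) stop("interval with start >= end in ", path)
  label_track(target_id, assay_class,
              data.frame(chrom = chrom, start = start, end = end,
                         stringsAsFactors = FALSE))
}

#' Construct a label track from intervals
#' @param target_id Label identifier.
#' @param assay_class Assay class string.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return A `label_track` object.
#' @export
label_track <- function(target_id, assay_class, intervals) {
  assay_class <- match.arg(assay_class, ASSAY_CLASSES)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0) {
    stopifnot(all(intervals$start < intervals$end))
    intervals <- intervals[order(intervals$chrom, intervals$start), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(target_id = target_id, assay_class = assay_class,
                 intervals = intervals),
            class = "label_track")
}

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end)
  )
}

#' Label genomic bins from peak tracks
#'
#' Tiles every chromosome with non-overlapping `bin_len`-bp bins anchored at
#' coordinate 0 (a trailing partial bin is discarded) and assigns a binary
#' label per track: 1 iff the track's (merged) peak intervals cover strictly
#' more than half of the bin. Bins with no positive label are dropped, so the
#' dataset contains only bins overlapping at least one epigenomic feature;
#' per-label negatives arise from the multi-label structure.
#'
#' @param genome A `genome_index` (defines chromosome names and lengths).
#' @param tracks List of `label_track` objects.
#' @param bin_len Bin size in bp (default 200).
#' @param keep_all_bins If `FALSE` (default), bins with no positive label
#'   are dropped, so the dataset holds only bins overlapping at least one
#'   epigenomic feature; if `TRUE`, every grid bin is retained and
#'   feature-free bins contribute all-negative rows.
#' @return A `label_matrix`: list with `bins` (data.frame chrom/start/end),
#'   `targets` (data.frame target_id/assay_class) and binary `values`
#'   (bins x targets).
#' @export
label_bins <- function(genome, tracks, bin_len = 200L,
                       keep_all_bins = FALSE) {
  stopifnot(length(tracks) > 0)
  bin_len <- as.integer(bin_len)
  half <- bin_len / 2
  targets <- data.frame(
    target_id = vapply(tracks, `[[`, "", "target_id"),
    assay_class = vapply(tracks, `[[`, "", "assay_class"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(targets$target_id)) stop("duplicate target_id in tracks")
  if (keep_all_bins) {
    # full bin grid over every chromosome (trailing partial bins discarded)
    n_bins_chrom <- genome$chrom_sizes %/% bin_len
    cand <- list(data.frame(
      chrom = rep(names(n_bins_chrom), n_bins_chrom),
      start = unlist(lapply(n_bins_chrom, function(n) {
        seq.int(0L, length.out = n) * bin_len
      }), use.names = FALSE),
      stringsAsFactors = FALSE
    ))
  } else {
    # candidate bins: only those touched by some peak (bins elsewhere can
    # never be positive, and all-negative bins are dropped anyway)
    cand <- list()
    for (tr in tracks) {
      iv <- tr$intervals
      iv <- iv[iv$chrom %in% names(genome$chrom_sizes), , drop = FALSE]
      if (nrow(iv) == 0) next
      n_bins_chrom <- genome$chrom_sizes[iv$chrom] %/% bin_len
      first <- pmax(0L, iv$start %/% bin_len)
      last <- pmin(n_bins_chrom - 1L, (iv$end - 1L) %/% bin_len)
      keep <- first <= last
      if (!any(keep)) next
      idx <- mapply(seq.int, first[keep], last[keep], SIMPLIFY = FALSE)
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = rep(iv$chrom[keep], lengths(idx)),
        start = unlist(idx) * bin_len,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(cand) == 0 || sum(vapply(cand, nrow, 0L)) == 0) {
    return(label_matrix_obj(
      data.frame(chrom = character(), start = integer(), end = integer()),
      targets, matrix(0L, 0, nrow(targets))))
  }
  bins <- unique(do.call(rbind, cand))
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  bins$end <- bins$start + bin_len
  rownames(bins) <- NULL

  bin_gr <- bins_to_granges(bins)
  values <- matrix(0L, nrow = nrow(bins), ncol = length(tracks))
  for (j in seq_along(tracks)) {
    iv <- tracks[[j]]$intervals
    if (nrow(iv) == 0) next
    gr <- GenomicRanges::reduce(intervals_to_granges(iv))
    hits <- GenomicRanges::findOverlaps(bin_gr, gr)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      bin_gr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
    cov <- tapply(ov, S4Vectors::queryHits(hits), sum)
    pos <- as.integer(names(cov))[cov > half]
    values[pos, j] <- 1L
  }
  if (!keep_all_bins) {
    keep <- rowSums(values) > 0
    bins <- bins[keep, , drop = FALSE]
    values <- values[keep, , drop = FALSE]
  }
  label_matrix_obj(bins, targets, values)
}

label_matrix_obj <- function(bins, targets, values) {
  rownames(bins) <- NULL
  colnames(values) <- targets$target_id
  structure(list(bins = bins, targets = targets, values = values),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x$bins), "bins x", nrow(x$targets), "targets;",
      "positive fraction", round(mean(x$values), 4), "\n")
  invisible(x)
}

#' Remove bins overlapping low-mappability/blacklist regions
#'
#' A bin is removed if it overlaps any blacklist interval by at least 1 bp
#' (the strictest reading of mappability exclusion).
#'
#' @param matrix A `label_matrix`.
#' @param blacklist data.frame with chrom, start, end (0-based half-open),
#'   e.g. from [read_bed3()].
#' @return Filtered `label_matrix`.
#' @export
filter_blacklist <- function(matrix, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(matrix)
  hit <- IRanges::overlapsAny(bins_to_granges(matrix$bins),
                              intervals_to_granges(blacklist))
  label_matrix_obj(matrix$bins[!hit, , drop = FALSE], matrix$targets,
                   matrix$values[!hit, , drop = FALSE])
}

#' Read a 3-column BED file of intervals
#' @param path BED path (0-based half-open).
#' @return data.frame with chrom, start, end.
#' @export
read_bed3 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs >= 3 columns: ", path)
  data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Split bins into train/validation/test by chromosome
#'
#' Mirrors whole-chromosome hold-out: validation bins come from
#' `val_chroms`, test bins from `test_chroms`, everything else trains. This
#' limits positional leakage between the sets.
#'
#' @param matrix A `label_matrix`.
#' @param val_chroms Character vector of validation chromosomes
#'   (default "chr7").
#' @param test_chroms Character vector of test chromosomes (default "chr8").
#' @return A `dataset_split`: list of integer index vectors `train`,
#'   `validation`, `test` into the rows of `matrix`.
#' @export
split_by_chromosome <- function(matrix, val_chroms = "chr7",
                                test_chroms = "chr8") {
  if (length(intersect(val_chroms, test_chroms)) > 0) {
    stop("validation and test chromosome sets overlap")
  }
  chrom <- matrix$bins$chrom
  validation <- which(chrom %in% val_chroms)
  test <- which(chrom %in% test_chroms)
  train <- setdiff(seq_along(chrom), c(validation, test))
  if (length(validation) == 0) warning("validation set is empty")
  if (length(test) == 0) warning("test set is empty")
  structure(list(train = train, validation = validation, test = test),
            class = "dataset_split")
}

#' Positive-class prevalence of one target
#'
#' Returns N+ / (N+ + N-) over an evaluated bin set; this is also the PR-AUC
#' of a no-skill classifier for that target.
#'
#' @param matrix A `label_matrix`.
#' @param target A `target_id` present in the matrix.
#' @param bins Optional integer vector of bin indices to evaluate over
#'   (default: all bins).
#' @return Fraction in \[0, 1\].
#' @export
class_prevalence <- function(matrix, target, bins = NULL) {
  j <- match(target, matrix$targets$target_id)
  if (is.na(j)) stop("unknown target: ", target)
  v <- matrix$values[, j]
  if (!is.null(bins)) v <- v[bins]
  if (length(v) == 0) stop("no bins to evaluate")
  mean(v)
}

#' Persist a label matrix as plain-text artifacts
#'
#' Writes `values.mtx` (MatrixMarket sparse), `bins.tsv` and `targets.tsv`
#' into a directory.
#'
#' @param matrix A `label_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_label_matrix <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(matrix$values, sparse = TRUE),
                  file.path(dir, "values.mtx"))
  utils::write.table(matrix$bins, file.path(dir, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$targets, file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a label matrix saved by [save_label_matrix()]
#' @param dir Directory containing values.mtx, bins.tsv, targets.tsv.
#' @return A `label_matrix`.
#' @export
load_label_matrix <- function(dir) {
  values <- as.matrix(Matrix::readMM(file.path(dir, "values.mtx")))
  storage.mode(values) <- "integer"
  bins <- utils::read.table(file.path(dir, "bins.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  targets <- utils::read.table(file.path(dir, "targets.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  label_matrix_obj(bins, targets, values)
}

#' Read a track manifest and parse all referenced peak files
#'
#' The manifest is a TSV with columns `file`, `target_id`, `assay_class`;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return List of `label_track` objects.
#' @export
read_track_manifest <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("file", "target_id", "assay_class") %in% names(tab)))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    parse_narrowpeak(f, tab$target_id[i], tab$assay_class[i])
  })
}
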