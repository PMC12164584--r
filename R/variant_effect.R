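#' Construct a variant table
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (VCF convention).
#' @param ref,alt Single-base reference/alternate alleles in {A,C,G,T}.
#' @param id Variant identifiers (rsID or ".").
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, id = ".") {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
    stop("only single-nucleotide variants are supported; ",
         "indels/multi-base alleles must be removed upstream")
  }
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A, C, G or T")
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  id = rep_len(as.character(id), length(chrom)),
                  ref = ref, alt = alt, stringsAsFactors = FALSE)
  class(v) <- c("variant_table", class(v))
  v
}

#' Read variants from VCF or TSV
#'
#' VCF: the first five columns (CHROM, POS, ID, REF, ALT) are used;
#' multi-allelic records are split into one row per alternate allele and
#' non-SNV alleles are dropped with a message. TSV: columns chrom, pos, id,
#' ref, alt (with header).
#'
#' @param path Input path; format picked by extension (`.vcf` vs anything
#'   else) unless `format` is given.
#' @param format `"vcf"`, `"tsv"` or `"auto"`.
#' @return A `variant_table`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(tab)))
    return(variant_table(tab$chrom, tab$pos, tab$ref, tab$alt, tab$id))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) stop("no variant records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5)) stop("VCF record with fewer than 5 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  id <- vapply(fields, `[[`, "", 3L)
  ref <- toupper(vapply(fields, `[[`, "", 4L))
  alts <- strsplit(toupper(vapply(fields, `[[`, "", 5L)), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  chrom <- rep(chrom, n_alt); pos <- rep(pos, n_alt); id <- rep(id, n_alt)
  ref <- rep(ref, n_alt); alt <- unlist(alts)
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (any(!snv)) {
    message("dropping ", sum(!snv), " non-SNV allele(s)")
  }
  if (!any(snv)) stop("no SNVs left after filtering")
  variant_table(chrom[snv], pos[snv], ref[snv], alt[snv], id[snv])
}

#' Locate the 200-bp grid bin harboring a variant
#'
#' The bin grid is anchored at coordinate 0; a variant at 1-based position
#' `pos` falls in bin `[floor((pos-1)/bin_len)*bin_len, +bin_len)`.
#'
#' @param variant One-row `variant_table` (or list with chrom/pos).
#' @param genome A `genome_index` (for bounds checking).
#' @param bin_len Bin size (default 200).
#' @return List with `chrom`, `start`, `end` (0-based half-open).
#' @export
locate_bin <- function(variant, genome, bin_len = 200L) {
  chrom <- variant$chrom[1]
  pos <- variant$pos[1]
  if (!chrom %in% names(genome$chrom_sizes)) {
    stop("unknown chromosome: ", chrom)
  }
  if (pos < 1 || pos > genome$chrom_sizes[[chrom]]) {
    stop("position ", pos, " outside ", chrom)
  }
  start <- ((pos - 1L) %/% bin_len) * bin_len
  list(chrom = chrom, start = start, end = start + as.integer(bin_len))
}

#' Substitute a variant allele into an extracted window
#'
#' Applies the single-base substitution at offset `(pos - 1) - window_start`
#' after checking that the window carries the expected reference base; a
#' mismatch raises an error naming the observed and expected bases (guarding
#' against genome-build or liftover mistakes).
#'
#' @param window Nucleotide string.
#' @param variant One-row `variant_table`.
#' @param window_start 0-based genomic start of the window. Note that for
#'   windows produced by [extract_window()] near chromosome starts this is
#'   the *virtual* (possibly negative) start including N padding.
#' @return The mutated window string.
#' @export
apply_variant <- function(window, variant, window_start) {
  off <- (variant$pos[1] - 1L) - window_start  # 0-based offset in window
  if (off < 0 || off >= nchar(window)) {
    stop("variant position outside the window")
  }
  have <- substr(window, off + 1L, off + 1L)
  if (have != variant$ref[1]) {
    stop("reference allele mismatch at ", variant$chrom[1], ":",
         variant$pos[1], ": window has '", have, "', variant expects '",
         variant$ref[1], "'")
  }
  substr(window, off + 1L, off + 1L) <- variant$alt[1]
  window
}

#' SNP activity difference (SAD) scores by in-silico mutagenesis
#'
#' For each variant, extracts the 2000-bp window centered on the 200-bp bin
#' harboring it, predicts label probabilities for the reference and the
#' mutated window, and scores each label as `SAD = |P_ref - P_alt|`.
#' Reference-allele mismatches are collected per variant (reported in the
#' `error` column) without aborting the batch.
#'
#' @param model A `trained_model` (or list with `params`, `model_config`).
#' @param genome A `genome_index`.
#' @param variants A `variant_table`.
#' @param bin_len Bin size (default 200).
#' @return A `sad_result` data.frame with one row per (variant, target):
#'   columns id, chrom, pos, ref, alt, target_id, p_ref, p_alt, sad; failed
#'   variants appear once with `error` set and NA scores.
#' @export
sad_scores <- function(model, genome, variants, bin_len = 200L) {
  cfg <- model$model_config
  targets <- if (!is.null(model$targets)) model$targets$target_id else
    paste0("target_", seq_len(cfg$n_targets))
  flank <- cfg$window_len - bin_len
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    res <- tryCatch({
      bin <- locate_bin(v, genome, bin_len)
      w_ref <- extract_window(genome, bin$chrom, bin$start, bin_len, flank)
      w_start <- bin$start - flank %/% 2L  # virtual start incl. N padding
      w_alt <- apply_variant(w_ref, v, w_start)
      codes <- rbind(encode_sequence(w_ref)$codes,
                     encode_sequence(w_alt)$codes)
      p <- predict_labels(codes, model$params, cfg)
      data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref,
                 alt = v$alt, target_id = targets,
                 p_ref = p[1, ], p_alt = p[2, ], sad = abs(p[1, ] - p[2, ]),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref,
                 alt = v$alt, target_id = NA_character_, p_ref = NA_real_,
                 p_alt = NA_real_, sad = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sad_result", class(res))
  res
}

#' SAD results as a variant x target matrix
#'
#' @param sad A `sad_result` from [sad_scores()].
#' @return Numeric matrix, rows = variants (named by id), cols = targets;
#'   failed variants are dropped.
#' @export
sad_matrix <- function(sad) {
  ok <- sad[is.na(sad$error), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successfully scored variants")
  key <- paste(ok$chrom, ok$pos, ok$ref, ok$alt, sep = ":")
  ids <- unique(data.frame(key = key, id = ok$id,
                           stringsAsFactors = FALSE))
  targets <- unique(ok$target_id)
  m <- matrix(NA_real_, nrow(ids), length(targets),
              dimnames = list(ids$id, targets))
  m[cbind(match(key, ids$key), match(ok$target_id, targets))] <- ok$sad
  m
}

#' Exclude variants at conversion-unstable positions
#'
#' Removes variants whose (0-based) position falls inside any of the given
#' 0-based half-open intervals, e.g. positions that lift over inconsistently
#' between genome builds. The number removed is reported via `message()`.
#'
#' @param variants A `variant_table`.
#' @param cup_intervals data.frame with chrom, start, end (0-based
#'   half-open), or NULL for no filtering.
#' @return Filtered `variant_table`.
#' @export
filter_unstable_positions <- function(variants, cup_intervals) {
  if (is.null(cup_intervals) || nrow(cup_intervals) == 0) return(variants)
  pos0 <- variants$pos - 1L
  hit <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(cup_intervals))) {
    hit <- hit | (variants$chrom == cup_intervals$chrom[i] &
                    pos0 >= cup_intervals$start[i] &
                    pos0 < cup_intervals$end[i])
  }
  message("excluding ", sum(hit),
          " variant(s) at conversion-unstable positions")
  variants[!hit, , drop = FALSE]
}

#' Write SAD results as TSV
#' @param sad A `sad_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sad_tsv <- function(sad, path) {
  utils::write.table(sad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
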