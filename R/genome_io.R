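#' @useDynLib chromattn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Integer code for each base. Only N -> 0 is externally mandated (so that the
# model can mask unknown bases); the ACGT assignment is a fixed package
# constant.
BASE_CODES <- c(N = 0L, A = 1L, C = 2L, G = 3L, T = 4L)

#' Load a reference genome from FASTA
#'
#' Reads a (plain or bgzipped) FASTA file into an in-memory genome index:
#' uppercased sequences plus a chromosome-size table. Sequences may contain
#' only A, C, G, T and N after uppercasing.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_index` object: list with `sequences` (named character
#'   vector of uppercase nucleotide strings) and `chrom_sizes` (named integer
#'   vector of lengths in bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "acgtACGTNN"), fa)
#' g <- load_fasta(fa)
#' g$chrom_sizes
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # Biostrings silently drops invalid one-letter codes; surface that as a
  # parse error instead of returning a shortened sequence
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("FASTA contains invalid sequence characters: ", path,
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sequences <- toupper(as.character(seqs))
  names(sequences) <- nm
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence for ", paste(nm[bad], collapse = ", "),
         " contains characters outside {A,C,G,T,N}")
  }
  genome_index(sequences)
}

#' Construct a genome index from named sequences
#'
#' @param sequences Named character vector of nucleotide strings.
#' @return A `genome_index` object.
#' @export
genome_index <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("alphabet must be a subset of {A,C,G,T,N}")
  }
  structure(
    list(sequences = sequences,
         chrom_sizes = stats::setNames(nchar(sequences), names(sequences))),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index with", length(x$sequences), "sequence(s), total",
      sum(as.numeric(x$chrom_sizes)), "bp\n")
  invisible(x)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named integer vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

#' Extract a model input window around a genomic bin
#'
#' Returns the sequence of the bin plus symmetric flanking sequence
#' (`flank_total / 2` on each side), so the window is centered on the bin.
#' Positions beyond the chromosome ends are padded with `N`; the encoder masks
#' them downstream, so bins near chromosome ends remain usable.
#'
#' @param genome A `genome_index`.
#' @param chrom Chromosome name.
#' @param bin_start 0-based start of the bin.
#' @param bin_len Bin length in bp (default 200).
#' @param flank_total Total flanking sequence in bp (default 1800, i.e. 900
#'   per side), giving 2000-bp windows.
#' @return Nucleotide string of length `bin_len + flank_total`.
#' @export
extract_window <- function(genome, chrom, bin_start, bin_len = 200L,
                           flank_total = 1800L) {
  if (!chrom %in% names(genome$sequences)) {
    stop("unknown chromosome: ", chrom)
  }
  stopifnot(flank_total %% 2 == 0)
  csize <- genome$chrom_sizes[[chrom]]
  bin_start <- as.integer(bin_start)
  if (bin_start < 0 || bin_start + bin_len > csize) {
    stop("bin [", bin_start, ",", bin_start + bin_len, ") outside ", chrom,
         " (length ", csize, ")")
  }
  flank <- flank_total %/% 2L
  w_start <- bin_start - flank           # 0-based, may be negative
  w_end <- bin_start + bin_len + flank   # exclusive, may exceed csize
  left_pad <- max(0L, -w_start)
  right_pad <- max(0L, w_end - csize)
  core <- substr(genome$sequences[[chrom]],
                 max(0L, w_start) + 1L, min(csize, w_end))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Encode a nucleotide string as integer codes with an N-mask
#'
#' Bases map to A=1, C=2, G=3, T=4 and N=0; the mask is 0 exactly at N
#' positions so later layers can ignore them.
#'
#' @param seq Nucleotide string over {A,C,G,T,N} (case-insensitive).
#' @return An `encoded_sequence`: list with integer `codes` and binary `mask`.
#' @examples
#' encode_sequence("ACGTN")
#' @export
encode_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- BASE_CODES[chars]
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  }
  structure(list(codes = unname(codes), mask = as.integer(codes != 0L)),
            class = "encoded_sequence")
}

#' Decode integer codes back to a nucleotide string
#'
#' @param codes Integer vector in {0,1,2,3,4}.
#' @return Nucleotide string.
#' @export
decode_sequence <- function(codes) {
  if (inherits(codes, "encoded_sequence")) codes <- codes$codes
  if (!all(codes %in% 0:4)) stop("codes must lie in {0,..,4}")
  paste(names(BASE_CODES)[match(codes, BASE_CODES)], collapse = "")
}

#' Encode many windows into a code matrix
#'
#' Convenience used by training and prediction: one row per window.
#'
#' @param windows Character vector of equal-length nucleotide strings.
#' @return Integer matrix, rows = windows, columns = positions.
#' @export
encode_windows <- function(windows) {
  stopifnot(length(windows) > 0)
  L <- unique(nchar(windows))
  if (length(L) != 1) stop("windows must have equal length")
  m <- matrix(0L, nrow = length(windows), ncol = L)
  for (i in seq_along(windows)) {
    m[i, ] <- encode_sequence(windows[[i]])$codes
  }
  m
}
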