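#' Specification of a synthetic regulatory-genomics universe
#'
#' Describes a random genome with planted sequence motifs, peak tracks
#' derived from the motif occurrences (emulating ENCODE-style narrowPeak
#' calls), and effect-labelled variants. Defaults are sized for desk-scale
#' training: 3 chromosomes of 300 kb, two distinct 10-bp motifs with 150
#' planted occurrences per chromosome each, 150-bp peak half-width and two
#' tracks (one per motif), yielding a few thousand positive bins. Validation
#' and testing use the second and third synthetic chromosome, mirroring the
#' chr7/chr8 hold-out design.
#'
#' @param n_chroms Number of chromosomes (named chrS1, chrS2, ...).
#' @param chrom_length Chromosome length in bp.
#' @param base_probs Background base composition (A, C, G, T).
#' @param motifs Character vector of motif consensus sequences; each track
#'   is driven by one motif.
#' @param occurrences_per_chrom Planted occurrences per chromosome per motif.
#' @param peak_half_width Peak half-width in bp around each occurrence.
#' @param tracks data.frame with target_id, assay_class, motif (index into
#'   `motifs`); default two tracks, one per motif.
#' @param n_effect_variants Number of motif-disrupting variants.
#' @param n_background_variants Number of background variants (>= 1 kb from
#'   any occurrence).
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chroms = 3L,
                           chrom_length = 300000L,
                           base_probs = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           motifs = c("TGACGTCATG", "CACGTGTTAC"),
                           occurrences_per_chrom = 150L,
                           peak_half_width = 150L,
                           tracks = NULL,
                           n_effect_variants = 50L,
                           n_background_variants = 50L,
                           seed = 42L) {
  stopifnot(n_chroms >= 1, chrom_length >= 1000, length(base_probs) == 4,
            abs(sum(base_probs) - 1) < 1e-8,
            all(nchar(motifs) <= 2 * peak_half_width))
  if (is.null(tracks)) {
    classes <- rep_len(c("chromatin_accessibility", "tf_binding",
                         "histone_modification"), length(motifs))
    tracks <- data.frame(
      target_id = paste0("synth", LETTERS[seq_along(motifs)], " | track"),
      assay_class = classes,
      motif = seq_along(motifs),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(tracks$motif %in% seq_along(motifs)))
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 base_probs = base_probs, motifs = toupper(motifs),
                 occurrences_per_chrom = as.integer(occurrences_per_chrom),
                 peak_half_width = as.integer(peak_half_width),
                 tracks = tracks,
                 n_effect_variants = as.integer(n_effect_variants),
                 n_background_variants = as.integer(n_background_variants),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a genome with planted motif occurrences
#'
#' Background bases are i.i.d. at the spec's composition; motif instances
#' are planted at non-overlapping uniformly sampled positions. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `genome` (a `genome_index`) and `truth` (data.frame of
#'   occurrence intervals: chrom, start, end, motif index).
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chrS", seq_len(spec$n_chroms))
  seqs <- character(spec$n_chroms)
  occ <- list()
  for (ci in seq_len(spec$n_chroms)) {
    s <- sample(bases, spec$chrom_length, replace = TRUE,
                prob = spec$base_probs)
    placed_start <- integer(0)
    placed_end <- integer(0)
    placed_motif <- integer(0)
    for (mi in seq_along(spec$motifs)) {
      mlen <- nchar(spec$motifs[mi])
      n_left <- spec$occurrences_per_chrom
      tries <- 0L
      max_tries <- 200L * spec$occurrences_per_chrom
      while (n_left > 0) {
        if ((tries <- tries + 1L) > max_tries) {
          stop("cannot place requested motif occurrences without overlap")
        }
        st <- sample.int(spec$chrom_length - mlen + 1L, 1L) - 1L
        en <- st + mlen
        if (any(st < placed_end & en > placed_start)) next
        placed_start <- c(placed_start, st)
        placed_end <- c(placed_end, en)
        placed_motif <- c(placed_motif, mi)
        s[(st + 1L):en] <- strsplit(spec$motifs[mi], "")[[1]]
        n_left <- n_left - 1L
      }
    }
    seqs[ci] <- paste(s, collapse = "")
    if (length(placed_start) > 0) {
      o <- order(placed_start)
      occ[[ci]] <- data.frame(chrom = chroms[ci],
                              start = placed_start[o], end = placed_end[o],
                              motif = placed_motif[o],
                              stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- chroms
  truth <- if (length(occ) > 0) do.call(rbind, occ) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               motif = integer())
  rownames(truth) <- NULL
  list(genome = genome_index(seqs), truth = truth)
}

#' Emit narrowPeak tracks around planted motif occurrences
#'
#' Each track's peaks are +/- `peak_half_width` windows anchored at its
#' motif occurrences' end coordinate, clipped at chromosome bounds, written
#' as valid narrowPeak (BED6+4). A manifest TSV mapping files to
#' target_id/assay_class is written alongside.
#'
#' @param truth Occurrence table from [simulate_genome()].
#' @param spec The `synthetic_spec`.
#' @param dir Output directory.
#' @param genome The `genome_index` (for clipping at chromosome ends).
#' @return Paths list: `peaks` (named character vector per target),
#'   `manifest`.
#' @export
emit_peak_tracks <- function(truth, spec, dir, genome) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(spec$tracks))
  for (j in seq_len(nrow(spec$tracks))) {
    tr <- spec$tracks[j, ]
    o <- truth[truth$motif == tr$motif, , drop = FALSE]
    start <- pmax(0L, o$end - spec$peak_half_width)
    end <- pmin(genome$chrom_sizes[o$chrom], o$end + spec$peak_half_width)
    bed <- data.frame(chrom = o$chrom, start = start, end = end,
                      name = paste0("peak", seq_len(nrow(o))), score = 0L,
                      strand = ".", signalValue = 1, pValue = -1,
                      qValue = -1, peak = -1L)
    f <- file.path(dir, paste0("track_", j, ".narrowPeak"))
    utils::write.table(bed, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[j] <- f
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(file = basename(files), target_id = spec$tracks$target_id,
               assay_class = spec$tracks$assay_class),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  list(peaks = stats::setNames(files, spec$tracks$target_id),
       manifest = manifest)
}

#' Simulate effect-labelled variants
#'
#' Motif-disrupting variants substitute a consensus base inside a planted
#' occurrence; background variants substitute a base at least 1 kb away
#' from every occurrence. Reference alleles always match the synthetic
#' genome, so every emitted variant passes the reference-allele check.
#'
#' @param truth Occurrence table from [simulate_genome()].
#' @param spec The `synthetic_spec`.
#' @param genome The `genome_index`.
#' @return List with `variants` (a `variant_table`) and `labels`
#'   (data.frame id, label in {motif_disrupting, background}).
#' @export
simulate_variants <- function(truth, spec, genome) {
  set.seed(spec$seed + 1L)
  bases <- c("A", "C", "G", "T")
  n_eff <- spec$n_effect_variants
  n_bg <- spec$n_background_variants
  if (n_eff > 0 && nrow(truth) == 0) {
    stop("no motif occurrences available for effect variants")
  }
  rows <- list()
  if (n_eff > 0) {
    pick <- sample.int(nrow(truth), n_eff, replace = n_eff > nrow(truth))
    for (k in seq_len(n_eff)) {
      o <- truth[pick[k], ]
      pos1 <- o$start + sample.int(o$end - o$start, 1L)  # 1-based
      ref <- substr(genome$sequences[[o$chrom]], pos1, pos1)
      alt <- sample(setdiff(bases, ref), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = o$chrom, pos = pos1, id = paste0("eff_", k), ref = ref,
        alt = alt, label = "motif_disrupting", stringsAsFactors = FALSE)
    }
  }
  if (n_bg > 0) {
    found <- 0L
    tries <- 0L
    max_tries <- 20000L * max(1L, n_bg)
    while (found < n_bg) {
      if ((tries <- tries + 1L) > max_tries) {
        stop("insufficient eligible background positions (>=1 kb from ",
             "all occurrences)")
      }
      chrom <- paste0("chrS", sample.int(spec$n_chroms, 1L))
      pos1 <- sample.int(genome$chrom_sizes[[chrom]], 1L)
      occ <- truth[truth$chrom == chrom, , drop = FALSE]
      pos0 <- pos1 - 1L
      if (nrow(occ) > 0 &&
          any(pos0 >= occ$start - 1000L & pos0 < occ$end + 1000L)) next
      ref <- substr(genome$sequences[[chrom]], pos1, pos1)
      if (ref == "N") next
      found <- found + 1L
      alt <- sample(setdiff(bases, ref), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos1, id = paste0("bg_", found), ref = ref,
        alt = alt, label = "background", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(variants = variant_table(tab$chrom, tab$pos, tab$ref, tab$alt,
                                tab$id),
       labels = tab[, c("id", "label")])
}

#' Materialize a complete synthetic fixture directory
#'
#' Writes FASTA, chrom.sizes, per-track narrowPeak files plus manifest,
#' a variants TSV and truth TSVs (occurrences and variant labels).
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory.
#' @return List of file paths plus the in-memory `genome`, `truth`,
#'   `variants` and `labels` objects.
#' @export
simulate_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(spec)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome$sequences), fasta)
  sizes <- file.path(dir, "genome.chrom.sizes")
  utils::write.table(
    data.frame(names(sim$genome$chrom_sizes), sim$genome$chrom_sizes),
    sizes, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  peaks <- emit_peak_tracks(sim$truth, spec, dir, sim$genome)
  vars <- simulate_variants(sim$truth, spec, sim$genome)
  var_path <- file.path(dir, "variants.tsv")
  utils::write.table(vars$variants, var_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "occurrences.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  labels_path <- file.path(dir, "variant_labels.tsv")
  utils::write.table(vars$labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, chrom_sizes = sizes, peaks = peaks$peaks,
       manifest = peaks$manifest, variants_tsv = var_path,
       occurrences_tsv = truth_path, variant_labels_tsv = labels_path,
       genome = sim$genome, truth = sim$truth, variants = vars$variants,
       labels = vars$labels)
}
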