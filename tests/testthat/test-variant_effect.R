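test_that("variant_table validates single-nucleotide alleles", {
  v <- variant_table("chr1", 100, "A", "G", "rs1")
  expect_equal(v$pos, 100L)
  expect_error(variant_table("chr1", 1, "AT", "A"), "single-nucleotide")
  expect_error(variant_table("chr1", 1, "A", "A"), "differ")
  expect_error(variant_table("chr1", 1, "A", "U"), "alleles must be")
})

test_that("read_variants parses VCF, splits multi-allelics, drops indels", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\trs10\tA\tG\t.\t.\t.",
               "chr1\t300\trs11\tC\tT,G\t.\t.\t.",
               "chr2\t50\trs12\tAT\tA\t.\t.\t."), vcf)
  v <- suppressMessages(read_variants(vcf))
  expect_equal(nrow(v), 3)  # rs11 split in two, indel rs12 dropped
  expect_equal(v$alt[v$id == "rs11"], c("T", "G"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "chr1", pos = 7, id = "rs1", ref = "A",
                         alt = "C"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  v2 <- read_variants(tsv)
  expect_equal(v2$pos, 7L)
})

test_that("locate_bin maps 1-based positions onto the 200-bp grid", {
  g <- make_genome(chr1 = random_sequence(2000, seed = 40))
  bin_of <- function(pos) {
    locate_bin(variant_table("chr1", pos, "A", "G"), g)$start
  }
  expect_equal(bin_of(1), 0L)
  expect_equal(bin_of(200), 0L)    # last base of the first bin
  expect_equal(bin_of(201), 200L)  # first base of the second bin
  expect_equal(bin_of(1000), 800L)
  expect_error(locate_bin(variant_table("chr1", 2001, "A", "G"), g),
               "outside")
  expect_error(locate_bin(variant_table("chrX", 5, "A", "G"), g),
               "unknown")
})

test_that("apply_variant substitutes one base after checking the reference", {
  v <- variant_table("chr1", 3, "A", "G")
  expect_equal(apply_variant("AAAA", v, window_start = 0), "AAGA")
  # mismatch names both the observed and the expected base
  vC <- variant_table("chr1", 3, "C", "G")
  err <- tryCatch(apply_variant("AAAA", vC, 0), error = conditionMessage)
  expect_match(err, "'A'")
  expect_match(err, "'C'")
  # alt equal to the present base is still applied (only ref is checked)
  vSame <- variant_table("chr1", 3, "A", "T")
  w <- "AATA"
  expect_error(apply_variant(w, vSame, 0), "mismatch")
  expect_error(apply_variant("AAAA", v, 10), "outside the window")
})

test_that("sad_scores computes |P_ref - P_alt| per target", {
  model <- tiny_random_model(n_targets = 3)
  g <- make_genome(chr1 = random_sequence(1000, seed = 41))
  base_at <- function(pos) substr(g$sequences[["chr1"]], pos, pos)
  pos <- 450
  ref <- base_at(pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- variant_table("chr1", pos, ref, alt, "v1")
  sad <- sad_scores(model, g, v, bin_len = 20L)
  expect_equal(nrow(sad), 3)
  expect_true(all(is.na(sad$error)))
  # recompute by hand: bin of pos 450 with bin_len 20 is [440, 460)
  w_ref <- extract_window(g, "chr1", 440L, 20L, 40L)
  w_alt <- w_ref
  substr(w_alt, pos - 420, pos - 420) <- alt
  p <- predict_labels(rbind(encode_sequence(w_ref)$codes,
                            encode_sequence(w_alt)$codes),
                      model$params, model$model_config)
  expect_equal(sad$sad, abs(p[1, ] - p[2, ]), tolerance = 1e-12)
  expect_equal(sad$p_ref, p[1, ], tolerance = 1e-12)
  # symmetry under ref/alt exchange: score the mutated genome back
  g2 <- g
  substr(g2$sequences[["chr1"]], pos, pos) <- alt
  g2 <- genome_index(g2$sequences)
  sad_back <- sad_scores(model, g2, variant_table("chr1", pos, alt, ref,
                                                  "v1b"), bin_len = 20L)
  expect_equal(sad_back$sad, sad$sad, tolerance = 1e-12)
})

test_that("sad_scores collects per-variant errors without aborting", {
  model <- tiny_random_model(n_targets = 2)
  g <- make_genome(chr1 = paste(rep("A", 500), collapse = ""))
  vs <- variant_table(c("chr1", "chr1"), c(100, 200), c("C", "A"),
                      c("G", "G"), c("bad", "good"))
  sad <- sad_scores(model, g, vs, bin_len = 20L)
  expect_match(sad$error[sad$id == "bad"][1], "mismatch")
  expect_true(all(is.na(sad$error[sad$id == "good"])))
  expect_equal(sum(is.na(sad$sad[sad$id == "good"])), 0)
  # the mutated base always lies inside the central bin of the window
  expect_true(all(sad$sad[!is.na(sad$sad)] >= 0 &
                    sad$sad[!is.na(sad$sad)] < 1))
})

test_that("sad_matrix reshapes long results to variants x targets", {
  model <- tiny_random_model(n_targets = 2)
  g <- make_genome(chr1 = random_sequence(800, seed = 42))
  ref1 <- substr(g$sequences[["chr1"]], 100, 100)
  ref2 <- substr(g$sequences[["chr1"]], 300, 300)
  vs <- variant_table(c("chr1", "chr1"), c(100, 300),
                      c(ref1, ref2),
                      c(setdiff(c("A", "C", "G", "T"), ref1)[1],
                        setdiff(c("A", "C", "G", "T"), ref2)[1]),
                      c("v1", "v2"))
  m <- sad_matrix(sad_scores(model, g, vs, bin_len = 20L))
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m), c("v1", "v2"))
  expect_false(anyNA(m))
})

test_that("conversion-unstable positions are excluded half-open", {
  vs <- variant_table(rep("chr1", 3), c(150, 200, 201), rep("A", 3),
                      rep("G", 3), c("in", "edge", "out"))
  cup <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  kept <- suppressMessages(filter_unstable_positions(vs, cup))
  # pos 150 (0-based 149) and pos 200 (0-based 199) fall inside [100, 200)
  expect_equal(kept$id, "out")
  expect_equal(nrow(suppressMessages(
    filter_unstable_positions(vs, NULL))), 3)
})
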