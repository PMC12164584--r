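test_that("parse_narrowpeak extracts intervals and tolerates dialects", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t350\tp1\t0\t.\t5\t-1\t-1\t120", f)
  tr <- parse_narrowpeak(f, "s | a", "tf_binding")
  expect_equal(tr$intervals,
               data.frame(chrom = "chr1", start = 100L, end = 350L))

  writeLines(character(), f)
  expect_equal(nrow(parse_narrowpeak(f, "s", "tf_binding")$intervals), 0)

  writeLines("chr1\t10\t20", f)  # plain 3-column BED
  expect_equal(nrow(parse_narrowpeak(f, "s", "tf_binding")$intervals), 1)

  writeLines("chr1\tx\t20", f)
  expect_error(parse_narrowpeak(f, "s", "tf_binding"), "non-numeric")
  writeLines("chr1\t30\t20\tp\t0\t.", f)
  expect_error(parse_narrowpeak(f, "s", "tf_binding"), "start >= end")
})

test_that("label_bins applies the strict more-than-half rule", {
  g <- make_genome(chr1 = random_sequence(1000, seed = 4))
  mk <- function(iv) label_track("t | x", "tf_binding", iv)
  lab <- function(iv) {
    m <- label_bins(g, list(mk(iv)))
    m
  }
  # overlap 130 > 100 -> positive
  m <- lab(data.frame(chrom = "chr1", start = 50L, end = 180L))
  expect_equal(m$bins$start, 0L)
  expect_equal(as.vector(m$values), 1L)
  # overlap exactly 100 -> negative (and the bin is dropped)
  m <- lab(data.frame(chrom = "chr1", start = 0L, end = 100L))
  expect_equal(nrow(m$bins), 0)
  # peak (150, 450): only the fully covered bin [200,400) is positive
  m <- lab(data.frame(chrom = "chr1", start = 150L, end = 450L))
  expect_equal(m$bins$start, 200L)
})

test_that("overlaps from one track are merged before thresholding", {
  g <- make_genome(chr1 = random_sequence(600, seed = 5))
  # two 60-bp pieces in bin [0,200): total 120 > 100 only if summed
  iv <- data.frame(chrom = c("chr1", "chr1"), start = c(0L, 100L),
                   end = c(60L, 160L))
  m <- label_bins(g, list(label_track("t", "tf_binding", iv)))
  expect_equal(m$bins$start, 0L)
  # overlapping duplicates are not double counted: [0,80) twice is 80 bp
  iv2 <- data.frame(chrom = c("chr1", "chr1"), start = c(0L, 0L),
                    end = c(80L, 80L))
  m2 <- label_bins(g, list(label_track("t", "tf_binding", iv2)))
  expect_equal(nrow(m2$bins), 0)
})

test_that("label matrix is invariant to peak input order", {
  g <- make_genome(chr1 = random_sequence(5000, seed = 6))
  set.seed(7)
  start <- sample(0:4700, 30)
  iv <- data.frame(chrom = "chr1", start = start,
                   end = start + sample(50:400, 30, TRUE))
  m1 <- label_bins(g, list(label_track("t", "tf_binding", iv)))
  m2 <- label_bins(g, list(label_track("t", "tf_binding",
                                       iv[sample(nrow(iv)), ])))
  expect_identical(m1$bins, m2$bins)
  expect_identical(m1$values, m2$values)
})

test_that("labeling agrees with the per-base brute-force oracle", {
  set.seed(8)
  g <- make_genome(chrZ = random_sequence(6000, seed = 8))
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    start <- sample(0:5700, n)
    iv <- data.frame(chrom = "chrZ", start = start,
                     end = pmin(6000L, start + sample(20:500, n, TRUE)))
    m <- label_bins(g, list(label_track("t", "tf_binding", iv)),
                    keep_all_bins = TRUE)
    for (b in seq_len(nrow(m$bins))) {
      ov <- brute_overlap(iv, m$bins$start[b], m$bins$end[b])
      expect_identical(unname(m$values[b, 1] == 1L), ov > 100,
                       label = sprintf("bin %d overlap %d", b, ov))
    }
  }
})

test_that("keep_all_bins retains the full grid; default drops negatives", {
  g <- make_genome(chr1 = random_sequence(1000, seed = 9))
  iv <- data.frame(chrom = "chr1", start = 0L, end = 150L)
  tr <- list(label_track("t", "tf_binding", iv))
  m_all <- label_bins(g, tr, keep_all_bins = TRUE)
  expect_equal(nrow(m_all$bins), 5)  # 1000 / 200
  expect_equal(sum(m_all$values), 1)
  m <- label_bins(g, tr)
  expect_equal(nrow(m$bins), 1)
  expect_true(all(rowSums(m$values) > 0))
})

test_that("filter_blacklist removes bins at >= 1 bp overlap", {
  g <- make_genome(chr1 = random_sequence(2000, seed = 10))
  iv <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  m <- label_bins(g, list(label_track("t", "tf_binding", iv)))
  expect_equal(nrow(m$bins), 10)
  bl <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(nrow(filter_blacklist(m, bl)$bins), 5)
  # 1-bp overlaps on both sides of a bin boundary
  bl2 <- data.frame(chrom = "chr1", start = 199L, end = 201L)
  kept <- filter_blacklist(m, bl2)
  expect_false(any(kept$bins$start %in% c(0L, 200L)))
  expect_equal(nrow(kept$bins), 8)
  # empty blacklist is the identity
  expect_equal(nrow(filter_blacklist(m, NULL)$bins), 10)
})

test_that("split_by_chromosome partitions bins by hold-out chromosome", {
  g <- make_genome(chr1 = random_sequence(1000, seed = 11),
                   chr7 = random_sequence(1000, seed = 12),
                   chr8 = random_sequence(1000, seed = 13))
  iv <- function(chrom) data.frame(chrom = chrom, start = 0L, end = 1000L)
  m <- label_bins(g, list(label_track("t", "tf_binding",
                                      rbind(iv("chr1"), iv("chr7"),
                                            iv("chr8")))))
  sp <- split_by_chromosome(m)
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_len(nrow(m$bins)))
  expect_true(all(m$bins$chrom[sp$validation] == "chr7"))
  expect_true(all(m$bins$chrom[sp$test] == "chr8"))
  expect_true(all(m$bins$chrom[sp$train] == "chr1"))
  expect_length(intersect(sp$train, c(sp$validation, sp$test)), 0)

  # parameterized hold-out with synthetic chromosome names
  g2 <- make_genome(chrS1 = random_sequence(600, seed = 14),
                    chrS2 = random_sequence(600, seed = 15),
                    chrS3 = random_sequence(600, seed = 16))
  m2 <- label_bins(g2, list(label_track("t", "tf_binding",
                                        rbind(iv("chrS1"), iv("chrS2"),
                                              iv("chrS3")))))
  sp2 <- split_by_chromosome(m2, val_chroms = "chrS2", test_chroms = "chrS3")
  expect_true(all(m2$bins$chrom[sp2$validation] == "chrS2"))
  expect_true(all(m2$bins$chrom[sp2$test] == "chrS3"))

  expect_error(split_by_chromosome(m, "chr7", "chr7"), "overlap")
  # both hold-out sets are empty for these chromosome names: two warnings
  expect_warning(expect_warning(split_by_chromosome(m2, "chr7", "chr8"),
                                "validation set is empty"),
                 "test set is empty")
})

test_that("class_prevalence returns the positive fraction", {
  g <- make_genome(chr1 = random_sequence(2000, seed = 17))
  iv <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  m <- label_bins(g, list(label_track("t", "tf_binding", iv)))
  expect_equal(class_prevalence(m, "t"), 1.0)
  m$values[1:3, 1] <- 0L
  expect_equal(class_prevalence(m, "t"), 0.7)
  expect_error(class_prevalence(m, "nope"), "unknown target")
})

test_that("label matrices round-trip through the text container", {
  g <- make_genome(chr1 = random_sequence(3000, seed = 18))
  set.seed(19)
  start <- sample(0:2500, 8)
  tracks <- list(
    label_track("a | atac", "chromatin_accessibility",
                data.frame(chrom = "chr1", start = start,
                           end = start + 300L)),
    label_track("b | chip", "tf_binding",
                data.frame(chrom = "chr1", start = start[1:4],
                           end = start[1:4] + 250L)))
  m <- label_bins(g, tracks)
  dir <- withr::local_tempdir()
  save_label_matrix(m, dir)
  m2 <- load_label_matrix(dir)
  expect_equal(m2$bins, m$bins)
  expect_equal(m2$targets, m$targets)
  expect_equal(m2$values, m$values)
})
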