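# Block I/O, inversion detection, feature coverage, RepeatMasker
# parsing, shared-TE filtering, TE/feature composition, ORF scanning.

test_that("MAF blocks round-trip through write and read", {
  blocks <- make_block_fixture(3, inverted = 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, f)
  back <- read_maf(f)
  expect_equal(as.data.frame(back), as.data.frame(blocks))
})

test_that("minus-strand MAF coordinates convert to forward intervals", {
  # hand conversion: srcSize 100, reverse-strand start 10, size 20
  # -> forward start = 100 - 10 - 20 = 70, end = 90
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "##maf version=1",
    "a score=0",
    "s mouse.chr1 5 20 + 1000 ACGTACGTACGTACGTACGT",
    "s human.chr2 10 20 - 100 ACGTACGTACGTACGTACGT",
    ""
  ), f)
  b <- read_maf(f)
  h <- b[b$species == "human", ]
  expect_equal(h$start, 70)
  expect_equal(h$end, 90)
  expect_identical(h$strand, "-")
  # round trip preserves the reverse-strand encoding
  f2 <- withr::local_tempfile(fileext = ".maf")
  write_maf(b, f2)
  expect_equal(as.data.frame(read_maf(f2)), as.data.frame(b))
})

test_that("malformed and empty MAF inputs behave as specified", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a", "s mouse.chr1 5 xx + 1000 ACGT"), f)
  expect_error(read_maf(f), regexp = "line 3", class = "rateshift_error_maf")
  writeLines(character(), f)
  expect_equal(nrow(read_maf(f)), 0L)
})

test_that("planted inversions are recovered as merged intervals", {
  one <- detect_inversions(make_block_fixture(5, inverted = 2, seed = 1),
                           "human")
  expect_equal(nrow(one), 1L)
  # block 2 spans [1250, 1450) by construction
  expect_equal(one$start, 1250)
  expect_equal(one$end, 1450)

  none <- detect_inversions(make_block_fixture(5, seed = 1), "human")
  expect_equal(nrow(none), 0L)

  two <- detect_inversions(
    make_block_fixture(8, inverted = c(2, 3, 7), seed = 1), "human"
  )
  expect_equal(nrow(two), 2L)
  expect_equal(two$n_blocks, c(2L, 1L))
})

test_that("inversion detection ignores input row order", {
  blocks <- make_block_fixture(8, inverted = c(2, 3, 7), seed = 6)
  set.seed(10)
  shuffled <- blocks[sample(nrow(blocks)), ]
  expect_equal(
    as.data.frame(detect_inversions(shuffled, "human",
                                    ref_species = "mouse")),
    as.data.frame(detect_inversions(blocks, "human", ref_species = "mouse"))
  )
  expect_error(detect_inversions(blocks, "armadillo"),
               class = "rateshift_error_blocks")
})

test_that("feature coverage reports fraction, status, inversion flag", {
  blocks <- make_block_fixture(5, inverted = 5, seed = 2)
  # block 1 spans [1000, 1200); block 5 (inverted) spans [2000, 2200)
  features <- tibble::tibble(
    id = c("inside", "outside", "partial_inv"),
    chrom = "chr10",
    start = c(1050, 9000, 2120),
    end = c(1150, 9100, 2320)
  )
  cov <- feature_coverage(blocks, features, species_list = "human")
  inside <- cov[cov$feature == "inside", ]
  expect_identical(inside$status, "covered")
  expect_equal(inside$fraction, 1.0)
  expect_false(inside$inverted)
  expect_identical(cov$status[cov$feature == "outside"], "absent")
  # [2120, 2200) = 80 of 200 bp inside the flipped block:
  # 0.4 < 0.5 -> partial, flagged
  pi <- cov[cov$feature == "partial_inv", ]
  expect_identical(pi$status, "partial")
  expect_equal(pi$fraction, 0.4)
  expect_true(pi$inverted)
  expect_true(all(cov$fraction >= 0 & cov$fraction <= 1))
})

test_that("RepeatMasker tables parse, collapse classes, round-trip", {
  tes <- tibble::tibble(
    name = c("MIR", "L1MD3", "(TA)n", "MER91A"),
    raw_class = c("SINE/MIR", "LINE/L1", "Simple_repeat", "DNA/hAT-Charlie"),
    chrom = "chr10", start = c(100, 500, 900, 1200),
    end = c(250, 800, 950, 1400), strand = c("+", "-", "+", "+")
  )
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(tes, f)
  got <- read_repeatmasker_out(f, species = "mouse")
  expect_equal(got$name, tes$name)
  expect_equal(got$repeat_class, c("SINE", "LINE", "Other", "DNA"))
  expect_equal(got$start, tes$start)
  expect_equal(got$end, tes$end)
  expect_equal(got$strand, tes$strand)
  ancient <- read_repeatmasker_out(f, species = "mouse", ancient_only = TRUE)
  expect_false("(TA)n" %in% ancient$name)

  writeLines(c("h1", "h2", ""), f)
  expect_equal(nrow(read_repeatmasker_out(f, "mouse")), 0L)
  writeLines(c("h1", "h2", "", "  225 10.0 bad record"), f)
  expect_error(read_repeatmasker_out(f, "mouse"),
               class = "rateshift_error_repeatmasker")
})

test_that("the shared-TE filter keeps the eleven ancestral elements", {
  kept <- shared_te_filter(make_te_fixture(), min_species = 2,
                           required_species = "mouse")
  expect_equal(nrow(kept), 11L)
  expect_identical(sort(kept$symbol), LETTERS[1:11])
  expect_false(any(c("DecoyM", "DecoyR") %in% kept$symbol))
  a <- kept[kept$symbol == "A", ]
  expect_identical(a$name, "MIR")
  expect_identical(a$repeat_class, "SINE")
  expect_identical(a$species[[1]], sort(c("mouse", "rat", "human", "dog")))
  empty <- shared_te_filter(make_te_fixture()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("TE/feature composition matches the locus layout", {
  comp <- te_feature_overlap(make_te_fixture(), locus_features())
  expect_identical(comp$te_symbols[comp$feature == "Pldi.intron1"],
                   "A, B, C, D")
  expect_identical(comp$te_symbols[comp$feature == "Ak158810.exon5"],
                   "G, H, I, J, K")
  expect_identical(comp$te_symbols[comp$feature == "Ak158810.intron1"],
                   "B, C")
  expect_identical(comp$te_symbols[comp$feature == "Ak158810.intron4"],
                   "E, F")
  exon_rows <- comp[grepl("exon[1-4]$", comp$feature), ]
  expect_true(all(exon_rows$n_te == 0))
  # alternative reading of the published table: element I duplicated
  comp_i <- te_feature_overlap(make_te_fixture(exon5_duplicate_i = TRUE),
                               locus_features())
  expect_identical(comp_i$te_symbols[comp_i$feature == "Ak158810.exon5"],
                   "G, H, I, I, K")
})

test_that("boundary-touching TEs do not count as overlapping", {
  tes <- tibble::tibble(symbol = "Z", name = "Z", chrom = "chr1",
                        start = 100, end = 200)
  feats <- tibble::tibble(id = c("left", "right"), chrom = "chr1",
                          start = c(0, 200), end = c(100, 300))
  comp <- te_feature_overlap(tes, feats)
  expect_true(all(comp$n_te == 0))
})

test_that("composition totals equal brute-force interval intersections", {
  set.seed(23)
  for (i in 1:10) {
    n_te <- sample(5:15, 1); n_f <- sample(3:8, 1)
    tes <- tibble::tibble(
      symbol = paste0("T", seq_len(n_te)), name = "X", chrom = "chr1",
      start = sample(0:500, n_te), end = 0
    )
    tes$end <- tes$start + sample(10:100, n_te, replace = TRUE)
    feats <- tibble::tibble(
      id = paste0("f", seq_len(n_f)), chrom = "chr1",
      start = sample(0:500, n_f), end = 0
    )
    feats$end <- feats$start + sample(20:150, n_f, replace = TRUE)
    comp <- te_feature_overlap(tes, feats)
    brute <- 0
    for (a in seq_len(n_te)) for (b in seq_len(n_f)) {
      if (tes$start[a] < feats$end[b] && feats$start[b] < tes$end[a]) {
        brute <- brute + 1
      }
    }
    expect_equal(sum(comp$n_te), brute)
  }
})

test_that("ORF scanning handles the minimal cases", {
  one <- find_orfs("ATGAAATGA", min_aa = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$length_aa, 2)
  expect_equal(one$start, 0)
  expect_equal(one$end, 9)
  expect_equal(nrow(find_orfs("CCCCCCTAA", min_aa = 1)), 0L)
  expect_error(find_orfs("ACGTX"), class = "rateshift_error_sequence")
})

test_that("the scanner agrees with the exhaustive oracle", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(300:3000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    min_aa <- sample(c(5, 10, 30), 1)
    got <- as.data.frame(find_orfs(s, min_aa = min_aa, frames = "six"))
    got <- got[, c("frame", "start", "end", "length_aa")]
    want <- orf_oracle(s, min_aa = min_aa, six_frame = TRUE)
    expect_equal(got[order(got$frame, got$start), ],
                 want[order(want$frame, want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("the synthetic transcript carries the designed ORF structure", {
  tx <- make_transcript_fixture(seed = 1)
  expect_equal(nchar(tx), 2900)
  orfs <- find_orfs(tx, min_aa = 30, frames = "six")
  expect_equal(nrow(orfs), 3L)
  expect_true(all(orfs$frame > 0))  # nothing on the minus strand
  expect_equal(orfs$length_aa, c(104, 72, 70))
  expect_lt(orfs$length_aa[1], 110)
  expect_equal(attr(orfs, "n_upstream_aug"), 2L)
  # deterministic per seed
  expect_identical(make_transcript_fixture(seed = 3),
                   make_transcript_fixture(seed = 3))
})

test_that("BED features round-trip", {
  feats <- locus_features()
  f <- withr::local_tempfile(fileext = ".bed")
  write_features(feats, f)
  back <- read_features(f)
  expect_equal(back$id, feats$id)
  expect_equal(back$start, feats$start)
  expect_equal(back$end, feats$end)
})
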