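test_that("block sequences concatenate the pattern the stated number of times", {
  toy <- make_block_sequence(c(A = 10, B = 10), repeats = 6)
  expect_s3_class(toy, "epi_sequence")
  expect_length(toy, 120)
  r <- rle(toy$states)
  expect_equal(r$lengths, rep(10, 12))
  expect_equal(unique(r$values), c("A", "B"))

  expect_length(make_block_sequence(c(A = 1)), 1)
  two <- make_block_sequence(c(A = 3, B = 2), repeats = 2)
  expect_equal(two$states,
               c("A", "A", "A", "B", "B", "A", "A", "A", "B", "B"))
  expect_error(make_block_sequence(data.frame(label = character(0),
                                              length = numeric(0))),
               "empty")
  expect_error(make_block_sequence(c(A = 0)), ">= 1")
})

test_that("random block sequences are reproducible with distinct neighbours", {
  s1 <- random_block_sequence(5, c(1, 1), alphabet = c("A", "B"), seed = 7)
  s2 <- random_block_sequence(5, c(1, 1), alphabet = c("A", "B"), seed = 7)
  expect_identical(s1$states, s2$states)
  expect_length(s1, 5)
  expect_true(all(s1$states[-1] != s1$states[-5]))

  s3 <- random_block_sequence(8, c(2, 6), alphabet = c("A", "B", "C"),
                              seed = 3)
  r <- rle(s3$states)
  expect_equal(length(r$lengths), 8)
  expect_true(all(r$lengths >= 2 & r$lengths <= 6))

  expect_error(random_block_sequence(3, c(1, 2), alphabet = "A"),
               "adjacent")
})

test_that("same-state indicator matches its definition", {
  s <- epi_sequence(c("A", "A", "B"))
  expect_equal(same_state_indicator(s),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  mono <- epi_sequence(rep("black", 4), alphabet = default_alphabet())
  expect_true(all(same_state_indicator(mono) == 1))
  d <- same_state_indicator(toy_ab())
  expect_true(isSymmetric(d))
  # 20-periodic block structure by construction
  expect_equal(d[1:100, 1:100], d[21:120, 21:120])
})

test_that("segmentation binning yields ceiling(region/bin) monomers", {
  seg <- synthetic_segmentation("chr3R", 23050000, 24360000)
  s <- load_segmentation(seg, c("chr3R", 23050000, 24360000),
                         bin_size = 10000)
  expect_length(s, 131)

  seg2 <- synthetic_segmentation("chr3R", 12160000, 13360000, seed = 9)
  s2 <- load_segmentation(seg2, c("chr3R", 12160000, 13360000),
                          bin_size = 10000)
  expect_length(s2, 120)

  one <- data.frame(chrom = "c", start = 0, end = 10000, state = "black")
  s3 <- load_segmentation(one, c("c", 0, 10000), bin_size = 10000)
  expect_equal(s3$states, "black")
})

test_that("binning follows majority rule with first-in-bin tie-breaking", {
  seg <- data.frame(chrom = "c",
                    start = c(0, 6000, 10000, 15000),
                    end = c(6000, 10000, 15000, 20000),
                    state = c("active", "black", "black", "active"))
  s <- load_segmentation(seg, c("c", 0, 20000), bin_size = 10000)
  expect_equal(s$states, c("active", "black"))

  # exact tie 5000/5000: the state appearing first in the bin wins
  tie <- data.frame(chrom = "c", start = c(0, 5000), end = c(5000, 10000),
                    state = c("Polycomb", "active"))
  s_tie <- load_segmentation(tie, c("c", 0, 10000), bin_size = 10000)
  expect_equal(s_tie$states, "Polycomb")

  # record order must not matter
  s_rev <- load_segmentation(tie[2:1, ], c("c", 0, 10000), bin_size = 10000)
  expect_equal(s_rev$states, "Polycomb")
})

test_that("merge map is applied before binning and gaps take the default label", {
  seg <- data.frame(chrom = "c", start = c(0, 10000),
                    end = c(10000, 20000),
                    state = c("active_housekeeping", "active_tissue"))
  s <- load_segmentation(seg, c("c", 0, 30000), bin_size = 10000,
                         merge_map = c(active_housekeeping = "active",
                                       active_tissue = "active"))
  expect_equal(s$states, c("active", "active", "black"))

  expect_error(load_segmentation(seg, c("c", 0, 30000), bin_size = 10000),
               "unknown label")
  expect_error(
    load_segmentation(seg, c("c", 100000, 200000), bin_size = 10000,
                      merge_map = c(active_housekeeping = "active",
                                    active_tissue = "active")),
    "no segmentation in region")
})

test_that("BED round trip and re-binning idempotence hold", {
  seg <- synthetic_segmentation("chr3R", 23050000, 24360000)
  s <- load_segmentation(seg, c("chr3R", 23050000, 24360000))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sequence_bed(s, path)
  s_back <- load_segmentation(path, c("chr3R", 23050000, 24360000))
  expect_identical(s_back$states, s$states)

  # binning an already-binned segmentation at the same bin size: identity
  binned <- data.frame(chrom = "chr3R",
                       start = 23050000 + 10000 * (seq_along(s$states) - 1),
                       end = pmin(23050000 + 10000 * seq_along(s$states),
                                  24360000),
                       state = s$states)
  s_again <- load_segmentation(binned, c("chr3R", 23050000, 24360000))
  expect_identical(s_again$states, s$states)
})

test_that("bead count is independent of interval fragmentation", {
  region <- c("c", 0, 95000)
  coarse <- data.frame(chrom = "c", start = 0, end = 95000, state = "black")
  cuts <- sort(c(0, 95000, c(137, 9999, 10001, 33333, 50000, 77777)))
  fine <- data.frame(chrom = "c", start = head(cuts, -1), end = cuts[-1],
                     state = "black")
  s1 <- load_segmentation(coarse, region, bin_size = 10000)
  s2 <- load_segmentation(fine, region, bin_size = 10000)
  expect_length(s1, 10)   # ceiling(95000/10000)
  expect_identical(s1$states, s2$states)
})

test_that("pattern strings parse into block specs", {
  p <- parse_block_pattern("(A10B10)x6")
  expect_equal(p$repeats, 6)
  expect_equal(p$blocks, c(A = 10, B = 10))
  expect_length(make_block_sequence(p$blocks, p$repeats), 120)

  p1 <- parse_block_pattern("(A1)x1")
  expect_length(make_block_sequence(p1$blocks, p1$repeats), 1)

  expect_error(parse_block_pattern("(A10B10x6"), "malformed")
})

test_that("epi_sequence validates its invariants", {
  expect_error(epi_sequence(character(0)), "at least one")
  expect_error(epi_sequence(c("A", "Z"), alphabet = c("A", "B")),
               "outside the alphabet")
  expect_error(epi_sequence("A", bin_size = -1), "positive")
  expect_error(epi_sequence("A", anchor = list(chrom = "c", start = -5)),
               ">= 0")
})
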