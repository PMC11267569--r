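# CGR / FCGR encoding: corner geometry, midpoint trajectory, rasterisation,
# and the closed-form k-mer correspondence.

test_that("nucleotide corners follow the clockwise sub-square reading", {
  expect_equal(nucleotide_corner("T"), c(x = 1, y = 1))
  expect_equal(nucleotide_corner("A"), c(x = -1, y = 1))
  expect_equal(nucleotide_corner("C"), c(x = -1, y = -1))
  expect_equal(nucleotide_corner("G"), c(x = 1, y = -1))
  expect_error(nucleotide_corner("N"), "N", class = "enhancaps_alphabet_error")
  # the GT sub-square must be the one nearest the G corner: at N = 4 the G
  # corner is (row 4, col 4); GT sits in the T quadrant's lower-right cell
  # clockwise from the outer corner: TT (1,4) -> GT (2,4) -> CT (2,3) -> AT (1,3)
  expect_equal(kmer_suffix_cell("TT", 4), c(row = 1, col = 4))
  expect_equal(kmer_suffix_cell("GT", 4), c(row = 2, col = 4))
  expect_equal(kmer_suffix_cell("CT", 4), c(row = 2, col = 3))
  expect_equal(kmer_suffix_cell("AT", 4), c(row = 1, col = 3))
})

test_that("cgr_encode iterates the midpoint map from the origin", {
  expect_equal(cgr_encode("T")[, c("x", "y")],
               tibble::tibble(x = 0.5, y = 0.5))
  traj <- cgr_encode("CATG")
  expect_equal(traj$x, c(-0.5, -0.75, 0.125, 0.5625))
  expect_equal(traj$y, c(-0.5, 0.25, 0.625, -0.1875))
  expect_equal(traj$residue, c("C", "A", "T", "G"))
  empty <- cgr_encode("")
  expect_equal(nrow(empty), 0L)
})

test_that("trajectories stay strictly inside the open square and are deterministic", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      s <- random_seq(150)
      tr <- cgr_encode(s)
      expect_equal(nrow(tr), 150L)
      expect_true(all(abs(tr$x) < 1 & abs(tr$y) < 1))
      expect_identical(tr, cgr_encode(s))
    }
  })
})

test_that("sequence normalisation case-folds, maps U to T, and enforces policy", {
  expect_equal(normalize_sequence("acgu"), "ACGT")
  expect_error(normalize_sequence("ACXGT"), "position 3",
               class = "enhancaps_alphabet_error")
  expect_equal(normalize_sequence("ACXGT", policy = "skip"), "ACGT")
  # skip emits no point for the bad character: same trajectory as without it
  expect_equal(cgr_encode("ACXGT", policy = "skip")[, c("x", "y")],
               cgr_encode("ACGT")[, c("x", "y")])
})

test_that("rasterisation bins points half-open with row 1 at the top", {
  img <- fcgr_rasterize(cgr_encode("T"), n = 2)
  expect_equal(unclass(img)[1, 2], 1L)
  expect_equal(sum(img), 1L)
  expect_error(fcgr_rasterize(cgr_encode("T"), n = 0),
               class = "enhancaps_parameter_error")
  # conservation at several resolutions
  withr::with_seed(5, {
    s <- random_seq(200)
    tr <- cgr_encode(s)
    for (n in c(1, 2, 7, 16, 64)) {
      expect_equal(sum(fcgr_rasterize(tr, n)), 200L)
    }
  })
  # normalization variants
  expect_equal(sum(fcgr_rasterize(tr <- cgr_encode("ACGT"), 4,
                                  normalization = "per_total")), 1)
  expect_equal(max(fcgr_rasterize(tr, 4, normalization = "per_max")), 1)
})

test_that("kmer_counts enumerates sliding windows exactly", {
  kc <- kmer_counts("ACGTACGT", 2)
  expect_equal(setNames(kc$count, kc$kmer),
               c(AC = 2L, CG = 2L, GT = 2L, TA = 1L))
  expect_equal(sum(kc$count), 7L)
  kc1 <- kmer_counts("AAAA", 1)
  expect_equal(setNames(kc1$count, kc1$kmer), c(A = 4L))
  expect_equal(nrow(kmer_counts("AC", 3)), 0L)
})

test_that("kmer_suffix_cell maps suffixes to their closed-form cell", {
  expect_equal(kmer_suffix_cell("T", 2), c(row = 1, col = 2))
  expect_equal(kmer_suffix_cell("A", 2), c(row = 1, col = 1))
  expect_equal(kmer_suffix_cell("C", 2), c(row = 2, col = 1))
  expect_equal(kmer_suffix_cell("G", 2), c(row = 2, col = 2))
  # hand-traced: "GT" lands at (0.75, 0.25) -> row 2, col 4 at N = 4
  expect_equal(kmer_suffix_cell("GT", 4), c(row = 2, col = 4))
  expect_error(kmer_suffix_cell("GT", 8), class = "enhancaps_parameter_error")
  expect_error(kmer_suffix_cell("NT", 4), class = "enhancaps_alphabet_error")
})

test_that("FCGR counts equal brute-force k-mer counts via the suffix map", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      s <- random_seq(120)
      tr <- cgr_encode(s)
      for (k in 1:4) {
        n <- 2^k
        img <- fcgr_rasterize(tr, n)
        # restrict to points i >= k
        img_k <- fcgr_rasterize(tr[k:nrow(tr), ], n)
        kc <- kmer_counts(s, k)
        expected <- matrix(0L, n, n)
        for (r in seq_len(nrow(kc))) {
          cell <- kmer_suffix_cell(kc$kmer[r], n)
          expected[cell["row"], cell["col"]] <- kc$count[r]
        }
        expect_identical(fcgr_counts(img_k), expected)
        # full image differs from the suffix-restricted one by <= k-1 points
        expect_lte(sum(abs(fcgr_counts(img) - expected)), k - 1)
      }
    }
  })
})

test_that("k-mer counts agree with an independent counter", {
  withr::with_seed(31, {
    s <- random_seq(300)
    for (k in c(1, 2, 3)) {
      ours <- kmer_counts(s, k)
      ref <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), k)
      ref <- ref[ref > 0]
      expect_equal(setNames(ours$count, ours$kmer),
                   setNames(as.integer(ref), names(ref))[ours$kmer])
      expect_setequal(ours$kmer, names(ref))
    }
  })
})

test_that("the cell of point i depends only on the last k residues", {
  withr::with_seed(41, {
    k <- 3; n <- 2^k
    suffix <- random_seq(k)
    for (rep in 1:5) {
      pre1 <- random_seq(30); pre2 <- random_seq(30)
      cell_of_last <- function(s) {
        tr <- cgr_encode(s)
        last <- tr[nrow(tr), ]
        c(row = floor((1 - last$y) / 2 * n) + 1,
          col = floor((last$x + 1) / 2 * n) + 1)
      }
      expect_equal(cell_of_last(paste0(pre1, suffix)),
                   cell_of_last(paste0(pre2, suffix)))
      expect_equal(cell_of_last(paste0(pre1, suffix)),
                   kmer_suffix_cell(suffix, n))
    }
  })
})

test_that("gc_content computes the G+C fraction and rejects empty input", {
  expect_equal(gc_content(c("GGCC", "ATAT", "ACGT")), c(1, 0, 0.5))
  expect_error(gc_content(""), class = "enhancaps_undefined_value_error")
})

test_that("fcgr_encode adds a validated list-column of images", {
  d <- tibble::tibble(id = c("a", "b"), sequence = c("ACGTACGT", "ggggcccc"))
  out <- fcgr_encode(d, n = 4)
  expect_s3_class(out, "tbl_df")
  expect_length(out$fcgr, 2L)
  expect_s3_class(out$fcgr[[1]], "fcgr_image")
  expect_equal(attr(out$fcgr[[1]], "resolution"), 4L)
  expect_equal(attr(out$fcgr[[2]], "id"), "b")
  expect_equal(sum(out$fcgr[[2]]), 8L)
  expect_error(fcgr_encode(d, sequence_col = "seqs"),
               class = "enhancaps_parameter_error")
})
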