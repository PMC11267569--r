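# Synthetic sequence generator: composition, determinism, motif planting,
# benchmark-shaped two-stage sets, and manifest replay.

test_that("per-position composition follows the GC profile", {
  all_gc <- sim_sequences(10, sim_profile("x", gc = 1, length = 100), seed = 1)
  expect_true(all(grepl("^[GC]+$", all_gc$sequence)))
  no_gc <- sim_sequences(5, sim_profile("x", gc = 0, length = 100), seed = 1)
  expect_true(all(grepl("^[AT]+$", no_gc$sequence)))
  # gc = 0.5 at n x length = 1000 x 200 draws: binomial se ~= 0.0011
  d <- sim_sequences(1000, sim_profile("x", gc = 0.5, length = 200), seed = 2)
  expect_lt(abs(mean(gc_content(d$sequence)) - 0.5), 3 * sqrt(0.25 / 200000))
  expect_error(sim_profile("x", gc = 1.2), class = "enhancaps_parameter_error")
})

test_that("generation is deterministic under seed", {
  p <- sim_profile("y", gc = 0.4, length = 50,
                   motifs = data.frame(motif = "GGGGGG", prob = 0.5))
  expect_identical(sim_sequences(20, p, seed = 33), sim_sequences(20, p, seed = 33))
  expect_false(identical(sim_sequences(20, p, seed = 33),
                         sim_sequences(20, p, seed = 34)))
})

test_that("motif planting substitutes in place", {
  withr::with_seed(3, {
    s <- random_seq(200)
    out <- plant_motif(s, "GGGGGG")
    expect_equal(nchar(out), 200L)
    expect_true(grepl("GGGGGG", out))
    out5 <- plant_motif(s, "ACGT", position = 5)
    expect_equal(substr(out5, 5, 8), "ACGT")
    expect_equal(substr(out5, 1, 4), substr(s, 1, 4))
    expect_error(plant_motif("ACG", "ACGTACGT"), class = "enhancaps_parameter_error")
    # fixed rng stream -> fixed offset
    o1 <- withr::with_seed(9, plant_motif(s, "TTTTT"))
    o2 <- withr::with_seed(9, plant_motif(s, "TTTTT"))
    expect_identical(o1, o2)
  })
  # motifs raise a class-conditional k-mer signal
  pm <- sim_profile("m", gc = 0.5, length = 100,
                    motifs = data.frame(motif = "GGGGGG", prob = 1))
  withm <- sim_sequences(30, pm, seed = 5)
  expect_true(all(grepl("GGGGGG", withm$sequence)))
})

test_that("benchmark-shaped generation has the right sizes, labels and GC order", {
  ds <- sim_enhancer_benchmark(n_train = c(enhancer = 10, nonenhancer = 10,
                                           strong = 5, weak = 5),
                               n_test = c(strong = 3, weak = 3, nonenhancer = 6),
                               seed = 11)
  s1 <- ds$stage1; s2 <- ds$stage2
  expect_equal(sum(s1$split == "train"), 20L)
  expect_equal(sum(s2$split == "train"), 10L)
  expect_setequal(unique(s1$label), c("enhancer", "nonenhancer"))
  expect_setequal(unique(s2$label), c("strong", "weak"))
  # the stage-2 test records are the stage-1 enhancer test records
  expect_setequal(s2$id[s2$split == "test"],
                  s1$id[s1$split == "test" & s1$label == "enhancer"])
  expect_equal(anyDuplicated(c(s1$id, s2$id[s2$split == "train"])), 0L)
  # GC ordering at n = 500/class under the default gap
  big <- sim_enhancer_benchmark(n_train = c(enhancer = 500, nonenhancer = 500,
                                            strong = 10, weak = 10),
                                n_test = c(strong = 2, weak = 2, nonenhancer = 2),
                                seed = 12)
  tr <- big$stage1[big$stage1$split == "train", ]
  expect_gt(mean(gc_content(tr$sequence[tr$label == "enhancer"])),
            mean(gc_content(tr$sequence[tr$label == "nonenhancer"])))
  expect_error(sim_enhancer_benchmark(n_train = c(enhancer = 1, nonenhancer = 4,
                                                  strong = 2, weak = 2),
                                      seed = 1),
               class = "enhancaps_parameter_error")
})

test_that("a manifest replays to the identical dataset", {
  ds <- sim_enhancer_benchmark(seed = 77)
  again <- sim_replay(ds$manifest)
  expect_identical(ds$stage1, again$stage1)
  expect_identical(ds$stage2, again$stage2)
})

test_that("GC-separated classes give separated mean FCGR images", {
  d <- sim_two_class(25, seed = 19) |> fcgr_encode(n = 16)
  mean_img <- function(lbl) {
    Reduce(`+`, lapply(d$fcgr[d$label == lbl], unclass)) / sum(d$label == lbl)
  }
  expect_gt(sum(abs(mean_img("positive") - mean_img("negative"))), 0)
})

test_that("profile GC ordering violations warn but proceed", {
  profs <- default_profiles <- enhancaps:::default_benchmark_profiles(50L)
  profs$strong$gc <- 0.4; profs$weak$gc <- 0.6
  expect_warning(
    sim_enhancer_benchmark(n_train = c(enhancer = 4, nonenhancer = 4,
                                       strong = 2, weak = 2),
                           n_test = c(strong = 2, weak = 2, nonenhancer = 2),
                           profiles = profs, length = 50L, seed = 3),
    "ordering")
})
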