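# Synthetic benchmark-shaped sequence generator. The only class contrast the
# real enhancer benchmark documents quantitatively is GC content (enhancers
# GC-richer than non-enhancers, strong GC-richer than weak), so the generator
# draws positions i.i.d. with P(G) = P(C) = gc/2, P(A) = P(T) = (1 - gc)/2
# and can additionally plant fixed k-mer motifs so that k-mer-resolution
# claims are testable independently of GC.

.sim_version <- "1"

#' Define a synthetic sequence class profile
#'
#' @param label Class label attached to generated records.
#' @param gc Target GC fraction in `[0, 1]`.
#' @param length Sequence length in bp (default 200, the benchmark's clip
#'   length).
#' @param motifs Optional data frame with columns `motif` (A/C/G/T string)
#'   and `prob` (per-sequence insertion probability in `[0, 1]`).
#' @return A `sim_profile` list.
#' @export
sim_profile <- function(label, gc, length = 200L, motifs = NULL) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    abort("`gc` must be a single value in [0, 1].",
          class = "enhancaps_parameter_error")
  }
  if (!is.numeric(length) || length < 1 || length != round(length)) {
    abort("`length` must be a positive integer.",
          class = "enhancaps_parameter_error")
  }
  if (!is.null(motifs)) {
    stopifnot(is.data.frame(motifs), all(c("motif", "prob") %in% names(motifs)))
    motifs$motif <- normalize_sequence(motifs$motif, "strict")
    if (any(nchar(motifs$motif) >= length)) {
      abort("Motifs must be shorter than the sequence length.",
            class = "enhancaps_parameter_error")
    }
    if (any(motifs$prob < 0 | motifs$prob > 1)) {
      abort("Motif probabilities must lie in [0, 1].",
            class = "enhancaps_parameter_error")
    }
  }
  structure(list(label = as.character(label), gc = gc,
                 length = as.integer(length), motifs = motifs),
            class = "sim_profile")
}

#' Generate one class of synthetic sequences
#'
#' Positions are i.i.d. with `P(G) = P(C) = gc/2`, `P(A) = P(T) = (1-gc)/2`;
#' motifs are then substituted in place at uniform-random offsets with their
#' stated per-sequence probabilities. Fully deterministic under `seed`.
#'
#' @param n Number of sequences (>= 1).
#' @param profile A [sim_profile()].
#' @param seed Integer RNG seed.
#' @param id_prefix Prefix for record identifiers.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
sim_sequences <- function(n, profile, seed, id_prefix = profile$label) {
  if (!inherits(profile, "sim_profile")) {
    abort("`profile` must be a `sim_profile`.", class = "enhancaps_parameter_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.", class = "enhancaps_parameter_error")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n <- as.integer(n)
  len <- profile$length
  p <- c(A = (1 - profile$gc) / 2, C = profile$gc / 2,
         G = profile$gc / 2, T = (1 - profile$gc) / 2)
  withr::local_seed(seed)
  draws <- sample(names(p), n * len, replace = TRUE, prob = p)
  seqs <- vapply(split(draws, rep(seq_len(n), each = len)),
                 paste0, character(1L), collapse = "")
  names(seqs) <- NULL
  if (!is.null(profile$motifs)) {
    for (r in seq_len(nrow(profile$motifs))) {
      motif <- profile$motifs$motif[r]
      hit <- runif(n) < profile$motifs$prob[r]
      for (i in which(hit)) {
        seqs[i] <- plant_motif(seqs[i], motif)
      }
    }
  }
  tibble(id = sprintf("%s_%0*d", id_prefix, nchar(n), seq_len(n)),
         sequence = seqs, label = profile$label)
}

#' Substitute a motif into a sequence at a (random) offset
#'
#' Length-preserving in-place substitution. If `position` is `NULL` the
#' offset is drawn uniformly from the current RNG stream.
#'
#' @param sequence A single DNA sequence.
#' @param motif Motif to plant (shorter than the sequence).
#' @param position Optional 1-based start; default uniform random.
#' @return The modified sequence.
#' @export
plant_motif <- function(sequence, motif, position = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  k <- nchar(motif)
  if (k > len) {
    abort("Motif is longer than the sequence.",
          class = "enhancaps_parameter_error")
  }
  if (is.null(position)) {
    position <- sample.int(len - k + 1L, 1L)
  }
  stopifnot(position >= 1L, position + k - 1L <= len)
  paste0(substr(sequence, 1L, position - 1L), motif,
         substr(sequence, position + k, len))
}

default_benchmark_profiles <- function(length = 200L) {
  list(
    nonenhancer = sim_profile("nonenhancer", gc = 0.40, length = length),
    weak        = sim_profile("weak",        gc = 0.55, length = length),
    strong      = sim_profile("strong",      gc = 0.65, length = length)
  )
}

#' Generate a two-stage benchmark-shaped synthetic dataset
#'
#' Emulates the enhancer benchmark's structure at any scale: a stage-1 set
#' (enhancers, built as an even strong/weak mix, versus non-enhancers), a
#' stage-2 set (strong versus weak), and a disjoint independent test split.
#' Default GC profiles follow the documented ordering
#' strong > weak > nonenhancer (0.65 / 0.55 / 0.40).
#'
#' @param n_train Named counts `c(enhancer = , nonenhancer = , strong = ,
#'   weak = )`; the benchmark's own sizes are 1484/1484/742/742. The stage-2
#'   train records double as the stage-1 enhancer records when
#'   `strong + weak == enhancer`.
#' @param n_test Named counts `c(strong = , weak = , nonenhancer = )`,
#'   benchmark sizes 100/100/200.
#' @param profiles Named list of [sim_profile()]s for `nonenhancer`, `weak`,
#'   `strong`.
#' @param length Sequence length in bp.
#' @param seed Integer RNG seed; regeneration from the returned manifest is
#'   exact.
#' @return A list with tibbles `stage1` and `stage2` (columns `id`,
#'   `sequence`, `label`, `split`) and a `manifest` list.
#' @export
sim_enhancer_benchmark <- function(n_train = c(enhancer = 148, nonenhancer = 148,
                                               strong = 74, weak = 74),
                                   n_test = c(strong = 10, weak = 10,
                                              nonenhancer = 20),
                                   profiles = default_benchmark_profiles(length),
                                   length = 200L, seed) {
  stopifnot(all(c("enhancer", "nonenhancer", "strong", "weak") %in% names(n_train)),
            all(c("strong", "weak", "nonenhancer") %in% names(n_test)))
  if (any(c(n_train, n_test) < 2)) {
    abort("All class sizes must be >= 2.", class = "enhancaps_parameter_error")
  }
  stopifnot(all(c("nonenhancer", "weak", "strong") %in% names(profiles)))
  if (profiles$strong$gc <= profiles$weak$gc) {
    warn("Profile GC ordering violates strong > weak; proceeding (stress test?).")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)

  # one sub-seed per block, derived deterministically from `seed`
  sub <- (as.integer(seed) * 101L + seq_len(6L) * 1009L) %% .Machine$integer.max
  n_str <- ceiling(n_train[["enhancer"]] / 2)
  n_wk <- n_train[["enhancer"]] - n_str
  tr_enh <- dplyr::bind_rows(
    sim_sequences(n_str, profiles$strong, sub[1L], id_prefix = "tr_enh_s"),
    sim_sequences(n_wk, profiles$weak, sub[2L], id_prefix = "tr_enh_w")
  )
  tr_non <- sim_sequences(n_train[["nonenhancer"]], profiles$nonenhancer,
                          sub[3L], id_prefix = "tr_non")
  te_str <- sim_sequences(n_test[["strong"]], profiles$strong, sub[4L],
                          id_prefix = "te_str")
  te_wk <- sim_sequences(n_test[["weak"]], profiles$weak, sub[5L],
                         id_prefix = "te_wk")
  te_non <- sim_sequences(n_test[["nonenhancer"]], profiles$nonenhancer,
                          sub[6L], id_prefix = "te_non")

  relab <- function(d, lab) dplyr::mutate(d, label = lab)
  stage1 <- dplyr::bind_rows(
    dplyr::mutate(relab(tr_enh, "enhancer"), split = "train"),
    dplyr::mutate(relab(tr_non, "nonenhancer"), split = "train"),
    dplyr::mutate(relab(dplyr::bind_rows(te_str, te_wk), "enhancer"), split = "test"),
    dplyr::mutate(relab(te_non, "nonenhancer"), split = "test")
  )
  tr_s2 <- dplyr::bind_rows(
    sim_sequences(n_train[["strong"]], profiles$strong,
                  (sub[1L] + 7L) %% .Machine$integer.max, id_prefix = "tr_s2_s"),
    sim_sequences(n_train[["weak"]], profiles$weak,
                  (sub[2L] + 7L) %% .Machine$integer.max, id_prefix = "tr_s2_w")
  )
  stage2 <- dplyr::bind_rows(
    dplyr::mutate(tr_s2, split = "train"),
    dplyr::mutate(dplyr::bind_rows(te_str, te_wk), split = "test")
  )
  manifest <- list(version = .sim_version, seed = seed,
                   n_train = as.list(n_train), n_test = as.list(n_test),
                   length = as.integer(length),
                   gc = lapply(profiles, `[[`, "gc"))
  list(stage1 = stage1, stage2 = stage2, manifest = manifest)
}

#' Replay a synthetic benchmark from its manifest
#'
#' @param manifest The `manifest` element returned by
#'   [sim_enhancer_benchmark()].
#' @return The identical dataset list.
#' @export
sim_replay <- function(manifest) {
  stopifnot(is.list(manifest), identical(manifest$version, .sim_version))
  profiles <- default_benchmark_profiles(manifest$length)
  for (nm in names(manifest$gc)) profiles[[nm]]$gc <- manifest$gc[[nm]]
  sim_enhancer_benchmark(n_train = unlist(manifest$n_train),
                         n_test = unlist(manifest$n_test),
                         profiles = profiles,
                         length = manifest$length, seed = manifest$seed)
}

#' Generate a simple two-class sequence set
#'
#' Convenience wrapper used in training experiments: `n_per_class` sequences
#' for each of a negative and a positive class that differ only in GC
#' fraction.
#'
#' @param n_per_class Sequences per class.
#' @param gc Length-2 named numeric, GC fractions `c(negative = , positive = )`.
#' @param labels Length-2 character, class labels (negative, positive).
#' @param length Sequence length in bp.
#' @param seed Integer RNG seed.
#' @param id_prefix Prefix on record ids (keep train/test draws disjoint by
#'   id, e.g. `"tr"` / `"te"`).
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @export
sim_two_class <- function(n_per_class, gc = c(negative = 0.40, positive = 0.60),
                          labels = c("negative", "positive"), length = 200L,
                          seed, id_prefix = "") {
  stopifnot(length(gc) == 2L, length(labels) == 2L)
  sub <- (as.integer(seed) * 131L + c(1L, 2L) * 2003L) %% .Machine$integer.max
  pre <- if (nzchar(id_prefix)) paste0(id_prefix, "_") else ""
  dplyr::bind_rows(
    sim_sequences(n_per_class, sim_profile(labels[1L], gc[[1L]], length),
                  sub[1L], id_prefix = paste0(pre, labels[1L])),
    sim_sequences(n_per_class, sim_profile(labels[2L], gc[[2L]], length),
                  sub[2L], id_prefix = paste0(pre, labels[2L]))
  )
}
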