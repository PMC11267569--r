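# Chaos game representation (CGR) of DNA and its frequency discretisation
# (FCGR). The CGR places residue i at the midpoint between the previous
# point and the corner assigned to that nucleotide; after >= k steps the
# point lies in the sub-square indexed by the length-k suffix, so an
# N = 2^k raster of point counts is (up to the first k-1 points) a k-mer
# count table.

# Corner assignment: A upper-left, C lower-left, G lower-right, T upper-right
# on the square [-1, 1]^2. Sub-squares of the T quadrant then read TT, GT,
# CT, AT clockwise from the outer corner.
.cgr_corners <- matrix(
  c(-1, +1,   # A
    -1, -1,   # C
    +1, -1,   # G
    +1, +1),  # T
  nrow = 4, ncol = 2, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("x", "y"))
)

#' Corner coordinates of a nucleotide in the CGR square
#'
#' Each canonical nucleotide owns one vertex of the unit square
#' \eqn{[-1,1]^2}: A upper-left \eqn{(-1,+1)}, C lower-left \eqn{(-1,-1)},
#' G lower-right \eqn{(+1,-1)}, T upper-right \eqn{(+1,+1)}.
#'
#' @param symbol A single character, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A named numeric vector `c(x = , y = )`.
#' @examples
#' nucleotide_corner("T")
#' @export
nucleotide_corner <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || is.na(symbol)) {
    abort("`symbol` must be a single character.", class = "enhancaps_alphabet_error")
  }
  if (!symbol %in% rownames(.cgr_corners)) {
    abort(
      sprintf("Invalid nucleotide '%s': expected one of A, C, G, T.", symbol),
      class = "enhancaps_alphabet_error"
    )
  }
  c(x = .cgr_corners[symbol, "x"], y = .cgr_corners[symbol, "y"])
}

#' Normalise a DNA sequence to the A/C/G/T alphabet
#'
#' Case-folds, maps U to T, and handles any remaining character according to
#' `policy`: `"strict"` raises an error naming the first offending character
#' and its position; `"skip"` silently drops offending characters (the CGR
#' walk keeps its previous position, i.e. emits no point for them).
#'
#' @param sequence Character vector of sequences.
#' @param policy `"strict"` (default) or `"skip"`.
#' @param ids Optional identifiers used in error messages.
#' @return Character vector of normalised sequences.
#' @export
normalize_sequence <- function(sequence, policy = c("strict", "skip"), ids = NULL) {
  policy <- match.arg(policy)
  out <- chartr("u", "T", toupper(sequence))
  out <- chartr("U", "T", out)
  bad <- regexpr("[^ACGT]", out)
  if (any(bad > 0L)) {
    if (policy == "strict") {
      i <- which(bad > 0L)[1L]
      ch <- substr(out[i], bad[i], bad[i])
      who <- if (!is.null(ids)) sprintf(" in record '%s'", ids[i]) else
        if (length(out) > 1L) sprintf(" in sequence %d", i) else ""
      abort(
        sprintf("Invalid character '%s' at position %d%s (alphabet is A/C/G/T; U folds to T).",
                ch, bad[i], who),
        class = "enhancaps_alphabet_error"
      )
    }
    out <- gsub("[^ACGT]", "", out)
  }
  out
}

#' Encode one DNA sequence as a CGR trajectory
#'
#' Starting from the origin, residue \eqn{i} is placed at the midpoint of the
#' previous point and the corner of nucleotide \eqn{s_i}:
#' \eqn{(x_i, y_i) = \frac{1}{2}\big((x_{i-1}, y_{i-1}) + corner(s_i)\big)},
#' with \eqn{(x_0, y_0) = (0, 0)}. All points lie strictly inside the open
#' square \eqn{(-1,1)^2}.
#'
#' @param sequence A single DNA sequence (character scalar).
#' @param policy Non-ACGT handling, see [normalize_sequence()].
#' @return A tibble with columns `index`, `residue`, `x`, `y`, one row per
#'   encoded residue (zero rows for an empty sequence).
#' @examples
#' cgr_encode("CATG")
#' @export
cgr_encode <- function(sequence, policy = c("strict", "skip")) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- normalize_sequence(sequence, policy)
  n <- nchar(seq)
  if (n == 0L) {
    return(tibble(index = integer(), residue = character(),
                  x = numeric(), y = numeric()))
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(res, rownames(.cgr_corners))
  xy <- cgr_walk_cpp(idx)
  tibble(index = seq_len(n), residue = res, x = xy[, 1L], y = xy[, 2L])
}

#' Rasterise a CGR trajectory into an N x N FCGR count image
#'
#' Point \eqn{(x, y)} increments the half-open cell with 1-based indices
#' `col = floor((x + 1) / 2 * n) + 1`, `row = floor((1 - y) / 2 * n) + 1`,
#' clamped to `[1, n]`, so row 1 is the top (y = +1) edge and column 1 the
#' left (x = -1) edge and rendered images match the conventional CGR
#' orientation (T quadrant upper right).
#'
#' @param traj A trajectory as returned by [cgr_encode()], or any data frame
#'   with numeric `x` and `y` columns.
#' @param n Resolution (positive integer). `n = 2^k` makes cells correspond
#'   to k-mers.
#' @param normalization `"raw"` integer counts (default), `"per_total"`
#'   counts / total points, or `"per_max"` counts / max count.
#' @return An `fcgr_image`: an `n` x `n` numeric matrix with attributes
#'   `resolution`, `total_points` and `normalization`.
#' @export
fcgr_rasterize <- function(traj, n = 64L,
                           normalization = c("raw", "per_total", "per_max")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.", class = "enhancaps_parameter_error")
  }
  n <- as.integer(n)
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)))
  npts <- nrow(traj)
  counts <- matrix(0L, n, n)
  if (npts > 0L) {
    col <- pmin(pmax(floor((traj$x + 1) / 2 * n), 0), n - 1L) + 1L
    row <- pmin(pmax(floor((1 - traj$y) / 2 * n), 0), n - 1L) + 1L
    counts <- matrix(tabulate((col - 1L) * n + row, nbins = n * n), n, n)
  }
  counts <- switch(normalization,
    raw = counts,
    per_total = if (npts > 0L) counts / npts else counts * 0,
    per_max = if (max(counts) > 0L) counts / max(counts) else counts * 0
  )
  new_fcgr_image(counts, n, npts, normalization)
}

new_fcgr_image <- function(counts, resolution, total_points, normalization,
                           id = NULL) {
  structure(counts,
            resolution = as.integer(resolution),
            total_points = as.integer(total_points),
            normalization = normalization,
            id = id,
            class = c("fcgr_image", class(counts)))
}

#' @export
print.fcgr_image <- function(x, ...) {
  cat(sprintf("<fcgr_image> %d x %d, %d points, normalization = %s\n",
              attr(x, "resolution"), attr(x, "resolution"),
              attr(x, "total_points"), attr(x, "normalization")))
  invisible(x)
}

#' Encode a table of sequences as FCGR images
#'
#' Data-frame-first wrapper over [cgr_encode()] + [fcgr_rasterize()]: adds an
#' `fcgr` list-column of [fcgr_rasterize()] images to `data`.
#'
#' @param data A data frame with a character column of DNA sequences.
#' @param n Raster resolution, default 64 (6-mer resolution).
#' @param policy Non-ACGT handling, see [normalize_sequence()].
#' @param normalization See [fcgr_rasterize()].
#' @param sequence_col Name of the sequence column.
#' @return `data` as a tibble with an added `fcgr` list-column.
#' @examples
#' tibble::tibble(id = "s1", sequence = "ACGTACGT") |> fcgr_encode(n = 4)
#' @export
fcgr_encode <- function(data, n = 64L, policy = c("strict", "skip"),
                        normalization = c("raw", "per_total", "per_max"),
                        sequence_col = "sequence") {
  policy <- match.arg(policy)
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(data))
  if (!sequence_col %in% names(data)) {
    abort(sprintf("Column '%s' not found in `data`.", sequence_col),
          class = "enhancaps_parameter_error")
  }
  data <- as_tibble(data)
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  seqs <- normalize_sequence(data[[sequence_col]], policy, ids = ids)
  data$fcgr <- purrr::map2(seqs, ids, function(s, id) {
    img <- fcgr_rasterize(cgr_encode(s, policy = "strict"), n = n,
                          normalization = normalization)
    attr(img, "id") <- id
    img
  })
  data
}

#' Exact k-mer counts of a sequence
#'
#' Sliding-window counts of every length-`k` substring; counts sum to
#' `nchar(sequence) - k + 1`. Serves as the brute-force oracle for the
#' FCGR/k-mer equivalence: at resolution `2^k` the FCGR cells are k-mer
#' counts (up to the first `k - 1` trajectory points).
#'
#' @param sequence A single normalised DNA sequence.
#' @param k Positive integer word length.
#' @return A tibble with columns `kmer`, `count` (zero rows if
#'   `k > nchar(sequence)`).
#' @examples
#' kmer_counts("ACGTACGT", 2)
#' @export
kmer_counts <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer.", class = "enhancaps_parameter_error")
  }
  len <- nchar(sequence)
  if (k > len) return(tibble(kmer = character(), count = integer()))
  starts <- seq_len(len - k + 1L)
  words <- substring(sequence, starts, starts + k - 1L)
  tab <- table(words)
  tibble(kmer = names(tab), count = as.integer(tab))
}

#' Closed-form FCGR cell of a k-mer suffix
#'
#' At resolution \eqn{N = 2^k}, every trajectory point whose length-k suffix
#' equals `kmer` falls in one fixed cell. Reading the suffix with its last
#' character as the most significant bit: the x-bit is 1 for G/T (right
#' half), the y-bit is 1 for A/T (upper half). Returns 1-based `(row, col)`
#' matching [fcgr_rasterize()] indexing (row 1 at the top).
#'
#' @param kmer Character scalar over A/C/G/T.
#' @param n Resolution; must equal `2^nchar(kmer)`.
#' @return Integer vector `c(row = , col = )`.
#' @examples
#' kmer_suffix_cell("T", 2)   # upper-right quadrant
#' kmer_suffix_cell("GT", 4)
#' @export
kmer_suffix_cell <- function(kmer, n) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  k <- nchar(kmer)
  if (k < 1L || grepl("[^ACGT]", kmer)) {
    abort("`kmer` must be a non-empty string over A/C/G/T.",
          class = "enhancaps_alphabet_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n != 2^k) {
    abort(sprintf("`n` must equal 2^nchar(kmer) = %d.", 2^k),
          class = "enhancaps_parameter_error")
  }
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  w <- 2^(seq_len(k) - 1L)  # position p has weight 2^(p-1): last char most significant
  col0 <- sum((chars %in% c("G", "T")) * w)
  row0 <- n - 1L - sum((chars %in% c("A", "T")) * w)
  c(row = as.integer(row0 + 1L), col = as.integer(col0 + 1L))
}

#' GC content of sequences
#'
#' @param sequence Character vector of normalised DNA sequences.
#' @return Numeric vector of (#G + #C) / length, in `[0, 1]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGT"))
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence))
  len <- nchar(sequence)
  if (any(len == 0L)) {
    abort("GC content is undefined for an empty sequence.",
          class = "enhancaps_undefined_value_error")
  }
  gc <- nchar(gsub("[^GCgc]", "", sequence))
  gc / len
}

#' Save / load a stack of FCGR images as a single container
#'
#' Compact single-file archive (RDS) holding the resolution, record ids,
#' normalization metadata and count matrices; `fcgr_load(fcgr_save(x))`
#' restores the `fcgr` list-column bit-exactly.
#'
#' @param data A data frame with an `fcgr` list-column (see [fcgr_encode()]).
#' @param path Container path (written atomically).
#' @return `fcgr_save` returns `path` invisibly; `fcgr_load` returns a
#'   tibble with `id` and `fcgr` columns.
#' @export
fcgr_save <- function(data, path) {
  stopifnot(is.data.frame(data), "fcgr" %in% names(data))
  imgs <- data$fcgr
  payload <- list(
    schema = "enhancaps-fcgr-1",
    resolution = attr(imgs[[1L]], "resolution"),
    normalization = attr(imgs[[1L]], "normalization"),
    ids = if ("id" %in% names(data)) as.character(data$id) else
      as.character(seq_along(imgs)),
    total_points = vapply(imgs, function(im) attr(im, "total_points"),
                          integer(1L)),
    counts = lapply(imgs, function(im) {
      m <- unclass(im)
      attributes(m) <- attributes(m)["dim"]
      m
    })
  )
  atomic_write(path, function(p) saveRDS(payload, p, version = 3L))
}

#' @rdname fcgr_save
#' @export
fcgr_load <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "enhancaps-fcgr-1")) {
    abort(sprintf("'%s' is not an FCGR container.", path),
          class = "enhancaps_version_error")
  }
  tibble(
    id = payload$ids,
    fcgr = purrr::pmap(
      list(payload$counts, payload$ids, payload$total_points),
      function(m, id, tp) {
        new_fcgr_image(m, payload$resolution, tp, payload$normalization,
                       id = id)
      })
  )
}

#' Write FCGR images as tab-delimited text
#'
#' One `<id>.tsv` file per record (plain numeric matrix, no header), written
#' atomically (temp file then rename).
#'
#' @param data A data frame with `fcgr` list-column (see [fcgr_encode()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
fcgr_write_tsv <- function(data, dir) {
  stopifnot(is.data.frame(data), "fcgr" %in% names(data))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  paths <- file.path(dir, paste0(ids, ".tsv"))
  for (i in seq_along(paths)) {
    m <- unclass(data$fcgr[[i]])
    attributes(m) <- attributes(m)["dim"]
    atomic_write(paths[i], function(p) {
      utils::write.table(m, p, sep = "\t", row.names = FALSE, col.names = FALSE)
    })
  }
  invisible(paths)
}
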