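# File formats: FASTA input (via Biostrings), sidecar label TSV, versioned
# model checkpoints. All writers are atomic (temp file in the target
# directory, then rename), so interrupted runs never leave half-written
# outputs.

.checkpoint_schema <- "enhancaps-checkpoint-1"
.label_tokens <- c("enhancer", "nonenhancer", "strong", "weak",
                   "positive", "negative")

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("Failed to move temporary file into place at '%s'.", path),
          class = "enhancaps_io_error")
  }
  invisible(path)
}

#' Read a FASTA file of DNA sequences
#'
#' Preserves record order and identifiers (first whitespace-delimited header
#' token); sequences are normalised (case-folded, U -> T) under `policy`. A
#' header token `|label=<token>` is parsed into a `label` column when
#' present.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param policy Non-ACGT handling, see [normalize_sequence()].
#' @return A tibble with columns `id`, `sequence`, `length` (and `label` if
#'   header tokens carry one).
#' @export
read_fasta <- function(path, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'.", path),
          class = "enhancaps_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("Malformed FASTA '%s': %s", path,
                                  conditionMessage(e)),
                          class = "enhancaps_format_error")
                  })
  if (length(set) == 0L) {
    abort(sprintf("FASTA '%s' contains no records.", path),
          class = "enhancaps_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  label <- ifelse(grepl("\\|label=", ids),
                  sub("^.*\\|label=", "", ids), NA_character_)
  ids <- sub("\\|label=.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA id '%s'.", ids[duplicated(ids)][1L]),
          class = "enhancaps_format_error")
  }
  seqs <- unname(normalize_sequence(as.character(set), policy, ids = ids))
  out <- tibble(id = ids, sequence = seqs, length = nchar(seqs))
  if (any(!is.na(label))) out$label <- label
  out
}

#' Write sequences to FASTA
#'
#' @param data Data frame with `id` and `sequence` columns.
#' @param path Output path (written atomically).
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(data, path, width = 70L) {
  stopifnot(is.data.frame(data), all(c("id", "sequence") %in% names(data)))
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(data))) {
      writeLines(paste0(">", data$id[i]), con)
      s <- data$sequence[i]
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  })
}

#' Load a sidecar label table
#'
#' Two-column TSV (`id`, `label`), labels restricted to the recognised
#' tokens (enhancer/nonenhancer, strong/weak, positive/negative). Duplicate
#' ids are an error; when `fasta_ids` is supplied every labelled id must
#' exist in it.
#'
#' @param path Path to the TSV (a header line `id<TAB>label` is optional).
#' @param fasta_ids Optional character vector of valid ids.
#' @return A tibble with columns `id`, `label`.
#' @export
load_labels <- function(path, fasta_ids = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Label file not found: '%s'.", path),
          class = "enhancaps_io_error")
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          col.names = c("id", "label"))
  if (nrow(df) && identical(tolower(df$id[1L]), "id")) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) {
    abort(sprintf("Label file '%s' is empty.", path),
          class = "enhancaps_format_error")
  }
  if (anyDuplicated(df$id)) {
    abort(sprintf("Duplicate id '%s' in label file.",
                  df$id[duplicated(df$id)][1L]),
          class = "enhancaps_format_error")
  }
  bad <- setdiff(unique(df$label), .label_tokens)
  if (length(bad)) {
    abort(sprintf("Unknown label token(s) %s; allowed: %s.",
                  paste(sQuote(bad), collapse = ", "),
                  paste(.label_tokens, collapse = ", ")),
          class = "enhancaps_format_error")
  }
  if (!is.null(fasta_ids)) {
    missing_ids <- setdiff(df$id, fasta_ids)
    if (length(missing_ids)) {
      abort(sprintf("Labelled id '%s' not present in the FASTA.",
                    missing_ids[1L]),
            class = "enhancaps_format_error")
    }
  }
  as_tibble(df)
}

#' Save / load a model checkpoint
#'
#' Single-file container (RDS) holding the config, parameters, class
#' mapping, training seed and a schema version; `load_model(save_model(x))`
#' reproduces forward outputs bit-exactly. Loading checks the schema
#' version and fails loudly on truncated or foreign files.
#'
#' @param model A `caps_model`.
#' @param path Checkpoint path (written atomically).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `caps_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "caps_model"))
  payload <- list(schema = .checkpoint_schema, model = model,
                  r_version = as.character(getRversion()))
  atomic_write(path, function(p) saveRDS(payload, p, version = 3L))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Checkpoint not found: '%s'.", path),
          class = "enhancaps_io_error")
  }
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Corrupt or truncated checkpoint '%s': %s", path,
                  conditionMessage(e)),
          class = "enhancaps_io_error")
  })
  if (!is.list(payload) || !identical(payload$schema, .checkpoint_schema)) {
    abort(sprintf(
      "Checkpoint '%s' has schema '%s'; this build reads '%s'. Re-train or convert.",
      path, format(payload$schema), .checkpoint_schema),
      class = "enhancaps_version_error")
  }
  payload$model
}

#' Write a tibble as TSV (atomic)
#'
#' @param data Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_atomic <- function(data, path) {
  atomic_write(path, function(p) {
    utils::write.table(data, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
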