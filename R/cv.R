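# Stratified k-fold assignment and exhaustive grid search with k-fold
# cross-validation. Winner selection is deterministic under seed; ties are
# broken by grid order (the Cartesian expansion order of the axes).

#' Assign stratified cross-validation folds
#'
#' Within each class, records are shuffled and dealt round-robin into `k`
#' folds, so per-fold class counts differ from proportionality by at most
#' one record. Deterministic under `seed`.
#'
#' @param data Labelled data frame.
#' @param k Number of folds (default 5).
#' @param seed Integer RNG seed.
#' @param label_col Name of the label column.
#' @return `data` with an added integer `.fold` column in `1:k`.
#' @export
stratified_kfold <- function(data, k = 5L, seed, label_col = "label") {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  if (!is.numeric(k) || k < 2 || k != round(k)) {
    abort("`k` must be an integer >= 2.", class = "enhancaps_parameter_error")
  }
  labs <- as.character(data[[label_col]])
  if (any(table(labs) < k)) {
    abort(sprintf("Every class needs at least k = %d records.", k),
          class = "enhancaps_parameter_error")
  }
  withr::local_seed(seed)
  fold <- integer(nrow(data))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  data <- as_tibble(data)
  data$.fold <- fold
  data
}

grid_tunable_training <- c("lr", "epochs", "batch_size")

#' Grid search with stratified k-fold cross-validation
#'
#' Exhaustively evaluates the Cartesian product of the grid axes, scoring
#' each combination by mean cross-validated accuracy (percent). Axes named
#' after [caps_config()] fields modify the architecture; axes `lr`,
#' `epochs`, `batch_size` modify training. Invalid combinations (e.g. a
#' geometry that does not fit the input) are kept in the table with `NA`
#' accuracy and an error message. The winner is the highest mean accuracy,
#' ties broken by grid order; results are reproducible under `seed`
#' (per-cell training seeds are derived from it, independent of evaluation
#' order).
#'
#' @param data Labelled tibble with an `fcgr` list-column.
#' @param grid Named list of axis values, e.g.
#'   `list(primary_dim = c(4, 8), lr = c(0.1, 1e-3))`.
#' @param base_config A [caps_config()] supplying all non-tuned fields.
#' @param k Folds (default 5).
#' @param seed Integer RNG seed.
#' @param epochs,batch_size,lr Training defaults for axes not in the grid.
#' @param positive,label_col Passed to [caps_train()].
#' @param verbose Print per-cell progress.
#' @return A `caps_grid`: list with `best_config` (a `caps_config`),
#'   `best_settings` (named list incl. training settings), and `cv_table`
#'   (one row per combination with `mean_accuracy` and per-fold results).
#' @export
caps_grid_search <- function(data, grid, base_config = NULL, k = 5L, seed,
                             epochs = 10L, batch_size = 32L, lr = 1e-3,
                             positive = NULL, label_col = "label",
                             verbose = FALSE) {
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)) ||
      any(names(grid) == "") || any(lengths(grid) == 0L)) {
    abort("`grid` must be a non-empty named list of non-empty axes.",
          class = "enhancaps_parameter_error")
  }
  if (is.null(base_config)) {
    n <- attr(data$fcgr[[1L]], "resolution")
    base_config <- caps_config_small(input_resolution = if (is.null(n)) 64L else n)
  }
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folded <- stratified_kfold(data, k = k, seed = seed, label_col = label_col)

  defaults <- list(lr = lr, epochs = epochs, batch_size = batch_size)
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- as.list(cells[ci, , drop = FALSE])
    cfg_over <- cell[setdiff(names(cell), grid_tunable_training)]
    train_over <- modifyList(defaults, cell[intersect(names(cell), grid_tunable_training)])
    fold_acc <- rep(NA_real_, k)
    err <- NA_character_
    cfg <- tryCatch(
      do.call(caps_config, modifyList(config_as_args(base_config), cfg_over)),
      error = function(e) {
        err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(cfg)) {
      for (fi in seq_len(k)) {
        fit <- tryCatch({
          tr <- folded[folded$.fold != fi, , drop = FALSE]
          te <- folded[folded$.fold == fi, , drop = FALSE]
          cell_seed <- (as.integer(seed) + ci * 7919L + fi * 104729L) %%
            .Machine$integer.max
          model <- caps_train(tr, config = cfg, epochs = train_over$epochs,
                              batch_size = train_over$batch_size,
                              lr = train_over$lr, seed = cell_seed,
                              positive = positive, label_col = label_col)
          caps_evaluate(model, te, label_col = label_col, train_ids = NULL)
        }, error = function(e) {
          err <<- conditionMessage(e)
          NULL
        })
        if (is.null(fit)) break
        fold_acc[fi] <- fit$accuracy
      }
    }
    rows[[ci]] <- dplyr::bind_cols(
      as_tibble(cells[ci, , drop = FALSE]),
      tibble(mean_accuracy = if (all(is.finite(fold_acc))) mean(fold_acc) else NA_real_,
             fold_accuracy = list(fold_acc), error = err)
    )
    if (verbose) {
      message(sprintf("grid cell %d/%d: mean accuracy %s", ci, nrow(cells),
                      format(rows[[ci]]$mean_accuracy)))
    }
  }
  cv_table <- dplyr::bind_rows(rows)
  if (all(is.na(cv_table$mean_accuracy))) {
    abort("No grid combination trained successfully.",
          class = "enhancaps_parameter_error")
  }
  best_i <- which.max(cv_table$mean_accuracy)  # first max: grid-order tie-break
  best_cell <- as.list(cells[best_i, , drop = FALSE])
  best_config <- do.call(caps_config, modifyList(
    config_as_args(base_config), best_cell[setdiff(names(best_cell), grid_tunable_training)]))
  best_settings <- modifyList(defaults,
                              best_cell[intersect(names(best_cell), grid_tunable_training)])
  structure(list(best_config = best_config, best_settings = best_settings,
                 best_index = best_i, cv_table = cv_table, k = as.integer(k),
                 seed = seed, metric = "mean CV accuracy"),
            class = "caps_grid")
}

# constructor arguments of a caps_config (drop derived fields)
config_as_args <- function(config) {
  stopifnot(inherits(config, "caps_config"))
  x <- unclass(config)
  x[setdiff(names(x), c("h1", "h2", "L", "n_classes"))]
}

#' @export
print.caps_grid <- function(x, ...) {
  cat(sprintf("<caps_grid> %d combinations x %d-fold CV (metric: %s)\n",
              nrow(x$cv_table), x$k, x$metric))
  cat(sprintf("  best (row %d): mean accuracy %.1f%%\n", x$best_index,
              x$cv_table$mean_accuracy[x$best_index]))
  invisible(x)
}

#' @method tidy caps_grid
#' @export
tidy.caps_grid <- function(x, ...) {
  dplyr::select(x$cv_table, -"fold_accuracy")
}
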