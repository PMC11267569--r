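# Training (Adam on the margin loss), prediction, evaluation, and
# capsule-feature export. The decision rule is argmax of type-capsule
# lengths: positive iff p_positive > p_negative (exact tie -> negative).

# canonical label pairs: c(negative, positive)
.known_pairs <- list(c("nonenhancer", "enhancer"), c("weak", "strong"),
                     c("negative", "positive"))

resolve_classes <- function(labels, positive = NULL) {
  labs <- unique(as.character(labels))
  if (length(labs) != 2L) {
    abort(sprintf("Expected exactly 2 classes, found %d (%s).",
                  length(labs), paste(sort(labs), collapse = ", ")),
          class = "enhancaps_parameter_error")
  }
  if (is.null(positive)) {
    for (pair in .known_pairs) {
      if (setequal(labs, pair)) return(c(negative = pair[1L], positive = pair[2L]))
    }
    abort(sprintf(
      "Cannot infer the positive class from labels {%s}; supply `positive`.",
      paste(sort(labs), collapse = ", ")), class = "enhancaps_parameter_error")
  }
  if (!positive %in% labs) {
    abort(sprintf("`positive` ('%s') is not one of the labels {%s}.",
                  positive, paste(sort(labs), collapse = ", ")),
          class = "enhancaps_parameter_error")
  }
  c(negative = setdiff(labs, positive), positive = positive)
}

# stack the fcgr list-column into an N x N x B array, validating resolution
image_array <- function(data, config) {
  stopifnot(is.data.frame(data))
  if (!"fcgr" %in% names(data)) {
    abort("`data` must carry an `fcgr` list-column; run fcgr_encode() first.",
          class = "enhancaps_parameter_error")
  }
  n <- config$input_resolution
  imgs <- data$fcgr
  ok <- vapply(imgs, function(im) is.matrix(im) && all(dim(im) == n), logical(1L))
  if (!all(ok)) {
    abort(sprintf("All FCGR images must be %d x %d to match the config.", n, n),
          class = "enhancaps_config_error")
  }
  arr <- array(0, dim = c(n, n, nrow(data)))
  for (i in seq_len(nrow(data))) arr[, , i] <- unclass(imgs[[i]])
  arr
}

#' Train the capsule network
#'
#' Minimises the margin loss over labelled FCGR images by minibatch Adam.
#' All randomness (parameter initialisation, minibatch shuffling) is driven
#' by `seed`; a fixed seed gives bit-identical parameters on one machine.
#' With `epochs = 0` the returned parameters equal the initialisation.
#'
#' @param data Tibble with an `fcgr` list-column (see [fcgr_encode()]) and a
#'   label column with exactly two classes.
#' @param config A [caps_config()]; default [caps_config_small()] at the
#'   data's FCGR resolution.
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3; the margin loss frequently
#'   diverges under much larger rates, which aborts with a diagnostic).
#' @param seed Integer RNG seed (required).
#' @param positive Label treated as the positive class; inferred for the
#'   canonical pairs enhancer/nonenhancer, strong/weak, positive/negative.
#' @param label_col Name of the label column.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param verbose Print the per-epoch loss.
#' @return A `caps_model`: parameters, config, class mapping, per-epoch
#'   loss history, and the training manifest (seed, epochs, lr, batch size,
#'   record ids).
#' @export
caps_train <- function(data, config = NULL, epochs = 30L, batch_size = 32L,
                       lr = 1e-3, seed, positive = NULL, label_col = "label",
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       verbose = FALSE) {
  stopifnot(is.data.frame(data))
  if (missing(seed)) {
    abort("`seed` is required: training is stochastic.",
          class = "enhancaps_parameter_error")
  }
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column '%s' not found.", label_col),
          class = "enhancaps_parameter_error")
  }
  if (is.null(config)) {
    n <- attr(data$fcgr[[1L]], "resolution")
    config <- caps_config_small(input_resolution = if (is.null(n)) 64L else n)
  }
  stopifnot(inherits(config, "caps_config"))
  classes <- resolve_classes(data[[label_col]], positive)
  y <- as.integer(data[[label_col]] == classes[["positive"]])  # 0 neg, 1 pos
  arr <- image_array(data, config)
  b <- dim(arr)[3L]

  params <- caps_init(config, seed)
  m_state <- lapply(params, function(x) x * 0)
  v_state <- lapply(params, function(x) x * 0)
  step <- 0L
  history <- numeric(epochs)

  withr::local_seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(b)
    starts <- seq(1L, b, by = batch_size)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + batch_size - 1L, b)]
      res <- caps_batch_cpp(arr[, , idx, drop = FALSE], y[idx], params,
                            unclass(config), grad = TRUE)
      if (!is.finite(res$loss)) {
        abort(sprintf(
          "Training diverged: non-finite loss at epoch %d (lr = %g). Lower the learning rate.",
          ep, lr), class = "enhancaps_numeric_error")
      }
      ep_loss <- ep_loss + res$loss * length(idx)
      step <- step + 1L
      corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
      for (nm in names(params)) {
        g <- res$grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
          lr * corr * m_state[[nm]] / (sqrt(v_state[[nm]]) + epsilon)
      }
    }
    history[ep] <- ep_loss / b
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, history[ep]))
  }

  structure(list(
    params = params, config = config, classes = classes,
    loss_history = tibble(epoch = seq_len(epochs), loss = history),
    seed = seed, epochs = as.integer(epochs), lr = lr,
    batch_size = as.integer(batch_size),
    train_ids = if ("id" %in% names(data)) as.character(data$id) else NULL,
    n_train = b, version = "1"
  ), class = "caps_model")
}

#' @export
print.caps_model <- function(x, ...) {
  cat(sprintf("<caps_model> %s vs %s | head = %s | trained %d epochs on %d records (seed %s)\n",
              x$classes[["positive"]], x$classes[["negative"]],
              x$config$head, x$epochs, x$n_train, format(x$seed)))
  if (x$epochs > 0) {
    cat(sprintf("  final margin loss: %.5f\n",
                x$loss_history$loss[x$epochs]))
  }
  invisible(x)
}

#' @method tidy caps_model
#' @export
tidy.caps_model <- function(x, ...) x$loss_history

#' @method glance caps_model
#' @export
glance.caps_model <- function(x, ...) {
  tibble(positive = x$classes[["positive"]], head = x$config$head,
         epochs = x$epochs, n_train = x$n_train, lr = x$lr,
         batch_size = x$batch_size, seed = x$seed,
         final_loss = if (x$epochs > 0) x$loss_history$loss[x$epochs] else NA_real_,
         n_parameters = sum(vapply(x$params, length, integer(1L))))
}

#' Predict class probabilities for FCGR-encoded records
#'
#' @param object A `caps_model`.
#' @param data Tibble with an `fcgr` list-column.
#' @param ... Unused.
#' @return A tibble with `id` (if present), `p_negative`, `p_positive`
#'   (type-capsule lengths; independent, not summing to 1), and `.pred`
#'   (predicted label: positive iff `p_positive > p_negative`).
#' @method predict caps_model
#' @export
predict.caps_model <- function(object, data, ...) {
  arr <- image_array(data, object$config)
  res <- caps_batch_cpp(arr, rep(-1L, dim(arr)[3L]), object$params,
                        unclass(object$config), grad = FALSE)
  out <- tibble(
    p_negative = res$p[, 1L],
    p_positive = res$p[, 2L],
    .pred = ifelse(res$p[, 2L] > res$p[, 1L],
                   object$classes[["positive"]], object$classes[["negative"]])
  )
  if ("id" %in% names(data)) out <- dplyr::bind_cols(tibble(id = data$id), out)
  out
}

#' Evaluate a model on labelled test records
#'
#' Runs the forward pass on every record, applies the decision rule
#' (positive iff `p_positive > p_negative`), assembles the confusion matrix
#' and the full metric suite; AUC uses `p_positive` as the score.
#'
#' @param model A `caps_model`.
#' @param data Labelled tibble with an `fcgr` list-column.
#' @param label_col Name of the label column.
#' @param train_ids Optional ids of the training set; overlap with `data`'s
#'   ids triggers a warning (test-set disjointness is the caller's
#'   responsibility). Defaults to the ids recorded at training time.
#' @return A `metrics_report` (see [confusion_metrics()]) with AUC.
#' @export
caps_evaluate <- function(model, data, label_col = "label",
                          train_ids = model$train_ids) {
  stopifnot(inherits(model, "caps_model"))
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column '%s' not found.", label_col),
          class = "enhancaps_parameter_error")
  }
  if (!is.null(train_ids) && "id" %in% names(data)) {
    overlap <- intersect(as.character(data$id), train_ids)
    if (length(overlap)) {
      warn(sprintf("%d test record(s) overlap the training set (e.g. '%s').",
                   length(overlap), overlap[1L]))
    }
  }
  pred <- predict(model, data)
  truth_pos <- data[[label_col]] == model$classes[["positive"]]
  call_pos <- pred$.pred == model$classes[["positive"]]
  cm <- c(tp = sum(truth_pos & call_pos), tn = sum(!truth_pos & !call_pos),
          fp = sum(!truth_pos & call_pos), fn = sum(truth_pos & !call_pos))
  auc <- auc_score(pred$p_positive, truth_pos, positive = TRUE)
  confusion_metrics(cm[["tp"]], cm[["tn"]], cm[["fp"]], cm[["fn"]], auc = auc)
}

#' Export capsule-layer feature vectors
#'
#' One row per record: the flattened post-squash primary-capsule activities
#' (`L * m` columns) or the concatenated type-capsule vectors (`2 * n`
#' columns, negative capsule then positive).
#'
#' @param model A `caps_model`.
#' @param data Tibble with an `fcgr` list-column.
#' @param layer `"primary"` or `"type"`.
#' @return A tibble: `id` plus feature columns `<layer>_1`, `<layer>_2`, ...
#' @export
export_embeddings <- function(model, data, layer = c("primary", "type")) {
  stopifnot(inherits(model, "caps_model"))
  layer <- match.arg(layer)
  if (layer == "type" && model$config$head == "dense") {
    abort("The dense-head ablation model has no type-capsule layer.",
          class = "enhancaps_parameter_error")
  }
  arr <- image_array(data, model$config)
  res <- caps_batch_cpp(arr, rep(-1L, dim(arr)[3L]), model$params,
                        unclass(model$config), grad = FALSE,
                        want_primary = layer == "primary",
                        want_type = layer == "type")
  feats <- if (layer == "primary") res$primary else res$type
  colnames(feats) <- paste0(layer, "_", seq_len(ncol(feats)))
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  dplyr::bind_cols(tibble(id = ids), as_tibble(feats))
}
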