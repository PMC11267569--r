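# Two-stage prediction: stage 1 calls enhancer vs nonenhancer, stage 2
# grades strength (strong vs weak). Both stages consume the same FCGR
# representation (identical resolution and input scaling).

#' Bundle two trained models into a two-stage classifier
#'
#' @param stage1 `caps_model` separating enhancers from non-enhancers
#'   (positive class `enhancer`).
#' @param stage2 `caps_model` separating strong from weak enhancers
#'   (positive class `strong`).
#' @return A `caps_two_stage` object.
#' @export
caps_two_stage <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "caps_model"), inherits(stage2, "caps_model"))
  if (stage1$config$input_resolution != stage2$config$input_resolution ||
      stage1$config$input_scaling != stage2$config$input_scaling) {
    abort("Both stages must share the FCGR resolution and input scaling.",
          class = "enhancaps_config_error")
  }
  structure(list(stage1 = stage1, stage2 = stage2,
                 n = stage1$config$input_resolution),
            class = "caps_two_stage")
}

#' @export
print.caps_two_stage <- function(x, ...) {
  cat(sprintf("<caps_two_stage> N = %d\n  stage 1: %s vs %s\n  stage 2: %s vs %s\n",
              x$n,
              x$stage1$classes[["positive"]], x$stage1$classes[["negative"]],
              x$stage2$classes[["positive"]], x$stage2$classes[["negative"]]))
  invisible(x)
}

#' Two-stage prediction
#'
#' `mode = "chained"` is the deployment semantics: stage 2 runs only on
#' records stage 1 called positive (enhancer); others get `NA` stage-2
#' fields. `mode = "independent"` runs both stages on every record — the
#' benchmark semantics under which strong/weak test sets are scored.
#' Stage-1 outputs are identical between modes.
#'
#' @param object A [caps_two_stage()] model.
#' @param data Tibble with an `fcgr` list-column at the shared resolution.
#' @param mode `"chained"` or `"independent"`.
#' @return A tibble with `id`, `p_enhancer`, `stage1_call`, `p_strong`,
#'   `stage2_call`.
#' @export
predict_two_stage <- function(object, data, mode = c("chained", "independent")) {
  stopifnot(inherits(object, "caps_two_stage"))
  mode <- match.arg(mode)
  s1 <- predict(object$stage1, data)
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_len(nrow(data)))
  out <- tibble(id = ids,
                p_enhancer = s1$p_positive,
                stage1_call = s1$.pred,
                p_strong = NA_real_,
                stage2_call = NA_character_)
  run2 <- if (mode == "independent") rep(TRUE, nrow(out)) else
    out$stage1_call == object$stage1$classes[["positive"]]
  if (any(run2)) {
    s2 <- predict(object$stage2, data[run2, , drop = FALSE])
    out$p_strong[run2] <- s2$p_positive
    out$stage2_call[run2] <- s2$.pred
  }
  out
}
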