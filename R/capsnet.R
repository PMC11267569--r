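# Capsule-network configuration and the capsule-math building blocks
# (squash, prediction vectors, dynamic routing, capsule lengths, margin
# loss) as plain R functions on matrices/arrays. Training and batched
# prediction run through the compiled core; these R forms define the
# semantics and serve small instances.

#' Capsule network configuration
#'
#' Geometry of the classifier: a convolutional frontend, a primary-capsule
#' convolution whose output is reshaped into `L` capsules of dimension
#' `primary_dim` (m), and a two-capsule type layer of dimension `type_dim`
#' (n) reached by `routing_iterations` (r) rounds of dynamic routing.
#' Defaults follow the original capsule-network geometry on 64 x 64 FCGR
#' input: 32 frontend filters (9 x 9, stride 1, ReLU), primary conv 9 x 9
#' stride 2 with 8 capsule maps of dimension m = 8, type capsules of
#' dimension n = 32, r = 3. See [caps_config_small()] for a lighter preset.
#'
#' @param input_resolution FCGR resolution N (image is N x N).
#' @param conv_filters,conv_kernel,conv_stride Frontend conv spec.
#' @param primary_kernel,primary_stride Primary-capsule conv spec.
#' @param primary_maps Number of capsule maps (capsules per spatial
#'   position of the primary conv output).
#' @param primary_dim Primary capsule dimension m.
#' @param type_dim Type capsule dimension n.
#' @param routing_iterations Routing rounds r (>= 1).
#' @param head `"capsule"` (routing + type capsules) or `"dense"` (ablation:
#'   sigmoid dense layer on the flattened primary-capsule activities).
#' @param input_scaling Image scaling before the frontend: `"per_max"`
#'   (default; counts divided by the per-image maximum, keeping inputs in
#'   `[0, 1]` independent of sequence length), `"per_total"`, or `"none"`.
#' @param m_plus,m_minus,lambda_down Margin-loss parameters.
#' @return A `caps_config` list, with derived fields `h1`, `h2` (conv output
#'   sizes) and `L` (primary capsule count).
#' @export
caps_config <- function(input_resolution = 64L,
                        conv_filters = 32L, conv_kernel = 9L, conv_stride = 1L,
                        primary_kernel = 9L, primary_stride = 2L,
                        primary_maps = 8L, primary_dim = 8L,
                        type_dim = 32L, routing_iterations = 3L,
                        head = c("capsule", "dense"),
                        input_scaling = c("per_max", "per_total", "none"),
                        m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5) {
  head <- match.arg(head)
  input_scaling <- match.arg(input_scaling)
  ints <- c(input_resolution = input_resolution, conv_filters = conv_filters,
            conv_kernel = conv_kernel, conv_stride = conv_stride,
            primary_kernel = primary_kernel, primary_stride = primary_stride,
            primary_maps = primary_maps, primary_dim = primary_dim,
            type_dim = type_dim, routing_iterations = routing_iterations)
  bad <- names(ints)[!is.finite(ints) | ints < 1 | ints != round(ints)]
  if (length(bad)) {
    abort(sprintf("Config fields must be positive integers: %s.",
                  paste(bad, collapse = ", ")),
          class = "enhancaps_config_error")
  }
  if (conv_kernel > input_resolution) {
    abort("Frontend kernel exceeds the input resolution.",
          class = "enhancaps_config_error")
  }
  h1 <- (input_resolution - conv_kernel) %/% conv_stride + 1L
  if (primary_kernel > h1) {
    abort("Primary-capsule kernel exceeds the frontend output size.",
          class = "enhancaps_config_error")
  }
  h2 <- (h1 - primary_kernel) %/% primary_stride + 1L
  cfg <- list(input_resolution = as.integer(input_resolution),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_stride = as.integer(conv_stride),
              primary_kernel = as.integer(primary_kernel),
              primary_stride = as.integer(primary_stride),
              primary_maps = as.integer(primary_maps),
              primary_dim = as.integer(primary_dim),
              type_dim = as.integer(type_dim),
              n_classes = 2L,
              routing_iterations = as.integer(routing_iterations),
              head = head, input_scaling = input_scaling,
              m_plus = m_plus, m_minus = m_minus, lambda_down = lambda_down,
              h1 = as.integer(h1), h2 = as.integer(h2),
              L = as.integer(h2 * h2 * primary_maps))
  structure(cfg, class = "caps_config")
}

#' Lightweight capsule-network preset
#'
#' A CPU-friendly geometry used throughout the package's experiments:
#' 8 frontend filters at stride 2, 2 primary-capsule maps of dimension 8
#' (L = 200 capsules on 64 x 64 input), 16-dimensional type capsules.
#'
#' @param ... Overrides passed to [caps_config()].
#' @export
caps_config_small <- function(...) {
  defaults <- list(conv_filters = 8L, conv_stride = 2L, primary_maps = 2L,
                   type_dim = 16L)
  do.call(caps_config, modifyList(defaults, list(...)))
}

#' @export
print.caps_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<caps_config> input %dx%d | conv %d@%dx%d/%d -> %dx%d | primary %d maps",
    " x dim %d (L = %d) | type %d x dim %d | routing r = %d | head = %s\n"),
    x$input_resolution, x$input_resolution, x$conv_filters, x$conv_kernel,
    x$conv_kernel, x$conv_stride, x$h1, x$h1, x$primary_maps, x$primary_dim,
    x$L, x$n_classes, x$type_dim, x$routing_iterations, x$head))
  invisible(x)
}

#' Initialise network parameters
#'
#' He-style normal initialisation for the conv kernels, Glorot-style for the
#' routing weight matrices, zero biases. Deterministic under `seed`.
#'
#' @param config A [caps_config()].
#' @param seed Integer RNG seed.
#' @return A named list of parameter arrays (`conv1_w`, `conv1_b`,
#'   `conv2_w`, `conv2_b`, and `W` of shape `n x m x L x J` or
#'   `dense_w`/`dense_b` for the dense head).
#' @export
caps_init <- function(config, seed) {
  stopifnot(inherits(config, "caps_config"))
  withr::local_seed(seed)
  k1 <- config$conv_kernel; k2 <- config$primary_kernel
  f <- config$conv_filters
  ch <- config$primary_maps * config$primary_dim
  m <- config$primary_dim; n <- config$type_dim
  L <- config$L; J <- config$n_classes
  params <- list(
    conv1_w = array(rnorm(k1 * k1 * f, sd = sqrt(2 / (k1 * k1))),
                    dim = c(k1, k1, f)),
    conv1_b = numeric(f),
    conv2_w = array(rnorm(k2 * k2 * f * ch, sd = sqrt(2 / (k2 * k2 * f))),
                    dim = c(k2, k2, f, ch)),
    conv2_b = numeric(ch)
  )
  if (config$head == "capsule") {
    params$W <- array(rnorm(n * m * L * J, sd = sqrt(2 / (m + n))),
                      dim = c(n, m, L, J))
  } else {
    params$dense_w <- matrix(rnorm(J * L * m, sd = sqrt(2 / (L * m + J))),
                             nrow = J)
    params$dense_b <- numeric(J)
  }
  params
}

#' Squash nonlinearity
#'
#' \deqn{squash(s) = \frac{\|s\|^2}{1 + \|s\|^2} \frac{s}{\|s\|}}
#' keeps the direction and maps the norm to `[0, 1)`; the zero vector maps
#' exactly to zero.
#'
#' @param s A numeric vector (one capsule) or matrix (one capsule per row).
#' @return Same shape as `s`.
#' @examples
#' squash(c(3, 4))   # norm 25/26
#' @export
squash <- function(s) {
  if (is.matrix(s)) {
    n2 <- rowSums(s^2)
    f <- ifelse(n2 > 0, sqrt(n2) / (1 + n2), 0)
    return(s * f)
  }
  stopifnot(is.numeric(s))
  n2 <- sum(s^2)
  if (!is.finite(n2)) abort("Non-finite input to squash.", class = "enhancaps_numeric_error")
  if (n2 == 0) return(s)
  s * (sqrt(n2) / (1 + n2))
}

#' Prediction vectors from primary capsules
#'
#' \eqn{\hat{u}_{j|i} = W_{i,j} u_i}: each primary capsule's activity is
#' mapped into the type-capsule space by its learnable weight matrix.
#'
#' @param u Primary capsule activities, an `L x m` matrix (one capsule per
#'   row).
#' @param w Weight array of shape `n x m x L x J`.
#' @return An array of shape `L x J x n`.
#' @export
compute_prediction_vectors <- function(u, w) {
  stopifnot(is.matrix(u), is.array(w))
  dw <- dim(w)
  if (length(dw) != 4L || dw[2L] != ncol(u) || dw[3L] != nrow(u)) {
    abort(sprintf(
      "Shape mismatch: u is %d x %d but W is %s (need n x m x L x J with m = %d, L = %d).",
      nrow(u), ncol(u), paste(dw, collapse = " x "), ncol(u), nrow(u)),
      class = "enhancaps_config_error")
  }
  L <- nrow(u); J <- dw[4L]; n <- dw[1L]
  uhat <- array(0, dim = c(L, J, n))
  for (i in seq_len(L)) {
    for (j in seq_len(J)) {
      uhat[i, j, ] <- w[, , i, j] %*% u[i, ]
    }
  }
  uhat
}

#' Dynamic routing between capsule layers
#'
#' Routing logits start at zero; each of the `r` rounds computes coupling
#' coefficients `c[i, ] = softmax(b[i, ])` (softmax across type capsules),
#' the weighted sums \eqn{S_j = \sum_i c_{i,j} \hat{u}_{j|i}}, the squashed
#' outputs \eqn{V_j}, and (on all but the last round) the agreement update
#' \eqn{b_{i,j} \mathrel{+}= \hat{u}_{j|i} \cdot V_j}.
#'
#' @param uhat Prediction vectors, array `L x J x n` (see
#'   [compute_prediction_vectors()]).
#' @param r Number of routing iterations (>= 1).
#' @return A list with `v` (J x n matrix of type capsules), `coupling`
#'   (L x J), and `s` (J x n pre-squash sums).
#' @export
dynamic_routing <- function(uhat, r = 3L) {
  stopifnot(is.array(uhat), length(dim(uhat)) == 3L)
  if (!is.numeric(r) || r < 1 || r != round(r)) {
    abort("`r` must be a positive integer.", class = "enhancaps_parameter_error")
  }
  if (!all(is.finite(uhat))) {
    abort("Non-finite prediction vectors.", class = "enhancaps_numeric_error")
  }
  L <- dim(uhat)[1L]; J <- dim(uhat)[2L]; n <- dim(uhat)[3L]
  b <- matrix(0, L, J)
  v <- s <- matrix(0, J, n)
  cc <- matrix(0, L, J)
  for (t in seq_len(r)) {
    eb <- exp(b - apply(b, 1L, max))
    cc <- eb / rowSums(eb)
    for (j in seq_len(J)) {
      s[j, ] <- colSums(matrix(uhat[, j, ], nrow = L) * cc[, j])
      v[j, ] <- squash(s[j, ])
    }
    if (t < r) {
      for (j in seq_len(J)) {
        b[, j] <- b[, j] + matrix(uhat[, j, ], nrow = L) %*% v[j, ]
      }
    }
  }
  list(v = v, coupling = cc, s = s)
}

#' Type-capsule lengths (class probabilities)
#'
#' The Euclidean norm of each type capsule is the predicted probability of
#' its class; post-squash lengths lie in `[0, 1)` and are not constrained to
#' sum to 1.
#'
#' @param v Type capsules: a matrix with one capsule per row, or a single
#'   numeric vector.
#' @return Numeric vector of lengths.
#' @examples
#' capsule_lengths(rbind(c(0.3, 0.4), c(0, 0)))
#' @export
capsule_lengths <- function(v) {
  if (is.matrix(v)) return(sqrt(rowSums(v^2)))
  sqrt(sum(v^2))
}

#' Margin loss on capsule lengths
#'
#' \deqn{L = \sum_j T_j \max(0, m^+ - p_j)^2 +
#'   \lambda (1 - T_j) \max(0, p_j - m^-)^2}
#' with \eqn{T_j = 1} for the true class.
#'
#' @param p Class probabilities (capsule lengths), numeric vector.
#' @param label 1-based index of the true class.
#' @param m_plus,m_minus,lambda_down Margin parameters (defaults 0.9, 0.1,
#'   0.5).
#' @return Non-negative scalar loss.
#' @examples
#' margin_loss(c(0.5, 0.5), label = 1)  # 0.24
#' @export
margin_loss <- function(p, label, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  stopifnot(is.numeric(p), label >= 1, label <= length(p))
  t_j <- as.numeric(seq_along(p) == label)
  sum(t_j * pmax(0, m_plus - p)^2 +
        lambda_down * (1 - t_j) * pmax(0, p - m_minus)^2)
}

#' Forward pass of the capsule network on one FCGR image
#'
#' Deterministic composition: input scaling, conv frontend, primary capsules
#' (conv + reshape + squash), prediction vectors, dynamic routing, capsule
#' lengths. Exposes the intermediate capsule activities for embedding
#' export.
#'
#' @param image An `fcgr_image` or plain N x N numeric matrix matching the
#'   config resolution.
#' @param params Parameter list from [caps_init()] (or a trained model's
#'   `$params`).
#' @param config The [caps_config()] the parameters were built for.
#' @return A list with `p` (length-2 class probabilities: negative, positive
#'   class order), `type` (n x J type-capsule matrix), `primary` (L x m
#'   post-squash primary activities), and `coupling` (L x J routing
#'   coefficients).
#' @export
caps_forward <- function(image, params, config) {
  stopifnot(inherits(config, "caps_config"))
  img <- unclass(image)
  if (!is.matrix(img) || nrow(img) != config$input_resolution ||
      ncol(img) != config$input_resolution) {
    abort(sprintf("Image must be a %d x %d matrix for this config.",
                  config$input_resolution, config$input_resolution),
          class = "enhancaps_config_error")
  }
  storage.mode(img) <- "double"
  caps_forward_cpp(img, params, unclass(config))
}
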