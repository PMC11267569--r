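# Independent straight-line oracles, written as naive loops with no shared
# code paths with the package internals.

# Full forward pass of the network: plain nested loops.
oracle_forward <- function(img, params, cfg) {
  x <- unclass(img)
  if (cfg$input_scaling == "per_max" && max(x) > 0) x <- x / max(x)
  if (cfg$input_scaling == "per_total" && sum(x) > 0) x <- x / sum(x)
  sq <- function(v) {
    n2 <- sum(v * v)
    if (n2 == 0) v else v * sqrt(n2) / (1 + n2)
  }
  k1 <- cfg$conv_kernel; s1 <- cfg$conv_stride; nf <- cfg$conv_filters
  h1 <- cfg$h1
  a1 <- array(0, c(h1, h1, nf))
  for (f in seq_len(nf)) {
    for (r in seq_len(h1)) {
      for (cc in seq_len(h1)) {
        r0 <- (r - 1) * s1; c0 <- (cc - 1) * s1
        a1[r, cc, f] <- sum(x[r0 + seq_len(k1), c0 + seq_len(k1)] *
                              params$conv1_w[, , f]) + params$conv1_b[f]
      }
    }
  }
  a1[a1 < 0] <- 0
  k2 <- cfg$primary_kernel; s2 <- cfg$primary_stride
  h2 <- cfg$h2; nch <- cfg$primary_maps * cfg$primary_dim
  z2 <- array(0, c(h2, h2, nch))
  for (ch in seq_len(nch)) {
    for (r in seq_len(h2)) {
      for (cc in seq_len(h2)) {
        r0 <- (r - 1) * s2; c0 <- (cc - 1) * s2
        acc <- 0
        for (f in seq_len(nf)) {
          acc <- acc + sum(a1[r0 + seq_len(k2), c0 + seq_len(k2), f] *
                             params$conv2_w[, , f, ch])
        }
        z2[r, cc, ch] <- acc + params$conv2_b[ch]
      }
    }
  }
  m <- cfg$primary_dim
  u <- matrix(0, cfg$L, m)
  for (p in seq_len(cfg$primary_maps)) {
    for (cc in seq_len(h2)) {
      for (r in seq_len(h2)) {
        i <- r + (cc - 1) * h2 + (p - 1) * h2 * h2
        u[i, ] <- sq(z2[r, cc, (p - 1) * m + seq_len(m)])
      }
    }
  }
  if (cfg$head == "dense") {
    z <- as.vector(params$dense_w %*% as.vector(u)) + params$dense_b
    return(list(p = 1 / (1 + exp(-z)), primary = u))
  }
  nn <- cfg$type_dim; jj <- cfg$n_classes
  uhat <- array(0, c(cfg$L, jj, nn))
  for (i in seq_len(cfg$L)) {
    for (j in seq_len(jj)) {
      uhat[i, j, ] <- params$W[, , i, j] %*% u[i, ]
    }
  }
  b <- matrix(0, cfg$L, jj)
  v <- matrix(0, jj, nn)
  for (t in seq_len(cfg$routing_iterations)) {
    cpl <- exp(b) / rowSums(exp(b))
    for (j in seq_len(jj)) {
      s_j <- rep(0, nn)
      for (i in seq_len(cfg$L)) s_j <- s_j + cpl[i, j] * uhat[i, j, ]
      v[j, ] <- sq(s_j)
    }
    if (t < cfg$routing_iterations) {
      for (i in seq_len(cfg$L)) {
        for (j in seq_len(jj)) {
          b[i, j] <- b[i, j] + sum(uhat[i, j, ] * v[j, ])
        }
      }
    }
  }
  list(p = sqrt(rowSums(v^2)), type = t(v), primary = u, coupling = cpl)
}

# AUC by brute-force enumeration of all positive-negative pairs.
oracle_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# bare count matrix of an fcgr_image (drop class and metadata attributes)
fcgr_counts <- function(img) {
  x <- unclass(img)
  attributes(x) <- list(dim = dim(x))
  x
}

# random DNA sequence
random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

# tiny network geometry used across capsule tests (8x8 input, L = 4)
tiny_config <- function(...) {
  args <- list(input_resolution = 8L, conv_filters = 1L, conv_kernel = 3L,
               conv_stride = 1L, primary_kernel = 3L, primary_stride = 2L,
               primary_maps = 1L, primary_dim = 2L, type_dim = 2L,
               routing_iterations = 2L)
  do.call(caps_config, utils::modifyList(args, list(...)))
}

# small 16x16 geometry that trains in well under a second
mini_config <- function(...) {
  args <- list(input_resolution = 16L, conv_filters = 2L, conv_kernel = 5L,
               conv_stride = 2L, primary_kernel = 3L, primary_stride = 1L,
               primary_maps = 1L, primary_dim = 4L, type_dim = 4L,
               routing_iterations = 2L)
  do.call(caps_config, utils::modifyList(args, list(...)))
}
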