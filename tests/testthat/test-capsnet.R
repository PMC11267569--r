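# Capsule math: squash, prediction vectors, routing, lengths, margin loss,
# and the compiled forward/backward pass against straight-line oracles.

test_that("squash keeps direction, bounds the norm below 1, maps zero to zero", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  u <- c(1, 0) # unit vector -> half length
  expect_equal(squash(u), 0.5 * u)
  expect_equal(squash(c(3, 4)), c(15 / 26, 20 / 26))
  withr::with_seed(2, {
    norms <- numeric(20)
    for (i in 1:20) {
      s <- rnorm(5) * 2^runif(1, -3, 3)
      v <- squash(s)
      ns <- sqrt(sum(s^2))
      expect_equal(sqrt(sum(v^2)), ns^2 / (1 + ns^2))
      expect_lt(sqrt(sum(v^2)), 1)
      expect_equal(v / sqrt(sum(v^2)), s / ns)
      norms[i] <- ns
    }
    # monotone in the input norm
    ord <- order(norms)
    out <- norms^2 / (1 + norms^2)
    expect_true(all(diff(out[ord]) > 0))
  })
  # matrix form is row-wise
  m <- rbind(c(3, 4), c(0, 0), c(1, 0))
  expect_equal(squash(m), rbind(c(15 / 26, 20 / 26), c(0, 0), c(0.5, 0)))
})

test_that("prediction vectors are the per-pair matrix products", {
  withr::with_seed(3, {
    L <- 3; m <- 2; n <- 2; J <- 2
    u <- matrix(rnorm(L * m), L, m)
    w <- array(rnorm(n * m * L * J), c(n, m, L, J))
    uhat <- compute_prediction_vectors(u, w)
    for (i in 1:L) for (j in 1:J) {
      manual <- c(w[1, 1, i, j] * u[i, 1] + w[1, 2, i, j] * u[i, 2],
                  w[2, 1, i, j] * u[i, 1] + w[2, 2, i, j] * u[i, 2])
      expect_equal(uhat[i, j, ], manual)
    }
    expect_equal(compute_prediction_vectors(u, w * 0), uhat * 0)
    # identity weights with m = n pass activities through
    wid <- array(0, c(m, m, L, J))
    for (i in 1:L) for (j in 1:J) wid[, , i, j] <- diag(m)
    uid <- compute_prediction_vectors(u, wid)
    for (j in 1:J) expect_equal(matrix(uid[, j, ], L), u)
    expect_error(compute_prediction_vectors(u, array(0, c(n, m + 1, L, J))),
                 class = "enhancaps_config_error")
  })
})

test_that("dynamic routing starts uniform and normalises coupling each round", {
  withr::with_seed(4, {
    L <- 5; J <- 2; n <- 3
    uhat <- array(rnorm(L * J * n), c(L, J, n))
    # r = 1: coefficients exactly uniform (softmax of zero logits)
    r1 <- dynamic_routing(uhat, r = 1)
    expect_equal(r1$coupling, matrix(0.5, L, J))
    for (r in 1:4) {
      rt <- dynamic_routing(uhat, r = r)
      expect_equal(rowSums(rt$coupling), rep(1, L))
      expect_true(all(rt$coupling >= 0))
      expect_true(all(capsule_lengths(rt$v) < 1))
    }
    # single capsule, one round: V_j = squash(v / 2)
    v <- rnorm(n)
    one <- array(0, c(1, 2, n)); one[1, 1, ] <- v; one[1, 2, ] <- v
    rt1 <- dynamic_routing(one, r = 1)
    expect_equal(rt1$v[1, ], squash(0.5 * v))
    expect_equal(rt1$v[2, ], squash(0.5 * v))
    # invariance to permutation of primary capsules
    perm <- sample(L)
    expect_equal(dynamic_routing(uhat[perm, , , drop = FALSE], r = 3)$v,
                 dynamic_routing(uhat, r = 3)$v)
    uhat[1, 1, 1] <- NaN
    expect_error(dynamic_routing(uhat, 2), class = "enhancaps_numeric_error")
  })
})

test_that("capsule lengths are Euclidean norms", {
  expect_equal(capsule_lengths(c(0.3, 0.4)), 0.5)
  expect_equal(capsule_lengths(rbind(c(0.3, 0.4), c(0, 0))), c(0.5, 0))
})

test_that("margin loss matches hand evaluation", {
  expect_equal(margin_loss(c(0.9, 0.1), label = 1), 0)
  expect_equal(margin_loss(c(1, 0), label = 1), 0)
  expect_equal(margin_loss(c(0.5, 0.5), label = 1), 0.16 + 0.5 * 0.16)
})

test_that("the compiled forward pass matches a straight-line implementation", {
  for (seed in c(1, 2)) {
    cfg <- tiny_config()
    params <- caps_init(cfg, seed)
    withr::with_seed(seed + 100, {
      img <- matrix(rpois(cfg$input_resolution^2, 2), cfg$input_resolution)
    })
    got <- caps_forward(img, params, cfg)
    want <- oracle_forward(img, params, cfg)
    expect_equal(got$p, want$p)
    expect_equal(got$primary, want$primary)
    expect_equal(got$type, want$type)
    expect_equal(got$coupling, want$coupling)
  }
  # dense ablation head against the same oracle
  cfgd <- tiny_config(head = "dense")
  params <- caps_init(cfgd, 9)
  withr::with_seed(9, img <- matrix(rpois(64, 3), 8))
  expect_equal(caps_forward(img, params, cfgd)$p,
               oracle_forward(img, params, cfgd)$p)
})

test_that("forward is deterministic, zero-propagating, and shape-checked", {
  cfg <- tiny_config()
  params <- caps_init(cfg, 5)
  withr::with_seed(6, img <- matrix(runif(64), 8))
  expect_identical(caps_forward(img, params, cfg)$p,
                   caps_forward(img, params, cfg)$p)
  zero <- lapply(params, function(x) x * 0)
  expect_equal(caps_forward(img * 0, zero, cfg)$p, c(0, 0))
  expect_error(caps_forward(matrix(0, 9, 9), params, cfg),
               class = "enhancaps_config_error")
})

test_that("analytic gradients agree with finite differences", {
  for (head in c("capsule", "dense")) {
    cfg <- tiny_config(head = head, routing_iterations = 3L)
    params <- caps_init(cfg, 13)
    withr::with_seed(14, {
      arr <- array(runif(64), c(8, 8, 1))
      res <- enhancaps:::caps_batch_cpp(arr, 1L, params, unclass(cfg), grad = TRUE)
      h <- 1e-5
      for (nm in names(params)) {
        for (ii in sample(length(params[[nm]]), min(10, length(params[[nm]])))) {
          up <- params; up[[nm]][ii] <- up[[nm]][ii] + h
          dn <- params; dn[[nm]][ii] <- dn[[nm]][ii] - h
          fd <- (enhancaps:::caps_batch_cpp(arr, 1L, up, unclass(cfg))$loss -
                   enhancaps:::caps_batch_cpp(arr, 1L, dn, unclass(cfg))$loss) / (2 * h)
          expect_equal(res$grads[[nm]][ii], fd, tolerance = 1e-4)
        }
      }
    })
  }
})

test_that("type-capsule output probabilities are invariant to permuting primary capsules with their W slices", {
  cfg <- tiny_config()
  params <- caps_init(cfg, 21)
  withr::with_seed(22, img <- matrix(rpois(64, 2), 8))
  base <- caps_forward(img, params, cfg)
  u <- base$primary
  perm <- c(3, 1, 4, 2)
  w_perm <- params$W[, , perm, , drop = FALSE]
  uhat <- compute_prediction_vectors(u[perm, , drop = FALSE], w_perm)
  rt <- dynamic_routing(uhat, cfg$routing_iterations)
  expect_equal(capsule_lengths(rt$v), base$p)
})
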