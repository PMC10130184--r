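test_that("hard-tanh clamps to [-1, 1]", {
  expect_equal(hard_tanh(1.5), 1)
  expect_equal(hard_tanh(-3), -1)
  expect_equal(hard_tanh(0.3), 0.3)
  expect_equal(hard_tanh(c(-2, 0, 2)), c(-1, 0, 1))
})

test_that("encoder features are bounded, deterministic and saturate correctly", {
  h <- toy_hypergraph()
  H <- incidence_matrix(h)
  p <- tiny_params(ncol(H))

  zero <- p
  zero$W_enc[] <- 0
  zero$b_enc[] <- 0
  expect_equal(init_features(H, zero), matrix(0, 3, 6), ignore_attr = TRUE)

  sat <- p
  sat$b_enc[] <- 10
  expect_true(all(init_features(H, sat) == 1))

  # identical incidence rows give identical features
  h2 <- hypergraph(list(R1 = c("A", "B"), R2 = c("A", "B", "C")))
  H2 <- incidence_matrix(h2)
  p2 <- tiny_params(2)
  X <- init_features(H2, p2)
  expect_equal(X[1, ], X[2, ])
  expect_true(all(abs(X) <= 1))

  expect_error(init_features(H[, 1, drop = FALSE], p), "does not match")
})

test_that("graph normalisation standardises per clique with the epsilon floor", {
  p <- list(gamma = 1, beta = 0, alpha = 1)
  # hand evaluation: column [1, 3] has mu = 2, population sd = 1
  X <- matrix(c(1, 3), 2, 1)
  expect_equal(graph_normalize(X, p), matrix(c(-1, 1), 2, 1))

  # singleton clique: sigma = 0 -> eps floor; with alpha = 1 the output is 0
  expect_equal(graph_normalize(matrix(5, 1, 1), p), matrix(0, 1, 1))

  # gamma = 0 collapses to beta
  p0 <- list(gamma = 0, beta = 0.7, alpha = 1)
  expect_equal(graph_normalize(matrix(rnorm(8), 4, 2), p0),
               matrix(0.7, 4, 2))
})

test_that("alpha dropout is identity when inactive and moment-preserving when active", {
  X <- matrix(rnorm(50), 10, 5)
  expect_identical(alpha_dropout(X, 0, training = TRUE, seed = 1), X)
  expect_identical(alpha_dropout(X, 0.5, training = FALSE, seed = 1), X)

  big <- matrix(rnorm(1e5), 1000, 100)
  out <- alpha_dropout(big, 0.1, training = TRUE, seed = 42)
  expect_lt(abs(mean(out)), 0.05)
  expect_lt(abs(stats::var(as.numeric(out)) - 1), 0.1)
})

test_that("scaled clique Laplacian matches closed forms", {
  l2 <- scaled_laplacian(2)
  expect_equal(l2$lambda_max, 2)
  expect_equal(l2$L_tilde, rbind(c(0, -1), c(-1, 0)))

  l3 <- scaled_laplacian(3)
  expect_equal(l3$lambda_max, 1.5)
  # spectrum of the rescaled Laplacian: 0 maps to -1, lambda_max maps to +1
  expect_equal(sort(eigen(l3$L_tilde, symmetric = TRUE)$values),
               c(-1, 1, 1))

  expect_equal(scaled_laplacian(1)$L_tilde, matrix(0, 1, 1))
  expect_error(scaled_laplacian(0), "positive integer")

  for (s in 2:12) {
    lap <- scaled_laplacian(s)
    expect_equal(lap$lambda_max, s / (s - 1), tolerance = 1e-12)
    ev <- eigen(lap$L_tilde, symmetric = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
    expect_equal(lap$L_tilde, t(lap$L_tilde))
  }
})

test_that("Chebyshev recursion matches the matrix-polynomial oracle", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- sample(2:8, 1)
      K <- sample(1:6, 1)
      # random symmetric matrix with spectrum in [-1, 1]
      Q <- qr.Q(qr(matrix(rnorm(s * s), s)))
      L <- Q %*% (runif(s, -1, 1) * t(Q))
      X <- matrix(rnorm(s * 5), s, 5)
      Z <- chebyshev_terms(X, L, K)
      for (k in seq_len(K)) {
        expected <- cheb_poly_eigen(L, k - 1) %*% X
        expect_equal(Z[[k]], expected, tolerance = 1e-6)
      }
    }
  })
})

test_that("Chebyshev convolution reduces correctly in limiting cases", {
  p <- tiny_params(3, d_enc = 4, d_conv = 3, K = 1)
  X <- matrix(rnorm(8), 2, 4)
  lap <- scaled_laplacian(2)
  # K = 1: per-node linear map, no cross-node mixing
  expect_equal(chebyshev_conv(X, lap, p),
               hard_tanh(X %*% t(p$W_conv_1)))

  # K = 2, s = 2: second-order term is the negated partner feature
  p2 <- tiny_params(3, d_enc = 4, d_conv = 3, K = 2)
  Z <- chebyshev_terms(X, lap$L_tilde, 2)
  expect_equal(Z[[2]], -X[c(2, 1), ])
  expect_equal(chebyshev_conv(X, lap, p2),
               hard_tanh(X %*% t(p2$W_conv_1) + Z[[2]] %*% t(p2$W_conv_2)))

  zero <- p2
  zero$W_conv_1[] <- 0
  zero$W_conv_2[] <- 0
  expect_equal(chebyshev_conv(X, lap, zero), matrix(0, 2, 3))
  expect_true(all(abs(chebyshev_conv(X * 100, lap, p2)) <= 1))
})

test_that("pooling functions match hand values and degenerate cases", {
  expect_equal(pool_frobenius(matrix(c(3, 4), 2, 1)), sqrt(25 / 2))
  expect_equal(pool_frobenius(matrix(c(-2, 0.5), 1, 2)), c(2, 0.5))
  expect_equal(pool_frobenius(matrix(0, 3, 2)), c(0, 0))

  expect_equal(pool_maxmin(matrix(c(1, 5, 2), 3, 1)), 4)
  expect_equal(pool_maxmin(matrix(c(7, -7), 1, 2)), c(0, 0))
  expect_equal(pool_maxmin(matrix(1, 4, 3)), c(0, 0, 0))
})

test_that("scoring is sigmoid of the affine map over (maxmin, norm)", {
  p <- list(w_score = rep(0, 8), b_score = 0)
  expect_equal(score_reaction(rep(1, 4), rep(1, 4), p), 0.5)
  p$b_score <- 10
  expect_equal(score_reaction(rep(0, 4), rep(0, 4), p), stats::plogis(10))
  p$w_score <- 1:8
  expect_equal(score_reaction(c(1, 0, 0, 0), rep(0, 4), p), stats::plogis(11))
  expect_error(score_reaction(rep(0, 3), rep(0, 4), p), "does not match")
})

test_that("pooled vectors and score are invariant to clique node order", {
  withr::with_seed(21, {
    p <- tiny_params(5, d_enc = 6, d_conv = 4, K = 3)
    for (i in 1:25) {
      s <- sample(2:8, 1)
      X <- matrix(rnorm(s * 6), s, 6)
      lap <- scaled_laplacian(s)
      perm <- sample(s)

      Xn <- graph_normalize(X, p)
      Xc <- chebyshev_conv(Xn, lap, p)
      Xn_p <- graph_normalize(X[perm, ], p)
      Xc_p <- chebyshev_conv(Xn_p, lap, p)
      # equivariance: permuting rows permutes convolved rows identically
      expect_equal(Xc_p, Xc[perm, ], tolerance = 1e-12)
      # invariance of both pooled vectors and the score
      expect_equal(pool_frobenius(Xc_p), pool_frobenius(Xc), tolerance = 1e-12)
      expect_equal(pool_maxmin(Xc_p), pool_maxmin(Xc), tolerance = 1e-12)
      expect_equal(
        score_reaction(pool_maxmin(Xc_p), pool_frobenius(Xc_p), p),
        score_reaction(pool_maxmin(Xc), pool_frobenius(Xc), p),
        tolerance = 1e-12
      )
    }
  })
})

test_that("checkpoints round-trip and validate shapes", {
  h <- small_gem()
  tc <- train_config(epochs = 3, hp = hyperparams(d_enc = 16, d_conv = 8, K = 2),
                     seed = 4)
  fit <- train_model(h, h$reactions[1:40], tc)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path, h)
  expect_equal(fit2$params, fit$params)
  expect_equal(fit2$H, fit$H)
  cand <- h$reactions[41:50]
  expect_equal(predict_scores(fit2, h, cand), predict_scores(fit, h, cand))

  broken <- readRDS(path)
  broken$m <- broken$m + 1L
  saveRDS(broken, path)
  expect_error(load_checkpoint(path, h), "inconsistent")
})
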