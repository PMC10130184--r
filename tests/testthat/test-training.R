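test_that("ranking loss matches hand-computed values", {
  expect_equal(ranking_loss(0.9, 0.1), log(1 + exp(-0.8)), tolerance = 1e-10)
  expect_equal(ranking_loss(0.9, 0.1), 0.37110, tolerance = 1e-5)
  expect_equal(ranking_loss(0.5, 0.5), log(2), tolerance = 1e-10)
  expect_equal(ranking_loss(1.0, 0.0), log(1 + exp(-1)), tolerance = 1e-10)
  expect_equal(ranking_loss(1.0, 0.0), 0.31326, tolerance = 1e-5)
  expect_error(ranking_loss(numeric(), 0.5), "non-empty")
})

test_that("ranking loss is floored at softplus(-1) for sigmoid scores", {
  withr::with_seed(14, {
    for (i in 1:100) {
      pos <- runif(sample(1:20, 1))
      neg <- runif(sample(1:20, 1))
      l <- ranking_loss(pos, neg)
      expect_gte(l, log(1 + exp(-1)))
      expect_true(is.finite(l) && l > 0)
    }
  })
})

test_that("ranking loss is monotone in its scores", {
  pos <- c(0.7, 0.6)
  neg <- c(0.3, 0.4)
  base <- ranking_loss(pos, neg)
  expect_lt(ranking_loss(c(0.8, 0.6), neg), base)
  expect_gt(ranking_loss(pos, c(0.5, 0.4)), base)
})

test_that("analytic loss gradient matches finite differences", {
  withr::with_seed(7, {
    for (i in 1:20) {
      pos <- runif(sample(2:10, 1))
      neg <- runif(sample(2:10, 1))
      g <- ranking_loss_grad(pos, neg)
      eps <- 1e-6
      for (j in seq_along(pos)) {
        up <- pos; up[j] <- pos[j] + eps
        dn <- pos; dn[j] <- pos[j] - eps
        num <- (ranking_loss(up, neg) - ranking_loss(dn, neg)) / (2 * eps)
        expect_equal(g$pos[j], num, tolerance = 1e-4)
      }
      for (j in seq_along(neg)) {
        up <- neg; up[j] <- neg[j] + eps
        dn <- neg; dn[j] <- neg[j] - eps
        num <- (ranking_loss(pos, up) - ranking_loss(pos, dn)) / (2 * eps)
        expect_equal(g$neg[j], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("Monte-Carlo splits have the stated sizes and are reproducible partitions", {
  E <- setNames(as.list(letters[1:10]), paste0("R", 1:10))
  sp <- monte_carlo_split(E, 0.6, n_runs = 3, seed = 2)
  expect_length(sp, 3)
  for (run in sp) {
    expect_length(run$train, 6)
    expect_length(run$test, 4)
    expect_length(intersect(names(run$train), names(run$test)), 0)
    expect_setequal(c(names(run$train), names(run$test)), names(E))
  }
  sp9 <- monte_carlo_split(E, 0.9, n_runs = 1, seed = 2)[[1]]
  expect_length(sp9$train, 9)
  expect_length(sp9$test, 1)

  expect_identical(sp, monte_carlo_split(E, 0.6, n_runs = 3, seed = 2))
  expect_false(identical(sp[[1]], sp[[2]]))
  expect_error(monte_carlo_split(E[1], 0.6), "at least 2")
  expect_error(monte_carlo_split(E, 1.2), "train_fraction")
})

test_that("training reduces the loss on a small synthetic network", {
  h <- small_gem(seed = 9)
  sub <- h$reactions[1:50]
  fit <- train_model(h, sub, train_config(epochs = 30, seed = 1))
  expect_length(fit$losses, 30)
  expect_true(all(is.finite(fit$losses) & fit$losses > 0))
  expect_lt(fit$losses[30], fit$losses[1])
})

test_that("training configuration is validated", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(negative_ratio = -1), "negative_ratio")
  h <- small_gem()
  expect_error(train_model(h, list(), train_config(epochs = 1)), "empty")
})

test_that("train then predict is bitwise reproducible under a fixed seed", {
  h <- small_gem(seed = 5)
  sub <- h$reactions[1:60]
  cand <- h$reactions[61:80]
  tc <- train_config(epochs = 8, hp = hyperparams(d_enc = 32, d_conv = 16),
                     seed = 33)
  fit1 <- train_model(h, sub, tc)
  fit2 <- train_model(h, sub, tc)
  expect_identical(fit1$losses, fit2$losses)
  expect_identical(predict_scores(fit1, h, cand), predict_scores(fit2, h, cand))

  fit3 <- train_model(h, sub, train_config(epochs = 8, hp = tc$hp, seed = 34))
  expect_false(identical(fit1$losses, fit3$losses))
})

test_that("candidates with unseen metabolites are flagged, not scored", {
  h <- small_gem()
  fit <- train_model(h, h$reactions[1:40],
                     train_config(epochs = 2, hp = hyperparams(d_enc = 16, d_conv = 8),
                                  seed = 1))
  cand <- c(h$reactions[41:45],
            list(alien = c("unobtainium", h$nodes[1])))
  expect_warning(out <- predict_scores(fit, h, cand), "not scored")
  expect_equal(nrow(out), 5L)
  expect_equal(attr(out, "unscorable"), "alien")
  expect_true(all(out$score > 0 & out$score < 1))

  empty <- suppressWarnings(predict_scores(fit, h, list(x = "unobtainium")))
  expect_equal(nrow(empty), 0L)
})

test_that("training configs round-trip through YAML and JSON files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "epochs: 40", "seed: 9", "negative_ratio: 0.5",
    "hyperparams:", "  d_enc: 64", "  d_conv: 32", "  K: 2",
    "  p_drop: 0.2", "  lr: 0.005"
  ), yml)
  cfg <- read_train_config(yml)
  expect_equal(cfg$epochs, 40L)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$negative_ratio, 0.5)
  expect_equal(cfg$hp$d_enc, 64L)
  expect_equal(cfg$hp$lr, 0.005)

  js <- tempfile(fileext = ".json")
  writeLines('{"epochs": 12, "hyperparams": {"K": 4}}', js)
  cfg2 <- read_train_config(js)
  expect_equal(cfg2$epochs, 12L)
  expect_equal(cfg2$hp$K, 4L)
  expect_equal(cfg2$hp$d_enc, 256L)  # default retained
})

test_that("loss logs are written as epoch/loss TSV", {
  h <- small_gem()
  fit <- train_model(h, h$reactions[1:30],
                     train_config(epochs = 4,
                                  hp = hyperparams(d_enc = 16, d_conv = 8),
                                  seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_loss_log(fit, path)
  log <- read.delim(path)
  expect_equal(names(log), c("epoch", "loss"))
  expect_equal(log$epoch, 1:4)
  expect_equal(log$loss, fit$losses)
})
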