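test_that("classification metrics match simple hand cases", {
  m <- classification_metrics(c(0.9, 0.1), c(1, 0))
  expect_equal(m$auroc, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(unname(m$counts), c(1L, 0L, 1L, 0L))

  tie <- classification_metrics(c(0.5, 0.5), c(1, 0))
  expect_equal(tie$auroc, 0.5)

  expect_warning(one <- classification_metrics(c(0.2, 0.8), c(1, 1)),
                 "single class")
  expect_true(is.na(one$auroc))
  expect_equal(one$recall, 0.5)  # one of the two positives clears 0.5
  expect_equal(one$precision, 1)
})

test_that("rank-based AUROC equals the brute-force pair count", {
  withr::with_seed(18, {
    for (i in 1:5) {
      n <- 200
      labels <- rbinom(n, 1, 0.4)
      labels[1:2] <- c(0, 1)
      # discretised scores force ties
      scores <- round(runif(n), 2)
      m <- suppressWarnings(classification_metrics(scores, labels))
      expect_equal(m$auroc, auroc_bruteforce(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(19, {
    scores <- runif(100)
    labels <- rbinom(100, 1, 0.5)
    labels[1:2] <- c(0, 1)
    a <- classification_metrics(scores, labels)$auroc
    expect_equal(classification_metrics(stats::qlogis(scores), labels)$auroc, a)
    expect_equal(classification_metrics(scores^3, labels)$auroc, a)
  })
})

test_that("confusion counts always partition the test set", {
  withr::with_seed(20, {
    for (i in 1:10) {
      n <- sample(10:60, 1)
      scores <- runif(n)
      labels <- rbinom(n, 1, 0.5)
      m <- suppressWarnings(classification_metrics(scores, labels))
      expect_equal(sum(m$counts), n)
      expect_equal(m$f1,
                   if (m$precision + m$recall > 0) {
                     2 * m$precision * m$recall / (m$precision + m$recall)
                   } else 0)
    }
  })
})

test_that("type-1 validation produces per-run reports and null controls sit at 0.5", {
  h <- small_gem(seed = 12)
  cfg <- train_config(epochs = 15, hp = hyperparams(d_enc = 64, d_conv = 32),
                      seed = 21)
  v <- validate_type1(h, n_runs = 3, config = cfg)
  expect_length(v$runs, 3)
  expect_equal(nrow(v$summary), 5)
  expect_true(all(v$per_run$auroc > 0 & v$per_run$auroc < 1))

  # scrambling the scorer's output (label permutation equivalent) gives chance
  null_scorer <- function(fit, h, candidates) {
    out <- predict_scores(fit, h, candidates)
    out$score <- withr::with_seed(1, runif(nrow(out)))
    out
  }
  v0 <- validate_type1(h, n_runs = 3, config = cfg, scorer = null_scorer)
  expect_lt(abs(mean(v0$per_run$auroc) - 0.5), 0.15)
})

test_that("top-k recovery is capped by k, monotone in k, and exact for a perfect ranking", {
  # perfect ranking: all removed reactions above all pool reactions
  ids <- c(paste0("rm", 1:50), paste0("pool", 1:100))
  rec_n <- rxngap:::top_k_recovery(ids, paste0("rm", 1:50), 50, 50)
  expect_equal(rec_n$rate, 1.0)
  rec_25 <- rxngap:::top_k_recovery(ids, paste0("rm", 1:50), 25, 50)
  expect_equal(rec_25$n_recovered, 25)
  expect_equal(rec_25$rate, 0.5)

  withr::with_seed(22, {
    shuffled <- sample(ids)
    rates <- vapply(c(10, 25, 50, 100, 150), function(k) {
      rxngap:::top_k_recovery(shuffled, paste0("rm", 1:50), k, 50)$rate
    }, numeric(1))
    expect_true(all(diff(rates) >= 0))
  })
})

test_that("random rankings recover at the permutation-null rate", {
  # k = N with a uniformly shuffled candidate order: expected rate N/(N+P)
  withr::with_seed(23, {
    N <- 40
    P <- 400
    ids <- c(paste0("rm", 1:N), paste0("pool", 1:P))
    rates <- vapply(1:300, function(i) {
      rxngap:::top_k_recovery(sample(ids), paste0("rm", 1:N), N, N)$rate
    }, numeric(1))
    expect_lt(abs(mean(rates) - N / (N + P)), 0.02)
  })
})

test_that("type-2 validation deduplicates the pool and reports all cutoffs", {
  h <- small_gem(seed = 13)
  pool <- c(generate_decoys(h, 60, seed = 3),
            setNames(h$reactions[1:3], paste0("dup", 1:3)))  # known duplicates
  cfg <- train_config(epochs = 10, hp = hyperparams(d_enc = 32, d_conv = 16),
                      seed = 31)
  v <- validate_type2(h, pool, n_runs = 2, config = cfg, ks = c(5L, 10L, NA))
  expect_length(v$runs, 2)
  expect_equal(v$summary$k, c("5", "10", "N"))
  for (df in v$runs) {
    expect_true(all(df$n_recovered <= pmin(c(5, 10, df$n_removed[1]),
                                           df$n_removed)))
    expect_true(all(df$rate >= 0 & df$rate <= 1))
    expect_true(all(diff(df$rate) >= 0))
  }
})

test_that("validation reports export as tidy TSV plus JSON summary", {
  h <- small_gem(seed = 14)
  cfg <- train_config(epochs = 5, hp = hyperparams(d_enc = 16, d_conv = 8),
                      seed = 3)
  v1 <- validate_type1(h, n_runs = 2, config = cfg)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  tidy <- write_validation_report(v1, tsv, js)
  expect_equal(names(tidy), c("run", "metric", "value"))
  expect_equal(nrow(tidy), 10)  # 2 runs x 5 metrics
  expect_equal(read.delim(tsv)$value, tidy$value)
  summ <- jsonlite::fromJSON(js)
  expect_equal(summ$metric, v1$summary$metric)

  v2 <- validate_type2(h, generate_decoys(h, 20, seed = 4), n_runs = 2,
                       config = cfg, ks = c(5L, NA))
  tidy2 <- write_validation_report(v2, tsv, js)
  expect_equal(nrow(tidy2), 4)  # 2 runs x 2 cutoffs
  expect_true(all(grepl("^recovery_top", tidy2$metric)))
})
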