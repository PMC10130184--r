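#' Threshold classification metrics
#'
#' AUROC is computed as the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counting one half
#' (rank/Mann-Whitney formulation). AUPRC is the step integral of the
#' precision-recall curve (average precision). Recall, precision and F1 come
#' from the confusion matrix at the score threshold (default 0.5, the
#' convention for mixed positive/negative test sets).
#'
#' @param scores numeric vector of confidence scores.
#' @param labels binary vector (1 = true reaction, 0 = fake), same length.
#' @param threshold score cutoff for the thresholded metrics.
#' @return list of class `rxngap_metrics` with `auroc`, `auprc`, `recall`,
#'   `precision`, `f1`, `threshold` and `counts` (TP/FP/TN/FN). If only one
#'   class is present, `auroc` and `auprc` are `NA` with a warning and the
#'   thresholded metrics are still returned.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  pos <- labels == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)

  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC/AUPRC undefined: labels contain a single class", call. = FALSE)
    auroc <- NA_real_
    auprc <- NA_real_
  } else {
    r <- rank(scores)
    auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    ord <- order(-scores)
    hits <- cumsum(labels[ord])
    prec_at <- hits / seq_along(hits)
    auprc <- sum(prec_at[labels[ord] == 1L]) / n_pos
  }

  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  structure(
    list(auroc = auroc, auprc = auprc, recall = recall, precision = precision,
         f1 = f1, threshold = threshold,
         counts = c(TP = tp, FP = fp, TN = tn, FN = fn)),
    class = "rxngap_metrics"
  )
}

#' Internal validation, type 1: threshold classification
#'
#' Per Monte-Carlo run the reaction set is split (60/40 by default), training
#' negatives and test negatives are sampled independently at 1:1, a model is
#' trained on the training positives, and the held-out positives plus their
#' derived negatives are scored and classified at the 0.5 threshold.
#'
#' @param h a `metabolic_hypergraph`.
#' @param train_fraction fraction of reactions used for training (default
#'   0.6).
#' @param n_runs number of Monte-Carlo runs (default 10).
#' @param config a [train_config()]; its seed drives the splits, the
#'   negative sampling and every training run.
#' @param scorer optional function `(fit, h, candidates) -> data.frame` used
#'   to score test candidates; defaults to [predict_scores()]. Supplying a
#'   scorer that ignores `fit` gives baseline controls (e.g. an untrained
#'   model).
#' @return list with `runs` (list of per-run `rxngap_metrics`), and
#'   `summary` (data.frame of mean and sd per metric across runs).
#' @export
validate_type1 <- function(h, train_fraction = 0.6, n_runs = 10L,
                           config = train_config(), scorer = predict_scores) {
  splits <- monte_carlo_split(h$reactions, train_fraction, n_runs,
                              seed = config$seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- splits[[r]]
    run_cfg <- config
    run_cfg$seed <- derive_seed(config$seed, 10000L + r)
    fit <- train_model(h, sp$train, run_cfg)
    test_neg <- sample_negative_set(sp$test, h, ratio = 1,
                                    seed = derive_seed(config$seed, 20000L + r))
    candidates <- c(sp$test, test_neg$negatives)
    labels <- c(rep(1L, length(sp$test)), rep(0L, length(test_neg$negatives)))
    scored <- scorer(fit, h, candidates)
    runs[[r]] <- classification_metrics(scored$score, labels)
  }
  metric_names <- c("auroc", "auprc", "recall", "precision", "f1")
  vals <- sapply(metric_names, function(mn) {
    vapply(runs, function(x) x[[mn]], numeric(1))
  })
  structure(
    list(runs = runs,
         per_run = as.data.frame(vals),
         summary = data.frame(
           metric = metric_names,
           mean = colMeans(vals),
           sd = apply(vals, 2, stats::sd),
           row.names = NULL
         )),
    class = "rxngap_validation1"
  )
}

top_k_recovery <- function(scored_ids, removed_ids, k, n_removed) {
  kk <- min(k, length(scored_ids))
  n_rec <- sum(utils::head(scored_ids, kk) %in% removed_ids)
  list(k = k, n_removed = n_removed, n_recovered = n_rec,
       rate = n_rec / n_removed)
}

#' Internal validation, type 2: top-k recovery from a reaction pool
#'
#' Per run the reaction set is split 90/10 (by default), the model is trained
#' on the 90% with 1:1 negatives, and the candidate set is the removed 10%
#' plus a pool of external reactions (deduplicated as member sets against the
#' training reactions and among themselves). All candidates are ranked by
#' score descending (stable order on ties) and the recovery rate
#' `|removed in top-k| / N` is reported at each cutoff; `NA` in `ks` means
#' `k = N`, the number of removed reactions.
#'
#' @param h a `metabolic_hypergraph`.
#' @param pool named list of member vectors (the candidate pool). Reactions
#'   with metabolites outside `h`'s node set are excluded and counted.
#' @param train_fraction default 0.9.
#' @param n_runs number of Monte-Carlo runs.
#' @param config a [train_config()].
#' @param ks integer cutoffs; `NA` stands for N (default `c(25, 50, 100,
#'   NA)`).
#' @param scorer optional scorer override as in [validate_type1()].
#' @return list with `runs` (per run: data.frame of k, n_removed,
#'   n_recovered, rate), `summary` (mean rate per cutoff) and
#'   `n_pool_excluded`.
#' @export
validate_type2 <- function(h, pool, train_fraction = 0.9, n_runs = 10L,
                           config = train_config(), ks = c(25L, 50L, 100L, NA),
                           scorer = predict_scores) {
  if (length(pool) == 0L) {
    stop_rxngap("candidate pool is empty", class = "rxngap_domain_error")
  }
  sc <- scoreable_reactions(h, pool)
  pool <- sc$scoreable
  splits <- monte_carlo_split(h$reactions, train_fraction, n_runs,
                              seed = config$seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- splits[[r]]
    run_cfg <- config
    run_cfg$seed <- derive_seed(config$seed, 30000L + r)
    fit <- train_model(h, sp$train, run_cfg)

    train_keys <- vapply(sp$train, member_key, character(1))
    removed_keys <- vapply(sp$test, member_key, character(1))
    pool_keys <- vapply(pool, member_key, character(1))
    keep_pool <- !(pool_keys %in% train_keys) & !(pool_keys %in% removed_keys) &
      !duplicated(pool_keys)
    candidates <- c(sp$test, pool[keep_pool])

    scored <- scorer(fit, h, candidates)
    ord <- order(-scored$score)  # stable: ties keep input order
    ranked_ids <- scored$reaction_id[ord]
    n_removed <- length(sp$test)
    res <- lapply(ks, function(k) {
      top_k_recovery(ranked_ids, names(sp$test),
                     if (is.na(k)) n_removed else k, n_removed)
    })
    runs[[r]] <- do.call(rbind, lapply(res, as.data.frame))
  }
  k_label <- ifelse(is.na(ks), "N", as.character(ks))
  rates <- sapply(seq_along(ks), function(i) {
    vapply(runs, function(df) df$rate[i], numeric(1))
  })
  rates <- matrix(rates, nrow = n_runs)
  structure(
    list(runs = runs,
         summary = data.frame(
           k = k_label,
           mean_rate = colMeans(rates),
           sd_rate = apply(rates, 2, stats::sd),
           row.names = NULL
         ),
         n_pool_excluded = length(sc$unscorable)),
    class = "rxngap_validation2"
  )
}

#' Write validation results as tidy TSV and a JSON summary
#'
#' Works for both validation protocols: the TSV is long-format
#' `(run, metric, value)` -- for top-k recovery the metric is
#' `recovery_top<k>` -- and the JSON holds the aggregated summary table.
#'
#' @param v an `rxngap_validation1` or `rxngap_validation2` object.
#' @param tsv,json output paths; either may be `NULL` to skip.
#' @return invisibly, the tidy data.frame.
#' @export
write_validation_report <- function(v, tsv = NULL, json = NULL) {
  if (inherits(v, "rxngap_validation1")) {
    tidy <- do.call(rbind, lapply(seq_along(v$runs), function(r) {
      data.frame(run = r,
                 metric = c("auroc", "auprc", "recall", "precision", "f1"),
                 value = unlist(v$runs[[r]][c("auroc", "auprc", "recall",
                                              "precision", "f1")],
                                use.names = FALSE))
    }))
  } else if (inherits(v, "rxngap_validation2")) {
    tidy <- do.call(rbind, lapply(seq_along(v$runs), function(r) {
      df <- v$runs[[r]]
      k_lab <- ifelse(df$k == df$n_removed, "N", as.character(df$k))
      data.frame(run = r, metric = paste0("recovery_top", k_lab),
                 value = df$rate)
    }))
  } else {
    stop_rxngap("unsupported validation object", class = "rxngap_domain_error")
  }
  if (!is.null(tsv)) {
    utils::write.table(tidy, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(v$summary, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(tidy)
}
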