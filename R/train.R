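#' Ranking loss over positive and negative scores
#'
#' `loss = mean_e softplus(mean_f(S_f) - S_e)`: the average, over positive
#' reactions e, of `log(1 + exp(mean_F - S_e))` where `mean_F` is the mean
#' score of the negative set. Minimising it pushes every positive score above
#' the average negative score. The loss is strictly positive; with sigmoid
#' scores the argument is bounded in (-1, 1), so the loss never falls below
#' `softplus(-1) ~= 0.3133`.
#'
#' @param pos_scores,neg_scores numeric vectors of scores in (0, 1); both
#'   non-empty.
#' @return scalar loss.
#' @export
ranking_loss <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_rxngap("ranking loss needs non-empty positive and negative score sets",
                class = "rxngap_domain_error")
  }
  mean(log1p(exp(mean(neg_scores) - pos_scores)))
}

#' @rdname ranking_loss
#' @return `ranking_loss_grad()`: list with `pos` and `neg`, the analytic
#'   gradients of the loss with respect to each score.
#' @export
ranking_loss_grad <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_rxngap("ranking loss needs non-empty positive and negative score sets",
                class = "rxngap_domain_error")
  }
  nE <- length(pos_scores)
  nF <- length(neg_scores)
  sig <- stats::plogis(mean(neg_scores) - pos_scores)
  list(pos = -sig / nE, neg = rep(sum(sig) / (nE * nF), nF))
}

#' Monte-Carlo train/test splits of a reaction set
#'
#' Each run shuffles the reactions with a run-specific derived seed and takes
#' the first `ceiling(train_fraction * |E|)` as training set, the rest as
#' test set. Splits are disjoint, exhaustive, and reproducible from `seed`.
#'
#' @param E named list of member vectors (|E| >= 2).
#' @param train_fraction in (0, 1); 0.6 and 0.9 are the conventional
#'   settings for threshold classification and top-k recovery respectively.
#' @param n_runs number of Monte-Carlo runs (default 10).
#' @param seed integer seed.
#' @return list of `n_runs` lists, each with `train` and `test` (named lists
#'   of member vectors).
#' @export
monte_carlo_split <- function(E, train_fraction = 0.6, n_runs = 10L, seed = 1L) {
  if (length(E) < 2L) {
    stop_rxngap("need at least 2 reactions to split", class = "rxngap_domain_error")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_rxngap("train_fraction must be in (0, 1)", class = "rxngap_domain_error")
  }
  m <- length(E)
  n_train <- ceiling(train_fraction * m)
  if (n_train >= m) n_train <- m - 1L
  lapply(seq_len(n_runs), function(r) {
    perm <- withr::with_seed(derive_seed(seed, r), sample(m))
    list(train = E[perm[seq_len(n_train)]], test = E[perm[(n_train + 1):m]])
  })
}

#' Training configuration
#'
#' @param epochs number of full-batch Adam epochs (default 100).
#' @param hp a [hyperparams()] object.
#' @param seed integer master seed; everything stochastic in training
#'   (parameter initialisation, per-epoch negative resampling, dropout masks)
#'   derives from it.
#' @param negative_ratio negatives per positive during training (default 1).
#' @return list of class `rxngap_train_config`.
#' @export
train_config <- function(epochs = 100L, hp = hyperparams(), seed = 1L,
                         negative_ratio = 1) {
  stopifnot(epochs >= 1, inherits(hp, "rxngap_hyperparams"), negative_ratio > 0)
  structure(
    list(epochs = as.integer(epochs), hp = hp, seed = as.integer(seed),
         negative_ratio = negative_ratio),
    class = "rxngap_train_config"
  )
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the reaction scorer
#'
#' Full-batch training on one metabolic hypergraph. The incidence matrix is
#' built from the training positives only. Each epoch resamples fresh
#' negatives (1:1 by default) with a per-epoch derived seed, runs the forward
#' pass on positive plus negative cliques with dropout active, computes the
#' ranking loss and takes one Adam step. The entire trajectory is a pure
#' function of `(h, train_reactions, config)`.
#'
#' @param h a `metabolic_hypergraph` (supplies the node universe and the
#'   negative-sampling pool).
#' @param train_reactions named list of member vectors: the positive
#'   reactions to train on. Defaults to all reactions of `h`.
#' @param config a [train_config()].
#' @return object of class `rxngap_fit`: list with `params`, `losses`
#'   (per-epoch), `H` (training incidence), `train_ids`, `config`.
#' @export
train_model <- function(h, train_reactions = h$reactions, config = train_config()) {
  stopifnot(inherits(config, "rxngap_train_config"))
  if (length(train_reactions) == 0L) {
    stop_rxngap("training reaction set is empty", class = "rxngap_domain_error")
  }
  hp <- config$hp
  H <- incidence_matrix(h, names(train_reactions))
  params <- init_model_params(hp, ncol(H), seed = derive_seed(config$seed, 0L))
  state <- adam_init(params)
  pos_cliques <- decompose_reactions(h, train_reactions, "positive")
  n_pos <- length(pos_cliques)
  losses <- numeric(config$epochs)

  withr::with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$epochs)) {
      negs <- sample_negative_set(train_reactions, h, ratio = config$negative_ratio,
                                  seed = derive_seed(config$seed, 1000L + epoch))
      neg_cliques <- decompose_reactions(h, negs$negatives, "negative")
      batch <- clique_batch(c(pos_cliques, neg_cliques))
      fw <- model_forward(H, batch, params, training = TRUE)
      pos_idx <- seq_len(n_pos)
      neg_idx <- n_pos + seq_along(neg_cliques)
      losses[epoch] <- ranking_loss(fw$scores[pos_idx], fw$scores[neg_idx])
      if (!is.finite(losses[epoch])) {
        stop_rxngap("non-finite training loss at epoch ", epoch,
                    class = "rxngap_training_error")
      }
      g <- ranking_loss_grad(fw$scores[pos_idx], fw$scores[neg_idx])
      dscore <- numeric(batch$n_cliques)
      dscore[pos_idx] <- g$pos
      dscore[neg_idx] <- g$neg
      grads <- model_backward(fw, dscore, params)
      upd <- adam_step(params, grads, state, lr = hp$lr)
      hp_attr <- attributes(params)
      params <- upd$params
      attributes(params) <- hp_attr
      state <- upd$state
    }
  })
  structure(
    list(params = params, losses = losses, H = H,
         train_ids = names(train_reactions), config = config),
    class = "rxngap_fit"
  )
}

#' @export
print.rxngap_fit <- function(x, ...) {
  cat(sprintf(
    "reaction-scorer fit: %d training reactions, %d epochs, loss %.4f -> %.4f\n",
    length(x$train_ids), length(x$losses), x$losses[1], x$losses[length(x$losses)]
  ))
  invisible(x)
}

#' Score candidate reactions with a trained model
#'
#' Evaluation-mode forward pass over candidate cliques; the incidence matrix
#' remains the training incidence. Candidates containing metabolites absent
#' from the hypergraph cannot receive encoder features (the model is
#' transductive): they are excluded from the scored output and reported in
#' the `unscorable` attribute (with a warning).
#'
#' @param fit an `rxngap_fit` from [train_model()].
#' @param h the `metabolic_hypergraph` the model was trained on.
#' @param candidates named list of member vectors.
#' @return data.frame with `reaction_id` and `score`, in input order;
#'   attribute `unscorable` holds the ids of excluded candidates.
#' @export
predict_scores <- function(fit, h, candidates) {
  stopifnot(inherits(fit, "rxngap_fit"))
  sc <- scoreable_reactions(h, candidates)
  if (length(sc$unscorable)) {
    warning(length(sc$unscorable),
            " candidate(s) contain metabolites absent from the network and were",
            " not scored", call. = FALSE)
  }
  if (length(sc$scoreable) == 0L) {
    out <- data.frame(reaction_id = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    cl <- decompose_reactions(h, sc$scoreable, "candidate")
    out <- forward_scores(fit$H, cl, fit$params, training = FALSE)
    out <- out[, c("reaction_id", "score")]
    rownames(out) <- NULL
  }
  attr(out, "unscorable") <- sc$unscorable
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the parameter arrays, the
#' hyperparameters, the training incidence width and the training reaction
#' ids. Loading validates shape consistency against the embedded
#' hyperparameters and incidence width.
#'
#' @param fit an `rxngap_fit`.
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns the `rxngap_fit` (without the
#'   incidence matrix `H`, which is rebuilt from the hypergraph via
#'   `restore_incidence()`).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "rxngap_fit"))
  obj <- list(
    params = unclass(fit$params),
    hp = unclass(params_hp(fit$params)),
    m = attr(fit$params, "m"),
    train_ids = fit$train_ids,
    losses = fit$losses,
    config = fit$config
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param h the hypergraph used for training (rebuilds the incidence matrix).
#' @export
load_checkpoint <- function(path, h) {
  obj <- readRDS(path)
  hp <- do.call(hyperparams, obj$hp)
  p <- obj$params
  ok <- identical(dim(p$W_enc), c(hp$d_enc, as.integer(obj$m))) &&
    length(p$b_enc) == hp$d_enc &&
    all(vapply(seq_len(hp$K), function(k) {
      identical(dim(p[[paste0("W_conv_", k)]]), c(hp$d_conv, hp$d_enc))
    }, logical(1))) &&
    length(p$w_score) == 2L * hp$d_conv
  if (!ok) {
    stop_rxngap("checkpoint parameter shapes are inconsistent with its ",
                "hyperparameters", class = "rxngap_format_error")
  }
  params <- structure(p, class = "rxngap_params", hyperparams = hp,
                      m = as.integer(obj$m))
  H <- incidence_matrix(h, obj$train_ids)
  structure(
    list(params = params, losses = obj$losses, H = H,
         train_ids = obj$train_ids, config = obj$config),
    class = "rxngap_fit"
  )
}

#' Read a training configuration from YAML or JSON
#'
#' The file mirrors [train_config()] / [hyperparams()]: top-level keys
#' `epochs`, `seed`, `negative_ratio`, and an optional `hyperparams` block
#' with `d_enc`, `d_conv`, `K`, `p_drop`, `lr`. Missing keys fall back to
#' the defaults. Files ending in `.json` are parsed as JSON, anything else
#' as YAML.
#'
#' @param path configuration file.
#' @return a `rxngap_train_config`.
#' @export
read_train_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  hp_args <- raw$hyperparams %||% list()
  hp <- do.call(hyperparams, hp_args)
  train_config(
    epochs = raw$epochs %||% 100L,
    hp = hp,
    seed = raw$seed %||% 1L,
    negative_ratio = raw$negative_ratio %||% 1
  )
}

#' Write the per-epoch loss trajectory as tab-separated text
#'
#' @param fit an `rxngap_fit`.
#' @param path output TSV (columns `epoch`, `loss`).
#' @return invisibly, `path`.
#' @export
write_loss_log <- function(fit, path) {
  stopifnot(inherits(fit, "rxngap_fit"))
  utils::write.table(
    data.frame(epoch = seq_along(fit$losses), loss = fit$losses),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
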