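#' Similarity of a candidate reaction to a model's reactions
#'
#' The maximum, over all existing reactions, of a similarity between member
#' sets. The default metric is the Jaccard index `|c intersect e| / |c union
#' e|`, a bounded, parameter-free correlation-like measure on binary
#' participation vectors; `method = "pearson"` instead uses the Pearson
#' correlation of the binary incidence columns over the node universe (which
#' can be negative). Gap-filling prefers *dissimilar* candidates, on the
#' rationale that dissimilar reactions are more likely to be functionally
#' complementary to the existing network.
#'
#' @param candidate character vector of metabolite ids.
#' @param existing named list of member vectors (non-empty).
#' @param method `"jaccard"` (default) or `"pearson"`.
#' @param nodes node universe for `method = "pearson"` (required there).
#' @return scalar similarity; in `[0, 1]` for Jaccard.
#' @export
similarity_score <- function(candidate, existing, method = c("jaccard", "pearson"),
                             nodes = NULL) {
  method <- match.arg(method)
  if (length(existing) == 0L) {
    stop_rxngap("existing reaction list is empty", class = "rxngap_domain_error")
  }
  candidate <- unique(as.character(candidate))
  if (method == "jaccard") {
    max(vapply(existing, function(e) {
      e <- unique(e)
      length(intersect(candidate, e)) / length(union(candidate, e))
    }, numeric(1)))
  } else {
    if (is.null(nodes)) {
      stop_rxngap("pearson similarity needs the node universe", class = "rxngap_domain_error")
    }
    cv <- as.numeric(nodes %in% candidate)
    max(vapply(existing, function(e) {
      ev <- as.numeric(nodes %in% e)
      if (stats::sd(cv) == 0 || stats::sd(ev) == 0) return(0)
      stats::cor(cv, ev)
    }, numeric(1)))
  }
}

#' Gap-filling configuration
#'
#' @param confidence_floor minimum averaged confidence score for a candidate
#'   to be considered (default 0.9995).
#' @param top_k number of reactions to add to the draft model (default 200).
#' @param n_score_runs Monte-Carlo training repeats over which candidate
#'   scores are averaged (default 5).
#' @param similarity similarity metric, `"jaccard"` or `"pearson"`.
#' @return list of class `rxngap_gapfill_config`.
#' @export
gapfill_config <- function(confidence_floor = 0.9995, top_k = 200L,
                           n_score_runs = 5L,
                           similarity = c("jaccard", "pearson")) {
  stopifnot(confidence_floor > 0, confidence_floor < 1, top_k >= 1,
            n_score_runs >= 1)
  structure(
    list(confidence_floor = confidence_floor, top_k = as.integer(top_k),
         n_score_runs = as.integer(n_score_runs),
         similarity = match.arg(similarity)),
    class = "rxngap_gapfill_config"
  )
}

#' Order high-confidence candidates by dissimilarity
#'
#' The ranking rule applied to already-computed averaged scores: candidates
#' whose mean confidence is at least the floor are retained and sorted by
#' similarity ascending (least similar to the draft model first; ties keep
#' input order). Ranks are 1-based over the retained set.
#'
#' @param scored data.frame with columns `reaction_id`, `mean_confidence`,
#'   `similarity`.
#' @param config a [gapfill_config()].
#' @return data.frame with columns `rank`, `reaction_id`, `mean_confidence`,
#'   `similarity`; zero rows (with a warning) if nothing passes the floor.
#' @export
rank_by_confidence_similarity <- function(scored, config = gapfill_config()) {
  keep <- scored$mean_confidence >= config$confidence_floor
  retained <- scored[keep, , drop = FALSE]
  if (nrow(retained) == 0L) {
    warning("no candidate reaches the confidence floor of ",
            config$confidence_floor, call. = FALSE)
  }
  ord <- order(retained$similarity)  # stable on ties
  retained <- retained[ord, , drop = FALSE]
  out <- data.frame(
    rank = seq_len(nrow(retained)),
    reaction_id = retained$reaction_id,
    mean_confidence = retained$mean_confidence,
    similarity = retained$similarity,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank a candidate pool for gap-filling a draft model
#'
#' Trains `n_score_runs` models with distinct derived seeds on the *entire*
#' reaction set of the draft model, averages each candidate's confidence
#' score over the runs, retains candidates whose mean score reaches the
#' confidence floor, and orders them by ascending similarity to the draft
#' reactions (least similar first). The caller truncates to `top_k` when
#' augmenting the model. Candidates containing metabolites absent from the
#' draft network are excluded and reported via the `unscorable` attribute.
#' Flux-based screening (e.g. against energy-generating cycles) is out of
#' scope here: the ranked list is meant to feed such downstream filters.
#'
#' @param h the draft model as a `metabolic_hypergraph`.
#' @param pool named list of member vectors: the candidate reactions.
#' @param config a [gapfill_config()].
#' @param tc a [train_config()]; its seed spawns one seed per scoring run.
#' @return data.frame as in [rank_by_confidence_similarity()], with
#'   attributes `unscorable` (excluded candidate ids) and `n_runs`.
#' @export
rank_candidates <- function(h, pool, config = gapfill_config(),
                            tc = train_config()) {
  sc <- scoreable_reactions(h, pool)
  if (length(sc$scoreable) == 0L) {
    stop_rxngap("no scoreable candidate in the pool", class = "rxngap_domain_error")
  }
  pool <- sc$scoreable
  score_mat <- matrix(0, length(pool), config$n_score_runs)
  for (run in seq_len(config$n_score_runs)) {
    run_cfg <- tc
    run_cfg$seed <- derive_seed(tc$seed, 40000L + run)
    fit <- train_model(h, h$reactions, run_cfg)
    scored <- predict_scores(fit, h, pool)
    score_mat[, run] <- scored$score
  }
  sims <- vapply(pool, similarity_score, numeric(1), existing = h$reactions,
                 method = config$similarity, nodes = h$nodes)
  scored <- data.frame(
    reaction_id = names(pool),
    mean_confidence = rowMeans(score_mat),
    similarity = unname(sims),
    stringsAsFactors = FALSE
  )
  out <- rank_by_confidence_similarity(scored, config)
  attr(out, "unscorable") <- sc$unscorable
  attr(out, "n_runs") <- config$n_score_runs
  out
}

#' Write an augmented model
#'
#' Appends the selected reactions to a draft model and writes the union to
#' `path`. The output format follows the file extension: `.xml` / `.sbml`
#' writes SBML (added reactions carry a note tag), anything else writes a
#' reaction table with an `added` flag column. An addition whose id collides
#' with an existing reaction id is renamed with an `_added` suffix (with a
#' message); re-reading the output recovers every member set.
#'
#' @param draft a `metabolic_hypergraph` (the draft model).
#' @param additions named list of member vectors to add.
#' @param path output file.
#' @return invisibly, the augmented `metabolic_hypergraph`.
#' @export
write_augmented_model <- function(draft, additions, path) {
  add <- additions
  if (length(add)) {
    bad <- !vapply(add, function(m) all(m %in% draft$nodes), logical(1))
    if (any(bad)) {
      stop_rxngap("addition references metabolites absent from the draft model: ",
                  names(add)[bad][1L], class = "rxngap_integrity_error")
    }
    clash <- names(add) %in% names(draft$reactions)
    if (any(clash)) {
      message(sum(clash), " addition id(s) clashed with draft ids; renamed with _added")
      names(add)[clash] <- paste0(names(add)[clash], "_added")
    }
  }
  combined <- c(draft$reactions, add)
  h_aug <- hypergraph(combined, nodes = draft$nodes)
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
    write_gem_sbml(h_aug, path, added = names(add))
  } else {
    write_reaction_table(h_aug, path, added = names(add))
  }
  invisible(h_aug)
}
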