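#' Negative sampling of fake reactions
#'
#' For a true reaction e, a fake reaction f of the same size is built by
#' keeping roughly half of e's metabolites and replacing the rest with
#' metabolites drawn uniformly from outside e. Exactly
#' `r = max(1, floor(|e| / 2))` members are replaced (so the kept majority is
#' `ceiling(|e| / 2)` on odd sizes, and a singleton reaction has its only
#' member replaced, guaranteeing f != e). The rationale is that half of a
#' valid reaction's metabolites plus random ones are extremely unlikely to
#' form another valid reaction.
#'
#' @param e character vector of metabolite ids (one reaction's member set).
#' @param h a `metabolic_hypergraph`; the replacement pool is `V - e` over
#'   `h`'s node set by default.
#' @param seed integer seed; the draw is a pure function of
#'   `(e, pool, seed)`.
#' @param pool optional character vector overriding the replacement universe
#'   (e.g. an external metabolite list); members of `e` are excluded from it.
#' @return character vector of metabolite ids, same length as `e`.
#' @export
sample_negative <- function(e, h, seed, pool = NULL) {
  e <- unique(as.character(e))
  s <- length(e)
  universe <- if (is.null(pool)) h$nodes else unique(as.character(pool))
  outside <- setdiff(universe, e)
  r <- max(1L, s %/% 2L)
  if (length(outside) < r) {
    stop_rxngap("replacement pool exhausted: need ", r, " metabolites outside the ",
                "reaction but only ", length(outside), " available",
                class = "rxngap_sampling_error")
  }
  withr::with_seed(seed, {
    keep <- if (s - r > 0L) sample(e, s - r) else character()
    gain <- sample(outside, r)
    c(keep, gain)
  })
}

#' Sample a set of negative reactions
#'
#' Draws `ceiling(ratio * |E|)` fake reactions from the positives `E`. With
#' the default 1:1 ratio each positive is the source of exactly one negative,
#' matching the training/testing balance used throughout; fractional ratios
#' choose source positives uniformly without replacement, ratios above 1
#' cycle through the positives and top up with uniform draws.
#'
#' @param E named list of member vectors (the positive reactions).
#' @param h a `metabolic_hypergraph`.
#' @param ratio positive number: negatives per positive (default 1).
#' @param seed integer seed; the whole set is a pure function of
#'   `(E, h, ratio, seed)`.
#' @param pool optional replacement universe, see [sample_negative()].
#' @return list with `negatives` (named list of member vectors, ids
#'   `<source>_neg<i>`) and `provenance` (character vector of source positive
#'   ids, parallel to `negatives`).
#' @export
sample_negative_set <- function(E, h, ratio = 1, seed = 1L, pool = NULL) {
  if (!is.numeric(ratio) || ratio <= 0) {
    stop_rxngap("ratio must be > 0", class = "rxngap_domain_error")
  }
  m <- length(E)
  n_neg <- ceiling(ratio * m)
  base <- rep(seq_len(m), floor(ratio))
  extra <- n_neg - length(base)
  idx <- if (extra > 0L) {
    picked <- withr::with_seed(derive_seed(seed, 0L), sample(m, extra))
    c(base, sort(picked))
  } else {
    base
  }
  negatives <- vector("list", n_neg)
  provenance <- character(n_neg)
  for (k in seq_len(n_neg)) {
    src <- idx[k]
    negatives[[k]] <- sample_negative(E[[src]], h, seed = derive_seed(seed, k),
                                      pool = pool)
    provenance[k] <- names(E)[src]
  }
  names(negatives) <- paste0(provenance, "_neg", seq_len(n_neg))
  list(negatives = negatives, provenance = provenance)
}
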