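#' Specification of a synthetic metabolic hypergraph
#'
#' The generator emulates the gross topology of genome-scale metabolic
#' networks: a small set of high-degree "currency" metabolites (the ATP /
#' H2O / proton analogues) that appear in a large share of reactions,
#' pathway-like modules among the remaining metabolites so that reactions
#' are locally coherent rather than uniform random sets, reaction
#' cardinalities mostly between 2 and 8, and a connected network. The module
#' structure is what makes held-out reactions predictable from the rest of
#' the network -- the property topology-based gap-filling relies on in real
#' metabolic models. The generator does not simulate stoichiometry,
#' directionality or biomass composition.
#'
#' @param n_metabolites number of metabolites (must be at least the largest
#'   reaction size).
#' @param n_reactions number of reactions.
#' @param hub_fraction fraction of metabolites designated currency hubs
#'   (default 0.03).
#' @param hub_attach_prob probability that a reaction includes a hub
#'   (default 0.6).
#' @param size_range inclusive bounds on reaction cardinality (default
#'   `c(2, 8)`).
#' @param n_modules number of pathway-like modules the non-hub metabolites
#'   are partitioned into (default 12).
#' @param within_module_prob probability that each non-hub member of a
#'   reaction is drawn from the reaction's home module rather than uniformly
#'   from all non-hubs (default 0.8).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `rxngap_gem_spec`.
#' @export
synthetic_gem_spec <- function(n_metabolites = 200L, n_reactions = 600L,
                               hub_fraction = 0.03, hub_attach_prob = 0.6,
                               size_range = c(2L, 8L), n_modules = 12L,
                               within_module_prob = 0.8, seed = 1L) {
  stopifnot(n_metabolites >= max(size_range), n_reactions >= 1,
            hub_fraction >= 0, hub_fraction <= 1,
            hub_attach_prob >= 0, hub_attach_prob <= 1,
            length(size_range) == 2L, size_range[1] >= 1,
            size_range[2] >= size_range[1],
            n_modules >= 1, within_module_prob >= 0, within_module_prob <= 1)
  structure(
    list(n_metabolites = as.integer(n_metabolites),
         n_reactions = as.integer(n_reactions),
         hub_fraction = hub_fraction, hub_attach_prob = hub_attach_prob,
         size_range = as.integer(size_range),
         n_modules = as.integer(n_modules),
         within_module_prob = within_module_prob,
         seed = as.integer(seed)),
    class = "rxngap_gem_spec"
  )
}

hypergraph_is_connected <- function(h) {
  edges <- unlist(lapply(names(h$reactions), function(id) {
    as.vector(rbind(paste0("rxn::", id), h$reactions[[id]]))
  }), use.names = FALSE)
  g <- igraph::make_graph(edges, directed = FALSE)
  isolated <- setdiff(h$nodes, unique(unlist(h$reactions, use.names = FALSE)))
  length(isolated) == 0L && igraph::is_connected(g)
}

#' Generate a synthetic metabolic hypergraph
#'
#' Draws `n_reactions` reactions: each size is uniform over `size_range`;
#' each reaction includes one hub metabolite with probability
#' `hub_attach_prob`; each reaction is assigned a home module uniformly, and
#' every non-hub member is drawn from that module with probability
#' `within_module_prob` (uniformly from all non-hubs otherwise), without
#' replacement. Generation is retried (up to 100 derived seeds) until the
#' hypergraph is connected with no isolated metabolite.
#'
#' @param spec a [synthetic_gem_spec()].
#' @return a `metabolic_hypergraph` with metabolites `hub01...` /
#'   `met0001...` and reactions `R0001...`.
#' @export
generate_gem <- function(spec) {
  stopifnot(inherits(spec, "rxngap_gem_spec"))
  n_hub <- max(if (spec$hub_fraction > 0) 1L else 0L,
               round(spec$hub_fraction * spec$n_metabolites))
  hubs <- if (n_hub > 0) sprintf("hub%02d", seq_len(n_hub)) else character()
  others <- sprintf("met%04d", seq_len(spec$n_metabolites - n_hub))
  nodes <- c(hubs, others)
  module_of <- rep_len(seq_len(spec$n_modules), length(others))
  modules <- split(others, module_of)
  for (attempt in seq_len(100L)) {
    h <- withr::with_seed(derive_seed(spec$seed, attempt - 1L), {
      members <- vector("list", spec$n_reactions)
      sizes_avail <- seq(spec$size_range[1], spec$size_range[2])
      for (i in seq_len(spec$n_reactions)) {
        s <- sizes_avail[sample.int(length(sizes_avail), 1L)]
        use_hub <- n_hub > 0 && stats::runif(1) < spec$hub_attach_prob
        mem <- character()
        if (use_hub) mem <- sample(hubs, 1L)
        n_rest <- min(s - length(mem), length(others))
        home <- modules[[sample.int(length(modules), 1L)]]
        n_within <- sum(stats::runif(n_rest) < spec$within_module_prob)
        n_within <- min(n_within, length(home))
        picked <- sample(home, n_within)
        leftover <- setdiff(others, picked)
        if (n_rest > n_within) {
          picked <- c(picked, sample(leftover, n_rest - n_within))
        }
        members[[i]] <- c(mem, picked)
      }
      names(members) <- sprintf("R%04d", seq_len(spec$n_reactions))
      hypergraph(members, nodes = nodes)
    })
    if (hypergraph_is_connected(h)) {
      return(h)
    }
  }
  stop_rxngap("could not generate a connected hypergraph in 100 attempts; ",
              "increase n_reactions or reduce n_metabolites",
              class = "rxngap_generation_error")
}

#' Artificially remove reactions
#'
#' Uniformly removes `ceiling(fraction * m)` reactions, returning the
#' reduced hypergraph and the removed set. Nodes keep their rows: metabolites
#' orphaned by the removal are not pruned, so incidence rows stay aligned
#' with the original network.
#'
#' @param h a `metabolic_hypergraph`.
#' @param fraction fraction of reactions to remove, in (0, 1).
#' @param seed integer seed.
#' @return list with `kept` (a `metabolic_hypergraph` over the original node
#'   set) and `removed` (named list of member vectors).
#' @export
plant_and_remove <- function(h, fraction, seed = 1L) {
  m <- length(h$reactions)
  n_rm <- ceiling(fraction * m)
  if (n_rm < 1L || n_rm >= m) {
    stop_rxngap("fraction must remove at least one and keep at least one reaction",
                class = "rxngap_domain_error")
  }
  rm_idx <- withr::with_seed(seed, sample(m, n_rm))
  list(
    kept = hypergraph(h$reactions[-rm_idx], nodes = h$nodes),
    removed = h$reactions[rm_idx]
  )
}

#' Generate decoy reactions for a recovery experiment
#'
#' Builds a pool of fake candidate reactions by applying the
#' negative-sampling operator to uniformly chosen real reactions of `h`:
#' each decoy keeps about half of a real reaction's metabolites and replaces
#' the rest with random ones. This mirrors how a universal-database pool
#' differs from the target network while keeping sizes realistic.
#'
#' @param h a `metabolic_hypergraph`.
#' @param n number of decoys.
#' @param seed integer seed.
#' @return named list of member vectors (`decoy0001...`).
#' @export
generate_decoys <- function(h, n, seed = 1L) {
  m <- length(h$reactions)
  src <- withr::with_seed(derive_seed(seed, 0L), sample(m, n, replace = TRUE))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- sample_negative(h$reactions[[src[i]]], h,
                                seed = derive_seed(seed, i))
  }
  names(out) <- sprintf("decoy%04d", seq_len(n))
  out
}
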