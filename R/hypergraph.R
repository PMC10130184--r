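#' Construct a metabolic hypergraph
#'
#' A metabolic network is modelled as an undirected hypergraph: every
#' metabolite is a node and every reaction is a hyperlink joining all
#' metabolites that participate in it (reactants and products alike;
#' stoichiometry and direction are ignored, participation is all that
#' matters). Node order is the order of first appearance, so incidence-matrix
#' rows are stable across runs.
#'
#' @param reactions named list; each element is a character vector of
#'   metabolite ids (the hyperlink's members), named by reaction id.
#'   Duplicate ids within one reaction are collapsed (set semantics).
#' @param nodes optional character vector fixing the node set and its order;
#'   must contain every metabolite referenced by `reactions`. Defaults to the
#'   metabolites in order of first appearance.
#' @return An object of class `metabolic_hypergraph` with elements `nodes`
#'   (character), `reactions` (named list of character member vectors) and
#'   `node_index` (named integer lookup of row positions).
#' @examples
#' h <- hypergraph(list(R1 = c("A", "B"), R2 = c("B", "C")))
#' h$nodes
#' @export
hypergraph <- function(reactions, nodes = NULL) {
  if (length(reactions) == 0L) {
    stop_rxngap("hypergraph needs at least one reaction", class = "rxngap_integrity_error")
  }
  ids <- names(reactions)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_rxngap("every reaction must have a non-empty id", class = "rxngap_integrity_error")
  }
  if (anyDuplicated(ids)) {
    stop_rxngap("duplicate reaction id: ", ids[duplicated(ids)][1L],
                class = "rxngap_integrity_error")
  }
  members <- lapply(reactions, function(m) {
    m <- unique(as.character(m))
    if (length(m) == 0L || any(!nzchar(m)) || anyNA(m)) {
      stop_rxngap("reaction with empty or invalid member list",
                  class = "rxngap_integrity_error")
    }
    m
  })
  names(members) <- ids
  seen <- unique(unlist(members, use.names = FALSE))
  if (is.null(nodes)) {
    nodes <- seen
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) {
      stop_rxngap("duplicate metabolite id in node set", class = "rxngap_integrity_error")
    }
    missing <- setdiff(seen, nodes)
    if (length(missing)) {
      stop_rxngap("reaction references undeclared metabolite: ", missing[1L],
                  class = "rxngap_integrity_error")
    }
  }
  structure(
    list(
      nodes = nodes,
      reactions = members,
      node_index = stats::setNames(seq_along(nodes), nodes)
    ),
    class = "metabolic_hypergraph"
  )
}

#' @export
print.metabolic_hypergraph <- function(x, ...) {
  sizes <- lengths(x$reactions)
  cat(sprintf(
    "metabolic hypergraph: %d metabolites, %d reactions (sizes %d-%d, median %g)\n",
    length(x$nodes), length(x$reactions),
    min(sizes), max(sizes), stats::median(sizes)
  ))
  invisible(x)
}

#' Number of metabolites and reactions
#'
#' @param h a `metabolic_hypergraph`.
#' @return `n_metabolites()`: integer count of nodes; `n_reactions()`:
#'   integer count of hyperlinks.
#' @export
n_metabolites <- function(h) length(h$nodes)

#' @rdname n_metabolites
#' @export
n_reactions <- function(h) length(h$reactions)

#' Incidence matrix of a hypergraph
#'
#' Builds the boolean participation matrix H: rows are metabolites (all nodes
#' of `h`, in their fixed order), columns the selected reactions; entry
#' (i, p) is 1 iff metabolite i belongs to reaction p. By convention only
#' positive (known) reactions are used as columns when training, so candidate
#' reactions never leak into the feature construction.
#'
#' @param h a `metabolic_hypergraph`.
#' @param columns character vector of reaction ids to use as columns, in
#'   order. Defaults to all reactions of `h`.
#' @return numeric 0/1 matrix with dimnames (metabolite ids x reaction ids).
#'   Column sums equal reaction sizes.
#' @examples
#' h <- hypergraph(list(R1 = c("A", "B"), R2 = c("B", "C")))
#' incidence_matrix(h)
#' @export
incidence_matrix <- function(h, columns = names(h$reactions)) {
  columns <- as.character(columns)
  unknown <- setdiff(columns, names(h$reactions))
  if (length(unknown)) {
    stop_rxngap("unknown reaction id: ", unknown[1L], class = "rxngap_lookup_error")
  }
  n <- length(h$nodes)
  H <- matrix(0, n, length(columns), dimnames = list(h$nodes, columns))
  for (j in seq_along(columns)) {
    H[h$node_index[h$reactions[[columns[j]]]], j] <- 1
  }
  H
}

#' Decompose reactions into disjoint cliques
#'
#' Every reaction becomes a fully connected subgraph (clique) over its member
#' metabolites. Cliques are disjoint objects even when reactions share
#' metabolites: two clique-nodes originating from the same metabolite share
#' the same initial feature vector but are normalised and convolved
#' independently within their own cliques.
#'
#' @param h a `metabolic_hypergraph` supplying the node row positions.
#' @param reactions named list of member vectors (defaults to `h$reactions`).
#' @param label tag attached to every clique: `"positive"`, `"negative"` or
#'   `"candidate"`.
#' @return list of cliques, each a list with `reaction_id`, `node_rows`
#'   (integer row positions) and `label`.
#' @export
decompose_reactions <- function(h, reactions = h$reactions,
                                label = c("positive", "negative", "candidate")) {
  label <- match.arg(label)
  ids <- names(reactions)
  out <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    members <- unique(as.character(reactions[[i]]))
    rows <- h$node_index[members]
    if (anyNA(rows)) {
      stop_rxngap("reaction ", ids[i], " references metabolite absent from hypergraph: ",
                  members[which(is.na(rows))[1L]], class = "rxngap_lookup_error")
    }
    out[[i]] <- list(reaction_id = ids[i], node_rows = unname(rows), label = label)
  }
  out
}

# Reactions whose members are all present in h's node set.
scoreable_reactions <- function(h, reactions) {
  ok <- vapply(reactions, function(m) all(m %in% h$nodes), logical(1))
  list(scoreable = reactions[ok], unscorable = names(reactions)[!ok])
}
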