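#' Read a genome-scale metabolic model from SBML
#'
#' Parses SBML Level 2/3 into a [hypergraph()]. One node is created per
#' species id (compartment-qualified ids such as `atp_c` / `atp_e` stay
#' distinct nodes) and one hyperlink per reaction, whose members are the
#' union of its reactant and product species. Stoichiometric coefficients and
#' reversibility flags are discarded: only participation matters. Boundary /
#' exchange reactions involving a single species yield singleton hyperlinks.
#'
#' @param path path to an SBML file with `listOfSpecies` and
#'   `listOfReactions`.
#' @return a `metabolic_hypergraph`. Node order follows `listOfSpecies`.
#' @export
read_gem_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_rxngap("SBML parse failure for '", path, "': ", conditionMessage(e),
                class = "rxngap_format_error")
  })
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) {
    stop_rxngap("SBML file has no listOfSpecies/species elements",
                class = "rxngap_format_error")
  }
  species <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(species)) {
    stop_rxngap("SBML species element missing an id attribute",
                class = "rxngap_format_error")
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) {
    stop_rxngap("SBML file has no listOfReactions/reaction elements",
                class = "rxngap_format_error")
  }
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyNA(rx_ids)) {
    stop_rxngap("SBML reaction element missing an id attribute",
                class = "rxngap_format_error")
  }
  members <- lapply(rx_nodes, function(rx) {
    refs <- xml2::xml_find_all(
      rx, "./listOfReactants/speciesReference | ./listOfProducts/speciesReference"
    )
    unique(xml2::xml_attr(refs, "species"))
  })
  names(members) <- rx_ids
  for (i in seq_along(members)) {
    bad <- setdiff(members[[i]], species)
    if (length(bad)) {
      stop_rxngap("reaction ", rx_ids[i], " references species '", bad[1L],
                  "' absent from listOfSpecies", class = "rxngap_integrity_error")
    }
    if (length(members[[i]]) == 0L) {
      stop_rxngap("reaction ", rx_ids[i], " has no reactant or product species",
                  class = "rxngap_integrity_error")
    }
  }
  hypergraph(members, nodes = species)
}

#' Read / write reaction tables
#'
#' Plain-text interchange formats for reaction sets: a TSV with columns
#' `reaction_id` and `metabolite_ids` (semicolon-separated members), or a
#' JSON array of `{"id": ..., "members": [...]}` objects. Files whose
#' extension is `.json` are treated as JSON, anything else as TSV. Duplicate
#' metabolite ids within one reaction are collapsed; duplicate reaction ids
#' or empty member lists are integrity errors. Candidate reaction pools use
#' the same formats.
#'
#' @param path file to read or write.
#' @return `read_reaction_table()` returns a `metabolic_hypergraph`;
#'   `read_reaction_pool()` returns the named list of member vectors without
#'   imposing a node universe; `write_reaction_table()` invisibly returns
#'   `path`.
#' @export
read_reaction_table <- function(path) {
  hypergraph(read_reaction_pool(path))
}

#' @rdname read_reaction_table
#' @export
read_reaction_pool <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    members <- lapply(recs, function(r) unique(as.character(r$members)))
    names(members) <- vapply(recs, function(r) as.character(r$id), character(1))
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    need <- c("reaction_id", "metabolite_ids")
    if (!all(need %in% names(tab))) {
      stop_rxngap("reaction table must have columns reaction_id and metabolite_ids",
                  class = "rxngap_format_error")
    }
    members <- lapply(strsplit(tab$metabolite_ids, ";", fixed = TRUE),
                      function(m) unique(m[nzchar(m)]))
    names(members) <- tab$reaction_id
  }
  if (anyDuplicated(names(members))) {
    stop_rxngap("duplicate reaction_id: ", names(members)[duplicated(names(members))][1L],
                class = "rxngap_integrity_error")
  }
  if (any(lengths(members) == 0L)) {
    stop_rxngap("reaction with empty member list: ",
                names(members)[lengths(members) == 0L][1L],
                class = "rxngap_integrity_error")
  }
  members
}

#' @rdname read_reaction_table
#' @param h a `metabolic_hypergraph`, or a named list of member vectors.
#' @param added optional character vector of reaction ids to flag in an
#'   `added` column (used when writing augmented models).
#' @export
write_reaction_table <- function(h, path, added = character()) {
  members <- if (inherits(h, "metabolic_hypergraph")) h$reactions else h
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- mapply(function(id, m) list(id = id, members = as.list(m)),
                   names(members), members, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    jsonlite::write_json(recs, path, auto_unbox = TRUE)
  } else {
    tab <- data.frame(
      reaction_id = names(members),
      metabolite_ids = vapply(members, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    )
    if (length(added)) tab$added <- tab$reaction_id %in% added
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# Minimal SBML Level 3 writer: participation only. Every member is emitted as
# a reactant speciesReference, which round-trips through read_gem_sbml (the
# reader takes the reactant/product union and ignores sides).
write_gem_sbml <- function(h, path, added = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  w('  <model id="model">')
  w('    <listOfSpecies>')
  for (s in h$nodes) {
    w('      <species id="', xml_escape(s), '" constant="false"/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (id in names(h$reactions)) {
    w('      <reaction id="', xml_escape(id), '" reversible="true" fast="false">')
    if (id %in% added) {
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        '<p>added by gap-filling</p></body></notes>')
    }
    w('        <listOfReactants>')
    for (m in h$reactions[[id]]) {
      w('          <speciesReference species="', xml_escape(m),
        '" constant="true"/>')
    }
    w('        </listOfReactants>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
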