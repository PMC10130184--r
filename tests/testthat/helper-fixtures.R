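# Shared fixtures, built in code at test time.

# Three-node toy network used across the core tests.
toy_hypergraph <- function() {
  hypergraph(list(R1 = c("A", "B"), R2 = c("B", "C")))
}

# A small but trainable synthetic network (fast enough for smoke training).
small_gem <- function(seed = 3) {
  generate_gem(synthetic_gem_spec(
    n_metabolites = 60, n_reactions = 120, n_modules = 5, seed = seed
  ))
}

# Tiny parameter set for hand-checkable forward passes.
tiny_params <- function(m, d_enc = 6, d_conv = 4, K = 3, seed = 1) {
  init_model_params(hyperparams(d_enc = d_enc, d_conv = d_conv, K = K,
                                p_drop = 0, lr = 0.01), m, seed = seed)
}

# Minimal SBML document (level 3) written to a temp file.
write_toy_sbml <- function(species, reactions, path = tempfile(fileext = ".xml"),
                           drop_species = character()) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '  <model id="toy">',
    '    <listOfSpecies>',
    sprintf('      <species id="%s"/>', setdiff(species, drop_species)),
    '    </listOfSpecies>',
    '    <listOfReactions>'
  )
  for (id in names(reactions)) {
    rx <- reactions[[id]]
    lines <- c(lines, sprintf('      <reaction id="%s">', id))
    if (length(rx$reactants)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="%s"/>', rx$reactants),
                 '        </listOfReactants>')
    }
    if (length(rx$products)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="%s"/>', rx$products),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  path
}

# Independent Chebyshev-polynomial oracle: T_k(L) via the eigendecomposition,
# T_k(L) = V diag(cos(k * acos(lambda))) V', valid for spectra in [-1, 1].
cheb_poly_eigen <- function(L, k) {
  eig <- eigen(L, symmetric = TRUE)
  lam <- pmin(pmax(eig$values, -1), 1)
  eig$vectors %*% (cos(k * acos(lam)) * t(eig$vectors))
}

# Brute-force AUROC: all positive-negative pairs, ties counting one half.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Untrained-model scorer for control experiments: scores candidates with
# freshly initialised parameters on the fit's training incidence.
untrained_scorer <- function(seed = 1) {
  function(fit, h, candidates) {
    hp <- attr(fit$params, "hyperparams")
    p0 <- init_model_params(hp, ncol(fit$H), seed = seed)
    fit0 <- structure(list(params = p0, H = fit$H, train_ids = fit$train_ids),
                      class = "rxngap_fit")
    predict_scores(fit0, h, candidates)
  }
}
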