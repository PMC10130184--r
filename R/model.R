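#' Model hyperparameters
#'
#' The universal hyperparameter set used for all metabolic models: encoder
#' feature dimension 256, convolutional feature dimension 128, Chebyshev
#' filter size 3, dropout probability 0.1 and learning rate 0.01. Performance
#' is insensitive to these within reasonable ranges, so no per-model tuning
#' is done.
#'
#' @param d_enc encoder feature dimension (>= 1).
#' @param d_conv convolutional feature dimension (>= 1).
#' @param K Chebyshev filter size (>= 1).
#' @param p_drop dropout probability in `[0, 1)`.
#' @param lr Adam learning rate (> 0).
#' @return list of class `rxngap_hyperparams`.
#' @export
hyperparams <- function(d_enc = 256L, d_conv = 128L, K = 3L,
                        p_drop = 0.1, lr = 0.01) {
  stopifnot(d_enc >= 1, d_conv >= 1, K >= 1, p_drop >= 0, p_drop < 1, lr > 0)
  structure(
    list(d_enc = as.integer(d_enc), d_conv = as.integer(d_conv),
         K = as.integer(K), p_drop = p_drop, lr = lr),
    class = "rxngap_hyperparams"
  )
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialise model parameters
#'
#' Uniform Glorot (fan-based) initialisation, fully determined by `seed`.
#' Parameters: encoder weights `W_enc` (d_enc x m) and bias `b_enc`;
#' graph-normalisation vectors `gamma` (scale, init 1), `beta` (shift, init
#' 0) and `alpha` (mean retention, init 1), each of length d_enc and shared
#' across cliques; `K` convolution weight matrices `W_conv_k` (d_conv x
#' d_enc, no bias); scoring weights `w_score` (length 2 d_conv) and scalar
#' bias `b_score`.
#'
#' @param hp a [hyperparams()] object.
#' @param m width of the training incidence matrix (number of positive
#'   reactions).
#' @param seed integer seed.
#' @return named list of parameter arrays of class `rxngap_params`, with the
#'   hyperparameters and `m` attached as attributes.
#' @export
init_model_params <- function(hp, m, seed = 1L) {
  stopifnot(inherits(hp, "rxngap_hyperparams"), m >= 1)
  params <- withr::with_seed(seed, {
    p <- list(
      W_enc = glorot(hp$d_enc, m),
      b_enc = numeric(hp$d_enc),
      gamma = rep(1, hp$d_enc),
      beta = numeric(hp$d_enc),
      alpha = rep(1, hp$d_enc)
    )
    for (k in seq_len(hp$K)) {
      p[[paste0("W_conv_", k)]] <- glorot(hp$d_conv, hp$d_enc)
    }
    p$w_score <- as.numeric(glorot(2L * hp$d_conv, 1L))
    p$b_score <- 0
    p
  })
  structure(params, class = "rxngap_params", hyperparams = hp, m = as.integer(m))
}

params_hp <- function(params) attr(params, "hyperparams")

#' Hard-tanh activation
#'
#' Clamps elementwise to `[-1, 1]`: 1 if `x >= 1`, -1 if `x <= -1`, else
#' `x`. Cheaper than tanh with equivalent behaviour in this architecture.
#'
#' @param x numeric scalar, vector or matrix.
#' @return same shape as `x`.
#' @export
hard_tanh <- function(x) pmin(pmax(x, -1), 1)

#' Initial metabolite features from the incidence matrix
#'
#' Encoder step: row i of the output is
#' `hard_tanh(W_enc h_i + b_enc)` where `h_i` is metabolite i's
#' incidence-matrix row. These initial features encode each metabolite's
#' crude topological relationship with all (training) reactions and are
#' shared by every clique containing the metabolite.
#'
#' @param H incidence matrix (n x m).
#' @param params model parameters; `W_enc` must have `m` columns.
#' @return n x d_enc matrix with entries in `[-1, 1]`.
#' @export
init_features <- function(H, params) {
  if (ncol(H) != ncol(params$W_enc)) {
    stop_rxngap("incidence width ", ncol(H), " does not match encoder width ",
                ncol(params$W_enc), class = "rxngap_dimension_error")
  }
  if (ncol(H) == 0L) {
    stop_rxngap("incidence matrix has zero columns; at least one training ",
                "reaction is required", class = "rxngap_dimension_error")
  }
  pre <- H %*% t(params$W_enc)
  hard_tanh(sweep(pre, 2, params$b_enc, "+"))
}

GRAPH_NORM_EPS <- 1e-5

#' Per-clique graph normalisation
#'
#' For one clique's feature block, each feature dimension j is standardised
#' over the clique's s nodes with a learnable mean-retention weight:
#' `x_ij -> gamma_j * (x_ij - alpha_j * mu_j) / sigma_j + beta_j`, where
#' `mu_j`, `sigma_j` are the mean and (population) standard deviation of
#' dimension j within the clique. `sigma_j` is floored at 1e-5 so singleton
#' or constant cliques stay finite. Applied independently per clique.
#'
#' @param X s x d feature matrix of one clique.
#' @param params model parameters (uses `gamma`, `beta`, `alpha`; recycled if
#'   shorter than d).
#' @return s x d normalised feature matrix.
#' @export
graph_normalize <- function(X, params) {
  X <- rbind(X)
  s <- nrow(X)
  d <- ncol(X)
  gamma <- rep_len(params$gamma, d)
  beta <- rep_len(params$beta, d)
  alpha <- rep_len(params$alpha, d)
  mu <- colMeans(X)
  sigma <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sige <- pmax(sigma, GRAPH_NORM_EPS)
  u <- sweep(X, 2, alpha * mu, "-")
  sweep(sweep(u, 2, gamma / sige, "*"), 2, beta, "+")
}

# SELU constants; alpha dropout replaces dropped entries by the SELU
# negative-saturation value and rescales to preserve mean and variance.
SELU_ALPHA <- 1.6732632423543772
SELU_LAMBDA <- 1.0507009873554805
ALPHA_DROP_SAT <- -SELU_LAMBDA * SELU_ALPHA

alpha_dropout_coefs <- function(p_drop) {
  q <- 1 - p_drop
  a <- 1 / sqrt(q * (1 + p_drop * ALPHA_DROP_SAT^2))
  list(a = a, b = -a * p_drop * ALPHA_DROP_SAT)
}

#' Alpha dropout
#'
#' SELU-compatible dropout: in training mode each entry is independently,
#' with probability `p_drop`, set to the SELU negative-saturation constant
#' (about -1.7581), and the whole tensor is then affinely rescaled so that
#' the expected mean and variance of a standardised input are preserved. In
#' evaluation mode (or with `p_drop = 0`) it is the identity.
#'
#' @param X numeric matrix.
#' @param p_drop dropout probability in `[0, 1)`.
#' @param training logical; dropout is only active when `TRUE`.
#' @param seed integer seed for the dropout mask (required when active).
#' @return matrix of the same shape.
#' @export
alpha_dropout <- function(X, p_drop, training = TRUE, seed = NULL) {
  if (!training || p_drop == 0) {
    return(X)
  }
  keep <- if (is.null(seed)) {
    stats::runif(length(X)) >= p_drop
  } else {
    withr::with_seed(seed, stats::runif(length(X)) >= p_drop)
  }
  co <- alpha_dropout_coefs(p_drop)
  Xp <- X
  Xp[!keep] <- ALPHA_DROP_SAT
  co$a * Xp + co$b
}

#' Scaled normalised Laplacian of a reaction clique
#'
#' A reaction of size s is a complete graph K_s, whose symmetric normalised
#' Laplacian `L = I - D^{-1/2} A D^{-1/2}` has the closed-form spectrum
#' `{0, s/(s-1) (multiplicity s-1)}`. The convolution operates on the
#' rescaled `L_tilde = (2 / lambda_max) L - I`, whose eigenvalues lie in
#' `[-1, 1]`. `lambda_max = s/(s-1)` is used in closed form. For a singleton
#' clique (s = 1) the degree matrix is singular and `L_tilde` is defined as
#' the 1 x 1 zero matrix, the limit that keeps the Chebyshev recursion
#' well-defined.
#'
#' @param s clique size (>= 1).
#' @return list with `L_tilde` (s x s symmetric matrix), `lambda_max` and
#'   `s`.
#' @export
scaled_laplacian <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != as.integer(s)) {
    stop_rxngap("clique size must be a positive integer", class = "rxngap_domain_error")
  }
  s <- as.integer(s)
  if (s == 1L) {
    return(list(L_tilde = matrix(0, 1, 1), lambda_max = 0, s = 1L))
  }
  lambda_max <- s / (s - 1)
  L <- diag(s) - (matrix(1, s, s) - diag(s)) / (s - 1)
  list(L_tilde = (2 / lambda_max) * L - diag(s), lambda_max = lambda_max, s = s)
}

#' Chebyshev polynomial terms on a clique
#'
#' Computes the Chebyshev basis terms of the spectral convolution by the
#' stable three-term recursion `Z1 = X`, `Z2 = L_tilde X`,
#' `Zk = 2 L_tilde Z(k-1) - Z(k-2)`, i.e. `Zk = T_(k-1)(L_tilde) X`.
#'
#' @param X s x d feature matrix.
#' @param L_tilde s x s scaled normalised Laplacian (spectrum in `[-1, 1]`).
#' @param K number of terms (filter size).
#' @return list of K matrices, each s x d.
#' @export
chebyshev_terms <- function(X, L_tilde, K) {
  X <- rbind(X)
  Z <- vector("list", K)
  Z[[1]] <- X
  if (K >= 2) Z[[2]] <- L_tilde %*% X
  for (k in seq_len(K)[-(1:2)]) {
    Z[[k]] <- 2 * (L_tilde %*% Z[[k - 1]]) - Z[[k - 2]]
  }
  Z
}

#' Chebyshev spectral graph convolution on one clique
#'
#' Refines each clique node's feature vector by mixing in the other members'
#' features: `x_hat_i = hard_tanh(sum_k W_conv_k z_i^(k))` with the terms of
#' [chebyshev_terms()]. No bias term is used. `K = 1` reduces to a per-node
#' linear map with no cross-node mixing.
#'
#' @param X s x d_enc feature matrix of one clique.
#' @param lap output of [scaled_laplacian()] for the clique's size.
#' @param params model parameters (`W_conv_1` ... `W_conv_K`).
#' @return s x d_conv matrix with entries in `[-1, 1]`.
#' @export
chebyshev_conv <- function(X, lap, params) {
  X <- rbind(X)
  hp <- params_hp(params)
  K <- if (!is.null(hp)) hp$K else sum(grepl("^W_conv_", names(params)))
  if (nrow(X) != lap$s) {
    stop_rxngap("feature rows (", nrow(X), ") do not match clique size (", lap$s, ")",
                class = "rxngap_dimension_error")
  }
  if (ncol(X) != ncol(params$W_conv_1)) {
    stop_rxngap("feature width ", ncol(X), " does not match convolution input width ",
                ncol(params$W_conv_1), class = "rxngap_dimension_error")
  }
  Z <- chebyshev_terms(X, lap$L_tilde, K)
  pre <- Z[[1]] %*% t(params$W_conv_1)
  for (k in seq_len(K)[-1]) {
    pre <- pre + Z[[k]] %*% t(params[[paste0("W_conv_", k)]])
  }
  hard_tanh(pre)
}

#' Pooling functions over a clique
#'
#' `pool_frobenius()` is the Frobenius-norm (l2) pooling: per feature
#' dimension j it returns `sqrt(mean_i x_ij^2)` over the clique's nodes.
#' `pool_maxmin()` returns `max_i x_ij - min_i x_ij`. Both are symmetric in
#' the node order and nonnegative; for a single-node clique the Frobenius
#' pool is the absolute value of the row and the max-min pool is zero.
#'
#' @param X s x d convolved feature matrix of one clique.
#' @return numeric vector of length d.
#' @export
pool_frobenius <- function(X) {
  X <- rbind(X)
  sqrt(colMeans(X^2))
}

#' @rdname pool_frobenius
#' @export
pool_maxmin <- function(X) {
  X <- rbind(X)
  apply(X, 2, max) - apply(X, 2, min)
}

#' Score a reaction from its pooled features
#'
#' Concatenates the two pooled vectors in the order (max-min, Frobenius),
#' applies the affine scoring map and the logistic sigmoid. The result is a
#' confidence score strictly in (0, 1).
#'
#' @param y_maxmin,y_norm pooled vectors of length d_conv.
#' @param params model parameters (`w_score`, `b_score`).
#' @return scalar probability.
#' @export
score_reaction <- function(y_maxmin, y_norm, params) {
  v <- c(y_maxmin, y_norm)
  if (length(v) != length(params$w_score)) {
    stop_rxngap("pooled feature length ", length(v), " does not match scoring ",
                "weights length ", length(params$w_score),
                class = "rxngap_dimension_error")
  }
  stats::plogis(sum(params$w_score * v) + params$b_score)
}
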