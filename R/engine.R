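# Batched forward/backward pass over a set of reaction cliques.
#
# The per-clique operations (graph normalisation, Chebyshev convolution,
# pooling) are mathematically independent across cliques, so all cliques are
# stacked into one tall feature matrix: per-clique statistics become grouped
# rowsum() calls and the Chebyshev mixing becomes multiplication by a sparse
# block-diagonal Laplacian. The expensive dense products (features x weight
# matrices) then run once per layer instead of once per clique.

# Multiply each column j of M by v[j].
colmul <- function(M, v) M * rep(v, each = nrow(M))

# Block-diagonal scaled Laplacian over all cliques, assembled directly as a
# general sparse matrix. For a complete graph K_s the scaled Laplacian has
# the closed form: diagonal (s - 2)/s, off-diagonal -2/s (s >= 2); a
# singleton clique contributes a zero block.
batch_laplacian <- function(sizes, start, N) {
  ii <- vector("list", 0L)
  jj <- vector("list", 0L)
  xx <- vector("list", 0L)
  for (s in unique(sizes)) {
    if (s == 1L) next
    cl <- which(sizes == s)
    offs <- start[cl] - 1L
    loc_i <- rep(seq_len(s), times = s)
    loc_j <- rep(seq_len(s), each = s)
    vals <- ifelse(loc_i == loc_j, (s - 2) / s, -2 / s)
    nz <- vals != 0
    ii <- c(ii, list(rep(offs, each = sum(nz)) + loc_i[nz]))
    jj <- c(jj, list(rep(offs, each = sum(nz)) + loc_j[nz]))
    xx <- c(xx, list(rep(vals[nz], times = length(cl))))
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(N, N)
  )
}

# Stack cliques into a batch: concatenated node rows, group index, and the
# block-diagonal scaled Laplacian over all cliques.
clique_batch <- function(cliques) {
  sizes <- vapply(cliques, function(cl) length(cl$node_rows), integer(1))
  rows <- unlist(lapply(cliques, `[[`, "node_rows"), use.names = FALSE)
  start <- cumsum(c(1L, sizes))[seq_along(sizes)]
  list(
    ids = vapply(cliques, `[[`, character(1), "reaction_id"),
    labels = vapply(cliques, `[[`, character(1), "label"),
    sizes = sizes,
    rows = rows,
    grp = rep(seq_along(cliques), sizes),
    start = start,
    Lb = batch_laplacian(sizes, start, length(rows)),
    n_cliques = length(cliques)
  )
}

# Grouped max/min pooling with first-occurrence argmax/argmin masks (used for
# the backward pass; ties send the gradient to the first extremal row).
pool_maxmin_batch <- function(Xhat, batch) {
  C <- batch$n_cliques
  d <- ncol(Xhat)
  N <- nrow(Xhat)
  ymax <- matrix(0, C, d)
  ymin <- matrix(0, C, d)
  Wmax <- matrix(FALSE, N, d)
  Wmin <- matrix(FALSE, N, d)
  for (s in unique(batch$sizes)) {
    cl <- which(batch$sizes == s)
    ng <- length(cl)
    idx <- rep(batch$start[cl], each = s) + seq_len(s) - 1L
    a <- array(Xhat[idx, , drop = FALSE], dim = c(s, ng, d))
    mx <- matrix(a[1, , ], ng, d)
    mn <- mx
    if (s > 1) {
      for (i in 2:s) {
        ai <- matrix(a[i, , ], ng, d)
        mx <- pmax(mx, ai)
        mn <- pmin(mn, ai)
      }
    }
    ymax[cl, ] <- mx
    ymin[cl, ] <- mn
    taken_mx <- matrix(FALSE, ng, d)
    taken_mn <- matrix(FALSE, ng, d)
    for (i in seq_len(s)) {
      ai <- matrix(a[i, , ], ng, d)
      rows_i <- batch$start[cl] + i - 1L
      sel_mx <- (ai == mx) & !taken_mx
      sel_mn <- (ai == mn) & !taken_mn
      Wmax[rows_i, ] <- sel_mx
      Wmin[rows_i, ] <- sel_mn
      taken_mx <- taken_mx | sel_mx
      taken_mn <- taken_mn | sel_mn
    }
  }
  list(ymm = ymax - ymin, Wmax = Wmax, Wmin = Wmin)
}

# Full forward pass. In training mode the dropout mask is drawn from the
# ambient RNG stream (callers control it with a seed wrapper).
model_forward <- function(H, batch, params, training = FALSE) {
  hp <- params_hp(params)
  pre_enc <- sweep(H %*% t(params$W_enc), 2, params$b_enc, "+")
  Minit <- abs(pre_enc) < 1
  Xinit <- hard_tanh(pre_enc)

  X0 <- Xinit[batch$rows, , drop = FALSE]
  grp <- batch$grp
  sizes <- batch$sizes

  mu <- rowsum(X0, grp) / sizes
  sigma <- sqrt(pmax(rowsum(X0^2, grp) / sizes - mu^2, 0))
  sige <- pmax(sigma, GRAPH_NORM_EPS)
  u <- X0 - colmul(mu, params$alpha)[grp, , drop = FALSE]
  Xn <- colmul(u / sige[grp, , drop = FALSE], params$gamma)
  Xn <- sweep(Xn, 2, params$beta, "+")

  if (training && hp$p_drop > 0) {
    keep <- matrix(stats::runif(length(Xn)) >= hp$p_drop, nrow(Xn), ncol(Xn))
    co <- alpha_dropout_coefs(hp$p_drop)
    X1 <- Xn
    X1[!keep] <- ALPHA_DROP_SAT
    X1 <- co$a * X1 + co$b
  } else {
    keep <- NULL
    co <- NULL
    X1 <- Xn
  }

  Z <- vector("list", hp$K)
  Z[[1]] <- X1
  if (hp$K >= 2) Z[[2]] <- as.matrix(batch$Lb %*% X1)
  for (k in seq_len(hp$K)[-(1:2)]) {
    Z[[k]] <- 2 * as.matrix(batch$Lb %*% Z[[k - 1]]) - Z[[k - 2]]
  }
  pre_conv <- Z[[1]] %*% t(params$W_conv_1)
  for (k in seq_len(hp$K)[-1]) {
    pre_conv <- pre_conv + Z[[k]] %*% t(params[[paste0("W_conv_", k)]])
  }
  Mc <- abs(pre_conv) < 1
  Xhat <- hard_tanh(pre_conv)

  ynorm <- sqrt(rowsum(Xhat^2, grp) / sizes)
  mm <- pool_maxmin_batch(Xhat, batch)
  Y <- cbind(mm$ymm, ynorm)
  t_lin <- as.numeric(Y %*% params$w_score) + params$b_score
  scores <- stats::plogis(t_lin)

  list(
    scores = scores, batch = batch, H = H,
    Minit = Minit, X0 = X0, mu = mu, sigma = sigma, sige = sige, u = u,
    keep = keep, drop_a = if (is.null(co)) NULL else co$a,
    Z = Z, Mc = Mc, Xhat = Xhat,
    ynorm = ynorm, ymm = mm$ymm, Wmax = mm$Wmax, Wmin = mm$Wmin,
    Y = Y, t_lin = t_lin, training = training
  )
}

# Backward pass: dscore is dLoss/dScore per clique; returns parameter grads.
model_backward <- function(fw, dscore, params) {
  hp <- params_hp(params)
  batch <- fw$batch
  grp <- batch$grp
  sizes <- batch$sizes
  d <- hp$d_conv

  dt <- dscore * fw$scores * (1 - fw$scores)
  grads <- list(
    w_score = as.numeric(crossprod(fw$Y, dt)),
    b_score = sum(dt)
  )
  dY <- tcrossprod(dt, params$w_score)
  dymm <- dY[, seq_len(d), drop = FALSE]
  dynorm <- dY[, d + seq_len(d), drop = FALSE]

  # Frobenius pooling backward (0 where the pooled value is 0).
  ratio <- dynorm / (fw$ynorm * sizes)
  ratio[fw$ynorm == 0] <- 0
  dXhat <- fw$Xhat * ratio[grp, , drop = FALSE]
  dmm_rows <- dymm[grp, , drop = FALSE]
  dXhat <- dXhat + fw$Wmax * dmm_rows - fw$Wmin * dmm_rows

  dP <- dXhat * fw$Mc
  dX1 <- dP %*% params$W_conv_1
  grads$W_conv_1 <- crossprod(dP, fw$Z[[1]])
  for (k in seq_len(hp$K)[-1]) {
    Wk <- params[[paste0("W_conv_", k)]]
    grads[[paste0("W_conv_", k)]] <- crossprod(dP, fw$Z[[k]])
    dZk <- dP %*% Wk
    # propagate through Zk = T_(k-1)(Lb) X1; Lb is symmetric.
    Pprev <- dZk
    Pcur <- as.matrix(batch$Lb %*% dZk)
    if (k > 2) {
      for (j in 3:k) {
        Pnext <- 2 * as.matrix(batch$Lb %*% Pcur) - Pprev
        Pprev <- Pcur
        Pcur <- Pnext
      }
    }
    dX1 <- dX1 + Pcur
  }

  dXn <- if (!is.null(fw$keep)) dX1 * (fw$drop_a * fw$keep) else dX1

  # Graph-normalisation backward.
  sige_rows <- fw$sige[grp, , drop = FALSE]
  G1 <- colmul(dXn, params$gamma) / sige_rows
  sum_G1 <- rowsum(G1, grp)
  Su <- rowsum(dXn * fw$u, grp)
  dv <- -colmul(Su, params$gamma) / fw$sige^2
  active <- fw$sigma > GRAPH_NORM_EPS
  sum_dXn <- rowsum(dXn, grp)

  grads$gamma <- colSums(dXn * fw$u / sige_rows)
  grads$beta <- colSums(dXn)
  grads$alpha <- -params$gamma * colSums(fw$mu / fw$sige * sum_dXn)

  dX0 <- G1 - colmul(sum_G1 / sizes, params$alpha)[grp, , drop = FALSE]
  sig_term <- (dv * active) / (sizes * pmax(fw$sigma, GRAPH_NORM_EPS))
  dX0 <- dX0 + (fw$X0 - fw$mu[grp, , drop = FALSE]) * sig_term[grp, , drop = FALSE]

  dXinit <- matrix(0, nrow(fw$Minit), ncol(fw$Minit))
  rs <- rowsum(dX0, batch$rows)
  dXinit[as.integer(rownames(rs)), ] <- rs

  dEpre <- dXinit * fw$Minit
  grads$W_enc <- crossprod(dEpre, fw$H)
  grads$b_enc <- colSums(dEpre)
  grads[names(params)]
}

#' Score reactions with a forward pass
#'
#' Composes the whole architecture -- encoder features from the incidence
#' matrix, then per clique graph normalisation, alpha dropout (training mode
#' only), Chebyshev convolution, the two pooling functions and the sigmoid
#' scoring layer -- and returns one confidence score per clique, order
#' preserved. In evaluation mode the result is a pure function of
#' `(H, cliques, params)`.
#'
#' @param H incidence matrix over the training reactions (n x m).
#' @param cliques list of cliques from [decompose_reactions()].
#' @param params model parameters.
#' @param training logical; enables dropout.
#' @param seed integer seed for the dropout mask when `training = TRUE`.
#' @return data.frame with columns `reaction_id`, `label`, `score` (each
#'   score strictly in (0, 1)).
#' @export
forward_scores <- function(H, cliques, params, training = FALSE, seed = NULL) {
  if (length(cliques) == 0L) {
    return(data.frame(reaction_id = character(), label = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  batch <- clique_batch(cliques)
  fw <- if (training && !is.null(seed)) {
    withr::with_seed(seed, model_forward(H, batch, params, training = TRUE))
  } else {
    model_forward(H, batch, params, training = training)
  }
  data.frame(reaction_id = batch$ids, label = batch$labels, score = fw$scores,
             stringsAsFactors = FALSE)
}
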