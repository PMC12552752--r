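## Two-level graph attention autoencoder: parameters and forward pass.
##
## Level 1 (cross-modality): features of both modalities exchange
## information along the feature connectivity graph; attention combines a
## genomic-distance prior with a data-driven coefficient. Level 2
## (within-modality): spots exchange information along the spatial graph
## through one attention layer followed by an attention-free aggregation
## layer. Decoders are exact mirrors with tied (transposed) projections
## and reused attentions.

relu <- function(x) { x[x < 0] <- 0; x }

elu <- function(x) { neg <- x < 0; x[neg] <- exp(x[neg]) - 1; x }

elu_grad <- function(pre) { g <- pre; pos <- pre > 0; g[pos] <- 1; g[!pos] <- exp(pre[!pos]); g }

sigmoid <- function(x) stats::plogis(x)

# group sums of x by integer group id g, aligned to 1..n
grpsum <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize the model state
#'
#' Allocates all trainable parameters: the cross-attention vectors `v1`,
#' `v2` (length `N`, applied to feature profiles across spots), per
#' modality the projections of the two encoder layers (`d_k -> hidden[1]
#' -> hidden[2]`) with the attention vectors of the first layer, and the
#' contrastive projection maps `M1`, `M2`. Decoder parameters are never
#' allocated: decoding reuses the transposed encoder projections and the
#' encoder attentions. Projections are Glorot-uniform; attention vectors
#' start at zero so the first forward pass uses the prior-only attention.
#'
#' @param n_spots number of spots `N`.
#' @param d1,d2 feature counts of the two modalities.
#' @param hidden encoder layer widths, default `c(512, 30)` (the second
#'   entry is the latent width).
#' @param d_proj width of the contrastive projections (default: latent
#'   width).
#' @param temp CLIP temperature parameter (the similarity scale is
#'   `exp(temp)`).
#' @param seed RNG seed driving initialization.
#' @return an object of class `model_state` with a named `params` list.
#' @export
init_model <- function(n_spots, d1, d2, hidden = c(512, 30),
                       d_proj = hidden[2], temp = 1, seed = 0) {
  stopifnot(length(hidden) == 2, n_spots >= 1, d1 >= 1, d2 >= 1)
  set.seed(seed)
  params <- list(
    v1 = numeric(n_spots), v2 = numeric(n_spots),
    W1_1 = glorot(d1, hidden[1]), vself_1 = numeric(hidden[1]),
    vnei_1 = numeric(hidden[1]), W2_1 = glorot(hidden[1], hidden[2]),
    W1_2 = glorot(d2, hidden[1]), vself_2 = numeric(hidden[1]),
    vnei_2 = numeric(hidden[1]), W2_2 = glorot(hidden[1], hidden[2]),
    M1 = glorot(hidden[2], d_proj), M2 = glorot(hidden[2], d_proj))
  structure(list(params = params, n_spots = n_spots, d1 = d1, d2 = d2,
                 hidden = hidden, d_proj = d_proj, temp = temp, seed = seed,
                 trained = FALSE),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<model_state> N=%d, d=(%d,%d), hidden=(%d,%d), d_proj=%d, %s, %d parameters\n",
              x$n_spots, x$d1, x$d2, x$hidden[1], x$hidden[2], x$d_proj,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

#' Cross-modality attention
#'
#' For every directed pair (target `f`, source `g`) along the feature
#' graph, including self-pairs, computes the raw coefficient
#' `e_fg = sigmoid(v1 . X_(f) + v2 . X_(g))` on the raw feature profiles
#' (no learned projection) and normalizes `prior * exp(e)` over each
#' target's neighborhood including its self-loop.
#'
#' @param X merged spots-by-features matrix (`N x (p+q)`).
#' @param graph a [build_feature_graph()] object aligned with the columns
#'   of `X`.
#' @param v1,v2 attention parameter vectors of length `N`.
#' @return list with per-directed-edge values `e` (coefficients) and
#'   `att` (normalized attentions), the edge arrays `ti`/`si`, and the
#'   sparse attention matrix `C` (`C[f, g]` = weight of source `g` for
#'   target `f`; rows sum to 1).
#' @export
cross_attention <- function(X, graph, v1, v2) {
  m <- length(graph$nodes)
  if (ncol(X) != m) stop("graph nodes do not align with the columns of X")
  if (!all(seq_len(m) %in% graph$ti[graph$ti == graph$si]))
    stop("node without a self-loop prior in the feature graph")
  a <- drop(crossprod(X, v1))
  b <- drop(crossprod(X, v2))
  e <- sigmoid(a[graph$ti] + b[graph$si])
  u <- graph$prior * exp(e)
  r <- grpsum(u, graph$ti, m)
  att <- u / r[graph$ti]
  C <- Matrix::sparseMatrix(i = graph$ti, j = graph$si, x = att, dims = c(m, m))
  list(e = e, att = att, ti = graph$ti, si = graph$si, C = C)
}

#' Cross-modality encoding
#'
#' Integrates every feature profile as the attention-weighted combination
#' of its neighborhood (self included) followed by ReLU.
#'
#' @param X merged `N x (p+q)` matrix.
#' @param att output of [cross_attention()].
#' @return the integrated matrix `Xbar` (same shape).
#' @export
cross_encode <- function(X, att) {
  relu(as.matrix(Matrix::tcrossprod(X, att$C)))
}

#' Cross-modality decoding (tied attentions, ELU)
#'
#' @param Xtld merged decoded matrix (`N x (p+q)`).
#' @param att the *encoder* attention object (reused, never refit).
#' @return reconstructed matrix `Xhat`.
#' @export
cross_decode <- function(Xtld, att) {
  elu(as.matrix(Matrix::tcrossprod(Xtld, att$C)))
}

# row-stochastic spatial attention matrix for one modality/layer
within_attention <- function(Hpre, sg, vself, vnei) {
  n <- nrow(Hpre)
  s <- drop(Hpre %*% vself)
  tt <- drop(Hpre %*% vnei)
  q <- sigmoid(s[sg$ii] + tt[sg$jj])
  w <- exp(q)
  r <- grpsum(w, sg$ii, n)
  attw <- w / r[sg$ii]
  P <- Matrix::sparseMatrix(i = sg$ii, j = sg$jj, x = attw, dims = c(n, n))
  list(q = q, att = attw, P = P)
}

#' Within-modality encoder (one attention layer + one aggregation layer)
#'
#' Layer 1 projects to the hidden width, computes spot-pair attention
#' coefficients `sigmoid(vself . (W1 x_i) + vnei . (W1 x_j))`, softmax-
#' normalizes them over each spot's spatial neighborhood (self included)
#' and aggregates with ELU. Layer 2 is the attention-free unweighted
#' neighbor sum through the second projection, again with ELU.
#'
#' @param Xbar_k integrated matrix for one modality (`N x d_k`).
#' @param sg a [build_spatial_graph()] object.
#' @param W1,vself,vnei,W2 the modality's encoder parameters.
#' @return list with the latent `Z` (`N x hidden[2]`), the attention
#'   object of layer 1, and the intermediates needed for decoding and
#'   backpropagation.
#' @export
within_encode <- function(Xbar_k, sg, W1, vself, vnei, W2) {
  if (nrow(Xbar_k) != length(sg$spot_ids)) stop("spot count mismatch")
  Hpre <- Xbar_k %*% W1
  at <- within_attention(Hpre, sg, vself, vnei)
  H1pre <- as.matrix(at$P %*% Hpre)
  H1 <- elu(H1pre)
  A1 <- as.matrix(sg$S %*% H1)
  Zpre <- A1 %*% W2
  Z <- elu(Zpre)
  list(Z = Z, att = at, Hpre = Hpre, H1pre = H1pre, H1 = H1, A1 = A1,
       Zpre = Zpre)
}

#' Within-modality decoder (tied projections and attentions)
#'
#' Mirrors the encoder with transposed projections: the inner layer reuses
#' the encoder's layer-1 attention, the outermost layer is attention-free.
#'
#' @param Z latent matrix (`N x hidden[2]`).
#' @param sg spatial graph.
#' @param enc the [within_encode()] output whose attentions are reused.
#' @param W1,W2 the *encoder* projections (the decoder applies their
#'   transposes; no decoder parameters exist).
#' @return list with `D0` (decoded `N x d_k`) and intermediates.
#' @export
within_decode <- function(Z, sg, enc, W1, W2) {
  D1pre <- as.matrix(enc$att$P %*% (Z %*% t(W2)))
  D1 <- elu(D1pre)
  D0pre <- as.matrix(sg$S %*% (D1 %*% t(W1)))
  D0 <- elu(D0pre)
  list(D0 = D0, D1pre = D1pre, D1 = D1, D0pre = D0pre)
}

#' Contrastive projections of the two latents
#'
#' @param Z1,Z2 latent matrices (`N x hidden[2]`).
#' @param M1,M2 projection matrices.
#' @return list with `f = Z1 M1` and `g = Z2 M2`, the final per-spot
#'   embeddings of the two modalities.
#' @export
project_clip <- function(Z1, Z2, M1, M2) {
  list(f = Z1 %*% M1, g = Z2 %*% M2)
}

#' Full forward pass
#'
#' Composes cross-modality encoding, within-modality encoding/decoding per
#' modality, cross-modality decoding, and the contrastive projections.
#' Deterministic given the state.
#'
#' @param X1,X2 preprocessed matrices (`N x p`, `N x q`), or a
#'   [spatial_multiome()] dataset via [forward_dataset()].
#' @param fg feature graph over the concatenated features.
#' @param sg spatial graph over the spots.
#' @param state a [init_model()] state.
#' @return list of class `forward_outputs` with the integrated matrix,
#'   latents, reconstructions, projected embeddings and all attention
#'   objects.
#' @export
model_forward <- function(X1, X2, fg, sg, state) {
  p <- ncol(X1); q <- ncol(X2)
  stopifnot(p == state$d1, q == state$d2, nrow(X1) == state$n_spots)
  X <- cbind(X1, X2)
  pr <- state$params
  catt <- cross_attention(X, fg, pr$v1, pr$v2)
  Xbar_pre <- as.matrix(Matrix::tcrossprod(X, catt$C))
  Xbar <- relu(Xbar_pre)
  enc1 <- within_encode(Xbar[, seq_len(p), drop = FALSE], sg,
                        pr$W1_1, pr$vself_1, pr$vnei_1, pr$W2_1)
  enc2 <- within_encode(Xbar[, p + seq_len(q), drop = FALSE], sg,
                        pr$W1_2, pr$vself_2, pr$vnei_2, pr$W2_2)
  dec1 <- within_decode(enc1$Z, sg, enc1, pr$W1_1, pr$W2_1)
  dec2 <- within_decode(enc2$Z, sg, enc2, pr$W1_2, pr$W2_2)
  Xtld <- cbind(dec1$D0, dec2$D0)
  Xhat_pre <- as.matrix(Matrix::tcrossprod(Xtld, catt$C))
  Xhat <- elu(Xhat_pre)
  proj <- project_clip(enc1$Z, enc2$Z, pr$M1, pr$M2)
  structure(list(X = X, p = p, q = q, catt = catt, Xbar_pre = Xbar_pre,
                 Xbar = Xbar, enc = list(enc1, enc2), dec = list(dec1, dec2),
                 Xtld = Xtld, Xhat_pre = Xhat_pre,
                 Xhat1 = Xhat[, seq_len(p), drop = FALSE],
                 Xhat2 = Xhat[, p + seq_len(q), drop = FALSE],
                 Z1 = enc1$Z, Z2 = enc2$Z, f = proj$f, g = proj$g),
            class = "forward_outputs")
}

#' Forward pass on a preprocessed dataset
#' @param dataset preprocessed [spatial_multiome()].
#' @inheritParams model_forward
#' @return see [model_forward()].
#' @export
forward_dataset <- function(dataset, fg, sg, state) {
  model_forward(as.matrix(dataset$modality1$values),
                as.matrix(dataset$modality2$values), fg, sg, state)
}
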