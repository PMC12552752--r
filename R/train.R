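#' Training configuration
#'
#' Defaults: Adam with initial learning rate 1e-4 and weight decay 1e-4,
#' 1000 full-batch iterations, CLIP temperature parameter 1 (similarity
#' scale `exp(1)`), and unit weights on the two loss components.
#'
#' @param lr learning rate.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param iterations number of optimization steps (>= 1).
#' @param temp CLIP temperature parameter.
#' @param recon_w,clip_w weights of the reconstruction and contrastive
#'   loss components.
#' @param hidden encoder widths (see [init_model()]).
#' @param d_proj contrastive projection width.
#' @param seed RNG seed for parameter initialization.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, iterations = 1000,
                         temp = 1, recon_w = 1, clip_w = 1,
                         hidden = c(512, 30), d_proj = hidden[2], seed = 0) {
  if (lr <= 0) stop("lr must be positive")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 iterations = as.integer(iterations), temp = temp,
                 recon_w = recon_w, clip_w = clip_w, hidden = hidden,
                 d_proj = d_proj, seed = seed),
            class = "train_config")
}

#' Reconstruction loss: sum of per-spot Euclidean norms
#'
#' `sum_i ||X1_i - Xhat1_i||_2 + sum_i ||X2_i - Xhat2_i||_2` (norms, not
#' squared norms).
#'
#' @param X1,X2 observed matrices.
#' @param Xhat1,Xhat2 reconstructions of matching shape.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(X1, X2, Xhat1, Xhat2) {
  if (!all(dim(X1) == dim(Xhat1)) || !all(dim(X2) == dim(Xhat2)))
    stop("shape mismatch between data and reconstruction")
  sum(sqrt(rowSums((X1 - Xhat1)^2))) + sum(sqrt(rowSums((X2 - Xhat2)^2)))
}

row_normalize <- function(M, what) {
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0))
    stop("zero-norm ", what, " embedding for spot(s) ",
         paste(utils::head(which(nrm == 0), 5), collapse = ", "))
  list(Mn = M / nrm, nrm = nrm)
}

row_softmax <- function(M) {
  E <- exp(M - apply(M, 1, max))
  E / rowSums(E)
}

#' Symmetric contrastive (CLIP) loss
#'
#' InfoNCE over cosine similarities scaled by `exp(temp)`, averaged over
#' both matching directions; the matched pair of every spot is the
#' diagonal.
#'
#' @param f,g embedding matrices (`N x d`), rows paired by spot.
#' @param temp temperature parameter.
#' @return scalar loss.
#' @export
clip_loss <- function(f, g, temp = 1) {
  if (!all(dim(f) == dim(g))) stop("shape mismatch between f and g")
  n <- nrow(f)
  Fn <- row_normalize(f, "f")$Mn
  Gn <- row_normalize(g, "g")$Mn
  Sc <- exp(temp) * Matrix::tcrossprod(Fn, Gn)
  Sc <- as.matrix(Sc)
  Pr <- row_softmax(Sc)
  Pc <- t(row_softmax(t(Sc)))
  -(sum(log(diag(Pr))) + sum(log(diag(Pc)))) / (2 * n)
}

## Reverse-mode gradients of recon_w * reconstruction + clip_w * CLIP
## with respect to every entry of state$params, matching model_forward().
model_backward <- function(fwd, state, sg, fg, recon_w = 1, clip_w = 1) {
  pr <- state$params
  p <- fwd$p; q <- fwd$q
  n <- state$n_spots
  m <- p + q
  X1 <- fwd$X[, seq_len(p), drop = FALSE]
  X2 <- fwd$X[, p + seq_len(q), drop = FALSE]

  ## --- loss heads ---
  # reconstruction: d/dXhat of sum of row norms
  grad_head <- function(X, Xhat) {
    R <- Xhat - X
    nrm <- sqrt(rowSums(R^2))
    scl <- ifelse(nrm > 0, recon_w / nrm, 0)
    R * scl
  }
  dXhat <- cbind(grad_head(X1, fwd$Xhat1), grad_head(X2, fwd$Xhat2))

  # CLIP head
  dF <- matrix(0, n, state$d_proj); dG <- dF
  if (clip_w != 0) {
    nf <- row_normalize(fwd$f, "f"); ng <- row_normalize(fwd$g, "g")
    Fn <- nf$Mn; Gn <- ng$Mn
    cexp <- exp(state$temp)
    Sc <- cexp * tcrossprod(Fn, Gn)
    Pr <- row_softmax(Sc)
    Pc <- t(row_softmax(t(Sc)))
    dSc <- clip_w / (2 * n) * (Pr + Pc)
    diag(dSc) <- diag(dSc) - clip_w / n
    dM <- cexp * dSc
    dFn <- dM %*% Gn
    dGn <- t(dM) %*% Fn
    dF <- (dFn - rowSums(dFn * Fn) * Fn) / nf$nrm
    dG <- (dGn - rowSums(dGn * Gn) * Gn) / ng$nrm
  }

  g <- stats::setNames(lapply(pr, function(x) x * 0), names(pr))

  ## --- cross decoder ---
  dXhat_pre <- dXhat * elu_grad(fwd$Xhat_pre)
  C <- fwd$catt$C
  dXtld <- as.matrix(dXhat_pre %*% C)
  CP <- crossprod(dXhat_pre, fwd$Xtld)      # m x m dense
  dC <- CP[cbind(fwd$catt$ti, fwd$catt$si)]

  dXbar <- matrix(0, n, m)

  ## --- per-modality within-modality autoencoder ---
  for (k in 1:2) {
    cols <- if (k == 1) seq_len(p) else p + seq_len(q)
    W1 <- pr[[paste0("W1_", k)]]; W2 <- pr[[paste0("W2_", k)]]
    vself <- pr[[paste0("vself_", k)]]; vnei <- pr[[paste0("vnei_", k)]]
    enc <- fwd$enc[[k]]; dec <- fwd$dec[[k]]
    P <- enc$att$P
    Z <- enc$Z

    dD0 <- dXtld[, cols, drop = FALSE]
    dD0pre <- dD0 * elu_grad(dec$D0pre)
    SD0 <- as.matrix(sg$S %*% dD0pre)
    dD1 <- SD0 %*% W1
    dW1 <- crossprod(dD0pre, as.matrix(sg$S %*% dec$D1))

    dD1pre <- dD1 * elu_grad(dec$D1pre)
    ZW2t <- Z %*% t(W2)
    dP_edge <- rowSums(dD1pre[sg$ii, , drop = FALSE] *
                       ZW2t[sg$jj, , drop = FALSE])
    dZ <- as.matrix(Matrix::crossprod(P, dD1pre)) %*% W2
    dW2 <- crossprod(dD1pre, as.matrix(P %*% Z))

    # CLIP projection head feeds the latent too
    dFk <- if (k == 1) dF else dG
    Mk <- if (k == 1) pr$M1 else pr$M2
    dZ <- dZ + dFk %*% t(Mk)
    g[[if (k == 1) "M1" else "M2"]] <- crossprod(Z, dFk)

    dZpre <- dZ * elu_grad(enc$Zpre)
    dH1 <- as.matrix(sg$S %*% (dZpre %*% t(W2)))
    dW2 <- dW2 + crossprod(enc$A1, dZpre)

    dH1pre <- dH1 * elu_grad(enc$H1pre)
    dHpre <- as.matrix(Matrix::crossprod(P, dH1pre))
    dP_edge <- dP_edge + rowSums(dH1pre[sg$ii, , drop = FALSE] *
                                 enc$Hpre[sg$jj, , drop = FALSE])

    # softmax + sigmoid backward on spatial edges
    attw <- enc$att$att
    dots <- grpsum(attw * dP_edge, sg$ii, n)
    dq <- attw * (dP_edge - dots[sg$ii])
    qv <- enc$att$q
    dq <- dq * qv * (1 - qv)
    ds <- grpsum(dq, sg$ii, n)
    dt <- grpsum(dq, sg$jj, n)
    dHpre <- dHpre + outer(ds, vself) + outer(dt, vnei)
    g[[paste0("vself_", k)]] <- drop(crossprod(enc$Hpre, ds))
    g[[paste0("vnei_", k)]] <- drop(crossprod(enc$Hpre, dt))

    Xbar_k <- fwd$Xbar[, cols, drop = FALSE]
    dXbar[, cols] <- dHpre %*% t(W1)
    dW1 <- dW1 + crossprod(Xbar_k, dHpre)

    g[[paste0("W1_", k)]] <- dW1
    g[[paste0("W2_", k)]] <- dW2
  }

  ## --- cross encoder ---
  dXbar_pre <- dXbar * (fwd$Xbar_pre > 0)
  CP2 <- crossprod(dXbar_pre, fwd$X)
  dC <- dC + CP2[cbind(fwd$catt$ti, fwd$catt$si)]

  # prior-weighted softmax + sigmoid backward on feature edges
  attc <- fwd$catt$att
  ti <- fwd$catt$ti; si <- fwd$catt$si
  dots <- grpsum(attc * dC, ti, m)
  dE <- attc * (dC - dots[ti])
  ev <- fwd$catt$e
  dz <- dE * ev * (1 - ev)
  da <- grpsum(dz, ti, m)
  db <- grpsum(dz, si, m)
  g$v1 <- drop(fwd$X %*% da)
  g$v2 <- drop(fwd$X %*% db)

  g
}

total_loss <- function(fwd, state, recon_w, clip_w) {
  p <- fwd$p; q <- fwd$q
  lr_ <- reconstruction_loss(fwd$X[, seq_len(p), drop = FALSE],
                             fwd$X[, p + seq_len(q), drop = FALSE],
                             fwd$Xhat1, fwd$Xhat2)
  lc <- if (clip_w != 0) clip_loss(fwd$f, fwd$g, state$temp) else 0
  c(total = recon_w * lr_ + clip_w * lc, recon = lr_, clip = lc)
}

#' Train the two-level graph attention autoencoder
#'
#' Full-batch Adam minimizing
#' `recon_w * reconstruction + clip_w * CLIP`. Deterministic given
#' `cfg$seed`.
#'
#' @param dataset preprocessed [spatial_multiome()].
#' @param fg feature graph over the concatenated features of `dataset`.
#' @param sg spatial graph over its spots.
#' @param cfg a [train_config()].
#' @param verbose print the loss every 100 iterations.
#' @return list with the trained `state` (class `model_state`), the final
#'   forward `outputs`, and the per-iteration loss `trace` (data.frame
#'   `iteration`, `total`, `recon`, `clip`).
#' @export
train_model <- function(dataset, fg, sg, cfg = train_config(), verbose = FALSE) {
  X1 <- as.matrix(dataset$modality1$values)
  X2 <- as.matrix(dataset$modality2$values)
  if (!identical(c(colnames(X1), colnames(X2)), fg$nodes))
    stop("feature graph nodes must equal the concatenated dataset features")
  state <- init_model(nrow(X1), ncol(X1), ncol(X2), hidden = cfg$hidden,
                      d_proj = cfg$d_proj, temp = cfg$temp, seed = cfg$seed)
  opt <- adam_init(state$params)
  trace <- matrix(NA_real_, cfg$iterations, 3,
                  dimnames = list(NULL, c("total", "recon", "clip")))
  for (it in seq_len(cfg$iterations)) {
    fwd <- model_forward(X1, X2, fg, sg, state)
    ls <- total_loss(fwd, state, cfg$recon_w, cfg$clip_w)
    if (!is.finite(ls["total"]))
      stop("non-finite loss at iteration ", it)
    trace[it, ] <- ls
    grads <- model_backward(fwd, state, sg, fg, cfg$recon_w, cfg$clip_w)
    upd <- adam_step(opt, state$params, grads, cfg$lr, cfg$weight_decay)
    state$params <- upd$params
    opt <- upd$opt
    if (verbose && (it == 1 || it %% 100 == 0))
      message(sprintf("iter %4d  total %.4f  recon %.4f  clip %.4f",
                      it, ls["total"], ls["recon"], ls["clip"]))
  }
  state$trained <- TRUE
  outputs <- model_forward(X1, X2, fg, sg, state)
  list(state = state,
       outputs = outputs,
       trace = data.frame(iteration = seq_len(cfg$iterations), trace),
       config = cfg)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gr
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}
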