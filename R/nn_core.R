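# Shared pieces of the compact CNN engine: parameter initialisation, Adam,
# batch normalisation (forward/backward), and the additive attention gate.
# Convolution/pooling kernels live in src/nn_ops.cpp; all parameters are kept
# in flat named lists so the optimiser is generic.

he_init <- function(cout, fan_in, ncol) {
  matrix(rnorm(cout * ncol, 0, sqrt(2 / fan_in)), cout, ncol)
}

xavier_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, 0, sqrt(1 / ncol)), nrow, ncol)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- batch normalisation over a mini-batch of (H, W, C) arrays -------------

bn2d_fw <- function(zs, gamma, beta, rm, rv, training,
                    momentum = 0.1, eps = 1e-5) {
  d <- dim(zs[[1]]); n <- d[1] * d[2]; C <- d[3]; B <- length(zs)
  N <- B * n
  if (training) {
    s1 <- numeric(C); s2 <- numeric(C)
    for (z in zs) {
      zm <- matrix(z, n, C)
      s1 <- s1 + .colSums(zm, n, C)
      s2 <- s2 + .colSums(zm * zm, n, C)
    }
    mu <- s1 / N
    va <- pmax(s2 / N - mu^2, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- vector("list", B); ys <- vector("list", B)
  mu_r <- rep(mu, each = n); is_r <- rep(invstd, each = n)
  ga_r <- rep(gamma, each = n); be_r <- rep(beta, each = n)
  for (b in seq_len(B)) {
    xh <- (matrix(zs[[b]], n, C) - mu_r) * is_r
    xhat[[b]] <- xh
    ys[[b]] <- array(xh * ga_r + be_r, d)
  }
  list(ys = ys, xhat = xhat, invstd = invstd, rm = rm, rv = rv, N = N, dim = d)
}

bn2d_bw <- function(gys, cache, gamma) {
  d <- cache$dim; n <- d[1] * d[2]; C <- d[3]; B <- length(gys)
  N <- cache$N
  dgamma <- numeric(C); dbeta <- numeric(C)
  gm <- vector("list", B)
  for (b in seq_len(B)) {
    g <- matrix(gys[[b]], n, C)
    gm[[b]] <- g
    dgamma <- dgamma + .colSums(g * cache$xhat[[b]], n, C)
    dbeta <- dbeta + .colSums(g, n, C)
  }
  coef <- rep(gamma * cache$invstd, each = n)
  mdb <- rep(dbeta / N, each = n)
  mdg <- rep(dgamma / N, each = n)
  gxs <- vector("list", B)
  for (b in seq_len(B))
    gxs[[b]] <- array(coef * (gm[[b]] - mdb - cache$xhat[[b]] * mdg), d)
  list(gxs = gxs, dgamma = dgamma, dbeta = dbeta)
}

# ---- additive attention gate ----------------------------------------------

#' Additive attention gate
#'
#' The gating block used on Attention U-Net skip connections: 1x1 linear maps
#' of the skip tensor `x` and the gating tensor `g` are summed, passed through
#' ReLU, projected to one channel, and squashed by a sigmoid to per-pixel
#' attention coefficients that multiply `x`.
#'
#' @param x Skip feature array (H, W, Cx).
#' @param g Gating feature array (H, W, Cx), same shape.
#' @param wx,wg Weight matrices (Cint x Cx) for skip and gating maps.
#' @param bg Bias vector (Cint).
#' @param psi Projection matrix (1 x Cint).
#' @param bpsi Scalar projection bias.
#' @return List with `gated` (x scaled by the coefficients) and `alpha`
#'   (H x W matrix of attention coefficients in (0, 1)).
#' @export
attention_gate <- function(x, g, wx, wg, bg, psi, bpsi) {
  f <- att_fw(x, g, wx, wg, bg, psi, bpsi)
  list(gated = f$y, alpha = matrix(f$alpha, dim(x)[1], dim(x)[2]))
}

att_fw <- function(x, g, wx, wg, bg, psi, bpsi) {
  d <- dim(x); n <- d[1] * d[2]; Cx <- d[3]
  xm <- matrix(x, n, Cx); gm <- matrix(g, n, Cx)
  q <- xm %*% t(wx) + gm %*% t(wg) + rep(bg, each = n)
  r <- pmax(q, 0)
  s <- drop(r %*% t(psi)) + bpsi
  alpha <- 1 / (1 + exp(-s))
  y <- array(xm * alpha, d)
  list(y = y, alpha = alpha, q = q, r = r, xm = xm, gm = gm, dim = d)
}

att_bw <- function(gy, cache, wx, wg, psi) {
  d <- cache$dim; n <- d[1] * d[2]; Cx <- d[3]
  gym <- matrix(gy, n, Cx)
  galpha <- .rowSums(gym * cache$xm, n, Cx)
  gxm <- gym * cache$alpha
  gs <- galpha * cache$alpha * (1 - cache$alpha)
  gpsi <- matrix(gs, 1, n) %*% cache$r
  gbpsi <- sum(gs)
  gq <- (gs %o% drop(psi)) * (cache$q > 0)
  gwx <- t(gq) %*% cache$xm
  gwg <- t(gq) %*% cache$gm
  gbg <- .colSums(gq, n, ncol(gq))
  gxm <- gxm + gq %*% wx
  ggm <- gq %*% wg
  list(gx = array(gxm, d), gg = array(ggm, d),
       gwx = gwx, gwg = gwg, gbg = gbg, gpsi = gpsi, gbpsi = gbpsi)
}

# stable binary cross-entropy with logits; returns loss and dL/dz (mean over
# all pixels and samples)
bce_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, dz = (1 / (1 + exp(-z)) - y) / length(z))
}

# channel concatenation of two (H, W, C) arrays
cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

deep_copy <- function(x) lapply(x, function(p) p + 0)
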