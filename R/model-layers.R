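## Neural-network primitives for the two-branch affinity regressor.
## Everything is plain R matrix arithmetic: activations for the drug branch
## are (batch, position, channel) arrays, convolutions go through im2col so
## that each layer is a single matrix product, and gradients are derived
## layer by layer (no framework). Channels-last, valid padding, stride 1.

.relu <- function(z) z * (z > 0)

## (B, L, D) array -> (B*Lout, f*D) matrix of unrolled windows
.im2col <- function(A, f) {
  d <- dim(A); B <- d[1]; L <- d[2]; D <- d[3]
  Lout <- L - f + 1L
  out <- matrix(0, B * Lout, f * D)
  for (k in seq_len(f))
    out[, ((k - 1L) * D + 1L):(k * D)] <-
      matrix(A[, k:(k + Lout - 1L), , drop = FALSE], B * Lout, D)
  out
}

## adjoint of .im2col: scatter window gradients back onto positions
.col2im <- function(dX, f, B, L, D) {
  Lout <- L - f + 1L
  dA <- array(0, c(B, L, D))
  for (k in seq_len(f)) {
    sl <- array(dX[, ((k - 1L) * D + 1L):(k * D)], c(B, Lout, D))
    dA[, k:(k + Lout - 1L), ] <- dA[, k:(k + Lout - 1L), , drop = FALSE] + sl
  }
  dA
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

## ---- parameter initialization -------------------------------------------

.initWeights <- function(cfg, nPanel, vocabSize, maxLen) {
  set.seed(cfg@seed)
  F1 <- cfg@nFilters; f <- cfg@filterLength; D <- cfg@embeddingDim
  ps <- cfg@proteinFcSizes; gs <- cfg@predictorFcSizes
  w <- list()
  ## protein branch: 3 FC layers on the panel-similarity vector
  dims <- c(nPanel, ps)
  for (i in 1:3) {
    w[[paste0("pfcW", i)]] <- .glorot(dims[i], dims[i + 1])
    w[[paste0("pfcB", i)]] <- numeric(dims[i + 1])
  }
  if (cfg@drugBranch == "cnn_sep") {
    V <- vocabSize + 2L                    # pad row 0 and unknown row K+1
    w$emb <- matrix(stats::runif(V * D, -0.05, 0.05), V, D)
    w$conv1W <- .glorot(f * D, F1);  w$conv1B <- numeric(F1)
    w$conv2W <- .glorot(f * F1, F1); w$conv2B <- numeric(F1)
    w$sepDwW <- .glorot(f, F1)             # depthwise: one length-f kernel
    w$sepPwW <- .glorot(F1, F1)            # pointwise: 1x1 channel mixing
    w$sepB <- numeric(F1)
    drugOut <- F1
  } else {
    ## fc baseline: 3 FC layers on the normalized code vector, no
    ## convolutional (or embedding) parameters at all
    dims <- c(maxLen, F1, F1, F1)
    for (i in 1:3) {
      w[[paste0("dfcW", i)]] <- .glorot(dims[i], dims[i + 1])
      w[[paste0("dfcB", i)]] <- numeric(dims[i + 1])
    }
    drugOut <- F1
  }
  ## predictor: 3 FC layers on the concatenated representation + output
  dims <- c(ps[3] + drugOut, gs)
  for (i in 1:3) {
    w[[paste0("ffcW", i)]] <- .glorot(dims[i], dims[i + 1])
    w[[paste0("ffcB", i)]] <- numeric(dims[i + 1])
  }
  w$outW <- .glorot(gs[3], 1L)
  w$outB <- numeric(1)
  w
}

## ---- forward pass --------------------------------------------------------

## P: (B, nPanel) protein encodings; Dc: (B, maxLen) integer codes.
## Returns list(pred=, cache=) with everything backward needs. Dropout
## masks are drawn from the current RNG stream iff training.
.netForward <- function(w, cfg, P, Dc, training = FALSE, codeScale = 1) {
  B <- nrow(P)
  cache <- list(P = P, Dc = Dc, training = training)
  ## protein branch
  a <- P
  for (i in 1:3) {
    z <- a %*% w[[paste0("pfcW", i)]] +
      rep(w[[paste0("pfcB", i)]], each = B)
    h <- .relu(z)
    cache[[paste0("pfcA", i)]] <- a; cache[[paste0("pfcZ", i)]] <- z
    a <- h
  }
  pOut <- a
  ## drug branch
  if (cfg@drugBranch == "cnn_sep") {
    f <- cfg@filterLength; D <- cfg@embeddingDim; F1 <- cfg@nFilters
    L <- ncol(Dc)
    emb <- array(w$emb[as.vector(Dc) + 1L, ], c(B, L, D))
    x1 <- .im2col(emb, f); z1 <- x1 %*% w$conv1W + rep(w$conv1B, each = nrow(x1))
    h1 <- array(.relu(z1), c(B, L - f + 1L, F1))
    x2 <- .im2col(h1, f); z2 <- x2 %*% w$conv2W + rep(w$conv2B, each = nrow(x2))
    L2 <- dim(h1)[2] - f + 1L
    h2 <- array(.relu(z2), c(B, L2, F1))
    ## separable layer: depthwise over positions within each channel...
    L3 <- L2 - f + 1L
    N3 <- B * L3
    dw <- matrix(0, N3, F1)
    for (k in seq_len(f)) {
      sl <- matrix(h2[, k:(k + L3 - 1L), , drop = FALSE], N3, F1)
      dw <- dw + sweep(sl, 2L, w$sepDwW[k, ], "*")
    }
    ## ...then pointwise channel mixing, one rectifier after the pair
    z3 <- dw %*% w$sepPwW + rep(w$sepB, each = N3)
    h3 <- array(.relu(z3), c(B, L3, F1))
    ## global max-pool over positions
    pooled <- matrix(0, B, F1); amax <- matrix(0L, B, F1)
    for (c in seq_len(F1)) {
      m <- matrix(h3[, , c], B, L3)
      idx <- max.col(m, ties.method = "first")
      amax[, c] <- idx
      pooled[, c] <- m[cbind(seq_len(B), idx)]
    }
    cache <- c(cache, list(emb = emb, x1 = x1, z1 = z1, h1 = h1,
                           x2 = x2, z2 = z2, h2 = h2, dw = dw, z3 = z3,
                           h3dim = dim(h3), amax = amax, L3 = L3))
    dOut <- pooled
  } else {
    a <- Dc / codeScale   # fixed scale: codes into [0, 1], batch-independent
    for (i in 1:3) {
      z <- a %*% w[[paste0("dfcW", i)]] +
        rep(w[[paste0("dfcB", i)]], each = B)
      h <- .relu(z)
      cache[[paste0("dfcA", i)]] <- a; cache[[paste0("dfcZ", i)]] <- z
      a <- h
    }
    dOut <- a
  }
  ## concatenate and predict
  cat0 <- cbind(pOut, dOut)
  cache$splitAt <- ncol(pOut)
  a <- cat0
  for (i in 1:3) {
    z <- a %*% w[[paste0("ffcW", i)]] +
      rep(w[[paste0("ffcB", i)]], each = B)
    h <- .relu(z)
    if (training && cfg@dropout > 0 && i <= 2) {
      mask <- (stats::runif(length(h)) >= cfg@dropout) / (1 - cfg@dropout)
      dim(mask) <- dim(h)
      h <- h * mask
      cache[[paste0("ffcM", i)]] <- mask
    }
    cache[[paste0("ffcA", i)]] <- a; cache[[paste0("ffcZ", i)]] <- z
    a <- h
  }
  pred <- drop(a %*% w$outW + w$outB)
  cache$ffcA4 <- a
  list(pred = pred, cache = cache)
}

## ---- backward pass -------------------------------------------------------

## dPred: gradient of the loss w.r.t. predictions (length B).
.netBackward <- function(w, cfg, cache, dPred) {
  g <- list()
  B <- length(dPred)
  dPred <- matrix(dPred, B, 1)
  g$outW <- crossprod(cache$ffcA4, dPred)
  g$outB <- sum(dPred)
  dA <- dPred %*% t(w$outW)
  for (i in 3:1) {
    mask <- cache[[paste0("ffcM", i)]]
    if (!is.null(mask)) dA <- dA * mask
    dZ <- dA * (cache[[paste0("ffcZ", i)]] > 0)
    g[[paste0("ffcW", i)]] <- crossprod(cache[[paste0("ffcA", i)]], dZ)
    g[[paste0("ffcB", i)]] <- colSums(dZ)
    dA <- dZ %*% t(w[[paste0("ffcW", i)]])
  }
  sp <- cache$splitAt
  dP <- dA[, seq_len(sp), drop = FALSE]
  dD <- dA[, -seq_len(sp), drop = FALSE]
  ## protein branch
  for (i in 3:1) {
    dZ <- dP * (cache[[paste0("pfcZ", i)]] > 0)
    g[[paste0("pfcW", i)]] <- crossprod(cache[[paste0("pfcA", i)]], dZ)
    g[[paste0("pfcB", i)]] <- colSums(dZ)
    dP <- dZ %*% t(w[[paste0("pfcW", i)]])
  }
  ## drug branch
  if (cfg@drugBranch == "cnn_sep") {
    f <- cfg@filterLength; F1 <- cfg@nFilters; D <- cfg@embeddingDim
    L3 <- cache$L3
    ## un-pool: route gradient to the argmax position per (sample, channel)
    dH3 <- array(0, cache$h3dim)
    for (c in seq_len(F1))
      dH3[cbind(seq_len(B), cache$amax[, c], c)] <- dD[, c]
    dZ3 <- matrix(dH3, B * L3, F1) * (cache$z3 > 0)
    g$sepPwW <- crossprod(cache$dw, dZ3)
    g$sepB <- colSums(dZ3)
    dDw <- dZ3 %*% t(w$sepPwW)
    g$sepDwW <- matrix(0, f, F1)
    L2 <- dim(cache$h2)[2]
    dH2 <- array(0, dim(cache$h2))
    for (k in seq_len(f)) {
      sl <- matrix(cache$h2[, k:(k + L3 - 1L), , drop = FALSE], B * L3, F1)
      g$sepDwW[k, ] <- colSums(sl * dDw)
      contrib <- array(sweep(dDw, 2L, w$sepDwW[k, ], "*"), c(B, L3, F1))
      dH2[, k:(k + L3 - 1L), ] <- dH2[, k:(k + L3 - 1L), , drop = FALSE] +
        contrib
    }
    dZ2 <- matrix(dH2, B * L2, F1) * (cache$z2 > 0)
    g$conv2W <- crossprod(cache$x2, dZ2)
    g$conv2B <- colSums(dZ2)
    dX2 <- dZ2 %*% t(w$conv2W)
    dH1 <- .col2im(dX2, f, B, dim(cache$h1)[2], F1)
    L1 <- dim(cache$h1)[2]
    dZ1 <- matrix(dH1, B * L1, F1) * (cache$z1 > 0)
    g$conv1W <- crossprod(cache$x1, dZ1)
    g$conv1B <- colSums(dZ1)
    dX1 <- dZ1 %*% t(w$conv1W)
    dEmb <- .col2im(dX1, f, B, ncol(cache$Dc), D)
    idx <- as.vector(cache$Dc) + 1L
    acc <- rowsum(matrix(dEmb, B * ncol(cache$Dc), D), group = idx)
    g$emb <- matrix(0, nrow(w$emb), D)
    g$emb[as.integer(rownames(acc)), ] <- acc
  } else {
    for (i in 3:1) {
      dZ <- dD * (cache[[paste0("dfcZ", i)]] > 0)
      g[[paste0("dfcW", i)]] <- crossprod(cache[[paste0("dfcA", i)]], dZ)
      g[[paste0("dfcB", i)]] <- colSums(dZ)
      dD <- dZ %*% t(w[[paste0("dfcW", i)]])
    }
  }
  g
}

## ---- Adam optimizer ------------------------------------------------------

.adamInit <- function(w) list(m = lapply(w, function(x) x * 0),
                              v = lapply(w, function(x) x * 0), t = 0L)

.adamStep <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(w = w, state = state)
}
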