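## Batched LSTM core with analytic backpropagation, written against base R
## matrix operations. Gate layout in the 4H-wide weight blocks is
## [input, forget, cell, output]. All categorical inputs are embedded; code k
## looks up row k+1 of its embedding matrix so that the reserved
## padding/missing code 0 has a (trainable but loss-masked) row of its own.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- parameter initialisation ----

## Head weights start at exactly zero so the untrained model emits uniform
## softmax predictions (loss ln C), a useful closed-form reference point.
initGeneratorParams <- function(schema, codebook, cfg) {
  withSeed(cfg$seed, {
    H <- cfg$hiddenSize
    dL <- cfg$embLabel
    dA <- cfg$embAttr
    dB <- cfg$embBaseline
    A <- attributeNames(schema)
    B <- baselineNames(schema)
    nLab <- length(codebook$labels)              # C + 1 incl. padding
    u <- function(nr, nc, s) matrix(runif(nr * nc, -s, s), nr, nc)
    embLabel <- u(nLab, dL, 0.1)
    embAttr <- lapply(codebook$attrs, function(e) u(e$n + 1L, dA, 0.1))
    embBase <- lapply(codebook$baseline, function(e) u(e$n, dB, 0.1))
    dIn <- dL + dA * length(A)
    dBase <- dB * length(B)
    lstm <- vector("list", cfg$nLayers)
    for (l in seq_len(cfg$nLayers)) {
      din <- if (l == 1) dIn else H
      s <- 1 / sqrt(H)
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1             # forget-gate bias: remember early
      lstm[[l]] <- list(Wx = u(din, 4 * H, s), Wh = u(H, 4 * H, s), b = b)
    }
    uW <- H + dBase
    headLabel <- list(W = matrix(0, uW, nLab), b = numeric(nLab))
    headAttr <- lapply(codebook$attrs, function(e)
      list(W = matrix(0, uW, e$n + 1L), b = numeric(e$n + 1L)))
    list(embLabel = embLabel, embAttr = embAttr, embBase = embBase,
         lstm = lstm, headLabel = headLabel, headAttr = headAttr)
  })
}

## ---- forward ----

gmEmbedBaseline <- function(params, base) {
  do.call(cbind, lapply(seq_along(params$embBase), function(v)
    params$embBase[[v]][base[, v], , drop = FALSE]))
}

freshState <- function(params, n) {
  H <- ncol(params$lstm[[1]]$Wh)  / 4L
  lapply(params$lstm, function(.)
    list(h = matrix(0, n, H), c = matrix(0, n, H)))
}

## labels: n x Tin codes 0..C; attrs: n x Tin x A codes; base: n x B codes.
## Returns logits for each head at every input position plus the carried
## state; with cache=TRUE also everything backward needs.
gmForward <- function(params, labels, attrs, base, state = NULL,
                      cache = FALSE) {
  n <- nrow(labels); Tin <- ncol(labels)
  A <- length(params$embAttr)
  H <- ncol(params$lstm[[1]]$Wh) / 4L
  nLayers <- length(params$lstm)
  if (is.null(state)) state <- freshState(params, n)
  bemb <- gmEmbedBaseline(params, base)
  labLogits <- array(0, dim = c(n, Tin, ncol(params$headLabel$W)))
  attrLogits <- lapply(params$headAttr, function(hh)
    array(0, dim = c(n, Tin, ncol(hh$W))))
  caches <- if (cache) vector("list", Tin) else NULL
  for (t in seq_len(Tin)) {
    x <- cbind(params$embLabel[labels[, t] + 1L, , drop = FALSE],
               do.call(cbind, lapply(seq_len(A), function(i)
                 params$embAttr[[i]][attrs[, t, i] + 1L, , drop = FALSE])))
    layerCache <- if (cache) vector("list", nLayers) else NULL
    inp <- x
    for (l in seq_len(nLayers)) {
      W <- params$lstm[[l]]
      hprev <- state[[l]]$h; cprev <- state[[l]]$c
      z <- inp %*% W$Wx + hprev %*% W$Wh +
        matrix(W$b, n, 4 * H, byrow = TRUE)
      i_ <- sigmoid(z[, 1:H, drop = FALSE])
      f_ <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      g_ <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o_ <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      cNew <- f_ * cprev + i_ * g_
      tc <- tanh(cNew)
      hNew <- o_ * tc
      if (cache)
        layerCache[[l]] <- list(inp = inp, hprev = hprev, cprev = cprev,
                                i = i_, f = f_, g = g_, o = o_, tc = tc)
      state[[l]] <- list(h = hNew, c = cNew)
      inp <- hNew
    }
    u <- cbind(inp, bemb)
    labLogits[, t, ] <- u %*% params$headLabel$W +
      matrix(params$headLabel$b, n, length(params$headLabel$b), byrow = TRUE)
    for (i in seq_len(A))
      attrLogits[[i]][, t, ] <- u %*% params$headAttr[[i]]$W +
        matrix(params$headAttr[[i]]$b, n,
               length(params$headAttr[[i]]$b), byrow = TRUE)
    if (cache) caches[[t]] <- list(layers = layerCache, u = u)
  }
  list(labelLogits = labLogits, attrLogits = attrLogits, state = state,
       caches = caches, bemb = bemb)
}

## ---- backward ----

zeroLike <- function(p) rapply(p, function(x) x * 0, how = "replace")

addRowsum <- function(G, d, idx) {
  rs <- rowsum(d, group = idx)
  rows <- as.integer(rownames(rs))
  G[rows, ] <- G[rows, , drop = FALSE] + rs
  G
}

## dLab: n x Tin x (C+1); dAttr: list of n x Tin x (Ci+1) gradients of the
## loss wrt the head logits. Returns gradients for every parameter.
gmBackward <- function(params, fwd, labels, attrs, base, dLab, dAttr) {
  n <- nrow(labels); Tin <- ncol(labels)
  A <- length(params$embAttr)
  H <- ncol(params$lstm[[1]]$Wh) / 4L
  nLayers <- length(params$lstm)
  dL <- ncol(params$embLabel)
  dAe <- if (A) ncol(params$embAttr[[1]]) else 0L
  g <- zeroLike(params)
  dhNext <- lapply(seq_len(nLayers), function(l) matrix(0, n, H))
  dcNext <- dhNext
  dBemb <- matrix(0, n, ncol(fwd$bemb))
  for (t in rev(seq_len(Tin))) {
    cc <- fwd$caches[[t]]
    u <- cc$u
    dlab_t <- matrix(dLab[, t, ], nrow = n)
    g$headLabel$W <- g$headLabel$W + crossprod(u, dlab_t)
    g$headLabel$b <- g$headLabel$b + colSums(dlab_t)
    dU <- dlab_t %*% t(params$headLabel$W)
    for (i in seq_len(A)) {
      da_t <- matrix(dAttr[[i]][, t, ], nrow = n)
      g$headAttr[[i]]$W <- g$headAttr[[i]]$W + crossprod(u, da_t)
      g$headAttr[[i]]$b <- g$headAttr[[i]]$b + colSums(da_t)
      dU <- dU + da_t %*% t(params$headAttr[[i]]$W)
    }
    dhTop <- dU[, seq_len(H), drop = FALSE]
    dBemb <- dBemb + dU[, -seq_len(H), drop = FALSE]
    dFromAbove <- dhTop
    for (l in rev(seq_len(nLayers))) {
      lc <- cc$layers[[l]]
      W <- params$lstm[[l]]
      dh <- dFromAbove + dhNext[[l]]
      do_ <- dh * lc$tc
      dc <- dcNext[[l]] + dh * lc$o * (1 - lc$tc^2)
      di <- dc * lc$g
      dg <- dc * lc$i
      df <- dc * lc$cprev
      dz <- cbind(di * lc$i * (1 - lc$i),
                  df * lc$f * (1 - lc$f),
                  dg * (1 - lc$g^2),
                  do_ * lc$o * (1 - lc$o))
      g$lstm[[l]]$Wx <- g$lstm[[l]]$Wx + crossprod(lc$inp, dz)
      g$lstm[[l]]$Wh <- g$lstm[[l]]$Wh + crossprod(lc$hprev, dz)
      g$lstm[[l]]$b <- g$lstm[[l]]$b + colSums(dz)
      dFromAbove <- dz %*% t(W$Wx)      # becomes dh of layer below (or dx)
      dhNext[[l]] <- dz %*% t(W$Wh)
      dcNext[[l]] <- dc * lc$f
    }
    dx <- dFromAbove                     # gradient wrt embedded input at t
    g$embLabel <- addRowsum(g$embLabel, dx[, seq_len(dL), drop = FALSE],
                            labels[, t] + 1L)
    for (i in seq_len(A)) {
      cols <- dL + (i - 1L) * dAe + seq_len(dAe)
      g$embAttr[[i]] <- addRowsum(g$embAttr[[i]],
                                  dx[, cols, drop = FALSE],
                                  attrs[, t, i] + 1L)
    }
  }
  off <- 0L
  for (v in seq_along(params$embBase)) {
    dBv <- ncol(params$embBase[[v]])
    g$embBase[[v]] <- addRowsum(g$embBase[[v]],
                                dBemb[, off + seq_len(dBv), drop = FALSE],
                                base[, v])
    off <- off + dBv
  }
  g
}

## ---- optimiser ----

adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params),
                                  t = 0L)

adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(unlist(rapply(grads, function(x) sum(x^2), how = "unlist"))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  st$t <- st$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- walk(params, grads, st$m, st$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = st$t))
}

## ---- masked cross-entropy with logit gradients ----

## logits: n x K matrix, target codes 0..K-1, mask: logical n. Returns the
## summed CE over masked rows, the count, and d(sum CE)/d(logits).
ceRows <- function(logits, target, mask) {
  n <- nrow(logits)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  tcol <- target + 1L
  ce <- log(Z) + mx - logits[cbind(seq_len(n), tcol)]
  d <- p
  d[cbind(seq_len(n), tcol)] <- d[cbind(seq_len(n), tcol)] - 1
  d[!mask, ] <- 0
  list(sum = sum(ce[mask]), count = sum(mask), d = d)
}
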