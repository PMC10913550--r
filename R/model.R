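# Recurrent autoencoder core: parameter construction, encoder/decoder
# forward passes, additive attention, variational head, greedy decoding.
#
# Conventions (documented layer set, used by countParameters):
#   encoder layer l: Wx (Din x G*H), Wh (H x G*H), bx, bh (G*H)
#     with G = 3 gates (GRU: r, z, n) or 4 (LSTM: i, f, g, o), Din = V for
#     layer 1 and H above.
#   attention (optional): W (H x H), b (H), v (H).
#   latent bridge: W (F x L), b (L), where F = m*H for GRU, 2*m*H for LSTM,
#     plus H if attention; absent only for the plain GRU with m = 1,
#     H = L and no attention (then z = h_T bitwise).
#   variational head: Wmu, Wlv (F x L), bmu, blv (L) replacing the bridge.
#   decoder initial state: GRU identity if m = 1 and H = L, else W (L x m*H),
#     b (m*H); LSTM always two maps (hidden and cell state).
#   decoder layers mirror the encoder; output layer W (H x V), b (V).

sigmoid <- function(x) 1 / (1 + exp(-x))
.addb <- function(M, b) M + rep(b, each = nrow(M))

.gates <- function(cfg) if (cfg@cell == "gru") 3L else 4L

.bridgeInputWidth <- function(cfg) {
  f <- cfg@numLayers * cfg@hiddenSize * (if (cfg@cell == "lstm") 2L else 1L)
  if (cfg@attention) f + cfg@hiddenSize else f
}

.hasBridge <- function(cfg) {
  if (cfg@variational) return(FALSE)          # heads instead
  !(cfg@cell == "gru" && cfg@numLayers == 1L && !cfg@attention &&
    cfg@hiddenSize == cfg@latentSize)
}

.decoderIdentityInit <- function(cfg) {
  cfg@cell == "gru" && cfg@numLayers == 1L &&
    cfg@hiddenSize == cfg@latentSize
}

.uniformInit <- function(nr, nc, fanIn) {
  lim <- 1 / sqrt(fanIn)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

initParams <- function(cfg, V, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    H <- cfg@hiddenSize; L <- cfg@latentSize; m <- cfg@numLayers
    G <- .gates(cfg)
    P <- list()
    mk <- function(side, l, Din) {
      P[[paste0(side, ".Wx.", l)]] <<- .uniformInit(Din, G * H, H)
      P[[paste0(side, ".Wh.", l)]] <<- .uniformInit(H, G * H, H)
      P[[paste0(side, ".bx.", l)]] <<- runif(G * H, -1, 1) / sqrt(H)
      P[[paste0(side, ".bh.", l)]] <<- runif(G * H, -1, 1) / sqrt(H)
    }
    for (l in seq_len(m)) mk("enc", l, if (l == 1L) V else H)
    if (cfg@attention) {
      P$att.W <- .uniformInit(H, H, H)
      P$att.b <- runif(H, -1, 1) / sqrt(H)
      P$att.v <- runif(H, -1, 1) / sqrt(H)
    }
    Fw <- .bridgeInputWidth(cfg)
    if (cfg@variational) {
      P$vae.Wmu <- .uniformInit(Fw, L, Fw)
      P$vae.bmu <- runif(L, -1, 1) / sqrt(Fw)
      P$vae.Wlv <- .uniformInit(Fw, L, Fw)
      P$vae.blv <- runif(L, -1, 1) / sqrt(Fw)
    } else if (.hasBridge(cfg)) {
      P$br.W <- .uniformInit(Fw, L, Fw)
      P$br.b <- runif(L, -1, 1) / sqrt(Fw)
    }
    if (cfg@cell == "gru") {
      if (!.decoderIdentityInit(cfg)) {
        P$dec0.W <- .uniformInit(L, m * H, L)
        P$dec0.b <- runif(m * H, -1, 1) / sqrt(L)
      }
    } else {
      P$dec0h.W <- .uniformInit(L, m * H, L)
      P$dec0h.b <- runif(m * H, -1, 1) / sqrt(L)
      P$dec0c.W <- .uniformInit(L, m * H, L)
      P$dec0c.b <- runif(m * H, -1, 1) / sqrt(L)
    }
    for (l in seq_len(m)) mk("dec", l, if (l == 1L) V else H)
    P$out.W <- .uniformInit(H, V, H)
    P$out.b <- runif(V, -1, 1) / sqrt(H)
    P
  })
}

#' Exact trainable-parameter count of an architecture
#'
#' Sums the sizes of every weight matrix and bias vector of the documented
#' layer set for a given configuration and vocabulary size.
#'
#' @param config a [ModelConfig-class].
#' @param vocabSize vocabulary size including specials.
#' @return integer parameter count.
#' @export
countParameters <- function(config, vocabSize) {
  P <- initParams(config, as.integer(vocabSize), seed = 0L)
  sum(vapply(P, length, 0L))
}

# ---- recurrent cells --------------------------------------------------------

# inp: B x Din, hprev/cprev: B x H; returns h (and c) plus backward cache
cellForward <- function(cell, inp, hprev, cprev, Wx, Wh, bx, bh, H) {
  gx <- .addb(inp %*% Wx, bx)
  gh <- .addb(hprev %*% Wh, bh)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1
  if (cell == "gru") {
    r <- sigmoid(gx[, i1, drop = FALSE] + gh[, i1, drop = FALSE])
    z <- sigmoid(gx[, i2, drop = FALSE] + gh[, i2, drop = FALSE])
    n <- tanh(gx[, i3, drop = FALSE] + r * gh[, i3, drop = FALSE])
    h <- (1 - z) * n + z * hprev
    list(h = h, c = NULL,
         cache = list(inp = inp, hprev = hprev, r = r, z = z, n = n,
                      ghn = gh[, i3, drop = FALSE]))
  } else {
    i4 <- 3L * H + i1
    g <- gx + gh
    i <- sigmoid(g[, i1, drop = FALSE])
    f <- sigmoid(g[, i2, drop = FALSE])
    gg <- tanh(g[, i3, drop = FALSE])
    o <- sigmoid(g[, i4, drop = FALSE])
    c <- f * cprev + i * gg
    tc <- tanh(c)
    h <- o * tc
    list(h = h, c = c,
         cache = list(inp = inp, hprev = hprev, cprev = cprev, i = i, f = f,
                      g = gg, o = o, tc = tc))
  }
}

# dh, dc: gradients wrt this step's (pre-mask) outputs
cellBackward <- function(cell, dh, dc, cache, Wx, Wh, H) {
  if (cell == "gru") {
    r <- cache$r; z <- cache$z; n <- cache$n; ghn <- cache$ghn
    hprev <- cache$hprev
    dz <- dh * (hprev - n)
    dn <- dh * (1 - z)
    dhprev <- dh * z
    dnp <- dn * (1 - n * n)              # pre-tanh
    dr <- dnp * ghn
    dghn <- dnp * r
    drp <- dr * r * (1 - r)
    dzp <- dz * z * (1 - z)
    dgx <- cbind(drp, dzp, dnp)
    dgh <- cbind(drp, dzp, dghn)
    list(dInp = dgx %*% t(Wx),
         dHprev = dhprev + dgh %*% t(Wh),
         dCprev = NULL,
         dWx = crossprod(cache$inp, dgx),
         dWh = crossprod(hprev, dgh),
         dbx = colSums(dgx), dbh = colSums(dgh))
  } else {
    i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
    do <- dh * tc
    dcT <- dh * o * (1 - tc * tc) + dc
    df <- dcT * cache$cprev
    di <- dcT * g
    dg <- dcT * i
    dCprev <- dcT * f
    dpre <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - g * g), do * o * (1 - o))
    list(dInp = dpre %*% t(Wx),
         dHprev = dpre %*% t(Wh),
         dCprev = dCprev,
         dWx = crossprod(cache$inp, dpre),
         dWh = crossprod(cache$hprev, dpre),
         dbx = colSums(dpre), dbh = colSums(dpre))
  }
}

# ---- attention --------------------------------------------------------------

#' Additive attention context over encoder step outputs
#'
#' Computes additive scores `v' tanh(W h_t + b)` over the step outputs,
#' softmax-normalizes them across steps (padded steps masked out) and
#' returns the weighted sum of step outputs.
#'
#' @param stepOutputs list of `B x H` matrices (one per step) or a single
#'   `T x H` matrix for a single sequence.
#' @param params list with `W` (HxH), `b` (H), `v` (H); randomly
#'   initialized from `seed` when omitted.
#' @param mask optional `T x B` logical matrix of valid steps.
#' @param seed seed for the default random parameters.
#' @return list with `context` (`B x H`) and `weights` (`T x B`).
#' @export
attentionContext <- function(stepOutputs, params = NULL, mask = NULL,
                             seed = 1L) {
  if (is.matrix(stepOutputs))
    stepOutputs <- lapply(seq_len(nrow(stepOutputs)),
                          function(t) stepOutputs[t, , drop = FALSE])
  Tn <- length(stepOutputs)
  stopifnot(Tn >= 1L)
  B <- nrow(stepOutputs[[1L]])
  H <- ncol(stepOutputs[[1L]])
  if (is.null(params))
    params <- withr::with_seed(as.integer(seed), list(
      W = .uniformInit(H, H, H), b = runif(H, -1, 1) / sqrt(H),
      v = runif(H, -1, 1) / sqrt(H)))
  if (is.null(mask)) mask <- matrix(TRUE, Tn, B)
  if (!any(mask)) stop("all attention steps are masked")
  fwd <- .attentionForward(stepOutputs, params$W, params$b, params$v, mask)
  list(context = fwd$context, weights = fwd$alpha)
}

.attentionForward <- function(Hs, W, b, v, mask) {
  Tn <- length(Hs); B <- nrow(Hs[[1L]])
  A <- vector("list", Tn)
  S <- matrix(-Inf, Tn, B)
  for (t in seq_len(Tn)) {
    a <- tanh(.addb(Hs[[t]] %*% W, b))
    A[[t]] <- a
    s <- as.vector(a %*% v)
    S[t, ] <- ifelse(mask[t, ], s, -Inf)
  }
  Sm <- sweep(S, 2L, apply(S, 2L, max), "-")
  E <- exp(Sm)
  alpha <- sweep(E, 2L, colSums(E), "/")
  context <- matrix(0, B, ncol(Hs[[1L]]))
  for (t in seq_len(Tn)) context <- context + alpha[t, ] * Hs[[t]]
  list(context = context, alpha = alpha, A = A, mask = mask)
}

# returns dHs (list), dW, db, dv
.attentionBackward <- function(dContext, fwd, Hs, W, v) {
  Tn <- length(Hs); B <- nrow(Hs[[1L]]); H <- ncol(Hs[[1L]])
  alpha <- fwd$alpha
  dAlpha <- matrix(0, Tn, B)
  dHs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dAlpha[t, ] <- rowSums(dContext * Hs[[t]])
    dHs[[t]] <- alpha[t, ] * dContext
  }
  dS <- alpha * sweep(dAlpha, 2L, colSums(alpha * dAlpha), "-")
  dS[!fwd$mask] <- 0
  dW <- matrix(0, H, H); db <- numeric(H); dv <- numeric(H)
  for (t in seq_len(Tn)) {
    a <- fwd$A[[t]]
    dv <- dv + colSums(a * dS[t, ])
    dpre <- (dS[t, ] %o% v) * (1 - a * a)
    dW <- dW + crossprod(Hs[[t]], dpre)
    db <- db + colSums(dpre)
    dHs[[t]] <- dHs[[t]] + dpre %*% t(W)
  }
  list(dHs = dHs, dW = dW, db = db, dv = dv)
}

# ---- encoder ----------------------------------------------------------------

# X: B x T x V one-hot array, lens: integer(B) incl. EOS
encoderForward <- function(P, cfg, X, lens, needCache = FALSE) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]
  H <- cfg@hiddenSize; m <- cfg@numLayers
  cell <- cfg@cell
  h <- lapply(seq_len(m), function(l) matrix(0, B, H))
  cst <- if (cell == "lstm") lapply(seq_len(m), function(l) matrix(0, B, H))
  topOut <- vector("list", Tn)
  caches <- if (needCache) vector("list", Tn)
  maskTB <- outer(seq_len(Tn), lens, "<=")
  for (t in seq_len(Tn)) {
    inp <- X[, t, , drop = TRUE]
    if (B == 1L) inp <- matrix(inp, 1L)
    mt <- maskTB[t, ]
    stepCache <- if (needCache) vector("list", m)
    for (l in seq_len(m)) {
      cf <- cellForward(cell, inp, h[[l]],
                        if (cell == "lstm") cst[[l]] else NULL,
                        P[[paste0("enc.Wx.", l)]], P[[paste0("enc.Wh.", l)]],
                        P[[paste0("enc.bx.", l)]], P[[paste0("enc.bh.", l)]],
                        H)
      hNew <- mt * cf$h + (1 - mt) * h[[l]]
      if (cell == "lstm") cst[[l]] <- mt * cf$c + (1 - mt) * cst[[l]]
      if (needCache) stepCache[[l]] <- cf$cache
      h[[l]] <- hNew
      inp <- hNew
    }
    topOut[[t]] <- h[[m]]
    if (needCache) caches[[t]] <- stepCache
  }
  list(hT = h, cT = cst, topOut = topOut, mask = maskTB,
       caches = caches, Tn = Tn, B = B)
}

# encoder final feature + latent (deterministic path: VAE returns the mean)
latentForward <- function(P, cfg, enc) {
  feats <- do.call(cbind, enc$hT)
  if (cfg@cell == "lstm") feats <- cbind(feats, do.call(cbind, enc$cT))
  attFwd <- NULL
  if (cfg@attention) {
    attFwd <- .attentionForward(enc$topOut, P$att.W, P$att.b, P$att.v,
                                enc$mask)
    feats <- cbind(feats, attFwd$context)
  }
  if (cfg@variational) {
    mu <- .addb(feats %*% P$vae.Wmu, P$vae.bmu)
    logvar <- .addb(feats %*% P$vae.Wlv, P$vae.blv)
    list(f = feats, z = mu, mu = mu, logvar = logvar, attFwd = attFwd)
  } else if (.hasBridge(cfg)) {
    list(f = feats, z = .addb(feats %*% P$br.W, P$br.b), mu = NULL,
         logvar = NULL, attFwd = attFwd)
  } else {
    list(f = feats, z = feats, mu = NULL, logvar = NULL, attFwd = attFwd)
  }
}

# decoder initial per-layer states from z
decoderInit <- function(P, cfg, z) {
  H <- cfg@hiddenSize; m <- cfg@numLayers
  splitLayers <- function(M) lapply(seq_len(m), function(l)
    M[, (l - 1L) * H + seq_len(H), drop = FALSE])
  if (cfg@cell == "gru") {
    if (.decoderIdentityInit(cfg)) list(h = list(z), c = NULL)
    else list(h = splitLayers(.addb(z %*% P$dec0.W, P$dec0.b)), c = NULL)
  } else {
    list(h = splitLayers(.addb(z %*% P$dec0h.W, P$dec0h.b)),
         c = splitLayers(.addb(z %*% P$dec0c.W, P$dec0c.b)))
  }
}

# teacher-forced decoder; Yin: B x T x V one-hot decoder inputs
decoderForward <- function(P, cfg, init, Yin, needCache = FALSE) {
  B <- dim(Yin)[1L]; Tn <- dim(Yin)[2L]
  H <- cfg@hiddenSize; m <- cfg@numLayers; cell <- cfg@cell
  h <- init$h; cst <- init$c
  logits <- vector("list", Tn)
  caches <- if (needCache) vector("list", Tn)
  tops <- if (needCache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    inp <- Yin[, t, , drop = TRUE]
    if (B == 1L) inp <- matrix(inp, 1L)
    stepCache <- if (needCache) vector("list", m)
    for (l in seq_len(m)) {
      cf <- cellForward(cell, inp, h[[l]],
                        if (cell == "lstm") cst[[l]] else NULL,
                        P[[paste0("dec.Wx.", l)]], P[[paste0("dec.Wh.", l)]],
                        P[[paste0("dec.bx.", l)]], P[[paste0("dec.bh.", l)]],
                        H)
      h[[l]] <- cf$h
      if (cell == "lstm") cst[[l]] <- cf$c
      if (needCache) stepCache[[l]] <- cf$cache
      inp <- cf$h
    }
    logits[[t]] <- .addb(h[[m]] %*% P$out.W, P$out.b)
    if (needCache) { caches[[t]] <- stepCache; tops[[t]] <- h[[m]] }
  }
  list(logits = logits, caches = caches, tops = tops, hT = h, cT = cst)
}

logSoftmax <- function(L) {
  mx <- apply(L, 1L, max)
  Ls <- L - mx
  Ls - log(rowSums(exp(Ls)))
}

softmaxRows <- function(L) {
  E <- exp(L - apply(L, 1L, max))
  E / rowSums(E)
}

# ---- variational utilities --------------------------------------------------

#' Reparameterization sampling for the variational head
#'
#' Draws `z = mu + exp(logvar / 2) * eps` with standard-normal `eps`,
#' deterministically per seed.
#'
#' @param mu,logvar numeric matrices (or vectors) of equal shape.
#' @param seed integer seed for `eps`.
#' @param eps optional fixed noise of the same shape (overrides sampling).
#' @return sample(s) of the same shape as `mu`.
#' @export
reparameterize <- function(mu, logvar, seed = 1L, eps = NULL) {
  stopifnot(length(mu) == length(logvar))
  if (is.null(eps))
    eps <- withr::with_seed(as.integer(seed),
                            array(rnorm(length(mu)), dim = dim(as.matrix(mu))))
  mu + exp(logvar / 2) * eps
}

#' Kullback-Leibler divergence of a diagonal Gaussian to the standard normal
#'
#' `KL = -1/2 * sum(1 + logvar - mu^2 - exp(logvar))` per sample; for a
#' matrix of samples (rows) the per-sample KLs are averaged.
#'
#' @param mu,logvar numeric vectors (one sample) or matrices (samples in
#'   rows).
#' @return scalar KL value.
#' @export
klDivergence <- function(mu, logvar) {
  stopifnot(length(mu) == length(logvar))
  perElem <- -0.5 * (1 + logvar - mu^2 - exp(logvar))
  if (is.matrix(mu)) mean(rowSums(perElem)) else sum(perElem)
}
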