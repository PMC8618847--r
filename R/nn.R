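# Internal neural-network engine: dense / 2-D valid convolution / GRU layers
# with analytic gradients and Adam. Shapes follow the frame-sequence layout
# used throughout: all frames of a batch are rows of a matrix, ordered
# sequence-major (row of frame t in sequence b = (b-1)*T + t).

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(n_in, n_out, dim = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

# ---- valid-convolution index tables --------------------------------------
# Frame blocks are flattened column-major: element (bin r, column c) of an
# h0 x w0 block sits at (c-1)*h0 + r. conv1 uses 3x3 filters, conv2 4x2;
# both valid padding, stride 1, matching the printed activation shapes.
.conv_indices <- function(h0, w0, f1) {
  h1 <- h0 - 2L; w1 <- w0 - 2L
  h2 <- h1 - 3L; w2 <- w1 - 1L
  if (h1 < 1L || w1 < 1L || h2 < 1L || w2 < 1L)
    stop("input block ", h0, "x", w0, " too small for the 3x3 + 4x2 conv stack")
  idx1 <- matrix(0L, h1 * w1, 9L)
  for (c0 in seq_len(w1)) for (r0 in seq_len(h1)) {
    p <- (c0 - 1L) * h1 + r0
    idx1[p, ] <- as.integer(outer(r0:(r0 + 2L), (c0:(c0 + 2L)) - 1L,
                                  function(r, c) c * h0 + r))
  }
  np1 <- h1 * w1
  idx2 <- matrix(0L, h2 * w2, 8L * f1)
  for (c0 in seq_len(w2)) for (r0 in seq_len(h2)) {
    q <- (c0 - 1L) * h2 + r0
    ix <- integer(0)
    for (f in seq_len(f1)) for (cc in c0:(c0 + 1L))
      ix <- c(ix, (f - 1L) * np1 + (cc - 1L) * h1 + (r0:(r0 + 3L)))
    idx2[q, ] <- as.integer(ix)
  }
  list(idx1 = idx1, idx2 = idx2, h1 = h1, w1 = w1, h2 = h2, w2 = w2,
       np1 = np1, np2 = h2 * w2)
}

.conv_fwd <- function(X0, P, ci, f1, f2) {
  Nf <- nrow(X0)
  Z1 <- matrix(0, Nf, ci$np1 * f1)
  for (p in seq_len(ci$np1)) {
    out <- X0[, ci$idx1[p, ], drop = FALSE] %*% P$W1
    Z1[, (seq_len(f1) - 1L) * ci$np1 + p] <-
      out + matrix(P$b1, Nf, f1, byrow = TRUE)
  }
  A1 <- pmax(Z1, 0)
  Z2 <- matrix(0, Nf, ci$np2 * f2)
  for (q in seq_len(ci$np2)) {
    out <- A1[, ci$idx2[q, ], drop = FALSE] %*% P$W2
    Z2[, (seq_len(f2) - 1L) * ci$np2 + q] <-
      out + matrix(P$b2, Nf, f2, byrow = TRUE)
  }
  A2 <- pmax(Z2, 0)
  list(A2 = A2, A1 = A1, Z1 = Z1, Z2 = Z2, X0 = X0)
}

.conv_bwd <- function(dA2, cache, P, ci, f1, f2) {
  dZ2 <- dA2 * (cache$Z2 > 0)
  dW2 <- matrix(0, nrow(P$W2), ncol(P$W2)); db2 <- numeric(f2)
  dA1 <- matrix(0, nrow(dZ2), ci$np1 * f1)
  for (q in seq_len(ci$np2)) {
    dout <- dZ2[, (seq_len(f2) - 1L) * ci$np2 + q, drop = FALSE]
    cols <- ci$idx2[q, ]
    dW2 <- dW2 + crossprod(cache$A1[, cols, drop = FALSE], dout)
    db2 <- db2 + colSums(dout)
    dA1[, cols] <- dA1[, cols] + dout %*% t(P$W2)
  }
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- matrix(0, 9L, f1); db1 <- numeric(f1)
  dX0 <- matrix(0, nrow(dZ1), ncol(cache$X0))
  for (p in seq_len(ci$np1)) {
    dout <- dZ1[, (seq_len(f1) - 1L) * ci$np1 + p, drop = FALSE]
    cols <- ci$idx1[p, ]
    dW1 <- dW1 + crossprod(cache$X0[, cols, drop = FALSE], dout)
    db1 <- db1 + colSums(dout)
    dX0[, cols] <- dX0[, cols] + dout %*% t(P$W1)
  }
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dX0 = dX0)
}

# ---- GRU (reset-after / double-bias formulation, ReLU candidate) ---------
# z_t = s(x W_z + bx_z + h W_z' + bh_z); r_t likewise;
# hh_t = relu(x W_h + bx_h + r_t * (h W_h' + bh_h));
# h_t = z_t * h_{t-1} + (1 - z_t) * hh_t.
.gru_fwd <- function(X, Wx, Wh, bx, bh, B, T) {
  H <- length(bx) %/% 3L
  iz <- seq_len(H); ir <- H + iz; ih <- 2L * H + iz
  XW <- X %*% Wx + matrix(bx, nrow(X), 3L * H, byrow = TRUE)
  h <- matrix(0, B, H)
  Z <- array(0, c(T, B, H)); R <- Z; HH <- Z; HP <- Z; Hprev <- Z
  Out <- matrix(0, B * T, H)
  rows0 <- (seq_len(B) - 1L) * T
  for (t in seq_len(T)) {
    rt <- rows0 + t
    xw <- XW[rt, , drop = FALSE]
    hw <- h %*% Wh + matrix(bh, B, 3L * H, byrow = TRUE)
    z <- .sigmoid(xw[, iz, drop = FALSE] + hw[, iz, drop = FALSE])
    r <- .sigmoid(xw[, ir, drop = FALSE] + hw[, ir, drop = FALSE])
    hp <- hw[, ih, drop = FALSE]
    hh <- pmax(xw[, ih, drop = FALSE] + r * hp, 0)
    Hprev[t, , ] <- h
    h <- z * h + (1 - z) * hh
    Z[t, , ] <- z; R[t, , ] <- r; HH[t, , ] <- hh; HP[t, , ] <- hp
    Out[rt, ] <- h
  }
  list(Out = Out, Z = Z, R = R, HH = HH, HP = HP, Hprev = Hprev)
}

.gru_bwd <- function(dOut, cache, X, Wx, Wh, B, T) {
  H <- ncol(cache$Out)
  sl <- function(A, t) matrix(A[t, , ], B, H)
  dWx <- matrix(0, ncol(X), 3L * H); dWh <- matrix(0, H, 3L * H)
  dbx <- numeric(3L * H); dbh <- numeric(3L * H)
  dX <- matrix(0, nrow(X), ncol(X))
  dh_next <- matrix(0, B, H)
  rows0 <- (seq_len(B) - 1L) * T
  for (t in rev(seq_len(T))) {
    rt <- rows0 + t
    dh <- dh_next + dOut[rt, , drop = FALSE]
    z <- sl(cache$Z, t); r <- sl(cache$R, t); hh <- sl(cache$HH, t)
    hp <- sl(cache$HP, t); hprev <- sl(cache$Hprev, t)
    dz <- dh * (hprev - hh)
    dch <- dh * (1 - z) * (hh > 0)
    dr <- dch * hp
    dhp <- dch * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    dXpre <- cbind(dz_pre, dr_pre, dch)
    dHpre <- cbind(dz_pre, dr_pre, dhp)
    Xt <- X[rt, , drop = FALSE]
    dWx <- dWx + crossprod(Xt, dXpre)
    dbx <- dbx + colSums(dXpre)
    dWh <- dWh + crossprod(hprev, dHpre)
    dbh <- dbh + colSums(dHpre)
    dX[rt, ] <- dXpre %*% t(Wx)
    dh_next <- dh * z + dHpre %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, dbx = dbx, dbh = dbh, dX = dX)
}

# Row indices reversing time within each sequence of a B x T layout.
.rev_index <- function(B, T) {
  as.vector(vapply(seq_len(B), function(b) (b - 1L) * T + rev(seq_len(T)),
                   integer(T)))
}

# Source-row table for concatenating the `context` adjacent frames' feature
# vectors (zero vector beyond sequence edges, encoded as row Nf + 1).
.context_index <- function(B, T, context) {
  half <- (context - 1L) %/% 2L
  Nf <- B * T
  base <- seq_len(Nf)
  t_of <- rep(seq_len(T), times = B)
  sapply(-half:half, function(o) {
    src <- base + o
    src[t_of + o < 1L | t_of + o > T] <- Nf + 1L
    src
  })
}

# ---- model forward/backward ----------------------------------------------

.crnn_forward <- function(P, X0, B, T, ci, spec, masks = NULL) {
  cv <- .conv_fwd(X0, P, ci, spec$conv1_filters, spec$conv2_filters)
  A2 <- cv$A2
  if (!is.null(masks)) A2 <- A2 * masks$m1
  f <- .gru_fwd(A2, P$Wxf, P$Whf, P$bxf, P$bhf, B, T)
  rev_i <- .rev_index(B, T)
  bwd <- .gru_fwd(A2[rev_i, , drop = FALSE], P$Wxb, P$Whb, P$bxb, P$bhb, B, T)
  Hcat <- cbind(f$Out, bwd$Out[rev_i, , drop = FALSE])
  if (!is.null(masks)) Hcat <- Hcat * masks$m2
  logits <- drop(Hcat %*% P$Wd) + P$bd
  list(prob = .sigmoid(logits), cv = cv, A2 = A2, f = f, bwd = bwd,
       Hcat = Hcat, rev_i = rev_i)
}

.crnn_backward <- function(P, fw, y, B, T, ci, spec, masks = NULL) {
  Nf <- length(fw$prob)
  dlogits <- (fw$prob - y) / Nf
  dWd <- crossprod(fw$Hcat, matrix(dlogits))
  dbd <- sum(dlogits)
  dHcat <- matrix(dlogits) %*% t(P$Wd)
  if (!is.null(masks)) dHcat <- dHcat * masks$m2
  H <- spec$gru_units
  dOutf <- dHcat[, seq_len(H), drop = FALSE]
  dOutb <- dHcat[, H + seq_len(H), drop = FALSE][fw$rev_i, , drop = FALSE]
  A2rev <- fw$A2[fw$rev_i, , drop = FALSE]
  gf <- .gru_bwd(dOutf, fw$f, fw$A2, P$Wxf, P$Whf, B, T)
  gb <- .gru_bwd(dOutb, fw$bwd, A2rev, P$Wxb, P$Whb, B, T)
  dA2 <- gf$dX + gb$dX[fw$rev_i, , drop = FALSE]
  if (!is.null(masks)) dA2 <- dA2 * masks$m1
  cg <- .conv_bwd(dA2, fw$cv, P, ci, spec$conv1_filters, spec$conv2_filters)
  list(W1 = cg$dW1, b1 = cg$db1, W2 = cg$dW2, b2 = cg$db2,
       Wxf = gf$dWx, Whf = gf$dWh, bxf = gf$dbx, bhf = gf$dbh,
       Wxb = gb$dWx, Whb = gb$dWh, bxb = gb$dbx, bhb = gb$dbh,
       Wd = dWd, bd = dbd)
}

.cdnn_forward <- function(P, X0, B, T, spec, masks = NULL) {
  Z1 <- X0 %*% P$W1 + matrix(P$b1, nrow(X0), length(P$b1), byrow = TRUE)
  A1 <- pmax(Z1, 0)
  cidx <- .context_index(B, T, spec$context)
  A1z <- rbind(A1, 0)
  d1 <- ncol(A1)
  C <- matrix(0, nrow(X0), spec$context * d1)
  for (j in seq_len(spec$context))
    C[, (j - 1L) * d1 + seq_len(d1)] <- A1z[cidx[, j], , drop = FALSE]
  if (!is.null(masks)) C <- C * masks$m1
  Z2 <- C %*% P$W2 + matrix(P$b2, nrow(C), length(P$b2), byrow = TRUE)
  A2 <- pmax(Z2, 0)
  logits <- drop(A2 %*% P$W3) + P$b3
  list(prob = .sigmoid(logits), Z1 = Z1, A1 = A1, C = C, Z2 = Z2, A2 = A2,
       X0 = X0, cidx = cidx)
}

.cdnn_backward <- function(P, fw, y, B, T, spec, masks = NULL) {
  Nf <- length(fw$prob)
  dlogits <- (fw$prob - y) / Nf
  dW3 <- crossprod(fw$A2, matrix(dlogits))
  db3 <- sum(dlogits)
  dA2 <- matrix(dlogits) %*% t(P$W3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$C, dZ2)
  db2 <- colSums(dZ2)
  dC <- dZ2 %*% t(P$W2)
  if (!is.null(masks)) dC <- dC * masks$m1
  d1 <- ncol(fw$A1)
  dA1 <- matrix(0, Nf, d1)
  for (j in seq_len(spec$context)) {
    src <- fw$cidx[, j]
    ok <- src <= Nf
    dA1[src[ok], ] <- dA1[src[ok], , drop = FALSE] +
      dC[ok, (j - 1L) * d1 + seq_len(d1), drop = FALSE]
  }
  dZ1 <- dA1 * (fw$Z1 > 0)
  list(W1 = crossprod(fw$X0, dZ1), b1 = colSums(dZ1),
       W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

.bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
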