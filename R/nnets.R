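# Minimal sequence classifiers for the tabular-as-sequence baselines: an
# Elman recurrent network and a single-head self-attention network, both
# trained full-batch with Adam on the multi-label binary cross-entropy.
# Sizes are tiny (sequence length <= 10, hidden <= 16), so plain R matrix
# code is fast enough and keeps the package dependency-free.

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(prob, y) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

adam_update <- function(state, grads, lr = 0.02, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

adam_init <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(par = par, m = zeros, v = zeros, t = 0)
}

## ---- Elman RNN -----------------------------------------------------------

rnn_init <- function(hidden, n_out, scale = 0.3) {
  list(
    Wx = matrix(rnorm(hidden, sd = scale), 1, hidden),
    Wh = matrix(rnorm(hidden * hidden, sd = scale / sqrt(hidden)), hidden, hidden),
    bh = rep(0, hidden),
    Wo = matrix(rnorm(hidden * n_out, sd = scale / sqrt(hidden)), hidden, n_out),
    bo = rep(0, n_out)
  )
}

# X: n x T input (each feature vector read as an ordered univariate
# sequence); returns list(prob, cache)
rnn_forward <- function(par, X) {
  n <- nrow(X); T_ <- ncol(X); H <- ncol(par$Wx)
  hs <- vector("list", T_)
  h <- matrix(0, n, H)
  for (t in seq_len(T_)) {
    h <- tanh(X[, t, drop = FALSE] %*% par$Wx + h %*% par$Wh +
                matrix(par$bh, n, H, byrow = TRUE))
    hs[[t]] <- h
  }
  logits <- h %*% par$Wo + matrix(par$bo, n, ncol(par$Wo), byrow = TRUE)
  list(prob = sigmoid(logits), hs = hs)
}

rnn_backward <- function(par, X, Y, fwd) {
  n <- nrow(X); T_ <- ncol(X); H <- ncol(par$Wx); K <- ncol(Y)
  dlogit <- (fwd$prob - Y) / (n * K)
  g <- list(Wx = par$Wx * 0, Wh = par$Wh * 0, bh = par$bh * 0,
            Wo = crossprod(fwd$hs[[T_]], dlogit), bo = colSums(dlogit))
  dh <- dlogit %*% t(par$Wo)
  for (t in rev(seq_len(T_))) {
    da <- dh * (1 - fwd$hs[[t]]^2)
    g$Wx <- g$Wx + crossprod(X[, t, drop = FALSE], da)
    hprev <- if (t > 1) fwd$hs[[t - 1]] else matrix(0, n, H)
    g$Wh <- g$Wh + crossprod(hprev, da)
    g$bh <- g$bh + colSums(da)
    dh <- da %*% t(par$Wh)
  }
  g
}

## ---- single-head self-attention ------------------------------------------

attn_init <- function(T_, d, n_out, scale = 0.3) {
  list(
    we = rnorm(d, sd = scale),
    P = matrix(rnorm(T_ * d, sd = scale), T_, d),
    Wq = matrix(rnorm(d * d, sd = scale / sqrt(d)), d, d),
    Wk = matrix(rnorm(d * d, sd = scale / sqrt(d)), d, d),
    Wv = matrix(rnorm(d * d, sd = scale / sqrt(d)), d, d),
    Wo = matrix(rnorm(d * n_out, sd = scale / sqrt(d)), d, n_out),
    bo = rep(0, n_out)
  )
}

attn_forward <- function(par, X) {
  n <- nrow(X); T_ <- ncol(X); d <- length(par$we)
  E <- Q <- K <- V <- vector("list", T_)
  for (t in seq_len(T_)) {
    E[[t]] <- X[, t] %o% par$we + matrix(par$P[t, ], n, d, byrow = TRUE)
    Q[[t]] <- E[[t]] %*% par$Wq
    K[[t]] <- E[[t]] %*% par$Wk
    V[[t]] <- E[[t]] %*% par$Wv
  }
  S <- array(0, c(n, T_, T_))
  for (t in seq_len(T_)) for (s in seq_len(T_)) {
    S[, t, s] <- rowSums(Q[[t]] * K[[s]]) / sqrt(d)
  }
  A <- array(0, c(n, T_, T_))
  for (t in seq_len(T_)) {
    St <- matrix(S[, t, ], n, T_)
    m <- apply(St, 1, max)
    ex <- exp(St - m)
    A[, t, ] <- ex / rowSums(ex)
  }
  Cs <- vector("list", T_)
  M <- matrix(0, n, d)
  for (t in seq_len(T_)) {
    Ct <- matrix(0, n, d)
    for (s in seq_len(T_)) Ct <- Ct + A[, t, s] * V[[s]]
    Cs[[t]] <- Ct
    M <- M + Ct / T_
  }
  logits <- M %*% par$Wo + matrix(par$bo, n, ncol(par$Wo), byrow = TRUE)
  list(prob = sigmoid(logits), E = E, Q = Q, K = K, V = V, A = A, M = M)
}

attn_backward <- function(par, X, Y, fwd) {
  n <- nrow(X); T_ <- ncol(X); d <- length(par$we); Kout <- ncol(Y)
  dlogit <- (fwd$prob - Y) / (n * Kout)
  g <- list(we = par$we * 0, P = par$P * 0, Wq = par$Wq * 0, Wk = par$Wk * 0,
            Wv = par$Wv * 0, Wo = crossprod(fwd$M, dlogit), bo = colSums(dlogit))
  dM <- dlogit %*% t(par$Wo)
  dE <- lapply(seq_len(T_), function(t) matrix(0, n, d))
  dV <- lapply(seq_len(T_), function(t) matrix(0, n, d))
  dQ <- lapply(seq_len(T_), function(t) matrix(0, n, d))
  dK <- lapply(seq_len(T_), function(t) matrix(0, n, d))
  for (t in seq_len(T_)) {
    dCt <- dM / T_
    # through the attention-weighted sum
    dS_t <- matrix(0, n, T_)                     # dL/dS[,t,s]
    for (s in seq_len(T_)) {
      dV[[s]] <- dV[[s]] + fwd$A[, t, s] * dCt
      dA_ts <- rowSums(dCt * fwd$V[[s]])
      dS_t[, s] <- dA_ts
    }
    # softmax backward over s
    At <- matrix(fwd$A[, t, ], n, T_)
    dS_t <- At * (dS_t - rowSums(dS_t * At))
    for (s in seq_len(T_)) {
      dQ[[t]] <- dQ[[t]] + dS_t[, s] * fwd$K[[s]] / sqrt(d)
      dK[[s]] <- dK[[s]] + dS_t[, s] * fwd$Q[[t]] / sqrt(d)
    }
  }
  for (t in seq_len(T_)) {
    g$Wq <- g$Wq + crossprod(fwd$E[[t]], dQ[[t]])
    g$Wk <- g$Wk + crossprod(fwd$E[[t]], dK[[t]])
    g$Wv <- g$Wv + crossprod(fwd$E[[t]], dV[[t]])
    dE[[t]] <- dE[[t]] + dQ[[t]] %*% t(par$Wq) + dK[[t]] %*% t(par$Wk) +
      dV[[t]] %*% t(par$Wv)
    g$we <- g$we + colSums(X[, t] * dE[[t]])
    g$P[t, ] <- g$P[t, ] + colSums(dE[[t]])
  }
  g
}

## ---- shared trainer -------------------------------------------------------

train_seqnet <- function(kind, X, Y, hidden = 12, d = 8, epochs = 250,
                         lr = 0.02, seed = 1) {
  with_local_seed(seed, {
    T_ <- ncol(X); K <- ncol(Y)
    par <- if (kind == "rnn") rnn_init(hidden, K) else attn_init(T_, d, K)
    st <- adam_init(par)
    for (e in seq_len(epochs)) {
      fwd <- if (kind == "rnn") rnn_forward(st$par, X) else attn_forward(st$par, X)
      grads <- if (kind == "rnn") rnn_backward(st$par, X, Y, fwd) else
        attn_backward(st$par, X, Y, fwd)
      st <- adam_update(st, grads, lr = lr)
    }
    st$par
  })
}

predict_seqnet <- function(kind, par, X) {
  fwd <- if (kind == "rnn") rnn_forward(par, X) else attn_forward(par, X)
  fwd$prob >= 0.5
}
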