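# Shared fixtures (built once per test run) and independent numeric oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  v <- .fixtures[[name]]
  if (is.null(v)) {
    v <- build()
    .fixtures[[name]] <- v
  }
  v
}

tiny_montage <- function() fixture("montage", function() make_montage(0))

tiny_session <- function() {
  fixture("session", function() {
    cfg <- sim_config(n_trials_per_class = 2L, trial_duration_s = 10, seed = 3L)
    simulate_session(cfg, tiny_montage(), 1L)
  })
}

tiny_views <- function() fixture("views", function() build_views(tiny_session()))

# central finite differences of fn at x
numgrad <- function(fn, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + eps
    xm <- x
    xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# brute-force oracle for one graph-convolution layer on a single sample
gcn_oracle <- function(H, A, W, b = rep(0, ncol(W))) {
  At <- pmax(A, 0) + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(At)))
  Z <- D %*% At %*% D %*% H %*% W
  pmax(sweep(Z, 2, b, "+"), 0)
}

# brute-force oracle for one additive graph-attention head (single sample),
# fully connected edge set with self-loops, LeakyReLU slope 0.2
gat_oracle <- function(H, W, a1, a2) {
  n <- nrow(H)
  Wh <- H %*% W
  f1 <- drop(Wh %*% a1)
  f2 <- drop(Wh %*% a2)
  lrelu <- function(x, s = 0.2) ifelse(x > 0, x, s * x)
  out <- matrix(0, n, ncol(Wh))
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- lrelu(f1[i] + f2)
    a <- exp(e - max(e))
    a <- a / sum(a)
    alpha[i, ] <- a
    out[i, ] <- lrelu(colSums(a * Wh))
  }
  list(output = out, alpha = alpha)
}

# brute-force scaled dot-product cross-attention oracle (single sample):
# queries from h2 attend over h1; returns the pooled attended vector
attention_oracle <- function(h1, h2, Wq, Wk, Wv, scale) {
  Q <- h2 %*% Wq
  K <- h1 %*% Wk
  V <- h1 %*% Wv
  S <- Q %*% t(K) / scale
  A <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r))
    e / sum(e)
  }))
  if (nrow(S) == 1L) A <- matrix(A, 1)
  colMeans(A %*% V)
}
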