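# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately take different computational routes than the
# package (SVD instead of the NIPALS inner loop, explicit lm() fits instead
# of the vectorized QR path) so agreement is evidence, not tautology.

# PLS via per-component SVD of the cross-product matrix: the dominant left
# singular vector of X'Y is the exact NIPALS fixed point for each component.
oracle_pls <- function(X, Y, A) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); J <- ncol(X)
  ssx <- sum(X^2); ssy <- sum(Y^2)
  Xa <- X
  W <- matrix(0, J, A); P <- matrix(0, J, A)
  Tm <- matrix(0, n, A); C <- matrix(0, ncol(Y), A)
  r2x <- r2y <- numeric(A)
  Yhat <- matrix(0, n, ncol(Y))
  for (a in seq_len(A)) {
    sv <- svd(crossprod(Xa, Y - Yhat), nu = 1, nv = 0)
    w <- sv$u[, 1]
    s <- sign(w[which.max(abs(w))]); w <- s * w
    t <- Xa %*% w
    tt <- drop(crossprod(t))
    p <- crossprod(Xa, t) / tt
    cc <- crossprod(Y - Yhat, t) / tt
    Xa <- Xa - tcrossprod(t, p)
    Yhat <- Yhat + tcrossprod(t, cc)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; C[, a] <- cc
    r2x[a] <- 1 - sum(Xa^2) / ssx
    r2y[a] <- 1 - sum((Y - Yhat)^2) / ssy
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  list(W = W, P = P, T = Tm, C = C, B = B, r2x = r2x, r2y = r2y)
}

# Q2 oracle reproducing the documented venetian-blinds assignment
# (fold f = sample position mod folds) with split-wise restandardization,
# but predicting through oracle_pls.
oracle_q2 <- function(X, Y, A, folds) {
  n <- nrow(X)
  fold_id <- rep_len(seq_len(folds), n)
  press <- numeric(A); ss <- 0
  for (f in seq_len(folds)) {
    te <- fold_id == f
    xm <- colMeans(X[!te, , drop = FALSE])
    xs <- apply(X[!te, , drop = FALSE], 2, sd); xs[xs == 0] <- 1
    Xtr <- sweep(sweep(X[!te, , drop = FALSE], 2, xm), 2, xs, `/`)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, xm), 2, xs, `/`)
    ym <- colMeans(Y[!te, , drop = FALSE])
    Ytr <- sweep(Y[!te, , drop = FALSE], 2, ym)
    Yte <- sweep(Y[te, , drop = FALSE], 2, ym)
    for (a in seq_len(A)) {
      o <- oracle_pls(Xtr, Ytr, a)
      press[a] <- press[a] + sum((Yte - Xte %*% o$B)^2)
    }
    ss <- ss + sum(Yte^2)
  }
  1 - press / ss
}

# exhaustive hypergeometric upper tail for small universes
oracle_hyper_upper <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random centered/scaled regression instance
random_instance <- function(seed, n = 20, J = 6, M = 1, noise = 0.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * J), n, J))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  B <- matrix(rnorm(J * M), J, M)
  Y <- scale(X %*% B + noise * matrix(rnorm(n * M), n, M), scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  list(X = X, Y = Y)
}

# small balanced factorial design for unit tests
tiny_design <- function(n_cell = 3, speed = FALSE) {
  n <- 4 * n_cell
  sp <- if (speed) 20 + seq_len(n) else NULL
  study_design(sprintf("s%02d", seq_len(n)),
               rep(c("HCR", "LCR", "HCR", "LCR"), each = n_cell),
               rep(c("Y", "Y", "O", "O"), each = n_cell),
               speed = sp)
}

# one simulated tissue, aligned and preprocessed; kept small for speed
small_processed_study <- function(seed, J = 20, ...) {
  sim <- simulate_study(simulation_config(tissues = c(serum = J), seed = seed,
                                          ...))
  al <- align(sim$matrices$serum, sim$design)
  pp <- preprocess_matrix(al$matrix, al$design)
  list(X = pp$matrix$values, design = al$design, matrix = pp$matrix,
       spec = pp$spec, truth = sim$truth)
}

`%+%` <- function(a, b) paste0(a, b)
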