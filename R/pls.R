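#' Build a PLS response matrix from the study design
#'
#' @param design A `StudyDesign`.
#' @param mode One of:
#'   * `"four_class"` — n x 4 one-hot class membership over
#'     HCR-Y / LCR-Y / HCR-O / LCR-O, column-centered (PLS-DA);
#'   * `"capacity"` — single centered column, HCR = +1, LCR = -1;
#'   * `"age"` — single centered column, O = +1, Y = -1;
#'   * `"speed"` — single centered, unit-variance-scaled running-speed
#'     column (PLS regression).
#' @return Numeric matrix with n rows; attribute `"y_coding"` describes the
#'   construction and, for class modes, attribute `"classes"` carries the
#'   per-sample class labels (used for stratified cross-validation).
#' @export
build_response <- function(design, mode = c("four_class", "capacity", "age",
                                            "speed")) {
  mode <- match.arg(mode)
  n <- nrow(design)
  if (mode == "four_class") {
    lev <- c("HCR-Y", "LCR-Y", "HCR-O", "LCR-O")
    cls <- paste(design$capacity, design$age, sep = "-")
    Y <- sapply(lev, function(l) as.numeric(cls == l))
    Y <- scale(Y, scale = FALSE)
    attr(Y, "classes") <- cls
  } else if (mode == "speed") {
    if (!"speed" %in% names(design) || anyNA(design$speed))
      stop("mode 'speed' requires a complete speed column in the design")
    Y <- scale(matrix(design$speed, ncol = 1))
    colnames(Y) <- "speed"
  } else {
    pm <- if (mode == "capacity") {
      ifelse(design$capacity == "HCR", 1, -1)
    } else {
      ifelse(design$age == "O", 1, -1)
    }
    Y <- scale(matrix(pm, ncol = 1), scale = FALSE)
    colnames(Y) <- mode
    attr(Y, "classes") <- as.character(if (mode == "capacity") design$capacity
                                       else design$age)
  }
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  attr(Y, "y_coding") <- mode
  Y
}

#' Fit a PLS model by NIPALS
#'
#' Wold's NIPALS with X-deflation per component (PLS2 regression mode).
#' The inner loop starts from the response column with the largest variance
#' and iterates to a relative weight change below `tol` or `max_iter`
#' iterations. Each weight vector's largest-magnitude element is made
#' positive, so results are deterministic up to that sign convention.
#'
#' @param X Centered (and typically unit-variance scaled) predictor matrix.
#' @param Y Centered response matrix (single or multiple columns).
#' @param A Number of components; truncated with a warning if it exceeds
#'   the effective rank of `X`.
#' @param tol Inner-loop relative convergence tolerance.
#' @param max_iter Inner-loop iteration cap.
#' @return Object of class `PLSModel` with weights `W` (J x A), X-loadings
#'   `P`, X-scores `T`, Y-loadings `C`, coefficient matrix `B`, cumulative
#'   `r2x`/`r2y` per component, per-component explained response sum of
#'   squares `ssy_comp`, and `vip`.
#' @export
fit_pls <- function(X, Y, A = 2, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X); J <- ncol(X); M <- ncol(Y)
  ssx_tot <- sum(X^2); ssy_tot <- sum(Y^2)
  if (ssx_tot == 0) stop("X has zero variance")
  if (ssy_tot == 0) stop("Y has zero variance")
  W <- matrix(0, J, A); P <- matrix(0, J, A)
  Tm <- matrix(0, n, A); C <- matrix(0, M, A)
  Xa <- X
  r2x <- numeric(A); r2y <- numeric(A); ssy_comp <- numeric(A)
  Yres <- Y
  a_used <- 0L
  for (a in seq_len(A)) {
    # NIPALS inner loop in its compact form: the classic
    # u -> w = X'u -> t = Xw -> c = Y't -> u = Yc cycle updates
    # w proportionally to (X'Y)(Y'X) w, so iterating on Z = X'Y gives the
    # identical weight sequence at a fraction of the cost per iteration.
    Z <- crossprod(Xa, Yres)                    # J x M
    j0 <- which.max(colSums(Yres^2) / (n - 1))  # start: max-variance Y column
    w <- Z[, j0, drop = TRUE]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    if (M > 1) {
      for (it in seq_len(max_iter)) {
        w_new <- Z %*% crossprod(Z, w)
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- sqrt(sum((w_new - w)^2))
        w <- w_new
        if (delta < tol) break
      }
    }
    t <- Xa %*% w
    tt <- drop(crossprod(t))
    if (tt < 1e-12 * ssx_tot / max(1, J)) break  # rank exhausted
    # sign convention: largest-|.| weight element positive
    s <- sign(w[which.max(abs(w))])
    if (s < 0) { w <- -w; t <- -t }
    p <- crossprod(Xa, t) / tt
    cc <- crossprod(Yres, t) / tt
    Xa <- Xa - tcrossprod(t, p)
    Yhat_a <- tcrossprod(t, cc)
    Yres <- Yres - Yhat_a
    a_used <- a
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; C[, a] <- cc
    ssy_comp[a] <- sum(Yhat_a^2)
    r2x[a] <- 1 - sum(Xa^2) / ssx_tot
    r2y[a] <- 1 - sum(Yres^2) / ssy_tot
  }
  if (a_used == 0L) stop("no PLS component could be extracted")
  if (a_used < A) {
    warning("requested ", A, " components but rank supports only ", a_used,
            "; truncating")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    C <- C[, seq_len(a_used), drop = FALSE]
    r2x <- r2x[seq_len(a_used)]; r2y <- r2y[seq_len(a_used)]
    ssy_comp <- ssy_comp[seq_len(a_used)]
  }
  # regression coefficients on the (centered/scaled) X scale
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(C)
  model <- structure(list(
    n_components = a_used, W = W, P = P, T = Tm, C = C, B = B,
    r2x = r2x, r2y = r2y, ssy_comp = ssy_comp,
    y_coding = attr(Y, "y_coding"),
    dimnames = list(predictors = colnames(X), responses = colnames(Y),
                    samples = rownames(X))
  ), class = "PLSModel")
  model$vip <- compute_vip(model)
  model
}

#' @export
print.PLSModel <- function(x, ...) {
  cat(sprintf("PLSModel: %d component(s); R2X = %.3f, R2Y = %.3f\n",
              x$n_components, x$r2x[x$n_components], x$r2y[x$n_components]))
  invisible(x)
}

#' Predict responses from a fitted PLS model
#'
#' @param object A `PLSModel`.
#' @param newdata Predictor matrix on the same (centered/scaled) scale as
#'   the training `X`.
#' @param ... Unused.
#' @return Predicted response matrix.
#' @export
predict.PLSModel <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$B
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( J * sum_a [ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )`
#' where `SSY_a` is the response sum of squares explained by component `a`.
#' By construction the mean of `VIP^2` over the J predictors is 1.
#'
#' @param model A fitted `PLSModel`.
#' @return Numeric vector of per-predictor VIP values.
#' @export
compute_vip <- function(model) {
  W <- model$W
  J <- nrow(W)
  ssy <- model$ssy_comp
  Wn2 <- sweep(W^2, 2, colSums(W^2), `/`)
  vip <- sqrt(J * drop(Wn2 %*% ssy) / sum(ssy))
  names(vip) <- model$dimnames$predictors
  vip
}

# fold assignment: venetian blinds interleaves samples in order; random is
# seeded; loo ignores `folds`. With strata, assignment interleaves within
# each stratum so every training split keeps all classes whenever possible.
.make_folds <- function(n, folds, scheme, seed = NULL, strata = NULL) {
  if (scheme == "loo") return(seq_len(n))
  if (folds < 2) stop("folds must be >= 2")
  if (scheme == "random" && !is.null(seed)) set.seed(as.integer(seed))
  out <- integer(n)
  blocks <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  for (idx in blocks) {
    if (scheme == "random") idx <- idx[sample.int(length(idx))]
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS / SS` per cumulative component, with PRESS accumulated
#' over held-out predictions from models refit on each training split.
#' Column centering/scaling of X and centering of Y are re-estimated inside
#' each training split and applied to the held-out block; SS is the total
#' response sum of squares of the held-out rows about the training means.
#'
#' @param X Predictor matrix (centered/scaled or raw; split-wise
#'   standardization is applied regardless).
#' @param Y Response matrix.
#' @param A Number of components.
#' @param folds Number of folds (ignored for `scheme = "loo"`).
#' @param scheme `"venetian_blinds"` (default), `"random"`, or `"loo"`.
#' @param seed Seed for `scheme = "random"`.
#' @param strata Optional per-sample labels; folds are stratified over them
#'   and a training split losing an entire stratum is an error.
#' @return Numeric vector `q2[1..A]` (cumulative components).
#' @export
cross_validate_q2 <- function(X, Y, A = 2,
                              folds = 7,
                              scheme = c("venetian_blinds", "random", "loo"),
                              seed = NULL, strata = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold_id <- .make_folds(n, folds, scheme, seed = seed, strata = strata)
  press <- numeric(A); ss <- 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    Ytr <- Y[!test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]
    if (!is.null(strata) &&
        !all(unique(strata) %in% strata[!test]))
      stop("a training split lost an entire class; use a stratified scheme ",
           "or fewer folds")
    xm <- colMeans(Xtr)
    xs <- apply(Xtr, 2, stats::sd)
    xs[xs == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, xm), 2, xs, `/`)
    Xte <- sweep(sweep(Xte, 2, xm), 2, xs, `/`)
    ym <- colMeans(Ytr)
    Ytr <- sweep(Ytr, 2, ym)
    Yte <- sweep(Yte, 2, ym)
    fit <- suppressWarnings(fit_pls(Xtr, Ytr, A = A))
    # cumulative predictions per component
    for (a in seq_len(A)) {
      aa <- min(a, fit$n_components)
      Ra <- fit$W[, 1:aa, drop = FALSE] %*%
        solve(crossprod(fit$P[, 1:aa, drop = FALSE],
                        fit$W[, 1:aa, drop = FALSE]))
      Ba <- Ra %*% t(fit$C[, 1:aa, drop = FALSE])
      press[a] <- press[a] + sum((Yte - Xte %*% Ba)^2)
    }
    ss <- ss + sum(Yte^2)
  }
  1 - press / ss
}

#' Permutation validation of a PLS model
#'
#' Refits the model on `G` row-permutations of the response, recording each
#' permuted fit's R2Y and cross-validated Q2 together with the similarity
#' between the permuted and original response (mean absolute column-wise
#' Pearson correlation). The permutation p-value uses the add-one
#' estimator `(1 + #\{perm Q2 >= observed\}) / (G + 1)`; the R2/Q2
#' intercepts come from least-squares lines through the G permuted points
#' plus the observed point at similarity 1.
#'
#' @inheritParams cross_validate_q2
#' @param G Number of permutations (the study convention is 200 per model).
#' @param seed Integer seed driving the permutations.
#' @return Object of class `PermutationResult`: `G`, `observed_q2`,
#'   `observed_r2y`, `perm_q2`, `perm_r2y`, `perm_similarity`,
#'   `q2_intercept`, `r2_intercept`, `p_value`.
#' @export
permutation_validate <- function(X, Y, A = 2, G = 200, folds = 7,
                                 scheme = c("venetian_blinds", "random", "loo"),
                                 seed = 1L, strata = NULL) {
  scheme <- match.arg(scheme)
  if (G < 1) stop("G must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (all(apply(Y, 2, stats::sd) == 0)) stop("constant response")
  obs_fit <- fit_pls(X, Y, A = A)
  obs_q2 <- cross_validate_q2(X, Y, A = A, folds = folds, scheme = scheme,
                              seed = seed, strata = strata)
  obs_q2 <- obs_q2[length(obs_q2)]
  set.seed(as.integer(seed))
  n <- nrow(Y)
  perm_q2 <- numeric(G); perm_r2y <- numeric(G); sim <- numeric(G)
  for (g in seq_len(G)) {
    perm <- sample.int(n)
    Yp <- Y[perm, , drop = FALSE]
    sp <- if (is.null(strata)) NULL else strata[perm]
    sim[g] <- mean(abs(diag(suppressWarnings(stats::cor(Yp, Y)))), na.rm = TRUE)
    fit_p <- suppressWarnings(fit_pls(X, Yp, A = A))
    perm_r2y[g] <- fit_p$r2y[fit_p$n_components]
    q2g <- cross_validate_q2(X, Yp, A = A, folds = folds, scheme = scheme,
                             seed = seed, strata = sp)
    perm_q2[g] <- q2g[length(q2g)]
  }
  p_value <- (1 + sum(perm_q2 >= obs_q2)) / (G + 1)
  q2_line <- stats::lm.fit(cbind(1, c(sim, 1)), c(perm_q2, obs_q2))
  r2_line <- stats::lm.fit(cbind(1, c(sim, 1)),
                           c(perm_r2y, obs_fit$r2y[obs_fit$n_components]))
  structure(list(
    G = G, observed_q2 = obs_q2,
    observed_r2y = obs_fit$r2y[obs_fit$n_components],
    perm_q2 = perm_q2, perm_r2y = perm_r2y, perm_similarity = sim,
    q2_intercept = unname(q2_line$coefficients[1]),
    r2_intercept = unname(r2_line$coefficients[1]),
    p_value = p_value
  ), class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(paste0("PermutationResult (G = %d): Q2 = %.3f, ",
                     "Q2 intercept = %.3f, p = %.4g\n"),
              x$G, x$observed_q2, x$q2_intercept, x$p_value))
  invisible(x)
}

#' Export component scores for plotting
#'
#' @param model A fitted `PLSModel` with at least 2 components.
#' @param design The aligned `StudyDesign`.
#' @return Data frame with `sample_id`, `t1`, `t2`, `group`.
#' @export
export_scores <- function(model, design) {
  if (model$n_components < 2)
    stop("score export needs a model with at least 2 components")
  data.frame(sample_id = design$sample_id,
             t1 = model$T[, 1], t2 = model$T[, 2],
             group = paste(design$capacity, design$age, sep = "-"),
             stringsAsFactors = FALSE)
}
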