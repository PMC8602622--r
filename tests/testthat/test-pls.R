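test_that("build_response encodes the design correctly in every mode", {
  d4 <- study_design(paste0("s", 1:4), c("HCR", "LCR", "HCR", "LCR"),
                     c("Y", "Y", "O", "O"))
  Y4 <- build_response(d4, "four_class")
  expect_equal(dim(Y4), c(4L, 4L))
  expect_equal(unname(colSums(Y4)), rep(0, 4))
  # one sample per group: un-centering recovers a permutation-like one-hot
  raw <- sweep(Y4, 2, colMeans(diag(4)), `+`)
  expect_equal(sort(unique(c(raw))), c(0, 1))
  expect_equal(unname(rowSums(raw)), rep(1, 4))
  expect_equal(attr(Y4, "classes"), c("HCR-Y", "LCR-Y", "HCR-O", "LCR-O"))

  d20 <- tiny_design(n_cell = 5)
  Yc <- build_response(d20, "capacity")
  expect_equal(sum(Yc), 0, tolerance = 1e-12)
  expect_length(unique(round(Yc, 10)), 2)

  # study-shaped design keeps the 10/10/6/8 counts in the one-hot columns
  sim <- simulate_study(simulation_config(seed = 2))
  Y <- build_response(sim$design, "four_class")
  expect_equal(as.integer(table(attr(Y, "classes"))[c("HCR-Y", "LCR-Y",
                                                      "HCR-O", "LCR-O")]),
               c(10L, 10L, 6L, 8L))
  Ys <- build_response(sim$design, "speed")
  expect_equal(sd(Ys), 1, tolerance = 1e-12)
  d_nospeed <- study_design("s1", "HCR", "Y")
  expect_error(build_response(d_nospeed, "speed"), "speed")
})

test_that("one-component weight equals the normalized X'Y closed form", {
  for (s in 1:5) {
    inst <- random_instance(s, n = 15, J = 8, M = 1)
    fit <- fit_pls(inst$X, inst$Y, A = 1)
    w_ref <- drop(crossprod(inst$X, inst$Y))
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    w_ref <- w_ref * sign(w_ref[which.max(abs(w_ref))])
    expect_equal(drop(fit$W), w_ref, tolerance = 1e-10)
  }
})

test_that("exact linear responses are fit perfectly and PLS reaches the OLS limit", {
  set.seed(31)
  X <- scale(matrix(rnorm(20 * 4), 20, 4))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- X %*% c(1, -2, 0.5, 3)
  y <- y - mean(y)
  fit2 <- fit_pls(X, y, A = 2)
  fit4 <- fit_pls(X, y, A = 4)
  expect_lt(1 - fit4$r2y[4], 1e-10)
  # full-rank single-response PLS = OLS predictions
  inst <- random_instance(77, n = 25, J = 5, M = 1, noise = 1)
  fit <- fit_pls(inst$X, inst$Y, A = 5)
  ols <- inst$X %*% solve(crossprod(inst$X), crossprod(inst$X, inst$Y))
  expect_equal(predict(fit, inst$X), ols, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("scores are orthogonal and deflation conserves X sum of squares", {
  for (s in 1:5) {
    inst <- random_instance(s + 100, n = 18, J = 10, M = 3, noise = 1)
    fit <- fit_pls(inst$X, inst$Y, A = 3)
    G <- crossprod(fit$T)
    off <- max(abs(G[upper.tri(G)])) / min(diag(G))
    expect_lt(off, 1e-8)
    # sum over components of ||t p'||^2 + residual = total
    Xres <- inst$X
    expl <- 0
    for (a in 1:3) {
      ta <- fit$T[, a]; pa <- fit$P[, a]
      expl <- expl + sum(tcrossprod(ta, pa)^2)
      Xres <- Xres - tcrossprod(ta, pa)
    }
    expect_equal(expl + sum(Xres^2), sum(inst$X^2), tolerance = 1e-8)
    expect_true(all(diff(c(0, fit$r2x)) > -1e-12))
    expect_true(all(diff(c(0, fit$r2y)) > -1e-12))
  }
})

test_that("fit matches the independent SVD-based reference", {
  for (s in 1:6) {
    inst <- random_instance(s + 200, n = 16, J = 7,
                            M = if (s %% 2) 1 else 3, noise = 0.8)
    fit <- fit_pls(inst$X, inst$Y, A = 2)
    ref <- oracle_pls(inst$X, inst$Y, 2)
    expect_equal(fit$r2x, ref$r2x, tolerance = 1e-6)
    expect_equal(fit$r2y, ref$r2y, tolerance = 1e-6)
    expect_equal(abs(fit$W), abs(ref$W), tolerance = 1e-6)
    expect_equal(fit$B, ref$B, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("weights agree with mixOmics up to component sign", {
  skip_if_not_installed("mixOmics")
  inst <- random_instance(17, n = 20, J = 9, M = 2, noise = 0.6)
  fit <- fit_pls(inst$X, inst$Y, A = 2)
  mo <- mixOmics::pls(inst$X, inst$Y, ncomp = 2, mode = "regression",
                      scale = FALSE)
  for (a in 1:2) {
    agreement <- abs(sum(fit$W[, a] * mo$loadings$X[, a]))
    expect_equal(agreement, 1, tolerance = 1e-6)
  }
})

test_that("VIP satisfies its normalization identities", {
  inst1 <- random_instance(5, n = 12, J = 1, M = 1)
  fit1 <- fit_pls(inst1$X, inst1$Y, A = 1)
  expect_equal(unname(fit1$vip), 1)
  # two identical predictors share VIP
  set.seed(41)
  x <- rnorm(14); x <- (x - mean(x)) / sd(x)
  X <- cbind(a = x, b = x)
  y <- matrix(x * 2 + rnorm(14, sd = 0.1)); y <- y - mean(y)
  fit_dup <- suppressWarnings(fit_pls(X, y, A = 1))
  expect_equal(fit_dup$vip[["a"]], fit_dup$vip[["b"]], tolerance = 1e-10)
  for (s in 1:5) {
    inst <- random_instance(s + 300, n = 15, J = 6, M = 2)
    fit <- fit_pls(inst$X, inst$Y, A = 2)
    expect_equal(sum(fit$vip^2), 6, tolerance = 1e-8)
  }
})

test_that("Q2 approaches 1 in the noiseless limit and stays below R2Y", {
  set.seed(51)
  X <- scale(matrix(rnorm(24 * 4), 24, 4))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  y <- X %*% c(2, -1, 1, 0.5); y <- y - mean(y)
  q2 <- cross_validate_q2(X, y, A = 4, scheme = "loo")
  expect_gt(q2[4], 1 - 1e-6)
  # with noise, Q2 <= R2Y for matched components
  for (s in 1:5) {
    inst <- random_instance(s + 400, n = 22, J = 6, M = 1, noise = 1.5)
    fit <- fit_pls(inst$X, inst$Y, A = 2)
    q2n <- cross_validate_q2(inst$X, inst$Y, A = 2, folds = 7)
    expect_lt(q2n[2], fit$r2y[2] + 1e-10)
  }
})

test_that("Q2 matches the independent CV oracle on the venetian-blinds scheme", {
  for (s in 1:4) {
    inst <- random_instance(s + 500, n = 21, J = 6, M = 2, noise = 1)
    q2 <- cross_validate_q2(inst$X, inst$Y, A = 2, folds = 7)
    expect_equal(q2, oracle_q2(inst$X, inst$Y, 2, 7), tolerance = 1e-6)
  }
})

test_that("fold schemes respect stratification and reject lost classes", {
  sim <- simulate_study(simulation_config(seed = 3))
  al <- align(sim$matrices$wat, sim$design)
  pp <- preprocess_matrix(al$matrix, al$design)
  Y <- build_response(al$design, "four_class")
  q2 <- cross_validate_q2(pp$matrix$values, Y, A = 2, folds = 6,
                          strata = attr(Y, "classes"))
  expect_length(q2, 2)
  # folds > smallest class without stratification must fail the class check
  expect_error(
    cross_validate_q2(pp$matrix$values, Y, A = 2, folds = 7,
                      scheme = "loo", strata = attr(Y, "classes")),
    NA)  # loo keeps classes: n - 1 samples always retain every class here
  expect_error(cross_validate_q2(pp$matrix$values, Y, A = 2, folds = 1),
               "folds")
})

test_that("permutation validation: G=1 enumerates to p in {1/2, 1}", {
  inst <- random_instance(61, n = 16, J = 5, M = 1, noise = 1)
  ps <- vapply(1:12, function(s)
    permutation_validate(inst$X, inst$Y, A = 2, G = 1, folds = 4,
                         seed = s)$p_value, numeric(1))
  expect_true(all(ps %in% c(0.5, 1)))
})

test_that("permutation validation flags a real effect and stores recomputable intercepts", {
  sim <- simulate_study(simulation_config(
    tissues = c(serum = 30), effect_capacity = 2, effect_age = 2,
    effect_interaction = 2, frac_affected = 0.5, seed = 13))
  al <- align(sim$matrices$serum, sim$design)
  pp <- preprocess_matrix(al$matrix, al$design)
  Y <- build_response(al$design, "four_class")
  pr <- permutation_validate(pp$matrix$values, Y, A = 2, G = 39, folds = 7,
                             seed = 8, strata = attr(Y, "classes"))
  expect_equal(pr$p_value, 1 / 40)
  expect_lt(pr$q2_intercept, 0)
  expect_gt(pr$observed_q2, max(pr$perm_q2))
  # intercept recomputable from the stored points
  line <- lm(c(pr$perm_q2, pr$observed_q2) ~ c(pr$perm_similarity, 1))
  expect_equal(unname(coef(line)[1]), pr$q2_intercept, tolerance = 1e-10)
  expect_error(permutation_validate(pp$matrix$values,
                                    matrix(1, nrow(pp$matrix$values)), A = 1,
                                    G = 2, seed = 1),
               "constant response")
})

test_that("score export carries scores and group labels through unchanged", {
  sim <- simulate_study(simulation_config(tissues = c(muscle = 12), seed = 9))
  al <- align(sim$matrices$muscle, sim$design)
  pp <- preprocess_matrix(al$matrix, al$design)
  Y <- build_response(al$design, "four_class")
  fit <- fit_pls(pp$matrix$values, Y, A = 2)
  tab <- export_scores(fit, al$design)
  expect_equal(nrow(tab), 34)
  expect_identical(tab$t1, unname(fit$T[, 1]))
  expect_identical(tab$t2, unname(fit$T[, 2]))
  expect_setequal(unique(tab$group), c("HCR-Y", "LCR-Y", "HCR-O", "LCR-O"))
  fit1 <- fit_pls(pp$matrix$values, Y, A = 1)
  expect_error(export_scores(fit1, al$design), "at least 2 components")
})
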