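test_that("boxcox matches its closed forms and rejects nonpositive input", {
  expect_equal(boxcox(c(1, exp(1), exp(2)), 0), c(0, 1, 2))
  x <- c(0.5, 1, 7.25)
  expect_equal(boxcox(x, 1), x - 1)
  expect_equal(boxcox(c(4, 9), 0.5), c(2, 4))
  expect_error(boxcox(c(1, 0), 0.5), "strictly positive")
  expect_error(boxcox(c(1, -2), 0), "strictly positive")
})

test_that("boxcox is strictly increasing for every lambda", {
  set.seed(3)
  x <- sort(rexp(50) + 0.01)
  for (l in c(-2, -0.5, 0, 0.3, 1, 2)) {
    expect_true(all(diff(boxcox(x, l)) > 0), label = paste("lambda", l))
  }
})

test_that("design residual moments match the bias-corrected oracle", {
  skip_if_not_installed("e1071")
  d <- tiny_design(n_cell = 5)
  set.seed(8)
  for (rep in 1:10) {
    v <- rnorm(20) + rep(rnorm(4, sd = 2), each = 5)
    mom <- design_residual_moments(v, d)
    res <- unlist(lapply(split(v, paste(d$capacity, d$age)),
                         function(g) g - mean(g)), use.names = FALSE)
    expect_equal(mom$skew, e1071::skewness(res, type = 2), tolerance = 1e-12)
    expect_equal(mom$kurtosis, e1071::kurtosis(res, type = 2), tolerance = 1e-12)
  }
})

test_that("symmetric residual patterns give zero skew; an outlier inflates it", {
  d <- tiny_design(n_cell = 4)
  means <- rep(c(10, 20, 30, 40), each = 4)
  v <- means + rep(c(-1, -0.5, 0.5, 1), times = 4)
  mom <- design_residual_moments(v, d)
  expect_equal(mom$skew, 0, tolerance = 1e-12)

  v_out <- v; v_out[1] <- v_out[1] + 50
  expect_gt(abs(design_residual_moments(v_out, d)$skew), 2)
  # and the criterion cannot be rescued at any lambda on positive data
  sp <- select_lambda(v_out, d)
  expect_false(sp$feasible)
})

test_that("a cell with fewer than 2 samples is rejected", {
  d <- study_design(paste0("s", 1:7),
                    c("HCR", "HCR", "LCR", "LCR", "HCR", "LCR", "LCR"),
                    c("Y", "Y", "Y", "Y", "O", "O", "O"))
  expect_error(design_residual_moments(rnorm(7), d), "at least 2 samples")
})

test_that("select_lambda recovers the generative exponent", {
  d <- tiny_design(n_cell = 8)
  set.seed(14)
  # truth lambda = 0: exp(Normal) data
  sel0 <- replicate(40, {
    v <- exp(rnorm(32, mean = 2, sd = 0.5))
    select_lambda(v, d)$lambda
  })
  expect_lte(abs(median(sel0)), 0.25)
  # truth lambda = 1: already-Normal data with a wide enough coefficient of
  # variation that curvature in the transform is detectable
  sel1 <- replicate(40, {
    v <- rnorm(32, mean = 15, sd = 4)
    select_lambda(v, d)$lambda
  })
  expect_lte(median(abs(sel1 - 1)), 0.6)
  expect_gte(mean(abs(sel1 - 1) <= 1), 0.85)
})

test_that("select_lambda flags degenerate and shifted inputs", {
  d <- tiny_design(n_cell = 3)
  sp <- select_lambda(rep(5, 12), d)
  expect_true(sp$degenerate)
  expect_false(sp$feasible)
  # nonpositive values get an automatic positive shift
  set.seed(2)
  v <- rnorm(12)
  sp2 <- select_lambda(v, d)
  expect_gt(sp2$shift, 0)
  expect_false(sp2$degenerate)
})

test_that("feasible flag is consistent with recomputed residual moments", {
  st <- small_processed_study(seed = 77, J = 25)
  sim <- simulate_study(simulation_config(tissues = c(serum = 25), seed = 77))
  al <- align(sim$matrices$serum, sim$design)
  for (j in which(st$spec$feasible)) {
    v <- boxcox(al$matrix$values[, st$spec$metabolite[j]] + st$spec$shift[j],
                st$spec$lambda[j])
    mom <- design_residual_moments(v, al$design)
    expect_lt(abs(mom$skew), 2)
    expect_lt(abs(mom$kurtosis), 2)
  }
})

test_that("unit-variance scaling centers, scales, drops constants, and is idempotent", {
  expect_equal(sd(unit_variance_scale(matrix(c(0, 2), 2, 1))$values), 1)
  set.seed(6)
  m <- matrix(rnorm(60, sd = 4), 12, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  sc <- unit_variance_scale(m)
  expect_equal(unname(apply(sc$values, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(colMeans(sc$values)), rep(0, 5), tolerance = 1e-12)
  twice <- unit_variance_scale(sc$values)
  expect_equal(twice$values, sc$values, tolerance = 1e-12)
  m2 <- cbind(m, const = 7)
  expect_warning(out <- unit_variance_scale(m2), "zero-variance")
  expect_equal(ncol(out$values), 5)
})

test_that("boxcox preserves within-column rank order through preprocessing", {
  st <- small_processed_study(seed = 19, J = 10)
  sim <- simulate_study(simulation_config(tissues = c(serum = 10), seed = 19))
  raw <- align(sim$matrices$serum, sim$design)$matrix$values
  for (m in colnames(st$X)) {
    expect_equal(order(st$X[, m]), order(raw[, m]), label = m)
  }
})

test_that("preprocess_matrix emits one spec row per metabolite and an identity path", {
  st <- small_processed_study(seed = 55, J = 15)
  expect_equal(nrow(st$spec), 15)
  expect_true(all(st$spec$retained[st$spec$feasible]))
  # lambda grid restricted to {1} reduces to plain centering/scaling
  sim <- simulate_study(simulation_config(tissues = c(serum = 8), seed = 3))
  al <- align(sim$matrices$serum, sim$design)
  pp1 <- preprocess_matrix(al$matrix, al$design, grid = 1)
  direct <- unit_variance_scale(al$matrix$values)$values
  expect_equal(pp1$matrix$values, direct, tolerance = 1e-12)
})
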