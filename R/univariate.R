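# Design matrices use treatment dummies with reference LCR, Young:
#   capacity = 1 for HCR, age = 1 for Old, interaction = their product.
# So beta_capacity is the HCR effect among the young and beta_interaction
# the extra old-HCR effect.
.group_design_matrix <- function(design) {
  cap <- as.numeric(design$capacity == "HCR")
  old <- as.numeric(design$age == "O")
  cbind(intercept = 1, capacity = cap, age = old, interaction = cap * old)
}

# OLS with coefficient table and the partial F of `full` vs `reduced`
# (column subsets of the same design matrix); returns NULL on singular fit
.ols_partial_f <- function(y, X_full, X_reduced) {
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) return(NULL)
  n <- length(y)
  beta <- qr.coef(qr_full, y)
  res_full <- qr.resid(qr_full, y)
  rss_full <- sum(res_full^2)
  df_res <- n - ncol(X_full)
  if (df_res <= 0) return(NULL)
  sigma2 <- rss_full / df_res
  XtX_inv <- chol2inv(qr.R(qr_full))
  se <- setNames(sqrt(sigma2 * diag(XtX_inv)), names(beta))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  rss_red <- sum(qr.resid(qr(X_reduced), y)^2)
  df_num <- ncol(X_full) - ncol(X_reduced)
  Fstat <- ((rss_red - rss_full) / df_num) / sigma2
  joint_p <- stats::pf(Fstat, df_num, df_res, lower.tail = FALSE)
  list(beta = beta, se = se, t = tval, p = pval,
       joint_F = Fstat, joint_p = joint_p, df = c(df_num, df_res), n = n)
}

#' Two-factor interaction model for one metabolite
#'
#' Ordinary least squares of the (transformed, scaled) metabolite on
#' capacity + age + capacity x age with treatment dummies (reference LCR,
#' Young), plus the 3-df joint F-test of the full factor block against the
#' intercept-only model — the "combined impact" p-value used with the VIP
#' rule.
#'
#' @param values Numeric vector (one metabolite), aligned with `design`.
#' @param design A `StudyDesign` with all four cells nonempty.
#' @return One-row data frame: `beta_capacity`, `beta_age`,
#'   `beta_interaction`, their `se_*`/`p_*`, `joint_F`, `joint_p`, `n_used`.
#' @export
fit_group_model <- function(values, design) {
  if (length(values) != nrow(design))
    stop("values and design have different lengths")
  if (any(table(design$capacity, design$age) == 0))
    stop("empty capacity x age cell; two-factor model is rank deficient")
  X <- .group_design_matrix(design)
  fit <- .ols_partial_f(values, X, X[, 1, drop = FALSE])
  if (is.null(fit)) stop("singular two-factor fit")
  data.frame(beta_capacity = fit$beta[["capacity"]],
             beta_age = fit$beta[["age"]],
             beta_interaction = fit$beta[["interaction"]],
             se_capacity = fit$se[["capacity"]],
             se_age = fit$se[["age"]],
             se_interaction = fit$se[["interaction"]],
             p_capacity = fit$p[["capacity"]],
             p_age = fit$p[["age"]],
             p_interaction = fit$p[["interaction"]],
             joint_F = fit$joint_F, joint_p = fit$joint_p, n_used = fit$n)
}

#' Running-speed association model for one metabolite
#'
#' OLS of speed on age + capacity + age x capacity + metabolite +
#' metabolite x age + metabolite x capacity + metabolite x age x capacity,
#' with the 4-df joint partial F of the metabolite-related block against
#' the design-only reduced model. A singular fit (e.g. a metabolite
#' constant within a cell) yields a flagged row with missing statistics
#' rather than an error.
#'
#' @param speed Numeric response vector (m/min).
#' @param metabolite Transformed metabolite vector (entered uncentered).
#' @param design Aligned `StudyDesign`.
#' @return One-row data frame: metabolite-block coefficients `beta_met`,
#'   `beta_met_age`, `beta_met_capacity`, `beta_met_age_capacity`,
#'   `joint_F`, `joint_p`, `singular`, `n_used`.
#' @export
fit_speed_model <- function(speed, metabolite, design) {
  if (anyNA(speed)) stop("speed contains missing values")
  D <- .group_design_matrix(design)
  met_block <- cbind(met = metabolite,
                     met_age = metabolite * D[, "age"],
                     met_capacity = metabolite * D[, "capacity"],
                     met_age_capacity = metabolite * D[, "interaction"])
  fit <- .ols_partial_f(speed, cbind(D, met_block), D)
  if (is.null(fit)) {
    return(data.frame(beta_met = NA_real_, beta_met_age = NA_real_,
                      beta_met_capacity = NA_real_,
                      beta_met_age_capacity = NA_real_,
                      joint_F = NA_real_, joint_p = NA_real_,
                      singular = TRUE, n_used = length(speed)))
  }
  data.frame(beta_met = fit$beta[["met"]],
             beta_met_age = fit$beta[["met_age"]],
             beta_met_capacity = fit$beta[["met_capacity"]],
             beta_met_age_capacity = fit$beta[["met_age_capacity"]],
             joint_F = fit$joint_F, joint_p = fit$joint_p,
             singular = FALSE, n_used = fit$n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH false-discovery-rate adjustment, preserving input order and
#' passing missing entries through.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Per-metabolite univariate analysis of a full tissue
#'
#' Applies [fit_group_model()] to every metabolite (vectorized over
#' metabolites, since all share one design matrix) and, when running speed
#' is available, [fit_speed_model()] with BH-FDR across the tissue's
#' metabolites.
#'
#' @param matrix A processed `MetaboliteMatrix` aligned with `design`.
#' @param design A `StudyDesign`.
#' @param with_speed Fit the speed-association models when a speed column
#'   exists (default `TRUE`).
#' @return List with `group` (one row per metabolite) and `speed` (one row
#'   per metabolite with `fdr_q`, or an empty data frame when speed is
#'   absent or disabled).
#' @export
run_univariate_suite <- function(matrix, design, with_speed = TRUE) {
  if (!identical(matrix$sample_ids, design$sample_id))
    stop("matrix and design are not aligned; call align() first")
  V <- matrix$values
  X <- .group_design_matrix(design)
  if (any(table(design$capacity, design$age) == 0))
    stop("empty capacity x age cell; two-factor model is rank deficient")
  # one QR for all metabolites
  qrX <- qr(X)
  n <- nrow(V)
  beta <- qr.coef(qrX, V)                       # 4 x J
  res <- qr.resid(qrX, V)
  rss_full <- colSums(res^2)
  df_res <- n - 4L
  sigma2 <- rss_full / df_res
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtX_inv), sigma2))      # 4 x J
  rownames(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  rss_red <- colSums(sweep(V, 2, colMeans(V))^2)
  Fstat <- ((rss_red - rss_full) / 3) / sigma2
  joint_p <- stats::pf(Fstat, 3, df_res, lower.tail = FALSE)
  group <- data.frame(
    metabolite = colnames(V),
    beta_capacity = beta["capacity", ], beta_age = beta["age", ],
    beta_interaction = beta["interaction", ],
    se_capacity = se["capacity", ], se_age = se["age", ],
    se_interaction = se["interaction", ],
    p_capacity = pval["capacity", ], p_age = pval["age", ],
    p_interaction = pval["interaction", ],
    joint_F = Fstat, joint_p = joint_p, n_used = n,
    row.names = NULL, stringsAsFactors = FALSE)

  speed_tab <- data.frame()
  if (with_speed && "speed" %in% names(design) && !anyNA(design$speed)) {
    rows <- lapply(seq_len(ncol(V)), function(j)
      fit_speed_model(design$speed, V[, j], design))
    speed_tab <- do.call(rbind, rows)
    speed_tab <- cbind(metabolite = colnames(V), speed_tab,
                       stringsAsFactors = FALSE)
    speed_tab$fdr_q <- bh_fdr(speed_tab$joint_p)
    n_sing <- sum(speed_tab$singular)
    if (n_sing > 0)
      message("speed models: ", n_sing, " singular fit(s) flagged")
    rownames(speed_tab) <- NULL
  }
  list(group = group, speed = speed_tab)
}
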