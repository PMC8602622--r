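#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` for `lambda = 0`;
#' strictly increasing in `x` for every `lambda`.
#'
#' @param values Strictly positive numeric vector.
#' @param lambda Exponent.
#' @return Transformed numeric vector.
#' @export
boxcox <- function(values, lambda) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("boxcox requires strictly positive finite values; apply a shift first")
  if (lambda == 0) log(values) else (values^lambda - 1) / lambda
}

# Bias-corrected (type-2 / SAS-style) sample skewness and excess kurtosis,
# columnwise over a matrix. Matches e1071::skewness/kurtosis with type = 2.
.moments_by_column <- function(mat) {
  n <- nrow(mat)
  if (n < 4) stop("need at least 4 observations for corrected moments")
  m <- colMeans(mat)
  d <- sweep(mat, 2, m)
  m2 <- colMeans(d^2)
  m3 <- colMeans(d^3)
  m4 <- colMeans(d^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(skew = skew, kurtosis = kurt)
}

#' Skewness and kurtosis of design residuals
#'
#' Fits the saturated two-factor cell-means model (one mean per
#' capacity-by-age cell), and returns the bias-corrected sample skewness and
#' excess kurtosis of its residuals. This is the quantity the transformation
#' criterion `|skew| < 2 and |kurtosis| < 2` is evaluated on.
#'
#' @param values Numeric vector, one value per design row.
#' @param design A `StudyDesign` aligned with `values`.
#' @return List with `skew` and `kurtosis`.
#' @export
design_residual_moments <- function(values, design) {
  res <- .design_residuals(as.matrix(values), design)
  mom <- .moments_by_column(res)
  list(skew = unname(mom$skew[1]), kurtosis = unname(mom$kurtosis[1]))
}

# residuals from the cell-means model, columnwise; cell index precomputable
.design_residuals <- function(mat, design, cell = NULL) {
  if (is.null(cell)) cell <- .design_cells(design)
  if (nrow(mat) != length(cell))
    stop("values and design have different lengths")
  counts <- tabulate(cell, nbins = max(cell))
  if (any(counts[unique(cell)] < 2))
    stop("each nonempty design cell needs at least 2 samples for residual moments")
  means <- rowsum(mat, cell) / counts[sort(unique(cell))]
  mat - means[match(cell, sort(unique(cell))), , drop = FALSE]
}

.design_cells <- function(design) {
  as.integer(interaction(design$capacity, design$age, drop = FALSE))
}

#' Select a Box-Cox exponent under the residual-moment criterion
#'
#' Evaluates the design-residual skewness and excess kurtosis of
#' `boxcox(values, lambda)` at every grid lambda. Among lambdas meeting the
#' acceptance band (`|skew| < 2` and `|kurtosis| < 2`) the one minimizing
#' `|skew| + |kurtosis| / 2` is chosen (kurtosis down-weighted as the
#' noisier moment); if none qualifies, the global minimizer is chosen and
#' the metabolite is flagged infeasible. Ties break toward the lambda
#' closest to 1, then the smaller lambda.
#'
#' @param values Numeric vector (shifted internally if any value <= 0).
#' @param design Aligned `StudyDesign`.
#' @param grid Numeric vector of candidate lambdas
#'   (default `seq(-2, 2, by = 0.1)`).
#' @return A one-row data frame (`TransformSpec` row): `lambda`, `shift`,
#'   `residual_skew`, `residual_kurtosis`, `feasible`, `degenerate`.
#' @export
select_lambda <- function(values, design, grid = seq(-2, 2, by = 0.1)) {
  if (length(grid) == 0) stop("empty lambda grid")
  shift <- 0
  if (any(values <= 0)) {
    pos <- values[values > 0]
    shift <- abs(min(values)) +
      (if (length(pos) > 0) min(pos) / 2 else 0.5)
    values <- values + shift
  }
  if (stats::sd(values) == 0 || any(!is.finite(log(values)))) {
    return(data.frame(lambda = NA_real_, shift = shift,
                      residual_skew = NA_real_, residual_kurtosis = NA_real_,
                      feasible = FALSE, degenerate = TRUE))
  }
  # all grid lambdas in one matrix: n x length(grid)
  lg <- log(values)
  trans <- vapply(grid, function(l) {
    if (l == 0) lg else (exp(l * lg) - 1) / l
  }, numeric(length(values)))
  res <- .design_residuals(trans, design)
  rsd <- apply(res, 2, stats::sd)
  ok_var <- is.finite(rsd) & rsd > 0
  mom <- .moments_by_column(res)
  skew <- ifelse(ok_var, mom$skew, Inf)
  kurt <- ifelse(ok_var, mom$kurtosis, Inf)
  feasible <- is.finite(skew) & is.finite(kurt) & abs(skew) < 2 & abs(kurt) < 2
  objective <- abs(skew) + abs(kurt) / 2
  cand <- if (any(feasible)) which(feasible) else which(is.finite(objective))
  if (length(cand) == 0) {
    return(data.frame(lambda = NA_real_, shift = shift,
                      residual_skew = NA_real_, residual_kurtosis = NA_real_,
                      feasible = FALSE, degenerate = TRUE))
  }
  # minimize objective; ties toward lambda closest to 1, then smaller lambda
  ord <- order(objective[cand], abs(grid[cand] - 1), grid[cand])
  best <- cand[ord[1]]
  data.frame(lambda = grid[best], shift = shift,
             residual_skew = unname(skew[best]),
             residual_kurtosis = unname(kurt[best]),
             feasible = any(feasible), degenerate = FALSE)
}

#' Center and unit-variance scale a matrix
#'
#' Each column is mean-centered and divided by its sample standard deviation
#' (denominator `n - 1`). Zero-variance columns are dropped with a warning.
#'
#' @param values Numeric matrix (samples x metabolites).
#' @param center Mean-center columns first (default `TRUE`; centering is
#'   required by the PLS stage).
#' @return List with `values` (scaled matrix), `scale_sd` and `center_mean`
#'   (named per retained column), and `dropped` (names of dropped columns).
#' @export
unit_variance_scale <- function(values, center = TRUE) {
  values <- as.matrix(values)
  sds <- apply(values, 2, stats::sd)
  drop <- which(!is.finite(sds) | sds == 0)
  if (length(drop) > 0) {
    warning("dropping ", length(drop), " zero-variance column(s): ",
            paste(colnames(values)[drop], collapse = ", "))
    values <- values[, -drop, drop = FALSE]
    sds <- sds[-drop]
  }
  mns <- colMeans(values)
  out <- if (center) sweep(values, 2, mns) else values
  out <- sweep(out, 2, sds, `/`)
  list(values = out, scale_sd = sds,
       center_mean = if (center) mns else setNames(rep(0, ncol(values)), colnames(values)),
       dropped = names(drop))
}

#' Transform and scale a full abundance matrix
#'
#' Applies [select_lambda()] then [unit_variance_scale()] per metabolite and
#' returns the processed matrix plus a per-metabolite `TransformSpec` table
#' (lambda, shift, residual moments, feasibility, scaling SD).
#'
#' @param matrix A `MetaboliteMatrix` aligned with `design`.
#' @param design A `StudyDesign`.
#' @param grid Candidate lambda grid.
#' @param center Mean-center after scaling selection (default `TRUE`).
#' @return List with `matrix` (processed `MetaboliteMatrix`) and `spec`
#'   (data frame, one row per input metabolite; dropped metabolites have
#'   `retained = FALSE`).
#' @export
preprocess_matrix <- function(matrix, design, grid = seq(-2, 2, by = 0.1),
                              center = TRUE) {
  if (!identical(matrix$sample_ids, design$sample_id))
    stop("matrix and design are not aligned; call align() first")
  vals <- matrix$values
  if (anyNA(vals))
    stop("matrix contains missing values; call handle_missing() first")
  J <- ncol(vals)
  specs <- vector("list", J)
  trans <- vals
  for (j in seq_len(J)) {
    sp <- select_lambda(vals[, j], design, grid = grid)
    specs[[j]] <- sp
    if (!sp$degenerate)
      trans[, j] <- boxcox(vals[, j] + sp$shift, sp$lambda)
  }
  spec <- do.call(rbind, specs)
  spec <- cbind(metabolite = colnames(vals), spec, stringsAsFactors = FALSE)
  keep <- !spec$degenerate
  if (any(!keep))
    warning("excluding ", sum(!keep), " degenerate metabolite(s): ",
            paste(spec$metabolite[!keep], collapse = ", "))
  scaled <- unit_variance_scale(trans[, keep, drop = FALSE], center = center)
  retained <- spec$metabolite %in% colnames(scaled$values)
  spec$retained <- retained
  spec$scale_sd <- NA_real_
  spec$scale_sd[match(names(scaled$scale_sd), spec$metabolite)] <- scaled$scale_sd
  rownames(spec) <- NULL
  list(matrix = metabolite_matrix(scaled$values, tissue = matrix$tissue),
       spec = spec)
}
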