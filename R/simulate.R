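#' Simulation configuration for the factorial metabolomics study
#'
#' Defaults emulate the study design the package targets: 34 animals in four
#' unbalanced capacity-by-age cells (HCR-Y 10, LCR-Y 10, HCR-O 6, LCR-O 8)
#' and targeted panels of 89 serum, 71 muscle and 71 white-adipose-tissue
#' metabolites. Raw abundances are log-normal: each planted effect is
#' expressed in units of the metabolite's within-group SD on the log scale,
#' so the Box-Cox stage should recover lambda near 0.
#'
#' @param n_per_group Named counts for `HCR-Y`, `LCR-Y`, `HCR-O`, `LCR-O`.
#' @param tissues Named integer vector: metabolite count per tissue.
#' @param effect_capacity,effect_age,effect_interaction Standardized effect
#'   sizes (log-scale SD units) for the planted capacity, age and
#'   capacity-by-age effects.
#' @param frac_affected Fraction of metabolites carrying each effect type
#'   (drawn independently per type; sets may overlap).
#' @param base_log_mean Range (length 2) for per-metabolite log-scale means.
#' @param base_log_sd Range (length 2) for per-metabolite log-scale SDs.
#' @param speed_model Named list of design coefficients for maximal running
#'   speed (m/min): `intercept` (LCR-Y mean), `capacity` (HCR offset), `age`
#'   (old offset in LCR), `interaction` (extra old-HCR offset). Defaults
#'   give HCR animals a large speed advantage at young age that shrinks with
#'   age, as in treadmill phenotyping of these lines.
#' @param speed_assoc_frac Fraction of first-tissue metabolites whose
#'   (standardized log) abundance additionally contributes to speed.
#' @param speed_assoc_coef Speed contribution (m/min per log-SD) of each
#'   associated metabolite.
#' @param noise_sd_speed Residual SD of speed (m/min).
#' @param block_correlation If `TRUE`, metabolites are correlated in blocks
#'   of `block_size` with common correlation `block_rho` on the log scale.
#' @param block_size,block_rho Block-correlation settings.
#' @param seed RNG seed making the run bit-reproducible.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_per_group = c("HCR-Y" = 10, "LCR-Y" = 10,
                                              "HCR-O" = 6, "LCR-O" = 8),
                              tissues = c(serum = 89, muscle = 71, wat = 71),
                              effect_capacity = 1.0,
                              effect_age = 1.0,
                              effect_interaction = 1.0,
                              frac_affected = 0.1,
                              base_log_mean = c(1, 4),
                              base_log_sd = c(0.3, 0.8),
                              speed_model = list(intercept = 20, capacity = 12,
                                                 age = -2, interaction = -6),
                              speed_assoc_frac = 0.05,
                              speed_assoc_coef = 1.5,
                              noise_sd_speed = 2,
                              block_correlation = FALSE,
                              block_size = 5, block_rho = 0.5,
                              seed = 1L) {
  required <- c("HCR-Y", "LCR-Y", "HCR-O", "LCR-O")
  if (!all(required %in% names(n_per_group)))
    stop("n_per_group must name all of: ", paste(required, collapse = ", "))
  n_per_group <- n_per_group[required]
  if (any(n_per_group <= 0)) stop("all group counts must be positive")
  if (any(tissues <= 0)) stop("all tissue metabolite counts must be positive")
  if (frac_affected < 0 || frac_affected > 1)
    stop("frac_affected must be in [0, 1]")
  if (speed_assoc_frac < 0 || speed_assoc_frac > 1)
    stop("speed_assoc_frac must be in [0, 1]")
  if (is.null(names(tissues))) stop("tissues must be named")
  structure(list(
    n_per_group = n_per_group, tissues = tissues,
    effect_capacity = effect_capacity, effect_age = effect_age,
    effect_interaction = effect_interaction, frac_affected = frac_affected,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    speed_model = speed_model, speed_assoc_frac = speed_assoc_frac,
    speed_assoc_coef = speed_assoc_coef, noise_sd_speed = noise_sd_speed,
    block_correlation = block_correlation, block_size = block_size,
    block_rho = block_rho, seed = as.integer(seed)
  ), class = "SimulationConfig")
}

#' Simulate a complete factorial metabolomics study
#'
#' Generates per-tissue abundance matrices, the study design with running
#' speed, and the ground-truth table of planted log-scale coefficients.
#' Abundances follow
#' `exp(mu_j + b1_j * capacity + b2_j * age + b3_j * capacity * age + eps)`
#' with `eps ~ Normal(0, sigma_j)` and 0/1 coding (HCR = 1, old = 1), so
#' all values are strictly positive. A metabolite with all three
#' coefficients zero is a true null.
#'
#' @param config A [simulation_config()].
#' @return List with `matrices` (named list of `MetaboliteMatrix`),
#'   `design` (`StudyDesign` with speed), and `truth` (data frame:
#'   tissue, metabolite, beta_capacity, beta_age, beta_interaction,
#'   sigma, speed_assoc, speed_coef).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_per_group
  capacity <- rep(c("HCR", "LCR", "HCR", "LCR"), times = n)
  age <- rep(c("Y", "Y", "O", "O"), times = n)
  ntot <- sum(n)
  ids <- sprintf("S%02d", seq_len(ntot))
  cap01 <- as.numeric(capacity == "HCR")
  age01 <- as.numeric(age == "O")

  matrices <- list()
  truth_rows <- list()
  for (tis in names(config$tissues)) {
    J <- config$tissues[[tis]]
    mu <- stats::runif(J, config$base_log_mean[1], config$base_log_mean[2])
    sigma <- stats::runif(J, config$base_log_sd[1], config$base_log_sd[2])
    plant <- function(effect) {
      hit <- stats::runif(J) < config$frac_affected
      sgn <- sample(c(-1, 1), J, replace = TRUE)
      ifelse(hit, sgn * effect * sigma, 0)
    }
    b1 <- plant(config$effect_capacity)
    b2 <- plant(config$effect_age)
    b3 <- plant(config$effect_interaction)
    eps <- matrix(stats::rnorm(ntot * J), ntot, J)
    if (config$block_correlation) {
      blocks <- split(seq_len(J), ceiling(seq_len(J) / config$block_size))
      rho <- config$block_rho
      for (blk in blocks) {
        z <- stats::rnorm(ntot)
        eps[, blk] <- sqrt(rho) * z + sqrt(1 - rho) * eps[, blk, drop = FALSE]
      }
    }
    logab <- outer(rep(1, ntot), mu) +
      outer(cap01, b1) + outer(age01, b2) + outer(cap01 * age01, b3) +
      sweep(eps, 2, sigma, `*`)
    met_ids <- sprintf("%s_m%03d", tis, seq_len(J))
    vals <- exp(logab)
    dimnames(vals) <- list(ids, met_ids)
    matrices[[tis]] <- metabolite_matrix(vals, tissue = tis)
    truth_rows[[tis]] <- data.frame(
      tissue = tis, metabolite = met_ids,
      beta_capacity = b1, beta_age = b2, beta_interaction = b3,
      sigma = sigma, speed_assoc = FALSE, speed_coef = 0,
      stringsAsFactors = FALSE)
  }

  # speed: design terms + contributions from a subset of the first tissue's
  # metabolites (standardized log abundance), + Gaussian noise
  sm <- config$speed_model
  speed <- sm$intercept + sm$capacity * cap01 + sm$age * age01 +
    sm$interaction * cap01 * age01
  first <- names(config$tissues)[1]
  J1 <- config$tissues[[first]]
  n_assoc <- round(config$speed_assoc_frac * J1)
  if (n_assoc > 0) {
    assoc <- sample.int(J1, n_assoc)
    zlog <- scale(log(matrices[[first]]$values[, assoc, drop = FALSE]))
    speed <- speed + rowSums(zlog) * config$speed_assoc_coef
    truth_rows[[first]]$speed_assoc[assoc] <- TRUE
    truth_rows[[first]]$speed_coef[assoc] <- config$speed_assoc_coef
  }
  speed <- pmax(speed + stats::rnorm(ntot, 0, config$noise_sd_speed), 1)

  design <- study_design(ids, capacity, age, speed = speed)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(matrices = matrices, design = design, truth = truth)
}

#' Permute design labels to create an exchangeable null
#'
#' Returns the design with the (capacity, age) label pairs jointly permuted
#' across samples, severing any metabolite-design association while
#' preserving the four cell sizes exactly. Speed stays attached to its
#' sample.
#'
#' @param matrix A `MetaboliteMatrix` aligned with `design` (used only to
#'   check alignment).
#' @param design A `StudyDesign`.
#' @param seed Integer RNG seed.
#' @return A permuted `StudyDesign`.
#' @export
null_permutation_dataset <- function(matrix, design, seed) {
  if (!identical(matrix$sample_ids, design$sample_id))
    stop("matrix and design are not aligned; call align() first")
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(design))
  out <- design
  out$capacity <- design$capacity[perm]
  out$age <- design$age[perm]
  out
}
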