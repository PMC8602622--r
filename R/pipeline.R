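.config_defaults <- function() {
  list(
    simulate = TRUE,
    inputs = list(design = NULL, tissues = list(), gmt = NULL),
    thresholds = list(vip = 1.0, p = 0.05, fdr = 0.05),
    pls = list(components = 2L, folds = 7L, scheme = "venetian_blinds",
               permutations = 200L),
    lambda_grid = list(min = -2, max = 2, step = 0.1),
    missing = list(policy = "impute", max_frac = 0.2),
    seed = 1L,
    outdir = "aerometab_out"
  )
}

# recursively overlay user values on defaults; unknown keys are an error
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key: ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && k != "tissues") {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

.check_num <- function(x, key, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop("config key '", key, "' must be a single number, got: ",
         deparse(x))
  if (x < lo || x > hi)
    stop("config key '", key, "' out of range [", lo, ", ", hi, "]: ", x)
  if (integer && x != round(x))
    stop("config key '", key, "' must be an integer: ", x)
  x
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (200 permutations per model,
#' VIP >= 1, p < 0.05, FDR < 0.05, 2 components, 7-fold CV, lambda grid
#' -2..2 step 0.1), rejects unknown keys, and type-checks every value.
#' An empty file yields the all-defaults configuration, which simulates the
#' default factorial study.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated list of class `PipelineConfig`.
#' @export
validate_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.config_defaults(), user)
  .check_num(cfg$pls$permutations, "pls.permutations", lo = 1, integer = TRUE)
  .check_num(cfg$pls$components, "pls.components", lo = 1, integer = TRUE)
  .check_num(cfg$pls$folds, "pls.folds", lo = 2, integer = TRUE)
  if (!cfg$pls$scheme %in% c("venetian_blinds", "random", "loo"))
    stop("config key 'pls.scheme' must be venetian_blinds, random or loo")
  .check_num(cfg$thresholds$vip, "thresholds.vip", lo = 1e-12)
  .check_num(cfg$thresholds$p, "thresholds.p", lo = 1e-12, hi = 1)
  .check_num(cfg$thresholds$fdr, "thresholds.fdr", lo = 1e-12, hi = 1)
  .check_num(cfg$lambda_grid$min, "lambda_grid.min")
  .check_num(cfg$lambda_grid$max, "lambda_grid.max")
  .check_num(cfg$lambda_grid$step, "lambda_grid.step", lo = 1e-6)
  if (cfg$lambda_grid$min > cfg$lambda_grid$max)
    stop("config key 'lambda_grid.min' exceeds 'lambda_grid.max'")
  if (!cfg$missing$policy %in% c("impute", "error"))
    stop("config key 'missing.policy' must be impute or error")
  .check_num(cfg$missing$max_frac, "missing.max_frac", lo = 0, hi = 1)
  .check_num(cfg$seed, "seed", integer = TRUE)
  if (!is.logical(cfg$simulate))
    stop("config key 'simulate' must be true/false")
  if (!cfg$simulate) {
    if (is.null(cfg$inputs$design) || length(cfg$inputs$tissues) == 0)
      stop("simulate=false requires inputs.design and at least one inputs.tissues entry")
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.lambda_grid <- function(cfg)
  seq(cfg$lambda_grid$min, cfg$lambda_grid$max, by = cfg$lambda_grid$step)

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Per tissue, in the analysis order of the study: transform/scale
#' (Box-Cox under the residual-moment criterion, then unit-variance
#' scaling), four-class PLS-DA with cross-validated Q2 and G-permutation
#' validation, VIP, per-metabolite two-factor regressions with joint
#' F-tests, running-speed association screening with BH-FDR, influential
#' -metabolite selection (VIP and joint-p), Venn partitioning with
#' direction arrows, and — when a GMT library is configured — pathway
#' over-representation analysis. All artifacts are written as CSV into the
#' configured output directory together with a YAML run manifest; the
#' outputs contain no timestamps, so a rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param config A [validate_config()] result (or `NULL` for defaults).
#' @param outdir Override for the configured output directory.
#' @return The output directory path, invisibly.
#' @export
run_all <- function(config = NULL, outdir = NULL) {
  if (is.null(config)) config <- validate_config(NULL)
  stopifnot(inherits(config, "PipelineConfig"))
  outdir <- if (is.null(outdir)) config$outdir else outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(e) {
    writeLines(paste("FAILED:", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(e)
  }
  tryCatch(.run_all_impl(config, outdir), error = on_fail)
  invisible(outdir)
}

.run_all_impl <- function(config, outdir) {
  if (file.exists(file.path(outdir, "FAILED")))
    unlink(file.path(outdir, "FAILED"))
  if (config$simulate) {
    sim <- simulate_study(simulation_config(seed = config$seed))
    matrices <- sim$matrices
    design <- sim$design
    .write_csv(sim$truth, file.path(outdir, "ground_truth.csv"))
    write_design(design, file.path(outdir, "design.csv"))
    gmt <- NULL
  } else {
    design <- read_design(config$inputs$design)
    matrices <- lapply(names(config$inputs$tissues), function(t)
      read_abundance_table(config$inputs$tissues[[t]], tissue = t))
    names(matrices) <- names(config$inputs$tissues)
    gmt <- if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt) else NULL
  }
  grid <- .lambda_grid(config)
  rule <- selection_rule(config$thresholds$vip, config$thresholds$p,
                         config$thresholds$fdr)
  for (i in seq_along(matrices)) {
    tis <- names(matrices)[i]
    message("run_all: tissue '", tis, "' (", ncol(matrices[[i]]$values),
            " metabolites)")
    al <- align(handle_missing(matrices[[i]],
                               policy = config$missing$policy,
                               max_missing_frac = config$missing$max_frac),
                design)
    pp <- preprocess_matrix(al$matrix, al$design, grid = grid)
    .write_csv(pp$spec, file.path(outdir, paste0(tis, "_transform_spec.csv")))
    X <- pp$matrix$values
    Y <- build_response(al$design, "four_class")
    strata <- attr(Y, "classes")
    tissue_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    fit <- fit_pls(X, Y, A = config$pls$components)
    perm <- permutation_validate(X, Y, A = config$pls$components,
                                 G = config$pls$permutations,
                                 folds = config$pls$folds,
                                 scheme = config$pls$scheme,
                                 seed = tissue_seed, strata = strata)
    .write_csv(data.frame(tissue = tis,
                          n_components = fit$n_components,
                          r2x = fit$r2x[fit$n_components],
                          r2y = fit$r2y[fit$n_components],
                          q2 = perm$observed_q2,
                          q2_intercept = perm$q2_intercept,
                          r2_intercept = perm$r2_intercept,
                          permutation_p = perm$p_value,
                          G = perm$G),
               file.path(outdir, paste0(tis, "_pls_summary.csv")))
    .write_csv(data.frame(metabolite = names(fit$vip), vip = unname(fit$vip)),
               file.path(outdir, paste0(tis, "_vip.csv")))
    .write_csv(export_scores(fit, al$design),
               file.path(outdir, paste0(tis, "_scores.csv")))
    .write_csv(data.frame(similarity = perm$perm_similarity,
                          q2 = perm$perm_q2, r2y = perm$perm_r2y),
               file.path(outdir, paste0(tis, "_permutation_points.csv")))
    uni <- run_univariate_suite(pp$matrix, al$design)
    .write_csv(uni$group,
               file.path(outdir, paste0(tis, "_univariate_group.csv")))
    if (nrow(uni$speed) > 0)
      .write_csv(uni$speed,
                 file.path(outdir, paste0(tis, "_univariate_speed.csv")))
    joint_p <- setNames(uni$group$joint_p, uni$group$metabolite)
    selected <- select_influential(fit$vip, joint_p, rule)
    part <- partition_venn(selected, uni$group,
                           p_threshold = config$thresholds$p)
    rep_tabs <- summarize_report(part, tissue = tis)
    .write_csv(as.data.frame(part),
               file.path(outdir, paste0(tis, "_venn_partition.csv")))
    .write_csv(rep_tabs$counts,
               file.path(outdir, paste0(tis, "_venn_counts.csv")))
    if (!is.null(gmt)) {
      enr <- enrich(selected, gmt, universe = pp$matrix$metabolite_ids)
      .write_csv(enr, file.path(outdir, paste0(tis, "_enrichment.csv")))
    }
  }
  manifest <- list(
    package = "aerometab",
    version = as.character(utils::packageVersion("aerometab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
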