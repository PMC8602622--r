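#' Thresholds for influential-metabolite selection
#'
#' The study convention: multivariate importance VIP >= 1 combined with a
#' univariate joint p < 0.05; speed-association screening uses an
#' FDR-corrected p < 0.05.
#'
#' @param vip_threshold VIP cutoff (selection uses `>=`).
#' @param p_threshold Joint-p cutoff (selection uses strict `<`).
#' @param fdr_threshold FDR q cutoff for speed associations (strict `<`).
#' @return A list of class `SelectionRule`.
#' @export
selection_rule <- function(vip_threshold = 1.0, p_threshold = 0.05,
                           fdr_threshold = 0.05) {
  if (vip_threshold <= 0 || p_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  if (p_threshold > 1 || fdr_threshold > 1)
    stop("p/fdr thresholds must be <= 1")
  structure(list(vip_threshold = vip_threshold, p_threshold = p_threshold,
                 fdr_threshold = fdr_threshold), class = "SelectionRule")
}

#' Select influential metabolites by combined VIP and joint-p evidence
#'
#' @param vip Named numeric vector of VIP values.
#' @param joint_p Named numeric vector of joint-model p-values over the same
#'   metabolite universe.
#' @param rule A [selection_rule()].
#' @return Character vector of selected metabolite identifiers.
#' @export
select_influential <- function(vip, joint_p, rule = selection_rule()) {
  if (is.null(names(vip)) || is.null(names(joint_p)))
    stop("vip and joint_p must be named by metabolite")
  if (!setequal(names(vip), names(joint_p)))
    stop("vip and joint_p cover different metabolite universes")
  joint_p <- joint_p[names(vip)]
  sel <- !is.na(vip) & !is.na(joint_p) &
    vip >= rule$vip_threshold & joint_p < rule$p_threshold
  names(vip)[sel]
}

.venn_regions <- c("capacity_only", "age_only", "interaction_only",
                   "capacity_age", "capacity_interaction",
                   "age_interaction", "all_three", "joint_only")

#' Venn partition of selected metabolites with direction arrows
#'
#' Each selected metabolite is assigned to the region defined by which of
#' its three per-term p-values (capacity, age, interaction, from the same
#' fitted two-factor model) fall below `p_threshold`; metabolites whose
#' joint test was significant but no single term qualifies land in the
#' `joint_only` bucket. Directions come from the signs of the qualifying
#' coefficients under the documented dummy coding, so "up" means higher in
#' HCR (capacity term) or higher in old animals (age term); arrows are
#' ordered capacity, age, interaction.
#'
#' @param selected Character vector of selected metabolites.
#' @param univariate The `group` table from [run_univariate_suite()]
#'   (columns `metabolite`, `p_capacity`, `p_age`, `p_interaction`,
#'   `beta_capacity`, `beta_age`, `beta_interaction`).
#' @param p_threshold Per-term significance threshold (default 0.05).
#' @return Data frame of class `VennPartition`: `metabolite`, `region`,
#'   logical `sig_capacity`/`sig_age`/`sig_interaction`,
#'   `dir_capacity`/`dir_age`/`dir_interaction` (`"up"`, `"down"`, or `""`),
#'   `arrows` (semicolon-separated, ordered capacity, age, interaction).
#' @export
partition_venn <- function(selected, univariate, p_threshold = 0.05) {
  if (!all(selected %in% univariate$metabolite))
    stop("selected metabolites missing from the univariate table: ",
         paste(setdiff(selected, univariate$metabolite), collapse = ", "))
  tab <- univariate[match(selected, univariate$metabolite), , drop = FALSE]
  sig <- cbind(capacity = tab$p_capacity < p_threshold,
               age = tab$p_age < p_threshold,
               interaction = tab$p_interaction < p_threshold)
  sig[is.na(sig)] <- FALSE
  region <- apply(sig, 1, function(s) {
    key <- paste(which(s), collapse = "")
    switch(key, "1" = "capacity_only", "2" = "age_only",
           "3" = "interaction_only", "12" = "capacity_age",
           "13" = "capacity_interaction", "23" = "age_interaction",
           "123" = "all_three", "joint_only")
  })
  dir_of <- function(beta, s) ifelse(s, ifelse(beta > 0, "up", "down"), "")
  dirs <- cbind(dir_of(tab$beta_capacity, sig[, "capacity"]),
                dir_of(tab$beta_age, sig[, "age"]),
                dir_of(tab$beta_interaction, sig[, "interaction"]))
  arrows <- apply(dirs, 1, function(d) paste(d[nzchar(d)], collapse = ";"))
  out <- data.frame(metabolite = selected,
                    region = if (length(selected)) region else character(0),
                    sig_capacity = sig[, "capacity"],
                    sig_age = sig[, "age"],
                    sig_interaction = sig[, "interaction"],
                    dir_capacity = dirs[, 1], dir_age = dirs[, 2],
                    dir_interaction = dirs[, 3],
                    arrows = arrows,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("VennPartition", "data.frame")
  out
}

#' Summarize a Venn partition as report tables
#'
#' @param partition A [partition_venn()] result.
#' @param tissue Tissue label stamped on the tables.
#' @return List with `counts` (one row per region, fixed order, plus the
#'   tissue and total) and `members` (per-region membership with arrows).
#' @export
summarize_report <- function(partition, tissue = "unspecified") {
  counts <- data.frame(tissue = tissue, region = .venn_regions,
                       n = vapply(.venn_regions,
                                  function(r) sum(partition$region == r),
                                  integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  members <- partition[order(match(partition$region, .venn_regions),
                             partition$metabolite),
                       c("metabolite", "region", "arrows"), drop = FALSE]
  members <- cbind(tissue = rep(tissue, nrow(members)), members,
                   stringsAsFactors = FALSE)
  rownames(members) <- NULL
  list(counts = counts, members = members)
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition:", nrow(x), "selected metabolite(s)\n")
  print(table(factor(x$region, levels = .venn_regions)))
  invisible(x)
}
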