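#' Construct a metabolite abundance matrix
#'
#' A `MetaboliteMatrix` holds a samples-by-metabolites numeric matrix for one
#' tissue, together with a tissue label and a flag recording whether all
#' values are strictly positive (a precondition for the Box-Cox transform).
#'
#' @param values Numeric matrix, rows = samples, columns = metabolites.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param metabolite_ids Character vector of unique metabolite identifiers
#'   (defaults to `colnames(values)`).
#' @param tissue Tissue label, e.g. `"serum"`, `"muscle"`, `"wat"`.
#' @param missing_report Optional data frame of (sample, metabolite)
#'   coordinates of cells that failed numeric parsing.
#' @return An object of class `MetaboliteMatrix`.
#' @export
metabolite_matrix <- function(values, sample_ids = rownames(values),
                              metabolite_ids = colnames(values),
                              tissue = "unspecified",
                              missing_report = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(metabolite_ids))
    stop("sample_ids and metabolite_ids are required (or set dimnames)")
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (nrow(values) != length(sample_ids))
    stop("row count (", nrow(values), ") != number of sample_ids (",
         length(sample_ids), ")")
  if (ncol(values) != length(metabolite_ids))
    stop("column count (", ncol(values), ") != number of metabolite_ids (",
         length(metabolite_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(list(
    values = values,
    sample_ids = sample_ids,
    metabolite_ids = metabolite_ids,
    tissue = tissue,
    all_positive = all(!is.na(values)) && all(values > 0),
    missing_report = missing_report
  ), class = "MetaboliteMatrix")
}

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  cat(sprintf("MetaboliteMatrix [%s]: %d samples x %d metabolites%s\n",
              x$tissue, nrow(x$values), ncol(x$values),
              if (x$all_positive) ", all positive" else ""))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing cells\n", n_na))
  invisible(x)
}

#' @export
dim.MetaboliteMatrix <- function(x) dim(x$values)

#' Construct a study design table
#'
#' Per-sample factor levels for the two grouping factors — intrinsic aerobic
#' capacity (HCR = high-capacity runner line, LCR = low-capacity runner line)
#' and age (Y = young, O = old) — plus an optional maximal running speed
#' (m/min).
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param capacity Factor/character in `{HCR, LCR}` per sample.
#' @param age Factor/character in `{Y, O}` per sample.
#' @param speed Optional nonnegative numeric vector (m/min).
#' @return A data frame of class `StudyDesign` with columns
#'   `sample_id`, `capacity`, `age` and optionally `speed`.
#' @export
study_design <- function(sample_ids, capacity, age, speed = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  capacity <- .validate_level(capacity, c("HCR", "LCR"), "capacity", sample_ids)
  age <- .validate_level(age, c("Y", "O"), "age", sample_ids)
  n <- length(sample_ids)
  if (length(capacity) != n || length(age) != n)
    stop("capacity and age must have one entry per sample")
  out <- data.frame(sample_id = sample_ids, capacity = capacity, age = age,
                    stringsAsFactors = FALSE)
  if (!is.null(speed)) {
    speed <- as.numeric(speed)
    if (length(speed) != n) stop("speed must have one entry per sample")
    if (any(!is.na(speed) & speed < 0)) stop("speed must be nonnegative")
    out$speed <- speed
  }
  class(out) <- c("StudyDesign", "data.frame")
  out
}

.validate_level <- function(x, levels, what, ids) {
  x <- toupper(trimws(as.character(x)))
  bad <- which(!x %in% levels)
  if (length(bad) > 0)
    stop("unknown ", what, " level '", x[bad[1]], "' for sample '",
         ids[bad[1]], "' (allowed: ", paste(levels, collapse = ", "), ")")
  factor(x, levels = levels)
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat(sprintf("StudyDesign: %d samples%s\n", nrow(x),
              if ("speed" %in% names(x)) " (with running speed)" else ""))
  print(table(capacity = x$capacity, age = x$age))
  invisible(x)
}

#' Cell counts of the capacity x age design
#'
#' @param design A `StudyDesign`.
#' @return Named integer vector over HCR-Y, LCR-Y, HCR-O, LCR-O.
#' @export
design_cell_counts <- function(design) {
  tab <- table(design$capacity, design$age)
  c("HCR-Y" = tab["HCR", "Y"], "LCR-Y" = tab["LCR", "Y"],
    "HCR-O" = tab["HCR", "O"], "LCR-O" = tab["LCR", "O"])
}

#' Construct a pathway library
#'
#' @param pathways Named list mapping pathway name to a character vector of
#'   metabolite identifiers (deduplicated on construction).
#' @param descriptions Optional named character vector of descriptions.
#' @param universe Optional explicit background metabolite set.
#' @return An object of class `PathwayLibrary`.
#' @export
pathway_library <- function(pathways, descriptions = NULL, universe = NULL) {
  if (length(pathways) == 0) stop("pathway library is empty")
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("all pathways must be named")
  if (anyDuplicated(names(pathways)))
    stop("duplicate pathway names: ",
         paste(unique(names(pathways)[duplicated(names(pathways))]), collapse = ", "))
  pathways <- lapply(pathways, function(m) unique(as.character(m)))
  sizes <- lengths(pathways)
  if (any(sizes == 0))
    stop("empty pathway: ", paste(names(pathways)[sizes == 0], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(pathways)), names(pathways))
  }
  structure(list(pathways = pathways,
                 descriptions = descriptions[names(pathways)],
                 universe = if (is.null(universe)) NULL else unique(as.character(universe))),
            class = "PathwayLibrary")
}

#' @export
print.PathwayLibrary <- function(x, ...) {
  cat(sprintf("PathwayLibrary: %d pathways, member sizes %d-%d\n",
              length(x$pathways), min(lengths(x$pathways)), max(lengths(x$pathways))))
  invisible(x)
}
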