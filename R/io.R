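#' Read a delimited abundance table
#'
#' Reads a CSV or TSV abundance table (delimiter auto-detected from the
#' header line) with one header row and row identifiers in the first column.
#' Non-numeric cells become `NA` and are listed in the attached missing-cell
#' report.
#'
#' @param path Path to a delimited text file.
#' @param tissue Tissue label stored on the result.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"metabolites_in_rows"`; the returned matrix is always samples-in-rows.
#' @return A [metabolite_matrix()].
#' @export
read_abundance_table <- function(path, tissue = "unspecified",
                                 orientation = c("samples_in_rows",
                                                 "metabolites_in_rows")) {
  orientation <- match.arg(orientation)
  parsed <- .read_delim_table(path)
  ids <- parsed$ids
  header <- parsed$header
  vals <- suppressWarnings(
    matrix(as.numeric(parsed$cells), nrow = length(ids),
           dimnames = list(ids, header)))
  miss <- which(is.na(vals) & parsed$cells != "" &
                  toupper(parsed$cells) != "NA", arr.ind = TRUE)
  na_cells <- which(is.na(vals), arr.ind = TRUE)
  report <- if (nrow(na_cells) > 0) {
    data.frame(row_id = rownames(vals)[na_cells[, 1]],
               col_id = colnames(vals)[na_cells[, 2]],
               raw = parsed$cells[na_cells],
               stringsAsFactors = FALSE)
  } else NULL
  if (orientation == "metabolites_in_rows") vals <- t(vals)
  metabolite_matrix(vals, tissue = tissue, missing_report = report)
}

# Shared low-level delimited reader: auto-detects , vs \t from the header,
# checks for ragged rows and duplicate IDs.
.read_delim_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("format error: file has no data rows: ", path)
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0) "\t" else ","
  split_all <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(split_all)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("format error: ragged row at line ", bad,
         " (", widths[bad], " fields, expected ", widths[1], ")")
  }
  header <- trimws(split_all[[1]][-1])
  body <- split_all[-1]
  ids <- trimws(vapply(body, `[`, character(1), 1))
  if (anyDuplicated(ids))
    stop("format error: duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(header))
    stop("format error: duplicate column ids: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  cells <- matrix(trimws(unlist(lapply(body, `[`, -1))),
                  nrow = length(ids), byrow = TRUE)
  list(ids = ids, header = header, cells = cells)
}

#' Write a MetaboliteMatrix (or plain table) as CSV
#'
#' Writes samples-in-rows with the sample identifier as first column `id`.
#'
#' @param x A `MetaboliteMatrix`, matrix, or data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "MetaboliteMatrix")) x <- x$values
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study-metadata table
#'
#' Expects columns `sample_id`, `capacity`, `age` and optionally `speed`
#' (CSV or TSV, auto-detected). Factor levels are validated
#' case-insensitively against HCR/LCR and Y/O.
#'
#' @param path Path to the metadata file.
#' @return A [study_design()].
#' @export
read_design <- function(path) {
  parsed <- .read_delim_table(path)
  cols <- c("sample_id", tolower(parsed$header))
  tab <- data.frame(parsed$ids, parsed$cells, stringsAsFactors = FALSE)
  names(tab) <- cols
  # allow sample_id to be a named column anywhere rather than first
  for (req in c("capacity", "age"))
    if (!req %in% names(tab)) stop("missing required column: ", req)
  speed <- if ("speed" %in% names(tab)) as.numeric(tab$speed) else NULL
  study_design(tab$sample_id, tab$capacity, tab$age, speed = speed)
}

#' Write a StudyDesign as CSV
#' @param design A `StudyDesign`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT pathway library
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' name, description, member identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return A [pathway_library()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("format error: GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, `[`, character(1), 2)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  pathway_library(setNames(members, nm), descriptions = setNames(desc, nm))
}

#' Write a PathwayLibrary to GMT
#' @param library A `PathwayLibrary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$pathways), function(nm) {
    paste(c(nm, library$descriptions[[nm]], library$pathways[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Align a MetaboliteMatrix with a StudyDesign
#'
#' Restricts both objects to the intersection of their sample identifiers
#' (case-sensitive exact match), in the matrix's sample order. Dropped
#' samples are reported via `message()`.
#'
#' @param matrix A `MetaboliteMatrix`.
#' @param design A `StudyDesign`.
#' @return List with elements `matrix` and `design`, sample-aligned.
#' @export
align <- function(matrix, design) {
  common <- intersect(matrix$sample_ids, design$sample_id)
  if (length(common) == 0) stop("no samples in common between matrix and design")
  dropped <- c(setdiff(matrix$sample_ids, common), setdiff(design$sample_id, common))
  if (length(dropped) > 0)
    message("align: dropped ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  keep <- matrix$sample_ids[matrix$sample_ids %in% common]
  m2 <- metabolite_matrix(matrix$values[keep, , drop = FALSE],
                          tissue = matrix$tissue,
                          missing_report = matrix$missing_report)
  d2 <- design[match(keep, design$sample_id), , drop = FALSE]
  rownames(d2) <- NULL
  class(d2) <- class(design)
  list(matrix = m2, design = d2)
}

#' Handle missing abundance cells
#'
#' Metabolites missing in more than `max_missing_frac` of samples are
#' dropped with a warning; remaining missing cells are imputed with half the
#' metabolite's observed minimum (standard practice for targeted panels
#' where missingness usually reflects values below the detection limit).
#' With `policy = "error"`, any missing cell is an error instead.
#'
#' @param matrix A `MetaboliteMatrix`.
#' @param policy `"impute"` (default) or `"error"`.
#' @param max_missing_frac Drop threshold on the per-metabolite missing
#'   fraction (default 0.2).
#' @return A `MetaboliteMatrix` with no missing cells.
#' @export
handle_missing <- function(matrix, policy = c("impute", "error"),
                           max_missing_frac = 0.2) {
  policy <- match.arg(policy)
  vals <- matrix$values
  if (!anyNA(vals)) return(matrix)
  if (policy == "error") {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("missing values present (imputation disabled), e.g. sample '",
         rownames(vals)[bad[1, 1]], "', metabolite '", colnames(vals)[bad[1, 2]], "'")
  }
  frac <- colMeans(is.na(vals))
  drop <- which(frac > max_missing_frac)
  if (length(drop) > 0) {
    warning("dropping ", length(drop), " metabolite(s) missing in >",
            round(100 * max_missing_frac), "% of samples: ",
            paste(colnames(vals)[drop], collapse = ", "))
    vals <- vals[, -drop, drop = FALSE]
  }
  for (j in seq_len(ncol(vals))) {
    nas <- is.na(vals[, j])
    if (any(nas)) vals[nas, j] <- min(vals[!nas, j]) / 2
  }
  metabolite_matrix(vals, tissue = matrix$tissue)
}
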