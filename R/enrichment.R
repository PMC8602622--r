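#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` members of a size-`K` pathway when sampling `n` metabolites
#' without replacement from a universe of `N`.
#'
#' @param N Universe size.
#' @param K Pathway size within the universe.
#' @param n Selected-set size.
#' @param k Observed hits (pathway members among the selected).
#' @return The upper-tail p-value (exactly 1 when `k = 0`).
#' @export
ora_pvalue <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n))
    stop("inconsistent counts: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the selected metabolites
#' against the measured universe (for targeted panels, the panel itself is
#' the correct background). Pathway member sets are intersected with the
#' universe before testing; pathways left empty are skipped with a message.
#' BH-FDR is applied across the tested pathways.
#'
#' @param selected Character vector of selected metabolites (must be a
#'   subset of `universe`).
#' @param library A [pathway_library()].
#' @param universe Character vector of background metabolites; defaults to
#'   the library's explicit universe when present.
#' @return `EnrichmentResult` data frame sorted by p: `pathway`,
#'   `description`, `universe_size`, `pathway_size`, `selected_size`,
#'   `hits`, `expected`, `p_value`, `fdr_q`, `members_hit`.
#' @export
enrich <- function(selected, library, universe = library$universe) {
  if (is.null(universe) || length(universe) == 0)
    stop("empty universe: supply the measured metabolite panel")
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe))
    stop("selected metabolites outside the universe: ",
         paste(setdiff(selected, universe), collapse = ", "))
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(library$pathways), function(nm) {
    members <- intersect(library$pathways[[nm]], universe)
    if (length(members) == 0) {
      message("enrich: pathway '", nm, "' shares no members with the universe; skipped")
      return(NULL)
    }
    hit <- intersect(members, selected)
    K <- length(members); k <- length(hit)
    data.frame(pathway = nm, description = library$descriptions[[nm]],
               universe_size = N, pathway_size = K, selected_size = n,
               hits = k, expected = n * K / N,
               p_value = ora_pvalue(N, K, n, k),
               members_hit = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(pathway = character(0), description = character(0),
                      universe_size = integer(0), pathway_size = integer(0),
                      selected_size = integer(0), hits = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      fdr_q = numeric(0), members_hit = character(0)))
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$pathway),
             c("pathway", "description", "universe_size", "pathway_size",
               "selected_size", "hits", "expected", "p_value", "fdr_q",
               "members_hit")]
  rownames(out) <- NULL
  out
}
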