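# Hypergeometric over-representation analysis of consensus gene lists
# against a user-supplied term -> gene map (a simplified stand-in for a
# DAVID-style GO analysis; no DAG propagation, no EASE discount).

#' Read a term membership table
#' @param path TSV with columns `term_id`, `term_name`, `gene_id` (one row
#'   per membership).
#' @return validated data.frame.
#' @export
read_term_map <- function(path) {
  tm <- read.delim(path, colClasses = "character")
  .require_cols(tm, c("term_id", "term_name", "gene_id"), "terms")
  if (nrow(tm) == 0L) format_error("terms: empty membership table")
  tm
}

#' Over-representation analysis (hypergeometric upper tail)
#'
#' Per term with `K` members in a universe of `N` genes, the probability of
#' observing at least the actual overlap `k` in a list of size `n`:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; BH-adjusted across tested
#' terms. Terms with no overlap are reported with p = 1.
#'
#' @param gene_list character vector of hit genes (must lie in `universe`).
#' @param universe character vector: all assayable genes.
#' @param term_map data.frame as from [read_term_map()].
#' @return data.frame(term_id, term_name, k, n, K, N, p_value, q_value),
#'   sorted by p-value.
#' @export
ora <- function(gene_list, universe, term_map) {
  universe <- unique(universe)
  if (length(universe) == 0L) config_error("ora: empty universe")
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray))
    consistency_error(sprintf("ora: gene(s) outside the universe: %s",
                              paste(utils::head(stray, 3), collapse = ", ")))
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(term_map[, c("term_id", "term_name")])
  N <- length(universe); n <- length(gene_list)
  members <- split(term_map$gene_id, term_map$term_id)
  K <- vapply(members, function(m) length(unique(m)), integer(1))
  k <- vapply(members, function(m) length(intersect(unique(m), gene_list)),
              integer(1))
  K <- K[terms$term_id]; k <- k[terms$term_id]
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    k = unname(k), n = n, K = unname(K), N = N,
                    p_value = unname(p),
                    q_value = unname(p.adjust(p, "BH")),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
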