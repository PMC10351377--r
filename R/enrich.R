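#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= x)` of drawing `x` or more members of a
#' `K`-gene set when sampling `n` query genes without replacement from a
#' universe of `N`.
#'
#' @param N Universe size.
#' @param K Gene-set size.
#' @param n Query size.
#' @param x Observed overlap.
#' @return p-value in `(0, 1]`.
#' @examples
#' hypergeom_test(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeom_test <- function(N, K, n, x) {
  N <- check_count(N, "N"); K <- check_count(K, "K", min = 0)
  n <- check_count(n, "n", min = 0); x <- check_count(x, "x", min = 0)
  if (K > N || n > N || x > min(K, n)) {
    abort("inconsistent counts: need x <= min(K, n) <= N",
          class = "mirimmune_validation_error")
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the result respects the input order.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, `adjusted[i] >= p[i]`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Assemble a gene-set collection against a background universe
#'
#' Members outside the universe are dropped (with a message); empty sets
#' are removed.
#'
#' @param sets Named list of character vectors.
#' @param universe Background gene list.
#' @return A list of class `gene_set_collection` (`sets`, `universe`).
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), length(universe) > 0)
  universe <- unique(universe)
  filtered <- lapply(sets, function(s) intersect(unique(s), universe))
  dropped <- sum(lengths(lapply(sets, unique))) - sum(lengths(filtered))
  if (dropped > 0) {
    inform(sprintf("dropped %d gene-set members outside the universe", dropped))
  }
  filtered <- filtered[lengths(filtered) > 0]
  structure(list(sets = filtered, universe = universe, planted_set = NULL),
            class = "gene_set_collection")
}

#' Over-representation analysis of a query gene list
#'
#' Tests each set of the collection for enrichment in the query by the
#' one-sided hypergeometric test, adjusts across all sets by
#' Benjamini-Hochberg, and returns the `top_k` records ranked by ascending
#' p-value (ties broken by set name).
#'
#' @param query Character vector of query genes; members outside the
#'   universe are dropped first.
#' @param collection A [gene_set_collection()] (or the output of
#'   [generate_gene_sets()]).
#' @param top_k Number of records to return (default 25); `Inf` keeps all.
#' @return Tibble with `set_name`, `set_size`, `query_size`, `overlap`,
#'   `universe_size`, `p_value`, `adjusted_p`, and list-column
#'   `overlap_genes`.
#' @export
enrich_query <- function(query, collection, top_k = 25) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  query <- intersect(unique(query), universe)
  if (length(query) == 0L) {
    abort("query is empty after restricting to the universe",
          class = "mirimmune_validation_error")
  }
  N <- length(universe)
  n <- length(query)
  recs <- purrr::imap(collection$sets, function(s, nm) {
    s <- intersect(s, universe)
    ov <- intersect(s, query)
    tibble::tibble(set_name = nm, set_size = length(s), query_size = n,
                   overlap = length(ov), universe_size = N,
                   p_value = hypergeom_test(N, length(s), n, length(ov)),
                   overlap_genes = list(sort(ov)))
  })
  out <- dplyr::bind_rows(recs)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- dplyr::arrange(out, p_value, set_name)
  out <- out[, c("set_name", "set_size", "query_size", "overlap",
                 "universe_size", "p_value", "adjusted_p", "overlap_genes")]
  head(out, top_k)
}
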