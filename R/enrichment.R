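# Down-regulation filter, target intersection, and hypergeometric gene-set
# enrichment with top-n ranking. The hypergeometric upper tail is computed
# locally, in log space, so the statistic is auditable end to end.

#' Filter genes by expression ratio
#'
#' Keeps a gene iff its treated/untreated expression ratio is strictly below
#' the cutoff ("below 0.8-fold").
#'
#' @param ratios Data frame with columns `gene_id` and `ratio` (> 0), or a
#'   named numeric vector.
#' @param cutoff Strict upper bound on the ratio (default 0.8).
#' @return Character vector of down-regulated gene ids.
#' @export
filter_downregulated <- function(ratios, cutoff = 0.8) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop_mc("filter_downregulated: cutoff must be a single positive number")
  if (is.numeric(ratios)) {
    ratios <- data.frame(gene_id = names(ratios), ratio = unname(ratios),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("gene_id", "ratio") %in% colnames(ratios)))
    stop_mc("filter_downregulated: need columns 'gene_id' and 'ratio'")
  if (anyDuplicated(ratios$gene_id))
    stop_mc("filter_downregulated: duplicate gene ids")
  if (any(!is.finite(ratios$ratio)) || any(ratios$ratio <= 0))
    stop_mc("filter_downregulated: ratios must be finite and > 0")
  ratios$gene_id[ratios$ratio < cutoff]
}

#' Intersect down-regulated genes with predicted targets
#'
#' Plain set intersection; the sizes of both inputs and of the result are
#' reported via a message, mirroring the pipeline's funnel bookkeeping.
#'
#' @param down Character vector of down-regulated gene ids.
#' @param predicted_targets Character vector of predicted target gene ids.
#' @return Character vector of genes in both sets.
#' @export
intersect_targets <- function(down, predicted_targets) {
  out <- intersect(down, predicted_targets)
  mc_msg(sprintf("intersect_targets: %d down-regulated x %d predicted targets -> %d genes",
                 length(unique(down)), length(unique(predicted_targets)),
                 length(out)))
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric with `N` genes in the universe, `K` of
#' them in the gene set, and a query of size `n`:
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, evaluated in log space
#' for numerical stability at large arguments.
#'
#' @param N Universe size.
#' @param K Genes of the set present in the universe.
#' @param n Query size.
#' @param k Observed overlap.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is_count(v)) stop_mc("hypergeom_tail: arguments must be non-negative integers")
  if (K > N || n > N) stop_mc("hypergeom_tail: need K <= N and n <= N")
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (k < lo || k > hi)
    stop_mc("hypergeom_tail: k = %d outside feasible range [%d, %d]", k, lo, hi)
  if (k <= lo) return(1)
  i <- k:hi
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Hypergeometric gene-set enrichment with top-n ranking
#'
#' Computes one upper-tail hypergeometric test per gene set against the
#' query, ranks terms by ascending p (ties broken by larger overlap `k`,
#' then lexicographic term id), and returns the `top_n` most significant
#' terms. Raw p-values drive the ranking; a Benjamini-Hochberg column is
#' emitted as an extra. Query genes outside the universe are dropped with a
#' warning; gene sets are intersected with the universe and terms with no
#' universe member are skipped.
#'
#' @param query Character vector of query gene ids.
#' @param gene_sets Named list of gene sets (as from [read_gmt()]).
#' @param universe Character vector of universe gene ids.
#' @param top_n Number of top terms to return (default 10).
#' @return Data frame of the top terms with columns `term_id`, `name`, `N`,
#'   `K`, `n`, `k`, `p`, `bh_q`, `rank`; the full ranked table is attached
#'   as attribute `full`.
#' @export
enrich <- function(query, gene_sets, universe, top_n = 10) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_mc("enrich: empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("enrich: %d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(gene_sets, function(s) {
    members <- intersect(unique(s$members), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    data.frame(term_id = s$term_id, name = s$name, N = N, K = K, n = n, k = k,
               p = hypergeom_tail(N, K, n, k), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop_mc("enrich: no gene set overlaps the universe")
  tab <- do.call(rbind, rows)
  tab$bh_q <- stats::p.adjust(tab$p, method = "BH")
  ord <- order(tab$p, -tab$k, tab$term_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  out <- utils::head(tab, top_n)
  attr(out, "full") <- tab
  out
}
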