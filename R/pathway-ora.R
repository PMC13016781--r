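#' Map aptamer ids to a deduplicated gene set with multimap flags
#'
#' Translates aptamer identifiers to gene identifiers through an annotation
#' table, handling the 1:N (one aptamer, several genes) and N:1 (several
#' aptamers, one gene) cases: the result is the deduplicated union of all
#' mapped genes, and a gene is multimap-flagged when any contributing
#' aptamer maps to more than one gene or when it receives more than one of
#' the queried aptamers. Aptamers absent from the annotation are dropped
#' with a `message()`.
#'
#' @param aptamers Character vector of aptamer ids.
#' @param annotation Long-format data frame `aptamer_id`, `gene_id` (and
#'   optionally `multimap_flag`, which is recomputed here).
#' @return Data frame `gene_id`, `multimap` (logical), one row per gene.
#' @export
map_to_genes <- function(aptamers, annotation) {
  if (nrow(annotation) == 0) stop("annotation is empty")
  stopifnot(all(c("aptamer_id", "gene_id") %in% names(annotation)))
  covered <- aptamers %in% annotation$aptamer_id
  if (any(!covered)) {
    message(sprintf("map_to_genes: %d aptamers without annotation dropped",
                    sum(!covered)))
    aptamers <- aptamers[covered]
  }
  sub <- annotation[annotation$aptamer_id %in% aptamers, , drop = FALSE]
  genes_per_apt <- table(sub$aptamer_id)
  apts_per_gene <- table(sub$gene_id)
  one_to_n <- names(genes_per_apt)[genes_per_apt > 1]
  flagged <- sub$gene_id[sub$aptamer_id %in% one_to_n]
  flagged <- union(flagged, names(apts_per_gene)[apts_per_gene > 1])
  genes <- sort(unique(sub$gene_id))
  data.frame(gene_id = genes, multimap = genes %in% flagged,
             stringsAsFactors = FALSE)
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, tests whether the differentially abundant genes hit
#' the set more often than expected from uniform sampling of the universe.
#' With `N` universe genes of which `K` lie in the set, and `n` mapped DE
#' genes of which `k` hit the set, the one-sided upper-tail p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg
#' q-values are computed across all tested sets; sets with no member in the
#' universe are skipped.
#'
#' @param de_genes Character vector of differentially abundant genes; must be
#'   a subset of `universe` (violations signal a universe-construction bug
#'   and raise an error).
#' @param universe Character vector: the sampling frame, typically every
#'   gene mapped from the measured aptamer panel.
#' @param collection A [gene_set_collection()].
#' @return Data frame of class `"ora_result"`, one row per tested set:
#'   `set`, `description`, `k`, `n`, `K`, `N`, `gene_ratio` (`"k/n"`),
#'   `p_value`, `q_value`, `hits` (`/`-separated gene ids); attribute
#'   `n_de` carries `n`.
#' @export
hypergeom_enrich <- function(de_genes, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe)) {
    stop("differentially abundant genes outside the universe: ",
         paste(head(setdiff(de_genes, universe), 3), collapse = ", "))
  }
  n_universe <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    big_k <- length(members)
    if (big_k == 0) return(NULL)
    hits <- intersect(de_genes, members)
    k <- length(hits)
    p <- phyper(k - 1, big_k, n_universe - big_k, n_de, lower.tail = FALSE)
    data.frame(set = nm, description = collection$descriptions[[nm]],
               k = k, n = n_de, K = big_k, N = n_universe,
               gene_ratio = sprintf("%d/%d", k, n_de),
               p_value = p,
               hits = paste(sort(hits), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), gene_ratio = character(0),
                      p_value = numeric(0), hits = character(0),
                      stringsAsFactors = FALSE)
  }
  out$q_value <- bh_adjust(out$p_value)
  out <- out[c("set", "description", "k", "n", "K", "N", "gene_ratio",
               "p_value", "q_value", "hits")]
  attr(out, "n_de") <- n_de
  class(out) <- c("ora_result", class(out))
  out
}

#' Dual-filter enriched pathways
#'
#' Keeps the gene sets that satisfy both enrichment criteria: adjusted
#' p-value below `alpha` and a hit count of at least ~`coverage_fraction`
#' of the mapped differentially abundant genes. The default threshold is
#' `floor(coverage_fraction * n)`; `min_hits` overrides it with an explicit
#' count when a different convention is wanted.
#'
#' @param results An `"ora_result"` from [hypergeom_enrich()].
#' @param alpha q-value threshold.
#' @param coverage_fraction Fraction of the mapped DE genes a pathway must
#'   contain; must lie in (0, 1).
#' @param min_hits Optional explicit minimum hit count overriding the
#'   fraction-derived threshold.
#' @return The filtered rows, ordered by increasing q-value, with attribute
#'   `min_hits` recording the threshold applied.
#' @export
filter_enriched <- function(results, alpha = 0.05, coverage_fraction = 0.05,
                            min_hits = NULL) {
  if (coverage_fraction <= 0 || coverage_fraction >= 1) {
    stop("coverage_fraction must lie in (0, 1)")
  }
  threshold <- if (!is.null(min_hits)) {
    as.integer(min_hits)
  } else {
    coverage_min_hits(attr(results, "n_de") %||%
                        (if (nrow(results)) results$n[1] else 0L),
                      coverage_fraction)
  }
  keep <- !is.na(results$q_value) & results$q_value < alpha &
    results$k >= threshold
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$q_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_hits") <- threshold
  attr(out, "n_de") <- attr(results, "n_de")
  out
}

#' Minimum-hit threshold implied by a coverage fraction
#'
#' @param n_de Number of mapped differentially abundant genes.
#' @param coverage_fraction Required fraction of `n_de`.
#' @return `floor(coverage_fraction * n_de)` as an integer.
#' @export
coverage_min_hits <- function(n_de, coverage_fraction = 0.05) {
  as.integer(floor(coverage_fraction * n_de))
}
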