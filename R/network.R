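#' Export a pathway-protein membership network
#'
#' Builds the bipartite network behind enrichment visualizations: pathway
#' nodes connected to their differentially abundant member genes. Gene nodes
#' carry the sign of the association (`sign` attribute, from `logFC`) and a
#' `multimap` attribute marking genes without a clean 1:1 aptamer mapping
#' (conventionally drawn with bold outlines). A `merge_sets` list collapses
#' closely related pathways (e.g. several complement-system variants) into a
#' single node whose edge set is the deduplicated union.
#'
#' @param enriched Filtered `"ora_result"` rows from [filter_enriched()]
#'   (must be non-empty).
#' @param gene_table Data frame `gene_id`, `logFC`, `multimap` giving, per
#'   differentially abundant gene, its association sign source and mapping
#'   flag (see [map_to_genes()]).
#' @param merge_sets Optional named list: each element is a character vector
#'   of pathway names to collapse into one node named after the element.
#'   Absent pathways are skipped with a warning.
#' @param out_dir Optional directory; when given, writes `nodes.tsv`,
#'   `edges.tsv` and `network.graphml` there.
#' @return List with `nodes` (`id`, `type`, `sign`, `multimap`), `edges`
#'   (`pathway`, `gene`) and `graph` (an igraph object).
#' @export
export_network <- function(enriched, gene_table, merge_sets = NULL,
                           out_dir = NULL) {
  if (nrow(enriched) == 0) stop("no enriched pathways to export")
  stopifnot(all(c("gene_id", "logFC", "multimap") %in% names(gene_table)))

  memberships <- setNames(strsplit(enriched$hits, "/", fixed = TRUE),
                          enriched$set)
  memberships <- memberships[lengths(memberships) > 0]

  if (!is.null(merge_sets)) {
    for (nm in names(merge_sets)) {
      present <- intersect(merge_sets[[nm]], names(memberships))
      absent <- setdiff(merge_sets[[nm]], names(memberships))
      if (length(absent) > 0) {
        warning("merge list names absent pathways, skipped: ",
                paste(absent, collapse = ", "))
      }
      if (length(present) == 0) next
      merged <- sort(unique(unlist(memberships[present])))
      memberships <- memberships[setdiff(names(memberships), present)]
      memberships[[nm]] <- merged
    }
  }

  edges <- data.frame(
    pathway = rep(names(memberships), lengths(memberships)),
    gene = unlist(memberships, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(edges$gene))
  gi <- match(genes, gene_table$gene_id)
  if (anyNA(gi)) {
    stop("hit genes missing from gene_table: ",
         paste(head(genes[is.na(gi)], 3), collapse = ", "))
  }
  nodes <- rbind(
    # pathway nodes carry neutral attribute values (sign 0, no flag)
    data.frame(id = names(memberships), type = "pathway", sign = 0L,
               multimap = FALSE, stringsAsFactors = FALSE),
    data.frame(id = genes, type = "protein",
               sign = as.integer(sign(gene_table$logFC[gi])),
               multimap = gene_table$multimap[gi], stringsAsFactors = FALSE)
  )
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(nodes, file.path(out_dir, "nodes.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    igraph::write_graph(graph, file.path(out_dir, "network.graphml"),
                        format = "graphml")
  }
  list(nodes = nodes, edges = edges, graph = graph)
}
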