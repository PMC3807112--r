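# Protein-interaction sub-networks of significant gene sets.
#
# The interaction network is treated as a plain undirected graph: the
# sub-graph induced by a phenotype-associated gene set, its connected
# components (largest first) and its high-degree hubs summarize how much of
# the signal sits in one interacting module.

#' Read a protein-interaction edge list
#'
#' TSV with columns `gene1`, `gene2` and optionally `score`; edges below
#' `min_score` are dropped when a score column exists.
#'
#' @param path TSV path.
#' @param min_score optional confidence cutoff.
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
read_ppi_edges <- function(path, min_score = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("gene1", "gene2")
  if (!is.null(min_score) && ncol(tab) >= 3L) {
    tab <- tab[tab[[3]] >= min_score, , drop = FALSE]
  }
  tab[, c("gene1", "gene2")]
}

#' Interaction sub-graph induced by a gene set
#'
#' Keeps edges with both endpoints in `genes` (deduplicated, self-loops
#' dropped); isolated genes are retained with degree 0.
#'
#' @param edges data.frame with columns `gene1`, `gene2`.
#' @param genes character vector of gene ids.
#' @return an `igraph` undirected graph on `genes`.
#' @export
induced_subgraph <- function(edges, genes) {
  genes <- unique(as.character(genes))
  keep <- edges$gene1 %in% genes & edges$gene2 %in% genes &
    edges$gene1 != edges$gene2
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    key <- apply(cbind(pmin(e$gene1, e$gene2), pmax(e$gene1, e$gene2)),
                 1L, paste, collapse = "\r")
    e <- e[!duplicated(key), , drop = FALSE]
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = genes)
}

#' Connected components and hubs of an interaction graph
#'
#' @param g an undirected `igraph` graph.
#' @param k_hub degree threshold for hub status (within the whole graph).
#' @return list with `components` (list of gene-id vectors, size-descending),
#'   `degrees` (data.frame `gene`, `degree`, `component`, `is_hub`).
#' @export
components_and_hubs <- function(g, k_hub = 10L) {
  stopifnot(k_hub >= 1)
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  comp_rank <- match(seq_along(comp$csize), ord)
  deg <- igraph::degree(g)
  degrees <- data.frame(
    gene = names(deg),
    degree = as.integer(deg),
    component = comp_rank[comp$membership],
    is_hub = deg >= k_hub,
    stringsAsFactors = FALSE
  )
  degrees <- degrees[order(degrees$component, -degrees$degree, degrees$gene), ]
  rownames(degrees) <- NULL
  components <- lapply(ord, function(k) {
    sort(names(comp$membership)[comp$membership == k])
  })
  list(components = components, degrees = degrees)
}

#' Write a component/degree report as TSV
#' @param report output of [components_and_hubs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ppi_report <- function(report, path) {
  utils::write.table(report$degrees, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
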