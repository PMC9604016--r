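# Protein-ligand interaction networks: the bipartite target-ligand
# association table projected onto targets. Edge weight = number of shared
# associated ligands; node size in the usual rendering = degree.

#' Build a protein-ligand interaction network
#'
#' Filters the consensus table at a minimum confidence, then projects the
#' bipartite target-ligand associations onto the targets: two targets are
#' connected iff they share at least one associated ligand, with the edge
#' weight equal to the number of shared ligands. Targets with ligands but no
#' shared ligand are kept as degree-0 nodes so per-target ligand counts stay
#' visible. Each node carries its ligand count (`n_ligands`) and its
#' `degree`.
#'
#' @param t a `consensus_table` from [build_consensus()].
#' @param min_confidence keep only pairings with at least this confidence
#'   (1-5).
#' @return an [igraph][igraph::igraph-package] graph; undirected, weighted,
#'   no self-edges, vertices and edges in sorted order (so exports are
#'   byte-stable).
#' @export
build_network <- function(t, min_confidence = 1L) {
  stopifnot(inherits(t, "consensus_table"))
  if (min_confidence < 1 || min_confidence > 5)
    stop("`min_confidence` must be in [1, 5]", call. = FALSE)
  t <- t[t$confidence >= min_confidence, , drop = FALSE]
  if (nrow(t) == 0L) {
    warning("no pairings at this confidence: empty network", call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  targets <- sort(unique(t$target_id))
  ligands <- sort(unique(t$ligand_id))
  inc <- matrix(0, length(targets), length(ligands),
                dimnames = list(targets, ligands))
  inc[cbind(match(t$target_id, targets), match(t$ligand_id, ligands))] <- 1
  shared <- tcrossprod(inc)  # shared-ligand counts between target pairs
  pairs <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  edges <- data.frame(from = targets[pairs[, 1]], to = targets[pairs[, 2]],
                      weight = shared[pairs], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  vert <- data.frame(name = targets, n_ligands = as.integer(rowSums(inc)),
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export a protein-ligand interaction network
#'
#' Nodes and edges are emitted in sorted order, so re-exporting an identical
#' network is byte-identical.
#'
#' @param g graph from [build_network()].
#' @param path output file path.
#' @param format `"edge_table"` (tab-delimited `target_a`, `target_b`,
#'   `weight`), `"sif"` (simple interaction format, relation
#'   `shares_ligands`; isolated nodes as bare lines), or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path,
                           format = c("edge_table", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el)) el <- el[order(el$from, el$to), , drop = FALSE]
  if (format == "edge_table") {
    out <- data.frame(target_a = el$from, target_b = el$to,
                      weight = el$weight, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- if (nrow(el))
      sprintf("%s\tshares_ligands\t%s", el$from, el$to) else character()
    isolated <- setdiff(igraph::V(g)$name,
                        unique(c(el$from, el$to)))
    writeLines(c(lines, sort(isolated)), path)
  }
  invisible(path)
}
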