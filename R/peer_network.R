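# Peer network: directed edges from each inefficient hospital to the
# best-practice hospitals (peers) it can learn from, weighted by the
# optimal intensity weights lambda. A peer's in-degree is its peer count
# (its influence on the safety performance of other hospitals).

#' Build the peer graph for one frontier
#'
#' @param scores,peers the tables from [score_frontiers()].
#' @param frontier `"group"` (default) or `"meta"`.
#' @return an [igraph::graph] (directed). Node attributes: `region`, `te`,
#'   `is_efficient`, `peer_count` (in-degree). Edge attribute: `weight`
#'   (lambda). Self-references of efficient units are omitted.
#' @export
build_peer_graph <- function(scores, peers, frontier = "group") {
  if (!frontier %in% c("group", "meta"))
    stop("frontier must be 'group' or 'meta'")
  sc <- scores[scores$frontier == frontier, , drop = FALSE]
  if (nrow(sc) == 0) stop("no scores for frontier '", frontier, "'")
  if (length(unique(sc$frontier)) != 1)
    stop("mixed-frontier input")
  pe <- peers[peers$frontier == frontier, , drop = FALSE]
  # drop self-references (efficient units cite themselves)
  pe <- pe[pe$dmu_id != pe$peer_id & pe$lambda > PEER_TOL, , drop = FALSE]

  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(sc$dmu_id, region = as.character(sc$region),
                     te = sc$te, is_efficient = sc$is_efficient)
  if (nrow(pe) > 0) {
    g <- igraph::add_edges(g, rbind(pe$dmu_id, pe$peer_id),
                           weight = pe$lambda)
  }
  igraph::V(g)$peer_count <- igraph::degree(g, mode = "in")
  g
}

#' Export a peer graph
#'
#' Writes an edge-list CSV (`source`, `target`, `weight`) and/or a
#' GraphML file with node attributes. With `pseudonymise = TRUE` all
#' hospital identifiers are replaced by stable salted hashes so exported
#' artefacts do not reveal hospital identities.
#'
#' @param graph an igraph from [build_peer_graph()].
#' @param path output path without extension.
#' @param format `"csv"`, `"graphml"` or both.
#' @param pseudonymise replace ids by salted pseudonyms.
#' @param salt salt for the pseudonym hash.
#' @return named character vector of files written, invisibly.
#' @export
export_graph <- function(graph, path, format = c("csv", "graphml"),
                         pseudonymise = FALSE, salt = "hacbench") {
  if (length(format) == 0 || !all(format %in% c("csv", "graphml")))
    stop("unknown export format; use 'csv' and/or 'graphml'")
  g <- graph
  if (pseudonymise) {
    igraph::V(g)$name <- pseudonymise_ids(igraph::V(g)$name, salt)
  }
  written <- character(0)
  if ("csv" %in% format) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(source = el[, 1], target = el[, 2],
                        weight = if (igraph::ecount(g) > 0)
                          igraph::E(g)$weight else numeric(0),
                        stringsAsFactors = FALSE)
    f <- paste0(path, "_edges.csv")
    utils::write.csv(edges, f, row.names = FALSE)
    written["csv"] <- f
  }
  if ("graphml" %in% format) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(g, f, format = "graphml")
    written["graphml"] <- f
  }
  invisible(written)
}

#' Read back an exported edge list
#'
#' @param file CSV written by [export_graph()].
#' @return data.frame `source`, `target`, `weight`.
#' @export
read_peer_edges <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric"))
}
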