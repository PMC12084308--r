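#' Build the directed cue-response graph
#'
#' For every cue and non-blank response in the table, a directed edge
#' cue -> response is created whose weight is the number of times that
#' response was produced for that cue. So if "cat" appears 20 times as a
#' response to the cue "dog", the edge dog -> cat has weight 20. Blank
#' cells are ignored; vertices are the tokens that occur as a cue or a
#' response.
#'
#' @param table a cleaned [norms_table()].
#' @return a directed weighted `igraph` graph with integer `weight` edge
#'   attribute and a `label` graph attribute from the table's source label.
#' @export
build_directed <- function(table) {
  cue <- rep(table$cue, 3L)
  resp <- c(table$R1, table$R2, table$R3)
  keep <- !is_blank(resp)
  cue <- cue[keep]
  resp <- resp[keep]
  if (length(cue) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  } else {
    key <- paste(cue, resp, sep = "\x1f")
    tab <- table(key)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    el <- data.frame(from = vapply(parts, `[[`, "", 1L),
                     to = vapply(parts, `[[`, "", 2L),
                     weight = as.integer(tab),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = TRUE)
  }
  g <- igraph::set_graph_attr(g, "label",
                              attr(table, "source_label") %||% "norms")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold a directed association graph to an undirected network
#'
#' Each unordered pair of nodes receives a single undirected edge whose
#' weight is the larger of the two directed weights (or the single directed
#' weight when only one direction exists): if dog -> cat has weight 20 and
#' cat -> dog weight 25, the undirected edge {dog, cat} has weight 25.
#' Self-loops are dropped; the semantic network carries none.
#'
#' @param g a directed weighted `igraph` graph.
#' @return an undirected weighted `igraph` graph (a semantic network).
#' @export
fold_undirected <- function(g) {
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "max", "ignore"))
  gu <- igraph::simplify(gu, remove.multiple = TRUE, remove.loops = TRUE,
                         edge.attr.comb = list(weight = "max", "ignore"))
  gu
}

#' Filter a semantic network
#'
#' The three filtering stages, applied in exactly this order:
#' \enumerate{
#'   \item remove nodes whose token is not in the lexicon (this is what
#'     eliminates nonsensical or non-word responses);
#'   \item remove idiosyncratic edges, i.e. edges of weight 1, so every
#'     surviving association was produced at least twice;
#'   \item keep only the largest connected component.
#' }
#' The order matters: a crafted graph filtered in a different order yields
#' a different (possibly disconnected) result.
#'
#' @param g an undirected weighted semantic network.
#' @param lexicon normalized lexicon entries (see [normalize_lexicon()]);
#'   multiword node tokens are matched with spaces, hyphens preserved.
#' @return the reduced network: connected, all weights >= 2, all nodes in
#'   the lexicon.
#' @export
filter_network <- function(g, lexicon) {
  keep <- igraph::V(g)$name %in% lexicon
  g1 <- igraph::induced_subgraph(g, which(keep))
  if (igraph::vcount(g1) == 0) {
    stop("filtering removed every node: no network node is in the lexicon")
  }
  g2 <- igraph::delete_edges(g1, igraph::E(g1)[igraph::E(g1)$weight < 2])
  comp <- igraph::components(g2)
  if (comp$no == 0 || max(comp$csize) == 0) {
    stop("filtering left an empty network")
  }
  big <- which.max(comp$csize)
  g3 <- igraph::induced_subgraph(g2, which(comp$membership == big))
  if (igraph::vcount(g3) == 0) stop("filtering left an empty network")
  g3
}

#' Basic statistics of an undirected network
#'
#' Density is \eqn{2E / (N (N - 1))} and average degree \eqn{2E / N},
#' the undirected conventions. Reports print density to 4 decimals and
#' average degree to 1 decimal; the raw values are returned.
#'
#' @param g an undirected `igraph` graph.
#' @return list of class `network_stats`: `n_nodes`, `n_edges`, `density`,
#'   `average_degree`.
#' @export
network_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("network_stats needs at least 2 nodes")
  out <- network_stats_from_counts(n, igraph::ecount(g))
  out$label <- igraph::graph_attr(g, "label")
  out
}

#' @rdname network_stats
#' @param n_nodes,n_edges node and edge counts of an undirected graph.
#' @export
network_stats_from_counts <- function(n_nodes, n_edges) {
  n <- as.numeric(n_nodes)
  e <- as.numeric(n_edges)
  if (n < 2) stop("network_stats needs at least 2 nodes")
  structure(list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    density = 2 * e / (n * (n - 1)),
    average_degree = 2 * e / n
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, "\n")
  cat(sprintf("  nodes: %d  edges: %d  density: %.4f  average degree: %.1f\n",
              x$n_nodes, x$n_edges, round(x$density, 4),
              round(x$average_degree, 1)))
  invisible(x)
}

# canonical unordered edge keys of an undirected graph
.edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g, names = TRUE)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  paste(a, b, sep = "\x1f")
}

#' Compare two semantic networks
#'
#' Node comparison over the two node sets: percentage of A nodes not in B,
#' percentage of all (union) nodes common to both, percentage of B nodes
#' not in A. The edge comparison uses the same three percentages but is
#' computed on the subgraphs induced by the common nodes, and edge identity
#' ignores weights. Percentages are rounded to the nearest integer for
#' reporting; raw values are retained.
#'
#' @param a,b undirected semantic networks.
#' @return list of class `network_comparison` with elements `nodes` and
#'   `edges` (each: `pct_a_only`, `pct_common`, `pct_b_only`, plus `raw`),
#'   and `edge_comparison_defined` (FALSE when the induced subgraphs carry
#'   no edges, in which case the edge percentages are reported as 0).
#' @export
compare_networks <- function(a, b) {
  na <- igraph::V(a)$name
  nb <- igraph::V(b)$name
  common <- intersect(na, nb)
  pcts <- function(xa, xb) {
    uni <- union(xa, xb)
    int <- intersect(xa, xb)
    raw <- c(
      pct_a_only = if (length(xa) == 0) 0 else 100 * length(setdiff(xa, xb)) / length(xa),
      pct_common = if (length(uni) == 0) 0 else 100 * length(int) / length(uni),
      pct_b_only = if (length(xb) == 0) 0 else 100 * length(setdiff(xb, xa)) / length(xb)
    )
    c(as.list(round(raw)), list(raw = raw))
  }
  nodes <- pcts(na, nb)
  ea <- .edge_keys(igraph::induced_subgraph(a, which(na %in% common)))
  eb <- .edge_keys(igraph::induced_subgraph(b, which(nb %in% common)))
  defined <- length(common) > 0 && (length(ea) + length(eb)) > 0
  edges <- pcts(ea, eb)
  structure(list(nodes = nodes, edges = edges,
                 edge_comparison_defined = defined),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("nodes: A-only %d%% | common %d%% | B-only %d%%\n",
              x$nodes$pct_a_only, x$nodes$pct_common, x$nodes$pct_b_only))
  if (x$edge_comparison_defined) {
    cat(sprintf("edges (common-node subgraphs): A-only %d%% | common %d%% | B-only %d%%\n",
                x$edges$pct_a_only, x$edges$pct_common, x$edges$pct_b_only))
  } else {
    cat("edges: comparison undefined (no edges between common nodes)\n")
  }
  invisible(x)
}

#' Export / import a weighted edge list
#'
#' Tab-separated `node1 node2 weight`, one edge per line, with a header.
#' GraphML export is available through [igraph::write_graph()] directly.
#'
#' @param g an undirected weighted `igraph` graph.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_edgelist_tsv()` returns the graph.
#' @export
write_edgelist_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                   weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"),
                          fileEncoding = "UTF-8")
  igraph::graph_from_data_frame(df, directed = FALSE)
}
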