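# shared fixtures: tiny graphs, noise presets, and data-frame comparison

zero_noise <- function() {
  list(misspelling = 0, leading_article = 0, blank = 0,
       nonsense_token = 0, pluralization = 0)
}

reversible_noise <- function() {
  list(misspelling = 0.05, leading_article = 0.05, blank = 0,
       nonsense_token = 0, pluralization = 0.05)
}

# column-wise equality of two norms tables, ignoring attributes
expect_norms_equal <- function(a, b) {
  for (col in c("cue", "R1", "R2", "R3")) {
    expect_identical(unname(a[[col]]), unname(b[[col]]))
  }
}

# undirected weighted graph from an edge data frame
ug <- function(from, to, weight) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE), directed = FALSE)
}

dg <- function(from, to, weight) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE), directed = TRUE)
}

# random connected weighted graph on n nodes (for simulator properties)
random_connected_graph <- function(n, p = 0.4, wmax = 5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- sample.int(wmax, igraph::ecount(g), replace = TRUE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# dense transition operator built independently of the simulator internals:
# entry (i, j) is the share of node j's activation arriving at i in one step
dense_spread_operator <- function(g, retention, weighted = TRUE) {
  n <- igraph::vcount(g)
  W <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (weighted) igraph::E(g)$weight else rep(1, nrow(el))
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    W[i, j] <- W[i, j] + w[e]
    W[j, i] <- W[j, i] + w[e]
  }
  s <- colSums(W)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (s[j] > 0) {
      M[, j] <- (1 - retention) * W[, j] / s[j]
      M[j, j] <- M[j, j] + retention
    } else {
      M[j, j] <- 1
    }
  }
  M
}
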