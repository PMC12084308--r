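#' Spreading-activation parameters
#'
#' Controls the retention/propagation process. At each synchronous time
#' step every node keeps `retention` of its activation and distributes the
#' remaining `1 - retention` among its neighbors proportionally to edge
#' weights (equally when `weighted = FALSE`); nodes without neighbors keep
#' everything. A nonzero `decay` multiplies all activation by
#' `1 - decay` after each step; activations below `suppress` are zeroed.
#' With `decay = 0` and `suppress = 0` total activation is conserved.
#'
#' `initial_activation = NULL` resolves, at run time, to the number of
#' nodes of the network being simulated, and `time_steps = NULL` to twice
#' the network diameter — the settings used for the priming validation.
#'
#' @param initial_activation nonnegative activation placed on the start
#'   node, or `NULL` (number of network nodes).
#' @param retention fraction in `[0, 1]` retained per step (default 0.5).
#' @param time_steps positive integer, or `NULL` (2 x diameter).
#' @param decay fraction in `[0, 1)` lost per step (default 0).
#' @param suppress threshold below which activation is zeroed (default 0).
#' @param weighted use edge weights when distributing (default TRUE).
#' @return list of class `spread_params`.
#' @export
spread_params <- function(initial_activation = NULL, retention = 0.5,
                          time_steps = NULL, decay = 0, suppress = 0,
                          weighted = TRUE) {
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  if (!is.null(time_steps) && time_steps < 1) stop("time_steps must be >= 1")
  if (decay < 0 || decay >= 1) stop("decay must be in [0, 1)")
  if (!is.null(initial_activation) && initial_activation < 0) {
    stop("initial_activation must be nonnegative")
  }
  structure(list(initial_activation = initial_activation,
                 retention = retention, time_steps = time_steps,
                 decay = decay, suppress = suppress, weighted = weighted),
            class = "spread_params")
}

.resolve_params <- function(params, g) {
  if (is.null(params$initial_activation)) {
    params$initial_activation <- igraph::vcount(g)
  }
  if (is.null(params$time_steps)) {
    params$time_steps <- 2L * net_diameter(g)
  }
  params
}

#' Unweighted diameter of a connected network
#'
#' The maximum over node pairs of the unweighted shortest-path length.
#' Edge weights in this pipeline encode association frequency (speed of
#' propagation), not distance, so path length is counted in hops.
#'
#' @param g a connected undirected `igraph` graph.
#' @return integer diameter.
#' @export
net_diameter <- function(g) {
  if (!igraph::is_connected(g)) {
    stop("diameter is defined on a connected network; filter the network first")
  }
  as.integer(igraph::diameter(g, directed = FALSE, weights = NA))
}

# One synchronous update of an n x k activation matrix.
# P is the column-stochastic propagation operator w_ij / strength_j
# (zero columns for isolated nodes); `retain` is the per-node retained
# fraction (1 for isolated nodes so they keep everything).
.spread_step <- function(A, P, retain, decay, suppress) {
  A1 <- retain * A + as.matrix(P %*% ((1 - retain) * A))
  if (decay > 0) A1 <- (1 - decay) * A1
  if (suppress > 0) A1[A1 < suppress] <- 0
  A1
}

.spread_operator <- function(g, params) {
  n <- igraph::vcount(g)
  W <- igraph::as_adjacency_matrix(g, attr = if (params$weighted &&
    "weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = TRUE)
  W <- W * 1.0  # force numeric sparse storage
  s <- Matrix::colSums(W)
  inv <- ifelse(s > 0, 1 / s, 0)
  P <- W %*% Matrix::Diagonal(n, x = inv)
  retain <- ifelse(s > 0, params$retention, 1)
  list(P = P, retain = retain)
}

#' Simulate spreading activation from one node
#'
#' Places `initial_activation` on `start` and runs `time_steps` synchronous
#' retention/propagation updates (see [spread_params()]).
#'
#' @param g an undirected (optionally weighted) `igraph` graph.
#' @param start name of the node to activate.
#' @param params a [spread_params()].
#' @param history if `TRUE`, also return the full activation trajectory.
#' @return named numeric vector of final activations (one per node). With
#'   `history = TRUE`, a matrix with `time_steps + 1` columns (step 0 is
#'   the initial state) and attribute `"final"`.
#' @export
spread <- function(g, start, params = spread_params(), history = FALSE) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  if (!(start %in% nodes)) stop("start node not in network: ", start)
  params <- .resolve_params(params, g)
  op <- .spread_operator(g, params)
  A <- matrix(0, nrow = length(nodes), ncol = 1, dimnames = list(nodes, start))
  A[match(start, nodes), 1] <- params$initial_activation
  if (history) traj <- matrix(A, nrow = length(nodes),
                              dimnames = list(nodes, NULL))
  for (t in seq_len(params$time_steps)) {
    A <- .spread_step(A, op$P, op$retain, params$decay, params$suppress)
    if (history) traj <- cbind(traj, A)
  }
  final <- stats::setNames(as.numeric(A), nodes)
  if (history) {
    colnames(traj) <- paste0("t", 0:params$time_steps)
    attr(traj, "final") <- final
    return(traj)
  }
  final
}

#' Final activation matrix over a set of primes
#'
#' Runs [spread()] from every prime and column-binds the final activation
#' vectors: rows are all network nodes, columns the activated primes. All
#' primes share the same parameters (resolved once against `g`), so the
#' result equals column-stacking individual runs.
#'
#' @param g an undirected (optionally weighted) `igraph` graph.
#' @param primes character vector of prime node names (duplicates allowed).
#' @param params a [spread_params()].
#' @return numeric matrix (nodes x primes) with attribute
#'   `normalized = FALSE` and the resolved parameters in attribute
#'   `"params"`.
#' @export
activation_matrix <- function(g, primes, params = spread_params()) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  missing <- setdiff(unique(primes), nodes)
  if (length(missing) > 0) {
    stop("prime node(s) not in network: ", paste(missing, collapse = ", "))
  }
  params <- .resolve_params(params, g)
  op <- .spread_operator(g, params)
  n <- length(nodes)
  k <- length(primes)
  A <- matrix(0, nrow = n, ncol = k, dimnames = list(nodes, primes))
  A[cbind(match(primes, nodes), seq_len(k))] <- params$initial_activation
  for (t in seq_len(params$time_steps)) {
    A <- .spread_step(A, op$P, op$retain, params$decay, params$suppress)
  }
  attr(A, "normalized") <- FALSE
  attr(A, "params") <- params
  A
}

#' Normalize an activation matrix
#'
#' L1 normalization, columns first and then rows: every column is divided
#' by its sum, then every nonzero row by its sum. This controls for node
#' centrality, so that the normalized final activations reflect priming
#' rather than hub effects. All-zero rows are left at zero and counted in
#' attribute `"zero_rows"`; an all-zero column is an error (a prime that
#' had no effect, impossible with zero decay).
#'
#' @param m an unnormalized matrix from [activation_matrix()].
#' @return the normalized matrix, entries in `[0, 1]`, attribute
#'   `normalized = TRUE`.
#' @export
normalize_matrix <- function(m) {
  if (isTRUE(attr(m, "normalized"))) return(m)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero activation column(s) for prime(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  m1 <- sweep(m, 2, cs, "/")
  rs <- rowSums(m1)
  nz <- rs > 0
  m1[nz, ] <- m1[nz, , drop = FALSE] / rs[nz]
  attr(m1, "normalized") <- TRUE
  attr(m1, "params") <- attr(m, "params")
  attr(m1, "zero_rows") <- sum(!nz)
  m1
}
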