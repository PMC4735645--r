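# Weighted graph topology of a band's connectivity matrix, following the
# Brain Connectivity Toolbox conventions: inverse-weight connection
# lengths, Dijkstra functional distances, Onnela weighted clustering with
# global max normalization, BCT-style weighted local efficiency.

# Accept a connectivity_matrix or a bare symmetric weight matrix.
as_weight_matrix <- function(W) {
  if (inherits(W, "connectivity_matrix")) W <- W$W
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (max(abs(W - t(W))) > 1e-9) stop("weight matrix must be symmetric")
  diag(W) <- 0
  W
}

#' Node strength
#'
#' Strength of a node is the sum of the weights of its connections to
#' all other nodes; the network mean is the arithmetic average of the
#' node strengths.
#'
#' @param W A `connectivity_matrix` or symmetric nonnegative matrix.
#' @return List with `strength` (per node) and `mean_strength`.
#' @export
node_strength <- function(W) {
  W <- as_weight_matrix(W)
  s <- rowSums(W)
  list(strength = s, mean_strength = mean(s))
}

#' Convert weights to connection lengths
#'
#' Inverse mapping `L_ij = 1 / W_ij`: strong connections are short.
#' Absent edges (weight 0) get infinite length; the diagonal stays 0.
#'
#' @param W A `connectivity_matrix` or symmetric nonnegative matrix.
#' @return The connection-length matrix.
#' @export
weight_to_length <- function(W) {
  W <- as_weight_matrix(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  L
}

#' Functional distance matrix (Dijkstra shortest paths)
#'
#' All-pairs shortest path lengths over the connection-length matrix.
#' Unreachable pairs have infinite distance.
#'
#' @param L Connection-length matrix (nonnegative; `Inf` = no edge).
#' @return Symmetric distance matrix `D` with zero diagonal.
#' @export
functional_distance <- function(L) {
  L <- as.matrix(L)
  if (any(L < 0)) stop("connection lengths must be nonnegative")
  diag(L) <- 0
  n <- nrow(L)
  adj <- L
  adj[!is.finite(adj)] <- 0 # igraph: 0 = no edge
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- dimnames(L)
  D
}

#' Characteristic path length
#'
#' Mean of the functional distance matrix over unordered node pairs with
#' finite distance (disconnected pairs are excluded from the mean).
#'
#' @param D Functional distance matrix.
#' @return Scalar; `NA_real_` when no finite pair exists.
#' @export
characteristic_path_length <- function(D) {
  D <- as.matrix(D)
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Weighted clustering coefficient
#'
#' Onnela geometric-mean-of-triangles formulation with global max
#' normalization: with `wh = W / max(W)`,
#' `C_i = sum_{j,h} (wh_ij wh_jh wh_ih)^(1/3) / (k_i (k_i - 1))`,
#' where `k_i` counts strictly positive neighbors. Nodes with fewer than
#' two neighbors score 0.
#'
#' @param W A `connectivity_matrix` or symmetric nonnegative matrix.
#' @return Per-node clustering coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(W) {
  W <- as_weight_matrix(W)
  mx <- max(W)
  if (mx == 0) return(stats::setNames(numeric(nrow(W)), rownames(W)))
  cw <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  tri <- diag(cw %*% cw %*% cw)
  C <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(C, rownames(W))
}

#' Weighted local efficiency
#'
#' BCT-style weighted local efficiency: for each node `u` with neighbor
#' set `V` (k = |V| >= 2),
#' `Eloc_u = sum_{j != h in V} (wh_uj wh_uh)^(1/3) / d_jh / (k (k - 1))`,
#' where `wh = W / max(W)` and `d_jh` is the shortest path between the
#' neighbors computed on the subgraph `V` with cube-root connection
#' lengths `(1 / wh)^(1/3)` (paths may only pass through neighbors of
#' `u`). Unreachable neighbor pairs contribute 0; nodes with fewer than
#' two neighbors score 0.
#'
#' @param W A `connectivity_matrix` or symmetric nonnegative matrix.
#' @return Per-node local efficiencies in `[0, 1]`.
#' @export
local_efficiency <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  mx <- max(W)
  out <- stats::setNames(numeric(n), rownames(W))
  if (mx == 0) return(out)
  wh <- W / mx
  for (u in seq_len(n)) {
    V <- which(wh[u, ] > 0)
    k <- length(V)
    if (k < 2) next
    Lsub <- ifelse(wh[V, V] > 0, (1 / wh[V, V])^(1 / 3), Inf)
    diag(Lsub) <- 0
    invd <- 1 / functional_distance(Lsub)
    diag(invd) <- 0
    invd[!is.finite(invd)] <- 0
    sw <- wh[u, V]^(1 / 3)
    out[u] <- sum(outer(sw, sw) * invd) / (k * (k - 1))
  }
  out
}

#' All graph metrics of one connectivity matrix
#'
#' Convenience bundle: node strengths, weighted clustering, local
#' efficiency, the connection-length and functional-distance matrices
#' and the characteristic path length.
#'
#' @param W A `connectivity_matrix` or symmetric nonnegative matrix.
#' @return A `graph_metrics` list.
#' @export
graph_metrics <- function(W) {
  M <- as_weight_matrix(W)
  st <- node_strength(M)
  L <- weight_to_length(M)
  D <- functional_distance(L)
  structure(list(strength = st$strength, mean_strength = st$mean_strength,
                 clustering = clustering_coefficient(M),
                 local_efficiency = local_efficiency(M),
                 lengths = L, distance = D,
                 char_path_length = characteristic_path_length(D)),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("<graph_metrics> %d nodes | mean strength %.4f | ",
                     "mean clustering %.4f | mean local efficiency %.4f | ",
                     "CPL %.4f\n"),
              length(x$strength), x$mean_strength, mean(x$clustering),
              mean(x$local_efficiency), x$char_path_length))
  invisible(x)
}
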