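# Independent brute-force oracles. These re-derive every graph quantity
# from first principles (no igraph, no package internals) so the package
# implementations are checked against a second, unrelated route.

# All-pairs shortest paths by Floyd-Warshall on a length matrix.
oracle_shortest_paths <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Onnela weighted clustering with global max normalization, by explicit
# triple enumeration.
oracle_clustering <- function(W) {
  n <- nrow(W)
  wh <- W / max(W)
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[j, h] * wh[i, h])^(1 / 3)
        }
      }
    }
    C[i] <- acc / (k * (k - 1))
  }
  C
}

# BCT-style weighted local efficiency: neighbor subgraph, cube-root
# lengths, Floyd-Warshall distances.
oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  wh <- W / max(W)
  E <- numeric(n)
  for (u in seq_len(n)) {
    V <- which(wh[u, ] > 0)
    k <- length(V)
    if (k < 2) next
    Ls <- ifelse(wh[V, V] > 0, (1 / wh[V, V])^(1 / 3), Inf)
    diag(Ls) <- 0
    d <- oracle_shortest_paths(Ls)
    acc <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b && is.finite(d[a, b])) {
          acc <- acc + (wh[u, V[a]] * wh[u, V[b]])^(1 / 3) / d[a, b]
        }
      }
    }
    E[u] <- acc / (k * (k - 1))
  }
  E
}

# Random sparse symmetric weight matrix in [0, 1), zero diagonal.
random_weight_matrix <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- sample(up, round(density * length(up)))
  W[on] <- runif(length(on), 0.05, 0.95)
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Two-way mixed ANOVA (between: group, within: band) from explicit sums
# of squares; balanced designs only.
oracle_mixed_anova <- function(A, B) {
  nb <- ncol(A)
  nA <- nrow(A); nB <- nrow(B)
  Y <- rbind(A, B)
  grp <- rep(c(1, 2), c(nA, nB))
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, grp, mean)
  band_means <- colMeans(Y)
  cell <- rbind(colMeans(A), colMeans(B))
  ss_between_subj <- nb * sum((subj_means - grand)^2)
  ss_group <- nb * sum(tabulate(grp) * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_band <- (nA + nB) * sum((band_means - grand)^2)
  ss_cells <- sum(rep(c(nA, nB), each = nb) *
                    (t(cell) - grand)^2)
  ss_gxb <- ss_cells - ss_group - ss_band
  ss_total <- sum((Y - grand)^2)
  ss_band_x_subj <- ss_total - ss_between_subj - ss_band - ss_gxb
  df_group <- 1; df_subj <- nA + nB - 2
  df_band <- nb - 1; df_int <- df_band
  df_err <- df_subj * df_band
  F_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  F_int <- (ss_gxb / df_int) / (ss_band_x_subj / df_err)
  list(F_group = F_group,
       p_group = stats::pf(F_group, df_group, df_subj, lower.tail = FALSE),
       F_interaction = F_int,
       p_interaction = stats::pf(F_int, df_int, df_err, lower.tail = FALSE))
}

# Small synthetic epoch_set used where a real recording is not needed.
toy_epochs <- function(n_channels = 3, n_epochs = 8, L = 256, rate = 128,
                       seed = 1) {
  set.seed(seed)
  m <- bundled_montage(if (n_channels <= 19) "1020-19" else "ba-84")
  eps <- lapply(seq_len(n_epochs), function(e) {
    matrix(rnorm(n_channels * L), n_channels, L)
  })
  structure(list(epochs = eps, rate = rate, epoch_length_s = L / rate,
                 labels = m$labels[seq_len(n_channels)],
                 coords = m$coords[seq_len(n_channels), , drop = FALSE]),
            class = "epoch_set")
}
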