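# Group-level statistics: physical-distance relations, Fisher r-to-z
# machinery, edgewise significance maps, cross-frequency coupling and the
# group x band repeated-measures ANOVA.

#' Pairwise physical distance between nodes
#'
#' Euclidean distance in MNI space:
#' `sqrt((x_i - x_j)^2 + (y_i - y_j)^2 + (z_i - z_j)^2)`, in mm.
#'
#' @param coords n x 3 coordinate matrix (or a `recording`).
#' @return Symmetric n x n distance matrix (mm), zero diagonal.
#' @export
physical_distance <- function(coords) {
  if (inherits(coords, "recording")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 coordinate triples")
  P <- as.matrix(stats::dist(coords))
  dimnames(P) <- list(rownames(coords), rownames(coords))
  P
}

# Upper-triangle edge values of a square matrix, in a fixed (column-major)
# order shared by every edgewise computation.
edge_values <- function(M) {
  M <- if (inherits(M, "connectivity_matrix")) M$W else as.matrix(M)
  M[upper.tri(M)]
}

#' Regress an edgewise quantity on physical distance
#'
#' Ordinary least squares of a per-edge quantity (connectivity weight or
#' functional distance) on the physical distance of the same edges, with
#' the Pearson correlation. Edges with non-finite values (disconnected
#' pairs) are excluded and counted.
#'
#' @param values Square matrix of the edge quantity (or
#'   `connectivity_matrix`).
#' @param P Physical distance matrix from [physical_distance()].
#' @return A `regression_result`: `slope`, `intercept`, `r`, `n`, `t`,
#'   `p` (two-sided, slope), `n_excluded`.
#' @export
distance_regression <- function(values, P) {
  y <- edge_values(values)
  x <- edge_values(P)
  keep <- is.finite(y) & is.finite(x)
  n_excl <- sum(!keep)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("need at least 3 finite edges")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["x", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 r = stats::cor(x, y), n = length(y),
                 t = unname(sm["x", "t value"]),
                 p = unname(sm["x", "Pr(>|t|)"]),
                 n_excluded = n_excl),
            class = "regression_result")
}

#' Compare distance-regression slopes between two groups
#'
#' Pools the edges of both groups into one regression
#' `value ~ distance * group` and t-tests the group x distance
#' interaction (two-sided). A positive t means group B's slope is the
#' larger; swapping the groups negates t.
#'
#' @param valuesA,valuesB Edge-quantity matrices for groups A and B.
#' @param P Shared physical distance matrix (matched node sets).
#' @return List with `t`, `p`, `df`, `slope_diff` (slope_B - slope_A)
#'   and the per-group slopes.
#' @export
compare_regression_slopes <- function(valuesA, valuesB, P) {
  pd <- edge_values(P)
  build <- function(vals, g) {
    y <- edge_values(vals)
    keep <- is.finite(y) & is.finite(pd)
    if (sum(keep) < 3) stop("need at least 3 finite edges per group")
    data.frame(y = y[keep], x = pd[keep], group = g)
  }
  df <- rbind(build(valuesA, "A"), build(valuesB, "B"))
  df$group <- factor(df$group, levels = c("A", "B"))
  fit <- stats::lm(y ~ x * group, data = df)
  sm <- summary(fit)$coefficients
  if (!("x:groupB" %in% rownames(sm))) stop("singular design")
  slopes <- c(A = unname(sm["x", "Estimate"]),
              B = unname(sm["x", "Estimate"] + sm["x:groupB", "Estimate"]))
  list(t = unname(sm["x:groupB", "t value"]),
       p = unname(sm["x:groupB", "Pr(>|t|)"]),
       df = fit$df.residual,
       slope_diff = unname(sm["x:groupB", "Estimate"]),
       slopes = slopes)
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)` with standard error `1 / sqrt(n - 3)`.
#'
#' @param r Correlation, `|r| < 1`.
#' @param n Sample size behind `r` (> 3).
#' @return List with `z` and `se`.
#' @export
#' @examples
#' fisher_z(0.5, 103) # z = 0.5493, se = 0.1
fisher_z <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher transform")
  if (any(n <= 3)) stop("need n > 3")
  list(z = atanh(r), se = 1 / sqrt(n - 3))
}

#' Compare two independent correlations (Fisher z test)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred
#' to the standard normal; two-sided p.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  z1 <- fisher_z(r1, n1); z2 <- fisher_z(r2, n2)
  z <- (z1$z - z2$z) / sqrt(z1$se^2 + z2$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cross-frequency coupling of shortest-path structure
#'
#' Pearson correlation, across unordered edges, between the functional
#' distances of a low band and a high band (parallel processing of the
#' same routes at two timescales shows up as a positive correlation).
#' Only edges finite in both bands enter; their count is the `n` used in
#' downstream Fisher z comparisons.
#'
#' @param D_low,D_high Functional distance matrices of the two bands
#'   (matched node sets).
#' @return List with `r`, `n` (finite common edges) and `n_excluded`.
#' @export
cross_frequency_coupling <- function(D_low, D_high) {
  x <- edge_values(D_low); y <- edge_values(D_high)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("need at least 3 common finite edges")
  list(r = stats::cor(x[keep], y[keep]), n = sum(keep),
       n_excluded = sum(!keep))
}

#' Edgewise group-difference map
#'
#' For every edge, the two groups' connectivity weights (bounded in
#' `[0, 1)`, treated as correlation-like) are compared with the Fisher z
#' test at the group sample sizes, Bonferroni-corrected over edges.
#' Significant edges are labelled by which group's functional distance
#' is longer, reproducing the tri-valued red/black/white map semantics:
#' `"A-longer"`, `"B-longer"`, `"ns"`.
#'
#' @param W_A,W_B Group connectivity weight matrices.
#' @param D_A,D_B Group functional distance matrices (direction labels).
#' @param n_A,n_B Group sample sizes (> 3), e.g. subjects per group.
#' @param alpha_level Family-wise significance level (default 0.05).
#' @return An `edgewise_map`: character matrix of edge classes plus
#'   `z` matrix, per-class `counts`, and the per-test level used.
#' @export
edgewise_group_map <- function(W_A, W_B, D_A, D_B, n_A, n_B,
                               alpha_level = 0.05) {
  A <- if (inherits(W_A, "connectivity_matrix")) W_A$W else as.matrix(W_A)
  B <- if (inherits(W_B, "connectivity_matrix")) W_B$W else as.matrix(W_B)
  DA <- as.matrix(D_A); DB <- as.matrix(D_B)
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(DA)),
            all(dim(A) == dim(DB)))
  if (n_A <= 3 || n_B <= 3) stop("group sample sizes must exceed 3")
  n <- nrow(A)
  n_edges <- n * (n - 1) / 2
  per_test <- alpha_level / n_edges
  se <- sqrt(1 / (n_A - 3) + 1 / (n_B - 3))
  Z <- (atanh(A) - atanh(B)) / se
  diag(Z) <- 0
  P <- 2 * stats::pnorm(-abs(Z))
  cls <- matrix("ns", n, n, dimnames = dimnames(A))
  sig <- P < per_test & upper.tri(P)
  sig <- sig | t(sig)
  a_longer <- DA > DB
  # distance tie or non-finite on both sides: fall back to weight direction
  und <- !is.finite(DA - DB) | DA == DB
  a_longer[und] <- A[und] < B[und]
  cls[sig & a_longer] <- "A-longer"
  cls[sig & !a_longer] <- "B-longer"
  diag(cls) <- "ns"
  ev <- cls[upper.tri(cls)]
  structure(list(classes = cls, z = Z,
                 counts = c("A-longer" = sum(ev == "A-longer"),
                            "B-longer" = sum(ev == "B-longer"),
                            ns = sum(ev == "ns")),
                 n_edges = n_edges, per_test_level = per_test),
            class = "edgewise_map")
}

#' Group x frequency-band repeated-measures ANOVA
#'
#' Two-way mixed ANOVA on a per-unit network metric measured in every
#' band: between-subject factor group, within-subject factor band. The
#' observational units are nodes (for strength, clustering, local
#' efficiency) or edges of the group networks. Reports the group main
#' effect (tested against units-within-group), the group x band
#' interaction (tested against the band x unit stratum), and per-band
#' simple contrasts: pooled-variance t-tests, reported as F = t^2 with
#' one-tailed p in the direction of the observed mean difference.
#'
#' @param valuesA,valuesB Units x bands numeric matrices, identical band
#'   columns in the same order (default: the eight canonical bands).
#' @param band_names Band labels; default from the column names.
#' @return A `group_band_anova` list: `group` (F, df, p), `interaction`
#'   (F, df, p), and `contrasts` (one row per band: F, t, df, one-tailed
#'   p, direction `"A>B"`/`"B>A"`, group means).
#' @export
group_band_anova <- function(valuesA, valuesB, band_names = NULL) {
  valuesA <- as.matrix(valuesA); valuesB <- as.matrix(valuesB)
  if (ncol(valuesA) != ncol(valuesB)) {
    stop("both groups must be measured in the same bands")
  }
  if (nrow(valuesA) < 2 || nrow(valuesB) < 2) {
    stop("need at least 2 units per group")
  }
  if (is.null(band_names)) band_names <- colnames(valuesA)
  if (is.null(band_names)) band_names <- paste0("band", seq_len(ncol(valuesA)))
  nb <- ncol(valuesA)
  nA <- nrow(valuesA); nB <- nrow(valuesB)
  df <- data.frame(
    value = c(as.vector(t(valuesA)), as.vector(t(valuesB))),
    band = factor(rep(band_names, times = nA + nB), levels = band_names),
    group = factor(rep(c("A", "B"), c(nA * nb, nB * nb)),
                   levels = c("A", "B")),
    unit = factor(rep(seq_len(nA + nB), each = nb))
  )
  if (any(!is.finite(df$value))) stop("metric values must be finite")
  fit <- stats::aov(value ~ group * band + Error(unit / band), data = df)
  sm <- summary(fit)
  btw <- sm[["Error: unit"]][[1]]
  wth <- sm[["Error: unit:band"]][[1]]
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    list(F = tab[i, "F value"], df = c(tab[i, "Df"],
                                       tab[nrow(tab), "Df"]),
         p = tab[i, "Pr(>F)"])
  }
  contrasts <- do.call(rbind, lapply(seq_len(nb), function(b) {
    a <- valuesA[, b]; bb <- valuesB[, b]
    sp <- sqrt(((nA - 1) * stats::var(a) + (nB - 1) * stats::var(bb)) /
                 (nA + nB - 2))
    t <- (mean(a) - mean(bb)) / (sp * sqrt(1 / nA + 1 / nB))
    if (!is.finite(t)) t <- 0
    data.frame(band = band_names[b], F = t^2, t = t, df = nA + nB - 2,
               p_one_tailed = stats::pt(abs(t), nA + nB - 2,
                                        lower.tail = FALSE),
               direction = if (t >= 0) "A>B" else "B>A",
               mean_A = mean(a), mean_B = mean(bb))
  }))
  structure(list(group = grab(btw, "group"),
                 interaction = grab(wth, "group:band"),
                 contrasts = contrasts),
            class = "group_band_anova")
}

#' @export
print.group_band_anova <- function(x, ...) {
  cat(sprintf("group main effect:      F = %.3f, p = %.4g\n",
              x$group$F, x$group$p))
  cat(sprintf("group x band interaction: F = %.3f, p = %.4g\n",
              x$interaction$F, x$interaction$p))
  cat("per-band simple contrasts (one-tailed):\n")
  print(x$contrasts[, c("band", "F", "p_one_tailed", "direction")],
        row.names = FALSE)
  invisible(x)
}
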