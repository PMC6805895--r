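## Cell ranking along a latent polarization axis: preprocessing, a
## fixed-point ICA with stability selection across repeated runs, component
## orientation against the anti-tumor zone, and the two grouping rules
## (sign split, extreme-quartile split).

#' Construct an expression matrix container
#'
#' @param values numeric genes x cells matrix (log scale) with unique row
#'   (gene) and column (cell) names; no missing values.
#' @param centered logical: have gene means already been removed?
#' @return an object of class `expression_matrix`: list with `values`,
#'   `genes`, `cells`, `centered`.
#' @export
expression_matrix <- function(values, centered = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and cell column names")
  if (anyDuplicated(rownames(values))) stop("gene symbols must be unique")
  if (centered && max(abs(rowMeans(values))) > 1e-9)
    stop("matrix declared centered but row means are not 0")
  structure(list(values = values, genes = rownames(values),
                 cells = colnames(values), centered = isTRUE(centered)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", length(x$genes), "genes x", length(x$cells),
      "cells;", if (x$centered) "centered" else "uncentered", "\n")
  invisible(x)
}

#' Log-transform and mean-center expression
#'
#' Raw values are transformed to log2(x + 1); already-log input is used as
#' is. Each gene is then centered to mean 0 across cells.
#'
#' @param values numeric genes x cells matrix, or an `expression_matrix`.
#' @param already_log logical; when FALSE, values must be non-negative.
#' @return a centered `expression_matrix`.
#' @export
preprocess <- function(values, already_log = TRUE) {
  if (inherits(values, "expression_matrix")) values <- values$values
  if (anyNA(values)) stop("input contains NaN/NA values")
  if (!already_log) {
    if (any(values < 0)) stop("raw expression must be non-negative")
    values <- log2(values + 1)
  }
  values <- values - rowMeans(values)
  expression_matrix(values, centered = TRUE)
}

## One FastICA fit on whitened data: fixed-point iteration with the
## log-cosh contrast (g = tanh) and symmetric decorrelation. Y is k x n with
## orthonormal-by-construction unit-variance rows. When the direction change
## stops halving (the period-2 oscillation fixed-point iterations fall into
## near weakly non-Gaussian directions) the update is stabilized by a
## sign-aligned half-step. Returns the k x k unmixing matrix and a
## convergence flag.
fastica_core <- function(Y, tol = 1e-4, max_iter = 200L) {
  k <- nrow(Y); n <- ncol(Y)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))  # random orthogonal start
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                       k) %*% t(e$vectors) %*% W
  }
  W <- sym_decor(W)
  converged <- FALSE
  prev_delta <- Inf
  for (it in seq_len(max_iter)) {
    U <- W %*% Y
    G <- tanh(U)
    W_new <- (G %*% t(Y)) / n - diag(rowMeans(1 - G^2), k) %*% W
    W_new <- sym_decor(W_new)
    # direction change per component, sign-invariant
    align <- rowSums(W_new * W)
    delta <- max(abs(1 - abs(align)))
    if (delta >= 0.5 * prev_delta && delta >= tol) {
      W_new <- sym_decor(0.5 * (W_new + sign(align) * W))
    }
    prev_delta <- delta
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged)
}

## Greedy stability clustering of pooled components by absolute Pearson
## correlation of their cell projections. Each cluster seeds on the
## unassigned component with most unassigned neighbours at |r| >= threshold.
cluster_components <- function(R, threshold = 0.85) {
  m <- nrow(R)
  unassigned <- rep(TRUE, m)
  clusters <- list()
  adj <- R >= threshold
  diag(adj) <- FALSE
  while (any(unassigned)) {
    cand <- which(unassigned)
    deg <- rowSums(adj[cand, unassigned, drop = FALSE])
    seed <- cand[which.max(deg)]  # ties: first index
    members <- which(unassigned & (adj[seed, ] | seq_len(m) == seed))
    clusters[[length(clusters) + 1L]] <- members
    unassigned[members] <- FALSE
  }
  clusters
}

## Cluster quality: mean intra-cluster |r| (0 for singletons) minus mean
## |r| to out-of-cluster components (0 when none), clamped to [0, 1].
cluster_stability <- function(R, members) {
  m <- nrow(R)
  if (length(members) > 1L) {
    sub <- R[members, members, drop = FALSE]
    intra <- mean(sub[upper.tri(sub)])
  } else intra <- 0
  outside <- setdiff(seq_len(m), members)
  extra <- if (length(outside)) mean(R[members, outside]) else 0
  min(max(intra - extra, 0), 1)
}

#' Run ICA with stability-based component selection
#'
#' Each run whitens the (optionally gene-bootstrapped) centered matrix by
#' truncated SVD and decomposes it with a fixed-point ICA (log-cosh
#' contrast, symmetric decorrelation) from a seeded random orthogonal start.
#' By default every run resamples the genes with replacement, so a component
#' must be reproducible under data perturbation — not merely under restarts
#' — to score as stable; spurious optima of noise do not survive this.
#' Components pooled across runs are clustered greedily at absolute Pearson
#' projection correlation >= `cluster_threshold`; each cluster's stability
#' index is its mean within-cluster similarity minus its mean similarity to
#' everything else, and the component returned for a cluster is the member
#' closest to the cluster centroid. Components are sorted by stability; the
#' most stable one is IC1, used downstream to rank cells. Gene loadings of
#' the returned components are per-gene least-squares coefficients on the
#' component's cell projection.
#'
#' @param matrix a centered `expression_matrix`.
#' @param n_components number of components; default `min(10, cells - 1)`.
#' @param n_runs number of resampled restarts pooled for stability (>= 2).
#' @param seed integer seed; per-run seeds default to `seed + 0:(n_runs-1)`.
#' @param tol convergence tolerance on the unmixing direction change.
#' @param max_iter maximum fixed-point iterations per run.
#' @param cluster_threshold |r| threshold for pooling components.
#' @param stability_warn clusters are "sufficiently stable" above this;
#'   a lower top stability triggers a warning (not an error).
#' @param run_seeds optional explicit integer vector of per-run seeds.
#' @param resample `"genes"` (bootstrap gene rows per run, the default) or
#'   `"none"` (restarts only).
#' @return an object of class `ica_result`: `projections` (cells x k),
#'   `loadings` (genes x k), `stability` (non-increasing, in \[0, 1\]),
#'   `selected` (index of IC1, always 1), `n_converged`.
#' @export
run_ica <- function(matrix, n_components = NULL, n_runs = 20L, seed = 1L,
                    tol = 1e-4, max_iter = 200L, cluster_threshold = 0.85,
                    stability_warn = 0.5, run_seeds = NULL,
                    resample = c("genes", "none")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  resample <- match.arg(resample)
  if (!matrix$centered) stop("run_ica requires a centered matrix")
  X <- matrix$values
  n_genes <- nrow(X); n_cells <- ncol(X)
  if (is.null(n_components)) n_components <- min(10L, n_cells - 1L)
  if (n_components > min(n_genes, n_cells))
    stop("n_components exceeds matrix rank bound")
  if (n_runs < 2L) stop("n_runs must be >= 2 for stability selection")
  if (is.null(run_seeds)) run_seeds <- seed + seq_len(n_runs) - 1L
  stopifnot(length(run_seeds) == n_runs)

  proj_pool <- vector("list", n_runs); conv <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[[r]])
    Xr <- if (resample == "genes")
      X[sample.int(n_genes, n_genes, replace = TRUE), , drop = FALSE]
    else X
    # per-run SVD whitening: rows of Y are uncorrelated unit-variance
    # cell signals
    sv <- svd(Xr, nu = 0, nv = n_components)
    Y <- t(sv$v[, seq_len(n_components), drop = FALSE]) * sqrt(n_cells)
    fit <- fastica_core(Y, tol = tol, max_iter = max_iter)
    conv[[r]] <- fit$converged
    proj_pool[[r]] <- t(fit$W %*% Y)              # cells x k projections
  }
  if (!any(conv)) stop("no ICA run converged; increase max_iter or tol")

  P <- do.call(cbind, proj_pool)                  # cells x (k * n_runs)
  R <- abs(stats::cor(P))
  clusters <- cluster_components(R, cluster_threshold)
  stab <- vapply(clusters, function(cl) cluster_stability(R, cl), numeric(1))
  reps <- vapply(clusters, function(cl) {
    if (length(cl) == 1L) return(cl)
    centroid_sim <- rowMeans(R[cl, cl, drop = FALSE])
    cl[which.max(centroid_sim)]
  }, integer(1))
  ord <- order(stab, decreasing = TRUE)
  stab <- stab[ord]; reps <- reps[ord]

  if (stab[[1]] < stability_warn)
    warning(sprintf(
      "top stability index %.3f is below the 'sufficiently stable' threshold %.2f",
      stab[[1]], stability_warn))

  projections <- P[, reps, drop = FALSE]
  # loadings on the original (un-resampled) genes: per-gene least squares
  # on each representative projection
  loadings <- (X %*% projections) %*%
    diag(1 / colSums(projections^2), length(reps))
  colnames(projections) <- colnames(loadings) <-
    paste0("IC", seq_along(reps))
  rownames(projections) <- matrix$cells
  rownames(loadings) <- matrix$genes
  structure(list(projections = projections, loadings = loadings,
                 stability = stab, selected = 1L,
                 n_converged = sum(conv)),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat("<ica_result>", ncol(x$projections), "stability-selected components;",
      "IC1 stability", format(x$stability[[1]], digits = 3), "\n")
  invisible(x)
}

#' @export
summary.ica_result <- function(object, ...) {
  data.frame(component = colnames(object$projections),
             stability = object$stability,
             row.names = NULL)
}

#' Plot per-cell IC1 projections
#'
#' @param x an `ica_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ica_result <- function(x, ...) {
  p <- sort(x$projections[, x$selected])
  graphics::plot(seq_along(p), p, xlab = "cell rank",
                 ylab = "IC1 projection", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Orient IC1 against the anti-tumor zone
#'
#' The sign of an independent component is arbitrary; for reproducible group
#' labels IC1 is flipped, if needed, so that its mean loading over the genes
#' of the hierarchy's anti-tumor zone is >= 0 (an exactly zero mean leaves
#' the component unchanged). Idempotent.
#'
#' @param result an `ica_result`.
#' @param hierarchy a `map_hierarchy` with an `"Anti-tumor"` zone.
#' @param matrix the `expression_matrix` the result was fitted on.
#' @return the (possibly sign-flipped) `ica_result`.
#' @export
orient_component <- function(result, hierarchy, matrix) {
  if (!"Anti-tumor" %in% names(hierarchy$zones))
    stop("hierarchy has no 'Anti-tumor' zone")
  anti <- hierarchy$genes$zone[["Anti-tumor"]]
  common <- intersect(anti, matrix$genes)
  if (length(common) == 0L)
    stop("anti-tumor zone shares no genes with the expression matrix")
  j <- result$selected
  m <- mean(result$loadings[common, j])
  if (m < 0) {
    result$loadings[, j] <- -result$loadings[, j]
    result$projections[, j] <- -result$projections[, j]
  }
  result$oriented <- TRUE
  result
}

#' Split cells by the sign of the IC1 projection
#'
#' Group 1 collects cells with positive IC1 projection, group 2 negative;
#' exactly-zero projections are unassigned.
#'
#' @param result an (oriented) `ica_result`.
#' @return an object of class `cell_groups`: named factor-like character
#'   vector per cell with levels `group1`, `group2`, `unassigned`.
#' @export
split_by_sign <- function(result) {
  p <- result$projections[, result$selected]
  lab <- ifelse(p > 0, "group1", ifelse(p < 0, "group2", "unassigned"))
  if (!any(lab == "group1") || !any(lab == "group2"))
    stop("sign split produced an empty group")
  structure(stats::setNames(lab, rownames(result$projections)),
            class = "cell_groups")
}

#' Split cells into extreme quartiles of the IC1 projection
#'
#' Keeps the "extreme" cells: group 2 is the first quartile (projection <=
#' Q1), group 1 the last (projection >= Q3, the anti-tumor side after
#' orientation); the middle is unassigned. Quartiles use the
#' linear-interpolation convention. Heavy boundary ties making either group
#' exceed 40% of cells are an error.
#'
#' @param result an (oriented) `ica_result`.
#' @return a `cell_groups` object.
#' @export
split_by_quartiles <- function(result) {
  p <- result$projections[, result$selected]
  if (length(p) < 8L) stop("quartile split needs at least 8 cells")
  q <- stats::quantile(p, c(0.25, 0.75), type = 7, names = FALSE)
  lab <- rep("unassigned", length(p))
  lab[p <= q[[1]]] <- "group2"
  lab[p >= q[[2]]] <- "group1"
  if (max(sum(lab == "group1"), sum(lab == "group2")) > 0.4 * length(p))
    stop("degenerate quartile boundaries: ties make a group exceed 40% of cells")
  structure(stats::setNames(lab, rownames(result$projections)),
            class = "cell_groups")
}

#' @export
print.cell_groups <- function(x, ...) {
  cat("<cell_groups>", sum(x == "group1"), "in group1,",
      sum(x == "group2"), "in group2,",
      sum(x == "unassigned"), "unassigned\n")
  invisible(x)
}

#' Principal-component coordinates of cells
#'
#' Projections of cells onto the first k right singular directions of the
#' centered matrix, ordered by singular value, with the sign convention that
#' each component's largest-magnitude gene loading is positive.
#'
#' @param matrix a centered `expression_matrix`.
#' @param k number of components (default 2).
#' @return cells x k numeric matrix with columns `PC1`, ...
#' @export
pca_coordinates <- function(matrix, k = 2L) {
  stopifnot(inherits(matrix, "expression_matrix"), matrix$centered)
  X <- matrix$values
  if (k > min(dim(X))) stop("k exceeds min(genes, cells)")
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                            k),
                  2, flip, `*`)
  dimnames(coords) <- list(matrix$cells, paste0("PC", seq_len(k)))
  coords
}
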