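# Independent oracles used to cross-check the package's statistics, plus
# small fixture builders. Everything here is deliberately brute-force.

# All-pairs shortest paths by Floyd-Warshall on a symbol adjacency matrix.
floyd_warshall <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      d[a, b] <- d[b, a] <- 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# FUNC oracle: mean pairwise FW distance binned to the 0-5 scale,
# re-derived from the declared rule rather than the package code.
func_oracle <- function(dist_matrix, participants) {
  participants <- unique(participants)
  if (length(participants) < 2L) return(0L)
  if (!all(participants %in% rownames(dist_matrix))) return(0L)
  d <- dist_matrix[participants, participants]
  vals <- d[upper.tri(d)]
  if (any(!is.finite(vals))) return(0L)
  dbar <- mean(vals)
  if (dbar <= 1) 5L else if (dbar <= 2) 4L else if (dbar <= 3) 3L
  else if (dbar <= 4) 2L else 1L
}

# Textbook Welch t statistic, degrees of freedom and two-sided p.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration with
# choose(); usable for universes up to ~20 genes.
hyper_tail_enum <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Random undirected graph on m nodes as an edge matrix (no self-loops).
random_graph_edges <- function(m, p) {
  nodes <- paste0("P", seq_len(m))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

# Random valid four-level hierarchy with genes drawn (with reuse) from a
# shared pool, so genes can sit in several pathways.
random_hierarchy <- function() {
  nz <- sample(2:3, 1)
  pool <- paste0("g", seq_len(sample(20:60, 1)))
  zones <- list(); metas <- list(); mods <- list(); paths <- list()
  mm_i <- 0; md_i <- 0; pw_i <- 0
  for (z in seq_len(nz)) {
    zn <- paste0("Z", z)
    mm_names <- paste0("MM", mm_i + seq_len(sample(1:3, 1))); mm_i <- mm_i + length(mm_names)
    zones[[zn]] <- mm_names
    for (mm in mm_names) {
      md_names <- paste0("MD", md_i + seq_len(sample(1:3, 1))); md_i <- md_i + length(md_names)
      metas[[mm]] <- md_names
      for (md in md_names) {
        pw_names <- paste0("PW", pw_i + seq_len(sample(1:3, 1))); pw_i <- pw_i + length(pw_names)
        mods[[md]] <- pw_names
        for (pw in pw_names) paths[[pw]] <- sample(pool, sample(1:8, 1))
      }
    }
  }
  build_hierarchy(zones, metas, mods, paths)
}

# Tiny single-chain hierarchy used across map-model tests.
chain_hierarchy <- function(genes = c("g1", "g2")) {
  build_hierarchy(zones = list(A = "M1"),
                  meta_modules = list(M1 = "mod1"),
                  modules = list(mod1 = "p1"),
                  pathways = list(p1 = genes))
}

# Expression matrix from a bare numeric matrix with default dimnames.
as_expr <- function(values, centered = FALSE) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  expression_matrix(values, centered = centered)
}

# Manually labelled cell groups.
as_groups <- function(labels, cells = names(labels)) {
  if (is.null(cells)) cells <- paste0("c", seq_along(labels))
  structure(stats::setNames(labels, cells), class = "cell_groups")
}
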