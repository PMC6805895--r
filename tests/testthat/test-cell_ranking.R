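test_that("preprocessing log-transforms and mean-centers per gene", {
  m <- as_expr(rbind(g1 = c(1, 3)))
  out <- preprocess(m, already_log = TRUE)
  expect_equal(unname(out$values[1, ]), c(-1, 1))
  expect_true(out$centered)

  raw <- as_expr(rbind(g1 = c(0, 3)))
  out2 <- preprocess(raw, already_log = FALSE)
  expect_equal(unname(out2$values[1, ]), c(-1, 1))  # log2(0+1)=0, log2(4)=2

  const <- as_expr(rbind(g1 = c(2, 2, 2)))
  expect_equal(unname(preprocess(const)$values[1, ]), c(0, 0, 0))

  neg <- as_expr(rbind(g1 = c(-1, 3)))
  expect_error(preprocess(neg, already_log = FALSE), "non-negative")
  bad <- rbind(g1 = c(NA, 3)); colnames(bad) <- c("c1", "c2")
  expect_error(preprocess(bad), "NaN/NA")

  expect_error(expression_matrix(rbind(g1 = c(1, 2)), centered = TRUE),
               "row names|column names")
})

make_sim <- function(seed = 1, ...) {
  spec <- simulation_spec(seed = seed, ...)
  map <- generate_map(spec)
  sim <- generate_cells(map$hierarchy, spec)
  list(spec = spec, map = map, sim = sim,
       expr = preprocess(sim$expression$values))
}

test_that("stability-selected ICA recovers the planted gradient", {
  s <- make_sim()
  res <- run_ica(s$expr, seed = 1)
  expect_true(!is.unsorted(rev(res$stability)))       # non-increasing
  expect_true(all(res$stability >= 0 & res$stability <= 1))
  expect_equal(res$selected, 1L)

  rho <- abs(cor(res$projections[, 1], s$sim$truth$latent,
                 method = "spearman"))
  expect_gte(rho, 0.9)

  # whitening: distinct selected components stay near-uncorrelated
  r12 <- abs(cor(res$projections[, 1], res$projections[, 2]))
  expect_lte(r12, 0.1)

  # duplicate runs with identical per-run seeds: top stability exactly 1
  res_dup <- run_ica(s$expr, n_runs = 5L, run_seeds = rep(7L, 5))
  expect_equal(res_dup$stability[1], 1, tolerance = 1e-9)

  # reproducibility of the whole procedure
  res2 <- run_ica(s$expr, seed = 1)
  expect_identical(res$projections, res2$projections)
})

test_that("pure Gaussian input yields no sufficiently stable component", {
  set.seed(40)
  hits <- 0L
  for (i in 1:10) {
    x <- matrix(rnorm(120 * 60), 120, 60,
                dimnames = list(paste0("g", 1:120), paste0("c", 1:60)))
    expr <- preprocess(x)
    res <- suppressWarnings(run_ica(expr, n_components = 5L, n_runs = 8L,
                                    seed = i))
    if (res$stability[1] < 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("component orientation is deterministic and idempotent", {
  s <- make_sim()
  res <- run_ica(s$expr, seed = 1)
  o1 <- orient_component(res, s$map$hierarchy, s$expr)
  anti <- intersect(s$map$hierarchy$genes$zone[["Anti-tumor"]], s$expr$genes)
  expect_gte(mean(o1$loadings[anti, 1]), 0)

  # idempotent
  o2 <- orient_component(o1, s$map$hierarchy, s$expr)
  expect_identical(o1$projections, o2$projections)

  # a negative mean loading gets flipped
  flipped <- res
  flipped$loadings[, 1] <- -o1$loadings[, 1]
  flipped$projections[, 1] <- -o1$projections[, 1]
  o3 <- orient_component(flipped, s$map$hierarchy, s$expr)
  expect_equal(o3$projections[, 1], o1$projections[, 1])

  # an exactly-zero mean loading is left unchanged
  zero <- res
  zero$loadings[, 1] <- rep(c(-1, 1), length.out = nrow(zero$loadings))
  zl <- zero$loadings[anti, 1]
  zero$loadings[anti, 1] <- zl - mean(zl)
  before <- zero$projections[, 1]
  expect_equal(orient_component(zero, s$map$hierarchy,
                                s$expr)$projections[, 1], before)

  # error when the anti-tumor zone shares no genes with the matrix
  small <- as_expr(matrix(rnorm(20), 4, 5,
                          dimnames = list(paste0("x", 1:4),
                                          paste0("c", 1:5))))
  expect_error(orient_component(res, s$map$hierarchy, small),
               "no genes")
})

fake_result <- function(p, cells = paste0("c", seq_along(p))) {
  structure(list(projections = matrix(p, ncol = 1,
                                      dimnames = list(cells, "IC1")),
                 selected = 1L), class = "ica_result")
}

test_that("sign split assigns groups by projection sign", {
  g <- split_by_sign(fake_result(c(1, 2, -1, -3)))
  expect_equal(as.character(g), c("group1", "group1", "group2", "group2"))

  g2 <- split_by_sign(fake_result(c(1, 0, -1)))
  expect_equal(unname(g2["c2"]), "unassigned")

  expect_error(split_by_sign(fake_result(c(1, 2, 3))), "empty group")
})

test_that("quartile split keeps the extreme cells", {
  g <- split_by_quartiles(fake_result(1:8))
  expect_equal(names(g)[g == "group2"], c("c1", "c2"))
  expect_equal(names(g)[g == "group1"], c("c7", "c8"))
  expect_equal(sum(g == "unassigned"), 4L)

  expect_error(split_by_quartiles(fake_result(rep(1, 10))), "degenerate")
  expect_error(split_by_quartiles(fake_result(1:5)), "at least 8")
})

test_that("group recovery matches the planted labels", {
  s <- make_sim()
  res <- orient_component(run_ica(s$expr, seed = 1), s$map$hierarchy, s$expr)
  g <- split_by_sign(res)
  truth <- s$sim$truth$group
  agree <- mean((g == "group1") == (truth == 1L))
  expect_gte(max(agree, 1 - agree), 0.95)

  # quartile split: extreme cells >= 95% pure w.r.t. planted labels
  gq <- split_by_quartiles(res)
  sel <- gq != "unassigned"
  agree_q <- mean((gq[sel] == "group1") == (truth[sel] == 1L))
  expect_gte(max(agree_q, 1 - agree_q), 0.95)

  # sign invariance: negating the data flips loadings, and orientation
  # restores the same grouping
  neg <- expression_matrix(-s$expr$values, centered = TRUE)
  resn <- orient_component(run_ica(neg, seed = 1), s$map$hierarchy, neg)
  gn <- split_by_sign(resn)
  agree_n <- mean((gn == "group1") == (g == "group1"))
  expect_gte(max(agree_n, 1 - agree_n), 0.95)
})

test_that("PCA coordinates agree with the covariance eigendecomposition", {
  # rank-1 matrix: second component carries ~no variance
  u <- rnorm(10); v <- rnorm(6)
  x <- outer(u, v)
  dimnames(x) <- list(paste0("g", 1:10), paste0("c", 1:6))
  xc <- preprocess(x)
  co <- pca_coordinates(xc, k = 2)
  expect_lt(var(co[, 2]) / var(co[, 1]), 1e-16)

  # projection property: coordinate variance bounded by matrix variance
  set.seed(12)
  y <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  yc <- preprocess(y)
  coy <- pca_coordinates(yc, k = 2)
  expect_lte(sum(apply(coy, 2, function(z) sum(z^2))),
             sum(yc$values^2) + 1e-8)

  # against the gene-covariance eigendecomposition oracle on a 10 x 6 matrix
  C <- crossprod(yc$values)            # cell-by-cell Gram matrix
  e <- eigen(C, symmetric = TRUE)
  for (j in 1:2) {
    oracle <- e$vectors[, j] * sqrt(e$values[j])
    r <- abs(cor(coy[, j], oracle))
    expect_equal(r, 1, tolerance = 1e-8)
    expect_equal(abs(coy[, j]), abs(oracle), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  expect_error(pca_coordinates(yc, k = 7), "exceeds")
})
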