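test_that("significance codes follow the standard mapping", {
  expect_equal(significance_code(c(5e-4, 5e-3, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", ""))
  expect_equal(significance_code(NA_real_), NA_character_)
})

test_that("variant-gene selection keeps the top half with lexicographic ties", {
  # variances 4, 3, 2, 1 after centering
  vals <- rbind(a = c(-2, 2), b = sqrt(3) * c(-1, 1), d = sqrt(2) * c(-1, 1),
                e = c(-1, 1) / sqrt(2))
  colnames(vals) <- c("c1", "c2")
  m <- expression_matrix(vals)
  expect_equal(select_variant_genes(m, c("a", "b", "d", "e")), c("a", "b"))

  # single gene: ceil(1/2) = 1
  expect_equal(select_variant_genes(m, "d"), "d")

  # five genes, variances (5, 5, 5, 1, 1): three kept, tie order lexicographic
  sd5 <- sqrt(5 / 2); sd1 <- sqrt(1 / 2)
  vals2 <- rbind(z5 = sd5 * c(-1, 1), a5 = sd5 * c(-1, 1),
                 m5 = sd5 * c(-1, 1), b1 = sd1 * c(-1, 1),
                 a1 = sd1 * c(-1, 1))
  colnames(vals2) <- c("c1", "c2")
  m2 <- expression_matrix(vals2)
  expect_equal(select_variant_genes(m2, rownames(vals2)),
               c("a5", "m5", "z5"))

  # genes absent from the matrix are dropped before selection
  expect_equal(select_variant_genes(m, c("a", "zz")), "a")
  expect_error(select_variant_genes(m, c("xx", "yy")), "no genes")
})

test_that("module scores are means over selected genes then cells", {
  vals <- rbind(g1 = c(1, 5), g2 = c(3, 1))
  colnames(vals) <- c("c1", "c2")
  m <- expression_matrix(vals)
  ms <- module_score(m, c("g1", "g2"), select = FALSE)
  expect_equal(unname(ms$cell_scores), c(2, 3))
  expect_equal(ms$group_score, 2.5)

  # hand-computed fixture: 3 genes x 2 cells
  vals3 <- rbind(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 9))
  colnames(vals3) <- c("c1", "c2")
  m3 <- expression_matrix(vals3)
  ms3 <- module_score(m3, c("g1", "g2", "g3"), select = FALSE)
  expect_equal(unname(ms3$cell_scores), c(3, 5))
  expect_equal(ms3$group_score, 4)

  # centered matrix: all-cells group score is 0
  s <- simulation_spec(n_cells = 30)
  map <- generate_map(s)
  expr <- preprocess(generate_cells(map$hierarchy, s)$expression$values)
  gs <- map$hierarchy$genes$module[[1]]
  expect_equal(module_score(expr, gs)$group_score, 0, tolerance = 1e-9)
})

test_that("group comparison is a two-sided Welch test with codes", {
  vals <- rbind(g1 = c(1, 2, 3, 1, 2, 3), g2 = c(2, 4, 6, 2, 4, 6))
  colnames(vals) <- paste0("c", 1:6)
  m <- expression_matrix(vals)
  gr <- as_groups(c(rep("group1", 3), rep("group2", 3)), paste0("c", 1:6))

  # identical score vectors in both groups: t = 0, p = 1, empty code
  row <- compare_groups(m, c("g1", "g2"), gr)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  expect_equal(row$code, "")
  expect_equal(row$direction, "tie")

  # agrees with the textbook Welch oracle to 1e-12
  set.seed(21)
  vals2 <- matrix(rnorm(4 * 12), 4, 12,
                  dimnames = list(paste0("g", 1:4), paste0("c", 1:12)))
  vals2[, 1:6] <- vals2[, 1:6] + 1
  m2 <- expression_matrix(vals2)
  gr2 <- as_groups(c(rep("group1", 6), rep("group2", 6)), paste0("c", 1:12))
  row2 <- compare_groups(m2, paste0("g", 1:4), gr2)
  sel <- select_variant_genes(m2, paste0("g", 1:4))
  s1 <- colMeans(vals2[sel, 1:6, drop = FALSE])
  s2 <- colMeans(vals2[sel, 7:12, drop = FALSE])
  o <- welch_oracle(s1, s2)
  expect_equal(row2$t, o$t, tolerance = 1e-12)
  expect_equal(row2$p, o$p, tolerance = 1e-12)

  # group-swap antisymmetry: t negates, p and code invariant
  gr_swap <- as_groups(c(rep("group2", 6), rep("group1", 6)),
                       paste0("c", 1:12))
  row_swap <- compare_groups(m2, paste0("g", 1:4), gr_swap)
  expect_equal(row_swap$t, -row2$t)
  expect_equal(row_swap$p, row2$p)
  expect_equal(row_swap$code, row2$code)

  # score linearity: shifting selected genes by c shifts scores, not t
  m3 <- expression_matrix(vals2 + 5)
  row3 <- compare_groups(m3, paste0("g", 1:4), gr2)
  expect_equal(row3$mean_group1, row2$mean_group1 + 5)
  expect_equal(row3$t, row2$t, tolerance = 1e-9)

  # pooled-variance variant matches t.test(var.equal = TRUE)
  row4 <- compare_groups(m2, paste0("g", 1:4), gr2, var_equal = TRUE)
  tt <- t.test(s1, s2, var.equal = TRUE)
  expect_equal(row4$t, unname(tt$statistic))

  # degenerate inputs raise
  gr_small <- as_groups(c("group1", rep("group2", 11)), paste0("c", 1:12))
  expect_error(compare_groups(m2, paste0("g", 1:4), gr_small),
               "at least 2")
  const <- expression_matrix(matrix(3, 2, 6,
                                    dimnames = list(c("g1", "g2"),
                                                    paste0("c", 1:6))))
  expect_error(compare_groups(const, c("g1", "g2"), gr),
               "zero variance")
})

test_that("level-wise scoring covers all sets and flags empty ones", {
  s <- simulation_spec()
  map <- generate_map(s)
  sim <- generate_cells(map$hierarchy, s)
  expr <- preprocess(sim$expression$values)
  res <- orient_component(run_ica(expr, seed = 1, n_runs = 6),
                          map$hierarchy, expr)
  gr <- split_by_sign(res)

  zt <- score_all(expr, map$hierarchy, gr, level = "zone")
  expect_equal(nrow(zt), 2L)

  mt <- score_all(expr, map$hierarchy, gr, level = "module")
  expect_equal(nrow(mt), 12L)
  # composition: identical to calling compare_groups per module
  one <- compare_groups(expr, map$hierarchy$genes$module[["MM1_1_mod2"]],
                        gr, name = "MM1_1_mod2")
  expect_equal(mt[mt$set == "MM1_1_mod2", ]$t, one$t)

  # recovery: sets at code <= * are exactly the planted active modules
  # (at most one false positive tolerated)
  called <- mt$set[!is.na(mt$p) & mt$p < 0.05]
  expect_true(all(sim$truth$active_modules %in% called))
  expect_lte(length(setdiff(called, sim$truth$active_modules)), 1L)

  # a gene set absent from the matrix is skipped, not dropped
  h2 <- build_hierarchy(zones = list(Z = "M"),
                        meta_modules = list(M = c("m1", "m2")),
                        modules = list(m1 = "p1", m2 = "p2"),
                        pathways = list(p1 = expr$genes[1:5],
                                        p2 = c("none1", "none2")))
  st <- score_all(expr, h2, gr, level = "module")
  expect_true(st$skipped[st$set == "m2"])
  expect_false(st$skipped[st$set == "m1"])

  # polarization: group1 (anti-tumor side) scores higher on its zone
  pol <- polarization_scores(expr, map$hierarchy, gr)
  anti <- pol[pol$set == "Anti-tumor", ]
  expect_equal(anti$direction, "group1")
  expect_lt(anti$p, 0.01)
  expect_error(polarization_scores(expr, h2, gr), "exactly two zones")
})

test_that("staining tables color by which group is higher", {
  tab <- data.frame(set = c("m1", "m2"), level = "module",
                    mean_group1 = c(0.4, 0.2), mean_group2 = c(-0.1, 0.2),
                    t = c(2, 0), p = c(0.04, 1), code = c("*", ""),
                    direction = c("group1", "tie"), n_genes = 3L,
                    skipped = FALSE, stringsAsFactors = FALSE)
  st <- staining_table(tab)
  expect_equal(st$color[st$set == "m1" & st$group == "group1"], "red")
  expect_equal(st$color[st$set == "m1" & st$group == "group2"], "green")
  expect_equal(st$color[st$set == "m2"], c("", ""))  # tie is neutral

  # round trip through CSV preserves all fields
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(st, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = c(color = "character"))
  expect_equal(back, st)
})

test_that("pathway heatmap keeps pathways with more than min_genes genes", {
  set.seed(31)
  genes <- paste0("g", 1:21)
  vals <- matrix(rnorm(21 * 12), 21, 12,
                 dimnames = list(genes, paste0("c", 1:12)))
  m <- expression_matrix(vals)
  gr <- as_groups(rep(c("group1", "group2"), each = 6), paste0("c", 1:12))
  h <- build_hierarchy(zones = list(Z = "M"),
                       meta_modules = list(M = "mod"),
                       modules = list(mod = c("small", "big")),
                       pathways = list(small = genes[1:10],
                                       big = genes[11:21]))
  hm <- pathway_heatmap_matrix(m, h, gr)      # "more than 10 molecules"
  expect_equal(rownames(hm$scores), "big")    # 10 genes excluded, 11 kept

  # included count equals a direct count of sets above the threshold
  map <- generate_map(simulation_spec(genes_per_pathway = 12L))
  s2 <- simulation_spec(genes_per_pathway = 12L)
  expr2 <- preprocess(generate_cells(map$hierarchy, s2)$expression$values)
  gr2 <- as_groups(rep(c("group1", "group2"), 100),
                   colnames(expr2$values))
  hm2 <- pathway_heatmap_matrix(expr2, map$hierarchy, gr2, min_genes = 10)
  direct <- sum(vapply(map$hierarchy$genes$pathway, function(g)
    length(intersect(g, expr2$genes)) >= 11, logical(1)))
  expect_equal(nrow(hm2$scores), direct)
  expect_named(hm2$codes, rownames(hm2$scores))
})
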