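## Module/pathway/zone activity scoring: select the top-half most variant
## genes of a set, average them per cell, compare the two cell groups with a
## t-test, and export staining / heatmap tables.

#' Significance code for a p value
#'
#' Standard code: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `.` p < 0.1,
#' otherwise empty.
#' @param p numeric vector of p values.
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*"
    else if (x < 0.1) "." else ""
  }, character(1))
}

#' Select the most variant half of a gene set
#'
#' Genes absent from the matrix are dropped; per-gene sample variance
#' (n - 1 denominator) is computed across ALL cells so the same selection
#' serves both groups; genes are ranked by variance descending with
#' lexicographic tie-break on the symbol, and the top `ceiling(n / 2)` are
#' kept — the genes at or above the median variability.
#'
#' @param matrix an `expression_matrix`.
#' @param gene_set character vector of gene symbols.
#' @return ordered character vector of retained gene symbols.
#' @export
select_variant_genes <- function(matrix, gene_set) {
  genes <- intersect(unique(gene_set), matrix$genes)
  if (length(genes) == 0L)
    stop("gene set shares no genes with the expression matrix")
  v <- apply(matrix$values[genes, , drop = FALSE], 1, stats::var)
  ord <- order(-v, genes)
  genes[ord][seq_len(ceiling(length(genes) / 2))]
}

#' Module activity score
#'
#' Per-cell score = mean expression over the selected genes; the group score
#' is the mean of the per-cell scores over the given cells.
#'
#' @param matrix an `expression_matrix`.
#' @param gene_set character vector of gene symbols; by default the top-half
#'   most variant genes are selected first (set `select = FALSE` if the set
#'   is already selected).
#' @param cells character vector of cell ids (default: all cells).
#' @param select apply [select_variant_genes()] first?
#' @return list with `cell_scores` (named numeric per cell) and
#'   `group_score` (their mean) and `genes_used`.
#' @export
module_score <- function(matrix, gene_set, cells = matrix$cells,
                         select = TRUE) {
  genes <- if (select) select_variant_genes(matrix, gene_set)
           else intersect(unique(gene_set), matrix$genes)
  if (length(genes) == 0L) stop("no genes to score")
  miss <- setdiff(cells, matrix$cells)
  if (length(miss)) stop("unknown cell id(s): ", paste(miss, collapse = ", "))
  cs <- colMeans(matrix$values[genes, cells, drop = FALSE])
  list(cell_scores = cs, group_score = mean(cs), genes_used = genes)
}

## Welch (default) or pooled-variance Student t-test on two score vectors.
score_t_test <- function(s1, s2, var_equal = FALSE) {
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each group needs at least 2 cells")
  if (stats::var(s1) == 0 && stats::var(s2) == 0)
    stop("zero variance in both groups")
  stats::t.test(s1, s2, var.equal = var_equal,
                alternative = "two.sided")
}

#' Compare module activity between two cell groups
#'
#' Computes the module score per cell, then a two-sided t-test (Welch by
#' default) of group 1 against group 2. The selection of variant genes is
#' done once on all cells, so both groups are scored on the same genes.
#'
#' @param matrix an `expression_matrix`.
#' @param gene_set character vector of gene symbols.
#' @param groups a `cell_groups` labelling.
#' @param name gene-set name for the output row.
#' @param level hierarchy level label for the output row.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return one-row data.frame: `set`, `level`, `mean_group1`, `mean_group2`,
#'   `t`, `p`, `code`, `direction` (which group scores higher; `"tie"` when
#'   equal), `n_genes`, `skipped`.
#' @export
compare_groups <- function(matrix, gene_set, groups, name = "set",
                           level = "module", var_equal = FALSE) {
  g1 <- names(groups)[groups == "group1"]
  g2 <- names(groups)[groups == "group2"]
  sel <- select_variant_genes(matrix, gene_set)
  s1 <- module_score(matrix, sel, g1, select = FALSE)$cell_scores
  s2 <- module_score(matrix, sel, g2, select = FALSE)$cell_scores
  tt <- score_t_test(s1, s2, var_equal = var_equal)
  m1 <- mean(s1); m2 <- mean(s2)
  data.frame(set = name, level = level, mean_group1 = m1, mean_group2 = m2,
             t = unname(tt$statistic), p = tt$p.value,
             code = significance_code(tt$p.value),
             direction = if (m1 > m2) "group1" else if (m2 > m1) "group2"
                         else "tie",
             n_genes = length(sel), skipped = FALSE,
             stringsAsFactors = FALSE)
}

## Empty-row placeholder for gene sets absent from the matrix.
skipped_row <- function(name, level) {
  data.frame(set = name, level = level, mean_group1 = NA_real_,
             mean_group2 = NA_real_, t = NA_real_, p = NA_real_,
             code = NA_character_, direction = NA_character_,
             n_genes = 0L, skipped = TRUE, stringsAsFactors = FALSE)
}

#' Score every gene set of a hierarchy level
#'
#' One row per container at the requested level; sets sharing no genes with
#' the matrix are flagged `skipped = TRUE` rather than dropped.
#'
#' @param matrix an `expression_matrix`.
#' @param hierarchy a `map_hierarchy`.
#' @param groups a `cell_groups` labelling.
#' @param level `"pathway"`, `"module"`, `"meta_module"` or `"zone"`.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return a `module_score_table` data.frame (see [compare_groups()]).
#' @export
score_all <- function(matrix, hierarchy, groups, level = "module",
                      var_equal = FALSE) {
  level <- match.arg(level, HIERARCHY_LEVELS)
  sets <- hierarchy$genes[[level]]
  rows <- lapply(names(sets), function(nm) {
    if (length(intersect(sets[[nm]], matrix$genes)) == 0L)
      return(skipped_row(nm, level))
    compare_groups(matrix, sets[[nm]], groups, name = nm, level = level,
                   var_equal = var_equal)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("module_score_table", class(out))
  out
}

#' Zone polarization scores
#'
#' The zone-level activity comparison for a two-zone (anti-tumor /
#' pro-tumor) hierarchy: each zone's gene set is the union of its member
#' modules' genes, scored with the same selection rule and test as any other
#' level.
#'
#' @inheritParams score_all
#' @return a two-row `module_score_table` (one row per zone).
#' @export
polarization_scores <- function(matrix, hierarchy, groups,
                                var_equal = FALSE) {
  if (length(hierarchy$zones) != 2L)
    stop("polarization scores require exactly two zones")
  score_all(matrix, hierarchy, groups, level = "zone", var_equal = var_equal)
}

#' Map staining table
#'
#' Tabular form of map staining: per gene set and group, the group's mean
#' score and a color — red when that group's mean exceeds the other's
#' (upregulated), green when lower (downregulated), empty on a tie
#' (neutral).
#'
#' @param table a `module_score_table`.
#' @return data.frame with columns `set`, `level`, `group`, `score`,
#'   `color`.
#' @export
staining_table <- function(table) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    if (isTRUE(r$skipped)) return(NULL)
    col1 <- if (r$mean_group1 > r$mean_group2) "red"
            else if (r$mean_group1 < r$mean_group2) "green" else ""
    col2 <- if (col1 == "red") "green" else if (col1 == "green") "red" else ""
    data.frame(set = rep(r$set, 2), level = rep(r$level, 2),
               group = c("group1", "group2"),
               score = c(r$mean_group1, r$mean_group2),
               color = c(col1, col2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway heatmap matrix
#'
#' Group-mean activity scores for the pathways large enough to score
#' reliably: only pathways with more than `min_genes` genes present in the
#' expression matrix are kept. Returns the sets x groups score matrix plus
#' per-pathway significance codes, ready for heatmap plotting elsewhere.
#'
#' @param matrix an `expression_matrix`.
#' @param hierarchy a `map_hierarchy`.
#' @param groups a `cell_groups` labelling.
#' @param min_genes pathways must have strictly more than this many genes in
#'   the matrix (default 10, i.e. "more than 10 molecules").
#' @return list with `scores` (pathways x 2 matrix, columns `group1`,
#'   `group2`), `codes` (named character) and `p` (named numeric).
#' @export
pathway_heatmap_matrix <- function(matrix, hierarchy, groups,
                                   min_genes = 10L) {
  sets <- hierarchy$genes$pathway
  size <- vapply(sets, function(g) length(intersect(g, matrix$genes)),
                 integer(1))
  keep <- names(sets)[size > min_genes]
  tab <- do.call(rbind, lapply(keep, function(nm)
    compare_groups(matrix, sets[[nm]], groups, name = nm,
                   level = "pathway")))
  if (is.null(tab)) {
    return(list(scores = matrix(numeric(), 0, 2,
                                dimnames = list(NULL, c("group1", "group2"))),
                codes = character(), p = numeric()))
  }
  scores <- cbind(group1 = tab$mean_group1, group2 = tab$mean_group2)
  rownames(scores) <- tab$set
  list(scores = scores,
       codes = stats::setNames(tab$code, tab$set),
       p = stats::setNames(tab$p, tab$set))
}
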