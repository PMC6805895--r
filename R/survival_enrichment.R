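## Overlap of map genes with a per-gene survival z-score table (z < 0 marks
## positive association with patient survival), chi-squared enrichment of
## the significant fraction against a genome-wide background, and the
## per-meta-module mean-z / sign-count summary.

#' Read a survival z-score table from CSV
#'
#' Columns `gene`, `z`, `p`; symbols must be unique and p in (0, 1].
#' @param path CSV file path.
#' @return a `survival_table` data.frame.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival_table(df)
}

validate_survival_table <- function(df) {
  need <- c("gene", "z", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("survival table gene symbols must be unique")
  if (any(df$p <= 0 | df$p > 1)) stop("p values must lie in (0, 1]")
  if (!inherits(df, "survival_table"))
    class(df) <- c("survival_table", class(df))
  df
}

#' Genes significantly associated with survival
#'
#' @param table a `survival_table`.
#' @param alpha significance level; rows with `p < alpha` (strict) are kept.
#' @return the significant subset of the table.
#' @export
significant_genes <- function(table, alpha = 0.05) {
  table <- validate_survival_table(table)
  table[table$p < alpha, , drop = FALSE]
}

## Guarded 1-df chi-squared goodness-of-fit of observed (k, n-k) against
## expected (n f, n (1-f)); cells with zero expectation contribute nothing.
chisq_gof <- function(k, n, f) {
  obs <- c(k, n - k)
  exp <- c(n * f, n * (1 - f))
  keep <- exp > 0
  stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Enrichment of map genes in survival-significant genes
#'
#' Overlaps the map's gene list with the survival table, counts the
#' significant genes among them and tests whether their fraction exceeds the
#' genome-wide background fraction. Default test: Pearson 1-df
#' goodness-of-fit of (k, n - k) against (n f, n (1 - f)), no continuity
#' correction; a 2x2 map-vs-genome contingency chi-squared is available via
#' `method = "contingency"` (requires the background totals).
#'
#' @param map_genes character vector of map gene symbols.
#' @param table a `survival_table`.
#' @param alpha per-gene significance level (default 0.05, strict).
#' @param background_fraction genome-wide significant fraction, in (0, 1).
#' @param p_threshold enrichment is called significant below this (default
#'   0.001).
#' @param method `"gof"` (default) or `"contingency"`.
#' @param background_n total number of genome genes scored; required for the
#'   contingency method.
#' @return list: `k` (significant map genes), `n` (map genes scored),
#'   `fraction`, `statistic`, `p`, `significant`.
#' @export
map_overlap_enrichment <- function(map_genes, table, alpha = 0.05,
                                   background_fraction,
                                   p_threshold = 0.001,
                                   method = c("gof", "contingency"),
                                   background_n = NULL) {
  method <- match.arg(method)
  stopifnot(background_fraction > 0, background_fraction < 1)
  table <- validate_survival_table(table)
  scored <- table[table$gene %in% map_genes, , drop = FALSE]
  n <- nrow(scored)
  if (n == 0L) stop("no map genes present in the survival table")
  k <- sum(scored$p < alpha)
  if (method == "gof") {
    ts <- chisq_gof(k, n, background_fraction)
  } else {
    if (is.null(background_n)) stop("contingency method needs background_n")
    bg_k <- round(background_fraction * background_n)
    tab <- rbind(c(k, n - k), c(bg_k, background_n - bg_k))
    ct <- stats::chisq.test(tab, correct = FALSE)
    ts <- list(statistic = unname(ct$statistic), p = ct$p.value)
  }
  list(k = k, n = n, fraction = k / n, statistic = ts$statistic, p = ts$p,
       significant = ts$p < p_threshold)
}

#' Survival summary per meta-module
#'
#' For each meta-module: the mean z over all its scored member genes, and
#' the counts of significant genes positively (z < 0) and negatively
#' (z > 0) associated with patient survival. Genes absent from the table are
#' excluded; meta-modules with no scored genes are flagged skipped. Rows are
#' sorted by mean z (most survival-favourable first).
#'
#' @param hierarchy a `map_hierarchy`.
#' @param table a `survival_table`.
#' @param alpha per-gene significance level (strict).
#' @return data.frame: `meta_module`, `mean_z`, `n_scored`,
#'   `positive_survival` (significant, z < 0), `negative_survival`
#'   (significant, z > 0), `skipped`.
#' @export
meta_module_summary <- function(hierarchy, table, alpha = 0.05) {
  table <- validate_survival_table(table)
  z <- stats::setNames(table$z, table$gene)
  p <- stats::setNames(table$p, table$gene)
  rows <- lapply(names(hierarchy$meta_modules), function(mm) {
    genes <- intersect(hierarchy$genes$meta_module[[mm]], table$gene)
    if (length(genes) == 0L) {
      return(data.frame(meta_module = mm, mean_z = NA_real_, n_scored = 0L,
                        positive_survival = NA_integer_,
                        negative_survival = NA_integer_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    sig <- genes[p[genes] < alpha]
    data.frame(meta_module = mm, mean_z = mean(z[genes]),
               n_scored = length(genes),
               positive_survival = sum(z[sig] < 0),
               negative_survival = sum(z[sig] > 0),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_z), , drop = FALSE]
}
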