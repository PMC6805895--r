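## Comparison of the map's gene and literature content against other
## pathway resources: overlap fractions, map-unique genes, per-module
## unique-gene enrichment (hypergeometric + BH), and publication-year
## statistics. Pure set arithmetic on canonicalised symbols.

#' Canonicalise gene symbols
#'
#' Uppercase and strip surrounding whitespace; no alias resolution.
#' @param genes character vector.
#' @return canonicalised character vector.
#' @export
canonicalize_symbols <- function(genes) {
  toupper(trimws(as.character(genes)))
}

#' Construct a resource gene set
#'
#' @param name resource name.
#' @param genes character vector of symbols (canonicalised on load).
#' @param pmids optional character vector of publication ids.
#' @param pub_years optional named numeric vector pmid -> year.
#' @return a list of class `resource_set`.
#' @export
resource_set <- function(name, genes, pmids = character(),
                         pub_years = NULL) {
  structure(list(name = name, genes = unique(canonicalize_symbols(genes)),
                 pmids = unique(as.character(pmids)),
                 pub_years = pub_years),
            class = "resource_set")
}

.gene_set <- function(x) {
  if (inherits(x, "resource_set")) x$genes
  else unique(canonicalize_symbols(x))
}

#' Overlap of the map gene set with another resource
#'
#' The denominator is the map set: the fraction is the share of map genes
#' also present in the other resource. The symmetric Jaccard index is
#' reported alongside.
#'
#' @param map_set map genes (character vector or `resource_set`); non-empty.
#' @param other the other resource's genes.
#' @return list: `intersection` (count), `fraction` (of map genes),
#'   `percent` (fraction as percent, one decimal), `jaccard`.
#' @export
overlap_fraction <- function(map_set, other) {
  m <- .gene_set(map_set); o <- .gene_set(other)
  if (length(m) == 0L) stop("map gene set is empty")
  i <- length(intersect(m, o))
  frac <- i / length(m)
  list(intersection = i, fraction = frac,
       percent = round(100 * frac, 1),
       jaccard = i / length(union(m, o)))
}

#' Genes unique to the map
#'
#' Map genes present in none of the other resources.
#'
#' @param map_set map genes.
#' @param others list of gene sets (character vectors or `resource_set`s).
#' @return sorted character vector.
#' @export
unique_genes <- function(map_set, others = list()) {
  m <- .gene_set(map_set)
  pooled <- unique(unlist(lapply(others, .gene_set), use.names = FALSE))
  sort(setdiff(m, pooled))
}

#' Enrichment of map-unique genes per hierarchy gene set
#'
#' For each gene set at the requested level, the hypergeometric upper-tail
#' probability of drawing at least its observed number of map-unique genes
#' when sampling its size from the map universe, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param hierarchy a `map_hierarchy` (its full gene list is the universe).
#' @param unique_set character vector, a subset of the hierarchy's genes.
#' @param level hierarchy level (default `"module"`).
#' @return data.frame: `set`, `k_unique`, `n_genes`, `p`, `q`.
#' @export
module_unique_enrichment <- function(hierarchy, unique_set,
                                     level = "module") {
  level <- match.arg(level, HIERARCHY_LEVELS)
  universe <- names(hierarchy$gene_index)
  uniq <- intersect(canonicalize_symbols(unique_set),
                    canonicalize_symbols(universe))
  outside <- setdiff(canonicalize_symbols(unique_set),
                     canonicalize_symbols(universe))
  if (length(outside)) stop("unique_set contains genes outside the hierarchy")
  N <- length(universe); K <- length(uniq)
  sets <- hierarchy$genes[[level]]
  rows <- lapply(names(sets), function(nm) {
    n <- length(sets[[nm]])
    k <- length(intersect(canonicalize_symbols(sets[[nm]]), uniq))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k_unique = k, n_genes = n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Literature overlap and recency statistics
#'
#' Set arithmetic on the PMIDs annotating the map versus other resources,
#' plus the fraction of map papers published in or after a cutoff year
#' (computed over papers with known years; `NA` when no years are known).
#'
#' @param map_pmids character vector of the map's PMIDs.
#' @param others list of character vectors of PMIDs.
#' @param pub_years named vector pmid -> year (map papers).
#' @param y0 cutoff year (default 2010).
#' @return list: `unique` (count of map-only PMIDs), `shared`,
#'   `recent_fraction`.
#' @export
literature_stats <- function(map_pmids, others = list(), pub_years = NULL,
                             y0 = 2010) {
  m <- unique(as.character(map_pmids))
  pooled <- unique(unlist(lapply(others, as.character), use.names = FALSE))
  uniq <- setdiff(m, pooled)
  recent <- NA_real_
  if (!is.null(pub_years) && length(pub_years)) {
    yrs <- pub_years[names(pub_years) %in% m]
    yrs <- yrs[!is.na(yrs)]
    if (length(yrs)) recent <- mean(yrs >= y0)
  }
  list(unique = length(uniq), shared = length(m) - length(uniq),
       recent_fraction = recent)
}
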