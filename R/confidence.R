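## Reaction confidence scores: REF from publication annotations, FUNC from
## shortest-path proximity of the participants in an external PPI network.
## Both are integers 0-5; 0 means undefined confidence.

REFERENCE_CATEGORIES <- c("experimental_immune", "review",
                          "experimental_nonimmune")

#' Default publication weights for the reference score
#'
#' Experimental innate-immunity-specific articles count full weight;
#' reviews and experimental articles from non-immune cells count half, so
#' five directly supporting experimental papers saturate the 0-5 scale.
#' @export
default_ref_weights <- c(experimental_immune = 1.0, review = 0.5,
                         experimental_nonimmune = 0.5)

#' Reference confidence score (REF)
#'
#' Reflects both the number and the weight of the publications annotating a
#' reaction: the weighted count is floored and capped at 5. An empty
#' annotation yields 0 (undefined confidence).
#'
#' @param references a character vector of publication categories
#'   (`"experimental_immune"`, `"review"`, `"experimental_nonimmune"`), or a
#'   data.frame with a `category` column.
#' @param weights named numeric weights per category (overridable).
#' @return integer in 0-5.
#' @examples
#' ref_score(c("review", "experimental_nonimmune"))  # floor(1.0) = 1
#' @export
ref_score <- function(references, weights = default_ref_weights) {
  cats <- if (is.data.frame(references)) references$category else references
  cats <- as.character(cats)
  if (length(cats) == 0L) return(0L)
  unknown <- setdiff(unique(cats), names(weights))
  if (length(unknown))
    stop("unknown reference category(ies): ", paste(unknown, collapse = ", "))
  w <- sum(weights[cats])
  as.integer(min(5, floor(w)))
}

#' Construct a protein-protein interaction graph
#'
#' Undirected, unweighted; self-loops are rejected and duplicate edges
#' collapsed.
#'
#' @param edges a 2-column matrix or data.frame of protein symbols, one edge
#'   per row.
#' @param nodes optional character vector of node symbols; defaults to the
#'   symbols appearing in `edges`. Extra isolated nodes are allowed.
#' @return an object of class `ppi_graph` wrapping an igraph graph.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(em) <- "character"
  if (nrow(em) && any(em[, 1] == em[, 2]))
    stop("self-loops are not allowed in a PPI graph")
  if (is.null(nodes)) nodes <- unique(as.vector(em))
  miss <- setdiff(unique(as.vector(em)), nodes)
  if (length(miss)) stop("edges reference unknown node(s): ",
                         paste(miss, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  structure(list(graph = g), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("<ppi_graph>", igraph::vcount(x$graph), "proteins,",
      igraph::ecount(x$graph), "interactions\n")
  invisible(x)
}

#' Read a PPI edge list (SIF-like TSV)
#'
#' Two tab-separated symbol columns; a third interaction-type column, if
#' present, is ignored.
#' @param path file path.
#' @return a `ppi_graph`.
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("PPI edge list needs at least two columns")
  ppi_graph(df[, 1:2])
}

#' Average pairwise shortest-path distance among proteins
#'
#' Mean over all unordered pairs of breadth-first shortest-path lengths in
#' the PPI graph. Undefined (returned as `NA`) when fewer than two proteins
#' are given, when any protein is absent from the graph, or when any pair is
#' disconnected.
#'
#' @param graph a `ppi_graph`.
#' @param proteins character vector of protein symbols.
#' @return a numeric scalar, or `NA_real_` when undefined.
#' @export
avg_pairwise_distance <- function(graph, proteins) {
  proteins <- unique(as.character(proteins))
  if (length(proteins) < 2L) return(NA_real_)
  if (!all(proteins %in% igraph::V(graph$graph)$name)) return(NA_real_)
  d <- igraph::distances(graph$graph, v = proteins, to = proteins)
  vals <- d[upper.tri(d)]
  if (any(!is.finite(vals))) return(NA_real_)
  mean(vals)
}

#' Functional proximity confidence score (FUNC)
#'
#' Bins the average pairwise PPI distance among a reaction's protein
#' participants (reactants, products and regulators of class protein) into
#' the 0-5 confidence scale. An undefined average distance (lone
#' participant, protein missing from the network, disconnected pair) gives
#' 0, i.e. undefined confidence. Default bins: d <= 1 -> 5, <= 2 -> 4,
#' <= 3 -> 3, <= 4 -> 2, otherwise 1.
#'
#' @param graph a `ppi_graph`.
#' @param reaction a `map_reaction` (or list with `reactants`, `products`,
#'   `regulators$id`).
#' @param entities a data.frame with columns `id`, `symbol`, `entity_class`
#'   used to resolve participant ids to protein symbols.
#' @param breaks increasing distance thresholds for scores `5:2`
#'   (overridable); distances above the last threshold score 1.
#' @return integer in 0-5.
#' @export
func_score <- function(graph, reaction, entities, breaks = c(1, 2, 3, 4)) {
  stopifnot(length(breaks) == 4L, !is.unsorted(breaks))
  ids <- unique(c(reaction$reactants, reaction$products,
                  reaction$regulators$id))
  idx <- match(ids, entities$id)
  if (anyNA(idx)) stop("reaction references ids absent from the entity table")
  is_prot <- entities$entity_class[idx] == "protein"
  participants <- unique(entities$symbol[idx][is_prot])
  dbar <- avg_pairwise_distance(graph, participants)
  if (is.na(dbar)) return(0L)
  bin <- findInterval(dbar, breaks, left.open = TRUE)  # 0 => d <= breaks[1]
  as.integer(5L - bin)
}

#' Score a table of reactions
#'
#' Convenience wrapper computing REF and FUNC for a list of reactions.
#'
#' @param reactions a list of `map_reaction` objects; each may carry a
#'   `reference_categories` attribute (character vector) used for REF; when
#'   absent, REF is computed from `ref_categories[[reaction id]]`.
#' @param graph a `ppi_graph`.
#' @param entities entity data.frame (see [func_score()]).
#' @param ref_categories optional named list: reaction id -> categories.
#' @return a data.frame with columns `id`, `ref_score`, `func_score`.
#' @export
score_reactions <- function(reactions, graph, entities,
                            ref_categories = list()) {
  rows <- lapply(reactions, function(r) {
    cats <- attr(r, "reference_categories")
    if (is.null(cats)) cats <- ref_categories[[r$id]]
    if (is.null(cats)) cats <- character()
    data.frame(id = r$id, ref_score = ref_score(cats),
               func_score = func_score(graph, r, entities),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
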