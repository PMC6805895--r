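## Closed vocabularies of the map data model.
ENTITY_CLASSES <- c("protein", "gene", "rna", "asrna", "simple_molecule",
                    "ion", "drug", "phenotype", "complex")
REGULATION_TYPES <- c("catalysis", "inhibition", "modulation", "trigger",
                      "physical_stimulation")
HIERARCHY_LEVELS <- c("pathway", "module", "meta_module", "zone")

#' Parse entity annotation tags
#'
#' Map entities are annotated with free-text tags of the form
#' `MODULE:<NAME>`, `PATHWAY:<NAME>` and `MAP:<NAME>` marking membership in
#' functional modules, signalling pathways and cell-type-specific maps.
#' The name is the maximal run of non-whitespace characters after the colon;
#' matching is case-sensitive and unknown prefixes are ignored.
#'
#' @param annotation_text a character scalar of free text.
#' @return an object of class `tag_set`: a list with character vectors
#'   `modules`, `pathways` and `cell_maps` (each sorted, unique).
#' @examples
#' parse_tags("MODULE:TUMOR_GROWTH PATHWAY:TGFB")
#' @export
parse_tags <- function(annotation_text) {
  stopifnot(is.character(annotation_text), length(annotation_text) == 1L)
  out <- list(modules = character(), pathways = character(),
              cell_maps = character())
  if (is.na(annotation_text) || !nzchar(annotation_text)) {
    return(structure(out, class = "tag_set"))
  }
  m <- gregexpr("\\b(MODULE|PATHWAY|MAP):\\S+", annotation_text)
  toks <- regmatches(annotation_text, m)[[1]]
  for (tok in toks) {
    colon <- regexpr(":", tok, fixed = TRUE)
    prefix <- substr(tok, 1L, colon - 1L)
    name <- substr(tok, colon + 1L, nchar(tok))
    slot <- switch(prefix, MODULE = "modules", PATHWAY = "pathways",
                   MAP = "cell_maps")
    out[[slot]] <- c(out[[slot]], name)
  }
  out <- lapply(out, function(x) sort(unique(x)))
  structure(out, class = "tag_set")
}

#' Format a tag_set back to its textual tag form
#'
#' Inverse of [parse_tags()]: emits space-separated `PREFIX:NAME` tokens.
#' @param x a `tag_set`.
#' @param ... ignored.
#' @export
format.tag_set <- function(x, ...) {
  paste(c(paste0("MODULE:", x$modules),
          paste0("PATHWAY:", x$pathways),
          paste0("MAP:", x$cell_maps)), collapse = " ")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("<tag_set>", format(x), "\n")
  invisible(x)
}

#' Create a map entity record
#'
#' Molecular objects on the maps: proteins, genes, RNAs, antisense RNAs,
#' simple molecules, ions, drugs, phenotypes and complexes. Protein, gene,
#' rna and asrna entities must carry a non-empty symbol.
#'
#' @param id opaque identifier.
#' @param symbol gene/protein symbol (HUGO-style).
#' @param entity_class one of the closed entity-class vocabulary.
#' @param tags a `tag_set` or an annotation string passed to [parse_tags()].
#' @param references character vector of PMIDs.
#' @return a list of class `map_entity`.
#' @export
map_entity <- function(id, symbol = "", entity_class, tags = parse_tags(""),
                       references = character()) {
  entity_class <- match.arg(entity_class, ENTITY_CLASSES)
  if (is.character(tags)) tags <- parse_tags(tags)
  if (entity_class %in% c("protein", "gene", "rna", "asrna") &&
      (!nzchar(symbol) || is.na(symbol))) {
    stop("entity of class '", entity_class, "' requires a non-empty symbol")
  }
  structure(list(id = as.character(id), symbol = as.character(symbol),
                 entity_class = entity_class, tags = tags,
                 references = as.character(references)),
            class = "map_entity")
}

#' Create a map reaction record
#'
#' Edges on the maps are biochemical reactions connecting reactant entities
#' to products, optionally regulated (catalysis, inhibition, modulation,
#' trigger, physical stimulation). Two confidence scores, `ref_score` and
#' `func_score` (integers 0-5, 0 = undefined confidence), may be attached.
#'
#' @param id opaque identifier.
#' @param reactants,products character vectors of entity ids.
#' @param regulators a data.frame with columns `id` (entity id) and `type`
#'   (regulation type), or NULL.
#' @param references character vector of PMIDs.
#' @param ref_score,func_score optional integer 0-5.
#' @param entity_ids if supplied, all referenced entity ids are checked
#'   against this vector.
#' @return a list of class `map_reaction`.
#' @export
map_reaction <- function(id, reactants, products, regulators = NULL,
                         references = character(), ref_score = NA_integer_,
                         func_score = NA_integer_, entity_ids = NULL) {
  if (is.null(regulators)) {
    regulators <- data.frame(id = character(), type = character(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "type") %in% names(regulators)))
  bad <- setdiff(regulators$type, REGULATION_TYPES)
  if (length(bad)) stop("unknown regulation type(s): ", paste(bad, collapse = ", "))
  for (s in list(ref_score, func_score)) {
    if (!is.na(s) && (s < 0 || s > 5 || s != round(s)))
      stop("confidence scores must be integers in [0, 5]")
  }
  if (!is.null(entity_ids)) {
    refd <- c(reactants, products, regulators$id)
    miss <- setdiff(refd, entity_ids)
    if (length(miss))
      stop("reaction references unknown entity id(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(id = as.character(id),
                 reactants = as.character(reactants),
                 products = as.character(products),
                 regulators = regulators,
                 references = as.character(references),
                 ref_score = as.integer(ref_score),
                 func_score = as.integer(func_score)),
            class = "map_reaction")
}

#' Build a validated four-level map hierarchy
#'
#' The map is organised as zones > meta-modules > modules > pathways, with
#' genes attached to pathways. Container levels partition containers: each
#' pathway belongs to exactly one module, each module to one meta-module,
#' each meta-module to one zone. A gene may appear in many pathways. Gene
#' sets of containers are unions of their children's gene sets, computed
#' bottom-up.
#'
#' @param zones named list: zone name -> character vector of meta-module names.
#' @param meta_modules named list: meta-module name -> module names.
#' @param modules named list: module name -> pathway names.
#' @param pathways named list: pathway name -> gene symbols (non-empty).
#' @return an object of class `map_hierarchy` with elements `zones`,
#'   `meta_modules`, `modules`, `pathways` (the definitions), `parent`
#'   (child -> parent lookup per level), `genes` (gene sets per container,
#'   per level) and `gene_index` (gene -> memberships at every level).
#' @examples
#' h <- build_hierarchy(
#'   zones        = list(A = "M1"),
#'   meta_modules = list(M1 = "mod1"),
#'   modules      = list(mod1 = "p1"),
#'   pathways     = list(p1 = c("g1", "g2")))
#' hierarchy_genes(h, "zone", "A")
#' @export
build_hierarchy <- function(zones, meta_modules, modules, pathways) {
  check_level <- function(defs, what) {
    if (is.null(names(defs)) || any(!nzchar(names(defs))) ||
        anyDuplicated(names(defs)))
      stop("definitions of ", what, " must have unique non-empty names")
  }
  check_level(zones, "zones"); check_level(meta_modules, "meta-modules")
  check_level(modules, "modules"); check_level(pathways, "pathways")

  parent_of <- function(defs, child_universe, what_child, what_parent) {
    children <- unlist(defs, use.names = FALSE)
    dup <- children[duplicated(children)]
    if (length(dup))
      stop(what_child, " assigned to two parents: ",
           paste(unique(dup), collapse = ", "))
    dangling <- setdiff(children, child_universe)
    if (length(dangling))
      stop("dangling ", what_child, " name(s) under ", what_parent, ": ",
           paste(dangling, collapse = ", "))
    orphan <- setdiff(child_universe, children)
    if (length(orphan))
      stop(what_child, " with no parent ", what_parent, ": ",
           paste(orphan, collapse = ", "))
    stats::setNames(rep(names(defs), lengths(defs)), children)
  }
  empty <- names(pathways)[lengths(pathways) == 0L]
  if (length(empty))
    stop("empty pathway gene set(s): ", paste(empty, collapse = ", "))

  parent <- list(
    pathway     = parent_of(modules, names(pathways), "pathway", "module"),
    module      = parent_of(meta_modules, names(modules), "module",
                            "meta-module"),
    meta_module = parent_of(zones, names(meta_modules), "meta-module", "zone"))

  genes <- list()
  genes$pathway <- lapply(pathways, function(g) sort(unique(as.character(g))))
  union_children <- function(defs, child_genes)
    lapply(defs, function(kids)
      sort(unique(unlist(child_genes[kids], use.names = FALSE))))
  genes$module      <- union_children(modules, genes$pathway)
  genes$meta_module <- union_children(meta_modules, genes$module)
  genes$zone        <- union_children(zones, genes$meta_module)

  all_genes <- sort(unique(unlist(genes$pathway, use.names = FALSE)))
  in_sets <- function(sets, g) names(sets)[vapply(sets, function(s)
    g %in% s, logical(1))]
  gene_index <- lapply(stats::setNames(all_genes, all_genes), function(g) {
    pw <- in_sets(genes$pathway, g)
    md <- sort(unique(unname(parent$pathway[pw])))
    mm <- sort(unique(unname(parent$module[md])))
    zn <- sort(unique(unname(parent$meta_module[mm])))
    list(pathways = sort(pw), modules = md, meta_modules = mm, zones = zn)
  })

  structure(list(zones = zones, meta_modules = meta_modules,
                 modules = modules, pathways = pathways,
                 parent = parent, genes = genes, gene_index = gene_index),
            class = "map_hierarchy")
}

#' @export
print.map_hierarchy <- function(x, ...) {
  cat("<map_hierarchy>", length(x$zones), "zones,",
      length(x$meta_modules), "meta-modules,", length(x$modules), "modules,",
      length(x$pathways), "pathways,", length(x$gene_index), "genes\n")
  invisible(x)
}

#' Gene set of a hierarchy container
#'
#' @param hierarchy a `map_hierarchy`.
#' @param level one of `"pathway"`, `"module"`, `"meta_module"`, `"zone"`.
#' @param name container name at that level.
#' @return sorted character vector of gene symbols.
#' @export
hierarchy_genes <- function(hierarchy, level, name) {
  level <- match.arg(level, HIERARCHY_LEVELS)
  gs <- hierarchy$genes[[level]][[name]]
  if (is.null(gs)) stop("no ", level, " named '", name, "'")
  gs
}

## Ancestry path "zone/meta_module/.../self" for a container.
ancestry_path <- function(hierarchy, level, name) {
  path <- name
  lv <- level
  while (lv != "zone") {
    name <- unname(hierarchy$parent[[lv]][name])
    path <- c(name, path)
    lv <- HIERARCHY_LEVELS[match(lv, HIERARCHY_LEVELS) + 1L]
  }
  paste(path, collapse = "/")
}

#' Extract gene sets at one hierarchy level
#'
#' One gene set per container at the requested level; the description field
#' carries the ancestry path (`zone/meta_module/...` down to the set itself)
#' and genes are ordered lexicographically.
#'
#' @inheritParams hierarchy_genes
#' @return a `gene_set_collection`.
#' @export
to_gene_sets <- function(hierarchy, level = "module") {
  level <- match.arg(level, HIERARCHY_LEVELS)
  nm <- names(hierarchy$genes[[level]])
  sets <- lapply(nm, function(n) {
    list(name = n, description = ancestry_path(hierarchy, level, n),
         genes = hierarchy$genes[[level]][[n]])
  })
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets a list of lists with elements `name`, `description`, `genes`.
#' @return an object of class `gene_set_collection`. Set names must be
#'   unique; genes are canonicalised to sorted unique character vectors.
#' @export
gene_set_collection <- function(sets) {
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("gene set names must be unique")
  sets <- lapply(sets, function(s) {
    s$genes <- sort(unique(as.character(s$genes)))
    s
  })
  structure(stats::setNames(sets, nm), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", length(x), "sets;",
      sum(vapply(x, function(s) length(s$genes), integer(1))),
      "gene memberships\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line, tab-separated: name, description, then gene symbols.
#' Blank lines and trailing empty fields are ignored.
#'
#' @param path file path.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[!(seq_along(f) > 2L & !nzchar(f))]  # drop trailing/empty gene fields
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    list(name = f[[1]], description = f[[2]], genes = f[-(1:2)])
  })
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `gene_set_collection`; empty gene sets are an error.
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  if (any(vapply(collection, function(s) length(s$genes) == 0L, logical(1))))
    stop("refusing to write empty gene sets")
  lines <- vapply(collection, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Entity counts per module and entity class
#'
#' Tabulates, for every module of the hierarchy, the number of tagged
#' entities overall (species) and per entity class, mirroring the content
#' table of a curated map resource. Entities whose tags resolve to no module
#' are counted under a reserved `"untagged"` row; a `"TOTAL"` row closes the
#' table.
#'
#' @param entities a data.frame with columns `id`, `symbol`, `entity_class`
#'   and `tags` (annotation strings parsed with [parse_tags()]), or a list of
#'   `map_entity` objects.
#' @param hierarchy a `map_hierarchy`; module tags not present in it are
#'   treated as untagged.
#' @return a data.frame with columns `module`, `species`, then one column per
#'   entity class.
#' @export
content_summary <- function(entities, hierarchy) {
  if (is.data.frame(entities)) {
    ents <- lapply(seq_len(nrow(entities)), function(i)
      list(entity_class = entities$entity_class[[i]],
           tags = parse_tags(entities$tags[[i]])))
  } else {
    ents <- entities
  }
  mods <- names(hierarchy$modules)
  rows <- c(mods, "untagged")
  counts <- matrix(0L, nrow = length(rows), ncol = length(ENTITY_CLASSES),
                   dimnames = list(rows, ENTITY_CLASSES))
  for (e in ents) {
    cls <- match.arg(e$entity_class, ENTITY_CLASSES)
    in_mods <- intersect(e$tags$modules, mods)
    if (length(in_mods) == 0L) in_mods <- "untagged"
    counts[in_mods, cls] <- counts[in_mods, cls] + 1L
  }
  out <- data.frame(module = rows, species = as.integer(rowSums(counts)),
                    counts, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  total <- data.frame(module = "TOTAL", species = sum(out$species),
                      as.list(colSums(counts)), check.names = FALSE,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Read an entity table from CSV
#'
#' Columns: id, symbol, entity_class, tags, references (`;`-joined PMIDs).
#' @param path CSV file path.
#' @return a data.frame.
#' @export
read_entity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "symbol", "entity_class", "tags", "references")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("entity table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$entity_class), ENTITY_CLASSES)
  if (length(bad)) stop("unknown entity class(es): ", paste(bad, collapse = ", "))
  df
}
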