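## Synthetic inputs with known ground truth: a two-zone map hierarchy,
## tagged entities, a PPI graph, single-cell log expression carrying one
## planted non-Gaussian polarization gradient, and per-gene survival
## z-scores. Every generator is a pure function of (spec, seed).

#' Simulation specification
#'
#' Defaults emulate a two-zone polarization map (anti-tumor vs pro-tumor)
#' measured in normalized log-scale single-cell RNA-seq: 2 zones x 2
#' meta-modules x 3 modules x 3 pathways x 15 genes = 540 genes, 200 cells,
#' a bimodal latent gradient with unit loading and Gaussian noise sd 0.5.
#'
#' @param n_zones number of zones (the first is the anti-tumor zone).
#' @param meta_modules_per_zone,modules_per_meta_module,pathways_per_module
#'   counts at each level (all >= 1).
#' @param genes_per_pathway genes per pathway (>= 1).
#' @param n_cells number of cells.
#' @param latent_distribution `"bimodal"` (+/-1 with Normal(0, 0.1) jitter)
#'   or `"uniform"` on (-1, 1).
#' @param loading_magnitude magnitude `a` of the planted gene loadings.
#' @param noise_sd Gaussian noise standard deviation.
#' @param fraction_active_modules fraction of modules carrying the gradient,
#'   allocated evenly across zones.
#' @param seed integer seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_zones = 2L, meta_modules_per_zone = 2L,
                            modules_per_meta_module = 3L,
                            pathways_per_module = 3L, genes_per_pathway = 15L,
                            n_cells = 200L,
                            latent_distribution = c("bimodal", "uniform"),
                            loading_magnitude = 1.0, noise_sd = 0.5,
                            fraction_active_modules = 0.5, seed = 1L) {
  latent_distribution <- match.arg(latent_distribution)
  counts <- c(n_zones, meta_modules_per_zone, modules_per_meta_module,
              pathways_per_module, genes_per_pathway, n_cells)
  stopifnot(all(counts >= 1L), noise_sd > 0, loading_magnitude > 0,
            fraction_active_modules >= 0, fraction_active_modules <= 1)
  structure(list(n_zones = as.integer(n_zones),
                 meta_modules_per_zone = as.integer(meta_modules_per_zone),
                 modules_per_meta_module = as.integer(modules_per_meta_module),
                 pathways_per_module = as.integer(pathways_per_module),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_cells = as.integer(n_cells),
                 latent_distribution = latent_distribution,
                 loading_magnitude = loading_magnitude, noise_sd = noise_sd,
                 fraction_active_modules = fraction_active_modules,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

## Deterministic entity-class cycle: mostly proteins with a sprinkle of
## gene/rna/asrna records so content tables have several populated columns.
.class_cycle <- c(rep("protein", 7), "gene", "rna", "asrna")

#' Generate a synthetic map hierarchy with tagged entities
#'
#' Builds the four-level hierarchy of the spec with synthetic gene symbols
#' G0001, G0002, ... (unique per pathway slot) and one tagged entity per
#' gene. Zone 1 is named `"Anti-tumor"`, zone 2 `"Pro-tumor"`; further zones
#' are `"Zone3"`, ... Entity classes cycle deterministically (7 proteins,
#' then one gene, rna and asrna per block of 10).
#'
#' @param spec a `simulation_spec`.
#' @return a list with `hierarchy` (a `map_hierarchy`), `entities` (a
#'   data.frame with id, symbol, entity_class, tags, references) and
#'   `class_counts` (the generator's own bookkeeping of entities per class).
#' @export
generate_map <- function(spec = simulation_spec()) {
  zn <- c("Anti-tumor", "Pro-tumor",
          if (spec$n_zones > 2L) paste0("Zone", 3:spec$n_zones))
  zn <- zn[seq_len(spec$n_zones)]
  zones <- list(); meta_modules <- list(); modules <- list(); pathways <- list()
  gi <- 0L
  for (zi in seq_along(zn)) {
    mm_names <- sprintf("MM%d_%d", zi, seq_len(spec$meta_modules_per_zone))
    zones[[zn[zi]]] <- mm_names
    for (mm in mm_names) {
      mod_names <- sprintf("%s_mod%d", mm, seq_len(spec$modules_per_meta_module))
      meta_modules[[mm]] <- mod_names
      for (md in mod_names) {
        pw_names <- sprintf("%s_p%d", md, seq_len(spec$pathways_per_module))
        modules[[md]] <- pw_names
        for (pw in pw_names) {
          g <- sprintf("G%04d", gi + seq_len(spec$genes_per_pathway))
          gi <- gi + spec$genes_per_pathway
          pathways[[pw]] <- g
        }
      }
    }
  }
  hierarchy <- build_hierarchy(zones, meta_modules, modules, pathways)

  genes <- sort(unlist(pathways, use.names = FALSE))
  idx <- lapply(genes, function(g) hierarchy$gene_index[[g]])
  tags <- vapply(seq_along(genes), function(i) {
    paste(c(paste0("MODULE:", idx[[i]]$modules),
            paste0("PATHWAY:", idx[[i]]$pathways),
            paste0("MAP:", idx[[i]]$zones)), collapse = " ")
  }, character(1))
  cls <- .class_cycle[((seq_along(genes) - 1L) %% length(.class_cycle)) + 1L]
  entities <- data.frame(id = paste0("e_", genes), symbol = genes,
                         entity_class = cls, tags = tags,
                         references = "", stringsAsFactors = FALSE)
  list(hierarchy = hierarchy, entities = entities,
       class_counts = table(factor(cls, levels = ENTITY_CLASSES)))
}

## Active-module selection and signed loadings: modules are sampled evenly
## per zone so both polarization directions carry signal.
plant_loadings <- function(hierarchy, spec) {
  set.seed(spec$seed)
  zones <- names(hierarchy$zones)
  active <- character()
  for (z in zones) {
    mods <- unlist(hierarchy$meta_modules[hierarchy$zones[[z]]],
                   use.names = FALSE)
    k <- round(spec$fraction_active_modules * length(mods))
    if (k > 0L) active <- c(active, sample(mods, k))
  }
  genes <- names(hierarchy$gene_index)
  s <- stats::setNames(numeric(length(genes)), genes)
  # first zone is the anti-tumor zone by construction
  anti_mods <- unlist(hierarchy$meta_modules[hierarchy$zones[[zones[1L]]]],
                      use.names = FALSE)
  for (md in active) {
    sign_md <- if (md %in% anti_mods) 1 else -1
    s[hierarchy$genes$module[[md]]] <- sign_md * spec$loading_magnitude
  }
  list(active_modules = sort(active), loadings = s)
}

#' Generate synthetic single-cell expression with a planted gradient
#'
#' Draws one latent polarization value per cell (bimodal: +/-1 plus
#' Normal(0, 0.1) jitter; or uniform(-1, 1)) and emits log-scale expression
#' `x[g, c] = s_g * t_c + noise`, with `s_g = +a` for genes of active
#' anti-tumor-zone modules, `-a` for active pro-tumor-zone modules and 0
#' otherwise. The matrix is returned uncentered; ground truth (latent,
#' group labels = sign(t), active modules, loadings) rides along.
#'
#' @param hierarchy a `map_hierarchy` from [generate_map()].
#' @param spec the `simulation_spec`.
#' @return a list with `expression` (an uncentered `expression_matrix`) and
#'   `truth` (list: `latent`, `group` in {1, 2}, `active_modules`,
#'   `loadings`).
#' @export
generate_cells <- function(hierarchy, spec = simulation_spec()) {
  planted <- plant_loadings(hierarchy, spec)
  set.seed(spec$seed + 1L)
  n <- spec$n_cells
  t_c <- switch(spec$latent_distribution,
    bimodal = sample(c(-1, 1), n, replace = TRUE) + stats::rnorm(n, 0, 0.1),
    uniform = stats::runif(n, -1, 1))
  genes <- names(planted$loadings)
  x <- outer(planted$loadings, t_c) +
    matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sd),
           nrow = length(genes))
  cells <- sprintf("cell%03d", seq_len(n))
  dimnames(x) <- list(genes, cells)
  expr <- expression_matrix(x, centered = FALSE)
  group <- ifelse(t_c > 0, 1L, 2L)
  list(expression = expr,
       truth = list(latent = stats::setNames(t_c, cells),
                    group = stats::setNames(group, cells),
                    active_modules = planted$active_modules,
                    loadings = planted$loadings))
}

#' Generate a synthetic PPI graph over the map's proteins
#'
#' Erdos-Renyi background over all protein entities plus densified edges
#' among proteins sharing a pathway, so within-pathway proximity is high —
#' the structure the functional proximity score rewards.
#'
#' @param map a list from [generate_map()] (`hierarchy` + `entities`).
#' @param intra_reaction_edge_prob edge probability within a pathway.
#' @param background_edge_prob background edge probability.
#' @param seed integer seed.
#' @return a `ppi_graph` over all protein symbols (isolated nodes kept).
#' @export
generate_ppi <- function(map, intra_reaction_edge_prob = 0.8,
                         background_edge_prob = 0.01, seed = 1L) {
  ent <- map$entities
  prot <- ent$symbol[ent$entity_class == "protein"]
  set.seed(seed)
  edges <- matrix(character(), ncol = 2)
  np <- length(prot)
  if (np >= 2L && background_edge_prob > 0) {
    pairs <- utils::combn(prot, 2L)
    keep <- stats::runif(ncol(pairs)) < background_edge_prob
    edges <- rbind(edges, t(pairs[, keep, drop = FALSE]))
  }
  if (intra_reaction_edge_prob > 0) {
    for (pw in names(map$hierarchy$pathways)) {
      pg <- intersect(map$hierarchy$genes$pathway[[pw]], prot)
      if (length(pg) < 2L) next
      pairs <- utils::combn(pg, 2L)
      keep <- stats::runif(ncol(pairs)) < intra_reaction_edge_prob
      edges <- rbind(edges, t(pairs[, keep, drop = FALSE]))
    }
  }
  ppi_graph(edges, nodes = prot)
}

#' Generate a synthetic per-gene survival z-score table
#'
#' Plants a mean z per meta-module; each gene draws `z ~ Normal(mu_m, 1)`
#' where `mu_m` is the mean of the planted means over the gene's
#' meta-modules. Two-sided p values come from the standard normal. The sign
#' convention follows pan-cancer survival meta-analyses: z < 0 marks
#' positive association with patient survival.
#'
#' @param hierarchy a `map_hierarchy`.
#' @param mu named numeric vector: meta-module name -> planted mean z.
#'   Meta-modules absent from `mu` get 0.
#' @param seed integer seed.
#' @return a data.frame of class `survival_table` with columns `gene`, `z`,
#'   `p`.
#' @export
generate_survival_zscores <- function(hierarchy, mu = NULL, seed = 1L) {
  mms <- names(hierarchy$meta_modules)
  mu_full <- stats::setNames(rep(0, length(mms)), mms)
  if (!is.null(mu)) {
    bad <- setdiff(names(mu), mms)
    if (length(bad)) stop("unknown meta-module(s) in mu: ",
                          paste(bad, collapse = ", "))
    mu_full[names(mu)] <- mu
  }
  genes <- names(hierarchy$gene_index)
  gene_mu <- vapply(genes, function(g)
    mean(mu_full[hierarchy$gene_index[[g]]$meta_modules]), numeric(1))
  set.seed(seed)
  z <- stats::rnorm(length(genes), gene_mu, 1)
  tab <- data.frame(gene = genes, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("survival_table", class(tab))
  tab
}
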