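#' Iterative walktrap community detection
#'
#' Runs walktrap community detection on a (sub)graph and recursively
#' re-clusters any community larger than `max_size` on its induced
#' subgraph, until all communities are at or below the size ceiling. A
#' community that walktrap cannot split further (the partition returns it
#' whole) is kept as-is and flagged unsplittable, with a warning, so that
#' no genes silently vanish. Communities with `min_size` nodes or fewer
#' are retained in the partition but excluded from the module list.
#'
#' Disconnected graphs are handled by clustering each connected component
#' separately; an empty graph yields an empty result.
#'
#' @param subgraph undirected igraph with named vertices.
#' @param max_size communities larger than this are re-clustered
#'   (default 300).
#' @param min_size communities must exceed this size to count as modules
#'   (default 10, i.e. modules have > 10 genes).
#' @param steps random-walk length of the walktrap algorithm (canonical
#'   default 4).
#' @param max_depth recursion-depth guard; deeper recursions abort with a
#'   diagnostic.
#' @return a `walktrap_communities` object: list with `communities` (list
#'   of character vectors partitioning the clustered nodes),
#'   `unsplittable` (logical flag per community) and `modules` (integer
#'   indices of communities with size > `min_size`).
#' @export
iterative_walktrap <- function(subgraph, max_size = 300L, min_size = 10L,
                               steps = 4L, max_depth = 20L) {
  stopifnot(max_size > min_size)
  comms <- list()
  flags <- logical(0)
  add <- function(genes, unsplit) {
    comms[[length(comms) + 1L]] <<- genes
    flags[length(flags) + 1L] <<- unsplit
  }
  recurse <- function(g, depth) {
    if (igraph::vcount(g) == 0) return(invisible(NULL))
    if (depth > max_depth) {
      stop("iterative walktrap exceeded recursion depth ", max_depth,
           " on a community of ", igraph::vcount(g), " nodes")
    }
    pieces <- igraph::decompose(g)
    for (comp in pieces) {
      if (igraph::vcount(comp) <= max_size) {
        # a small connected component needs no further splitting to meet
        # the ceiling, but walktrap still refines it at the top level
        if (depth == 0L && igraph::vcount(comp) > 1) {
          wt <- igraph::cluster_walktrap(comp, steps = steps)
          memb <- igraph::membership(wt)
          for (cid in sort(unique(memb))) {
            add(names(memb)[memb == cid], FALSE)
          }
        } else {
          add(igraph::V(comp)$name, FALSE)
        }
        next
      }
      wt <- igraph::cluster_walktrap(comp, steps = steps)
      memb <- igraph::membership(wt)
      ids <- sort(unique(memb))
      if (length(ids) == 1L) {
        warning("community of ", igraph::vcount(comp),
                " nodes could not be split further; kept with an ",
                "unsplittable flag")
        add(igraph::V(comp)$name, TRUE)
        next
      }
      for (cid in ids) {
        genes <- names(memb)[memb == cid]
        if (length(genes) > max_size) {
          recurse(igraph::induced_subgraph(comp, genes), depth + 1L)
        } else {
          add(genes, FALSE)
        }
      }
    }
    invisible(NULL)
  }
  recurse(subgraph, 0L)
  structure(list(communities = comms,
                 unsplittable = flags,
                 modules = which(lengths(comms) > min_size)),
            class = "walktrap_communities")
}

#' @export
print.walktrap_communities <- function(x, ...) {
  cat("iterative walktrap: ", length(x$communities), " communities, ",
      length(x$modules), " modules (>", 0, " genes), ",
      sum(x$unsplittable), " unsplittable\n", sep = "")
  invisible(x)
}

#' Score module significance by Kolmogorov-Smirnov test
#'
#' For each module, compares the propagation scores of its member genes
#' against all other scored genes with a two-sample Kolmogorov-Smirnov
#' test and adjusts the resulting p-values across modules by
#' Benjamini-Hochberg. A module is called significant when its members'
#' scores are stochastically greater than the background and the adjusted
#' p-value falls below `alpha`.
#'
#' The default alternative is one-sided ("greater" member scores), since a
#' disease module is one enriched in high propagation scores; a two-sided
#' test is available via `alternative`. Note that testing for
#' stochastically greater member scores corresponds to
#' `ks.test(member, background, alternative = "less")` in R's CDF-based
#' convention; the translation is handled internally.
#'
#' @param modules list of character vectors (gene sets); every gene must
#'   be scored.
#' @param scores `ppr_scores` or named numeric vector covering the score
#'   universe used as background (members are excluded per test).
#' @param alpha significance level applied to BH-adjusted p-values.
#' @param alternative `"greater"` (members stochastically greater,
#'   default) or `"two.sided"`.
#' @return data.frame with one row per module: `module`, `n_genes`,
#'   `ks_statistic`, `p_raw`, `p_adjusted`, `significant`.
#' @export
ks_module_significance <- function(modules, scores, alpha = 0.05,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  s <- score_vector(scores)
  if (!length(modules)) {
    return(data.frame(module = integer(0), n_genes = integer(0),
                      ks_statistic = numeric(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  }
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  res <- lapply(modules, function(genes) {
    if (!all(genes %in% names(s))) {
      stop("module contains unscored gene(s): ",
           paste(head(setdiff(genes, names(s)), 5), collapse = ", "))
    }
    member <- s[genes]
    background <- s[setdiff(names(s), genes)]
    if (!length(background)) {
      stop("module equals the entire scored node set; no background left")
    }
    kt <- suppressWarnings(
      ks.test(member, background, alternative = ks_alt))
    c(D = unname(kt$statistic), p = kt$p.value)
  })
  res <- do.call(rbind, res)
  p_adj <- p.adjust(res[, "p"], method = "BH")
  data.frame(module = seq_along(modules),
             n_genes = lengths(modules),
             ks_statistic = res[, "D"],
             p_raw = res[, "p"],
             p_adjusted = p_adj,
             significant = p_adj < alpha,
             row.names = NULL)
}

#' Discover significant disease modules from seeds
#'
#' Composes the full network-expansion pipeline: personalized PageRank
#' diffusion of the seed weights, selection of the top-ranked node
#' fraction, iterative walktrap clustering of the induced subgraph, and
#' Kolmogorov-Smirnov module significance with Benjamini-Hochberg control
#' across the modules of the run.
#'
#' @param net undirected igraph with named vertices.
#' @param seeds a `seed_set`.
#' @param damping,fraction,max_size,min_size,steps,alpha,alternative
#'   stage parameters; see [personalized_pagerank()],
#'   [select_top_fraction()], [iterative_walktrap()] and
#'   [ks_module_significance()].
#' @param background `"selected"` (default) scores modules against the
#'   other genes of the selected subgraph, on which clustering operates;
#'   `"all"` uses every scored gene of the interactome.
#' @return a `module_catalog` object: list with `trait`, `modules` (list
#'   of gene vectors, modules only), `table` (per-module statistics,
#'   including the unsplittable flag), `communities` (the full partition)
#'   and `params`.
#' @export
discover_significant_modules <- function(net, seeds, damping = 0.85,
                                         fraction = 0.25, max_size = 300L,
                                         min_size = 10L, steps = 4L,
                                         alpha = 0.05,
                                         alternative = "greater",
                                         background = c("selected", "all")) {
  background <- match.arg(background)
  ppr <- personalized_pagerank(net, seeds, damping = damping)
  expansion <- select_top_fraction(ppr, fraction = fraction)
  sub <- igraph::induced_subgraph(net, expansion$selected)
  wt <- iterative_walktrap(sub, max_size = max_size, min_size = min_size,
                           steps = steps)
  modules <- wt$communities[wt$modules]
  bg_scores <- if (background == "selected") {
    ppr$scores[expansion$selected]
  } else {
    ppr$scores
  }
  tab <- ks_module_significance(modules, bg_scores, alpha = alpha,
                                alternative = alternative)
  tab$unsplittable <- wt$unsplittable[wt$modules]
  structure(list(trait = seeds$trait,
                 modules = modules,
                 table = tab,
                 communities = wt,
                 expansion = expansion,
                 params = list(damping = damping, fraction = fraction,
                               max_size = max_size, min_size = min_size,
                               steps = steps, alpha = alpha,
                               alternative = alternative,
                               background = background)),
            class = "module_catalog")
}

#' @export
print.module_catalog <- function(x, ...) {
  cat("module catalog for trait '", x$trait, "': ", length(x$modules),
      " modules, ", sum(x$table$significant), " significant\n", sep = "")
  invisible(x)
}

#' Union of genes in significant modules
#'
#' @param catalog a `module_catalog`.
#' @return character vector: all genes found in significant modules of the
#'   trait (the per-disease gene union used for bulk overlap analyses).
#' @export
all_module_genes <- function(catalog) {
  stopifnot(inherits(catalog, "module_catalog"))
  idx <- which(catalog$table$significant)
  sort(unique(unlist(catalog$modules[idx])))
}

#' Assemble a module catalog by hand
#'
#' Mostly useful in tests and for importing module lists computed
#' elsewhere; [discover_significant_modules()] is the standard
#' constructor.
#'
#' @param trait trait label.
#' @param modules list of character gene vectors.
#' @param significant logical vector, one flag per module.
#' @return a `module_catalog`.
#' @export
module_catalog <- function(trait, modules, significant) {
  stopifnot(length(modules) == length(significant))
  tab <- data.frame(module = seq_along(modules), n_genes = lengths(modules),
                    ks_statistic = NA_real_, p_raw = NA_real_,
                    p_adjusted = NA_real_, significant = significant,
                    unsplittable = FALSE)
  structure(list(trait = trait, modules = modules, table = tab,
                 communities = NULL, expansion = NULL, params = list()),
            class = "module_catalog")
}
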