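#' Jaccard index of two gene sets
#'
#' @param a,b character vectors (duplicates ignored). At least one must be
#'   nonempty.
#' @return `|a n b| / |a u b|`, in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) stop("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / length(u)
}

#' Pairwise disease similarity from module catalogs
#'
#' For each trait, pools all genes found in its significant modules and
#' computes the pairwise Jaccard index between these per-disease gene
#' unions.
#'
#' @param catalogs list of `module_catalog` objects (>= 2).
#' @return symmetric matrix of Jaccard values with trait labels as
#'   dimnames. A catalog with no significant modules contributes a row and
#'   column of zeros, with a warning.
#' @export
disease_similarity_matrix <- function(catalogs) {
  if (length(catalogs) < 2) stop("need at least two module catalogs")
  traits <- vapply(catalogs, function(x) x$trait, "")
  unions <- lapply(catalogs, all_module_genes)
  empty <- lengths(unions) == 0
  if (any(empty)) {
    warning("catalog(s) with zero significant modules: ",
            paste(traits[empty], collapse = ", "),
            "; their similarities are reported as 0")
  }
  n <- length(catalogs)
  m <- matrix(0, n, n, dimnames = list(traits, traits))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- if (empty[i] || empty[j]) {
        0
      } else {
        jaccard_index(unions[[i]], unions[[j]])
      }
    }
  }
  m
}

#' Group modules shared across diseases
#'
#' Builds a graph whose vertices are the significant modules of all
#' catalogs, with an edge between two modules of *different* traits
#' whenever their gene-level Jaccard index reaches `threshold`. Connected
#' components spanning at least two traits are returned as module groups;
#' within-trait components are discarded.
#'
#' @param catalogs list of `module_catalog` objects.
#' @param threshold minimum Jaccard index for an edge (default 0.7).
#' @return list of `module_group` objects, each a list with `members`
#'   (data.frame of `trait`, `module`), `traits_covered` and
#'   `union_genes`. May be empty.
#' @export
group_shared_modules <- function(catalogs, threshold = 0.7) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  entries <- list()
  for (cat_ in catalogs) {
    for (i in which(cat_$table$significant)) {
      entries[[length(entries) + 1L]] <-
        list(trait = cat_$trait, module = i, genes = cat_$modules[[i]])
    }
  }
  n <- length(entries)
  if (n < 2) return(list())
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (entries[[i]]$trait == entries[[j]]$trait) next
      if (jaccard_index(entries[[i]]$genes, entries[[j]]$genes) >= threshold) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  groups <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    traits <- unique(vapply(entries[idx], function(e) e$trait, ""))
    if (length(traits) < 2) next
    groups[[length(groups) + 1L]] <- structure(list(
      members = data.frame(
        trait = vapply(entries[idx], function(e) e$trait, ""),
        module = vapply(entries[idx], function(e) e$module, 0L)),
      traits_covered = sort(traits),
      union_genes = sort(unique(unlist(lapply(entries[idx],
                                              function(e) e$genes))))),
      class = "module_group")
  }
  groups
}

#' @export
print.module_group <- function(x, ...) {
  cat("module group: ", nrow(x$members), " modules across traits ",
      paste(x$traits_covered, collapse = ", "), " (",
      length(x$union_genes), " genes)\n", sep = "")
  invisible(x)
}

#' Read gene-set annotations in GMT format
#'
#' Thin wrapper around [fgsea::gmtPathways()] that canonicalizes gene
#' identifiers the same way as the rest of the package.
#'
#' @param path GMT file (term, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, canonical_gene)
}

#' Fisher over-representation test for gene sets
#'
#' For every annotation term, tests whether the query genes hit the term
#' more often than expected under hypergeometric sampling from the
#' background (the one-sided Fisher exact test of the 2x2 table), and
#' adjusts p-values across terms by Benjamini-Hochberg.
#'
#' Annotation gene sets are intersected with the background before
#' testing; terms with no background hits are skipped.
#'
#' @param query character vector of genes; must be nonempty and a subset
#'   of `background`.
#' @param annotation named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame sorted by `p_adjusted`, with columns `term`, `k`
#'   (query hits), `K` (background hits), `n` (query size), `N`
#'   (background size), `p_raw`, `p_adjusted`.
#' @export
fisher_enrichment <- function(query, annotation, background) {
  query <- unique(query); background <- unique(background)
  if (!length(query)) stop("empty query gene set")
  if (!all(query %in% background)) {
    stop("query must be a subset of the background universe")
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    hits <- intersect(annotation[[term]], background)
    K <- length(hits)
    if (K == 0) return(NULL)
    k <- length(intersect(query, hits))
    # one-sided over-representation p: upper hypergeometric tail,
    # identical to fisher.test(..., alternative = "greater")
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_raw = p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0)))
  }
  rows$p_adjusted <- p.adjust(rows$p_raw, method = "BH")
  rows <- rows[order(rows$p_adjusted, rows$p_raw), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
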