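#' Read a protein-interaction edge table
#'
#' Edge tables are tab-separated files with a header and columns
#' `gene_a`, `gene_b` and (optionally) `score`. Lines starting with `#`
#' are ignored. Gene identifiers are treated as opaque strings and
#' canonicalized by whitespace-stripping and upper-casing; no identifier
#' mapping service is consulted.
#'
#' @param path path to a TSV file.
#' @param source label recorded as the origin of every edge; defaults to
#'   the file name.
#' @return a data.frame with columns `gene_a`, `gene_b`, `score`
#'   (`NA` when the table carries no score column) and `source`.
#' @export
read_edge_table <- function(path, source = basename(path)) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_a", "gene_b")
  if (!all(required %in% names(df))) {
    stop("edge table ", path, " must have columns 'gene_a' and 'gene_b'")
  }
  bad <- which(is.na(df$gene_a) | is.na(df$gene_b) |
                 !nzchar(trimws(as.character(df$gene_a))) |
                 !nzchar(trimws(as.character(df$gene_b))))
  if (length(bad)) {
    stop("malformed edge row(s) in ", path, " (missing gene identifier): row ",
         paste(bad, collapse = ", "))
  }
  score <- if ("score" %in% names(df)) {
    s <- suppressWarnings(as.numeric(df$score))
    nonnum <- which(is.na(s) & !is.na(df$score) & nzchar(as.character(df$score)))
    if (length(nonnum)) {
      stop("malformed edge row(s) in ", path, " (non-numeric score): row ",
           paste(nonnum, collapse = ", "))
    }
    out_of_range <- which(!is.na(s) & (s < 0 | s > 1))
    if (length(out_of_range)) {
      stop("malformed edge row(s) in ", path, " (score outside [0,1]): row ",
           paste(out_of_range, collapse = ", "))
    }
    s
  } else {
    rep(NA_real_, nrow(df))
  }
  data.frame(gene_a = canonical_gene(df$gene_a),
             gene_b = canonical_gene(df$gene_b),
             score = score,
             source = source,
             stringsAsFactors = FALSE)
}

canonical_gene <- function(x) toupper(trimws(as.character(x)))

#' Build a composite interactome from edge tables
#'
#' Merges one or more edge tables into a single undirected simple graph.
#' Edges are stored with endpoints in lexicographic order; self-loops are
#' removed and duplicate edges collapsed, keeping the maximum score when
#' scores conflict. Tables that carry a confidence score are filtered at a
#' strict threshold (`score > score_threshold`, mirroring a combined-score
#' cutoff such as 0.75); tables without scores pass all their edges.
#'
#' @param edge_tables a data.frame as returned by [read_edge_table()], a
#'   list of such data.frames, or a character vector of file paths.
#' @param score_threshold numeric in \[0, 1\]; edges with
#'   `score <= score_threshold` are dropped from scored tables.
#' @param quiet suppress the node/edge count message.
#' @return an undirected simple [igraph::igraph] with named vertices.
#' @export
build_interactome <- function(edge_tables, score_threshold = 0.75,
                              quiet = FALSE) {
  if (!is.numeric(score_threshold) || length(score_threshold) != 1 ||
      is.na(score_threshold) || score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must be a single number in [0, 1]")
  }
  if (is.character(edge_tables)) {
    edge_tables <- lapply(edge_tables, read_edge_table)
  } else if (is.data.frame(edge_tables)) {
    edge_tables <- list(edge_tables)
  }
  edges <- do.call(rbind, lapply(edge_tables, function(tab) {
    tab[, c("gene_a", "gene_b", "score")]
  }))
  # strict-threshold filter for scored rows; scoreless rows pass through
  keep <- is.na(edges$score) | edges$score > score_threshold
  edges <- edges[keep, , drop = FALSE]
  # canonical unordered pairs, drop self-loops
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  if (!length(a)) {
    stop("empty interactome: no edges survive the score filter and ",
         "self-loop removal")
  }
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a[!dup], b[!dup]), directed = FALSE)
  if (!quiet) {
    message("interactome: ", igraph::vcount(g), " nodes, ",
            igraph::ecount(g), " edges")
  }
  g
}

#' Dump an interactome back to an edge table
#'
#' Writes (or returns) the canonical edge list of a graph in the same TSV
#' shape accepted by [read_edge_table()], so that
#' `build_interactome(interactome_edges(g))` reproduces `g`.
#'
#' @param net an undirected igraph with named vertices.
#' @param path optional file to write a TSV to.
#' @return invisibly, a data.frame with `gene_a`, `gene_b` (lexicographic
#'   order) and an all-`NA` `score` column.
#' @export
interactome_edges <- function(net, path = NULL) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = pmin(el[, 1], el[, 2]),
                   gene_b = pmax(el[, 1], el[, 2]),
                   score = NA_real_, stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}

#' Read a GWAS-style association table
#'
#' @param path TSV with a header and columns `trait`, `gene`, `pvalue`.
#' @return data.frame with canonicalized gene identifiers.
#' @export
read_seed_table <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("trait", "gene", "pvalue")
  if (!all(required %in% names(df))) {
    stop("association table must have columns 'trait', 'gene' and 'pvalue'")
  }
  df$gene <- canonical_gene(df$gene)
  df$pvalue <- as.numeric(df$pvalue)
  df
}

#' Build a seed set from association p-values
#'
#' Converts per-gene association p-values into nonnegative starting
#' weights `-log10(p)` for network propagation. Rows from all pooled
#' traits are combined; when a gene appears several times (within or
#' across the pooled traits) the highest weight, i.e. the smallest
#' p-value, is kept.
#'
#' @param association_table data.frame with `trait`, `gene`, `pvalue`
#'   columns (e.g. from [read_seed_table()]), or a path to such a TSV.
#' @param traits_to_pool character vector of trait labels to pool (for
#'   example an ALS and a sporadic-ALS catalogue entry).
#' @param label trait label recorded on the result; defaults to the pooled
#'   trait names joined with "+".
#' @return a `seed_set` object: list with `trait` and `weights`, a named
#'   nonnegative numeric vector.
#' @export
load_seed_weights <- function(association_table, traits_to_pool,
                              label = paste(traits_to_pool, collapse = "+")) {
  if (is.character(association_table) && length(association_table) == 1) {
    association_table <- read_seed_table(association_table)
  }
  df <- association_table[association_table$trait %in% traits_to_pool, ,
                          drop = FALSE]
  if (!nrow(df)) {
    stop("no association rows found for trait(s): ",
         paste(traits_to_pool, collapse = ", "))
  }
  p <- as.numeric(df$pvalue)
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]; offending row(s): ",
         paste(which(is.na(p) | p <= 0 | p > 1), collapse = ", "))
  }
  w <- -log10(p)
  gene <- canonical_gene(df$gene)
  weights <- tapply(w, gene, max)
  weights <- setNames(as.numeric(weights), names(weights))
  seed_set(label, weights)
}

#' Construct a seed set
#'
#' @param trait trait label.
#' @param weights named nonnegative numeric vector of starting weights
#'   (typically `-log10` p-values).
#' @return a `seed_set` object.
#' @export
seed_set <- function(trait, weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("seed weights must be a named numeric vector")
  }
  if (anyDuplicated(names(weights))) stop("seed genes must be unique")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("seed weights must be finite and nonnegative")
  }
  structure(list(trait = as.character(trait), weights = weights),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed set for trait '", x$trait, "': ", length(x$weights),
      " genes, total weight ", format(sum(x$weights), digits = 4), "\n",
      sep = "")
  invisible(x)
}
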