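#' Diffuse seed weights with personalized PageRank
#'
#' Computes the stationary distribution of a random walk on the
#' interactome that, with probability `1 - damping`, restarts at a seed
#' gene drawn in proportion to its starting weight. This is the fixed
#' point of
#' \deqn{x = (1 - d)\,p + d\,W x}
#' where `p` is the seed weight vector normalized to sum one and `W` the
#' column-stochastic adjacency matrix (each neighbour receives an equal
#' share of a node's mass). Solved by power iteration on a sparse matrix;
#' any mass sitting on degree-zero nodes is redistributed through the
#' personalization vector, the standard PageRank convention for dangling
#' nodes.
#'
#' Seed genes absent from the network are dropped with a warning; if no
#' seed overlaps the network, an error is raised.
#'
#' @param net undirected igraph with named vertices.
#' @param seeds a `seed_set` (see [seed_set()]) or a named nonnegative
#'   numeric vector of weights.
#' @param damping probability of following an edge rather than
#'   restarting; in `[0, 1)`. The value is not dictated by the method and
#'   defaults to the conventional 0.85.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter maximum number of iterations before a non-convergence
#'   error (the error reports the residual).
#' @return a `ppr_scores` object: list with `scores` (named probabilities
#'   summing to 1), `damping`, `trait`, `iterations`, `residual`.
#' @export
personalized_pagerank <- function(net, seeds, damping = 0.85,
                                  tol = 1e-12, max_iter = 1000L) {
  if (!is.numeric(damping) || length(damping) != 1 || is.na(damping) ||
      damping < 0 || damping >= 1) {
    stop("damping must be a single number in [0, 1)")
  }
  if (inherits(seeds, "seed_set")) {
    trait <- seeds$trait
    w <- seeds$weights
  } else {
    trait <- NA_character_
    w <- seeds
  }
  nodes <- igraph::V(net)$name
  missing <- setdiff(names(w), nodes)
  if (length(missing)) {
    warning(length(missing), " seed gene(s) not in the network were dropped: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    w <- w[setdiff(names(w), missing)]
  }
  if (!length(w)) stop("no seed gene overlaps the network")
  if (sum(w) <= 0) stop("seed weights sum to zero after restriction to the network")

  n <- length(nodes)
  p <- numeric(n)
  p[match(names(w), nodes)] <- w
  p <- p / sum(p)

  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  x <- p
  iter <- 0L
  residual <- Inf
  repeat {
    iter <- iter + 1L
    spread <- x / pmax(deg, 1)
    spread[dangling] <- 0
    x_new <- as.numeric(A %*% spread) * damping +
      (1 - damping + damping * sum(x[dangling])) * p
    residual <- sum(abs(x_new - x))
    x <- x_new
    if (residual < tol) break
    if (iter >= max_iter) {
      stop("personalized PageRank did not converge after ", max_iter,
           " iterations (L1 residual ", format(residual, digits = 3), ")")
    }
  }
  x <- x / sum(x)  # guard against rounding drift
  structure(list(scores = setNames(x, nodes), damping = damping,
                 trait = trait, iterations = iter, residual = residual),
            class = "ppr_scores")
}

#' @export
print.ppr_scores <- function(x, ...) {
  cat("personalized PageRank scores: ", length(x$scores), " nodes (trait '",
      x$trait, "', damping ", x$damping, ", ", x$iterations,
      " iterations)\n", sep = "")
  invisible(x)
}

score_vector <- function(scores) {
  if (inherits(scores, "ppr_scores")) scores$scores else scores
}

#' Select the top-ranked fraction of propagated nodes
#'
#' Keeps the `ceiling(fraction * N)` nodes with the highest propagation
#' scores (for example the upper 25% of the PageRank ranking, which feeds
#' community detection). Ties at the cutoff are broken by lexicographic
#' node identifier so the selection is deterministic.
#'
#' @param scores a `ppr_scores` object or named numeric vector.
#' @param fraction fraction of nodes to keep, in (0, 1].
#' @return an `expansion` object: list with `selected` (node names in rank
#'   order), `fraction` and the input `scores`.
#' @export
select_top_fraction <- function(scores, fraction = 0.25) {
  s <- score_vector(scores)
  if (!length(s)) stop("empty score map")
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]")
  }
  k <- ceiling(fraction * length(s))
  ord <- order(-s, names(s))
  structure(list(selected = names(s)[ord][seq_len(k)],
                 fraction = fraction,
                 scores = scores),
            class = "expansion")
}

#' @export
print.expansion <- function(x, ...) {
  cat("expansion: ", length(x$selected), " nodes selected (top ",
      format(100 * x$fraction), "%)\n", sep = "")
  invisible(x)
}
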