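#' Read a differential transcript/protein table
#'
#' @param path TSV with header and columns `gene`, `layer` (one of
#'   `transcript`, `protein`), `log2_ratio`, `pvalue`.
#' @return data.frame with canonicalized gene identifiers.
#' @export
read_omics_table <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "layer", "log2_ratio", "pvalue")
  if (!all(required %in% names(df))) {
    stop("omics table must have columns 'gene', 'layer', 'log2_ratio', 'pvalue'")
  }
  df$gene <- canonical_gene(df$gene)
  df$log2_ratio <- as.numeric(df$log2_ratio)
  df$pvalue <- as.numeric(df$pvalue)
  if (any(!is.finite(df$log2_ratio))) stop("log2_ratio must be finite")
  if (any(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (anyDuplicated(df[, c("gene", "layer")])) {
    stop("one record per (gene, layer) expected")
  }
  df
}

#' Significance A outlier statistic for log ratios
#'
#' Scores how extreme each (averaged) log ratio is relative to the bulk of
#' the distribution, using the asymmetric robust z of the Perseus
#' Significance A definition: with r0 the median and r1, r-1 the 84.13th
#' and 15.87th percentiles (the one-sigma quantiles of a normal),
#' \deqn{z = (r - r_0)/(r_1 - r_0)} for ratios above the median and
#' \deqn{z = (r_0 - r)/(r_0 - r_{-1})} below it, and the outlier p-value
#' is the normal upper tail \eqn{p = \tfrac12 \mathrm{erfc}(z/\sqrt2)}.
#' A ratio at the median has z = 0 and p = 0.5; p decreases strictly as
#' the ratio moves away from the median on either side.
#'
#' @param ratios named numeric vector of (averaged) log2 ratios; at least
#'   8 finite values so the percentiles are meaningful.
#' @return data.frame with columns `gene`, `ratio`, `z`, `p`, in the input
#'   order.
#' @export
significance_a <- function(ratios) {
  if (length(ratios) < 8) stop("need at least 8 ratios for Significance A")
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  if (is.null(names(ratios))) names(ratios) <- as.character(seq_along(ratios))
  q <- quantile(ratios, c(0.1587, 0.5, 0.8413), type = 7, names = FALSE)
  r_lo <- q[1]; r0 <- q[2]; r_hi <- q[3]
  if (r_hi <= r0 || r0 <= r_lo) {
    stop("degenerate ratio spread: one-sigma percentile equals the median")
  }
  z <- ifelse(ratios >= r0, (ratios - r0) / (r_hi - r0),
              (r0 - ratios) / (r0 - r_lo))
  p <- pnorm(z, lower.tail = FALSE)   # = 0.5 * erfc(z / sqrt(2))
  data.frame(gene = names(ratios), ratio = unname(ratios),
             z = unname(z), p = unname(p), row.names = NULL)
}

#' Overlap of three network expansions
#'
#' Takes the module catalogs of the three input layers (GWAS,
#' transcriptome, proteome), pools each layer's significant-module genes,
#' and reports all pairwise intersection counts plus the triple-overlap
#' gene set.
#'
#' @param gwas_cat,tx_cat,prot_cat `module_catalog` objects from the same
#'   interactome.
#' @return a `triple_overlap` object: list with `per_set_genes` (named
#'   list of the three unions), `pairwise_counts` (named integer vector),
#'   `triple_genes`, and `union_size` (size of the three-way union, so the
#'   inclusion-exclusion identity can be checked directly).
#' @export
integrate_expansions <- function(gwas_cat, tx_cat, prot_cat) {
  sets <- list(gwas = all_module_genes(gwas_cat),
               transcriptome = all_module_genes(tx_cat),
               proteome = all_module_genes(prot_cat))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("layer(s) with no significant-module genes: ",
            paste(names(sets)[empty], collapse = ", "))
  }
  pairwise <- c(
    gwas_transcriptome = length(intersect(sets$gwas, sets$transcriptome)),
    gwas_proteome = length(intersect(sets$gwas, sets$proteome)),
    transcriptome_proteome = length(intersect(sets$transcriptome,
                                              sets$proteome)))
  triple <- Reduce(intersect, sets)
  structure(list(per_set_genes = sets,
                 pairwise_counts = pairwise,
                 triple_genes = sort(triple),
                 union_size = length(unique(unlist(sets)))),
            class = "triple_overlap")
}

#' @export
print.triple_overlap <- function(x, ...) {
  cat("triple overlap: |gwas| = ", length(x$per_set_genes$gwas),
      ", |tx| = ", length(x$per_set_genes$transcriptome),
      ", |prot| = ", length(x$per_set_genes$proteome),
      "; triple = ", length(x$triple_genes), " genes\n", sep = "")
  invisible(x)
}

#' Select sign-concordant multi-omics candidate genes
#'
#' From the triple-overlap gene set, keeps genes whose transcript and
#' protein records are both significant at `alpha` and whose log2 ratios
#' agree in sign ("corresponding changes" at both layers). Genes missing a
#' record in either layer are excluded with a warning.
#'
#' @param triple a `triple_overlap` object or character vector of genes.
#' @param tx,prot data.frames with columns `gene`, `log2_ratio`, `pvalue`
#'   (e.g. from [read_omics_table()], one layer each).
#' @param alpha per-layer significance threshold (default 0.05).
#' @return data.frame with columns `gene`, `log2_transcript`,
#'   `log2_protein`, `direction` (`"up"` or `"down"`).
#' @export
select_concordant_candidates <- function(triple, tx, prot, alpha = 0.05) {
  genes <- if (inherits(triple, "triple_overlap")) triple$triple_genes
           else unique(triple)
  tx_i <- match(genes, tx$gene)
  prot_i <- match(genes, prot$gene)
  missing <- is.na(tx_i) | is.na(prot_i)
  if (any(missing)) {
    warning(sum(missing), " triple-overlap gene(s) lack a transcript or ",
            "protein record and were excluded: ",
            paste(head(genes[missing], 5), collapse = ", "),
            if (sum(missing) > 5) ", ...")
  }
  genes <- genes[!missing]; tx_i <- tx_i[!missing]; prot_i <- prot_i[!missing]
  lt <- tx$log2_ratio[tx_i]; lp <- prot$log2_ratio[prot_i]
  keep <- tx$pvalue[tx_i] < alpha & prot$pvalue[prot_i] < alpha &
    sign(lt) == sign(lp) & sign(lt) != 0
  data.frame(gene = genes[keep],
             log2_transcript = lt[keep],
             log2_protein = lp[keep],
             direction = ifelse(lt[keep] > 0, "up", "down"),
             row.names = NULL)
}
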