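#' Collapse probe-level expression to gene level
#'
#' Genes represented by multiple probes are summarized as the arithmetic
#' mean of their probes' values, per sample. Probes without a gene mapping
#' (absent from `probe_to_gene`, or mapped to `NA`/`""`) are dropped and
#' their count reported via `message()`.
#'
#' @param values numeric probe-by-sample matrix with probe ids as rownames.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol.
#' @return a gene-by-sample numeric matrix (genes in the order of first
#'   appearance of their probes).
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (!is.matrix(values) || nrow(values) == 0 || ncol(values) == 0)
    stop_input("'values' must be a non-empty probe x sample matrix")
  if (is.null(rownames(values))) stop_input("'values' must carry probe ids as rownames")
  genes <- probe_to_gene[rownames(values)]
  mapped <- !is.na(genes) & genes != ""
  n_drop <- sum(!mapped)
  if (n_drop > 0) message("collapse_probes: dropping ", n_drop, " unmapped probe(s)")
  if (!any(mapped)) stop_input("no probe maps to a gene")
  v <- values[mapped, , drop = FALSE]
  g <- factor(genes[mapped], levels = unique(genes[mapped]))
  sums <- rowsum(v, g, reorder = FALSE)
  sums / as.vector(table(g)[levels(g)])
}

#' Adjust a gene-expression matrix for platform location/scale bias
#'
#' Per gene, each platform's values are recentered to the pooled (all-sample)
#' mean and rescaled to the pooled SD - a simplified location-scale
#' standardization that removes additive and multiplicative platform bias.
#' It is deliberately lighter than empirical-Bayes batch correction (no
#' shrinkage across genes, no covariates); the per-gene transform is affine
#' and increasing, so within-platform rank order is preserved. An
#' empirical-Bayes method can be slotted in behind the same signature.
#'
#' Platforms contributing fewer than 2 samples (or a gene with zero
#' within-platform variance) are centered only, with a warning for the
#' former.
#'
#' @param gene_matrix numeric gene-by-sample matrix.
#' @param platform character or factor of length `ncol(gene_matrix)`.
#' @return adjusted matrix of identical dimensions and dimnames.
#' @export
adjust_platforms <- function(gene_matrix, platform) {
  if (!is.matrix(gene_matrix)) stop_input("'gene_matrix' must be a matrix")
  if (length(platform) != ncol(gene_matrix))
    stop_input("'platform' must have one label per sample column")
  platform <- as.factor(droplevels(as.factor(platform)))
  if (nlevels(platform) < 2) return(gene_matrix)
  pooled_mean <- rowMeans(gene_matrix)
  pooled_sd <- apply(gene_matrix, 1, stats::sd)
  out <- gene_matrix
  for (pl in levels(platform)) {
    idx <- platform == pl
    sub <- gene_matrix[, idx, drop = FALSE]
    m <- rowMeans(sub)
    if (sum(idx) < 2) {
      warning("platform '", pl, "' has < 2 samples; centering only")
      out[, idx] <- sub - m + pooled_mean
    } else {
      s <- apply(sub, 1, stats::sd)
      scale_fac <- ifelse(s > 0 & pooled_sd > 0, pooled_sd / s, 1)
      out[, idx] <- (sub - m) * scale_fac + pooled_mean
    }
  }
  out
}

#' Read / write gene-expression matrices as delimited text
#'
#' Genes in rows, samples in columns, first column holding gene ids.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_expression_matrix()` returns a numeric matrix.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_expression_matrix
#' @param m numeric matrix to write.
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
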