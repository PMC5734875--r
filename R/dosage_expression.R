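#' Select the expressed gene set
#'
#' A gene counts as expressed when its median signal across the reference
#' lines clears the platform cutoff: log2 intensity >= 5 (signal >= 32) for
#' arrays, RPKM >= 1 by default for RNA-seq. Selecting the set on normal
#' reference lines and reusing it unchanged for cancer lines guards against
#' inflation of the X:autosome ratio by X-enriched genes that are silent in
#' normal tissue but awaken in tumours.
#'
#' @param expr Gene-by-line matrix: log2 intensities (`platform = "array"`)
#'   or linear RPKM (`platform = "rnaseq"`).
#' @param genes Annotation `data.frame` with `gene_id` and `chrom` matching
#'   `rownames(expr)`.
#' @param platform `"array"` or `"rnaseq"`.
#' @param cutoff Expression cutoff on the platform's scale; defaults to 5
#'   (log2) for arrays and 1 (RPKM) for RNA-seq.
#' @param reference_lines Columns over which the per-gene median is taken
#'   (default: all lines). Pass the normal lines here to reuse their set for
#'   cancer lines.
#' @param strict Use a strict `>` comparison instead of the inclusive `>=`
#'   (the RPKM > 0 filter needs this).
#' @return Character vector of expressed gene ids.
#' @export
expressed_gene_set <- function(expr, genes, platform = c("array", "rnaseq"),
                               cutoff = NULL, reference_lines = colnames(expr),
                               strict = FALSE) {
  platform <- match.arg(platform)
  cutoff <- cutoff %||% switch(platform, array = 5, rnaseq = 1)
  missing_ref <- setdiff(reference_lines, colnames(expr))
  if (length(missing_ref)) {
    stopf("reference lines absent from expression matrix: %s",
          paste(missing_ref, collapse = ", "))
  }
  med <- apply(expr[, reference_lines, drop = FALSE], 1L, stats::median)
  pass <- if (strict) med > cutoff else med >= cutoff
  set <- rownames(expr)[pass]
  if (!length(set)) stopf("no genes pass the expression cutoff %g", cutoff)
  set
}

#' X:autosome expression ratio for one line
#'
#' E_X/A is the ratio of the median expression of expressed X-linked genes
#' to that of expressed autosomal genes, on the linear scale (array log2
#' intensities are un-logged first: a ratio of medians of logs is not a
#' dosage ratio). Values below 1 indicate incomplete dosage compensation of
#' a single active X against diploid autosomes.
#'
#' @param line_expr Named numeric vector of one line's expression values
#'   (log2 for arrays, linear for RNA-seq).
#' @param genes Annotation with `gene_id`, `chrom`.
#' @param gene_set Expressed gene ids from [expressed_gene_set()].
#' @param platform `"array"` or `"rnaseq"`.
#' @param min_genes Minimum expressed genes required on the X and on the
#'   autosomes.
#' @param exclude Gene ids excluded from the X set (default XIST, which
#'   reports Xi presence, not dosage; add pseudoautosomal genes here if
#'   annotated).
#' @return E_X/A as a single positive number.
#' @export
compute_exa <- function(line_expr, genes, gene_set, platform = c("array", "rnaseq"),
                        min_genes = 5L, exclude = "XIST") {
  platform <- match.arg(platform)
  keep <- intersect(names(line_expr), setdiff(gene_set, exclude))
  chrom <- stats::setNames(genes$chrom, genes$gene_id)[keep]
  vals <- line_expr[keep]
  if (platform == "array") vals <- 2^vals
  on_x <- chrom == "X"
  on_a <- chrom %in% as.character(1:22)
  if (sum(on_x) < min_genes || sum(on_a) < min_genes) {
    stopf("compute_exa: fewer than %d expressed genes on X (%d) or autosomes (%d)",
          min_genes, sum(on_x), sum(on_a))
  }
  med_a <- stats::median(vals[on_a])
  if (med_a == 0) stopf("compute_exa: zero autosomal median expression")
  stats::median(vals[on_x]) / med_a
}

#' E_X/A for every line of a panel
#'
#' @param expr Gene-by-line matrix.
#' @param genes Annotation with `gene_id`, `chrom`.
#' @param platform,cutoff,reference_lines,strict Passed to
#'   [expressed_gene_set()].
#' @param group Optional named group per line (e.g. `"NF"`, `"NM"`, `"CF"`,
#'   `"CM"` for normal/cancer female/male).
#' @param ... Passed to [compute_exa()].
#' @return `data.frame` with `line`, `exa` and (if given) `group`; carries
#'   the gene set and cutoff as attributes.
#' @export
exa_panel <- function(expr, genes, platform = c("array", "rnaseq"),
                      cutoff = NULL, reference_lines = colnames(expr),
                      strict = FALSE, group = NULL, ...) {
  platform <- match.arg(platform)
  set <- expressed_gene_set(expr, genes, platform, cutoff, reference_lines, strict)
  exa <- vapply(colnames(expr), function(l) {
    compute_exa(expr[, l], genes, set, platform, ...)
  }, numeric(1))
  out <- data.frame(line = colnames(expr), exa = unname(exa),
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group[out$line]
  attr(out, "gene_set") <- set
  attr(out, "cutoff") <- cutoff %||% switch(platform, array = 5, rnaseq = 1)
  out
}

#' X-linked differential expression between one-Xa and two-Xa male lines
#'
#' Per-gene two-sided two-sample t-tests across all X-linked genes between
#' Xa\[Y\] and XaXa\[Y\] lines, with Benjamini-Hochberg adjustment across
#' the tested genes. Both the raw-p significance flag (as used for
#' per-gene dot annotation at p < 0.05) and the BH-adjusted flag are
#' reported.
#'
#' @param expr Gene-by-line log2 matrix.
#' @param genes Annotation with `gene_id`, `chrom`.
#' @param group1,group2 Line ids of the two groups (>= 3 lines each).
#' @param alpha Significance level for the flags.
#' @return `data.frame` per X-linked gene: `gene`, `t`, `p`, `p_adj`,
#'   `significant` (raw p), `significant_adj`, `zero_variance`.
#' @export
x_dosage_de <- function(expr, genes, group1, group2, alpha = 0.05) {
  if (length(group1) < 3L || length(group2) < 3L) {
    stopf("x_dosage_de: need at least 3 lines per group (got %d and %d)",
          length(group1), length(group2))
  }
  x_genes <- genes$gene_id[genes$chrom == "X"]
  x_genes <- intersect(x_genes, rownames(expr))
  res <- lapply(x_genes, function(g) {
    a <- expr[g, group1]
    b <- expr[g, group2]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(gene = g, t = NA_real_, p = NA_real_,
                        zero_variance = TRUE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b)
    data.frame(gene = g, t = unname(tt$statistic), p = tt$p.value,
               zero_variance = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out$significant_adj <- !is.na(out$p_adj) & out$p_adj < alpha
  out[c("gene", "t", "p", "p_adj", "significant", "significant_adj", "zero_variance")]
}
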