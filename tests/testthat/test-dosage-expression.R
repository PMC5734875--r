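make_expr <- function(values, chrom) {
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(chrom)), chrom = chrom,
                      stringsAsFactors = FALSE)
  mat <- matrix(values, nrow = length(chrom),
                dimnames = list(genes$gene_id, sprintf("L%02d", seq_len(length(values) / length(chrom)))))
  list(mat = mat, genes = genes)
}

test_that("expressed gene set uses inclusive cutoffs and is monotone in the cutoff", {
  e <- make_expr(c(5.0, 4.99, 7, 2, 6, 5.5), rep(c("1", "X"), 3))
  set5 <- expressed_gene_set(e$mat, e$genes, "array", cutoff = 5)
  expect_true("g01" %in% set5)    # exactly at the boundary: included
  expect_false("g02" %in% set5)
  # raising the cutoff never adds genes
  for (cut in c(5.5, 6, 6.5)) {
    expect_true(all(expressed_gene_set(e$mat, e$genes, "array", cutoff = cut) %in% set5))
  }
  # strict comparison excludes the boundary (the RPKM > 0 style filter)
  expect_false("g01" %in% expressed_gene_set(e$mat, e$genes, "array", cutoff = 5,
                                             strict = TRUE))
  expect_error(expressed_gene_set(e$mat, e$genes, "array", cutoff = 99), "no genes")
})

test_that("the gene set selected on reference lines is reused unchanged", {
  # gene g2 expressed only in the "cancer" line; selecting on the normal line
  # excludes it everywhere
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("1", "X"))
  mat <- cbind(normal = c(8, 2), cancer = c(8, 9))
  rownames(mat) <- genes$gene_id
  set <- expressed_gene_set(mat, genes, "array", reference_lines = "normal")
  expect_identical(set, "g1")
})

test_that("E_X/A is a linear-scale ratio of medians with the expected symmetries", {
  # identical X and autosomal distributions give exactly 1
  vals <- rep(c(6, 7, 8, 9, 10), 2)
  e <- make_expr(c(vals[1:5], vals[1:5]), rep(c("1", "X"), each = 5))
  le <- e$mat[, 1]
  expect_equal(compute_exa(le, e$genes, rownames(e$mat), "array"), 1.0)
  # scaling all autosomal values by k divides E_X/A by k (log2 shift)
  le2 <- le
  le2[e$genes$chrom == "1"] <- le2[e$genes$chrom == "1"] + log2(4)
  expect_equal(compute_exa(le2, e$genes, rownames(e$mat), "array"), 1 / 4)
  # zero autosomal median on the linear scale is impossible for arrays, but
  # rnaseq input can hit it
  ln <- c(rep(0, 5), rep(3, 5))
  names(ln) <- e$genes$gene_id
  expect_error(compute_exa(ln, e$genes, e$genes$gene_id, "rnaseq"),
               "zero autosomal median")
  # too few genes on one side
  expect_error(compute_exa(le, e$genes, rownames(e$mat)[1:6], "array"),
               "fewer than")
})

test_that("dosage-linear panels separate planted karyotype groups by 4/3", {
  p <- generate_panel(panel_config(
    n_lines = 120, n_female = 0, n_male = 120, probes_per_chromosome = 40,
    genotype_freqs = c("C(1:2)" = 0.5, "C(2:3)" = 0.5),
    genes_per_chromosome = 40, expr_sd = 0.3, noise_probe_fraction = 0,
    seed = 41
  ))
  ex <- exa_panel(p$expression, p$genes, platform = "array")
  lab <- p$truth$lines$label[match(ex$line, p$truth$lines$line)]
  ratio <- mean(ex$exa[lab == "C(2:3)"]) / mean(ex$exa[lab == "C(1:2)"])
  expect_equal(ratio, 4 / 3, tolerance = 0.03)
})

test_that("a panel of normal C(1:2) lines centres near the compensated ratio", {
  p <- generate_panel(panel_config(
    n_lines = 60, n_female = 0, n_male = 60, probes_per_chromosome = 40,
    genotype_freqs = c("C(1:2)" = 1), genes_per_chromosome = 40,
    expr_sd = 0.3, noise_probe_fraction = 0, seed = 43
  ))
  ex <- exa_panel(p$expression, p$genes, platform = "array")
  expect_equal(median(ex$exa), 0.84, tolerance = 0.03)
})

test_that("X dosage contrast finds planted 2x dosage and adjusts honestly", {
  p <- generate_panel(panel_config(
    n_lines = 100, n_female = 0, n_male = 100, probes_per_chromosome = 60,
    genotype_freqs = c("C(1:2)" = 0.5, "C(2:2)" = 0.5),
    genes_per_chromosome = 30, expr_sd = 1, noise_probe_fraction = 0,
    seed = 45
  ))
  st <- call_states(p)
  k <- karyotype_panel(st, p$expression, p$truth$lines[c("line", "sex")])
  g1 <- k$line[k$sex_genotype == "Xa[Y]"]
  g2 <- k$line[k$sex_genotype == "XaXa[Y]"]
  expect_gte(length(g1), 3)
  expect_gte(length(g2), 3)
  de <- x_dosage_de(p$expression, p$genes, g1, g2)
  # strong power at ~50/50 lines and a twofold shift
  expect_gt(mean(de$significant[de$gene != "XIST"]), 0.9)
  # BH adjustment matches the brute-force step-up formula on our own p-values
  ok <- !is.na(de$p)
  p_sorted <- sort(de$p[ok])
  m <- length(p_sorted)
  bh <- rev(cummin(rev(p_sorted * m / seq_len(m))))
  expect_equal(sort(de$p_adj[ok]), pmin(bh, 1))
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})

test_that("zero-variance genes are flagged, not tested", {
  genes <- data.frame(gene_id = c("gA", "gX1", "gX2"), chrom = c("1", "X", "X"))
  set.seed(47)
  mat <- rbind(gA = rnorm(8, 8), gX1 = rep(5, 8), gX2 = rnorm(8, 8))
  colnames(mat) <- sprintf("L%d", 1:8)
  de <- x_dosage_de(mat, genes, colnames(mat)[1:4], colnames(mat)[5:8])
  expect_true(de$zero_variance[de$gene == "gX1"])
  expect_true(is.na(de$p[de$gene == "gX1"]))
  expect_false(de$zero_variance[de$gene == "gX2"])
})
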