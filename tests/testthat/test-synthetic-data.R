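test_that("panel_config validates its fields", {
  expect_error(panel_config(n_lines = 10, n_female = 4, n_male = 4),
               "n_female")
  expect_error(panel_config(loh_base_rate = 1.3), "probability")
  expect_error(panel_config(genotype_freqs = c("C(1:2)" = 0.7, "C(2:3)" = 0.2)),
               "sum to 1")
  expect_error(panel_config(genotype_freqs = c(bogus = 1)), "malformed")
})

test_that("a degenerate single-genotype noise-free panel is fully determined", {
  p <- generate_panel(panel_config(
    n_lines = 10, n_female = 5, n_male = 5, probes_per_chromosome = 60,
    genotype_freqs = c("C(1:2)" = 1), loh_base_rate = 0,
    loh_size_slope = 0, x_loh_rate = 1,
    noise_probe_fraction = 0, seed = 2
  ))
  st <- call_states(p, min_probes = 50)
  auto <- st[st$chrom %in% as.character(1:22), ]
  expect_false(any(auto$loh))
  expect_true(all(auto$copy_number == 2L))
  k <- karyotype_panel(st, p$expression, p$truth$lines[c("line", "sex")])
  expect_true(all(k$xa_count == 1L))
  expect_true(all(k$n_A == 2L))
  expect_true(all(k$label == "C(1:2)"))
})

test_that("planted genotype frequencies match the configured distribution", {
  cfg <- panel_config(probes_per_chromosome = 40, genes_per_chromosome = 4,
                      seed = 1)
  p <- generate_panel(cfg)
  f <- cfg$genotype_freqs[["C(1:2)"]]
  obs <- mean(p$truth$lines$label == "C(1:2)")
  sd3 <- 3 * sqrt(f * (1 - f) / cfg$n_lines)
  expect_lt(abs(obs - f), sd3)
  # all drawn labels come from the configured support
  expect_true(all(p$truth$lines$label %in% names(cfg$genotype_freqs)))
})

test_that("planted autosomal LOH rate matches the base rate", {
  cfg <- panel_config(probes_per_chromosome = 40, genes_per_chromosome = 4,
                      loh_base_rate = 0.13, loh_size_slope = 0, seed = 3)
  p <- generate_panel(cfg)
  st <- p$truth$states
  loh <- st$loh[st$chrom %in% as.character(1:22)]
  sd3 <- 3 * sqrt(0.13 * 0.87 / length(loh))
  expect_lt(abs(mean(loh) - 0.13), sd3)
})

test_that("XIST truth is silent exactly when all planted X's are active", {
  p <- clean_panel(seed = 19)
  tl <- p$truth$lines
  has_xi <- tl$sex == "female" & !tl$x_loh
  expect_identical(tl$xist == "expressed", has_xi)
  # expression matrix respects the truth with a wide margin around log2 = 5
  xist <- p$expression["XIST", tl$line]
  expect_true(all(xist[has_xi] > 5))
  expect_true(all(xist[!has_xi] < 5))
})

test_that("cohesive sublines spread gains one chromosome at a time", {
  s <- generate_sublines(subline_config(n_sublines = 5, mode = "cohesive",
                                        total_gains = 10, seed = 4))
  for (i in seq_len(nrow(s))) {
    g <- gain_histogram(unlist(s[i, -1]))
    expect_identical(unname(g$hist), c(3L, 10L, 0L))
    expect_equal(g$lambda_hat, 10 / 13)
    expect_lt(max(g$delta), 2)
  }
  # pairwise constraint holds for random totals too
  s2 <- generate_sublines(subline_config(n_sublines = 30, mode = "cohesive",
                                         lambda = 16 / 13, seed = 5))
  deltas <- vapply(seq_len(nrow(s2)), function(i) {
    max(gain_histogram(unlist(s2[i, -1]))$delta)
  }, numeric(1))
  expect_true(all(deltas <= 1))
})

test_that("independent sublines follow the Poisson null", {
  s0 <- generate_sublines(subline_config(n_sublines = 8, mode = "independent",
                                         lambda = 0, seed = 6))
  expect_true(all(s0[paste0("chr", largest_autosomes())] == 2L))

  lam <- 0.77
  s <- generate_sublines(subline_config(n_sublines = 10000, mode = "independent",
                                        lambda = lam, seed = 7))
  gains <- as.matrix(s[paste0("chr", largest_autosomes())]) - 2L
  p0 <- exp(-lam)
  obs <- mean(gains == 0)
  sd3 <- 3 * sqrt(p0 * (1 - p0) / length(gains))
  expect_lt(abs(obs - p0), sd3)
})

test_that("panel I/O round-trips losslessly", {
  p <- clean_panel(n_lines = 6, n_female = 3, n_male = 3, probes = 60, seed = 8)
  d <- withr::local_tempdir()
  write_panel(p, d)
  p2 <- read_panel(d)
  expect_identical(p2$probes, p$probes)
  expect_identical(p2$truth$lines, p$truth$lines)
  expect_equal(p2$truth$states, p$truth$states, ignore_attr = TRUE)
  expect_equal(p2$expression, p$expression, tolerance = 1e-12)
  expect_equal(unclass(p2$config), unclass(p$config), tolerance = 1e-9)
})

test_that("an empty panel writes header-only tables and reads back", {
  p <- generate_panel(panel_config(n_lines = 0, n_female = 0, n_male = 0))
  d <- withr::local_tempdir()
  write_panel(p, d)
  expect_length(readLines(file.path(d, "truth.tsv")), 1L)
  p2 <- read_panel(d)
  expect_length(p2$probes, 0L)
  expect_identical(nrow(p2$truth$lines), 0L)
})

test_that("truncated probe files raise a parse error naming the line", {
  p <- clean_panel(n_lines = 2, n_female = 1, n_male = 1, probes = 60, seed = 9)
  d <- withr::local_tempdir()
  write_panel(p, d)
  f <- file.path(d, sprintf("probes_%s.tsv", p$truth$lines$line[1]))
  lines <- readLines(f)
  lines[7] <- "truncated\trow"
  writeLines(lines, f)
  expect_error(read_panel(d), "line 7")
})

test_that("generation is deterministic given the seed", {
  a <- clean_panel(n_lines = 6, n_female = 3, n_male = 3, probes = 40, seed = 10)
  b <- clean_panel(n_lines = 6, n_female = 3, n_male = 3, probes = 40, seed = 10)
  expect_identical(a$probes, b$probes)
  expect_identical(a$expression, b$expression)
  c <- clean_panel(n_lines = 6, n_female = 3, n_male = 3, probes = 40, seed = 12)
  expect_false(identical(a$expression, c$expression))
})
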