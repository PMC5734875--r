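#' Default karyotype genotype frequencies for the panel generator
#'
#' Per-genotype frequencies whose cluster tally (see [tally_clusters()])
#' reproduces the observed cluster frequencies
#' \[x1, x2, x3, x4\] = \[0.374, 0.087, 0.292, 0.128\] of a large cancer
#' cell-line panel, with the remaining 0.119 spread over marginal genotypes
#' (C(3:4), C(1:4), C(4:4)) that fall outside the four clusters. The split
#' of each cluster into its constituent genotypes is a modelling choice
#' (only cluster sums are observable); see the package vignette.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_genotype_freqs <- function() {
  c(
    "C(1:2)" = 0.355, "C(1:1)" = 0.009, "C(1:3)" = 0.020,
    "C(2:2)" = 0.067, "C(3:2)" = 0.020,
    "C(2:3)" = 0.252, "C(3:3)" = 0.030,
    "C(2:4)" = 0.128,
    "C(3:4)" = 0.050, "C(1:4)" = 0.040, "C(4:4)" = 0.029
  )
}

#' Configuration for a synthetic cell-line panel
#'
#' Describes a panel of cell lines genotyped on a SNP array: per-probe
#' genotypes and allele-specific copy numbers per chromosome (emulating
#' allele-specific copy-number caller output), plus a log2 expression matrix
#' with chromosome annotation including XIST. Defaults emulate the study
#' conditions of a 620-line panel (279 female, 341 male) with a median
#' autosomal LOH rate of about 13%, whole-X LOH in 37% of female lines and
#' Y loss in 40% of male lines.
#'
#' @param n_lines Total number of cell lines.
#' @param n_female,n_male Lines derived from female/male tissue; must sum to
#'   `n_lines`.
#' @param probes_per_chromosome SNP probes simulated per chromosome.
#' @param genotype_freqs Named probabilities over C(Xa:A) labels from which
#'   each line's true karyotype is drawn; must sum to 1.
#' @param loh_base_rate Probability that a given autosome of a line has lost
#'   one homolog (LOH), at the mean autosome length.
#' @param loh_size_slope Change in LOH probability per megabase of chromosome
#'   length (negative: smaller chromosomes lose more).
#' @param x_loh_rate Probability that a female line has whole-X LOH (such
#'   lines have only active X's and silent XIST).
#' @param y_loss_rate Probability that a male line has lost the Y.
#' @param noise_probe_fraction Probability that a probe contradicts the
#'   chromosome-level truth (genotype flipped and copy number jittered).
#' @param het_rate Per-probe heterozygosity probability on non-LOH
#'   chromosomes.
#' @param genes_per_chromosome Expression-array genes per chromosome (an
#'   extra XIST gene is always added on the X).
#' @param expr_sd Standard deviation of per-gene log2 intensities.
#' @param x_expression_offset Additive log2 offset applied to X-linked genes;
#'   the default `log2(0.84)` reproduces the X:autosome expression ratio
#'   (about 0.84) of karyotypically normal C(1:2) lines, as expected under
#'   incomplete X upregulation.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `panel_config` (a named list).
#' @seealso [generate_panel()]
#' @export
panel_config <- function(n_lines = 620L,
                         n_female = 279L,
                         n_male = 341L,
                         probes_per_chromosome = 500L,
                         genotype_freqs = default_genotype_freqs(),
                         loh_base_rate = 0.13,
                         loh_size_slope = -3e-4,
                         x_loh_rate = 0.37,
                         y_loss_rate = 0.40,
                         noise_probe_fraction = 0.01,
                         het_rate = 0.30,
                         genes_per_chromosome = 30L,
                         expr_sd = 1,
                         x_expression_offset = log2(0.84),
                         seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_female = as.integer(n_female),
    n_male = as.integer(n_male),
    probes_per_chromosome = as.integer(probes_per_chromosome),
    genotype_freqs = genotype_freqs,
    loh_base_rate = loh_base_rate, loh_size_slope = loh_size_slope,
    x_loh_rate = x_loh_rate, y_loss_rate = y_loss_rate,
    noise_probe_fraction = noise_probe_fraction, het_rate = het_rate,
    genes_per_chromosome = as.integer(genes_per_chromosome),
    expr_sd = expr_sd, x_expression_offset = x_expression_offset,
    seed = as.integer(seed)
  )
  validate_panel_config(cfg)
  structure(cfg, class = "panel_config")
}

validate_panel_config <- function(cfg) {
  for (p in c("loh_base_rate", "x_loh_rate", "y_loss_rate",
              "noise_probe_fraction", "het_rate")) {
    if (!is_prob(cfg[[p]])) stopf("panel_config: '%s' must be a probability in [0,1]", p)
  }
  if (!is_count(cfg$n_lines) || !is_count(cfg$n_female) || !is_count(cfg$n_male)) {
    stopf("panel_config: line counts must be non-negative integers")
  }
  if (cfg$n_female + cfg$n_male != cfg$n_lines) {
    stopf("panel_config: n_female (%d) + n_male (%d) != n_lines (%d)",
          cfg$n_female, cfg$n_male, cfg$n_lines)
  }
  gf <- cfg$genotype_freqs
  if (is.null(names(gf)) || any(!nzchar(names(gf)))) {
    stopf("panel_config: genotype_freqs must be a named vector of C(Xa:A) labels")
  }
  if (any(gf < 0 | gf > 1)) stopf("panel_config: genotype_freqs entries must lie in [0,1]")
  if (abs(sum(gf) - 1) > 1e-9) {
    stopf("panel_config: genotype_freqs must sum to 1 (got %.12f)", sum(gf))
  }
  parse_cxa_label(names(gf))  # errors on malformed labels
  invisible(cfg)
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %d lines (%dF/%dM), %d probes/chrom, seed %d\n",
              x$n_lines, x$n_female, x$n_male, x$probes_per_chromosome, x$seed))
  invisible(x)
}

# per-autosome LOH probability as a linear function of chromosome length
autosome_loh_rates <- function(cfg, chrom_tab) {
  auto <- chrom_tab[chrom_tab$is_autosome, ]
  rate <- cfg$loh_base_rate +
    cfg$loh_size_slope * (auto$length_mb - mean(auto$length_mb))
  stats::setNames(clamp(rate, 0, 1), auto$chrom)
}

#' Generate a synthetic cell-line panel with planted truth
#'
#' Draws a true C(Xa:A) karyotype for every line, plants chromosome-level
#' LOH and copy-number states, then synthesizes probe-level genotype tables
#' and a log2 expression matrix consistent with those states. Draw order
#' (fixed so results are reproducible across versions): line sexes, karyotype
#' labels, autosomal LOH flags, female X-LOH flags, male Y-loss flags, then
#' per line the probe genotypes, probe noise, and finally the expression
#' matrix and XIST row.
#'
#' Planted semantics: every autosome of a line carries `n_A` copies; LOH
#' autosomes are fully homozygous. Female lines with whole-X LOH carry
#' `xa_count` identical active X's (isodisomy when 2); females without X LOH
#' additionally carry one inactive X (heterozygous, XIST expressed) and are
#' not usable for active-X counting. Male X's are hemizygous-homozygous with
#' `xa_count` copies; XIST is always silent in males. X-linked expression
#' scales linearly with the active-X count, autosomal expression with
#' copy/2.
#'
#' @param cfg A [panel_config()].
#' @return An object of class `synthetic_panel`: a list with elements
#'   `probes` (named list of per-line probe `data.frame`s with columns
#'   `probe_id`, `chrom`, `pos`, `genotype` in \{AA, AB, BB, NC\},
#'   `total_cn`, `minor_cn`), `expression` (gene-by-line numeric matrix of
#'   log2 intensities), `genes` (annotation: `gene_id`, `chrom`), `truth`
#'   (list of `lines` and `states` data frames with the planted ground
#'   truth) and `config`.
#' @export
#' @examples
#' p <- generate_panel(panel_config(n_lines = 6, n_female = 3, n_male = 3,
#'                                  probes_per_chromosome = 60, seed = 7))
#' names(p)
generate_panel <- function(cfg) {
  if (!inherits(cfg, "panel_config")) cfg <- do.call(panel_config, cfg)
  validate_panel_config(cfg)
  set.seed(cfg$seed)
  chrom_tab <- chromosome_table()
  n <- cfg$n_lines
  line_id <- sprintf("L%04d", seq_len(n))

  sex <- sample(rep(c("female", "male"), c(cfg$n_female, cfg$n_male)))
  labels <- if (n > 0) {
    sample(names(cfg$genotype_freqs), n, replace = TRUE, prob = cfg$genotype_freqs)
  } else character(0)
  karyo <- parse_cxa_label(labels)
  xa <- karyo$xa_count
  n_A <- karyo$n_A

  loh_rates <- autosome_loh_rates(cfg, chrom_tab)
  autosomes <- names(loh_rates)
  # autosomal LOH flags: matrix line x autosome
  loh_auto <- matrix(
    stats::runif(n * length(autosomes)) < rep(loh_rates, each = n),
    nrow = n, ncol = length(autosomes), dimnames = list(line_id, autosomes)
  )
  x_loh <- ifelse(sex == "female", stats::runif(n) < cfg$x_loh_rate, TRUE)
  y_lost <- ifelse(sex == "male", stats::runif(n) < cfg$y_loss_rate, NA)

  # planted per-chromosome states (long format)
  empty_states <- data.frame(line = character(0), chrom = character(0),
                             loh = logical(0), copy = integer(0),
                             stringsAsFactors = FALSE)
  states <- do.call(rbind, c(list(empty_states), lapply(seq_len(n), function(i) {
    chrom <- chrom_tab$chrom
    loh <- logical(length(chrom))
    copy <- integer(length(chrom))
    ia <- chrom %in% autosomes
    loh[ia] <- loh_auto[i, chrom[ia]]
    copy[ia] <- n_A[i]
    xi <- chrom == "X"
    if (sex[i] == "male") {
      loh[xi] <- TRUE          # hemizygous or isodisomic: no heterozygosity
      copy[xi] <- xa[i]
    } else if (x_loh[i]) {
      loh[xi] <- TRUE
      copy[xi] <- xa[i]
    } else {
      loh[xi] <- FALSE         # active X(s) plus one inactive X
      copy[xi] <- xa[i] + 1L
    }
    yi <- chrom == "Y"
    loh[yi] <- NA
    copy[yi] <- if (sex[i] == "male" && !y_lost[i]) 1L else 0L
    data.frame(line = line_id[i], chrom = chrom, loh = loh, copy = copy,
               stringsAsFactors = FALSE)
  })))

  truth_lines <- data.frame(
    line = line_id, sex = sex, label = labels,
    xa_count = xa, n_A = n_A, x_loh = x_loh, y_lost = y_lost,
    xist = ifelse(sex == "female" & !x_loh, "expressed", "silent"),
    stringsAsFactors = FALSE
  )

  probes <- stats::setNames(lapply(seq_len(n), function(i) {
    st <- states[states$line == line_id[i], ]
    simulate_line_probes(cfg, chrom_tab, st)
  }), line_id)

  expr <- simulate_expression(cfg, chrom_tab, truth_lines, states)

  structure(
    list(probes = probes, expression = expr$mat, genes = expr$genes,
         truth = list(lines = truth_lines, states = states), config = cfg),
    class = "synthetic_panel"
  )
}

# probe table for one line given its planted chromosome states
simulate_line_probes <- function(cfg, chrom_tab, states_line) {
  npp <- cfg$probes_per_chromosome
  rows <- lapply(seq_len(nrow(states_line)), function(k) {
    chrom <- states_line$chrom[k]
    copy <- states_line$copy[k]
    hom <- isTRUE(states_line$loh[k])
    len <- chrom_tab$length_mb[chrom_tab$chrom == chrom] * 1e6
    pos <- as.integer(round(seq(1, len, length.out = npp)))
    if (chrom == "Y") {
      geno <- rep("NC", npp)   # no diploid genotype on the Y
    } else if (hom) {
      geno <- sample(c("AA", "BB"), npp, replace = TRUE)
    } else {
      geno <- ifelse(stats::runif(npp) < cfg$het_rate, "AB",
                     sample(c("AA", "BB"), npp, replace = TRUE))
    }
    minor <- if (hom || chrom == "Y") 0L else as.integer(copy %/% 2L)
    data.frame(
      probe_id = sprintf("p_%s_%04d", chrom, seq_len(npp)),
      chrom = chrom, pos = pos, genotype = geno,
      total_cn = copy, minor_cn = minor,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (cfg$noise_probe_fraction > 0) {
    idx <- which(stats::runif(nrow(tab)) < cfg$noise_probe_fraction)
    if (length(idx)) {
      g <- tab$genotype[idx]
      tab$genotype[idx] <- ifelse(g == "AB", "AA", ifelse(g == "NC", "NC", "AB"))
      tab$total_cn[idx] <- pmax(0L, tab$total_cn[idx] +
                                  sample(c(-1L, 1L), length(idx), replace = TRUE))
    }
  }
  rownames(tab) <- NULL
  tab
}

# gene-by-line log2 expression matrix with chromosome annotation and XIST
simulate_expression <- function(cfg, chrom_tab, truth_lines, states) {
  gpc <- cfg$genes_per_chromosome
  expr_chroms <- chrom_tab$chrom[chrom_tab$chrom != "Y"]
  genes <- data.frame(
    gene_id = unlist(lapply(expr_chroms, function(ch) sprintf("G%s_%03d", ch, seq_len(gpc)))),
    chrom = rep(expr_chroms, each = gpc),
    stringsAsFactors = FALSE
  )
  genes <- rbind(genes, data.frame(gene_id = "XIST", chrom = "X"))
  n <- nrow(truth_lines)
  mat <- matrix(stats::rnorm(nrow(genes) * n, mean = 8, sd = cfg$expr_sd),
                nrow = nrow(genes),
                dimnames = list(genes$gene_id, truth_lines$line))
  if (n > 0) {
    # per-line copy of each autosome (lines in truth order)
    copy_wide <- vapply(truth_lines$line, function(l) {
      st <- states[states$line == l, ]
      stats::setNames(st$copy, st$chrom)[expr_chroms]
    }, numeric(length(expr_chroms)))
    for (j in seq_len(n)) {
      on_x <- genes$chrom == "X"
      dose_a <- log2(copy_wide[match(genes$chrom, expr_chroms), j] / 2)
      mat[!on_x, j] <- mat[!on_x, j] + dose_a[!on_x]
      mat[on_x, j] <- mat[on_x, j] + cfg$x_expression_offset +
        log2(truth_lines$xa_count[j])
    }
    mat["XIST", ] <- ifelse(truth_lines$xist == "expressed", 9, 2) +
      stats::rnorm(n, sd = 0.3)
  }
  list(mat = mat, genes = genes)
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d lines, %d probes/line, %d genes\n",
              length(x$probes),
              if (length(x$probes)) nrow(x$probes[[1]]) else 0L,
              nrow(x$expression)))
  invisible(x)
}
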