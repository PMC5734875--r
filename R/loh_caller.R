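#' Call loss of heterozygosity for one chromosome
#'
#' A chromosome is scored as having undergone LOH when at least 95% of its
#' genotyped SNP probes are homozygous. No-call (`NC`) probes carry no
#' zygosity information and are excluded from both numerator and
#' denominator. LOH is irreversible: the lost heterozygosity cannot be
#' regained even if copy number is later restored.
#'
#' @param genotypes Character vector of probe genotypes (`AA`, `AB`, `BB`,
#'   `NC`).
#' @param loh_threshold Homozygous fraction at or above which LOH is called
#'   (inclusive boundary).
#' @param min_probes Minimum number of genotyped probes for the call to be
#'   assessable; below it `NA` (not assessable, distinct from `FALSE`) is
#'   returned.
#' @return `TRUE`, `FALSE` or `NA`, with attribute `fraction_hom`.
#' @export
#' @examples
#' call_loh(c(rep("AA", 96), rep("AB", 4)))   # TRUE
#' call_loh(c(rep("AA", 94), rep("AB", 6)))   # FALSE
call_loh <- function(genotypes, loh_threshold = 0.95, min_probes = 50L) {
  g <- genotypes[genotypes %in% c("AA", "AB", "BB")]
  n <- length(g)
  if (n < min_probes) {
    return(structure(NA, fraction_hom = if (n) mean(g != "AB") else NA_real_))
  }
  frac <- mean(g != "AB")
  structure(frac >= loh_threshold, fraction_hom = frac)
}

#' Call the integer copy number of one chromosome
#'
#' The chromosome is assigned copy number k (k in 0..4) when at least 95% of
#' its probes report the same total copy number k; otherwise the copy number
#' is undetermined (`NA`).
#'
#' @param total_cn Integer vector of per-probe total copy numbers.
#' @param cn_threshold Modal fraction at or above which the copy number is
#'   assigned (inclusive).
#' @param min_probes Minimum probes for assessability.
#' @return Integer copy number or `NA`, with attribute `modal_cn_fraction`.
#' @export
#' @examples
#' call_copy_number(rep(3L, 97))          # 3
#' call_copy_number(rep(c(2L, 3L), 50))   # NA: maximally mixed
call_copy_number <- function(total_cn, cn_threshold = 0.95, min_probes = 50L) {
  cn <- total_cn[!is.na(total_cn)]
  n <- length(cn)
  if (n < min_probes) return(structure(NA_integer_, modal_cn_fraction = NA_real_))
  tab <- table(cn)
  modal <- as.integer(names(tab)[which.max(tab)])
  frac <- max(tab) / n
  out <- if (frac >= cn_threshold && modal %in% 0:4) modal else NA_integer_
  structure(out, modal_cn_fraction = frac)
}

#' Call Y-chromosome loss
#'
#' The Y is scored as lost when strictly more than 60% of its probes report
#' zero copies. The lenient threshold reflects that a sizeable minority of
#' Y-array probes cross-hybridize with X-homologous sequence and report
#' non-zero copies even when the Y is absent.
#'
#' @param total_cn Integer vector of per-probe total copy numbers on the Y.
#' @param zero_fraction_threshold Fraction of zero-copy probes that must be
#'   exceeded (strict inequality).
#' @param min_probes Minimum probes for assessability.
#' @return `TRUE`, `FALSE` or `NA`, with attribute `zero_fraction`.
#' @export
#' @examples
#' call_y_loss(rep(c(0L, 1L), c(61, 39)))  # TRUE
#' call_y_loss(rep(c(0L, 1L), c(60, 40)))  # FALSE: exactly 60% is not "more"
call_y_loss <- function(total_cn, zero_fraction_threshold = 0.60, min_probes = 50L) {
  cn <- total_cn[!is.na(total_cn)]
  n <- length(cn)
  if (n < min_probes) return(structure(NA, zero_fraction = NA_real_))
  frac <- mean(cn == 0)
  structure(frac > zero_fraction_threshold, zero_fraction = frac)
}

#' Call chromosome states for every line of a panel
#'
#' Applies [call_loh()] and [call_copy_number()] per chromosome and
#' [call_y_loss()] on the Y for each line's probe table.
#'
#' @param panel A `synthetic_panel`, or a named list of probe
#'   `data.frame`s (columns `chrom`, `genotype`, `total_cn`).
#' @param loh_threshold,cn_threshold,min_probes Passed to the per-chromosome
#'   callers.
#' @return A `data.frame` with one row per line and chromosome: `line`,
#'   `chrom`, `loh`, `copy_number`, `fraction_hom`, `modal_cn_fraction`,
#'   plus `y_lost` (non-`NA` on Y rows only).
#' @export
call_states <- function(panel, loh_threshold = 0.95, cn_threshold = 0.95,
                        min_probes = 50L) {
  probes <- if (inherits(panel, "synthetic_panel")) panel$probes else panel
  do.call(rbind, lapply(names(probes), function(l) {
    tab <- probes[[l]]
    do.call(rbind, lapply(unique(tab$chrom), function(ch) {
      sub <- tab[tab$chrom == ch, ]
      loh <- call_loh(sub$genotype, loh_threshold, min_probes)
      cn <- call_copy_number(sub$total_cn, cn_threshold, min_probes)
      y <- if (ch == "Y") call_y_loss(sub$total_cn, min_probes = min_probes) else NA
      data.frame(
        line = l, chrom = ch,
        loh = if (ch == "Y") NA else as.logical(loh),
        copy_number = as.integer(cn),
        fraction_hom = attr(loh, "fraction_hom") %||% NA_real_,
        modal_cn_fraction = attr(cn, "modal_cn_fraction") %||% NA_real_,
        y_lost = as.logical(y),
        stringsAsFactors = FALSE
      )
    }))
  }))
}

#' Panel-level LOH summary
#'
#' Computes per-chromosome LOH percentages separately for male- and
#' female-derived lines, the male/female Pearson correlation over the 22
#' autosomes, an ordinary least-squares regression of autosomal LOH
#' percentage (all lines) on chromosome size, and the LOH percentage the
#' autosomal regression predicts for a chromosome the size of the X. An
#' X (or Y) loss rate far above that prediction indicates preferential loss
#' of the sex chromosome rather than generic instability.
#'
#' @param states Output of [call_states()].
#' @param sex Named character vector (`"female"`/`"male"`) keyed by line id,
#'   or a `data.frame` with columns `line` and `sex`.
#' @param size_metric `"size"` (chromosome length in Mb, default) or
#'   `"rank"` (size rank) as the regression covariate.
#' @return A list of class `panel_loh_summary`: `by_chrom` (chrom, LOH%
#'   female, male, all, n assessable), `mf_correlation`, `regression`
#'   (slope, intercept, r, p, degenerate flag) and `x_predicted_loh_pct`.
#' @export
summarize_panel_loh <- function(states, sex, size_metric = c("size", "rank")) {
  size_metric <- match.arg(size_metric)
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$line)
  states$sex <- sex[states$line]
  if (any(is.na(states$sex))) stopf("summarize_panel_loh: lines with unknown sex")
  for (s in c("female", "male")) {
    if (sum(sex == s) < 2) stopf("summarize_panel_loh: need >= 2 %s lines", s)
  }
  chrom_tab <- chromosome_table()
  auto <- chrom_tab$chrom[chrom_tab$is_autosome]

  pct <- function(df) {
    ok <- !is.na(df$loh)
    if (!any(ok)) return(NA_real_)
    100 * mean(df$loh[ok])
  }
  by_chrom <- do.call(rbind, lapply(c(auto, "X"), function(ch) {
    sub <- states[states$chrom == ch, ]
    data.frame(
      chrom = ch,
      loh_pct_female = pct(sub[sub$sex == "female", ]),
      loh_pct_male = pct(sub[sub$sex == "male", ]),
      loh_pct_all = pct(sub),
      n_assessable = sum(!is.na(sub$loh)),
      stringsAsFactors = FALSE
    )
  }))
  dropped <- by_chrom$chrom[is.na(by_chrom$loh_pct_all)]
  if (length(dropped)) {
    warning("chromosomes with no assessable lines excluded: ",
            paste(dropped, collapse = ", "))
  }

  ba <- by_chrom[by_chrom$chrom %in% auto & !is.na(by_chrom$loh_pct_all), ]
  mf_r <- if (stats::sd(ba$loh_pct_female) == 0 || stats::sd(ba$loh_pct_male) == 0) {
    NA_real_
  } else {
    stats::cor(ba$loh_pct_female, ba$loh_pct_male)
  }

  covariate <- if (size_metric == "size") {
    stats::setNames(chrom_tab$length_mb, chrom_tab$chrom)
  } else {
    stats::setNames(chrom_tab$size_rank, chrom_tab$chrom)
  }
  x <- covariate[ba$chrom]
  y <- ba$loh_pct_all
  degenerate <- stats::sd(y) == 0 || nrow(ba) < 3
  if (degenerate) {
    reg <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, degenerate = TRUE)
    x_pred <- if (stats::sd(y) == 0) y[1] else NA_real_
  } else {
    fit <- stats::lm(y ~ x)
    ct <- summary(fit)$coefficients
    reg <- list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r = stats::cor(x, y),
      p = unname(ct[2L, 4L]),
      degenerate = FALSE
    )
    x_pred <- unname(reg$intercept + reg$slope * covariate[["X"]])
  }

  structure(
    list(by_chrom = by_chrom, mf_correlation = mf_r, regression = reg,
         x_predicted_loh_pct = x_pred, size_metric = size_metric),
    class = "panel_loh_summary"
  )
}

#' @export
print.panel_loh_summary <- function(x, ...) {
  cat(sprintf("<panel_loh_summary> M/F autosomal LOH correlation r = %.3f\n",
              x$mf_correlation))
  cat(sprintf("  size regression: slope %.4g, r %.3f, p %.3g%s\n",
              x$regression$slope, x$regression$r, x$regression$p,
              if (isTRUE(x$regression$degenerate)) " (degenerate)" else ""))
  cat(sprintf("  predicted LOH%% for an X-sized autosome: %.2f\n",
              x$x_predicted_loh_pct))
  invisible(x)
}
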