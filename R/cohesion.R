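#' Gain histogram and Poisson mean of one subline
#'
#' Gains are copy counts minus the diploid baseline of 2 over the 13
#' largest autosomes, binned as \{0, 1, >= 2\}. The maximum-likelihood
#' Poisson mean is the sample mean of the gains. Fractional copy estimates
#' (e.g. depth-based) are rounded to the nearest integer first.
#'
#' @param copies Numeric copy counts named by chromosome (`"1"`..`"22"` or
#'   `"chr1"`.. style); all 13 largest autosomes must be present with
#'   copies in 2--4.
#' @return List with `hist` (named integer vector over bins `"0"`, `"1"`,
#'   `">=2"`), `gains` (per-chromosome), `lambda_hat` and `delta` (13 x 13
#'   matrix of pairwise gain differences Delta_ij).
#' @export
#' @examples
#' g <- gain_histogram(setNames(c(rep(3, 10), rep(2, 3)), largest_autosomes()))
#' g$lambda_hat  # 10/13
gain_histogram <- function(copies) {
  if (is.null(names(copies))) stopf("gain_histogram: copies must be named by chromosome")
  names(copies) <- sub("^chr", "", names(copies))
  big <- largest_autosomes(13)
  missing <- setdiff(big, names(copies))
  if (length(missing)) {
    stopf("gain_histogram: missing copy calls for chromosome(s) %s",
          paste(missing, collapse = ", "))
  }
  cn <- round(as.numeric(copies[big]))
  if (any(is.na(cn))) stopf("gain_histogram: NA copy calls among the 13 largest autosomes")
  if (any(cn < 2 | cn > 4)) {
    stopf("gain_histogram: copies outside 2-4 (losses are not modelled): %s",
          paste(big[cn < 2 | cn > 4], collapse = ", "))
  }
  gains <- as.integer(cn - 2L)
  hist <- c("0" = sum(gains == 0L), "1" = sum(gains == 1L), ">=2" = sum(gains >= 2L))
  list(
    hist = hist,
    gains = stats::setNames(gains, big),
    lambda_hat = mean(gains),
    delta = abs(outer(gains, gains, `-`))
  )
}

# expected bin counts for 13 chromosomes under Poisson(lambda), >=2 merged
poisson_expected <- function(lambda, n_chrom = 13) {
  n_chrom * c("0" = stats::dpois(0, lambda),
              "1" = stats::dpois(1, lambda),
              ">=2" = stats::ppois(1, lambda, lower.tail = FALSE))
}

#' Chi-square test of independent (Poisson) autosome gains
#'
#' Under per-chromosome independence the number of autosomes gaining x
#' copies follows Poisson(lambda); cohesive gain (one chromosome at a time,
#' pairwise difference Delta_ij held below 2) concentrates mass on two
#' adjacent gain values, producing an excess at x = 1 when lambda < 1. The
#' test compares the observed \{0, 1, >= 2\} histogram with its Poisson
#' expectation, per subline or pooled. Pooled expectations are the sum of
#' per-subline Poisson expectations (a mixture, since each subline has its
#' own lambda-hat); pooling is restricted to sublines with lambda-hat below
#' `lambda_max`, where the two models differ most.
#'
#' @param profiles Subline profiles: the `data.frame` from
#'   [generate_sublines()] (or any with a `subline` column and per-chromosome
#'   copy columns), or a list of [gain_histogram()] results.
#' @param pooled Pool sublines into one composite histogram?
#' @param lambda_max Pooling keeps sublines with `lambda_hat < lambda_max`.
#' @return For `pooled = TRUE` a single `cohesion_result`; otherwise a list
#'   of them, one per subline. A `cohesion_result` carries `observed`,
#'   `expected`, `statistic`, `df`, `p_value`, `lambda_hat` (vector of the
#'   means used) and `verdict` (`"cohesive (non-Poisson)"`,
#'   `"consistent with independent gains"` or `"not applicable"` when all
#'   per-subline means are zero).
#' @export
poisson_chisq <- function(profiles, pooled = FALSE, lambda_max = 1.0) {
  gh <- as_gain_histograms(profiles)
  if (!length(gh)) stopf("poisson_chisq: no sublines supplied")
  if (!pooled) {
    out <- lapply(gh, function(g) cohesion_chisq_one(list(g)))
    names(out) <- names(gh)
    if (length(out) == 1L) out[[1L]] else out
  } else {
    keep <- vapply(gh, function(g) g$lambda_hat < lambda_max, TRUE)
    if (!any(keep)) {
      stopf("poisson_chisq: no sublines with lambda_hat < %g to pool", lambda_max)
    }
    cohesion_chisq_one(gh[keep])
  }
}

as_gain_histograms <- function(profiles) {
  if (is.data.frame(profiles)) {
    chrom_cols <- setdiff(names(profiles), "subline")
    ids <- profiles$subline %||% sprintf("S%02d", seq_len(nrow(profiles)))
    gh <- lapply(seq_len(nrow(profiles)), function(i) {
      gain_histogram(stats::setNames(as.numeric(profiles[i, chrom_cols]), chrom_cols))
    })
    stats::setNames(gh, ids)
  } else if (is.list(profiles) && !is.null(profiles$hist)) {
    list(profiles)
  } else {
    profiles
  }
}

cohesion_chisq_one <- function(gh_list) {
  lambdas <- vapply(gh_list, `[[`, numeric(1), "lambda_hat")
  observed <- Reduce(`+`, lapply(gh_list, `[[`, "hist"))
  expected <- Reduce(`+`, lapply(lambdas, poisson_expected))
  base <- list(observed = observed, expected = expected,
               lambda_hat = lambdas, n_sublines = length(gh_list))
  if (all(lambdas == 0)) {
    return(structure(c(base, list(statistic = NA_real_, df = NA_integer_,
                                  p_value = NA_real_, verdict = "not applicable")),
                     class = "cohesion_result"))
  }
  use <- expected > 0
  k <- sum(use)
  stat <- sum((observed[use] - expected[use])^2 / expected[use])
  m <- length(lambdas)  # one mean estimated per subline, from these same data
  df <- max(1L, k - 1L - min(m, k - 2L))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  verdict <- if (p < 0.05) "cohesive (non-Poisson)" else "consistent with independent gains"
  structure(c(base, list(statistic = stat, df = df, p_value = p, verdict = verdict)),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("<cohesion_result> %d subline(s), lambda_hat = %s\n",
              x$n_sublines, paste(sprintf("%.3f", x$lambda_hat), collapse = ", ")))
  cat("  observed:", paste(sprintf("%s=%g", names(x$observed), x$observed),
                           collapse = ", "), "\n")
  cat("  expected:", paste(sprintf("%s=%.2f", names(x$expected), x$expected),
                           collapse = ", "), "\n")
  if (identical(x$verdict, "not applicable")) {
    cat("  test not applicable (no gains observed)\n")
  } else {
    cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g -> %s\n",
                x$statistic, x$df, x$p_value, x$verdict))
  }
  invisible(x)
}
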