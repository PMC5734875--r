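#' Configuration for synthetic clonally-expanded sublines
#'
#' Emulates single-cell-derived sublines of a near-triploid line whose
#' chromosome copy numbers are estimated from sequencing depth. Gains are
#' counted relative to the diploid baseline over the 13 largest autosomes.
#'
#' Two modes:
#' \describe{
#'   \item{`independent`}{each of the 13 largest autosomes gains
#'     Poisson(`lambda`) extra copies independently, truncated at 2 extra
#'     (copies stay in 2--4) — the null model of per-chromosome
#'     independence.}
#'   \item{`cohesive`}{a total number of gains (Poisson(13*`lambda`), or
#'     `total_gains` if given) is distributed one chromosome at a time,
#'     always to a chromosome with the current minimum gain, so the pairwise
#'     gain difference Delta_ij never reaches 2 — one extra copy can be
#'     tolerated, two cannot. Gain counts therefore take at most two
#'     adjacent values.}
#' }
#'
#' @param n_sublines Number of sublines.
#' @param mode `"cohesive"` or `"independent"`.
#' @param lambda Expected gains per autosome (>= 0).
#' @param total_gains Optional fixed total number of gains per subline
#'   (cohesive mode only); overrides the Poisson draw.
#' @param seed Integer seed.
#' @return An object of class `subline_config`.
#' @export
subline_config <- function(n_sublines = 6L,
                           mode = c("cohesive", "independent"),
                           lambda = 10 / 13,
                           total_gains = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stopf("subline_config: lambda must be a single non-negative number")
  }
  if (!is_count(n_sublines)) stopf("subline_config: n_sublines must be a count")
  if (!is.null(total_gains)) {
    if (!is_count(total_gains)) stopf("subline_config: total_gains must be a count")
    if (mode != "cohesive") stopf("subline_config: total_gains applies to cohesive mode only")
  }
  structure(
    list(n_sublines = as.integer(n_sublines), mode = mode, lambda = lambda,
         total_gains = total_gains, seed = as.integer(seed)),
    class = "subline_config"
  )
}

#' Generate subline chromosome copy profiles
#'
#' @param cfg A [subline_config()].
#' @return A `data.frame` with one row per subline and one column per
#'   chromosome (`chr1`..`chr22`, `chrX`) holding integer copy counts, plus
#'   a `subline` id column. Copies are 2 + gains on the 13 largest
#'   autosomes; the remaining chromosomes and the X stay at their baseline
#'   (2) — smaller autosomes are not modelled because the cohesion
#'   constraint is loosened for them.
#' @seealso [gain_histogram()], [poisson_chisq()]
#' @export
#' @examples
#' generate_sublines(subline_config(n_sublines = 2, mode = "cohesive",
#'                                  total_gains = 10, seed = 3))
generate_sublines <- function(cfg) {
  if (!inherits(cfg, "subline_config")) cfg <- do.call(subline_config, cfg)
  set.seed(cfg$seed)
  big <- largest_autosomes(13)
  all_chrom <- chromosome_table()$chrom
  all_chrom <- all_chrom[all_chrom != "Y"]
  out <- lapply(seq_len(cfg$n_sublines), function(i) {
    gains <- stats::setNames(rep(0L, 13L), big)
    if (cfg$mode == "independent") {
      gains[] <- pmin(stats::rpois(13L, cfg$lambda), 2L)
    } else {
      total <- cfg$total_gains %||% stats::rpois(1L, 13 * cfg$lambda)
      total <- min(total, 26L)  # copies capped at 4 per chromosome
      for (g in seq_len(total)) {
        cand <- which(gains == min(gains))
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        gains[pick] <- gains[pick] + 1L
      }
    }
    copies <- stats::setNames(rep(2L, length(all_chrom)), all_chrom)
    copies[big] <- 2L + gains
    copies
  })
  prof <- as.data.frame(do.call(rbind, out))
  names(prof) <- paste0("chr", all_chrom)
  cbind(data.frame(subline = sprintf("S%02d", seq_len(cfg$n_sublines)),
                   stringsAsFactors = FALSE), prof)
}
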